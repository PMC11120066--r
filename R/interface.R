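#' @title Pipeline interface: configuration, file formats, CLI
#' @description Ties the modules into the pipeline
#'   simulate -> fit -> predict -> assess -> validate.  File conventions:
#'   comma-separated UTF-8 CSV with a mandatory header row, '.' decimal,
#'   ISO-8601 dates, units embedded in column names; every writer prefixes
#'   a `#`-comment header recording package version, seed and a config
#'   hash, so outputs are byte-identical across reruns of the same
#'   config + seed.
#' @name interface
NULL

# ---- config ----------------------------------------------------------------

#' Parse a plain-text key-value run configuration
#'
#' One `key: value` (or `key = value`) pair per line; `#` comments and
#' blank lines ignored; comma-separated values become numeric vectors when
#' parseable.
#'
#' @param path config file.
#' @return a named list of class `run_config` with a `config_hash`
#'   attribute.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*[:=]\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L)
      .bs_stop(sprintf("read_run_config: malformed line '%s'", ln))
    val <- trimws(strsplit(m[3L], ",")[[1]])
    num <- suppressWarnings(as.numeric(val))
    out[[m[2L]]] <- if (!anyNA(num)) num else val
  }
  attr(out, "config_hash") <- .config_hash(out)
  class(out) <- "run_config"
  out
}

# order-independent cheap content hash (no external digest dependency)
.config_hash <- function(x) {
  if (length(x) == 0L) return("00000000")
  s <- paste(names(x)[order(names(x))],
             vapply(x[order(names(x))], paste, "", collapse = ","),
             sep = "=", collapse = ";")
  raw <- utf8ToInt(s)
  h <- 5381
  for (ch in raw) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}

.bs_header <- function(seed = NA, config_hash = "none") {
  sprintf("# brachysafe %s seed=%s config=%s",
          as.character(utils::packageVersion("brachysafe")),
          as.character(seed), config_hash)
}

.write_csv_with_header <- function(df, path, seed = NA, config_hash = "none") {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.bs_header(seed, config_hash), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.read_csv_skip_header <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

# ---- file schemas ----------------------------------------------------------

#' Write / read a depth-dose series CSV
#'
#' Columns: `distance_cm`, `depth_cm`, `h10_per_decay_pSv`, `rel_se`,
#' `n_histories`, `seed`.
#'
#' @param series a `depth_dose_series` (or list of them).
#' @param path output file.
#' @param seed,config_hash recorded in the comment header.
#' @return `path` (writer) / a data.frame with `distance_cm` column
#'   (reader).
#' @export
write_depth_series_csv <- function(series, path, seed = NA,
                                   config_hash = "none") {
  if (inherits(series, "depth_dose_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, function(s)
    data.frame(distance_cm = attr(s, "distance_cm"),
               depth_cm = s$depth_cm,
               h10_per_decay_pSv = s$h10_pSv_per_decay,
               rel_se = s$rel_se, n_histories = s$n_histories,
               seed = s$seed)))
  .write_csv_with_header(df, path, seed, config_hash)
}

#' @rdname write_depth_series_csv
#' @export
read_depth_series_csv <- function(path) {
  d <- .read_csv_skip_header(path)
  need <- c("distance_cm", "depth_cm", "h10_per_decay_pSv")
  miss <- setdiff(need, names(d))
  if (length(miss))
    .bs_stop("read_depth_series_csv: missing column(s) ",
             paste(miss, collapse = ", "))
  d
}

#' Read a patient/implant cohort CSV
#'
#' Required columns: `patient_id`, `sk_U`, `lambda_cGy_h_U`, `cf`,
#' `implant_date`, `wet_ant_cm`, `wet_post_cm`, `wet_left_cm`,
#' `wet_right_cm` (the schema [generate_cohort()] writes).
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_cohort_csv <- function(path) {
  d <- .read_csv_skip_header(path)
  need <- c("patient_id", "sk_U", "lambda_cGy_h_U", "cf", "implant_date",
            "wet_ant_cm", "wet_post_cm", "wet_left_cm", "wet_right_cm")
  miss <- setdiff(need, names(d))
  if (length(miss))
    .bs_stop("read_cohort_csv: missing column(s) ",
             paste(miss, collapse = ", "))
  bad <- which(!is.finite(d$sk_U) | d$sk_U < 0)
  if (length(bad))
    .bs_stop("read_cohort_csv: invalid sk_U at row(s) ",
             paste(bad, collapse = ", "))
  d$implant_date <- as.Date(d$implant_date)
  d
}

#' Write a cohort CSV
#'
#' @param cohort data.frame from [generate_cohort()].
#' @param path output file.
#' @param seed,config_hash recorded in the comment header.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path, seed = NA, config_hash = "none") {
  .write_csv_with_header(cohort, path, seed, config_hash)
}

#' Predict dose rates for every patient in a cohort
#'
#' @param cohort data.frame in the cohort CSV schema.
#' @param eval_date evaluation date (default: each implant date, day 0).
#' @param models model set keyed by distance class.
#' @param decay a [decay_data()].
#' @return data.frame `patient_id`, `direction`, `distance_cm`, `wet_cm`,
#'   `h10_uSv_h`, `eval_date`.
#' @export
predict_cohort <- function(cohort, eval_date = NULL,
                           models = paper_model_registry(),
                           decay = decay_data()) {
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    p <- cohort[i, ]
    implant <- source_implant(p$sk_U, p$lambda_cGy_h_U, p$cf, p$implant_date)
    geom <- patient_geometry(p$wet_ant_cm, p$wet_post_cm,
                             p$wet_left_cm, p$wet_right_cm)
    pr <- predict_patient(implant, geom, eval_date = eval_date,
                          decay = decay, models = models)
    cbind(patient_id = p$patient_id, pr)
  })
  do.call(rbind, rows)
}

# ---- pipeline --------------------------------------------------------------

.cfg_get <- function(config, key, default) {
  if (!is.null(config[[key]])) config[[key]] else default
}

#' Run one pipeline stage
#'
#' Subcommands:
#' * `simulate`: Monte Carlo depth series at each detector distance ->
#'   depth-series CSV.
#' * `fit`: normalize a simulate output and fit exponential models ->
#'   fit JSON (requires >= 3 depths per distance).
#' * `synth`: generate a synthetic cohort -> cohort CSV.
#' * `predict`: cohort CSV -> per-patient dose-rate CSV.
#' * `assess`: cumulative doses for caregiver/public scenarios against
#'   release limits -> JSON report.
#' * `validate`: emulated measured-vs-predicted comparison with
#'   Mann-Whitney tests -> JSON report.
#'
#' @param subcommand one of the above.
#' @param config a [read_run_config()] result or named list.
#' @param out output file path.
#' @param seed overrides `config$seed`.
#' @return path of the artifact written, invisibly.
#' @export
run_pipeline <- function(subcommand = c("simulate", "fit", "synth",
                                        "predict", "assess", "validate"),
                         config = list(), out, seed = NULL) {
  subcommand <- match.arg(subcommand)
  hash <- attr(config, "config_hash")
  if (is.null(hash)) hash <- .config_hash(config)
  seed <- as.integer(if (!is.null(seed)) seed else .cfg_get(config, "seed", 1))
  models <- .models_from_config(config)

  switch(subcommand,
    simulate = {
      depths <- .cfg_get(config, "depths", 1:20)
      dists <- .cfg_get(config, "distances", c(0, 30, 100))
      nh <- .cfg_get(config, "n_histories", 20000)
      series <- lapply(seq_along(dists), function(i)
        simulate_depth_series(depths, dists[i], nh,
                              seed = seed + 1000L * i))
      message(sprintf("[simulate] seed=%d histories=%d depths=%d distances=%s",
                      seed, nh, length(depths),
                      paste(dists, collapse = "/")))
      write_depth_series_csv(series, out, seed, hash)
    },
    fit = {
      d <- read_depth_series_csv(.cfg_required(config, "input"))
      fits <- lapply(split(d, d$distance_cm), function(g) {
        if (nrow(g) < 3L)
          .bs_stop("fit: need >= 3 depths per distance (schema error in ",
                   "column depth_cm, distance ", g$distance_cm[1L], ")")
        s <- data.frame(depth_cm = g$depth_cm, value = g$h10_per_decay_pSv)
        ns <- normalize_series(s,
                               .cfg_get(config, "reference_depth_cm", 1))
        attr(ns, "distance_cm") <- g$distance_cm[1L]
        fit_exponential(ns)
      })
      write_fit_json(fits, out,
                     reference_depth_cm = .cfg_get(config,
                                                   "reference_depth_cm", 1))
    },
    synth = {
      spec <- cohort_spec(n_patients = .cfg_get(config, "n_patients", 21),
                          seed = seed)
      message(sprintf("[synth] seed=%d n=%d", seed, spec$n_patients))
      write_cohort_csv(generate_cohort(spec), out, seed, hash)
    },
    predict = {
      cohort <- read_cohort_csv(.cfg_required(config, "input"))
      pred <- predict_cohort(cohort, models = models)
      .write_csv_with_header(pred, out, seed, hash)
    },
    assess = {
      pred <- .read_csv_skip_header(.cfg_required(config, "input"))
      rate100 <- pred[pred$distance_cm == 100, ]
      mean_rate <- mean(rate100$h10_uSv_h)
      scen_care <- exposure_scenario("caregiver",
        daily_hours = .cfg_get(config, "caregiver_hours", 6),
        occupancy = .cfg_get(config, "caregiver_occupancy", 1))
      scen_pub <- exposure_scenario("public",
        daily_hours = .cfg_get(config, "public_hours", 2),
        occupancy = .cfg_get(config, "public_occupancy", 0.25))
      dc <- cumulative_dose(mean_rate, scen_care)
      dp <- cumulative_dose(mean_rate, scen_pub)
      rep <- list(
        seed = seed, config = hash,
        mean_rate_100cm_uSv_h = mean_rate,
        caregiver = c(list(dose_mSv = dc), check_release(dc, "caregiver")),
        public = c(list(dose_mSv = dp), check_release(dp, "public")),
        limits_mSv = as.list(regulatory_limits()),
        boundary = "inclusive (dose equal to the limit is compliant)")
      jsonlite::write_json(rep, out, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      invisible(out)
    },
    validate = {
      cohort <- read_cohort_csv(.cfg_required(config, "input"))
      meas <- simulate_patient_measurements(cohort, seed = seed,
                                            models = models)
      summ <- summarize_differences(meas$measured_uSv_h,
                                    meas$predicted_uSv_h,
                                    meas$distance_cm)
      tests <- lapply(split(meas, meas$distance_cm), function(g)
        mann_whitney_u(g$measured_uSv_h, g$predicted_uSv_h)[
          c("U", "n1", "n2", "p_value", "method")])
      rep <- list(seed = seed, config = hash,
                  by_distance = summ$by_group,
                  max_abs_pct = summ$max_abs_pct,
                  mann_whitney = tests)
      jsonlite::write_json(rep, out, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, dataframe = "rows")
      invisible(out)
    })
}

.cfg_required <- function(config, key) {
  v <- config[[key]]
  if (is.null(v)) .bs_stop(sprintf("config: required key '%s' missing", key))
  v
}

.models_from_config <- function(config) {
  src <- .cfg_get(config, "model", "paper")
  if (identical(src, "paper")) return(paper_model_registry())
  if (startsWith(src, "fitted:")) return(read_fit_json(sub("^fitted:", "", src)))
  .bs_stop("config: model must be 'paper' or 'fitted:<path>'")
}

#' Command-line entry point
#'
#' `brachysafe_cli(c("simulate", "--out", "series.csv", "--seed", "7"))`;
#' flags: `--config <file>`, `--seed <int>`, `--out <path>`,
#' `--model paper|fitted:<path>`, `--input <path>`, `--n-histories <int>`,
#' `--distances a,b,c`, `--depths a,b,...`.  Returns (and, when run via
#' `Rscript`, exits with) 0 on success, 1 on error.
#'
#' @param args character vector of CLI arguments.
#' @return integer exit status, invisibly.
#' @export
brachysafe_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: brachysafe <simulate|fit|synth|predict|assess|validate>",
                 "[--config f] [--seed n] [--out f] [--input f]",
                 "[--model paper|fitted:<path>] [--n-histories n]",
                 "[--distances a,b,c] [--depths a,b,...]")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1L]
  if (!cmd %in% c("simulate", "fit", "synth", "predict", "assess",
                  "validate")) {
    message("unknown subcommand '", cmd, "'\n", usage)
    return(invisible(1L))
  }
  opt <- list(); i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (i + 1L > length(args)) { message(usage); return(invisible(1L)) }
    opt[[key]] <- args[i + 1L]; i <- i + 2L
  }
  status <- tryCatch({
    config <- if (!is.null(opt$config)) read_run_config(opt$config)
              else structure(list(), class = "run_config")
    for (k in c("model", "input")) if (!is.null(opt[[k]])) config[[k]] <- opt[[k]]
    if (!is.null(opt[["n-histories"]]))
      config$n_histories <- as.numeric(opt[["n-histories"]])
    for (k in c("distances", "depths")) if (!is.null(opt[[k]]))
      config[[k]] <- as.numeric(strsplit(opt[[k]], ",")[[1]])
    out <- if (!is.null(opt$out)) opt$out else .bs_stop("--out is required")
    run_pipeline(cmd, config, out,
                 seed = if (!is.null(opt$seed)) as.integer(opt$seed))
    0L
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}
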