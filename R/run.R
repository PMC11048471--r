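#' Experiment configuration
#'
#' @param sim An [sim_config()].
#' @param thresholds Optional fixed `fr_policy` (e.g.
#'   [reference_thresholds()]); if `NULL`, thresholds are calibrated
#'   from the simulated impostor scores.
#' @param calibration `"subset"` or `"pooled"` (used when `thresholds`
#'   is `NULL`; the calibrated policy is reported alongside a fixed one
#'   either way).
#' @param output_dir Directory for artifacts.
#' @param log_level `"quiet"` or `"info"` (messages to stderr).
#' @return A list of class `fr_run_config`.
#' @export
run_config <- function(sim = sim_config(), thresholds = NULL,
                       calibration = c("subset", "pooled"),
                       output_dir = "faceverify-run",
                       log_level = c("info", "quiet")) {
  calibration <- match.arg(calibration)
  log_level <- match.arg(log_level)
  if (!is.null(thresholds) && !inherits(thresholds, "fr_policy"))
    stop("thresholds must be an fr_policy or NULL", call. = FALSE)
  structure(list(sim = sim, thresholds = thresholds,
                 calibration = calibration, output_dir = output_dir,
                 log_level = log_level),
            class = "fr_run_config")
}

#' Read an experiment configuration from YAML or JSON
#'
#' The format is auto-detected from the file extension (`.yaml`/`.yml`
#' vs `.json`).  Recognized keys: `n_patients`, `dim`, `rho`, `seed`,
#' `profile` (list of entries `{mask, eyes, position, illumination,
#' mean, sd}`, or absent for the default profile), `thresholds`
#' (`{unmasked, masked}` or absent), `calibration`, `output_dir`,
#' `log_level`.
#'
#' @param path Config file path.
#' @return An `fr_run_config`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("config must be .yaml, .yml or .json", call. = FALSE)
  profile <- if (is.null(raw$profile)) default_profile() else {
    pr <- as.data.frame(raw$profile, stringsAsFactors = FALSE)
    pr$condition <- ifelse(
      !is.null(pr$role) & pr$role %in% "control", "control",
      condition_key(pr))
    if (!is.null(pr$role) && any(pr$role %in% "control"))
      pr$condition[pr$role == "control"] <- "control"
    condition_profile(pr[, c("mask", "eyes", "position", "illumination",
                             "condition")], pr$mean, pr$sd)
  }
  sim <- sim_config(
    n_patients = raw$n_patients %||% 100,
    dim = raw$dim %||% 512,
    rho = raw$rho %||% 0.01,
    seed = raw$seed %||% 1,
    profile = profile
  )
  thresholds <- if (!is.null(raw$thresholds))
    threshold_policy(raw$thresholds$unmasked, raw$thresholds$masked, "fixed")
  run_config(sim = sim, thresholds = thresholds,
             calibration = raw$calibration %||% "subset",
             output_dir = raw$output_dir %||% "faceverify-run",
             log_level = raw$log_level %||% "info")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full verification experiment
#'
#' Pipeline: build the synthetic gallery, score all genuine/impostor
#' pairs over the 18-condition design, calibrate (or apply fixed)
#' thresholds, compute FAR/FRR curves per mask status, and assemble the
#' certification-rate report.  All artifacts are written under
#' `config$output_dir`: `gallery.csv`, `scores.csv`, `curve_unmasked.csv`,
#' `curve_masked.csv`, `thresholds.json` (the policy actually applied),
#' `thresholds_calibrated.json` (always reported, never silently
#' substituted for a fixed policy), `report.json`, `report.csv`, and
#' `manifest.json` (seed, config hash, package and R versions).  The
#' same config and seed reproduce every artifact byte for byte.
#'
#' @param config An [run_config()].
#' @return The `fr_report`, invisibly, with the gallery and scores
#'   attached as attributes `gallery` and `scores`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "fr_run_config"))
  log_info <- function(...) {
    if (config$log_level == "info") message("[faceverify] ", ...)
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(config$output_dir))
    stop("cannot create output directory ", config$output_dir, call. = FALSE)

  log_info("building gallery (", config$sim$n_patients, " patients, dim ",
           config$sim$dim, ", seed ", config$sim$seed, ")")
  gallery <- build_gallery(config$sim)
  scores <- score_all_pairs(gallery)

  calibrated <- calibrate_thresholds(scores, config$calibration)
  policy <- config$thresholds %||% calibrated
  log_info(sprintf("thresholds: unmasked %.4f, masked %.4f (%s)",
                   policy$threshold_unmasked, policy$threshold_masked,
                   policy$calibration))

  factorial <- fr_design()
  factorial <- factorial$condition[
    factorial$position %in% c("sitting", "supine")]
  sc_fact <- scores[scores$condition %in% factorial, , drop = FALSE]
  curve_un <- far_frr_curve(sc_fact[sc_fact$mask == "no", , drop = FALSE])
  curve_ma <- far_frr_curve(sc_fact[sc_fact$mask == "yes", , drop = FALSE])

  report <- build_report(scores, policy)

  out <- config$output_dir
  write_gallery(gallery, file.path(out, "gallery.csv"))
  write_scores(scores, file.path(out, "scores.csv"))
  write_curve(curve_un, file.path(out, "curve_unmasked.csv"))
  write_curve(curve_ma, file.path(out, "curve_masked.csv"))
  write_policy(policy, file.path(out, "thresholds.json"))
  write_policy(calibrated, file.path(out, "thresholds_calibrated.json"))
  write_report(report, out)
  write_manifest(config, file.path(out, "manifest.json"))
  log_info("artifacts written to ", out)

  attr(report, "gallery") <- gallery
  attr(report, "scores") <- scores
  invisible(report)
}

write_manifest <- function(config, path) {
  cfg <- list(
    n_patients = config$sim$n_patients, dim = config$sim$dim,
    rho = config$sim$rho, seed = config$sim$seed,
    profile = as.data.frame(config$sim$profile),
    thresholds = if (!is.null(config$thresholds))
      unclass(config$thresholds),
    calibration = config$calibration
  )
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    seed = config$sim$seed,
    config = cfg,
    config_md5 = unname(tools::md5sum(tmp)),
    package_version = as.character(utils::packageVersion("faceverify")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Ingest an external score table
#'
#' Reads a score CSV in the [write_scores()] schema (columns
#' `ref_patient`, `probe_patient`, `mask`, `eyes`, `position`,
#' `illumination`, `cs`, `as`, `genuine`) and validates it: `cs` in
#' `[-1, 1]`, `as` in `[0, 1]`, `as = 0.5*cs + 0.5` within 1e-9, and
#' `genuine` exactly when `ref_patient == probe_patient`.  Lets score
#' tables exported from real verification systems flow into the same
#' threshold and rate analysis as simulated ones.
#'
#' @param path CSV path.
#' @return An `fr_scores` data frame.
#' @export
ingest_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("ref_patient", "probe_patient", "mask", "eyes", "position",
            "illumination", "cs", "as", "genuine")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("score CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(df) > 0) {
    # data line numbers are offset by the header
    line <- function(i) i + 1L
    if (!is.numeric(df$cs) || !is.numeric(df$as)) {
      bad <- which(is.na(suppressWarnings(as.numeric(df$cs))) |
                     is.na(suppressWarnings(as.numeric(df$as))))
      stop("malformed numeric field at line ", line(bad[1]), call. = FALSE)
    }
    df$genuine <- as.logical(df$genuine)
    if (anyNA(df$genuine))
      stop("malformed genuine flag at line ",
           line(which(is.na(df$genuine))[1]), call. = FALSE)
    bad <- which(df$as < 0 | df$as > 1 | df$cs < -1 | df$cs > 1)
    if (length(bad) > 0)
      stop("score out of bounds at line ", line(bad[1]), call. = FALSE)
    bad <- which(abs(df$as - (0.5 * df$cs + 0.5)) > 1e-9)
    if (length(bad) > 0)
      stop("as != 0.5*cs + 0.5 at line ", line(bad[1]), call. = FALSE)
    bad <- which(df$genuine != (df$ref_patient == df$probe_patient))
    if (length(bad) > 0)
      stop("genuine flag inconsistent with patient ids at line ",
           line(bad[1]), call. = FALSE)
    check_condition_levels(df)
    df$condition <- condition_key(df)
  } else {
    df$condition <- character(0)
  }
  df <- df[, c("ref_patient", "probe_patient", "mask", "eyes", "position",
               "illumination", "condition", "cs", "as", "genuine")]
  new_scores(df,
             n_patients = length(unique(df$ref_patient)),
             conditions = unique(df$condition),
             seed = NA_integer_)
}
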