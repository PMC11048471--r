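#' False acceptance and false rejection rates at a threshold
#'
#' Acceptance is strictly greater-than: a comparison is accepted when
#' `AS > t`.  `far()` is the fraction of impostor records accepted;
#' `frr()` is the fraction of genuine records rejected (`AS <= t`).  The
#' certification (success) rate reported elsewhere is `(1 - FRR) * 100`.
#'
#' @param scores An `fr_scores` data frame.
#' @param t Decision threshold in `[0, 1]`.
#' @return A rate in `[0, 1]`.
#' @export
far <- function(scores, t) {
  imp <- scores$as[!scores$genuine]
  if (length(imp) == 0)
    stop("no impostor records in score set", call. = FALSE)
  mean(imp > t)
}

#' @rdname far
#' @export
frr <- function(scores, t) {
  gen <- scores$as[scores$genuine]
  if (length(gen) == 0)
    stop("no genuine records in score set", call. = FALSE)
  mean(gen <= t)
}

#' FAR/FRR trade-off curve
#'
#' Evaluates [far()] and [frr()] on a threshold grid.  The default grid
#' is the sorted unique observed scores plus the endpoints 0 and 1, which
#' captures every step of both empirical curves.  Along the grid FAR is
#' non-increasing and FRR is non-decreasing; at or above the maximum
#' observed score FAR is exactly 0.
#'
#' @param scores An `fr_scores` data frame with at least one genuine and
#'   one impostor record.
#' @param grid Optional ascending numeric vector of thresholds.
#' @return A data frame of class `fr_curve` with columns `threshold`,
#'   `far`, `frr`.
#' @export
far_frr_curve <- function(scores, grid = NULL) {
  if (nrow(scores) == 0) stop("empty score set", call. = FALSE)
  if (is.null(grid)) {
    grid <- sort(unique(c(0, 1, scores$as)))
  } else {
    if (is.unsorted(grid, strictly = TRUE))
      stop("user-supplied grid must be strictly ascending", call. = FALSE)
  }
  imp <- scores$as[!scores$genuine]
  gen <- scores$as[scores$genuine]
  curve <- data.frame(
    threshold = grid,
    far = vapply(grid, function(t) mean(imp > t), numeric(1)),
    frr = vapply(grid, function(t) mean(gen <= t), numeric(1))
  )
  class(curve) <- c("fr_curve", "data.frame")
  curve
}

#' Zero-FAR decision threshold
#'
#' The smallest threshold at which no impostor comparison is accepted.
#' Under the strict greater-than acceptance rule this is exactly the
#' maximum impostor authentication score of the calibration subset:
#' `far()` at the returned value is 0 on that subset, and positive at
#' any strictly smaller threshold.  In patient identification zero
#' wrong-patient acceptance is the binding requirement, so thresholds
#' are set here rather than at an equal-error point.
#'
#' @param scores An `fr_scores` data frame.
#' @param mask_status `"no"`, `"yes"`, or `NULL` to pool all impostor
#'   records regardless of mask status.
#' @return The threshold (a score in `[0, 1]`).
#' @export
zero_far_threshold <- function(scores, mask_status = NULL) {
  keep <- !scores$genuine
  if (!is.null(mask_status)) {
    if (!mask_status %in% c("no", "yes"))
      stop("mask_status must be \"no\", \"yes\" or NULL", call. = FALSE)
    keep <- keep & scores$mask == mask_status
  }
  if (!any(keep))
    stop("no impostor records for the requested calibration subset",
         call. = FALSE)
  max(scores$as[keep])
}

#' Accept/reject decision
#'
#' @param as_score Authentication score(s) in `[0, 1]`.
#' @param t Threshold in `[0, 1]`.
#' @return Logical: `TRUE` (accept) iff `as_score > t`; a tie rejects.
#' @export
decide <- function(as_score, t) {
  stopifnot(all(as_score >= 0 & as_score <= 1), t >= 0, t <= 1)
  as_score > t
}

#' Per-mask-status threshold policy
#'
#' Masked and unmasked comparisons get separate thresholds because the
#' zero-FAR score differs between them (the verification engine detects
#' mask wearing and the score distributions shift).  All mask-free
#' conditions -- including the nighttime lateral postures -- use the
#' unmasked threshold.
#'
#' @param unmasked,masked Thresholds in `[0, 1]`.
#' @param calibration Label recording how the thresholds were obtained
#'   (`"subset"`, `"pooled"`, `"fixed"`, ...).
#' @return A list of class `fr_policy`.
#' @export
threshold_policy <- function(unmasked, masked, calibration = "fixed") {
  stopifnot(unmasked >= 0, unmasked <= 1, masked >= 0, masked <= 1)
  structure(list(threshold_unmasked = as.numeric(unmasked),
                 threshold_masked = as.numeric(masked),
                 calibration = calibration),
            class = "fr_policy")
}

#' Calibrate a zero-FAR threshold policy from scores
#'
#' With `calibration = "subset"` (default) each threshold is the maximum
#' impostor AS over its own mask status' conditions; `"pooled"` uses the
#' maximum over all impostor records for both, a sensitivity-analysis
#' switch (a pooled maximum cannot produce two distinct thresholds).
#'
#' @param scores An `fr_scores` data frame containing impostor records
#'   for both mask statuses.
#' @param calibration `"subset"` or `"pooled"`.
#' @return An `fr_policy`.
#' @export
calibrate_thresholds <- function(scores, calibration = c("subset", "pooled")) {
  calibration <- match.arg(calibration)
  if (calibration == "pooled") {
    t <- zero_far_threshold(scores, NULL)
    threshold_policy(t, t, "pooled")
  } else {
    threshold_policy(zero_far_threshold(scores, "no"),
                     zero_far_threshold(scores, "yes"),
                     "subset")
  }
}

#' Reference threshold policy from the clinical evaluation
#'
#' The zero-FAR thresholds measured in the hospital study this package
#' emulates: 0.642 without a mask and 0.620 with a mask.  These are
#' extreme values of the real engine's impostor-score tail; they are
#' shipped as fixed constants for reproducing the published
#' certification rates and are never silently substituted for
#' simulation-derived thresholds (which [calibrate_thresholds()] reports
#' separately).
#'
#' @return An `fr_policy` with `calibration = "reference"`.
#' @export
reference_thresholds <- function() {
  threshold_policy(0.642, 0.620, "reference")
}

#' @export
print.fr_policy <- function(x, ...) {
  cat("Threshold policy (", x$calibration, " calibration)\n", sep = "")
  cat(sprintf("  unmasked: %.6g\n  masked:   %.6g\n",
              x$threshold_unmasked, x$threshold_masked))
  invisible(x)
}

#' Write a FAR/FRR curve or threshold policy to disk
#'
#' @param curve An `fr_curve`.
#' @param policy An `fr_policy`.
#' @param path Output path (CSV for curves, JSON for policies).
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "fr_curve"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_curve
#' @export
write_policy <- function(policy, path) {
  stopifnot(inherits(policy, "fr_policy"))
  jsonlite::write_json(unclass(policy), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
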