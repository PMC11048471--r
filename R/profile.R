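#' Per-condition genuine-score distribution profile
#'
#' A condition profile attaches to every probe condition (plus the
#' enrolment control) the mean and standard deviation of the genuine
#' authentication score (AS) observed for that condition.  The simulator
#' draws genuine scores from these distributions, so a profile fully
#' determines the genuine-score behaviour of a synthetic cohort.
#'
#' @param conditions Data frame of conditions as returned by
#'   [fr_design()] (optionally plus [fr_control()]).
#' @param mean Numeric vector of mean AS per condition, each in (0, 1).
#' @param sd Numeric vector of AS standard deviations, each >= 0.
#' @return A data frame of class `fr_profile` with the condition columns
#'   plus `mean` and `sd`.
#' @seealso [default_profile()]
#' @export
condition_profile <- function(conditions, mean, sd) {
  stopifnot(nrow(conditions) == length(mean), length(mean) == length(sd))
  check_condition_levels(conditions)
  if (any(sd < 0)) stop("sd must be >= 0", call. = FALSE)
  if (any(mean <= 0 | mean >= 1) && !all(mean > 0 & mean < 1)) {
    # mean AS of 0 or 1 maps to cosine -1/+1, outside the open interval
    bad <- which(mean <= 0 | mean >= 1)
    stop("mean AS must lie in (0, 1); offending entries: ",
         paste(conditions$condition[bad], collapse = ", "), call. = FALSE)
  }
  p <- conditions
  p$mean <- as.numeric(mean)
  p$sd <- as.numeric(sd)
  if (anyDuplicated(p$condition))
    stop("duplicate condition entries in profile", call. = FALSE)
  class(p) <- c("fr_profile", "data.frame")
  p
}

#' Default condition profile: the published clinical score summaries
#'
#' Ships the per-condition genuine authentication-score means and SDs
#' measured on a 100-patient hospital cohort with a deep-learning face
#' engine (correct-matching column of the study's score table), one row
#' per probe condition in canonical design order.  The `control` entry
#' describes the enrolment reference image: it is drawn at a fixed cosine
#' of 0.95 to the patient's latent identity (AS 0.975, sd 0), a
#' documented modelling choice -- genuine scores are defined against the
#' reference, so this value only influences impostor geometry, and only
#' marginally.
#'
#' @return An `fr_profile` with 19 rows (18 probe conditions + control).
#' @export
#' @examples
#' p <- default_profile()
#' subset(p, condition == "no.open.sitting.sufficient")  # 0.785 +/- 0.004
default_profile <- function() {
  d <- rbind(fr_design(), fr_control())
  mean <- c(
    # unmasked: sitting/sufficient, supine/sufficient, sitting/low, supine/low
    0.785, 0.767, 0.710, 0.699, 0.741, 0.731, 0.703, 0.691,
    # masked, same order
    0.714, 0.688, 0.659, 0.638, 0.681, 0.664, 0.656, 0.636,
    # nighttime lateral (right, left)
    0.701, 0.702,
    # control / reference perturbation
    0.975
  )
  sd <- c(
    0.004, 0.012, 0.020, 0.021, 0.012, 0.013, 0.018, 0.019,
    0.015, 0.021, 0.023, 0.027, 0.020, 0.026, 0.022, 0.027,
    0.019, 0.019,
    0
  )
  condition_profile(d, mean, sd)
}

# Look up profile row for a condition key; error names the condition.
profile_entry <- function(profile, key) {
  i <- match(key, profile$condition)
  if (anyNA(i))
    stop("profile is missing entries for condition(s): ",
         paste(key[is.na(i)], collapse = ", "), call. = FALSE)
  profile[i, , drop = FALSE]
}
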