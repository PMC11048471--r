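#' The 18-condition probe design
#'
#' Enumerates the photographic conditions under which every patient in the
#' cohort is probed: the 16 factorial combinations of mask wearing
#' (no/yes), eye state (open/closed), posture (sitting/supine) and
#' illumination (sufficient / low, i.e. 3--4 lux), followed by the two
#' extra nighttime patterns (right and left lateral posture, which occur
#' only without a mask, with eyes closed, under low illumination).
#'
#' The order is canonical and fixed: mask-major, then illumination, then
#' posture, with eye state varying fastest, ending with the two lateral
#' conditions.  The first condition is the standard one (no mask, open
#' eyes, sitting, sufficient illumination).
#'
#' @return A data frame with 18 rows and columns `mask` (`"no"`/`"yes"`),
#'   `eyes` (`"open"`/`"closed"`), `position` (`"sitting"`, `"supine"`,
#'   `"supine_right_lateral"`, `"supine_left_lateral"`), `illumination`
#'   (`"sufficient"`/`"low"`) and `condition`, a unique key string.
#' @seealso [fr_control()] for the enrolment reference condition,
#'   [default_profile()] for the genuine-score distribution attached to
#'   each condition.
#' @export
#' @examples
#' d <- fr_design()
#' nrow(d)        # 18
#' d[1, ]         # the standard condition
fr_design <- function() {
  grid <- expand.grid(
    eyes = c("open", "closed"),
    position = c("sitting", "supine"),
    illumination = c("sufficient", "low"),
    mask = c("no", "yes"),
    stringsAsFactors = FALSE
  )
  grid <- grid[, c("mask", "eyes", "position", "illumination")]
  lateral <- data.frame(
    mask = "no", eyes = "closed",
    position = c("supine_right_lateral", "supine_left_lateral"),
    illumination = "low",
    stringsAsFactors = FALSE
  )
  d <- rbind(grid, lateral)
  rownames(d) <- NULL
  d$condition <- condition_key(d)
  d
}

#' The enrolment control condition
#'
#' The reference image for every patient is taken once, at enrolment,
#' under the standard condition: no mask, eyes open, sitting, sufficient
#' illumination.  Its profile entry governs how far the reference
#' embedding sits from the patient's latent identity.
#'
#' @return A one-row data frame in the same shape as [fr_design()], with
#'   `condition = "control"`.
#' @export
fr_control <- function() {
  data.frame(
    mask = "no", eyes = "open", position = "sitting",
    illumination = "sufficient", condition = "control",
    stringsAsFactors = FALSE
  )
}

#' Build the key string identifying a condition
#'
#' @param cond A data frame with columns `mask`, `eyes`, `position`,
#'   `illumination` (one row per condition).
#' @return Character vector of keys, e.g. `"no.open.sitting.sufficient"`.
#' @export
condition_key <- function(cond) {
  paste(cond$mask, cond$eyes, cond$position, cond$illumination, sep = ".")
}

# Validate condition factor levels; stops with the offending value.
check_condition_levels <- function(cond) {
  chk <- function(x, levels, what) {
    bad <- setdiff(unique(x), levels)
    if (length(bad) > 0)
      stop("invalid ", what, ": ", paste(bad, collapse = ", "), call. = FALSE)
  }
  chk(cond$mask, c("no", "yes"), "mask")
  chk(cond$eyes, c("open", "closed"), "eyes")
  chk(cond$position,
      c("sitting", "supine", "supine_right_lateral", "supine_left_lateral"),
      "position")
  chk(cond$illumination, c("sufficient", "low"), "illumination")
  lat <- cond$position %in% c("supine_right_lateral", "supine_left_lateral")
  if (any(lat & (cond$mask != "no" | cond$eyes != "closed" |
                   cond$illumination != "low")))
    stop("lateral positions occur only with mask=no, eyes=closed, ",
         "illumination=low", call. = FALSE)
  invisible(cond)
}
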