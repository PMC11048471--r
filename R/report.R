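#' Per-condition certification rates
#'
#' For each condition with genuine records, counts the genuine
#' comparisons accepted at that condition's threshold (the masked or
#' unmasked threshold of `policy`, by the condition's mask status) and
#' reports the success rate `100 * successes / n` -- equivalently
#' `(1 - FRR) * 100`.
#'
#' @param scores An `fr_scores` data frame.
#' @param policy An `fr_policy`.
#' @return A data frame (class `fr_condition_rates`) with the condition
#'   columns plus `n`, `successes`, `rate` (percent).
#' @export
success_rates <- function(scores, policy) {
  stopifnot(inherits(policy, "fr_policy"))
  gen <- scores[scores$genuine, , drop = FALSE]
  if (nrow(gen) == 0) stop("no genuine records in score set", call. = FALSE)
  keys <- unique(gen$condition)
  out <- do.call(rbind, lapply(keys, function(key) {
    g <- gen[gen$condition == key, , drop = FALSE]
    t <- if (g$mask[1] == "yes") policy$threshold_masked
         else policy$threshold_unmasked
    data.frame(mask = g$mask[1], eyes = g$eyes[1], position = g$position[1],
               illumination = g$illumination[1], condition = key,
               n = nrow(g), successes = sum(decide(g$as, t)),
               stringsAsFactors = FALSE)
  }))
  out$rate <- 100 * out$successes / out$n
  rownames(out) <- NULL
  class(out) <- c("fr_condition_rates", "data.frame")
  out
}

#' Aggregate certification rates
#'
#' Pools the per-condition counts into the study's summary groups:
#' \describe{
#'   \item{overall_unmasked / overall_masked}{all 8 factorial conditions
#'     of that mask status (800 comparisons in the default cohort).}
#'   \item{adverse_unmasked / adverse_masked}{the 7 factorial conditions
#'     excluding the standard one (open eyes, sitting, sufficient
#'     illumination) of that mask status.}
#'   \item{nighttime}{no mask, closed eyes, low illumination, in the
#'     supine and the two lateral postures (300 comparisons); these are
#'     mask-free, so they were thresholded at the unmasked threshold.}
#' }
#' Pooled rates are exact ratios of summed integer counts.
#'
#' @param per_condition An `fr_condition_rates` data frame covering every
#'   constituent condition (i.e. the full 18-condition design).
#' @return A data frame (class `fr_aggregate_rates`) with columns
#'   `group`, `n`, `successes`, `rate` (percent).
#' @export
aggregate_rates <- function(per_condition) {
  stopifnot(inherits(per_condition, "fr_condition_rates"))
  pc <- per_condition
  factorial <- pc$position %in% c("sitting", "supine")
  standard <- pc$eyes == "open" & pc$position == "sitting" &
    pc$illumination == "sufficient"
  groups <- list(
    overall_unmasked = factorial & pc$mask == "no",
    overall_masked = factorial & pc$mask == "yes",
    adverse_unmasked = factorial & pc$mask == "no" & !standard,
    adverse_masked = factorial & pc$mask == "yes" & !standard,
    nighttime = pc$mask == "no" & pc$eyes == "closed" &
      pc$illumination == "low" &
      pc$position %in% c("supine", "supine_right_lateral",
                         "supine_left_lateral")
  )
  expected <- c(overall_unmasked = 8L, overall_masked = 8L,
                adverse_unmasked = 7L, adverse_masked = 7L, nighttime = 3L)
  out <- do.call(rbind, lapply(names(groups), function(gname) {
    sel <- groups[[gname]]
    if (sum(sel) != expected[[gname]])
      stop("aggregate ", gname, " needs ", expected[[gname]],
           " conditions but found ", sum(sel),
           "; per-condition table is incomplete", call. = FALSE)
    data.frame(group = gname, n = sum(pc$n[sel]),
               successes = sum(pc$successes[sel]),
               stringsAsFactors = FALSE)
  }))
  out$rate <- 100 * out$successes / out$n
  rownames(out) <- NULL
  class(out) <- c("fr_aggregate_rates", "data.frame")
  out
}

#' Welch's two-sample t-test from summary statistics
#'
#' Unequal-variance t-test with Satterthwaite degrees of freedom,
#' computed from group means, SDs and sizes:
#' `t = (x_mean - y_mean) / sqrt(sx^2/nx + sy^2/ny)`, two-sided p from
#' the t distribution.  Used to compare genuine against impostor score
#' distributions (and condition against condition) without needing the
#' raw per-image scores.
#'
#' @param x_mean,x_sd,x_n First group's mean, SD, size (`x_n >= 2`).
#' @param y_mean,y_sd,y_n Second group's.
#' @return A list of class `fr_welch`: `t_stat`, `df`, `p_two_sided`,
#'   `group_means`, `group_sds`, `group_ns`.
#' @export
#' @examples
#' welch_t(0.785, 0.004, 100, 0.508, 0.025, 100)  # t ~ 109.4
welch_t <- function(x_mean, x_sd, x_n, y_mean, y_sd, y_n) {
  if (x_sd < 0 || y_sd < 0) stop("sds must be >= 0", call. = FALSE)
  if (x_n < 2 || y_n < 2) stop("group sizes must be >= 2", call. = FALSE)
  if (x_sd == 0 && y_sd == 0)
    stop("both groups have zero variance; t statistic is degenerate",
         call. = FALSE)
  vx <- x_sd^2 / x_n
  vy <- y_sd^2 / y_n
  se <- sqrt(vx + vy)
  t_stat <- (x_mean - y_mean) / se
  df <- (vx + vy)^2 / (vx^2 / (x_n - 1) + vy^2 / (y_n - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  structure(list(t_stat = t_stat, df = df, p_two_sided = p,
                 group_means = c(x_mean, y_mean),
                 group_sds = c(x_sd, y_sd),
                 group_ns = c(x_n, y_n)),
            class = "fr_welch")
}

#' @export
print.fr_welch <- function(x, ...) {
  p <- if (x$p_two_sided < 1e-15) "<1e-15" else
    format(x$p_two_sided, digits = 4)
  cat(sprintf("Welch two-sample t-test: t = %.4g, df = %.4g, p = %s\n",
              x$t_stat, x$df, p))
  invisible(x)
}

#' Analytic success-rate prediction under a normal score model
#'
#' Treats a condition's genuine AS as `Normal(mu, sigma^2)` (ignoring
#' the `[0, 1]` truncation, which is negligible at the score levels this
#' package models) and returns `P(AS > t) = 1 - pnorm((t - mu)/sigma)`.
#' Serves as the closed-form oracle against which Monte-Carlo
#' certification rates are checked.
#'
#' @param mu Mean genuine AS.
#' @param sigma AS standard deviation (> 0).
#' @param t Decision threshold.
#' @return Predicted acceptance probability in `[0, 1]` (vectorized).
#' @export
predicted_success_rate <- function(mu, sigma, t) {
  if (any(sigma <= 0)) stop("sigma must be > 0", call. = FALSE)
  1 - stats::pnorm((t - mu) / sigma)
}

#' Full verification report
#'
#' Combines per-condition rates, the pooled aggregates, and per-condition
#' Welch tests of genuine vs impostor AS into one object.
#'
#' @param scores An `fr_scores` data frame covering the full design
#'   (genuine and impostor records).
#' @param policy An `fr_policy`.
#' @return A list of class `fr_report` with elements `per_condition`,
#'   `aggregates`, `tests` (one Welch result per condition, genuine vs
#'   impostor) and `policy`.
#' @export
build_report <- function(scores, policy) {
  per <- success_rates(scores, policy)
  agg <- aggregate_rates(per)
  tests <- do.call(rbind, lapply(per$condition, function(key) {
    g <- scores$as[scores$genuine & scores$condition == key]
    i <- scores$as[!scores$genuine & scores$condition == key]
    w <- welch_t(mean(g), stats::sd(g), length(g),
                 mean(i), stats::sd(i), length(i))
    data.frame(condition = key, genuine_mean = mean(g),
               impostor_mean = mean(i), t_stat = w$t_stat, df = w$df,
               p_two_sided = w$p_two_sided, stringsAsFactors = FALSE)
  }))
  structure(list(per_condition = per, aggregates = agg, tests = tests,
                 policy = policy),
            class = "fr_report")
}

#' @export
print.fr_report <- function(x, digits = 1, ...) {
  cat("1:1 verification report\n")
  cat(sprintf("Thresholds: unmasked %.3f, masked %.3f (%s)\n\n",
              x$policy$threshold_unmasked, x$policy$threshold_masked,
              x$policy$calibration))
  per <- x$per_condition
  per$rate <- round(per$rate, digits)
  print(as.data.frame(per[, c("mask", "eyes", "position", "illumination",
                              "n", "successes", "rate")]), row.names = FALSE)
  cat("\nAggregates:\n")
  agg <- x$aggregates
  agg$rate <- round(agg$rate, digits)
  print(as.data.frame(agg), row.names = FALSE)
  if (!is.null(x$tests)) {
    cat("\nGenuine vs impostor (Welch), largest p across conditions: ")
    pmax_ <- max(x$tests$p_two_sided)
    cat(if (pmax_ < 1e-15) "<1e-15" else format(pmax_, digits = 3), "\n")
  }
  invisible(x)
}

#' Write a verification report to disk
#'
#' Writes `report.json` (full machine-readable report, numeric p-values
#' kept as numbers), `report.csv` (the per-condition table: mask, eyes,
#' position, illumination, n, successes, rate) next to it.
#'
#' @param report An `fr_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "fr_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(dir, "report.json")
  csv_path <- file.path(dir, "report.csv")
  jsonlite::write_json(
    list(policy = unclass(report$policy),
         per_condition = as.data.frame(report$per_condition),
         aggregates = as.data.frame(report$aggregates),
         tests = report$tests),
    json_path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(
    report$per_condition[, c("mask", "eyes", "position", "illumination",
                             "n", "successes", "rate")]),
    csv_path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(c(json = json_path, csv = csv_path))
}
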