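#' Simulation configuration for a synthetic patient cohort
#'
#' @param n_patients Number of patients (>= 2). Default 100, the size of
#'   the clinical cohort the default profile was measured on.
#' @param dim Embedding dimensionality (>= 2).  Default 512: the
#'   engine being emulated uses roughly 2000 correlated features, but the
#'   printed impostor-score spread (AS SD of about 0.022) implies an
#'   effective isotropic dimension of about (0.5/0.022)^2, i.e. ~516.
#' @param rho Population coherence in [0, 1): the squared-cosine weight
#'   of a shared population direction in every latent identity.  Default
#'   0.01, which puts the mean impostor AS at 0.5 + 0.5*rho = 0.505,
#'   matching the published wrong-matching means (0.502--0.509).
#' @param seed Integer master seed; every draw in the simulation derives
#'   from it through per-patient, per-condition substreams.
#' @param profile An [fr_profile][condition_profile] with one entry per
#'   design condition plus the control; default [default_profile()].
#' @return A list of class `fr_sim_config`.
#' @export
sim_config <- function(n_patients = 100, dim = 512, rho = 0.01, seed = 1,
                       profile = default_profile()) {
  if (!is.numeric(dim) || dim < 2)
    stop("dim must be >= 2", call. = FALSE)
  if (!is.numeric(n_patients) || n_patients < 2)
    stop("n_patients must be >= 2", call. = FALSE)
  if (!is.numeric(rho) || rho < 0 || rho >= 1)
    stop("rho must lie in [0, 1)", call. = FALSE)
  if (!inherits(profile, "fr_profile"))
    stop("profile must be built with condition_profile()", call. = FALSE)
  structure(
    list(n_patients = as.integer(n_patients), dim = as.integer(dim),
         rho = as.numeric(rho), seed = as.integer(seed), profile = profile),
    class = "fr_sim_config"
  )
}

unit_normalize <- function(v) {
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) stop("zero vector cannot be normalized", call. = FALSE)
  v / nrm
}

# Isotropic unit vector from the current RNG stream.
runif_sphere <- function(dim) unit_normalize(stats::rnorm(dim))

#' Draw latent identity vectors
#'
#' Each patient's latent identity is a unit vector
#' `normalize(sqrt(rho) * m + sqrt(1 - rho) * z)` where `m` is a single
#' population direction shared by the whole cohort and `z` is an
#' isotropic unit draw.  With `rho = 0` identities are uniform on the
#' sphere and the expected impostor cosine is 0; with small `rho > 0`
#' the expected impostor cosine is approximately `rho`, lifting the mean
#' impostor AS to about `0.5 + 0.5 * rho`.
#'
#' Draws are fully determined by `config$seed` (identity `i` always uses
#' the cohort's `i`-th RNG stream), so the same config yields the same
#' identities regardless of `n`.
#'
#' @param config An [sim_config()].
#' @param n Number of identities to draw (defaults to
#'   `config$n_patients`).
#' @return An `n` x `dim` matrix with unit-norm rows.
#' @export
sample_identity <- function(config, n = config$n_patients) {
  stopifnot(inherits(config, "fr_sim_config"))
  m <- population_direction(config)
  s <- parallel::nextRNGStream(lecuyer_seed(config$seed))
  out <- matrix(0, nrow = n, ncol = config$dim)
  for (i in seq_len(n)) {
    out[i, ] <- with_stream(s, function() {
      z <- runif_sphere(config$dim)
      unit_normalize(sqrt(config$rho) * m + sqrt(1 - config$rho) * z)
    })
    s <- parallel::nextRNGStream(s)
  }
  out
}

#' Shared population direction of a simulated cohort
#'
#' @param config An [sim_config()].
#' @return A unit vector of length `config$dim`, deterministic in the
#'   seed.
#' @export
population_direction <- function(config) {
  stopifnot(inherits(config, "fr_sim_config"))
  with_stream(lecuyer_seed(config$seed), function() runif_sphere(config$dim))
}

#' Sample a probe embedding at a prescribed authentication-score
#' distribution
#'
#' Draws a target cosine `c` from a normal distribution with mean
#' `2*mu - 1` and SD `2*sigma`, truncated to `[-1, 1]` (inverse-CDF
#' sampling), then places the probe at exactly that angle from the
#' reference by the tangent-normal construction
#' `c * reference + sqrt(1 - c^2) * w`, with `w` uniform on the unit
#' tangent sphere orthogonal to the reference.  By construction the
#' authentication score of (reference, probe) is `0.5*c + 0.5`, so
#' genuine AS values follow the truncated-normal image of (`mu`,
#' `sigma`).
#'
#' `c` is additionally clipped to `[-1 + 1e-12, 1 - 1e-12]` so that
#' `sqrt(1 - c^2)` stays real; the boundary case `mu = 1, sigma = 0`
#' therefore returns (numerically) the reference itself.
#'
#' Draws come from the current global RNG stream; [build_gallery()]
#' manages per-condition substreams around this.
#'
#' @param reference Unit-norm numeric vector (length >= 2).
#' @param mu Target mean AS in [0, 1].
#' @param sigma Target AS standard deviation, >= 0.
#' @return A unit-norm probe vector of the same length.
#' @export
sample_probe <- function(reference, mu, sigma) {
  if (!is.numeric(sigma) || sigma < 0)
    stop("sigma must be >= 0", call. = FALSE)
  if (!is.numeric(mu) || mu < 0 || mu > 1)
    stop("mu must lie in [0, 1]", call. = FALSE)
  if (length(reference) < 2)
    stop("reference must have dimension >= 2", call. = FALSE)
  m <- 2 * mu - 1
  s <- 2 * sigma
  if (s == 0) {
    cc <- m
  } else {
    lo <- stats::pnorm((-1 - m) / s)
    hi <- stats::pnorm((1 - m) / s)
    u <- stats::runif(1, lo, hi)
    cc <- m + s * stats::qnorm(u)
  }
  eps <- 1e-12
  cc <- min(max(cc, -1 + eps), 1 - eps)
  w <- tangent_vector(reference)
  cc * reference + sqrt(1 - cc^2) * w
}

# Uniform unit vector orthogonal to `ref`: isotropic draw, projected off
# ref, normalized; redrawn on the measure-zero degenerate residual.
tangent_vector <- function(ref) {
  repeat {
    z <- stats::rnorm(length(ref))
    r <- z - sum(z * ref) * ref
    nrm <- sqrt(sum(r^2))
    if (nrm > 1e-12) return(r / nrm)
  }
}

#' Build a synthetic patient gallery
#'
#' Simulates the full cohort: for each patient a latent identity vector,
#' one enrolment reference drawn at the control profile entry's AS
#' around the identity, and one probe per design condition drawn around
#' the *reference* with that condition's profile (mean, sd) -- so
#' genuine scores match the profile by construction while the latent
#' identities and shared population direction shape impostor scores.
#'
#' @param config An [sim_config()] whose profile covers every design
#'   condition plus the control.
#' @return An object of class `fr_gallery`: a list with `config`, the
#'   design, an `index` data frame (one row per embedding: `patient_id`,
#'   `role`, condition columns) and the embedding matrix `embeddings`
#'   (rows aligned with `index`, unit norm).
#' @export
#' @examples
#' g <- build_gallery(sim_config(n_patients = 2, dim = 8, seed = 7))
#' nrow(g$embeddings)  # 2 patients x (1 reference + 18 probes)
build_gallery <- function(config) {
  stopifnot(inherits(config, "fr_sim_config"))
  design <- fr_design()
  prof <- profile_entry(config$profile, c("control", design$condition))
  ctrl <- prof[1, ]
  cond_prof <- prof[-1, ]

  n <- config$n_patients
  n_cond <- nrow(design)
  per_patient <- 1L + n_cond
  emb <- matrix(0, nrow = n * per_patient, ncol = config$dim)

  m <- population_direction(config)
  stream <- parallel::nextRNGStream(lecuyer_seed(config$seed))
  row <- 0L
  for (i in seq_len(n)) {
    sub <- stream
    identity <- with_stream(sub, function() {
      z <- runif_sphere(config$dim)
      unit_normalize(sqrt(config$rho) * m + sqrt(1 - config$rho) * z)
    })
    sub <- parallel::nextRNGSubStream(sub)
    reference <- with_stream(sub, function()
      sample_probe(identity, ctrl$mean, ctrl$sd))
    row <- row + 1L
    emb[row, ] <- reference
    for (k in seq_len(n_cond)) {
      sub <- parallel::nextRNGSubStream(sub)
      emb[row + k, ] <- with_stream(sub, function()
        sample_probe(reference, cond_prof$mean[k], cond_prof$sd[k]))
    }
    row <- row + n_cond
    stream <- parallel::nextRNGStream(stream)
  }

  ids <- sprintf("P%03d", seq_len(n))
  index <- data.frame(
    patient_id = rep(ids, each = per_patient),
    role = rep(c("reference", rep("probe", n_cond)), n),
    mask = rep(c(ctrl$mask, design$mask), n),
    eyes = rep(c(ctrl$eyes, design$eyes), n),
    position = rep(c(ctrl$position, design$position), n),
    illumination = rep(c(ctrl$illumination, design$illumination), n),
    condition = rep(c("control", design$condition), n),
    stringsAsFactors = FALSE
  )
  structure(
    list(config = config, design = design, index = index, embeddings = emb),
    class = "fr_gallery"
  )
}

#' @export
print.fr_gallery <- function(x, ...) {
  cat("Synthetic verification gallery\n")
  cat("  patients:  ", x$config$n_patients, "\n")
  cat("  dim:       ", x$config$dim, "\n")
  cat("  embeddings:", nrow(x$embeddings),
      "(1 reference + ", nrow(x$design), "probes each)\n")
  cat("  seed:      ", x$config$seed, "\n")
  invisible(x)
}

#' Write / read a gallery as delimited text
#'
#' One row per embedding: `patient_id`, `role`, the four condition
#' columns, then the `dim` numeric coordinates (`V1` ... `Vdim`),
#' serialized at full precision.  UTF-8, comma-separated, header
#' mandatory.
#'
#' @param gallery An `fr_gallery`.
#' @param path Output CSV path.
#' @return `write_gallery` returns `path` invisibly; `read_gallery`
#'   returns an `fr_gallery` (with `config` reduced to the cohort
#'   geometry: seed and profile are not stored in the CSV).
#' @export
write_gallery <- function(gallery, path) {
  stopifnot(inherits(gallery, "fr_gallery"))
  coords <- as.data.frame(gallery$embeddings)
  names(coords) <- paste0("V", seq_len(ncol(coords)))
  df <- cbind(gallery$index[, c("patient_id", "role", "mask", "eyes",
                                "position", "illumination")], coords)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_gallery
#' @export
read_gallery <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("patient_id", "role", "mask", "eyes", "position", "illumination")
  if (!all(need %in% names(df)))
    stop("gallery CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  vcols <- grep("^V[0-9]+$", names(df), value = TRUE)
  if (length(vcols) < 2) stop("gallery CSV has no embedding columns",
                              call. = FALSE)
  emb <- as.matrix(df[, vcols])
  dimnames(emb) <- NULL
  index <- df[, need]
  index$condition <- ifelse(index$role == "reference", "control",
                            condition_key(index))
  ids <- unique(index$patient_id)
  structure(
    list(config = list(n_patients = length(ids), dim = ncol(emb)),
         design = fr_design(), index = index, embeddings = emb),
    class = "fr_gallery"
  )
}
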