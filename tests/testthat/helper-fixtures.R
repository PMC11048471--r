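# Shared fixtures and independent brute-force oracles.

tiny_config <- function(n = 3, dim = 16, seed = 11, rho = 0.01) {
  sim_config(n_patients = n, dim = dim, rho = rho, seed = seed)
}

tiny_gallery <- function(n = 3, dim = 16, seed = 11) {
  build_gallery(tiny_config(n, dim, seed))
}

# Enumeration oracle for score-record counts: walk every (ref, probe,
# condition) triple with explicit loops, independent of score_all_pairs.
oracle_pair_counts <- function(n_patients, n_conditions) {
  genuine <- 0L; impostor <- 0L
  for (i in seq_len(n_patients))
    for (j in seq_len(n_patients))
      for (k in seq_len(n_conditions)) {
        if (i == j) genuine <- genuine + 1L else impostor <- impostor + 1L
      }
  list(genuine = genuine, impostor = impostor)
}

# Counting oracle for FAR/FRR: explicit loops over records.
oracle_far <- function(impostor_scores, t) {
  hits <- 0L
  for (s in impostor_scores) if (s > t) hits <- hits + 1L
  hits / length(impostor_scores)
}

oracle_frr <- function(genuine_scores, t) {
  hits <- 0L
  for (s in genuine_scores) if (s <= t) hits <- hits + 1L
  hits / length(genuine_scores)
}

# Build an fr_scores object directly from score vectors (bypasses the
# simulator) for threshold/rate unit tests.
scores_from_values <- function(genuine_as, impostor_as, mask = "no",
                               eyes = "open", position = "sitting",
                               illumination = "sufficient") {
  mk <- function(as_vals, genuine) {
    n <- length(as_vals)
    if (n == 0) return(NULL)
    data.frame(
      ref_patient = sprintf("P%03d", seq_len(n)),
      probe_patient = if (genuine) sprintf("P%03d", seq_len(n))
                      else sprintf("Q%03d", seq_len(n)),
      mask = mask, eyes = eyes, position = position,
      illumination = illumination,
      condition = paste(mask, eyes, position, illumination, sep = "."),
      cs = 2 * as_vals - 1, as = as_vals, genuine = genuine,
      stringsAsFactors = FALSE
    )
  }
  df <- rbind(mk(genuine_as, TRUE), mk(impostor_as, FALSE))
  faceverify:::new_scores(df, n_patients = length(genuine_as),
                          conditions = unique(df$condition),
                          seed = NA_integer_)
}

# Vectors with exact sample mean and SD, for summary-stat test oracles.
exact_moments <- function(m, s, n) {
  z <- stats::rnorm(n)
  z <- (z - mean(z)) / stats::sd(z)
  m + s * z
}
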