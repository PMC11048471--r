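#' Cosine similarity of two embeddings
#'
#' `CS = (a . b) / (||a|| ||b||)`.  Symmetric, deterministic, and
#' clamped to `[-1, 1]` only against floating-point overshoot (at most
#' 1e-9).
#'
#' @param a,b Numeric vectors of equal length, neither all-zero.
#' @return Cosine similarity in `[-1, 1]`.
#' @export
#' @examples
#' cosine_similarity(c(1, 0), c(0, 1))  # 0
cosine_similarity <- function(a, b) {
  if (length(a) != length(b))
    stop("embeddings have different dimensions (", length(a), " vs ",
         length(b), ")", call. = FALSE)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("cosine similarity of a zero vector is undefined", call. = FALSE)
  clamp_cosine(sum(a * b) / (na * nb))
}

clamp_cosine <- function(cs) {
  if (any(abs(cs) > 1 + 1e-9))
    stop("cosine similarity outside [-1, 1]", call. = FALSE)
  pmin(pmax(cs, -1), 1)
}

#' Authentication score
#'
#' The affine map from cosine similarity to the unit interval:
#' `AS = 0.5 * CS + 0.5`, so AS(-1) = 0, AS(0) = 0.5, AS(1) = 1.  Higher
#' AS indicates stronger evidence that the two face images belong to the
#' same person.
#'
#' @param cs Cosine similarity value(s) in `[-1, 1]` (tolerance 1e-9).
#' @return Authentication score(s) in `[0, 1]`.
#' @export
authentication_score <- function(cs) {
  0.5 * clamp_cosine(cs) + 0.5
}

#' Score every genuine and impostor comparison of a gallery
#'
#' Runs the 1:1 verification protocol exhaustively: for each selected
#' condition, each patient's reference is compared against that
#' patient's own probe (one genuine record) and against every other
#' patient's probe (impostor records).  Comparisons are directional
#' (reference_i vs probe_j) and not deduplicated, because references and
#' probes are distinct images.
#'
#' Record counts therefore satisfy `genuine = n_patients * |conditions|`
#' and `impostor = n_patients * (n_patients - 1) * |conditions|`; the
#' default 100-patient cohort over the 16 factorial conditions yields
#' 158,400 impostor records.
#'
#' @param gallery An `fr_gallery`.
#' @param conditions Character vector of condition keys to score
#'   (subset of `gallery$design$condition`); default all 18.
#' @return An `fr_scores` data frame, ordered by (reference patient,
#'   probe patient, condition index), with columns `ref_patient`,
#'   `probe_patient`, `mask`, `eyes`, `position`, `illumination`,
#'   `condition`, `cs`, `as`, `genuine`.  Metadata (`n_patients`,
#'   `conditions`, `seed`) is carried in attributes.
#' @export
score_all_pairs <- function(gallery, conditions = NULL) {
  stopifnot(inherits(gallery, "fr_gallery"))
  design <- gallery$design
  if (is.null(conditions)) conditions <- design$condition
  if (length(conditions) == 0)
    stop("empty condition subset", call. = FALSE)
  unknown <- setdiff(conditions, design$condition)
  if (length(unknown) > 0)
    stop("conditions not in the design: ", paste(unknown, collapse = ", "),
         call. = FALSE)

  idx <- gallery$index
  refs <- gallery$embeddings[idx$role == "reference", , drop = FALSE]
  ids <- idx$patient_id[idx$role == "reference"]
  n <- length(ids)

  pieces <- vector("list", length(conditions))
  for (k in seq_along(conditions)) {
    key <- conditions[k]
    sel <- idx$condition == key & idx$role == "probe"
    probes <- gallery$embeddings[sel, , drop = FALSE]
    pid <- idx$patient_id[sel]
    if (!identical(pid, ids))
      stop("gallery is incomplete for condition ", key, call. = FALSE)
    cs <- clamp_cosine(tcrossprod(refs, probes))  # [i, j] = ref_i . probe_j
    drow <- design[design$condition == key, ]
    pieces[[k]] <- data.frame(
      ref_patient = rep(ids, each = n),
      probe_patient = rep(ids, n),
      mask = drow$mask, eyes = drow$eyes, position = drow$position,
      illumination = drow$illumination, condition = key,
      cond_index = k,
      cs = as.vector(t(cs)),
      stringsAsFactors = FALSE
    )
  }
  rec <- do.call(rbind, pieces)
  rec <- rec[order(rec$ref_patient, rec$probe_patient, rec$cond_index), ]
  rec$cond_index <- NULL
  rec$as <- authentication_score(rec$cs)
  rec$genuine <- rec$ref_patient == rec$probe_patient
  rownames(rec) <- NULL
  new_scores(rec,
             n_patients = n,
             conditions = conditions,
             seed = if (!is.null(gallery$config$seed)) gallery$config$seed
             else NA_integer_)
}

new_scores <- function(df, n_patients, conditions, seed) {
  structure(df,
            n_patients = n_patients,
            conditions = conditions,
            seed = seed,
            class = c("fr_scores", "data.frame"))
}

#' Write / read a score set as delimited text
#'
#' CSV with columns `ref_patient`, `probe_patient`, `mask`, `eyes`,
#' `position`, `illumination`, `cs`, `as`, `genuine`; numeric columns
#' serialized at 17 significant digits so a round trip is lossless.
#'
#' @param scores An `fr_scores` object.
#' @param path CSV path.
#' @return `write_scores` returns `path` invisibly; use
#'   [ingest_scores()] to read and validate a score CSV.
#' @export
write_scores <- function(scores, path) {
  stopifnot(inherits(scores, "fr_scores"))
  df <- as.data.frame(scores)
  df$condition <- NULL
  df$cs <- sprintf("%.17g", df$cs)
  df$as <- sprintf("%.17g", df$as)
  df$genuine <- ifelse(df$genuine, "TRUE", "FALSE")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
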