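#' Quantify category-based criteria from hit counts
#'
#' Converts the species-by-OG hit-count matrix into criteria values using the
#' category rules: an nOG contributes \code{-hitN} (its presence hurts
#' production), a pOG contributes \code{hitN} when present but a flat penalty
#' of \code{-1} when absent (\code{hitN = 0}), and an rOG contributes
#' \code{hitN}.
#'
#' @param hit_matrix nonnegative integer matrix, columns in catalog order
#' @param catalog an \code{ffasc_catalog}
#' @return numeric criteria matrix of the same shape and dimnames
#' @export
quantify_criteria <- function(hit_matrix, catalog) {
  ogs <- og_ids(catalog)
  if (!is.matrix(hit_matrix) || ncol(hit_matrix) != length(ogs) ||
      (!is.null(colnames(hit_matrix)) && !identical(colnames(hit_matrix), ogs)))
    ffasc_error("ffasc_alignment_error",
                "hit matrix columns do not match catalog OG order")
  if (any(hit_matrix < 0) || any(hit_matrix != round(hit_matrix)))
    ffasc_error("ffasc_domain_error", "hit counts must be nonnegative integers")
  cat_of <- catalog$ogs$category
  out <- matrix(as.numeric(hit_matrix), nrow(hit_matrix), ncol(hit_matrix),
                dimnames = dimnames(hit_matrix))
  n_cols <- which(cat_of == "nOG")
  p_cols <- which(cat_of == "pOG")
  out[, n_cols] <- -out[, n_cols, drop = FALSE]
  pz <- out[, p_cols, drop = FALSE]
  pz[pz == 0] <- -1
  out[, p_cols] <- pz
  out
}

#' Unweighted potential score of one species
#'
#' The sum of its quantified criteria values (all criteria weighted equally).
#'
#' @param x numeric criteria vector (one row of the criteria matrix)
#' @return scalar score; higher means better fatty-acid production potential
#' @export
score_unweighted <- function(x) sum(as.numeric(x))

#' Weighted potential score of one species
#'
#' @param x numeric criteria vector
#' @param w numeric weight vector of the same length
#' @return the inner product \code{w' x}
#' @export
score_weighted <- function(x, w) {
  if (length(x) != length(w))
    ffasc_error("ffasc_length_error", sprintf(
      "criteria vector length %d != weight vector length %d",
      length(x), length(w)))
  sum(as.numeric(w) * as.numeric(x))
}

#' Score every species in a criteria matrix
#'
#' @param criteria numeric species-by-OG criteria matrix
#' @param weights numeric weight vector, or NULL for unit weights
#' @return named numeric vector of raw scores
#' @export
score_species <- function(criteria, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, ncol(criteria))
  if (length(weights) != ncol(criteria))
    ffasc_error("ffasc_length_error", "weight length != number of criteria")
  drop(criteria %*% weights)
}

#' Rank species by score
#'
#' Higher scores are better; the top rank is 1. Ties are broken by ascending
#' species id so the ranking is deterministic.
#'
#' @param scores named numeric vector, species id -> raw score
#' @param normalize \code{"minmax"} (default; requires n >= 2 and non-equal
#'   scores) or \code{"none"} (normalized column reported as NA)
#' @return data.frame with columns \code{rank}, \code{species_id},
#'   \code{raw_score}, \code{normalized_score}, ordered by rank
#' @export
rank_species <- function(scores, normalize = c("minmax", "none")) {
  normalize <- match.arg(normalize)
  stopifnot(length(scores) >= 1L, !is.null(names(scores)))
  ord <- order(-scores, names(scores), method = "radix")
  out <- data.frame(rank = seq_along(scores),
                    species_id = names(scores)[ord],
                    raw_score = unname(scores[ord]),
                    stringsAsFactors = FALSE)
  out$normalized_score <- if (normalize == "minmax" && length(scores) >= 2L)
    normalize_scores(out$raw_score) else NA_real_
  out
}

#' Min-max normalize scores to [0, 1]
#'
#' The maximal score maps to exactly 1 and the minimal to exactly 0;
#' invariant under affine transforms of the input.
#'
#' @param scores numeric vector, n >= 2, not all equal
#' @return numeric vector in [0, 1]
#' @export
normalize_scores <- function(scores) {
  stopifnot(length(scores) >= 2L)
  rng <- range(scores)
  if (rng[1] == rng[2])
    ffasc_error("ffasc_degenerate_error",
                "degenerate normalization: all scores equal")
  (scores - rng[1]) / (rng[2] - rng[1])
}

#' Rank of selected species within a ranking table
#'
#' @param ranking data.frame from \code{\link{rank_species}}
#' @param species_id one or more species ids
#' @return integer rank(s)
#' @export
rank_of <- function(ranking, species_id) {
  idx <- match(species_id, ranking$species_id)
  if (anyNA(idx))
    ffasc_error("ffasc_unknown_species_error", sprintf(
      "species not in ranking: %s",
      paste(species_id[is.na(idx)], collapse = ", ")))
  ranking$rank[idx]
}

#' Write a ranking table to TSV
#'
#' Scores are reported to 6 decimals.
#' @param ranking data.frame from \code{\link{rank_species}}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_ranking <- function(ranking, path) {
  out <- ranking
  out$raw_score <- sprintf("%.6f", out$raw_score)
  out$normalized_score <- ifelse(is.na(out$normalized_score), "NA",
                                 sprintf("%.6f", out$normalized_score))
  utils::write.table(out[, c("rank", "species_id", "raw_score",
                             "normalized_score")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
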