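#' Binarize a hit-count matrix to presence/absence
#'
#' @param hit_matrix nonnegative integer matrix
#' @return 0/1 integer matrix of the same shape: 1 iff hitN > 0
#' @export
binarize <- function(hit_matrix) {
  out <- matrix(as.integer(hit_matrix > 0), nrow(hit_matrix), ncol(hit_matrix),
                dimnames = dimnames(hit_matrix))
  out
}

#' Compare two binary presence/absence annotation matrices
#'
#' Reconciles the two matrices by strain and OG labels, subtracts the second
#' from the first cell-wise and accounts for agreement per OG: an OG is
#' \code{identical} when every strain agrees, \code{a_only} when every
#' disagreement is presence in \code{a} alone (+1), \code{b_only} when every
#' disagreement is presence in \code{b} alone (-1), and \code{mixed} when
#' both directions occur. Per-OG signed difference sums lie in [-n, n] for
#' n strains.
#'
#' @param a,b 0/1 matrices with strain rownames and OG colnames; label sets
#'   must match (order is reconciled by label)
#' @return list of class \code{ffasc_comparison}: \code{per_og} data.frame
#'   (og_id, diff_sum, n_a_only, n_b_only, class), \code{class_counts},
#'   \code{class_percent} (over the number of OGs), \code{n_strains}
#' @export
compare_annotations <- function(a, b) {
  if (!setequal(rownames(a), rownames(b)) || !setequal(colnames(a), colnames(b)))
    ffasc_error("ffasc_label_mismatch_error", sprintf(
      "label sets differ; strains only in one matrix: [%s]; OGs only in one matrix: [%s]",
      paste(c(setdiff(rownames(a), rownames(b)),
              setdiff(rownames(b), rownames(a))), collapse = ", "),
      paste(c(setdiff(colnames(a), colnames(b)),
              setdiff(colnames(b), colnames(a))), collapse = ", ")))
  stopifnot(all(a %in% 0:1), all(b %in% 0:1))
  b <- b[rownames(a), colnames(a), drop = FALSE]
  d <- a - b
  n <- nrow(a)
  n_pos <- colSums(d == 1)
  n_neg <- colSums(d == -1)
  cls <- ifelse(n_pos + n_neg == 0, "identical",
         ifelse(n_neg == 0, "a_only",
         ifelse(n_pos == 0, "b_only", "mixed")))
  per_og <- data.frame(og_id = colnames(a), diff_sum = colSums(d),
                       n_a_only = n_pos, n_b_only = n_neg, class = cls,
                       row.names = NULL, stringsAsFactors = FALSE)
  lv <- c("identical", "a_only", "b_only", "mixed")
  counts <- table(factor(cls, levels = lv))
  structure(list(per_og = per_og,
                 class_counts = stats::setNames(as.integer(counts), lv),
                 class_percent = stats::setNames(100 * as.integer(counts) /
                                                   ncol(a), lv),
                 n_strains = n),
            class = "ffasc_comparison")
}

#' @export
print.ffasc_comparison <- function(x, ...) {
  cat(sprintf("ffasc annotation comparison over %d strains, %d OGs\n",
              x$n_strains, nrow(x$per_og)))
  pct <- sprintf("%s %.1f%%", names(x$class_percent), x$class_percent)
  cat(" ", paste(pct, collapse = ", "), "\n")
  invisible(x)
}
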