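#' K-means partition of species criteria vectors
#'
#' Best-of-restarts Lloyd's algorithm under squared Euclidean distance,
#' deterministic given the seed. Restarts with empty clusters are discarded.
#'
#' @param matrix numeric species-by-criteria matrix (rows clustered)
#' @param k number of clusters, \code{1 <= k <= nrow(matrix)}
#' @param seed integer RNG seed
#' @param n_restarts random restarts (default 25)
#' @return list of class \code{ffasc_clustering}: \code{labels} (named
#'   integer vector in 1..k), \code{k}, \code{tot_withinss}, \code{centers}
#' @export
kmeans_cluster <- function(matrix, k, seed = 1L, n_restarts = 25L) {
  n <- nrow(matrix)
  if (k > n)
    ffasc_error("ffasc_domain_error", sprintf("k = %d exceeds n = %d", k, n))
  if (k == n) {
    labels <- stats::setNames(seq_len(n), rownames(matrix))
    return(structure(list(labels = labels, k = k, tot_withinss = 0,
                          centers = matrix), class = "ffasc_clustering"))
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    km <- tryCatch(
      suppressWarnings(stats::kmeans(matrix, centers = k, iter.max = 100L,
                                     algorithm = "Lloyd")),
      error = function(e) NULL)
    if (is.null(km) || any(km$size == 0L)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best))
    ffasc_error("ffasc_degenerate_error",
                "no restart produced k nonempty clusters")
  structure(list(labels = stats::setNames(best$cluster, rownames(matrix)),
                 k = k, tot_withinss = best$tot.withinss,
                 centers = best$centers),
            class = "ffasc_clustering")
}

#' Average silhouette width of a partition
#'
#' For each point, \code{a} is its mean distance to the other members of its
#' cluster and \code{b} the smallest mean distance to any other cluster; the
#' silhouette width is \code{(b - a) / max(a, b)}. Points in singleton
#' clusters contribute 0, and the 0/0 case (all relevant distances equal)
#' is taken as 0. The average lies in [-1, 1]; values near 1 indicate points
#' sit well inside their own cluster.
#'
#' @param matrix numeric data matrix (rows are points)
#' @param labels integer cluster labels in 1..k (or an
#'   \code{ffasc_clustering})
#' @return average silhouette width
#' @export
average_silhouette <- function(matrix, labels) {
  if (inherits(labels, "ffasc_clustering")) labels <- labels$labels
  labels <- as.integer(labels)
  k <- length(unique(labels))
  if (k < 2L)
    ffasc_error("ffasc_domain_error", "silhouette requires k >= 2")
  d <- as.matrix(stats::dist(matrix))
  n <- nrow(d)
  s <- vapply(seq_len(n), function(i) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) return(0)   # singleton convention
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(d[i, labels == g]), numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Calinski-Harabasz index of a partition
#'
#' The variance-ratio criterion \code{[B / (k - 1)] / [W / (n - k)]}, with
#' \code{B} the between-cluster and \code{W} the within-cluster sum of
#' squares about the centroids. Larger is better. When \code{W = 0} (all
#' clusters collapse to points) the index is unbounded and \code{Inf} is
#' returned as the infinite-separation sentinel.
#'
#' @inheritParams average_silhouette
#' @return CH index (possibly \code{Inf})
#' @export
calinski_harabasz <- function(matrix, labels) {
  if (inherits(labels, "ffasc_clustering")) labels <- labels$labels
  labels <- as.integer(labels)
  n <- nrow(matrix)
  k <- length(unique(labels))
  if (k < 2L || k >= n)
    ffasc_error("ffasc_domain_error", "CH index requires 2 <= k < n")
  grand <- colMeans(matrix)
  W <- 0; B <- 0
  for (g in unique(labels)) {
    rows <- matrix[labels == g, , drop = FALSE]
    cen <- colMeans(rows)
    W <- W + sum(sweep(rows, 2, cen)^2)
    B <- B + nrow(rows) * sum((cen - grand)^2)
  }
  if (W == 0) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

#' Scan cluster numbers and select the natural k using outgroup species
#'
#' The outgroup (e.g. the diatoms among cyanobacteria) acts as a planted
#' outlier set: clustering is considered natural from the smallest k at
#' which the outgroup occupies its own cluster, exclusively and together
#' (\code{exclusive_together}), up to and including the first k at which
#' the outgroup starts splitting over several clusters (\code{split});
#' before that the outgroup is \code{mixed} with in-group species. Within
#' this candidate range the k with the highest average silhouette width is
#' selected; the CH index is reported for all candidates.
#'
#' @param matrix numeric species-by-criteria matrix with rownames
#' @param outlier_ids character vector of outgroup species ids
#' @param k_min,k_max scan range (defaults 2 and 12)
#' @param seed RNG seed for the k-means restarts
#' @param n_restarts restarts per k
#' @return list of class \code{ffasc_k_report}: \code{per_k} data.frame
#'   (k, outlier_status, avg_silhouette, ch_index, candidate),
#'   \code{labels} (list of label vectors by k), \code{selected_k}
#'   (NA if no k isolates the outgroup), \code{warnings}
#' @export
select_natural_k <- function(matrix, outlier_ids, k_min = 2L, k_max = 12L,
                             seed = 1L, n_restarts = 25L) {
  if (!length(outlier_ids) || !all(outlier_ids %in% rownames(matrix)))
    ffasc_error("ffasc_unknown_species_error",
                "outlier_ids must be a nonempty subset of the row names")
  ks <- seq.int(k_min, k_max)
  out_idx <- rownames(matrix) %in% outlier_ids
  status <- character(length(ks)); sil <- ch <- rep(NA_real_, length(ks))
  labels <- vector("list", length(ks)); names(labels) <- ks
  for (i in seq_along(ks)) {
    cl <- kmeans_cluster(matrix, ks[i], seed = seed + i, n_restarts = n_restarts)
    labels[[i]] <- cl$labels
    out_cl <- unique(cl$labels[out_idx])
    pure <- !any(cl$labels[!out_idx] %in% out_cl)
    status[i] <- if (!pure) "mixed"
                 else if (length(out_cl) == 1L) "exclusive_together"
                 else "split"
    sil[i] <- average_silhouette(matrix, cl)
    ch[i] <- if (ks[i] < nrow(matrix)) calinski_harabasz(matrix, cl) else NA_real_
  }
  first_tog <- which(status == "exclusive_together")[1]
  warnings <- character(0)
  candidate <- rep(FALSE, length(ks))
  selected_k <- NA_integer_
  if (is.na(first_tog)) {
    warnings <- "no k isolates the outgroup in a single exclusive cluster"
  } else {
    first_split <- which(status == "split" & seq_along(ks) > first_tog)[1]
    last <- if (is.na(first_split)) length(ks) else first_split
    candidate[first_tog:last] <- TRUE
    selected_k <- ks[candidate][which.max(sil[candidate])]
  }
  structure(list(per_k = data.frame(k = ks, outlier_status = status,
                                    avg_silhouette = sil, ch_index = ch,
                                    candidate = candidate),
                 labels = labels, selected_k = selected_k,
                 warnings = warnings),
            class = "ffasc_k_report")
}

#' @export
print.ffasc_k_report <- function(x, ...) {
  cat("ffasc natural-k scan\n")
  print(x$per_k, row.names = FALSE)
  cat(sprintf("selected k: %s\n", x$selected_k))
  if (length(x$warnings)) cat("warning:", x$warnings, sep = "\n  ")
  invisible(x)
}

#' Add tiny uniform noise to a matrix before heatmap clustering
#'
#' Perturbs every entry by \code{uniform(-0.5, 0.5) * 1e-10} to avoid
#' singular-matrix problems in correlation-based distances on constant
#' rows/columns. Deterministic given the seed; the perturbation never
#' exceeds 0.5e-10 in absolute value.
#'
#' @param matrix numeric matrix
#' @param seed integer RNG seed
#' @return perturbed matrix of the same shape
#' @export
heatmap_transform <- function(matrix, seed = 1L) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  matrix + (stats::runif(length(matrix)) - 0.5) * 1e-10
}

zscore <- function(v) {
  s <- stats::sd(v)
  if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
}

spearman_dist <- function(m) {
  # rows of m are observations; distance = 1 - Spearman rank correlation
  r <- suppressWarnings(stats::cor(t(m), method = "spearman"))
  if (anyNA(r)) {
    warning("constant row/column: undefined rank correlation, distance set to maximum (2)")
    r[is.na(r)] <- -1
  }
  stats::as.dist(1 - r)
}

#' Heatmap row/column ordering by rank-correlation average linkage
#'
#' Standardizes rows then columns (z-scores), computes
#' \code{1 - Spearman} correlation distances for both axes, clusters each
#' with average-linkage agglomeration and returns the dendrogram leaf
#' orders. Constant rows or columns (undefined correlation) are placed at
#' the maximum distance 2 with a warning.
#'
#' @param matrix numeric matrix, at least 2 x 2
#' @return list of class \code{ffasc_heatmap_layout}: \code{row_order},
#'   \code{column_order} (permutations), \code{row_hclust},
#'   \code{column_hclust}, \code{standardized} (the z-scored matrix)
#' @export
heatmap_order <- function(matrix) {
  stopifnot(nrow(matrix) >= 2L, ncol(matrix) >= 2L)
  z <- t(apply(matrix, 1, zscore))
  z <- apply(z, 2, zscore)
  dimnames(z) <- dimnames(matrix)
  hr <- stats::hclust(spearman_dist(z), method = "average")
  hc <- stats::hclust(spearman_dist(t(z)), method = "average")
  structure(list(row_order = hr$order, column_order = hc$order,
                 row_hclust = hr, column_hclust = hc, standardized = z),
            class = "ffasc_heatmap_layout")
}
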