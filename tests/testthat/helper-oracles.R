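# Independent brute-force oracles used to cross-check the implementation.

# per-entry category rule lookup, written as a plain switch
oracle_quantify_entry <- function(hitN, category) {
  switch(category,
         nOG = -hitN,
         pOG = if (hitN > 0) hitN else -1,
         rOG = hitN)
}

# silhouette by direct double loop over points and clusters
oracle_silhouette <- function(mat, labels) {
  n <- nrow(mat)
  d <- function(i, j) sqrt(sum((mat[i, ] - mat[j, ])^2))
  widths <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (!length(own)) { widths[i] <- 0; next }
    a <- mean(vapply(own, function(j) d(i, j), numeric(1)))
    b <- Inf
    for (g in setdiff(unique(labels), labels[i])) {
      other <- which(labels == g)
      b <- min(b, mean(vapply(other, function(j) d(i, j), numeric(1))))
    }
    widths[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(widths)
}

# CH index straight from sums of squares
oracle_ch <- function(mat, labels) {
  n <- nrow(mat); k <- length(unique(labels))
  grand <- colMeans(mat)
  W <- 0; B <- 0
  for (g in unique(labels)) {
    rows <- mat[labels == g, , drop = FALSE]
    cen <- colMeans(rows)
    for (i in seq_len(nrow(rows))) W <- W + sum((rows[i, ] - cen)^2)
    B <- B + nrow(rows) * sum((cen - grand)^2)
  }
  if (W == 0) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

# naive agglomerative average linkage: merge heights from the original
# pairwise distances, recomputing the group-average distance each step
oracle_average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  groups <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  avg <- function(g1, g2) mean(d[g1, g2])
  while (length(groups) > 1L) {
    best <- c(NA, NA); bh <- Inf
    for (i in seq_along(groups)) for (j in seq_len(i - 1L)) {
      h <- avg(groups[[i]], groups[[j]])
      if (h < bh) { bh <- h; best <- c(i, j) }
    }
    heights <- c(heights, bh)
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  heights
}

# exact Euclidean projection onto box + sum constraint by KKT active-set
# enumeration (feasible only for small m)
oracle_project <- function(v, lb, ub, s) {
  m <- length(v)
  best <- NULL; bestd <- Inf
  states <- expand.grid(rep(list(c("lb", "free", "ub")), m),
                        stringsAsFactors = FALSE)
  for (r in seq_len(nrow(states))) {
    st <- unlist(states[r, ])
    n_free <- sum(st == "free")
    w <- numeric(m)
    w[st == "lb"] <- lb; w[st == "ub"] <- ub
    if (n_free == 0) {
      if (abs(sum(w) - s) > 1e-9) next
    } else {
      lambda <- (s - sum(w[st != "free"]) - sum(v[st == "free"])) / n_free
      w[st == "free"] <- v[st == "free"] + lambda
      # KKT: free coords inside box, clipped coords pushed outward
      if (any(w[st == "free"] < lb - 1e-12) ||
          any(w[st == "free"] > ub + 1e-12)) next
      if (any(st == "lb") && any(v[st == "lb"] + lambda > lb + 1e-12)) next
      if (any(st == "ub") && any(v[st == "ub"] + lambda < ub - 1e-12)) next
    }
    dd <- sum((w - v)^2)
    if (dd < bestd) { bestd <- dd; best <- w }
  }
  best
}

# count-based comparison oracle: per-OG class by explicit cell counting
oracle_compare <- function(a, b) {
  b <- b[rownames(a), colnames(a), drop = FALSE]
  out <- data.frame(og_id = colnames(a), diff_sum = NA_real_,
                    class = NA_character_, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(a))) {
    diffs <- a[, j] - b[, j]
    out$diff_sum[j] <- sum(diffs)
    out$class[j] <-
      if (all(diffs == 0)) "identical"
      else if (all(diffs >= 0)) "a_only"
      else if (all(diffs <= 0)) "b_only"
      else "mixed"
  }
  out
}

random_criteria_matrix <- function(n, catalog, max_hit = 10L, seed = 1L) {
  set.seed(seed)
  m <- length(og_ids(catalog))
  hits <- matrix(sample(0:max_hit, n * m, replace = TRUE), n, m,
                 dimnames = list(sprintf("s%02d", seq_len(n)), og_ids(catalog)))
  hits
}
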