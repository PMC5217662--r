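test_that("k-means handles degenerate k and recovers planted blobs", {
  m <- matrix(rnorm(40), 10, 4, dimnames = list(sprintf("s%02d", 1:10), NULL))
  one <- kmeans_cluster(m, 1, seed = 2)
  expect_true(all(one$labels == 1L))
  alln <- kmeans_cluster(m, 10, seed = 2)
  expect_equal(sort(unname(alln$labels)), 1:10)
  expect_equal(alln$tot_withinss, 0)
  expect_error(kmeans_cluster(m, 11, seed = 2), class = "ffasc_domain_error")

  blobs <- rbind(matrix(rnorm(40, 0, 0.2), 10, 4),
                 matrix(rnorm(40, 8, 0.2), 10, 4))
  rownames(blobs) <- sprintf("b%02d", 1:20)
  cl <- kmeans_cluster(blobs, 2, seed = 3)
  expect_equal(length(unique(cl$labels[1:10])), 1L)
  expect_equal(length(unique(cl$labels[11:20])), 1L)
  expect_false(cl$labels[1] == cl$labels[11])
  expect_identical(kmeans_cluster(blobs, 2, seed = 3)$labels, cl$labels)
})

test_that("silhouette matches the hand formula and brute-force oracle", {
  # two tight, far-apart pairs
  pairs <- matrix(c(0, 0, 0, 0.1, 10, 0, 10, 0.1), 4, 2, byrow = TRUE)
  lab <- c(1, 1, 2, 2)
  s <- average_silhouette(pairs, lab)
  expect_gt(s, 0.9)
  # hand formula on the 4 points: a = 0.1, b = mean(d to other pair)
  d <- as.matrix(dist(pairs))
  widths <- sapply(1:4, function(i) {
    a <- d[i, setdiff(which(lab == lab[i]), i)]
    b <- mean(d[i, lab != lab[i]])
    (b - a) / max(a, b)
  })
  expect_equal(s, mean(widths), tolerance = 1e-12)

  ident <- matrix(1, 6, 3)
  expect_equal(average_silhouette(ident, rep(1:2, each = 3)), 0)
  expect_error(average_silhouette(pairs, rep(1, 4)),
               class = "ffasc_domain_error")

  set.seed(62)
  for (r in 1:10) {
    n <- sample(6:30, 1)
    mat <- matrix(rnorm(n * 3), n, 3)
    lab <- sample(1:3, n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(average_silhouette(mat, lab), oracle_silhouette(mat, lab),
                 tolerance = 1e-9)
  }
})

test_that("silhouette agrees with the cluster package on regular partitions", {
  set.seed(77)
  mat <- matrix(rnorm(60), 20, 3)
  lab <- sample(1:4, 20, replace = TRUE)
  sil <- cluster::silhouette(lab, dist(mat))
  expect_equal(average_silhouette(mat, lab), mean(sil[, "sil_width"]),
               tolerance = 1e-9)
})

test_that("Calinski-Harabasz matches its formula and grows with separation", {
  set.seed(83)
  mat <- matrix(rnorm(60), 20, 3)
  lab <- sample(1:4, 20, replace = TRUE)
  expect_equal(calinski_harabasz(mat, lab), oracle_ch(mat, lab),
               tolerance = 1e-9)

  base <- matrix(c(0, 0, 1, 0, 5, 0, 6, 0), 4, 2, byrow = TRUE)
  lab <- c(1, 1, 2, 2)
  ch1 <- calinski_harabasz(base, lab)
  wider <- base; wider[3:4, 1] <- wider[3:4, 1] + 5
  expect_gt(calinski_harabasz(wider, lab), ch1)

  collapsed <- matrix(rep(c(0, 0, 1, 1), each = 2), 4, 2)
  expect_equal(calinski_harabasz(collapsed, c(1, 1, 2, 2)), Inf)
})

test_that("natural-k scan isolates the planted outgroup and recovers k", {
  cl <- generate_clustered_species(5, cluster_sizes = 25, n_outliers = 3,
                                   seed = 1)
  rep <- select_natural_k(cl$matrix, cl$outlier_ids, 2, 12, seed = 1)
  st <- rep$per_k$outlier_status
  expect_equal(rep$selected_k, 6L)                 # 5 blobs + outgroup
  expect_true(rep$per_k$candidate[rep$per_k$k == 6])
  first_tog <- which(st == "exclusive_together")[1]
  expect_true(all(st[seq_len(first_tog - 1)] == "mixed"))
  expect_true(any(st == "split"))
  expect_gt(which(st == "split")[1], first_tog)    # together before split

  # statuses are internally consistent on unstructured data
  set.seed(19)
  noise <- matrix(rnorm(40 * 4), 40, 4,
                  dimnames = list(sprintf("n%02d", 1:40), NULL))
  r2 <- select_natural_k(noise, c("n01", "n02"), 2, 8, seed = 19)
  expect_true(all(r2$per_k$outlier_status %in%
                    c("mixed", "exclusive_together", "split")))
  expect_true(all(r2$per_k$avg_silhouette >= -1 & r2$per_k$avg_silhouette <= 1))
  if (is.na(r2$selected_k)) expect_true(length(r2$warnings) > 0)
  else expect_true(r2$selected_k %in% r2$per_k$k[r2$per_k$candidate])
})

test_that("outliers identical to each other and remote separate at k = 2", {
  mat <- rbind(matrix(rnorm(30, 0, 1), 10, 3),
               matrix(rep(c(50, 50, 50), each = 3), 3, 3))
  rownames(mat) <- c(sprintf("s%02d", 1:10), sprintf("o%d", 1:3))
  rep <- select_natural_k(mat, sprintf("o%d", 1:3), 2, 4, seed = 4)
  expect_equal(rep$per_k$outlier_status[1], "exclusive_together")
})

test_that("heatmap noise is tiny, deterministic and seed-controlled", {
  m <- matrix(rnorm(30), 5, 6)
  t1 <- heatmap_transform(m, seed = 9)
  expect_lte(max(abs(t1 - m)), 0.5e-10)
  expect_identical(heatmap_transform(m, seed = 9), t1)
  expect_false(identical(heatmap_transform(m, seed = 10), t1))
  z <- heatmap_transform(matrix(0, 3, 3), seed = 1)
  expect_true(all(z >= -0.5e-10 & z <= 0.5e-10))
})

test_that("heatmap ordering gives valid permutations with duplicates adjacent", {
  # 2 x 2 is inherently degenerate for rank correlation (two-point rows);
  # the layout must still be a valid permutation, with the max-distance
  # fallback warning
  small <- matrix(c(1, 2, 3, 4), 2, 2)
  lay <- suppressWarnings(heatmap_order(small))
  expect_setequal(lay$row_order, 1:2)
  expect_setequal(lay$column_order, 1:2)

  set.seed(31)
  m <- matrix(rnorm(48), 6, 8)
  m[4, ] <- m[2, ]                                  # duplicated row
  lay <- heatmap_order(m)
  pos <- match(c(2, 4), lay$row_order)
  expect_equal(abs(diff(pos)), 1)                   # zero-distance pair adjacent

  # linkage heights equal the brute-force average-linkage oracle
  z <- lay$standardized
  d <- 1 - cor(t(z), method = "spearman")
  expect_equal(sort(lay$row_hclust$height),
               sort(oracle_average_linkage_heights(d)), tolerance = 1e-9)

  # a flat matrix standardizes to all-zero rows: rank correlation is
  # undefined everywhere and every distance falls back to the maximum
  expect_warning(expect_warning(heatmap_order(matrix(5, 4, 5)), "constant"),
                 "constant")   # both axes fall back
})
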