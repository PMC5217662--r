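toy_blast <- c(
  "tesA\tsp1_p01\t80.0\t100\t20\t0\t1\t100\t1\t100\t1e-30\t200",
  "tesA\tsp1_p02\t60.0\t100\t40\t0\t1\t100\t1\t100\t2e-05\t90",
  "fabD\tsp1_p03\t55.0\t100\t45\t0\t1\t100\t1\t100\t0.002\t40")

test_that("BLAST tabular parsing maps fields 1, 2 and 11", {
  hits <- parse_blast_tabular(toy_blast, "sp1")
  expect_equal(nrow(hits), 3L)
  expect_equal(hits$query_protein_id, c("tesA", "tesA", "fabD"))
  expect_equal(hits$target_protein_id, c("sp1_p01", "sp1_p02", "sp1_p03"))
  expect_equal(hits$e_value, c(1e-30, 2e-5, 2e-3))
  expect_true(all(hits$target_species_id == "sp1"))

  expect_equal(nrow(parse_blast_tabular(character(0), "sp1")), 0L)
  expect_error(parse_blast_tabular("tesA\tsp1_p01\t1e-5", "sp1"),
               class = "ffasc_parse_error")
  bad <- sub("1e-30", "not-a-number", toy_blast[1])
  expect_error(parse_blast_tabular(bad, "sp1"), class = "ffasc_parse_error")
})

test_that("domtblout parsing extracts targets and version-stripped accessions", {
  lines <- c(
    "# comment",
    "sp1_p01 -  300 Acyl_transf PF00108.21 120 1e-40 150.0 0.1 1 2 1e-42 1e-40 149.0 0.1 1 120 10 129 8 131 0.98 -",
    "sp1_p01 -  300 Thioester   PF01234.5  80  1e-20  70.0 0.0 2 2 1e-22 1e-20  69.0 0.0 1  80 200 279 198 281 0.95 -")
  ann <- parse_domtblout(lines)
  expect_equal(nrow(ann), 2L)
  expect_equal(ann$target_protein_id, c("sp1_p01", "sp1_p01"))
  expect_equal(ann$domain_accession, c("PF00108", "PF01234"))
  expect_true(all(ann$meets_trusted_cutoff))
  expect_equal(nrow(parse_domtblout(c("# only", "# comments"))), 0L)
})

test_that("e-value filtering keeps the inclusive boundary and is idempotent", {
  hits <- parse_blast_tabular(c(
    "q\tt1\t1\t1\t1\t1\t1\t1\t1\t1\t1e-5\t1",
    "q\tt2\t1\t1\t1\t1\t1\t1\t1\t1\t1e-4\t1",
    "q\tt3\t1\t1\t1\t1\t1\t1\t1\t1\t1e-3\t1"), "s")
  kept <- filter_by_evalue(hits)
  expect_equal(kept$target_protein_id, c("t1", "t2"))
  expect_identical(filter_by_evalue(kept), kept)
  expect_equal(nrow(filter_by_evalue(hits[0, ])), 0L)
  expect_identical(filter_by_evalue(hits, 10), hits)
})

test_that("domain-completeness keeps only targets carrying every required domain", {
  # one query with two required domains; x has both, y and z miss one
  catalog <- og_catalog(
    data.frame(og_id = "OG1", category = "pOG", action_label = "insert"),
    data.frame(protein_id = "A", og_id = "OG1"),
    list(A = c("PFdomain1", "PFdomain2")))
  hits <- data.frame(query_protein_id = "A",
                     target_protein_id = c("x", "y", "z"),
                     target_species_id = "s", e_value = 1e-20,
                     stringsAsFactors = FALSE)
  ann <- data.frame(
    target_protein_id = c("x", "x", "y", "z"),
    domain_accession = c("PFdomain1", "PFdomain2", "PFdomain1", "PFdomain2"),
    meets_trusted_cutoff = TRUE, stringsAsFactors = FALSE)
  kept <- select_domain_complete_hits(hits, ann, catalog)
  expect_equal(kept$target_protein_id, "x")

  # vacuous requirement keeps everything
  cat2 <- og_catalog(catalog$ogs, catalog$members)
  expect_equal(nrow(select_domain_complete_hits(hits, ann, cat2)), 3L)

  # sub-threshold annotation rows are ignored
  ann$meets_trusted_cutoff[2] <- FALSE
  expect_equal(nrow(select_domain_complete_hits(hits, ann, catalog)), 0L)

  expect_error(select_domain_complete_hits(
    transform(hits, query_protein_id = "unknown"), ann, catalog),
    class = "ffasc_unknown_protein_error")
})

test_that("domain filter equals the per-hit subset-inclusion oracle", {
  set.seed(71)
  catalog <- generate_catalog(10, members_per_og = 2, domains_per_member = 2,
                              seed = 71)
  queries <- catalog$members$protein_id
  pool <- unique(unlist(catalog$domain_requirements))
  targets <- sprintf("t%03d", 1:200)
  have <- lapply(targets, function(t) sample(pool, sample(0:4, 1)))
  names(have) <- targets
  hits <- data.frame(
    query_protein_id = sample(queries, 200, replace = TRUE),
    target_protein_id = sample(targets, 200, replace = TRUE),
    target_species_id = "s", e_value = 1e-10, stringsAsFactors = FALSE)
  ann <- data.frame(
    target_protein_id = rep(targets, lengths(have)),
    domain_accession = unlist(have),
    meets_trusted_cutoff = TRUE, stringsAsFactors = FALSE)
  kept <- select_domain_complete_hits(hits, ann, catalog)
  oracle <- vapply(seq_len(nrow(hits)), function(i) {
    req <- catalog$domain_requirements[[hits$query_protein_id[i]]]
    all(req %in% have[[hits$target_protein_id[i]]])
  }, logical(1))
  expect_identical(kept, hits[oracle, ])
})

test_that("hit matrix counts distinct query-target pairs per OG", {
  catalog <- og_catalog(
    data.frame(og_id = "OG1", category = "rOG", action_label = "present"),
    data.frame(protein_id = c("m1", "m2"), og_id = c("OG1", "OG1")))
  none <- build_hit_matrix(
    data.frame(query_protein_id = character(0),
               target_protein_id = character(0),
               target_species_id = character(0), e_value = numeric(0)),
    generate_catalog(49, seed = 2), sprintf("s%d", 1:3))
  expect_equal(dim(none), c(3L, 49L))
  expect_true(all(none == 0L))

  # two members hitting the same target protein count as two pairs
  hits <- data.frame(query_protein_id = c("m1", "m2", "m1"),
                     target_protein_id = c("t", "t", "t"),
                     target_species_id = "s1", e_value = 1e-9,
                     stringsAsFactors = FALSE)  # third row = duplicate HSP
  mat <- build_hit_matrix(hits, catalog, c("s1", "s2"))
  expect_equal(mat["s1", "OG1"], 2L)
  expect_equal(mat["s2", "OG1"], 0L)
  # alternative counting unit: distinct targets only
  expect_equal(build_hit_matrix(hits, catalog, "s1",
                                count_unit = "targets")[1, 1], 1L)

  expect_error(build_hit_matrix(transform(hits, target_species_id = "nope"),
                                catalog, c("s1", "s2")),
               class = "ffasc_unknown_species_error")
})

test_that("removing a hit never increases any matrix entry", {
  catalog <- generate_catalog(6, members_per_og = 2, seed = 8)
  b <- generate_fixture_bundle(catalog, 4, seed = 8)
  hits <- do.call(rbind, lapply(b$species_ids, function(s)
    parse_blast_tabular(b$blast_files[[s]], s)))
  full <- build_hit_matrix(hits, catalog, b$species_ids)
  set.seed(8)
  for (drop in sample(nrow(hits), 10)) {
    less <- build_hit_matrix(hits[-drop, ], catalog, b$species_ids)
    expect_true(all(less <= full))
  }
})
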