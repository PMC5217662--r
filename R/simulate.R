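with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  force(code)
}

#' Generate a synthetic OG catalog
#'
#' Builds a catalog with the requested shape: category counts follow the
#' given fractions (largest-remainder rounding, so they sum to
#' \code{n_ogs}), every OG gets \code{members_per_og} member proteins and
#' every member \code{domains_per_member} required Pfam-style accessions.
#' Action labels follow the category (knockout for nOG, overexpression for
#' pOG, present for rOG). Deterministic given the seed.
#'
#' @param n_ogs number of OGs (>= 1)
#' @param category_fractions named numeric vector over nOG/pOG/rOG summing
#'   to 1; default matches the shipped catalog's 13/24/12 split
#' @param members_per_og members per OG (default 1)
#' @param domains_per_member required domains per member (default 2)
#' @param seed integer seed
#' @return an \code{ffasc_catalog}
#' @export
generate_catalog <- function(n_ogs,
                             category_fractions = c(nOG = 13, pOG = 24,
                                                    rOG = 12) / 49,
                             members_per_og = 1L, domains_per_member = 2L,
                             seed = 1L) {
  if (n_ogs < 1L)
    ffasc_error("ffasc_domain_error", "n_ogs must be >= 1")
  stopifnot(abs(sum(category_fractions) - 1) < 1e-9,
            setequal(names(category_fractions), OG_CATEGORIES))
  raw <- category_fractions[OG_CATEGORIES] * n_ogs
  cnt <- floor(raw)
  rem <- n_ogs - sum(cnt)
  if (rem > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1
  }
  with_seed(seed, {
    categories <- rep(OG_CATEGORIES, times = cnt)
    action <- c(nOG = "knockout", pOG = "overexpression",
                rOG = "present")[categories]
    ogs <- data.frame(og_id = sprintf("synOG%04d", seq_len(n_ogs)),
                      category = categories, action_label = unname(action),
                      stringsAsFactors = FALSE)
    members <- data.frame(
      protein_id = sprintf("synOG%04d_p%02d",
                           rep(seq_len(n_ogs), each = members_per_og),
                           rep(seq_len(members_per_og), n_ogs)),
      og_id = rep(ogs$og_id, each = members_per_og),
      stringsAsFactors = FALSE)
    dr <- lapply(seq_len(nrow(members)), function(i)
      if (domains_per_member == 0L) character(0)
      else sprintf("PF%05d", sample.int(99999L, domains_per_member)))
    names(dr) <- members$protein_id
    og_catalog(ogs, members, dr)
  })
}

blast_line <- function(q, t, evalue) {
  paste(q, t, "75.00", "180", "45", "0", "1", "180", "1", "180",
        format(evalue, scientific = TRUE), "250.0", sep = "\t")
}

domtbl_line <- function(target, accession) {
  # domtblout layout: target name/acc/tlen, query name/acc/qlen, then scores
  paste(target, "-", "300", sub("\\..*$", "", accession),
        paste0(accession, ".21"), "120",
        "1e-40", "150.0", "0.1", "1", "1", "1e-42", "1e-40", "149.0", "0.1",
        "1", "120", "10", "129", "8", "131", "0.98", "-")
}

#' Generate a full synthetic screening fixture with known ground truth
#'
#' Plants a species-by-OG hit-count matrix (Poisson counts with per-category
#' means), then renders it as syntactically valid BLAST outfmt-6 and HMMER
#' domtblout payloads per species: every planted (query, target) pair gets a
#' passing e-value and complete domain annotations. Decoy hits that must be
#' removed by exactly one filter are injected on top: e-value decoys exceed
#' the 1e-4 threshold but are domain-complete; domain decoys pass the
#' e-value filter but lack one required domain. Replaying the parse/filter/
#' count pipeline on the payloads reproduces the planted matrix exactly.
#'
#' @param catalog an \code{ffasc_catalog}
#' @param n_species number of screened species
#' @param hit_rate_params named Poisson means per category
#'   (default \code{c(nOG = 0.5, pOG = 1.5, rOG = 1.0)})
#' @param decoy_params list with counts \code{n_evalue} and \code{n_domain}
#'   (defaults 0); domain decoys require at least one catalog member with a
#'   nonempty domain requirement
#' @param seed integer seed
#' @return list of class \code{ffasc_fixture_bundle}: \code{catalog},
#'   \code{species_ids}, \code{ground_truth} (integer matrix),
#'   \code{blast_files} and \code{domtbl_files} (named lists of text lines
#'   per species), \code{decoy_log} (data.frame with the filter each decoy
#'   must fail)
#' @export
generate_fixture_bundle <- function(catalog, n_species,
                                    hit_rate_params = c(nOG = 0.5, pOG = 1.5,
                                                        rOG = 1.0),
                                    decoy_params = list(n_evalue = 0L,
                                                        n_domain = 0L),
                                    seed = 1L) {
  with_seed(seed, {
    species <- sprintf("sp%03d", seq_len(n_species))
    ogs <- og_ids(catalog)
    m <- length(ogs)
    means <- hit_rate_params[catalog$ogs$category]
    gt <- matrix(stats::rpois(n_species * m, rep(means, each = n_species)),
                 n_species, m, dimnames = list(species, ogs))
    members_by_og <- split(catalog$members$protein_id, catalog$members$og_id)
    blast <- stats::setNames(vector("list", n_species), species)
    domtbl <- stats::setNames(vector("list", n_species), species)
    counter <- 0L
    for (i in seq_len(n_species)) {
      blines <- character(0); dlines <- character(0)
      for (j in seq_len(m)) {
        h <- gt[i, j]
        if (h == 0L) next
        mem <- members_by_og[[ogs[j]]]
        for (t in seq_len(h)) {
          counter <- counter + 1L
          q <- mem[(t - 1L) %% length(mem) + 1L]
          tgt <- sprintf("%s_t%06d", species[i], counter)
          blines <- c(blines, blast_line(q, tgt, 10^-stats::runif(1, 6, 40)))
          if (stats::runif(1) < 0.15)  # second HSP for the same pair
            blines <- c(blines, blast_line(q, tgt, 10^-stats::runif(1, 5, 20)))
          dlines <- c(dlines, vapply(catalog$domain_requirements[[q]],
                                     function(a) domtbl_line(tgt, a), ""))
        }
      }
      blast[[i]] <- blines
      domtbl[[i]] <- dlines
    }
    n_ev <- decoy_params$n_evalue %||% 0L
    n_dom <- decoy_params$n_domain %||% 0L
    with_domains <- names(Filter(length, catalog$domain_requirements))
    if (n_dom > 0L && !length(with_domains))
      ffasc_error("ffasc_infeasible_error",
                  "domain decoys need a catalog member with required domains")
    log <- list()
    for (d in seq_len(n_ev + n_dom)) {
      type <- if (d <= n_ev) "evalue" else "domain"
      i <- sample.int(n_species, 1L)
      q <- if (type == "domain") sample(with_domains, 1L)
           else sample(catalog$members$protein_id, 1L)
      counter <- counter + 1L
      tgt <- sprintf("%s_d%06d", species[i], counter)
      if (type == "evalue") {
        blast[[i]] <- c(blast[[i]], blast_line(q, tgt, 10^-stats::runif(1, 0.5, 3.9)))
        domtbl[[i]] <- c(domtbl[[i]], vapply(catalog$domain_requirements[[q]],
                                             function(a) domtbl_line(tgt, a), ""))
      } else {
        blast[[i]] <- c(blast[[i]], blast_line(q, tgt, 10^-stats::runif(1, 6, 40)))
        req <- catalog$domain_requirements[[q]]
        keep <- setdiff(req, sample(req, 1L))   # one required domain missing
        domtbl[[i]] <- c(domtbl[[i]], vapply(keep, function(a) domtbl_line(tgt, a), ""))
      }
      log[[d]] <- data.frame(species_id = species[i], query_protein_id = q,
                             target_protein_id = tgt, filter = type,
                             stringsAsFactors = FALSE)
    }
    structure(list(catalog = catalog, species_ids = species, ground_truth = gt,
                   blast_files = blast, domtbl_files = domtbl,
                   decoy_log = if (length(log)) do.call(rbind, log)
                               else data.frame(species_id = character(0),
                                               query_protein_id = character(0),
                                               target_protein_id = character(0),
                                               filter = character(0))),
              class = "ffasc_fixture_bundle")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Replay the screening pipeline on a fixture bundle
#'
#' Parses the bundle's BLAST and domtblout payloads, applies the e-value and
#' domain-completeness filters and counts hits; used to check that the
#' reconstruction equals the planted ground truth.
#'
#' @param bundle an \code{ffasc_fixture_bundle}
#' @param evalue_threshold e-value cutoff (default 1e-4)
#' @return integer hit matrix comparable to \code{bundle$ground_truth}
#' @export
replay_pipeline <- function(bundle, evalue_threshold = 1e-4) {
  hits <- do.call(rbind, lapply(bundle$species_ids, function(s)
    parse_blast_tabular(bundle$blast_files[[s]], s)))
  ann <- do.call(rbind, lapply(bundle$species_ids, function(s)
    parse_domtblout(bundle$domtbl_files[[s]])))
  hits <- filter_by_evalue(hits, evalue_threshold)
  hits <- select_domain_complete_hits(hits, ann, bundle$catalog)
  build_hit_matrix(hits, bundle$catalog, bundle$species_ids)
}

#' Generate a criteria matrix with a planted reference pair
#'
#' Emulates the optimization setting: a positive and a negative reference
#' strain whose criteria rows differ exactly by \code{planted_delta}, among
#' background species drawn around the pair's midpoint.
#'
#' @param catalog an \code{ffasc_catalog} (provides OG ids / columns)
#' @param n_species total species including the two references (>= 2)
#' @param planted_delta numeric vector of per-OG effect sizes (length =
#'   number of OGs)
#' @param seed integer seed
#' @param background_sd spread of the background species around the
#'   midpoint (default 0.5)
#' @return list: \code{criteria} (matrix), \code{pos_id}, \code{neg_id}
#' @export
generate_reference_pair <- function(catalog, n_species, planted_delta,
                                    seed = 1L, background_sd = 0.5) {
  m <- length(og_ids(catalog))
  stopifnot(length(planted_delta) == m, n_species >= 2L)
  with_seed(seed, {
    mid <- stats::rnorm(m, 0, 1)
    rows <- rbind(pos_ref = mid + planted_delta / 2,
                  neg_ref = mid - planted_delta / 2)
    if (n_species > 2L) {
      bg <- t(vapply(seq_len(n_species - 2L),
                     function(i) mid + stats::rnorm(m, 0, background_sd),
                     numeric(m)))
      rownames(bg) <- sprintf("bg%03d", seq_len(n_species - 2L))
      rows <- rbind(rows, bg)
    }
    colnames(rows) <- og_ids(catalog)
    list(criteria = rows, pos_id = "pos_ref", neg_id = "neg_ref")
  })
}

#' Generate clustered species with a planted outgroup
#'
#' Emulates the cluster-number validation layout: \code{k} Gaussian blobs of
#' in-group species at mutual center distance \code{separation}, plus a
#' small outgroup placed well away from every blob but mutually closer to
#' each other (internal spread \code{outlier_sd}), mimicking taxonomically
#' distinct outliers used to read off the natural cluster count.
#'
#' @param k number of in-group blobs (>= 2)
#' @param cluster_sizes integer vector of blob sizes (length k, or scalar)
#' @param separation distance between blob centers (> 0; default 6)
#' @param n_outliers outgroup size (default 3)
#' @param seed integer seed
#' @param n_features dimensionality (default 8; raised to k if smaller)
#' @param outlier_sd outgroup internal spread (default 2)
#' @param outlier_factor outgroup center distance in units of
#'   \code{separation} (default 1)
#' @return list: \code{matrix} (with rownames), \code{labels} (planted blob
#'   labels, outgroup = k + 1), \code{outlier_ids}
#' @export
generate_clustered_species <- function(k, cluster_sizes = 25L, separation = 6,
                                       n_outliers = 3L, seed = 1L,
                                       n_features = 8L, outlier_sd = 2,
                                       outlier_factor = 1) {
  stopifnot(k >= 2L, separation > 0)
  if (length(cluster_sizes) == 1L) cluster_sizes <- rep(cluster_sizes, k)
  stopifnot(length(cluster_sizes) == k)
  m <- max(n_features, k)
  with_seed(seed, {
    centers <- matrix(0, k, m)
    centers[cbind(seq_len(k), seq_len(k))] <- separation / sqrt(2)
    pts <- do.call(rbind, lapply(seq_len(k), function(g)
      matrix(stats::rnorm(cluster_sizes[g] * m, 0, 1), ncol = m) +
        matrix(centers[g, ], cluster_sizes[g], m, byrow = TRUE)))
    labels <- rep(seq_len(k), cluster_sizes)
    if (n_outliers > 0L) {
      out_center <- rep(-outlier_factor * separation / sqrt(m), m)
      outs <- matrix(stats::rnorm(n_outliers * m, 0, outlier_sd), ncol = m) +
        matrix(out_center, n_outliers, m, byrow = TRUE)
      pts <- rbind(pts, outs)
      labels <- c(labels, rep(k + 1L, n_outliers))
    }
    ids <- c(sprintf("sp%03d", seq_len(sum(cluster_sizes))),
             if (n_outliers > 0L) sprintf("out%02d", seq_len(n_outliers)))
    rownames(pts) <- ids
    list(matrix = pts, labels = stats::setNames(labels, ids),
         outlier_ids = ids[labels == k + 1L])
  })
}
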