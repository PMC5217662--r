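#' Parse BLAST tabular (outfmt 6) homology hits
#'
#' Reads the 12-column tab-separated BLAST output format. Only
#' \code{qseqid} (field 1), \code{sseqid} (field 2) and \code{evalue}
#' (field 11) are used; the remaining columns are ignored. Line order is
#' preserved.
#'
#' @param lines character vector of outfmt-6 lines, or a file path
#' @param species_id identifier of the screened proteome the hits belong to
#' @return data.frame with columns \code{query_protein_id},
#'   \code{target_protein_id}, \code{target_species_id}, \code{e_value}
#' @export
parse_blast_tabular <- function(lines, species_id) {
  if (length(lines) == 1L && file.exists(lines)) lines <- readLines(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(query_protein_id = character(0),
                      target_protein_id = character(0),
                      target_species_id = character(0),
                      e_value = numeric(0), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L))
    ffasc_error("ffasc_parse_error", sprintf(
      "BLAST tabular line %d has %d fields (>= 12 required)",
      which(nf < 12L)[1], nf[which(nf < 12L)[1]]))
  ev <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 11L)))
  if (anyNA(ev))
    ffasc_error("ffasc_parse_error", sprintf(
      "BLAST tabular line %d: non-numeric e-value", which(is.na(ev))[1]))
  data.frame(query_protein_id = vapply(fields, `[[`, "", 1L),
             target_protein_id = vapply(fields, `[[`, "", 2L),
             target_species_id = species_id,
             e_value = ev, stringsAsFactors = FALSE)
}

#' Parse HMMER domtblout domain annotations
#'
#' Reads HMMER's per-domain table. The target protein id is taken from
#' column 1 and the matched domain family accession from column 5 (the query
#' HMM accession, as produced by \code{hmmsearch --domtblout} against protein
#' sequences); version suffixes (\code{.NN}) are stripped so that
#' \code{PF00108.21} matches a required accession \code{PF00108}. Rows are
#' assumed to have been produced with the model's trusted cutoff (HMMER
#' \code{--cut_tc}) so every row marks a trusted domain occurrence; a
#' \code{meets_trusted_cutoff} flag is carried for producers that emit
#' sub-threshold rows.
#'
#' @param lines character vector of domtblout lines, or a file path
#' @param meets_trusted_cutoff default flag value for parsed rows
#' @return data.frame with columns \code{target_protein_id},
#'   \code{domain_accession}, \code{meets_trusted_cutoff}
#' @export
parse_domtblout <- function(lines, meets_trusted_cutoff = TRUE) {
  if (length(lines) == 1L && file.exists(lines)) lines <- readLines(lines)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(target_protein_id = character(0),
                      domain_accession = character(0),
                      meets_trusted_cutoff = logical(0),
                      stringsAsFactors = FALSE))
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- lengths(fields)
  if (any(nf < 5L))
    ffasc_error("ffasc_parse_error", sprintf(
      "domtblout line %d has %d fields (>= 5 required)",
      which(nf < 5L)[1], nf[which(nf < 5L)[1]]))
  acc <- sub("\\.[0-9]+$", "", vapply(fields, `[[`, "", 5L))
  data.frame(target_protein_id = vapply(fields, `[[`, "", 1L),
             domain_accession = acc,
             meets_trusted_cutoff = meets_trusted_cutoff,
             stringsAsFactors = FALSE)
}

#' Filter homology hits by e-value
#'
#' Retains hits with \code{e_value <= threshold} (inclusive boundary),
#' preserving order. Idempotent.
#'
#' @param hits data.frame as returned by \code{\link{parse_blast_tabular}}
#' @param threshold e-value cutoff, default \code{1e-4}
#' @return filtered data.frame
#' @export
filter_by_evalue <- function(hits, threshold = 1e-4) {
  stopifnot(threshold > 0)
  hits[hits$e_value <= threshold, , drop = FALSE]
}

#' Apply the domain-completeness filter to homology hits
#'
#' A hit of catalog protein \code{q} against target protein \code{t} is kept
#' only if the set of trusted domain accessions annotated on \code{t} is a
#' superset of the domain families required for \code{q}: a homolog missing
#' any required domain is discarded as a weak hit. Queries with an empty
#' required set keep all their hits.
#'
#' @param hits data.frame of homology hits
#' @param annotations data.frame as returned by \code{\link{parse_domtblout}};
#'   rows with \code{meets_trusted_cutoff} FALSE are ignored
#' @param catalog an \code{ffasc_catalog} providing the required domains
#' @return filtered data.frame, original order preserved
#' @export
select_domain_complete_hits <- function(hits, annotations, catalog) {
  unknown <- setdiff(hits$query_protein_id, names(catalog$member_index))
  if (length(unknown))
    ffasc_error("ffasc_unknown_protein_error", sprintf(
      "hit references protein(s) not in catalog: %s",
      paste(unique(unknown), collapse = ", ")))
  if (!nrow(hits)) return(hits)
  ann <- annotations[annotations$meets_trusted_cutoff, , drop = FALSE]
  have <- split(ann$domain_accession, ann$target_protein_id)
  keep <- vapply(seq_len(nrow(hits)), function(i) {
    req <- catalog$domain_requirements[[hits$query_protein_id[i]]]
    if (!length(req)) return(TRUE)
    all(req %in% have[[hits$target_protein_id[i]]])
  }, logical(1))
  hits[keep, , drop = FALSE]
}

#' Build the species-by-OG hit-count matrix
#'
#' Entry (i, j) is hitN: the number of distinct (query protein, target
#' protein) pairs among the filtered hits whose query belongs to OG j and
#' whose target species is i. Multiple HSPs for the same pair collapse to
#' one. With \code{count_unit = "targets"} distinct target proteins per OG
#' are counted instead (a target hit by two members of one OG counts once).
#'
#' @param hits data.frame of hits already passed through the e-value and
#'   domain-completeness filters
#' @param catalog an \code{ffasc_catalog}; its OG order defines column order
#' @param species_ids character vector of row ids; species without hits get
#'   all-zero rows
#' @param count_unit \code{"pairs"} (default) or \code{"targets"}
#' @return integer matrix with \code{species_ids} rownames and OG id colnames
#' @export
build_hit_matrix <- function(hits, catalog, species_ids,
                             count_unit = c("pairs", "targets")) {
  count_unit <- match.arg(count_unit)
  unknown_sp <- setdiff(hits$target_species_id, species_ids)
  if (length(unknown_sp))
    ffasc_error("ffasc_unknown_species_error", sprintf(
      "hit references species not in species_ids: %s",
      paste(unique(unknown_sp), collapse = ", ")))
  unknown_q <- setdiff(hits$query_protein_id, names(catalog$member_index))
  if (length(unknown_q))
    ffasc_error("ffasc_unknown_protein_error", sprintf(
      "hit references protein(s) not in catalog: %s",
      paste(unique(unknown_q), collapse = ", ")))
  ogs <- og_ids(catalog)
  mat <- matrix(0L, nrow = length(species_ids), ncol = length(ogs),
                dimnames = list(species_ids, ogs))
  if (nrow(hits)) {
    og_of <- catalog$member_index[hits$query_protein_id]
    key <- if (count_unit == "pairs")
      paste(hits$target_species_id, og_of, hits$query_protein_id,
            hits$target_protein_id, sep = "\r")
    else
      paste(hits$target_species_id, og_of, hits$target_protein_id, sep = "\r")
    dedup <- !duplicated(key)
    tab <- table(factor(hits$target_species_id[dedup], levels = species_ids),
                 factor(og_of[dedup], levels = ogs))
    mat[] <- as.integer(tab)
  }
  mat
}

#' Read or write a hit matrix as labeled TSV
#'
#' Row names are species ids, header holds OG ids (catalog order).
#' @param mat integer matrix
#' @param path file path
#' @return for read: the matrix; for write: \code{path}, invisibly
#' @export
write_hit_matrix <- function(mat, path) {
  df <- data.frame(species_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hit_matrix
#' @export
read_hit_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
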