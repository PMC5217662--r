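OG_CATEGORIES <- c("nOG", "pOG", "rOG")
OG_ACTIONS <- c("present", "overexpression", "insert",
                "knockout", "knockdown", "underexpression")

ffasc_error <- function(subclass, msg, ...) {
  stop(structure(
    class = c(subclass, "ffasc_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Construct an orthologous-group catalog
#'
#' An OG catalog defines the screening criteria: each orthologous group (OG)
#' carries a category -- \code{nOG} (presence hurts fatty-acid production),
#' \code{pOG} (presence helps) or \code{rOG} (required for the pathway) -- an
#' action label describing the engineering evidence behind it, its member
#' proteins, and the domain-family accessions each member requires for a
#' homology hit to be trusted.
#'
#' @param ogs data.frame with columns \code{og_id}, \code{category},
#'   \code{action_label}; row order defines the column order of every matrix
#'   derived from the catalog.
#' @param members data.frame with columns \code{protein_id}, \code{og_id}.
#' @param domain_requirements named list mapping \code{protein_id} to a
#'   character vector of domain accessions (may be empty).
#' @return An object of class \code{ffasc_catalog} with elements \code{ogs},
#'   \code{members}, \code{domain_requirements} and \code{member_index} (a
#'   named character vector, protein_id -> og_id).
#' @export
og_catalog <- function(ogs, members, domain_requirements = list()) {
  ogs <- as.data.frame(ogs, stringsAsFactors = FALSE)
  members <- as.data.frame(members, stringsAsFactors = FALSE)
  if (anyDuplicated(ogs$og_id))
    ffasc_error("ffasc_duplicate_og_error", sprintf(
      "duplicate og_id definition: %s",
      paste(unique(ogs$og_id[duplicated(ogs$og_id)]), collapse = ", ")))
  bad_cat <- setdiff(unique(ogs$category), OG_CATEGORIES)
  if (length(bad_cat))
    ffasc_error("ffasc_unknown_category_error",
                sprintf("unknown category: %s", paste(bad_cat, collapse = ", ")))
  bad_act <- setdiff(unique(ogs$action_label), OG_ACTIONS)
  if (length(bad_act))
    ffasc_error("ffasc_unknown_action_error",
                sprintf("unknown action label: %s", paste(bad_act, collapse = ", ")))
  if (anyDuplicated(members$protein_id))
    ffasc_error("ffasc_duplicate_membership_error", sprintf(
      "protein assigned to more than one OG: %s",
      paste(unique(members$protein_id[duplicated(members$protein_id)]),
            collapse = ", ")))
  if (!all(members$og_id %in% ogs$og_id))
    ffasc_error("ffasc_unknown_og_error", sprintf(
      "member references undefined og_id: %s",
      paste(setdiff(members$og_id, ogs$og_id), collapse = ", ")))
  if (!all(ogs$og_id %in% members$og_id))
    ffasc_error("ffasc_empty_og_error", sprintf(
      "OG without members: %s",
      paste(setdiff(ogs$og_id, members$og_id), collapse = ", ")))
  extra <- setdiff(names(domain_requirements), members$protein_id)
  if (length(extra))
    ffasc_error("ffasc_unknown_protein_error", sprintf(
      "domain requirement for unknown protein: %s", paste(extra, collapse = ", ")))
  dr <- lapply(members$protein_id, function(p) {
    acc <- domain_requirements[[p]]
    if (is.null(acc)) character(0) else {
      acc <- as.character(acc)
      if (any(!nzchar(acc)))
        ffasc_error("ffasc_empty_accession_error",
                    sprintf("empty domain accession for protein %s", p))
      unique(acc)
    }
  })
  names(dr) <- members$protein_id
  member_index <- stats::setNames(members$og_id, members$protein_id)
  structure(list(ogs = ogs, members = members,
                 domain_requirements = dr, member_index = member_index),
            class = "ffasc_catalog")
}

#' @export
print.ffasc_catalog <- function(x, ...) {
  cnt <- table(factor(x$ogs$category, levels = OG_CATEGORIES))
  cat(sprintf("ffasc OG catalog: %d OGs (nOG %d, pOG %d, rOG %d), %d member proteins\n",
              nrow(x$ogs), cnt[["nOG"]], cnt[["pOG"]], cnt[["rOG"]],
              nrow(x$members)))
  invisible(x)
}

#' OG ids of a catalog, in column order
#' @param catalog an \code{ffasc_catalog}
#' @return character vector of OG ids in the order matrices use for columns
#' @export
og_ids <- function(catalog) catalog$ogs$og_id

#' Load an OG catalog from a TSV file
#'
#' The catalog format is a UTF-8 TSV with \code{#} comment lines and columns
#' \code{og_id}, \code{category}, \code{action_label}, \code{member_protein_id},
#' \code{domain_accessions} (semicolon-separated, possibly empty): one row per
#' member protein. OG column order is the order of first appearance.
#'
#' @param path path to the catalog file
#' @return an \code{ffasc_catalog}
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) ffasc_error("ffasc_io_error",
                                      sprintf("catalog file not found: %s", path))
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("og_id", "category", "action_label", "member_protein_id",
            "domain_accessions")
  if (!all(need %in% names(df)))
    ffasc_error("ffasc_format_error", sprintf(
      "catalog file missing columns: %s",
      paste(setdiff(need, names(df)), collapse = ", ")))
  first <- !duplicated(df$og_id)
  ogs <- df[first, c("og_id", "category", "action_label")]
  rownames(ogs) <- NULL
  # an og_id reappearing with a different category/action is a conflicting
  # redefinition, reported as a duplicate-OG error
  key <- paste(df$og_id, df$category, df$action_label, sep = "\r")
  ref <- stats::setNames(key[first], df$og_id[first])
  if (any(key != ref[df$og_id]))
    ffasc_error("ffasc_duplicate_og_error", sprintf(
      "conflicting redefinition of og_id: %s",
      paste(unique(df$og_id[key != ref[df$og_id]]), collapse = ", ")))
  members <- data.frame(protein_id = df$member_protein_id, og_id = df$og_id,
                        stringsAsFactors = FALSE)
  dr <- lapply(df$domain_accessions, function(s) {
    if (is.na(s) || !nzchar(s)) character(0)
    else strsplit(s, ";", fixed = TRUE)[[1]]
  })
  names(dr) <- df$member_protein_id
  og_catalog(ogs, members, dr)
}

#' Save an OG catalog to a TSV file
#'
#' Writes the canonical one-row-per-member format read by
#' \code{\link{load_catalog}}; \code{save_catalog(load_catalog(f), g)} is
#' byte-identical to a canonically formatted \code{f}.
#'
#' @param catalog an \code{ffasc_catalog}
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
save_catalog <- function(catalog, path) {
  m <- catalog$members
  ord <- order(match(m$og_id, catalog$ogs$og_id))
  m <- m[ord, , drop = FALSE]
  og_info <- catalog$ogs[match(m$og_id, catalog$ogs$og_id), ]
  acc <- vapply(catalog$domain_requirements[m$protein_id],
                paste, character(1), collapse = ";")
  out <- data.frame(og_id = m$og_id, category = og_info$category,
                    action_label = og_info$action_label,
                    member_protein_id = m$protein_id,
                    domain_accessions = acc, stringsAsFactors = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con)
  writeLines(do.call(paste, c(unname(out), sep = "\t")), con)
  invisible(path)
}

#' Load the default OG catalog shipped with the package
#'
#' The default catalog holds the 49 orthologous groups relevant for free
#' fatty-acid production and excretion in cyanobacteria (13 nOG, 24 pOG,
#' 12 rOG) with 64 member proteins. Domain requirements are empty by default
#' and are meant to be supplied by the user for their Pfam annotation set.
#'
#' @return an \code{ffasc_catalog} with 49 OGs and 64 members
#' @export
default_catalog <- function() {
  load_catalog(system.file("extdata", "og_catalog.tsv", package = "ffasc",
                           mustWork = TRUE))
}

#' Validate an OG catalog and summarize its composition
#'
#' Report-only: never mutates or errors on the catalog content (structural
#' violations are impossible to represent in an \code{ffasc_catalog}).
#'
#' @param catalog an \code{ffasc_catalog}
#' @return list with \code{n_ogs}, \code{n_members}, \code{category_counts}
#'   (named integer vector over nOG/pOG/rOG), \code{members_without_domains}
#'   (character vector) and \code{warnings} (character vector)
#' @export
validate_catalog <- function(catalog) {
  cnt <- table(factor(catalog$ogs$category, levels = OG_CATEGORIES))
  no_dom <- names(Filter(function(d) length(d) == 0L,
                         catalog$domain_requirements))
  warns <- character(0)
  if (nrow(catalog$ogs) == 0L) warns <- c(warns, "empty catalog")
  if (length(no_dom))
    warns <- c(warns, sprintf(
      "%d member protein(s) have no domain requirements; their hits bypass the domain-completeness filter",
      length(no_dom)))
  list(n_ogs = nrow(catalog$ogs), n_members = nrow(catalog$members),
       category_counts = stats::setNames(as.integer(cnt), OG_CATEGORIES),
       members_without_domains = no_dom, warnings = warns)
}
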