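#' KEGG orthologues unique to one taxonomic domain
#'
#' Scans an ORF annotation catalogue and returns the KO identifiers whose
#' every occurrence is annotated with the given domain — the screen used to
#' shortlist marker-gene candidates (e.g. uniquely archaeal orthologues)
#' before identity scoring.
#'
#' @param catalog Data frame with at least `ko_id` and `domain` columns;
#'   rows with missing `ko_id` are ignored.
#' @param domain Domain label, e.g. `"Archaea"`.
#' @return Character vector of KO ids, sorted lexicographically; empty if
#'   the domain does not occur.
#' @export
unique_domain_kos <- function(catalog, domain) {
  stopifnot(is.data.frame(catalog), nrow(catalog) >= 1L,
            all(c("ko_id", "domain") %in% names(catalog)))
  cat2 <- catalog[!is.na(catalog$ko_id), , drop = FALSE]
  bad <- !grepl("^K[0-9]+$", cat2$ko_id)
  if (any(bad)) stop("malformed KO id: ", cat2$ko_id[bad][1L])
  in_dom <- tapply(cat2$domain == domain, cat2$ko_id, all)
  present <- tapply(cat2$domain == domain, cat2$ko_id, any)
  sort(names(in_dom)[in_dom & present])
}

#' Strong residue-similarity classes
#'
#' The standard strongly-conserved amino-acid groups (as used by common
#' alignment viewers to mark `:` columns). Used as the default
#' `similar_rule` for protein-mode identity reports; for nucleotide
#' alignments the rule is empty and similar counts are zero.
#' @format A character vector; each element is one class.
#' @export
strong_similarity_classes <- c("STA", "NEQK", "NHQK", "NDEQ", "QHRK",
                               "MILV", "MILF", "HY", "FYW")

#' Cross-group alignment identity report
#'
#' Column-unanimity identity statistics for a group of aligned sequences:
#' `identical_positions` counts columns where all residues are identical
#' and gap-free; `similar_positions` counts the remaining gap-free columns
#' whose residues all fall inside one similarity class; the identity
#' percentage is `100 * identical / alignment_length_used`, where the
#' denominator excludes columns that are gaps in every record.
#'
#' @param aln A [multi_alignment()] of the group's sequences (protein or
#'   nucleotide; residues are compared as uppercase characters).
#' @param group_name Label for the report row.
#' @param similar_rule Character vector of residue classes (each a string
#'   of residues); `NULL` for nucleotide mode (no similar positions). Use
#'   [strong_similarity_classes] for proteins.
#' @return One-row data frame: `group_name`, `n_sequences`,
#'   `percent_identity`, `identical_positions`, `similar_positions`,
#'   `alignment_length_used`.
#' @export
group_identity_report <- function(aln, group_name, similar_rule = NULL) {
  stopifnot(inherits(aln, "multi_alignment"))
  if (nrow(aln$records) < 2L)
    stop("identity report needs >= 2 sequences")
  m <- do.call(rbind, strsplit(toupper(aln$records$seq), "", fixed = TRUE))
  has_gap <- colSums(m == "-") > 0L
  all_gap <- colSums(m == "-") == nrow(m)
  len_used <- sum(!all_gap)
  identical_col <- !has_gap & apply(m, 2L, function(col) all(col == col[1L]))
  similar_col <- rep(FALSE, ncol(m))
  if (!is.null(similar_rule) && length(similar_rule) > 0L) {
    classes <- lapply(similar_rule, function(cl) strsplit(toupper(cl), "")[[1L]])
    cand <- which(!has_gap & !identical_col)
    similar_col[cand] <- vapply(cand, function(j) {
      any(vapply(classes, function(cl) all(m[, j] %in% cl), TRUE))
    }, TRUE)
  }
  data.frame(group_name = group_name,
             n_sequences = nrow(m),
             percent_identity = 100 * sum(identical_col) / len_used,
             identical_positions = sum(identical_col),
             similar_positions = sum(similar_col),
             alignment_length_used = len_used,
             stringsAsFactors = FALSE)
}

#' Rank candidate marker genes by worst-group identity
#'
#' Orders genes by how conserved their worst taxonomic group is: genes are
#' sorted by descending minimum-over-groups identity percentage, ties
#' broken by descending minimum identical-position count, then by gene id.
#' A gene whose weakest order still aligns at high identity is a better
#' LAMP marker than one that collapses in any group.
#'
#' @param reports Data frame with columns `gene`, `group_name`,
#'   `percent_identity`, `identical_positions` (one row per gene x group;
#'   every gene must cover the same group set).
#' @return Character vector of gene ids, best candidate first.
#' @export
rank_markers <- function(reports) {
  stopifnot(is.data.frame(reports),
            all(c("gene", "group_name", "percent_identity",
                  "identical_positions") %in% names(reports)))
  groups_by_gene <- tapply(reports$group_name, reports$gene,
                           function(g) paste(sort(g), collapse = "\r"))
  if (length(unique(groups_by_gene)) != 1L)
    stop("genes cover inconsistent group sets")
  min_id <- tapply(reports$percent_identity, reports$gene, min)
  min_ident <- tapply(reports$identical_positions, reports$gene, min)
  genes <- names(min_id)
  genes[order(-min_id, -min_ident[genes], genes)]
}
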