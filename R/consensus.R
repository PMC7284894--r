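#' Per-column base profiles of an alignment
#'
#' Counts A/C/G/T and gaps in every alignment column (after uppercasing;
#' `U` is counted as `T`) and computes the per-column identity fraction:
#' the modal base count divided by the number of non-gap rows. Profiling
#' requires concrete bases; alignments containing ambiguity codes other
#' than `U` are rejected.
#'
#' @param aln A [multi_alignment()] with at least two records.
#' @return A data frame with one row per column: `index` (0-based), `A`,
#'   `C`, `G`, `T`, `gap_count`, `identity_fraction`.
#' @export
column_profiles <- function(aln) {
  stopifnot(inherits(aln, "multi_alignment"))
  if (nrow(aln$records) < 2L) stop("column_profiles() needs >= 2 records")
  m <- .aln_matrix(aln)
  bad <- !(m %in% c("A", "C", "G", "T", "-"))
  if (any(bad))
    stop("ambiguous base '", m[bad][1L], "' in alignment; profiles require ",
         "concrete A/C/G/T sequences")
  counts <- vapply(c("A", "C", "G", "T", "-"),
                   function(b) colSums(m == b), numeric(ncol(m)))
  counts <- matrix(counts, ncol = 5L,
                   dimnames = list(NULL, c("A", "C", "G", "T", "gap")))
  nongap <- nrow(m) - counts[, "gap"]
  top <- apply(counts[, 1:4, drop = FALSE], 1L, max)
  data.frame(index = seq_len(ncol(m)) - 1L,
             A = counts[, "A"], C = counts[, "C"],
             G = counts[, "G"], T = counts[, "T"],
             gap_count = counts[, "gap"],
             identity_fraction = ifelse(nongap > 0, top / nongap, 0))
}

#' Detect conserved alignment regions
#'
#' Returns the maximal runs of columns whose identity fraction is strictly
#' greater than `threshold` (the conserved-region rule used when choosing
#' consensus tracts for primer design: a column at exactly the threshold
#' breaks a run) and whose gap fraction does not exceed `max_gap_frac`.
#' Runs shorter than `min_len` columns are dropped.
#'
#' @param profiles Output of [column_profiles()].
#' @param threshold Identity threshold in `(0, 1]` (default 0.8).
#' @param min_len Minimum region length in columns.
#' @param max_gap_frac Maximum tolerated per-column gap fraction.
#' @return A data frame with `start`, `end` (0-based half-open) and
#'   `mean_identity`, sorted and non-overlapping.
#' @export
conserved_regions <- function(profiles, threshold = 0.8, min_len = 40L,
                              max_gap_frac = 0.1) {
  stopifnot(threshold > 0, threshold <= 1)
  n_rows <- profiles$gap_count + profiles$A + profiles$C + profiles$G + profiles$T
  ok <- profiles$identity_fraction > threshold &
    profiles$gap_count / n_rows <= max_gap_frac
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_len)
  out <- data.frame(start = profiles$index[starts[keep]],
                    end = profiles$index[ends[keep]] + 1L)
  out$mean_identity <- vapply(seq_len(nrow(out)), function(i) {
    mean(profiles$identity_fraction[(out$start[i] + 1L):out$end[i]])
  }, 0)
  out
}

#' Degenerate IUPAC consensus over an alignment span
#'
#' For each column in `span`, emits the IUPAC code covering exactly the
#' bases whose frequency among non-gap rows is at least `min_base_frac`
#' (`N` when all four qualify). If no base reaches the cutoff (possible
#' when `min_base_frac > 0.25`), the code falls back to the modal base
#' set. Gap-only columns are an error; gaps never appear in the output.
#'
#' @param aln A [multi_alignment()].
#' @param span Integer pair `(start, end)`, 0-based half-open columns.
#' @param min_base_frac Minimum base frequency for inclusion (default 0.2,
#'   which reproduces the 2-3-fold degeneracy typical of consensus primers
#'   built from a handful of genomes).
#' @return IUPAC string of length `end - start`.
#' @export
degenerate_consensus <- function(aln, span, min_base_frac = 0.2) {
  stopifnot(inherits(aln, "multi_alignment"), length(span) == 2L)
  start <- span[[1L]]; end <- span[[2L]]
  if (start < 0L || end > aln$length || start >= end)
    stop("span [", start, ",", end, ") outside alignment of length ", aln$length)
  m <- .aln_matrix(aln)[, (start + 1L):end, drop = FALSE]
  codes <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    col <- col[col != "-"]
    if (length(col) == 0L)
      stop("column ", start + j - 1L, " is entirely gaps")
    if (!all(col %in% c("A", "C", "G", "T")))
      stop("ambiguous base in column ", start + j - 1L,
           "; consensus requires concrete input sequences")
    freq <- table(factor(col, levels = c("A", "C", "G", "T"))) / length(col)
    bases <- names(freq)[freq >= min_base_frac]
    if (length(bases) == 0L) bases <- names(freq)[freq == max(freq)]
    iupac_code(bases)
  }, "")
  paste(codes, collapse = "")
}
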