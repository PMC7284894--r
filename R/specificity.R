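#' In-silico specificity rules
#'
#' Mismatch policy for binding-site scanning and the positivity rule for
#' predicted amplification. Defaults: up to 2 total mismatches per primer
#' site but none in the 3'-terminal 5 nt of the extension-competent
#' primers (3'-end fidelity governs polymerase extension), and an F2-B2
#' span allowed up to 1.5x the design maximum (amplification tolerates
#' looser geometry than design).
#'
#' @param max_mismatch Maximum total mismatches per site.
#' @param max_3prime_mismatch Maximum mismatches within the 3'-terminal
#'   5 nt.
#' @param span_slack Multiplier on the upper F2-B2 design bound used in
#'   the amplification call.
#' @return List of class `specificity_rules`.
#' @export
specificity_rules <- function(max_mismatch = 2L, max_3prime_mismatch = 0L,
                              span_slack = 1.5) {
  stopifnot(max_mismatch >= 0L, max_3prime_mismatch >= 0L, span_slack >= 1)
  structure(list(max_mismatch = max_mismatch,
                 max_3prime_mismatch = max_3prime_mismatch,
                 span_slack = span_slack), class = "specificity_rules")
}

#' Find primer binding sites in a concrete subject sequence
#'
#' Exhaustively scans both strands of a subject for positions where the
#' (possibly degenerate) primer can anneal: a subject base matches when it
#' is covered by the primer's IUPAC code at that position, i.e. when some
#' concrete expansion of the primer matches. Hits are reported when total
#' mismatches and 3'-terminal mismatches (last 5 nt of the primer) are
#' within the rule limits.
#'
#' @param primer A primer candidate (list with `seq`) or an IUPAC string.
#' @param subject A single [seq_records()] row or a concrete A/C/G/T
#'   string.
#' @param rules A [specificity_rules()] object.
#' @param role Role label copied onto hits.
#' @return Data frame of hits: `primer_role`, `subject_id`,
#'   `subject_genus`, `start` (0-based, on the subject's forward strand),
#'   `strand`, `mismatches`, `three_prime_mismatches`.
#' @export
find_binding_sites <- function(primer, subject, rules = specificity_rules(),
                               role = NA_character_) {
  if (is.list(primer)) {
    if (is.na(role) && !is.null(primer$role)) role <- primer$role
    primer <- primer$seq
  }
  if (is.data.frame(subject)) {
    sid <- subject$id[1L]; sgenus <- subject$genus[1L]
    subject <- subject$seq[1L]
  } else {
    sid <- NA_character_; sgenus <- NA_character_
  }
  pch <- .seq_chars(primer)
  sch <- .seq_chars(subject)
  if (!all(sch %in% c("A", "C", "G", "T")))
    stop("subject must be a concrete A/C/G/T sequence")
  m <- length(pch); n <- length(sch)
  empty <- data.frame(primer_role = character(0), subject_id = character(0),
                      subject_genus = character(0), start = integer(0),
                      strand = character(0), mismatches = integer(0),
                      three_prime_mismatches = integer(0))
  if (m > n) return(empty)
  scan <- function(pch, idx3) {
    starts <- 0:(n - m)
    mm <- integer(length(starts)); mm3 <- integer(length(starts))
    for (k in seq_along(starts)) {
      comp <- .iupac_compatible(pch, sch[(starts[k] + 1L):(starts[k] + m)])
      mm[k] <- sum(!comp)
      mm3[k] <- sum(!comp[idx3])
    }
    keep <- mm <= rules$max_mismatch & mm3 <= rules$max_3prime_mismatch
    list(start = starts[keep], mm = mm[keep], mm3 = mm3[keep])
  }
  # on the plus strand the primer's 3'-terminal 5 nt are the last 5 scanned
  # positions; on the minus strand (scanning with the reverse complement)
  # they are the first 5
  fwd <- scan(pch, max(1L, m - 4L):m)
  rev <- scan(.seq_chars(reverse_complement(primer)), seq_len(min(5L, m)))
  out <- rbind(
    if (length(fwd$start)) data.frame(primer_role = role, subject_id = sid,
                                      subject_genus = sgenus, start = fwd$start,
                                      strand = "+", mismatches = fwd$mm,
                                      three_prime_mismatches = fwd$mm3),
    if (length(rev$start)) data.frame(primer_role = role, subject_id = sid,
                                      subject_genus = sgenus, start = rev$start,
                                      strand = "-", mismatches = rev$mm,
                                      three_prime_mismatches = rev$mm3))
  if (is.null(out)) empty else out[order(out$start, out$strand), , drop = FALSE]
}

# expected strand of each role's footprint match on an on-target sense
# subject, given the design orientation conventions
.role_subject_strand <- c(F3 = "+", F2 = "+", F1c = "-", B1c = "+",
                          B2 = "-", B3 = "-")

#' Predict LAMP amplification of one subject
#'
#' A subject is called positive when footprints for all six required
#' primers occur in canonical LAMP order and orientation (F3, F2, F1, B1,
#' B2, B3 along one strand, with the role-specific strand conventions) and
#' the F2-B2 span lies within the design window stretched by
#' `rules$span_slack` at the top. Loop primers never gate the call. Both
#' subject orientations are tested.
#'
#' @param set A [lamp_primer_set].
#' @param subject A single [seq_records()] row or a concrete sequence
#'   string.
#' @param constraints A [design_constraints()] object (for the span
#'   window).
#' @param rules A [specificity_rules()] object.
#' @return List of class `amplification_call`: `subject_id`,
#'   `subject_genus`, `positive`, and `geometry` (ordered footprint data
#'   frame, or `NULL` when negative).
#' @export
predict_amplification <- function(set, subject,
                                  constraints = design_constraints(),
                                  rules = specificity_rules()) {
  stopifnot(inherits(set, "lamp_primer_set"))
  roles <- c("F3", "F2", "F1c", "B1c", "B2", "B3")
  if (!all(roles %in% names(set$primers)))
    stop("primer set lacks required roles")
  if (is.data.frame(subject)) {
    sid <- subject$id[1L]; sgenus <- subject$genus[1L]
    sseq <- subject$seq[1L]
  } else {
    sid <- NA_character_; sgenus <- NA_character_; sseq <- subject
  }
  span_lo <- constraints$dist_F2_B2[1L]
  span_hi <- constraints$dist_F2_B2[2L] * rules$span_slack
  try_orientation <- function(seqstr, flipped) {
    hits <- lapply(roles, function(r) {
      h <- find_binding_sites(set$primers[[r]], seqstr, rules, role = r)
      h[h$strand == .role_subject_strand[[r]], , drop = FALSE]
    })
    names(hits) <- roles
    if (any(vapply(hits, nrow, 0L) == 0L)) return(NULL)
    lens <- vapply(roles, function(r) nchar(set$primers[[r]]$seq), 0L)
    # greedy left-to-right chaining; ordering is on footprint edges
    for (i2 in seq_len(nrow(hits$F2))) {
      f2 <- hits$F2$start[i2]
      b2cand <- hits$B2$start[hits$B2$start >= f2 + lens[["F2"]]]
      for (b2 in b2cand) {
        span <- b2 + lens[["B2"]] - f2
        if (span < span_lo || span > span_hi) next
        f3 <- hits$F3$start[hits$F3$start + lens[["F3"]] <= f2]
        f1 <- hits$F1c$start[hits$F1c$start >= f2 + lens[["F2"]]]
        f1 <- f1[f1 + lens[["F1c"]] <= b2]
        if (!length(f3) || !length(f1)) next
        f1 <- f1[1L]
        b1 <- hits$B1c$start[hits$B1c$start >= f1 + lens[["F1c"]]]
        b1 <- b1[b1 + lens[["B1c"]] <= b2]
        if (!length(b1)) next
        b1 <- b1[1L]
        b3 <- hits$B3$start[hits$B3$start >= b2 + lens[["B2"]]]
        if (!length(b3)) next
        geom <- data.frame(
          role = roles,
          start = c(f3[length(f3)], f2, f1, b1, b2, b3[1L]),
          strand = unname(.role_subject_strand[roles]),
          flipped_subject = flipped)
        return(geom)
      }
    }
    NULL
  }
  geom <- try_orientation(sseq, FALSE)
  if (is.null(geom)) geom <- try_orientation(reverse_complement(sseq), TRUE)
  structure(list(subject_id = sid, subject_genus = sgenus,
                 positive = !is.null(geom), geometry = geom),
            class = "amplification_call")
}

#' @export
print.amplification_call <- function(x, ...) {
  cat("amplification call:", x$subject_id, "-",
      if (x$positive) "POSITIVE" else "negative", "\n")
  if (!is.null(x$geometry)) print(x$geometry)
  invisible(x)
}

#' Per-genus specificity matrix for a primer set
#'
#' Runs [predict_amplification()] over every record of a labelled
#' database and tabulates predicted positives per genus. A set is
#' genus-specific when positives occur only in its target genus.
#'
#' @param set A [lamp_primer_set].
#' @param db A [seq_records()] data frame with genus labels (missing
#'   genera are grouped as `"unassigned"`).
#' @param constraints,rules Passed to [predict_amplification()].
#' @return Data frame (`genus`, `n_subjects`, `n_positive`) with
#'   attributes `target_genus`, `specific` and `calls` (per-record call
#'   list).
#' @export
specificity_matrix <- function(set, db, constraints = design_constraints(),
                               rules = specificity_rules()) {
  if (nrow(db) == 0L) {
    out <- data.frame(genus = character(0), n_subjects = integer(0),
                      n_positive = integer(0))
    attr(out, "target_genus") <- set$genus
    attr(out, "specific") <- NA
    return(out)
  }
  calls <- lapply(seq_len(nrow(db)), function(i)
    predict_amplification(set, db[i, , drop = FALSE], constraints, rules))
  genus <- ifelse(is.na(db$genus), "unassigned", db$genus)
  pos <- vapply(calls, function(cl) cl$positive, TRUE)
  out <- data.frame(genus = sort(unique(genus)))
  out$n_subjects <- vapply(out$genus, function(g) sum(genus == g), 0L)
  out$n_positive <- vapply(out$genus, function(g) sum(pos[genus == g]), 0L)
  attr(out, "target_genus") <- set$genus
  attr(out, "specific") <- all(out$n_positive[out$genus != set$genus] == 0L)
  attr(out, "calls") <- calls
  out
}
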