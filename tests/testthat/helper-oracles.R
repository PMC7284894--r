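# Independent oracle implementations, deliberately coded differently from
# the package internals: the unified nearest-neighbour table is re-typed
# with only the ten unique stacks and resolved through reverse
# complementation, scans are naive loops, and nothing here touches
# package internals.

oracle_nn <- list(
  AA = c(h = -7.9, s = -22.2), AT = c(h = -7.2, s = -20.4),
  TA = c(h = -7.2, s = -21.3), CA = c(h = -8.5, s = -22.7),
  GT = c(h = -8.4, s = -22.4), CT = c(h = -7.8, s = -21.0),
  GA = c(h = -8.2, s = -22.2), CG = c(h = -10.6, s = -27.2),
  GC = c(h = -9.8, s = -24.4), GG = c(h = -8.0, s = -19.9))

oracle_rc <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

oracle_stack <- function(di) {
  if (!is.null(oracle_nn[[di]])) oracle_nn[[di]] else oracle_nn[[oracle_rc(di)]]
}

# concrete-sequence Tm under the same published parameter set and salt
# correction, built position by position
oracle_tm <- function(seq, na_mM = 50, primer_uM = 0.1) {
  ch <- strsplit(seq, "")[[1]]
  dH <- 0; dS <- 0
  for (i in seq_len(length(ch) - 1)) {
    st <- oracle_stack(paste0(ch[i], ch[i + 1]))
    dH <- dH + st[["h"]]; dS <- dS + st[["s"]]
  }
  for (term in ch[c(1, length(ch))]) {
    if (term %in% c("G", "C")) { dH <- dH + 0.1; dS <- dS - 2.8 }
    else { dH <- dH + 2.3; dS <- dS + 4.1 }
  }
  dS <- dS + 0.368 * (length(ch) - 1) * log(na_mM / 1000)
  dH * 1000 / (dS + 1.987 * log(primer_uM * 1e-6 / 4)) - 273.15
}

oracle_stack_dG37 <- function(di) {
  st <- oracle_stack(di)
  st[["h"]] - 310.15 * st[["s"]] / 1000
}

oracle_end_dG <- function(seq, end, window = 6) {
  n <- nchar(seq)
  sub <- if (end == "5prime") substr(seq, 1, window)
         else substr(seq, n - window + 1, n)
  ch <- strsplit(sub, "")[[1]]
  sum(vapply(seq_len(length(ch) - 1),
             function(i) oracle_stack_dG37(paste0(ch[i], ch[i + 1])), 0))
}

oracle_init_dG37 <- function(base) {
  if (base %in% c("G", "C")) 0.1 + 310.15 * 2.8 / 1000
  else 2.3 - 310.15 * 4.1 / 1000
}

# most stable complementary run between concrete a and b over every
# antiparallel offset (mode "any"), by exhaustive enumeration
oracle_dimer_any <- function(a, b) {
  ach <- strsplit(a, "")[[1]]
  bch <- rev(strsplit(b, "")[[1]])
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  best <- 0
  for (off in (-(length(bch) - 1)):(length(ach) - 1)) {
    idx <- max(1, 1 + off):min(length(ach), length(bch) + off)
    pairing <- comp[ach[idx]] == bch[idx - off]
    run_start <- NA
    for (k in seq_len(length(pairing) + 1)) {
      on <- k <= length(pairing) && pairing[k]
      if (on && is.na(run_start)) run_start <- k
      if (!on && !is.na(run_start)) {
        run_len <- k - run_start
        if (run_len >= 2) {
          pos <- idx[run_start:(k - 1)]
          dg <- oracle_init_dG37(ach[pos[1]]) +
            oracle_init_dG37(ach[pos[length(pos)]])
          for (p in seq_len(length(pos) - 1))
            dg <- dg + oracle_stack_dG37(paste0(ach[pos[p]], ach[pos[p + 1]]))
          best <- min(best, dg)
        }
        run_start <- NA
      }
    }
  }
  best
}

# naive sliding scanner: all start/strand combinations where some
# expansion of the primer matches within the mismatch limits
oracle_scan <- function(primer, subject, max_mm = 2, max_mm3 = 0) {
  exps <- expand_degenerate(primer)
  n <- nchar(subject); m <- nchar(primer)
  rows <- list()
  for (strand in c("+", "-")) {
    for (start in 0:(n - m)) {
      window <- substr(subject, start + 1, start + m)
      target <- if (strand == "+") window else oracle_rc(window)
      # best expansion: minimum total mismatches, then 3' mismatches
      best <- NULL
      for (e in exps) {
        ec <- strsplit(e, "")[[1]]; tc <- strsplit(target, "")[[1]]
        mm <- sum(ec != tc)
        mm3 <- sum((ec != tc)[max(1, m - 4):m])
        if (is.null(best) || mm < best[1] || (mm == best[1] && mm3 < best[2]))
          best <- c(mm, mm3)
      }
      if (best[1] <= max_mm && best[2] <= max_mm3)
        rows[[length(rows) + 1]] <- data.frame(start = start, strand = strand,
                                               mismatches = best[1])
    }
  }
  if (!length(rows)) return(data.frame(start = integer(0), strand = character(0),
                                       mismatches = integer(0)))
  out <- do.call(rbind, rows)
  out[order(out$start, out$strand), , drop = FALSE]
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# a tiny alignment fixture builder
aln_of <- function(...) {
  seqs <- c(...)
  multi_alignment(seq_records(paste0("s", seq_along(seqs)), seqs, aligned = TRUE))
}
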