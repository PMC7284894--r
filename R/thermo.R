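# Unified nearest-neighbour parameters for DNA/DNA duplexes
# (SantaLucia 1998 unified set). dH in kcal/mol, dS in cal/(mol*K).
# Keys are the 5'->3' dinucleotide on the reported strand; the ten unique
# stacks are mirrored onto their reverse complements.
.nn_dH <- c(
  AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
  CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
  TT = -7.9, AC = -8.4, TG = -8.5, AG = -7.8, TC = -8.2, CC = -8.0
)
.nn_dS <- c(
  AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
  CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
  TT = -22.2, AC = -22.4, TG = -22.7, AG = -21.0, TC = -22.2, CC = -19.9
)
# duplex initiation terms, by terminal base
.init_dH <- c(A = 2.3, T = 2.3, C = 0.1, G = 0.1)
.init_dS <- c(A = 4.1, T = 4.1, C = -2.8, G = -2.8)

.gas_const <- 1.987  # cal/(mol*K)

#' Thermodynamic model conditions
#'
#' Conditions under which nearest-neighbour melting temperatures and duplex
#' free energies are evaluated. Defaults approximate the conditions of
#' common LAMP primer-design software: 50 mM monovalent salt and 0.1 uM
#' primer, with free energies reported at 37 degrees C.
#'
#' @param monovalent_mM Monovalent cation concentration in mM.
#' @param primer_uM Total primer strand concentration in uM.
#' @param dG_temp_C Temperature at which stack free energies are evaluated.
#' @param degeneracy_cap Largest degeneracy for which exact
#'   expansion-averaging of degenerate primers is attempted.
#' @return A list of class `thermo_conditions`.
#' @export
thermo_conditions <- function(monovalent_mM = 50, primer_uM = 0.1,
                              dG_temp_C = 37, degeneracy_cap = 256L) {
  stopifnot(monovalent_mM > 0, primer_uM > 0)
  structure(list(monovalent_mM = monovalent_mM, primer_uM = primer_uM,
                 dG_temp_C = dG_temp_C, degeneracy_cap = degeneracy_cap),
            class = "thermo_conditions")
}

# dH (kcal/mol) and dS (cal/mol/K) of a concrete duplex, with initiation
# and salt-corrected entropy
.duplex_thermo <- function(chars, na_M) {
  di <- paste0(chars[-length(chars)], chars[-1L])
  dH <- sum(.nn_dH[di]) + .init_dH[[chars[1L]]] + .init_dH[[chars[length(chars)]]]
  dS <- sum(.nn_dS[di]) + .init_dS[[chars[1L]]] + .init_dS[[chars[length(chars)]]]
  dS <- dS + 0.368 * (length(chars) - 1L) * log(na_M)
  c(dH = dH, dS = dS)
}

.tm_concrete <- function(seq, cond) {
  chars <- .seq_chars(seq)
  th <- .duplex_thermo(chars, cond$monovalent_mM / 1000)
  ct <- cond$primer_uM * 1e-6
  th[["dH"]] * 1000 / (th[["dS"]] + .gas_const * log(ct / 4)) - 273.15
}

#' Nearest-neighbour melting temperature
#'
#' Duplex melting temperature of a primer against its perfect complement,
#' from the unified DNA nearest-neighbour parameter set with a
#' monovalent-salt entropy correction. Degenerate primers are scored as the
#' mean Tm over all concrete expansions (exact enumeration, guarded by
#' `conditions$degeneracy_cap`).
#'
#' @param seq IUPAC nucleotide string, length >= 8.
#' @param conditions A [thermo_conditions()] object.
#' @return Melting temperature in degrees C.
#' @export
melting_temperature <- function(seq, conditions = thermo_conditions()) {
  if (nchar(seq) < 8L) stop("melting_temperature() requires length >= 8")
  d <- degeneracy(seq)
  if (d > conditions$degeneracy_cap)
    stop("degeneracy ", d, " exceeds cap ", conditions$degeneracy_cap,
         "; sample expansions explicitly if this is intended")
  mean(vapply(expand_degenerate(seq, cap = conditions$degeneracy_cap),
              .tm_concrete, 0, cond = conditions))
}

# sum of stack dG at the evaluation temperature over a window of bases
# (no initiation terms); degenerate windows averaged over expansions
.window_dG <- function(seq, cond) {
  temp_K <- cond$dG_temp_C + 273.15
  mean(vapply(expand_degenerate(seq, cap = cond$degeneracy_cap), function(s) {
    chars <- .seq_chars(s)
    di <- paste0(chars[-length(chars)], chars[-1L])
    sum(.nn_dH[di] - temp_K * .nn_dS[di] / 1000)
  }, 0))
}

#' Terminal end stability
#'
#' Free energy of duplex formation over a primer's terminal window: the sum
#' of nearest-neighbour stack dG values (at `conditions$dG_temp_C`) across
#' the first (`end = "5prime"`) or last (`end = "3prime"`) `window` bases.
#' More negative values indicate a more stable, more extension-competent
#' end. Degenerate positions are averaged over expansions.
#'
#' @param seq IUPAC nucleotide string.
#' @param end `"5prime"` or `"3prime"`.
#' @param window Number of terminal bases considered (default 6).
#' @param conditions A [thermo_conditions()] object.
#' @return Free energy in kcal/mol.
#' @export
end_stability <- function(seq, end = c("3prime", "5prime"), window = 6L,
                          conditions = thermo_conditions()) {
  end <- match.arg(end)
  n <- nchar(seq)
  if (window > n) stop("window (", window, ") exceeds sequence length ", n)
  sub <- if (end == "5prime") substr(seq, 1L, window)
         else substr(seq, n - window + 1L, n)
  .window_dG(sub, conditions)
}

#' Primer-dimer score
#'
#' Scans all ungapped antiparallel pairings of two primers and scores
#' complementary runs of two or more consecutive Watson-Crick pairs by
#' their duplex free energy: the sum of nearest-neighbour stack dG values
#' plus the two duplex-initiation terms, at `conditions$dG_temp_C`. The
#' score is the minimum (most stable) run free energy found; a pair of
#' primers with no complementary run of length >= 2 scores 0. Degenerate
#' positions pair if any expansion pairs, and runs are scored by their
#' most stable consistent realization, so the score is a worst-case bound.
#' The score is symmetric in its arguments.
#'
#' Two modes are provided. `"three_prime"` (the default, and the one
#' checked against the -2.5 kcal/mol design floor) scores only runs that
#' reach the 3'-terminal base of either primer: a 3'-anchored duplex is
#' the species a polymerase can extend into a primer-dimer artifact, and
#' only for such duplexes is a floor as strict as -2.5 kcal/mol
#' meaningful — interior complementary runs below that energy occur in
#' essentially every usable primer pair. `"any"` scores every run at every
#' offset, as a diagnostic of total cross-complementarity.
#'
#' @param a,b IUPAC nucleotide strings.
#' @param conditions A [thermo_conditions()] object.
#' @param mode `"three_prime"` or `"any"` (see Details).
#' @return Minimum run free energy in kcal/mol (<= 0).
#' @export
dimer_score <- function(a, b, conditions = thermo_conditions(),
                        mode = c("three_prime", "any")) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  mode <- match.arg(mode)
  temp_K <- conditions$dG_temp_C + 273.15
  init_G <- .init_dH - temp_K * .init_dS / 1000
  scan <- function(a, b, anchored) {
    ach <- .seq_chars(a)
    bch <- rev(.seq_chars(b))    # antiparallel: reverse of b under a
    best <- 0
    for (off in (-(length(bch) - 1L)):(length(ach) - 1L)) {
      i <- max(1L, 1L + off):min(length(ach), length(bch) + off)
      j <- i - off
      # per-position sets of concrete a-strand bases consistent with pairing
      sets <- mapply(function(ai, bj) {
        intersect(.iupac_sets[[ai]],
                  chartr("ACGT", "TGCA", .iupac_sets[[bj]]))
      }, ach[i], bch[j], SIMPLIFY = FALSE)
      paired <- lengths(sets) > 0L
      r <- rle(paired)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      runs <- which(r$values & r$lengths >= 2L)
      if (anchored) {
        # keep only the run containing the 3'-terminal base of `a`
        runs <- runs[ends[runs] == length(i) & i[length(i)] == length(ach)]
      }
      for (k in runs) {
        dg <- min(init_G[sets[[starts[k]]]]) + min(init_G[sets[[ends[k]]]])
        for (p in starts[k]:(ends[k] - 1L)) {
          di <- as.vector(outer(sets[[p]], sets[[p + 1L]], paste0))
          dg <- dg + min(.nn_dH[di] - temp_K * .nn_dS[di] / 1000)
        }
        if (dg < best) best <- dg
      }
    }
    best
  }
  if (mode == "any") {
    scan(a, b, FALSE)            # symmetric by construction
  } else {
    min(scan(a, b, TRUE), scan(b, a, TRUE))
  }
}
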