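#' @importFrom Biostrings IUPAC_CODE_MAP
NULL

# code -> character vector of concrete bases, derived from the Biostrings map.
# 'U' is an alias for 'T' on input; internally everything is DNA.
.iupac_sets <- local({
  m <- lapply(strsplit(Biostrings::IUPAC_CODE_MAP, ""), identity)
  m[["U"]] <- "T"
  m
})

# reverse lookup: sorted concrete-base string -> code
.iupac_codes <- local({
  keys <- vapply(.iupac_sets, function(b) paste(sort(b), collapse = ""), "")
  stats::setNames(names(.iupac_sets), keys)[!duplicated(keys)]
})

.iupac_alphabet <- c(names(.iupac_sets), "U")

#' IUPAC nucleotide helpers
#'
#' Small utilities over the IUPAC degenerate nucleotide alphabet
#' (A, C, G, T plus the eleven ambiguity codes; `U` is accepted and read
#' as `T`).
#'
#' @param code A single IUPAC character.
#' @return `iupac_bases()` returns the character vector of concrete bases
#'   covered by `code`; `iupac_code()` performs the reverse lookup.
#' @examples
#' iupac_bases("Y")      # "C" "T"
#' iupac_code(c("C", "G", "T"))  # "B"
#' @export
iupac_bases <- function(code) {
  stopifnot(is.character(code), length(code) == 1L, nchar(code) == 1L)
  b <- .iupac_sets[[toupper(code)]]
  if (is.null(b)) stop("not an IUPAC nucleotide code: '", code, "'")
  b
}

#' @rdname iupac_bases
#' @param bases Character vector of concrete bases (subset of A/C/G/T).
#' @export
iupac_code <- function(bases) {
  bases <- toupper(bases)
  if (!all(bases %in% c("A", "C", "G", "T")) || length(bases) < 1L)
    stop("bases must be a non-empty subset of A/C/G/T")
  key <- paste(sort(unique(bases)), collapse = "")
  code <- .iupac_codes[[key]]
  if (is.null(code)) stop("no IUPAC code for base set ", key)
  code
}

# split a sequence string into an uppercase character vector, mapping U -> T
.seq_chars <- function(seq) {
  x <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  x[x == "U"] <- "T"
  x
}

.check_iupac <- function(seq, allow_gap = FALSE, what = "sequence") {
  x <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  ok <- x %in% .iupac_alphabet | (allow_gap & x == "-")
  if (!all(ok)) {
    i <- which(!ok)[1L]
    stop("non-IUPAC character '", x[i], "' at position ", i, " in ", what)
  }
  invisible(TRUE)
}

#' Reverse complement of an IUPAC string
#'
#' Complements every position (degenerate codes map to the code of the
#' complemented base set, e.g. `R` -> `Y`, `B` -> `V`) and reverses the
#' sequence.
#'
#' @param seq IUPAC nucleotide string (no gaps).
#' @return The reverse complement, 5'->3'.
#' @export
reverse_complement <- function(seq) {
  .check_iupac(seq, what = "reverse_complement() input")
  x <- chartr("ACGTUMRWSYKVHDBN", "TGCAAKYWSRMBDHVN", toupper(seq))
  paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Degeneracy of an IUPAC string
#'
#' Product over positions of the number of concrete bases each code covers.
#'
#' @param seq IUPAC nucleotide string.
#' @return Integer degeneracy (1 for a fully concrete sequence).
#' @export
degeneracy <- function(seq) {
  .check_iupac(seq, what = "degeneracy() input")
  prod(vapply(.seq_chars(seq), function(ch) length(.iupac_sets[[ch]]), 1L))
}

#' Expand a degenerate sequence into all concrete realizations
#'
#' @param seq IUPAC nucleotide string.
#' @param cap Maximum permitted degeneracy; expansion beyond it is an error
#'   (default 4096).
#' @return Character vector of all A/C/G/T realizations, in lexicographic
#'   order; its length is `degeneracy(seq)`.
#' @examples
#' expand_degenerate("AY")  # "AC" "AT"
#' @export
expand_degenerate <- function(seq, cap = 4096L) {
  d <- degeneracy(seq)
  if (d > cap)
    stop("degeneracy ", d, " exceeds cap ", cap,
         "; consider sampling expansions instead")
  sets <- lapply(.seq_chars(seq), function(ch) .iupac_sets[[ch]])
  out <- ""
  for (s in sets) out <- as.vector(outer(out, s, paste0))
  sort(out)
}

#' Expected GC content of an IUPAC string
#'
#' Each position contributes the probability of drawing G or C uniformly
#' from the bases its code covers (`S` = 1, `Y` = 0.5, `N` = 0.5, ...).
#'
#' @param seq IUPAC nucleotide string; gaps are an error.
#' @return GC percentage in `[0, 100]`.
#' @examples
#' gc_fraction("AYGC")  # 62.5
#' @export
gc_fraction <- function(seq) {
  if (grepl("-", seq, fixed = TRUE))
    stop("gap character in gc_fraction() input")
  .check_iupac(seq, what = "gc_fraction() input")
  p <- vapply(.seq_chars(seq), function(ch) {
    b <- .iupac_sets[[ch]]
    sum(b %in% c("G", "C")) / length(b)
  }, 0)
  100 * mean(p)
}

# TRUE where the concrete subject base is covered by the (possibly
# degenerate) primer code; vectorized over equal-length character vectors.
.iupac_compatible <- local({
  lut <- matrix(FALSE, nrow = length(.iupac_sets), ncol = 4,
                dimnames = list(names(.iupac_sets), c("A", "C", "G", "T")))
  for (code in rownames(lut)) lut[code, .iupac_sets[[code]]] <- TRUE
  function(primer_chars, subject_chars) {
    lut[cbind(primer_chars, subject_chars)]
  }
})
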