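#' Construct a table of labelled sequence records
#'
#' The package's working container for sequence collections is a plain
#' data frame with columns `id`, `seq`, `genus`, `order`, `domain`.
#' Sequences are uppercase IUPAC nucleotide strings; gaps (`-`) are only
#' permitted when `aligned = TRUE`.
#'
#' @param id Character vector of unique record ids.
#' @param seq Character vector of sequences.
#' @param genus,order,domain Optional taxonomy labels (NA allowed).
#' @param aligned Allow gap characters.
#' @param alphabet `"nucleotide"` (IUPAC codes, the default) or
#'   `"protein"` (one-letter amino acids, for identity reports over
#'   protein alignments).
#' @return A `data.frame` with class `seq_records`.
#' @export
seq_records <- function(id, seq, genus = NA_character_, order = NA_character_,
                        domain = NA_character_, aligned = FALSE,
                        alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  stopifnot(length(id) == length(seq), length(id) >= 1L)
  if (anyDuplicated(id)) stop("duplicate record id: ", id[duplicated(id)][1L])
  seq <- toupper(seq)
  if (any(!nzchar(seq))) stop("empty sequence for record ", id[!nzchar(seq)][1L])
  if (alphabet == "nucleotide") {
    for (k in seq_along(seq))
      .check_iupac(seq[k], allow_gap = aligned, what = paste0("record '", id[k], "'"))
  } else {
    bad <- grepl(if (aligned) "[^A-Z*-]" else "[^A-Z*]", seq)
    if (any(bad)) stop("invalid protein character in record ", id[bad][1L])
  }
  out <- data.frame(id = as.character(id), seq = seq,
                    genus = as.character(genus), order = as.character(order),
                    domain = as.character(domain), stringsAsFactors = FALSE)
  class(out) <- c("seq_records", "data.frame")
  out
}

#' Multiple sequence alignment container
#'
#' Wraps a [seq_records()] table whose sequences all have equal length.
#' Columns are indexed 0-based internally; the gap character is `-`.
#'
#' @param records A `seq_records` data frame (gapped sequences allowed).
#' @return An object of class `multi_alignment` with fields `records` and
#'   `length`.
#' @export
multi_alignment <- function(records) {
  if (!inherits(records, "seq_records"))
    records <- seq_records(records$id, records$seq, records$genus,
                           records$order, records$domain, aligned = TRUE)
  lens <- nchar(records$seq)
  if (length(unique(lens)) != 1L)
    stop("alignment records differ in length: ", paste(unique(lens), collapse = ", "))
  if (lens[1L] < 1L) stop("alignment length must be >= 1")
  structure(list(records = records, length = lens[1L]), class = "multi_alignment")
}

#' @export
print.multi_alignment <- function(x, ...) {
  cat("multi_alignment:", nrow(x$records), "sequences x", x$length, "columns\n")
  invisible(x)
}

# alignment as a character matrix (rows = records), uppercase, U -> T
.aln_matrix <- function(aln) {
  m <- do.call(rbind, lapply(aln$records$seq, .seq_chars))
  rownames(m) <- aln$records$id
  m
}

.subset_aln_cols <- function(aln, keep) {
  recs <- aln$records
  recs$seq <- vapply(recs$seq, function(s) {
    paste(strsplit(s, "", fixed = TRUE)[[1L]][keep], collapse = "")
  }, "", USE.NAMES = FALSE)
  multi_alignment(recs)
}

#' Read a FASTA file into labelled sequence records
#'
#' Headers are parsed with a pipe-delimited convention
#' `id|genus|order|domain`; trailing fields may be omitted. Sequences are
#' uppercased and validated against the IUPAC nucleotide alphabet (gaps
#' allowed when `aligned = TRUE`, for aligned FASTA).
#'
#' @param path Path to a FASTA file.
#' @param aligned Accept gap characters (aligned FASTA).
#' @return A [seq_records()] data frame, in file order.
#' @export
read_fasta <- function(path, aligned = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  fields <- strsplit(names(set), "|", fixed = TRUE)
  get <- function(i) vapply(fields, function(f) {
    v <- if (length(f) >= i) trimws(f[i]) else ""
    if (nzchar(v)) v else NA_character_
  }, "")
  seq_records(id = get(1L), seq = as.character(set), genus = get(2L),
              order = get(3L), domain = get(4L), aligned = aligned)
}

#' Write sequence records to FASTA
#'
#' Inverse of [read_fasta()]: metadata is serialized back into
#' pipe-delimited headers, so a read/write round trip reproduces ids,
#' sequences and taxonomy labels exactly.
#'
#' @param records A [seq_records()] data frame.
#' @param path Output path.
#' @param wrap Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, wrap = 60L) {
  stopifnot(nrow(records) >= 1L, wrap >= 1L)
  if (anyDuplicated(records$id))
    stop("duplicate record id: ", records$id[duplicated(records$id)][1L])
  hdr <- apply(cbind(records$id, records$genus, records$order, records$domain),
               1L, function(f) {
    f[is.na(f)] <- ""
    while (length(f) > 1L && !nzchar(f[length(f)])) f <- f[-length(f)]
    paste(f, collapse = "|")
  })
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path, width = wrap)
  invisible(path)
}

.random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                 collapse = "")

# mutate each position independently with probability `rate`, substituting
# a uniform draw from the three other bases
.mutate_seq <- function(chars, rate) {
  hit <- stats::runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  }
  chars
}

# per-branch change probability giving an expected pairwise identity `ident`
# between two sequences separated by the eigenvalue product `lam_other` on
# the rest of the path (uniform substitution model: P(match) = 1/4 + 3/4 * lam)
.rate_for_identity <- function(ident, n_branches, lam_other = 1) {
  if (ident < 0.25) stop("requested identity ", ident,
                         " below the 0.25 floor of the uniform model")
  lam <- ((ident - 0.25) * 4 / 3 / lam_other)^(1 / n_branches)
  if (lam > 1 + 1e-9) stop("requested identities are inconsistent")
  0.75 * (1 - min(lam, 1))
}

#' Simulate a multi-genus marker-gene alignment with planted structure
#'
#' Generates an ungapped alignment of `n_genera * seqs_per_genus`
#' sequences from a star-of-stars model: a random root sequence, one
#' mutated ancestor per genus, and independently mutated leaves, with
#' per-branch substitution rates solved so the expected pairwise identity
#' within and between genera matches the request (uniform substitution to
#' one of the three other bases). `n_conserved_windows` non-overlapping
#' windows of `window_len` columns are planted as fully conserved (every
#' record carries the root base), emulating the highly conserved tracts of
#' a marker gene from which LAMP consensus sequences are taken.
#'
#' @param n_genera,seqs_per_genus,length Alignment dimensions.
#' @param within_identity,between_identity Target expected pairwise
#'   identities (fractions; `0.25 <= between <= within <= 1`).
#' @param n_conserved_windows,window_len Planted conserved windows.
#' @param seed Integer seed; the simulation is a pure function of its
#'   arguments and the seed.
#' @return A list with `alignment` (a [multi_alignment()]) and `truth`
#'   (list with `planted_conserved_windows`, 0-based half-open).
#' @export
simulate_marker_alignment <- function(n_genera = 4L, seqs_per_genus = 4L,
                                      length = 1500L,
                                      within_identity = 0.9,
                                      between_identity = 0.7,
                                      n_conserved_windows = 3L,
                                      window_len = 250L, seed = 1L) {
  stopifnot(between_identity <= within_identity, within_identity <= 1,
            n_genera >= 1L, seqs_per_genus >= 1L)
  if (n_conserved_windows * (window_len + 1L) > length + 1L)
    stop("cannot pack ", n_conserved_windows, " windows of ", window_len,
         " columns into ", length, " columns without overlap")
  withr::with_seed(seed, {
    r_within <- .rate_for_identity(within_identity, n_branches = 2L)
    lam_w <- (1 - r_within * 4 / 3)^2
    r_between <- if (n_genera > 1L)
      .rate_for_identity(between_identity, n_branches = 2L, lam_other = lam_w)
    else 0
    root <- .seq_chars(.random_dna(length))
    # evenly spaced non-overlapping windows, jittered
    gap_total <- length - n_conserved_windows * window_len
    if (n_conserved_windows > 0L) {
      slack <- floor(gap_total / (n_conserved_windows + 1L))
      starts <- cumsum(rep(c(slack, window_len), n_conserved_windows))[
        seq(1L, by = 2L, length.out = n_conserved_windows)]
      windows <- cbind(start = starts, end = starts + window_len)
    } else windows <- cbind(start = integer(0), end = integer(0))
    frozen <- unlist(apply(windows, 1L, function(w) seq(w[1L] + 1L, w[2L])),
                     use.names = FALSE)
    recs <- list(); k <- 0L
    for (g in seq_len(n_genera)) {
      anc <- .mutate_seq(root, r_between)
      for (s in seq_len(seqs_per_genus)) {
        leaf <- .mutate_seq(anc, r_within)
        leaf[frozen] <- root[frozen]
        k <- k + 1L
        recs[[k]] <- data.frame(
          id = sprintf("g%02d_s%02d", g, s),
          seq = paste(leaf, collapse = ""),
          genus = sprintf("Genus%02d", g), order = sprintf("Order%02d", g),
          domain = "Archaea", stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, recs)
    aln <- multi_alignment(seq_records(df$id, df$seq, df$genus, df$order, df$domain))
    list(alignment = aln,
         truth = list(planted_conserved_windows =
                        lapply(seq_len(nrow(windows)), function(i)
                          c(start = unname(windows[i, 1L]),
                            end = unname(windows[i, 2L])))))
  })
}

#' Simulate an ORF annotation catalogue with planted domain-unique KOs
#'
#' Emulates the shape of a KEGG-annotated metagenome ORF table: each ORF
#' carries a KO identifier and a domain/genus taxonomy call. A fraction of
#' the KOs is planted as uniquely archaeal (every carrying ORF is
#' annotated Archaea); every other KO is guaranteed to occur in at least
#' two domains.
#'
#' @param n_orfs,n_kos Catalogue dimensions.
#' @param frac_archaea_unique Fraction of KOs planted as archaea-unique.
#' @param seed Integer seed.
#' @return List with `catalog` (data frame: orf_id, ko_id, domain, genus,
#'   length_aa) and `truth` (list with `planted_unique_kos`).
#' @export
simulate_orf_catalog <- function(n_orfs = 1000L, n_kos = 50L,
                                 frac_archaea_unique = 0.2, seed = 1L) {
  stopifnot(frac_archaea_unique >= 0, frac_archaea_unique <= 1)
  if (n_kos > n_orfs) stop("n_kos (", n_kos, ") exceeds n_orfs (", n_orfs, ")")
  n_unique <- round(frac_archaea_unique * n_kos)
  if (n_unique + 2L * (n_kos - n_unique) > n_orfs)
    stop("n_orfs too small: shared KOs need at least two ORFs each")
  withr::with_seed(seed, {
    kos <- sprintf("K%05d", sample.int(99999L, n_kos))
    unique_kos <- sort(if (n_unique > 0L) kos[seq_len(n_unique)] else character(0))
    shared_kos <- setdiff(kos, unique_kos)
    domains <- c("Archaea", "Bacteria", "Eukaryota")
    genera_by_dom <- list(
      Archaea = c("Methanoculleus", "Methanothermobacter", "Methanococcus",
                  "Methanobrevibacter"),
      Bacteria = c("Escherichia", "Bacillus", "Staphylococcus"),
      Eukaryota = c("Saccharomyces", "Triticum"))
    rows <- list(); k <- 0L
    add <- function(ko, dom) {
      k <<- k + 1L
      rows[[k]] <<- data.frame(
        orf_id = sprintf("ORF_%06d", k), ko_id = ko, domain = dom,
        genus = sample(genera_by_dom[[dom]], 1L),
        length_aa = sample(80:800, 1L), stringsAsFactors = FALSE)
    }
    for (ko in unique_kos) add(ko, "Archaea")
    for (ko in shared_kos) for (dom in sample(domains, 2L)) add(ko, dom)
    while (k < n_orfs) {
      ko <- sample(kos, 1L)
      # shared KOs may appear anywhere; unique ones stay archaeal
      add(ko, if (ko %in% unique_kos) "Archaea" else sample(domains, 1L))
    }
    catalog <- do.call(rbind, rows)
    catalog$orf_id <- sprintf("ORF_%06d", seq_len(nrow(catalog)))
    list(catalog = catalog, truth = list(planted_unique_kos = unique_kos))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a labelled target database around a LAMP primer set
#'
#' Builds synthetic genomic fragments for in-silico specificity screening:
#' on-target records carry all six primer binding sites in canonical LAMP
#' order, orientation and spacing (taken from the set's own footprint
#' geometry, with degenerate positions resolved at random); off-target
#' decoys carry the same sites mutated at `decoy_divergence` per base, plus
#' pure-background decoys emulating distant EF-2-like genes that share no
#' full binding sites.
#'
#' @param primer_set A [lamp_primer_set] from [assemble_sets()].
#' @param n_on_target,n_off_target Record counts.
#' @param decoy_divergence Per-base substitution probability applied to
#'   binding sites in divergent decoys.
#' @param flank Background bases added on each side.
#' @param seed Integer seed.
#' @return List with `db` (a [seq_records()]) and `truth` (planted binding
#'   loci and the on-target id set).
#' @export
simulate_target_db <- function(primer_set, n_on_target = 3L, n_off_target = 5L,
                               decoy_divergence = 0.3, flank = 60L, seed = 1L) {
  stopifnot(inherits(primer_set, "lamp_primer_set"))
  roles <- c("F3", "F2", "F1c", "B1c", "B2", "B3")
  prs <- primer_set$primers[roles]
  withr::with_seed(seed, {
    span0 <- min(vapply(prs, function(p) p$start, 0L))
    span1 <- max(vapply(prs, function(p) p$end, 0L))
    make_record <- function(id, genus, mutate_rate) {
      len <- flank + (span1 - span0) + flank
      chars <- .seq_chars(.random_dna(len))
      loci <- list()
      for (role in roles) {
        p <- prs[[role]]
        sense <- if (p$strand == "+") p$seq else reverse_complement(p$seq)
        site <- .seq_chars(sample(expand_degenerate(sense), 1L))
        if (mutate_rate > 0) site <- .mutate_seq(site, mutate_rate)
        at <- flank + (p$start - span0)
        chars[(at + 1L):(at + length(site))] <- site
        loci[[role]] <- list(record_id = id, primer_role = role,
                             start = at, strand = p$strand)
      }
      list(seq = paste(chars, collapse = ""), loci = loci, genus = genus)
    }
    ids <- character(0); seqs <- character(0); genera <- character(0)
    loci <- list(); on_ids <- character(0)
    for (i in seq_len(n_on_target)) {
      id <- sprintf("target_%02d", i)
      r <- make_record(id, primer_set$genus, 0)
      ids <- c(ids, id); seqs <- c(seqs, r$seq)
      genera <- c(genera, primer_set$genus)
      loci <- c(loci, r$loci); on_ids <- c(on_ids, id)
    }
    if (n_off_target > 0L) {
      n_div <- ceiling(n_off_target / 2)
      for (i in seq_len(n_off_target)) {
        id <- sprintf("decoy_%02d", i)
        genus <- sprintf("OffTarget%02d", (i %% 3L) + 1L)
        r <- if (i <= n_div) make_record(id, genus, decoy_divergence)
        else list(seq = .random_dna(flank + (span1 - span0) + flank),
                  loci = NULL, genus = genus)
        ids <- c(ids, id); seqs <- c(seqs, r$seq); genera <- c(genera, genus)
      }
    }
    db <- seq_records(ids, seqs, genus = genera, domain = "Archaea")
    list(db = db,
         truth = list(planted_binding_loci = loci, on_target_ids = on_ids,
                      decoy_divergence = decoy_divergence))
  })
}

#' Simulate a consensus sequence with a planted feasible LAMP layout
#'
#' Rejection-samples six primer footprints (F3, F2, F1, B1, B2, B3) whose
#' sequences individually satisfy the design constraints (length, Tm, GC,
#' end stability) and whose spacing satisfies the F2-B2, loop, F2-F3 and
#' F1-B1 distance windows, then embeds them in random background. Used to
#' exercise the designer on inputs where at least one compliant primer set
#' is known to exist.
#'
#' @param constraints A [design_constraints()] object.
#' @param conditions A [thermo_conditions()] object.
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling attempts per footprint.
#' @return List with `consensus` (character string) and `truth` (planted
#'   footprint coordinates, 0-based half-open, and primer sequences).
#' @export
simulate_lamp_template <- function(constraints = design_constraints(),
                                   conditions = thermo_conditions(),
                                   seed = 1L, max_tries = 20000L) {
  cns <- constraints
  withr::with_seed(seed, {
    draw <- function(len_rng, tm_rng, check5 = FALSE) {
      for (i in seq_len(max_tries)) {
        len <- sample(len_rng[1L]:len_rng[2L], 1L)
        s <- .random_dna(len)
        if (gc_fraction(s) < cns$gc_pct[1L] || gc_fraction(s) > cns$gc_pct[2L]) next
        tm <- .tm_concrete(s, conditions)
        if (tm < tm_rng[1L] || tm > tm_rng[2L]) next
        if (end_stability(s, "3prime", conditions = conditions) >
            cns$dG_3prime_stability_max) next
        if (check5 && end_stability(s, "5prime", conditions = conditions) >
            cns$dG_5prime_stability_max) next
        return(s)
      }
      stop("could not sample a compliant footprint in ", max_tries, " tries")
    }
    # all six drawn in as-synthesized primer space (3'/5' rules apply to
    # the primer, not its footprint); minus-strand primers are embedded as
    # their reverse complement below
    f3 <- draw(cns$len_F3_B3, cns$tm_F3_B3)
    f2 <- draw(cns$len_F2_B2, cns$tm_F2_B2)
    f1c <- draw(cns$len_F1c_B1c, cns$tm_F1c_B1c, check5 = TRUE)
    b1c <- draw(cns$len_F1c_B1c, cns$tm_F1c_B1c, check5 = TRUE)
    b2 <- draw(cns$len_F2_B2, cns$tm_F2_B2)
    b3 <- draw(cns$len_F3_B3, cns$tm_F3_B3)
    f1 <- reverse_complement(f1c)  # sense footprint of F1c
    b1 <- b1c                      # B1c reads the sense strand as-is
    gap_f23 <- sample(cns$dist_F2_F3[1L]:cns$dist_F2_F3[2L], 1L)
    # loop distances are 5'-anchored (F2 5' -> F1 5'), so the footprint gap
    # is the sampled loop distance minus the F2/B2 length
    loop_f <- sample(max(cns$dist_loop_F1c_F2[1L], nchar(f2)):
                       cns$dist_loop_F1c_F2[2L], 1L)
    gap_loop_f <- loop_f - nchar(f2)
    gap_f1b1 <- sample(0:4, 1L)
    loop_b <- sample(max(cns$dist_loop_F1c_F2[1L], nchar(b2)):
                       cns$dist_loop_F1c_F2[2L], 1L)
    gap_loop_b <- loop_b - nchar(b2)
    gap_b23 <- sample(cns$dist_F2_F3[1L]:cns$dist_F2_F3[2L], 1L)
    lead <- 10L; tail <- 10L
    pieces <- list(.random_dna(lead), f3, .random_dna(gap_f23), f2,
                   .random_dna(gap_loop_f), f1, .random_dna(gap_f1b1), b1,
                   .random_dna(gap_loop_b), reverse_complement(b2),
                   .random_dna(gap_b23), reverse_complement(b3),
                   .random_dna(tail))
    lens <- vapply(pieces, nchar, 0L)
    offs <- cumsum(c(0L, lens))[seq_along(lens)]
    consensus <- paste(unlist(pieces), collapse = "")
    fp <- function(i) c(start = offs[i], end = offs[i] + lens[i])
    truth <- list(
      footprints = list(F3 = fp(2L), F2 = fp(4L), F1 = fp(6L), B1 = fp(8L),
                        B2 = fp(10L), B3 = fp(12L)),
      primers = list(F3 = f3, F2 = f2, F1c = f1c, B1c = b1c,
                     B2 = b2, B3 = b3))
    span <- truth$footprints$B2[["end"]] - truth$footprints$F2[["start"]]
    retry <- span < cns$dist_F2_B2[1L] || span > cns$dist_F2_B2[2L]
    if (!retry) {
      # the planted six must also survive the pairwise dimer screen, so a
      # compliant set is guaranteed to exist on this template
      prs <- unlist(truth$primers)
      for (a in 1:5) {
        for (b in (a + 1):6) {
          if (dimer_score(prs[[a]], prs[[b]], conditions) < cns$dG_dimer_min) {
            retry <- TRUE
            break
          }
        }
        if (retry) break
      }
    }
    if (retry)
      return(simulate_lamp_template(cns, conditions, seed + 7919L, max_tries))
    list(consensus = consensus, truth = truth)
  })
}
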