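test_that("FASTA parsing fills metadata from pipe-delimited headers", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a|Methanoculleus", "ACGT", ">b", "acgtacgt"), f)
  recs <- read_fasta(f)
  expect_equal(nrow(recs), 2L)
  expect_equal(recs$genus[1], "Methanoculleus")
  expect_true(is.na(recs$genus[2]))
  expect_equal(recs$seq[2], "ACGTACGT")  # uppercased
})

test_that("non-IUPAC characters are rejected with record and position", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">bad", "ACGZT"), f)
  expect_error(read_fasta(f), "'Z' at position 4.*bad")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  file.create(f2)
  expect_error(read_fasta(f2), "empty")
})

test_that("FASTA write/read round trip preserves ids, sequences and taxonomy", {
  withr::with_seed(21, {
    recs <- seq_records(id = sprintf("r%02d", 1:10),
                       seq = replicate(10, random_dna(sample(50:120, 1))),
                       genus = sample(c("Methanoculleus", NA), 10, TRUE),
                       order = "Methanomicrobiales", domain = "Archaea")
  })
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, f, wrap = 60)
  back <- read_fasta(f)
  expect_equal(back$id, recs$id)
  expect_equal(back$seq, recs$seq)
  expect_equal(back$genus, recs$genus)
  expect_equal(back$domain, recs$domain)
  expect_error(write_fasta(seq_records(c("a", "a"), c("ACGT", "ACGT")), f),
               "duplicate")
})

test_that("simulated alignments hit the requested identities and plant conserved windows", {
  sim <- simulate_marker_alignment(n_genera = 4, seqs_per_genus = 4,
                                   length = 1500, within_identity = 0.9,
                                   between_identity = 0.7,
                                   n_conserved_windows = 3, window_len = 250,
                                   seed = 7)
  aln <- sim$alignment
  expect_equal(nrow(aln$records), 16L)
  expect_equal(aln$length, 1500L)
  wins <- sim$truth$planted_conserved_windows
  expect_length(wins, 3L)
  m <- do.call(rbind, strsplit(aln$records$seq, ""))
  inside <- unlist(lapply(wins, function(w) (w[["start"]] + 1):w[["end"]]))
  # planted windows fully conserved across every record
  expect_true(all(apply(m[, inside], 2, function(col) length(unique(col)) == 1)))
  outside <- setdiff(seq_len(ncol(m)), inside)
  same_genus <- mean(m[1, outside] == m[2, outside])
  diff_genus <- mean(m[1, outside] == m[5, outside])
  expect_lt(abs(same_genus - 0.9), 0.05)
  expect_lt(abs(diff_genus - 0.7), 0.05)
})

test_that("alignment simulation is deterministic and honours degenerate limits", {
  a <- simulate_marker_alignment(seed = 5)
  b <- simulate_marker_alignment(seed = 5)
  expect_identical(a$alignment$records$seq, b$alignment$records$seq)
  allsame <- simulate_marker_alignment(n_genera = 2, seqs_per_genus = 3,
                                       length = 200, within_identity = 1,
                                       between_identity = 1,
                                       n_conserved_windows = 0, window_len = 0,
                                       seed = 1)
  expect_equal(length(unique(allsame$alignment$records$seq)), 1L)
  expect_error(simulate_marker_alignment(length = 400, n_conserved_windows = 3,
                                         window_len = 200, seed = 1),
               "pack")
})

test_that("ORF catalogue simulation plants exactly the requested unique KOs", {
  sim <- simulate_orf_catalog(n_orfs = 1000, n_kos = 50,
                              frac_archaea_unique = 0.2, seed = 13)
  expect_length(sim$truth$planted_unique_kos, 10L)
  cat <- sim$catalog
  for (ko in sim$truth$planted_unique_kos)
    expect_true(all(cat$domain[cat$ko_id == ko] == "Archaea"))
  other <- setdiff(unique(cat$ko_id), sim$truth$planted_unique_kos)
  for (ko in other)
    expect_gte(length(unique(cat$domain[cat$ko_id == ko])), 2L)
  none <- simulate_orf_catalog(n_orfs = 100, n_kos = 10,
                               frac_archaea_unique = 0, seed = 1)
  expect_length(none$truth$planted_unique_kos, 0L)
  expect_error(simulate_orf_catalog(n_orfs = 5, n_kos = 10, seed = 1),
               "exceeds")
  a <- simulate_orf_catalog(seed = 2); b <- simulate_orf_catalog(seed = 2)
  expect_identical(a$catalog, b$catalog)
})

test_that("target databases plant all six sites on-target and diverge decoys", {
  tpl <- simulate_lamp_template(seed = 3)
  roles <- c("F3", "F2", "F1c", "B1c", "B2", "B3")
  cands <- lapply(stats::setNames(roles, roles), function(r)
    enumerate_candidates(tpl$consensus, r))
  set <- assemble_sets(cands, max_sets = 1, genus = "G")[[1]]
  db <- simulate_target_db(set, n_on_target = 2, n_off_target = 2,
                           decoy_divergence = 0, seed = 8)
  # zero divergence: decoy sites identical to target sites (worst case)
  loci <- db$truth$planted_binding_loci
  expect_true(all(vapply(loci, function(l) l$primer_role %in% roles, TRUE)))
  on <- db$db[db$db$id == "target_01", ]
  f3 <- set$primers$F3
  expect_equal(substr(on$seq, loci[[1]]$start + 1,
                      loci[[1]]$start + nchar(f3$seq)) %in%
                 expand_degenerate(f3$seq), TRUE)
  a <- simulate_target_db(set, seed = 4); b <- simulate_target_db(set, seed = 4)
  expect_identical(a$db$seq, b$db$seq)
})
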