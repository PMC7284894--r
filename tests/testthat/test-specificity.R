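make_set <- function(seed = 3) {
  tpl <- simulate_lamp_template(seed = seed)
  roles <- c("F3", "F2", "F1c", "B1c", "B2", "B3")
  cands <- lapply(stats::setNames(roles, roles), function(r)
    enumerate_candidates(tpl$consensus, r))
  assemble_sets(cands, max_sets = 1, genus = "TargetGenus")[[1]]
}

test_that("binding-site scanning matches the brute-force expansion oracle", {
  withr::with_seed(41, {
    for (rep in 1:6) {
      primer <- paste(sample(c("A", "C", "G", "T", "Y", "R"), 18, TRUE,
                             prob = c(rep(0.22, 4), 0.06, 0.06)), collapse = "")
      subject <- random_dna(300)
      # plant an exact site and a one-mismatch site
      site <- expand_degenerate(primer)[1]
      substr(subject, 41, 40 + nchar(site)) <- site
      mut <- site
      substr(mut, 9, 9) <- setdiff(c("A", "C", "G", "T"),
                                   substr(site, 9, 9))[1]
      substr(subject, 141, 140 + nchar(mut)) <- mut
      for (mm in 0:2) {
        rules <- specificity_rules(max_mismatch = mm, max_3prime_mismatch = 0)
        got <- find_binding_sites(primer, subject, rules)
        want <- oracle_scan(primer, subject, max_mm = mm, max_mm3 = 0)
        expect_equal(got$start, want$start)
        expect_equal(got$strand, want$strand)
        expect_equal(got$mismatches, want$mismatches)
      }
    }
  })
})

test_that("mismatch tolerance is monotone and reverse-strand sites are found", {
  primer <- "GCATTGCCAGTACGGATCAA"
  subject <- paste0(strrep("A", 30), reverse_complement(primer), strrep("C", 30))
  hits <- find_binding_sites(primer, subject, specificity_rules(0, 0))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "-")
  expect_equal(hits$start, 30L)
  # internal mismatch found at max_mismatch 1 but not 0 (position 39 sits
  # away from the primer's 3'-terminal 5 nt on the minus strand)
  mut <- subject
  substr(mut, 39, 39) <- "A"
  expect_equal(nrow(find_binding_sites(primer, mut, specificity_rules(0, 0))), 0L)
  expect_equal(nrow(find_binding_sites(primer, mut, specificity_rules(1, 0))), 1L)
  withr::with_seed(42, {
    subject2 <- random_dna(500)
    n_prev <- -1L
    for (mm in 0:3) {
      n <- nrow(find_binding_sites(primer, subject2,
                                   specificity_rules(mm, mm)))
      expect_gte(n, n_prev)
      n_prev <- n
    }
  })
})

test_that("3'-terminal mismatches gate hits independently of total mismatches", {
  primer <- "GCATTGCCAGTACGGATCAA"
  subject <- paste0(strrep("C", 20), primer, strrep("C", 20))
  # mutate the 3'-terminal base of the planted site
  mut <- subject
  substr(mut, 40, 40) <- "G"
  expect_equal(nrow(find_binding_sites(primer, mut, specificity_rules(2, 0))), 0L)
  expect_equal(nrow(find_binding_sites(primer, mut, specificity_rules(2, 1))), 1L)
})

test_that("amplification calls recover planted truth with precision and recall 1", {
  set <- make_set(seed = 3)
  db <- simulate_target_db(set, n_on_target = 3, n_off_target = 6,
                           decoy_divergence = 0.3, seed = 19)
  calls <- lapply(seq_len(nrow(db$db)), function(i)
    predict_amplification(set, db$db[i, , drop = FALSE]))
  pos_ids <- db$db$id[vapply(calls, function(x) x$positive, TRUE)]
  expect_setequal(pos_ids, db$truth$on_target_ids)
  # positives carry full supporting geometry, one hit per role
  for (cl in calls[vapply(calls, function(x) x$positive, TRUE)]) {
    expect_equal(cl$geometry$role, c("F3", "F2", "F1c", "B1c", "B2", "B3"))
    expect_true(all(diff(cl$geometry$start) > 0))
  }
})

test_that("a subject missing one inner site is negative", {
  set <- make_set(seed = 5)
  db <- simulate_target_db(set, n_on_target = 1, n_off_target = 0, seed = 2)
  rec <- db$db[1, , drop = FALSE]
  expect_true(predict_amplification(set, rec)$positive)
  # knock out the F2 site
  f2 <- db$truth$planted_binding_loci[["F2"]]
  broken <- rec
  len <- nchar(set$primers$F2$seq)
  substr(broken$seq, f2$start + 1, f2$start + len) <- strrep("A", len)
  expect_false(predict_amplification(set, broken)$positive)
  # subjects are recognized in reverse-complement orientation too
  flipped <- rec
  flipped$seq <- reverse_complement(rec$seq)
  expect_true(predict_amplification(set, flipped)$positive)
})

test_that("eukaryotic-style decoys with only partial primer matches stay negative", {
  set <- make_set(seed = 8)
  withr::with_seed(23, {
    decoy <- random_dna(400)
    # plant just the two outer primer sites, no inner geometry
    f3 <- set$primers$F3$seq
    substr(decoy, 51, 50 + nchar(f3)) <- expand_degenerate(f3)[1]
  })
  rec <- seq_records("euk_decoy", decoy, genus = "Triticum")
  expect_false(predict_amplification(set, rec)$positive)
})

test_that("the specificity matrix labels genus-specific sets correctly", {
  set <- make_set(seed = 3)
  db <- simulate_target_db(set, n_on_target = 2, n_off_target = 4,
                           decoy_divergence = 0.35, seed = 29)
  m <- specificity_matrix(set, db$db)
  expect_true(attr(m, "specific"))
  expect_equal(sum(m$n_positive), 2L)
  expect_equal(m$n_positive[m$genus == "TargetGenus"], 2L)
  # planting full sites in an off-target genus breaks specificity
  clone <- db$db
  clone$genus[clone$id == "target_02"] <- "OffTargetX"
  m2 <- specificity_matrix(set, clone)
  expect_false(attr(m2, "specific"))
  empty <- specificity_matrix(set, db$db[0, , drop = FALSE])
  expect_equal(nrow(empty), 0L)
})
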