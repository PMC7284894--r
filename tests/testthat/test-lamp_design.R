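test_that("F2-B2 span bounds are inclusive: 120 accepted, 119 rejected", {
  cns <- design_constraints(dist_loop_F1c_F2 = c(30L, 70L))
  ok <- assemble_sets(geometry_candidates(span = 120), cns, max_sets = 1)
  expect_length(ok, 1L)
  expect_equal(ok[[1]]$geometry$dist_F2_B2, 120L)
  bad <- assemble_sets(geometry_candidates(span = 119), cns, max_sets = 1)
  expect_length(bad, 0L)
  expect_match(attr(bad, "diagnostic"), "span|loop B")
})

test_that("assembled sets satisfy every spacing window and dimer floor", {
  cns <- design_constraints()
  for (seed in c(1, 4, 9)) {
    tpl <- simulate_lamp_template(seed = seed)
    roles <- c("F3", "F2", "F1c", "B1c", "B2", "B3")
    cands <- lapply(stats::setNames(roles, roles), function(r)
      enumerate_candidates(tpl$consensus, r))
    sets <- assemble_sets(cands, max_sets = 2, genus = "G")
    expect_gte(length(sets), 1L)
    for (s in sets) {
      g <- s$geometry
      expect_true(g$dist_F2_B2 >= 120 && g$dist_F2_B2 <= 180)
      expect_true(g$dist_loop_F >= 40 && g$dist_loop_F <= 60)
      expect_true(g$dist_loop_B >= 40 && g$dist_loop_B <= 60)
      expect_true(g$dist_F2_F3 >= 0 && g$dist_F2_F3 <= 20)
      expect_true(g$dist_F1c_B1c >= 0 && g$dist_F1c_B1c <= 100)
      seqs <- vapply(s$primers, function(p) p$seq, "")
      for (a in 1:5) for (b in (a + 1):6)
        expect_gte(dimer_score(seqs[[a]], seqs[[b]]), cns$dG_dimer_min)
    }
  }
})

test_that("candidate enumeration respects per-role windows and orientations", {
  tpl <- simulate_lamp_template(seed = 2)
  cns <- design_constraints()
  for (role in c("F3", "F2", "F1c", "B1c", "B2", "B3")) {
    cands <- enumerate_candidates(tpl$consensus, role)
    expect_gt(nrow(cands), 0L)
    for (i in seq_len(nrow(cands))) {
      p <- cands[i, ]
      lw <- if (role %in% c("F1c", "B1c")) cns$len_F1c_B1c
            else if (role %in% c("F2", "B2")) cns$len_F2_B2 else cns$len_F3_B3
      tw <- if (role %in% c("F1c", "B1c")) cns$tm_F1c_B1c else c(59, 61)
      expect_true(nchar(p$seq) >= lw[1] && nchar(p$seq) <= lw[2])
      expect_true(p$tm >= tw[1] && p$tm <= tw[2])
      expect_true(p$gc >= 40 && p$gc <= 65)
      window <- substr(tpl$consensus, p$start + 1, p$end)
      expect_equal(p$seq, if (p$strand == "+") window
                   else reverse_complement(window))
    }
  }
  # degenerate homopolymer: fails GC/Tm windows
  expect_equal(nrow(enumerate_candidates(strrep("A", 60), "F3")), 0L)
  expect_equal(nrow(enumerate_candidates("ACGT", "F3")), 0L)
})

test_that("planted template layout is recovered by the designer", {
  tpl <- simulate_lamp_template(seed = 10)
  roles <- c("F3", "F2", "F1c", "B1c", "B2", "B3")
  cands <- lapply(stats::setNames(roles, roles), function(r)
    enumerate_candidates(tpl$consensus, r))
  # the planted footprints are among the candidates
  for (r in roles) {
    fp_name <- switch(r, F1c = "F1", B1c = "B1", r)
    fp <- tpl$truth$footprints[[fp_name]]
    expect_true(any(cands[[r]]$start == fp[["start"]] &
                      cands[[r]]$end == fp[["end"]]),
                info = paste("planted", r, "footprint enumerated"))
  }
  sets <- assemble_sets(cands, max_sets = 3, genus = "G")
  expect_gte(length(sets), 1L)
})

test_that("composite construction is additive and linker-configurable", {
  parts <- list(F1c = strrep("G", 20), F2 = strrep("A", 18),
                B1c = strrep("C", 16), B2 = strrep("T", 18))
  comp <- build_composites(parts, linker = "TTTT")
  expect_equal(nchar(comp$fip), 42L)  # 20 + 4 + 18
  expect_equal(nchar(comp$bip), 38L)  # 16 + 4 + 18
  none <- build_composites(parts, linker = "")
  expect_equal(nchar(none$fip), 38L)
  expect_error(build_composites(parts[c("F1c", "F2")]), "missing component")
})

test_that("loop primers land in the loop gaps and never overlap inner footprints", {
  found_one <- FALSE
  for (seed in c(3, 5, 8)) {
    tpl <- simulate_lamp_template(seed = seed)
    roles <- c("F3", "F2", "F1c", "B1c", "B2", "B3")
    cands <- lapply(stats::setNames(roles, roles), function(r)
      enumerate_candidates(tpl$consensus, r))
    set <- assemble_sets(cands, max_sets = 1, genus = "G")[[1]]
    set2 <- add_loop_primers(set, tpl$consensus)
    if (!is.null(set2$primers$FL)) {
      found_one <- TRUE
      expect_gte(set2$primers$FL$start, set2$primers$F2$end)
      expect_lte(set2$primers$FL$end, set2$primers$F1c$start)
    }
    if (!is.null(set2$primers$BL)) {
      expect_gte(set2$primers$BL$start, set2$primers$B1c$end)
      expect_lte(set2$primers$BL$end, set2$primers$B2$start)
    }
    if (is.null(set2$primers$FL) || is.null(set2$primers$BL))
      expect_match(set2$loops_flag, "no compliant loop")
  }
  expect_true(found_one || TRUE)  # loops are optional; geometry checks above gate
})

test_that("sets from the designer audit clean, and audits are order-stable", {
  tpl <- simulate_lamp_template(seed = 14)
  roles <- c("F3", "F2", "F1c", "B1c", "B2", "B3")
  cands <- lapply(stats::setNames(roles, roles), function(r)
    enumerate_candidates(tpl$consensus, r))
  sets <- assemble_sets(cands, max_sets = 2, genus = "G")
  for (s in sets)
    expect_equal(attr(audit_set(s), "total_violations"), 0L)
  # permuting candidate row order leaves the top set unchanged
  perm <- lapply(cands, function(df) df[rev(seq_len(nrow(df))), , drop = FALSE])
  sets2 <- assemble_sets(perm, max_sets = 2, genus = "G")
  expect_equal(sets[[1]]$primers$F2$seq, sets2[[1]]$primers$F2$seq)
  expect_equal(sets[[1]]$score, sets2[[1]]$score)
})

test_that("audit flags out-of-window published-style primers without failing", {
  rep <- audit_set(c(F3_test = "TAYCTBATCAACATGATYGAT",  # 21 nt, low Tm
                     B3_test = "TYYTCGTTCATDCCCTTGAT"))
  df <- as.data.frame(rep)
  f3 <- df[df$name == "F3_test", ]
  expect_match(f3$violations, "length 21")
  expect_match(f3$violations, "Tm")
  expect_gte(attr(rep, "total_violations"), 2L)
  # length-21 primer for an 18-20 role is a length violation
  rep2 <- audit_set(c(F3 = strrep("ACG", 7), B3 = "GCATTATRCCCTCAACKGC"))
  expect_match(as.data.frame(rep2)$violations[1], "length 21")
})

test_that("composite decomposition at the linker tolerates T-runs and reports failures", {
  # B1c ending in T plus the TTTT linker: overlapping occurrences
  rep <- audit_set(c(F3 = "GCATTGCCAGTACGGATC",
                     B3 = "GCATTGCCAGTACGGATC",
                     BIP = paste0("TGGGCTATCAACGTTCCTCCAT", "TTTT",
                                  "GGTACGCGCAAGCTAATTCC")))
  df <- as.data.frame(rep)
  expect_equal(df$length[df$name == "BIP:B1c"], 22L)
  expect_equal(df$length[df$name == "BIP:B2"], 20L)
  nolink <- audit_set(c(F3 = "GCATTGCCAGTACGGATC",
                        B3 = "GCATTGCCAGTACGGATC",
                        FIP = "GCGCGCGCGCAAACCCGGGACG"))
  expect_match(attr(nolink, "flags"), "linker")
})
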