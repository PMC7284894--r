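# minimal hand-built candidate rows for geometry tests; poly-A sequences
# cannot dimerize and the fields assemble_sets needs are filled directly
fake_candidate <- function(role, start, len) {
  data.frame(role = role, start = start, end = start + len,
             strand = if (role %in% c("F3", "F2", "B1c")) "+" else "-",
             seq = paste(rep("A", len), collapse = ""),
             tm = 60, gc = 50, dG3 = -5, dG5 = -5, degeneracy = 1L,
             stringsAsFactors = FALSE)
}

# layout: F3 [0,20), F2 [25,45), F1 [65,85), B1 [85,105), B2 ends at
# 25 + span; a loop window widened to [30,70] isolates the span bound
geometry_candidates <- function(span) {
  list(F3 = fake_candidate("F3", 0, 20),
       F2 = fake_candidate("F2", 25, 20),
       F1c = fake_candidate("F1c", 65, 20),
       B1c = fake_candidate("B1c", 85, 20),
       B2 = fake_candidate("B2", 25 + span - 20, 20),
       B3 = fake_candidate("B3", 25 + span + 5, 20))
}
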