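test_that("column conservation classes follow the occurrence and class rules", {
  aln <- c(a = "KDA", b = "KEV", c = "KEL", d = "TAI", e = "AGM", f = "SSF")
  cc <- classify_columns(aln)
  # K,K,K,T,A,S: identical (K x3); D,E,E,A,G,S: class (negative x3, not
  # identical); A,V,L,I,M,F: nonpolar x6 -> class conserved
  expect_equal(cc$class,
               c("identical_conserved", "class_conserved", "class_conserved"))
  # D,K,S,A,L,W: no residue or class reaches 3 (polar x2, nonpolar x2)
  aln2 <- c(a = "D", b = "K", c = "S", d = "A", e = "L", f = "W")
  expect_equal(classify_columns(aln2)$class, "unconserved")
  # gaps never count toward any tally
  aln3 <- c(a = "K", b = "K", c = "-", d = "-", e = "K", f = "T")
  expect_equal(classify_columns(aln3)$class, "identical_conserved")
  aln4 <- c(a = "K", b = "K", c = "-", d = "-", e = "-", f = "T")
  expect_equal(classify_columns(aln4)$class, "unconserved")
})

test_that("classification and support agree with a per-column recount on random alignments", {
  alpha <- c(unlist(strsplit("ACDEFGHIKLMNPQRSTVWY", "")), "-")
  for (seed in 1:5) {
    set.seed(seed)
    aln <- vapply(1:6, function(i)
      paste(sample(alpha, 40, replace = TRUE), collapse = ""), character(1))
    names(aln) <- paste0("row", 1:6)
    got <- classify_columns(aln, target_id = "row1")
    want <- oracle_classify(aln, target_id = "row1")
    expect_equal(got$class, want$class)
    expect_equal(got$basic_support, want$support)
    cand <- find_candidate_columns(aln, "row1", min_support = 3)
    tchars <- strsplit(aln[["row1"]], "")[[1]]
    manual <- which(want$support >= 3 & !tchars %in% c("K", "R", "-"))
    expect_setequal(cand$column, manual)
  }
})

test_that("candidate columns require a non-basic, non-gap target residue", {
  # col1: target S, support 3 -> kept; col2: target K (basic) -> excluded;
  # col3: target gapped -> excluded; col4: support only 2 -> excluded
  aln <- c(FGF1 = "SK-A", o1 = "KKKK", o2 = "RKKR", o3 = "KKKT", o4 = "TTTT")
  expect_equal(find_candidate_columns(aln, "FGF1")$column, 1L)
  aln2 <- c(FGF1 = "SKGA", o1 = "KKKK", o2 = "RKKR", o3 = "KKKK", o4 = "TTTT")
  expect_setequal(find_candidate_columns(aln2, "FGF1")$column, c(1, 3, 4))
  expect_error(find_candidate_columns(aln, "nope"), "target_id")
})

test_that("numbering conversion matches the sequence-derived mapping", {
  full <- fgf1_full_sequence()
  ggs <- fgf1_gg_sequence()
  cons <- fgf1_construct_sequence()
  # independent oracle: locate both strings inside the full-length sequence
  off_g <- as.integer(regexpr(ggs, full, fixed = TRUE)) - 1L     # 15
  off_c <- as.integer(regexpr(substr(cons, 3, nchar(cons)), full,
                              fixed = TRUE)) - 3L                # 18
  expect_equal(off_g, 15L)
  expect_equal(off_c, 18L)
  for (g in seq_len(140)) {
    expected <- g + off_g - off_c
    if (expected >= 3 && expected <= nchar(cons)) {
      p <- convert_numbering(g, "gimenez_gallego", "construct")
      expect_identical(p, expected)
      # the residues really are the same letter
      expect_identical(substr(ggs, g, g), substr(cons, p, p))
      # round trip
      expect_identical(convert_numbering(p, "construct", "gimenez_gallego"), g)
    } else {
      expect_error(convert_numbering(g, "gimenez_gallego", "construct"),
                   "unmapped")
    }
  }
  # the Met-Ala leader has no Gimenez-Gallego number
  expect_error(convert_numbering(1, "construct", "gimenez_gallego"))
  expect_error(convert_numbering(150, "gimenez_gallego", "full_length"),
               "outside")
})

test_that("apply_mutations validates wild types, preserves length, and commutes", {
  base <- fgf1_construct_sequence()
  mm <- parse_mutation(c("S116R", "S17K", "L72R"))
  mut <- apply_mutations(base, mm)
  expect_equal(nchar(mut), nchar(base))
  expect_equal(hamming_distance(base, mut), 3L)
  idx <- vapply(c(116, 17, 72), convert_numbering, integer(1),
                from = "gimenez_gallego", to = "construct")
  expect_equal(substring(mut, idx, idx), c("R", "K", "R"))
  # order independence
  expect_identical(apply_mutations(base, mm[c(3, 1, 2), ]), mut)
  # empty set is the identity
  expect_identical(apply_mutations(base, parse_mutation(character(0))), base)
  # re-applying fails the wild-type check (S is gone)
  expect_error(apply_mutations(mut, parse_mutation("S116R")),
               "wild-type mismatch.*S116R")
  # typeset variant "S17 K" is tolerated
  expect_identical(parse_mutation("S17 K"), parse_mutation("S17K"))
})

test_that("the variant panel has 13 members with the shared mutation sets", {
  panel <- build_variant_panel()
  expect_length(panel, 13L)
  expect_s3_class(panel[["FGF1_HS_BCD"]], "variant_definition")
  for (v in panel) {
    mm <- variant_mutations(v)
    expect_true(all(c("Y94", "N95") %in% paste0(mm$wt, mm$position)))
    expect_setequal(
      paste0(mm$wt[mm$tag == "stability"], mm$position[mm$tag == "stability"],
             mm$new[mm$tag == "stability"]),
      c("C16S", "Q40P", "S47I", "C83S", "H93G", "C117S"))
    expect_equal(nchar(v$sequence), nchar(fgf1_construct_sequence()))
  }
  # ABCD differs from the base variant at exactly 4 positions
  expect_equal(hamming_distance(panel[["FGF1_HS"]]$sequence,
                                panel[["FGF1_HS_ABCD"]]$sequence), 4L)
  # manifest + FASTA round trip
  fa <- withr::local_tempfile(fileext = ".fasta")
  mf <- withr::local_tempfile(fileext = ".csv")
  manifest <- write_variant_panel(panel, fa, mf)
  expect_equal(sort(unique(manifest$variant)), sort(names(panel)))
  seqs <- read_alignment(fa)
  expect_identical(unname(seqs[["FGF1_HS_BCD"]]),
                   panel[["FGF1_HS_BCD"]]$sequence)
})
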