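test_that("PDB parsing flags ligands, drops waters, and reports malformed lines", {
  st <- make_toy_complex(6, 5, seed = 2)
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_structure(st, tf)
  rt <- read_structure(tf)
  expect_equal(sum(rt$is_ligand), sum(st$is_ligand))
  # ligand-name override reassigns flags
  rt2 <- read_structure(tf, ligand_names = character(0))
  expect_equal(sum(rt2$is_ligand), 0L)
  rt3 <- read_structure(tf, ligand_names = c("LIG", "ALA"))
  expect_equal(sum(rt3$is_ligand), nrow(rt3))
  # waters-only input is rejected
  waters <- paste0(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O")
  expect_error(read_structure(waters), "waters|ligand|protein")
  # malformed coordinate field errors with its line number
  lines <- readLines(tf)
  i <- grep("^ATOM", lines)[3]
  substr(lines[i], 33, 36) <- "abcd"
  expect_error(read_structure(paste(lines, collapse = "\n")),
               paste0("line ", i))
})

test_that("ligand distance equals the 3-4-5 construction and the all-pairs oracle", {
  # residue atom at (3,4,0), ligand atom at the origin -> 5 A
  df <- data.frame(
    eleno = 1:3, atom = c("CA", "CB", "C1"),
    resname = c("ALA", "ALA", "LIG"), chain = c("A", "A", "L"),
    resno = c(1L, 1L, 1L), x = c(3, 10, 0), y = c(4, 10, 0),
    z = c(0, 10, 0), element = c("C", "C", "C"),
    is_ligand = c(FALSE, FALSE, TRUE), stringsAsFactors = FALSE)
  class(df) <- c("fgf_structure", "data.frame")
  expect_equal(min_distance_to_ligand(df, 1), 5)
  # adding a farther ligand atom leaves the minimum unchanged
  df2 <- rbind(df, transform(df[3, ], eleno = 4, atom = "C2", x = 50))
  class(df2) <- c("fgf_structure", "data.frame")
  expect_equal(min_distance_to_ligand(df2, 1), 5)
  expect_error(min_distance_to_ligand(df, 99), "not found")
  # random structures vs brute force, including one ~500-atom instance
  sizes <- list(c(8, 4), c(20, 6), c(80, 6))
  for (k in seq_along(sizes)) {
    st <- random_structure(sizes[[k]][1], sizes[[k]][2], seed = k)
    for (p in sample(sizes[[k]][1], 5))
      expect_equal(min_distance_to_ligand(st, p), oracle_min_dist(st, p),
                   tolerance = 1e-9)
  }
})

test_that("clash detection equals the brute-force oracle under identical exclusions", {
  for (seed in 1:4) {
    st <- random_structure(15, 6, box = 14, seed = seed)
    for (p in 2:14) {
      got <- detect_clashes(st, p, clash_cutoff = 2.4)
      expect_identical(got$clash, oracle_clash(st, p, 2.4),
                       info = paste("seed", seed, "res", p))
    }
  }
  # far-field: nearest non-neighbor atom beyond the cutoff -> no clash
  st <- make_toy_complex(9, 6, seed = 1)
  expect_false(detect_clashes(st, 5, clash_cutoff = 2.4)$clash)
})

test_that("in-silico substitution edits only the side chain, with template arithmetic", {
  st <- make_toy_complex(9, 5, seed = 1, sequence = "AAAASAAAA")
  bb_before <- subset(as.data.frame(st), resno == 5 &
                        atom %in% c("N", "CA", "C", "O"))
  # S -> K adds exactly the four Lys heavy atoms beyond CB
  mk <- mutate_residue(st, 5, "K")
  expect_equal(nrow(mk) - nrow(st), 4L)
  expect_setequal(mk$atom[mk$resno == 5 & !mk$is_ligand & mk$chain == "A"],
                  c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ"))
  bb_after <- subset(as.data.frame(mk), resno == 5 & chain == "A" &
                       atom %in% c("N", "CA", "C", "O"))
  expect_equal(bb_after[order(bb_after$atom), c("x", "y", "z")],
               bb_before[order(bb_before$atom), c("x", "y", "z")],
               ignore_attr = TRUE)
  # terminal atom sits |template| * 1.53 A from CB along the CA->CB axis
  cb <- unlist(subset(as.data.frame(mk), resno == 5 & atom == "CB",
                      c("x", "y", "z")))
  ca <- unlist(subset(as.data.frame(mk), resno == 5 & atom == "CA",
                      c("x", "y", "z")))
  nz <- unlist(subset(as.data.frame(mk), resno == 5 & atom == "NZ",
                      c("x", "y", "z")))
  u <- (cb - ca) / sqrt(sum((cb - ca)^2))
  expect_equal(unname(nz), unname(cb + 4 * 1.53 * u), tolerance = 1e-9)
  # shrinking to Gly truncates to backbone only
  mg <- mutate_residue(st, 5, "G")
  expect_setequal(mg$atom[mg$resno == 5 & !mg$is_ligand & mg$chain == "A"],
                  c("N", "CA", "C", "O"))
  expect_lt(nrow(mg), nrow(st))
  # a Gly source residue gets a rebuilt CB before extension
  mr <- mutate_residue(mg, 5, "R")
  expect_true("CB" %in% mr$atom[mr$resno == 5 & mr$chain == "A"])
  expect_equal(sum(mr$resno == 5 & !mr$is_ligand & mr$chain == "A"), 11L)
})

test_that("the candidate pipeline recovers planted sites and honors cutoffs", {
  # 3 planted passers + 1 far decoy + 1 clashing decoy -> exactly 3
  target <- strrep("S", 40)
  sm <- c("10" = 3L, "18" = 4L, "26" = 3L, "33" = 3L, "5" = 3L)
  aln <- make_toy_alignment(target, sm, n_rows = 6, seed = 11)
  st <- make_toy_complex(40, 5, clash_positions = 33, seed = 11,
                         near_positions = c(10, 18, 26, 33))
  cand <- design_candidates(aln, "FGF1", st, target_scheme = "full_length",
                            vicinity_cutoff = 8, min_support = 3)
  expect_setequal(cand$position, c(10, 18, 26))  # 5 is far, 33 clashes
  expect_true(all(cand$proposed == "R"))          # R preferred when both pass
  expect_false(any(cand$clash))
  expect_equal(cand$rank, seq_len(nrow(cand)))
  # zero vicinity cutoff excludes everything
  cand0 <- design_candidates(aln, "FGF1", st,
                             target_scheme = "full_length",
                             vicinity_cutoff = 0)
  expect_equal(nrow(cand0), 0L)
  # monotonicity: candidates non-decreasing in vicinity cutoff,
  # non-increasing in support threshold and in clash strictness
  counts_vic <- vapply(c(0, 3, 5, 8, 30), function(v)
    nrow(design_candidates(aln, "FGF1", st, target_scheme = "full_length",
                           vicinity_cutoff = v)), integer(1))
  expect_true(all(diff(counts_vic) >= 0))
  counts_sup <- vapply(c(1, 3, 4, 5), function(s)
    nrow(design_candidates(aln, "FGF1", st, target_scheme = "full_length",
                           min_support = s)), integer(1))
  expect_true(all(diff(counts_sup) <= 0))
  counts_clash <- vapply(c(0.5, 2.4, 4.0), function(cl)
    nrow(design_candidates(aln, "FGF1", st, target_scheme = "full_length",
                           clash_cutoff = cl)), integer(1))
  expect_true(all(diff(counts_clash) <= 0))
})

test_that("design output is invariant to rigid-body motion of the structure", {
  target <- strrep("S", 30)
  sm <- c("8" = 3L, "15" = 4L, "22" = 3L)
  aln <- make_toy_alignment(target, sm, n_rows = 6, seed = 4)
  st <- make_toy_complex(30, 5, seed = 4, near_positions = c(8, 15, 22))
  cand <- design_candidates(aln, "FGF1", st, target_scheme = "full_length")
  R <- random_rotation(99)
  st_rot <- rotate_structure(st, R, shift = c(11.2, -5.1, 3.3))
  cand_rot <- design_candidates(aln, "FGF1", st_rot,
                                target_scheme = "full_length")
  expect_equal(cand_rot$position, cand$position)
  expect_equal(cand_rot$proposed, cand$proposed)
  expect_equal(cand_rot$min_dist_A, cand$min_dist_A, tolerance = 1e-9)
  # and to atom order
  perm <- sample(nrow(st))
  st_perm <- st[perm, ]
  class(st_perm) <- class(st)
  cand_perm <- design_candidates(aln, "FGF1", st_perm,
                                 target_scheme = "full_length")
  expect_equal(cand_perm$position, cand$position)
  expect_equal(cand_perm$min_dist_A, cand$min_dist_A)
})
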