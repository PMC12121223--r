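test_that("toy complexes place the ligand at the requested offset and are deterministic", {
  st <- make_toy_complex(10, ligand_offset = 5, seed = 1)
  flagged <- attr(st, "near_positions")
  expect_equal(min_distance_to_ligand(st, flagged), 5.0)
  st2 <- make_toy_complex(10, ligand_offset = 5, seed = 1)
  expect_identical(st, st2)
  # offset is exact for every anchored residue, and only for them
  st3 <- make_toy_complex(30, ligand_offset = 6.5, seed = 2,
                          near_positions = c(5, 14, 22))
  for (p in c(5, 14, 22))
    expect_equal(min_distance_to_ligand(st3, p), 6.5)
  expect_gt(min_distance_to_ligand(st3, 28), 6.5)
})

test_that("planted clash positions clash after side-chain extension, verified by oracle", {
  st <- make_toy_complex(10, 5, clash_positions = c(4), seed = 1)
  expect_false(detect_clashes(st, 4)$clash)   # wild type is clash-free
  mut <- mutate_residue(st, 4, "K")
  res <- detect_clashes(mut, 4)
  expect_true(res$clash)
  expect_true(oracle_clash(mut, 4))
  expect_gt(nrow(res$pairs), 0)
  # an untouched residue stays clash-free
  mut7 <- mutate_residue(st, 7, "R")
  expect_false(detect_clashes(mut7, 7)$clash)
  expect_false(oracle_clash(mut7, 7))
  expect_error(make_toy_complex(10, 5, clash_positions = 11),
               "clash_positions")
  expect_error(make_toy_complex(2, 5), "n_residues")
})

test_that("generated PDB text re-parses to the identical atom set", {
  st <- make_toy_complex(8, 4.2, clash_positions = 3, seed = 9,
                         sequence = "ASTDEGLV")
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_structure(st, tf)
  rt <- read_structure(tf)
  expect_equal(nrow(rt), nrow(st))
  for (col in c("atom", "resname", "chain", "resno", "x", "y", "z",
                "is_ligand"))
    expect_equal(rt[[col]], st[[col]], ignore_attr = TRUE)
  # idempotence: a second write-read cycle changes nothing
  tf2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(rt, tf2)
  expect_equal(read_structure(tf2), rt, ignore_attr = TRUE)
})

test_that("toy alignments carry exactly the planted basic-residue support", {
  target <- "ASTLSENQVT"
  sm <- c("2" = 2L, "5" = 3L, "8" = 4L)
  aln <- make_toy_alignment(target, sm, n_rows = 6, seed = 3)
  expect_identical(aln[["FGF1"]], target)
  recount <- oracle_classify(aln, target_id = "FGF1")
  expect_equal(recount$support[c(2, 5, 8)], c(2L, 3L, 4L))
  expect_true(all(recount$support[-c(2, 5, 8)] == 0))
  expect_equal(recount$support, attr(aln, "support_map"),
               ignore_attr = TRUE)
  # threshold rule: support-3 and support-4 columns marked, support-2 not
  cand <- find_candidate_columns(aln, "FGF1", min_support = 3)
  expect_setequal(cand$column, c(5, 8))
  # determinism and impossible counts
  expect_identical(make_toy_alignment(target, sm, 6, seed = 3), aln)
  expect_error(make_toy_alignment(target, c("2" = 6L), n_rows = 6),
               "impossible")
})

test_that("sensorgram generator follows the closed-form binding model", {
  spec0 <- synthetic_spec(seed = 1, noise_sd = 0)
  # at C = KD the association plateau is rmax / 2
  kon <- 0.42; koff <- 0.15; rmax <- 2
  kd <- koff / kon
  sg <- simulate_sensorgram(kon, koff, rmax, kd, t_assoc = 2000,
                            t_dissoc = 100, spec = spec0)
  plateau <- max(sg$response[sg$phase == "association"])
  expect_equal(plateau, rmax / 2, tolerance = 1e-6)
  # observed association rate is kon*C + koff (0.318 1/s for C = 0.4)
  sg4 <- simulate_sensorgram(kon, koff, rmax, 0.4, spec = spec0)
  a <- sg4[sg4$phase == "association", ]
  kobs <- 0.42 * 0.4 + 0.15
  req <- rmax * 0.4 / (0.4 + kd)
  expect_equal(a$response, req * (1 - exp(-kobs * a$time_s)),
               tolerance = 1e-12)
  expect_equal(kobs, 0.318)
  # dissociation tail decays to zero
  sg_long <- simulate_sensorgram(kon, koff, rmax, 0.4, t_dissoc = 2000,
                                 spec = spec0)
  expect_lt(min(tail(sg_long$response, 5)), 1e-6)
  expect_error(simulate_sensorgram(-1, 0.1, 1, 0.4), "rates")
  expect_error(simulate_sensorgram(1, 0.1, 1, numeric(0)), "concentrations")
})

test_that("melting-curve generator matches the two-state model and its noise contract", {
  spec0 <- synthetic_spec(seed = 1, noise_sd = 0)
  bl <- c(0.1, -0.0005, 1.0, -0.002)
  mc <- simulate_melting_curve(66.32, 300, baselines = bl, spec = spec0)
  # at T = tm the signal is exactly midway between the two baselines
  mid_n <- bl[1] + bl[2] * 66.32
  mid_d <- bl[3] + bl[4] * 66.32
  sig_tm <- two_state_signal(66.32, 66.32, 300, bl[1:2], bl[3:4])
  expect_equal(sig_tm, (mid_n + mid_d) / 2)
  expect_equal(mc$signal, two_state_signal(mc$temp_C, 66.32, 300,
                                           bl[1:2], bl[3:4]))
  expect_error(simulate_melting_curve(15, 300), "scan window")
  expect_error(simulate_melting_curve(66, -5), "dH")
  # identical spec -> identical noisy curve; different seed -> different
  spec_n <- synthetic_spec(seed = 7, noise_sd = 0.01)
  m1 <- simulate_melting_curve(66.32, 300, spec = spec_n)
  m2 <- simulate_melting_curve(66.32, 300, spec = spec_n)
  m3 <- simulate_melting_curve(66.32, 300,
                               spec = synthetic_spec(8, noise_sd = 0.01))
  expect_identical(m1, m2)
  expect_false(identical(m1$signal, m3$signal))
})

test_that("generators leave the global RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_melting_curve(66, 300,
                                   spec = synthetic_spec(5, noise_sd = 0.1)))
  invisible(simulate_sensorgram(0.4, 0.2, 1, 0.4,
                                spec = synthetic_spec(5, noise_sd = 0.1)))
  invisible(make_toy_alignment("ASTL", c("2" = 2L), 5, seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("elution generator round-trips the peak molarity and scales with calibration", {
  cal <- gradient_calibration(slope = 61, intercept = 36.5)
  spec0 <- synthetic_spec(seed = 1, noise_sd = 0)
  pr <- simulate_elution(cal, 1.60, spec = spec0)
  pk <- elution_peak(pr, cal)
  expect_equal(pk$peak_nacl, 1.60, tolerance = 1e-3)
  # doubling the slope doubles peak conductivity relative to the intercept
  cal2 <- gradient_calibration(slope = 122, intercept = 36.5)
  pk2 <- elution_peak(simulate_elution(cal2, 1.60, spec = spec0), cal2)
  expect_equal(pk2$peak_conductivity - 36.5,
               2 * (pk$peak_conductivity - 36.5), tolerance = 1e-6)
  expect_error(simulate_elution(cal, 2.5), "gradient")
  # noisy profiles: recovered peak within 0.01 M across seeds
  for (s in 1:3) {
    prn <- simulate_elution(cal, 1.46, spec = synthetic_spec(s))
    expect_lt(abs(elution_peak(prn, cal)$peak_nacl - 1.46), 0.01)
  }
})
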