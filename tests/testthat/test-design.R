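toy_rel <- function() {
  ab <- aa_alphabet()
  m <- matrix(0, 20, 20, dimnames = list(ab, ab))
  m["D", "R"] <- m["R", "D"] <- -1
  m["E", "R"] <- m["R", "E"] <- -2
  rel_from_matrix(m)
}

test_that("position scores are direct lookups (OO) and three-term sums (OT)", {
  rel <- toy_rel()
  tgt <- target_region("DED")
  expect_equal(position_score(rel, tgt, 1L, 1L, "R", mode = "OO"), -1)
  expect_equal(position_score(rel, tgt, 2L, 1L, "R", mode = "OT"), -4)
  expect_error(position_score(rel, tgt, 1L, 1L, "R", mode = "OT"),
               "sequence end")
  # truncate variant drops the missing neighbour instead
  expect_equal(position_score(rel, tgt, 1L, 1L, "R", mode = "OT",
                              ot_edge = "truncate"), -3)
})

test_that("candidate scores agree with independent re-evaluation on random instances", {
  for (seed in c(3, 14, 15)) {
    rel <- relative_energy_table(random_energy_table(seed))
    set.seed(seed)
    tgt <- target_region(paste(sample(aa_alphabet(), 12, replace = TRUE),
                               collapse = ""))
    for (cand in aa_alphabet()) {
      i <- 5L
      expect_equal(position_score(rel, tgt, 4L, 2L, cand, mode = "OO"),
                   rel$energies[tgt$residues[i], cand])
      expect_equal(position_score(rel, tgt, 4L, 2L, cand, mode = "OT"),
                   sum(rel$energies[tgt$residues[c(i - 1L, i, i + 1L)], cand]))
    }
  }
})

test_that("forced argmin designs and A/G tie handling", {
  ab <- aa_alphabet()
  rel <- toy_rel()
  tgt <- target_region("DDDD")
  res <- design_window(rel, tgt, 1L, design_spec(4, "OO"))
  expect_identical(res$peptide, "RRRR")
  expect_equal(res$total_energy, -4)
  expect_equal(res$total_energy, sum(res$per_position$energy), tolerance = 1e-9)

  # G and A tie as argmin of column D: A must be emitted either way
  m <- matrix(0, 20, 20, dimnames = list(ab, ab))
  m["D", "A"] <- m["A", "D"] <- -3
  m["D", "G"] <- m["G", "D"] <- -3
  rel_tie <- rel_from_matrix(m)
  for (g2a in c(TRUE, FALSE)) {
    r <- design_window(rel_tie, target_region("DD"), 1L,
                       design_spec(2, "OO", gly_to_ala = g2a))
    expect_identical(r$peptide, "AA")
  }
  # but when G is strictly better and kept as candidate, it wins
  m["D", "G"] <- m["G", "D"] <- -4
  rg <- design_window(rel_from_matrix(m), target_region("D"), 1L,
                      design_spec(1, "OO", gly_to_ala = FALSE))
  expect_identical(rg$peptide, "G")
  ra <- design_window(rel_from_matrix(m), target_region("D"), 1L,
                      design_spec(1, "OO", gly_to_ala = TRUE))
  expect_identical(ra$peptide, "A")
})

test_that("greedy design equals the exhaustive optimum for length 3", {
  n_ok <- 0L
  for (seed in 1:100) {
    rel <- relative_energy_table(random_energy_table(seed + 2000))
    set.seed(seed + 2000)
    tgt <- target_region(paste(sample(aa_alphabet(), 6, replace = TRUE),
                               collapse = ""))
    mode <- if (seed %% 2 == 0) "OO" else "OT"
    spec <- design_spec(3, mode, gly_to_ala = FALSE)
    res <- design_window(rel, tgt, 2L, spec)
    oracle <- oracle_exhaustive_L3(rel, tgt, 2L, mode)
    expect_equal(res$total_energy, oracle$total, tolerance = 1e-10)
    expect_identical(res$peptide, oracle$peptide)
    n_ok <- n_ok + 1L
  }
  expect_identical(n_ok, 100L)
})

test_that("register scan: window counts, ordering and brute-force minimum", {
  rel <- relative_energy_table(synthetic_md_table())
  tgt <- p53_nt_target()
  oo <- scan_designs(rel, tgt, design_spec(10, "OO"))
  ot <- scan_designs(rel, tgt, design_spec(10, "OT"))
  expect_length(oo, 85L)   # 94 - 10 + 1
  expect_length(ot, 83L)   # both ends need neighbours
  e_oo <- vapply(oo, `[[`, numeric(1), "total_energy")
  expect_true(all(diff(e_oo) >= -1e-12))
  # best window equals brute-force minimum over all windows
  brute <- min(vapply(1:85, function(s) {
    design_window(rel, tgt, s, design_spec(10, "OO"))$total_energy
  }, numeric(1)))
  expect_equal(oo[[1]]$total_energy, brute)
  # degenerate scan: target exactly one admissible window
  one <- scan_designs(rel, target_region("ACDEFGHIKL"), design_spec(10, "OO"))
  expect_length(one, 1L)
})

test_that("chosen position energies are never beaten by an alternative residue", {
  rel <- relative_energy_table(random_energy_table(77))
  set.seed(77)
  tgt <- target_region(paste(sample(aa_alphabet(), 20, replace = TRUE),
                             collapse = ""))
  spec <- design_spec(6, "OT")
  res <- design_window(rel, tgt, 3L, spec)
  for (p in seq_len(6)) {
    cands <- aa_alphabet()[aa_alphabet() != "G"]  # gly_to_ala default
    alts <- vapply(cands, function(c) {
      position_score(rel, tgt, 3L, p, c, mode = "OT")
    }, numeric(1))
    expect_lte(res$per_position$energy[p], min(alts) + 1e-12)
  }
})

test_that("candidate selection honours the composition cap with diagnostics", {
  mk <- function(peptide, energy, start = 1L) {
    structure(list(peptide = peptide, window_start = start,
                   target_start = start, target_end = start + nchar(peptide) - 1L,
                   total_energy = energy, mode = "OO", constrained = FALSE,
                   per_position = NULL),
              class = "design_result")
  }
  results <- list(mk("RRRRRRRR", -10), mk("RRKRDERW", -9.5, 2L),
                  mk("ACDEFGHI", -5, 3L))
  # inactive constraint: global minimum
  sel0 <- select_candidate(results, design_spec(8, "OO"))
  expect_identical(sel0$peptide, "RRRRRRRR")
  expect_false(sel0$constrained)
  # homopolymer blocked, alternative within delta_e chosen and flagged
  spec <- design_spec(8, "OO", max_single_residue_fraction = 0.75, delta_e = 1)
  sel <- select_candidate(results, spec)
  expect_identical(sel$peptide, "RRKRDERW")
  expect_true(sel$constrained)
  expect_s3_class(attr(sel, "report"), "data.frame")
  # nothing admissible within delta_e: informative error
  tight <- design_spec(8, "OO", max_single_residue_fraction = 0.3, delta_e = 1)
  expect_error(select_candidate(results, tight), "nearest miss")
})

test_that("relaxing delta_e or the cap never raises the selected energy", {
  rel <- relative_energy_table(synthetic_md_table())
  tgt <- p53_nt_target()
  results <- scan_designs(rel, tgt, design_spec(16, "OT"))
  # monotonicity holds over whichever relaxations admit a feasible choice
  pick <- function(cap, de) {
    tryCatch(select_candidate(results, design_spec(
      16, "OT", max_single_residue_fraction = cap,
      delta_e = de))$total_energy,
      error = function(e) NA_real_)
  }
  by_delta <- vapply(c(2, 5, 10, 20, 40), pick, numeric(1), cap = 0.75)
  by_delta <- by_delta[!is.na(by_delta)]
  expect_gte(length(by_delta), 2L)
  expect_true(all(diff(by_delta) <= 1e-12))
  by_cap <- vapply(c(0.6, 0.8, 0.9, 1.0), pick, numeric(1), de = 40)
  by_cap <- by_cap[!is.na(by_cap)]
  expect_gte(length(by_cap), 2L)
  expect_true(all(diff(by_cap) <= 1e-12))
})

test_that("designs are deterministic and translate with constant table shifts", {
  rel <- relative_energy_table(random_energy_table(55))
  set.seed(55)
  tgt <- target_region(paste(sample(aa_alphabet(), 30, replace = TRUE),
                             collapse = ""))
  for (mode in c("OO", "OT")) {
    spec <- design_spec(5, mode)
    a <- scan_designs(rel, tgt, spec)
    b <- scan_designs(rel, tgt, spec)
    expect_identical(lapply(a, `[[`, "peptide"), lapply(b, `[[`, "peptide"))
    shifted <- rel_from_matrix(rel$energies + 0.37)
    s <- scan_designs(shifted, tgt, spec)
    factor <- if (mode == "OO") 5 else 15  # 3 contacts per position in OT
    for (k in seq_along(a)) {
      expect_identical(s[[k]]$peptide, a[[k]]$peptide)
      expect_equal(s[[k]]$total_energy, a[[k]]$total_energy + factor * 0.37,
                   tolerance = 1e-9)
    }
  }
})

test_that("complementary windows apply biological numbering offsets", {
  rel <- toy_rel()
  tgt1 <- target_region("DDDDDDDDDDDD", numbering_offset = 1L)
  r1 <- design_window(rel, tgt1, 3L, design_spec(10, "OO"))
  expect_equal(unname(complementary_window(r1)), c(3L, 12L))
  tgt37 <- target_region("DDDDDDDDDDDD", numbering_offset = 37L)
  r37 <- design_window(rel, tgt37, 1L, design_spec(10, "OO"))
  expect_equal(unname(complementary_window(r37)), c(37L, 46L))
  # fixture round trip: every scanned window lies within residues 1-94
  relm <- relative_energy_table(synthetic_md_table())
  for (r in scan_designs(relm, p53_nt_target(), design_spec(10, "OT"))) {
    w <- complementary_window(r)
    expect_gte(w[["start"]], 1L)
    expect_lte(w[["end"]], 94L)
  }
})
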