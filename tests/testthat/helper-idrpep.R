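# Shared fixtures and independent oracles, all built in code.

# random symmetric 20x20 contact-energy table
random_energy_table <- function(seed, sd = 1) {
  set.seed(seed)
  ab <- aa_alphabet()
  m <- matrix(rnorm(400, sd = sd), 20, 20, dimnames = list(ab, ab))
  m <- (m + t(m)) / 2
  contact_energy_table(m, source_tag = "user", label = sprintf("seed %d", seed))
}

# wrap an arbitrary symmetric matrix as a relative-energy table
rel_from_matrix <- function(m) {
  ab <- aa_alphabet()
  if (is.null(dimnames(m))) dimnames(m) <- list(ab, ab)
  structure(list(energies = m, source_tag = "user", label = "test",
                 means_mode = "externally_supplied"),
            class = "relative_energy_table")
}

# brute-force oracle for mean energies: explicit double loop
oracle_mean_energies <- function(table) {
  ab <- aa_alphabet()
  e_ir <- numeric(20)
  for (i in seq_len(20)) {
    s <- 0
    for (j in seq_len(20)) s <- s + table$energies[ab[i], ab[j]]
    e_ir[i] <- s / 20
  }
  list(per_residue = stats::setNames(e_ir, ab), global = sum(e_ir) / 20)
}

# brute-force oracle for the four-term relative energy, one pair at a time
oracle_relative_entry <- function(table, i, j) {
  mo <- oracle_mean_energies(table)
  table$energies[i, j] + mo$global - mo$per_residue[[i]] - mo$per_residue[[j]]
}

# exhaustive design oracle for peptide length 3: enumerate all 20^3
# sequences and minimise the explicit total (independent of the greedy
# code path; scores recomputed through position_score)
oracle_exhaustive_L3 <- function(rel, target, window_start, mode,
                                 candidates = aa_alphabet()) {
  nc <- length(candidates)
  s1 <- vapply(candidates, function(c) {
    position_score(rel, target, window_start, 1L, c, mode = mode)
  }, numeric(1))
  s2 <- vapply(candidates, function(c) {
    position_score(rel, target, window_start, 2L, c, mode = mode)
  }, numeric(1))
  s3 <- vapply(candidates, function(c) {
    position_score(rel, target, window_start, 3L, c, mode = mode)
  }, numeric(1))
  totals <- outer(outer(s1, s2, `+`), s3, `+`)  # nc x nc x nc
  best <- which(totals == min(totals), arr.ind = TRUE)
  # deterministic tie-break: lexicographically first sequence
  best <- best[order(best[, 1], best[, 2], best[, 3]), , drop = FALSE][1L, ]
  list(peptide = paste(candidates[best], collapse = ""),
       total = min(totals))
}

# a smooth double-well PMF on the 3-14.5 A protocol range (kcal/mol):
# contact well near 4.5 A, desolvation barrier near 8 A, flat at large xi
double_well_pmf <- function(x) {
  -2 * exp(-(x - 4.5)^2 / (2 * 1.0^2)) + 0.8 * exp(-(x - 8.0)^2 / (2 * 1.5^2))
}

# simulate the full window protocol against a known PMF; several
# independent runs per window are pooled as in the sampling protocol
simulate_protocol_windows <- function(true_pmf, n_per_run, seed,
                                      runs = umbrella_protocol()$runs_per_window,
                                      protocol = umbrella_protocol()) {
  lapply(seq_along(protocol$centers), function(k) {
    samples <- unlist(lapply(seq_len(runs), function(r) {
      simulate_biased_samples(true_pmf, center = protocol$centers[k],
                              spring = protocol$spring, n = n_per_run,
                              seed = seed + 1000L * r + k)$samples
    }))
    umbrella_window(center = protocol$centers[k], spring = protocol$spring,
                    samples = samples)
  })
}

# RMSD between a recovered profile and a truth function, both pinned to
# zero at the profile reference
profile_rmsd <- function(profile, truth) {
  tr <- truth(profile$grid)
  tr <- tr - tr[length(tr)]
  sqrt(mean((profile$values - tr)^2))
}
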