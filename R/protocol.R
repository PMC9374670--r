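## Bookkeeping helpers for the pairwise-simulation protocol and the
## combinatorics of peptide sequence space.

#' Number of unordered residue pairs
#'
#' With self-pairs included, an alphabet of `n` residue types has
#' `n (n + 1) / 2` unordered pairs (210 for the 20 amino acids) -- the
#' number of pairwise systems a full contact-energy table requires.
#'
#' @param n Alphabet size (default 20).
#' @return Integer pair count.
#' @export
residue_pair_count <- function(n = 20L) {
  n <- as.integer(n)
  (n * (n + 1L)) %/% 2L
}

#' Size of peptide sequence space
#'
#' `alphabet_size ^ length` as a double (exact for 20^16, whose mantissa
#' fits IEEE double precision).
#'
#' @param length Peptide length in residues.
#' @param alphabet_size Number of residue types (default 20).
#' @return Number of distinct sequences.
#' @export
sequence_space_size <- function(length, alphabet_size = 20) {
  alphabet_size ^ length
}

#' The umbrella-sampling window protocol
#'
#' The reaction-coordinate protocol used for residue-pair binding free
#' energies: centre-of-mass distance sampled on 3.0-14.5 Angstrom in 24
#' windows of 0.5 A, spring constant ~239 kcal/mol/A^2 (~1000 kJ/mol/A^2),
#' 5 ns per window of which the last 3 ns are kept, and 4 independent runs
#' per window.
#'
#' @param xi_min,xi_max Reaction-coordinate range (Angstrom).
#' @param spacing Window spacing (Angstrom).
#' @param spring Spring constant (kcal/mol/A^2).
#' @param ns_per_window Simulated time per window per run (ns).
#' @param ns_burn_in Discarded equilibration time per window (ns).
#' @param runs_per_window Independent repeats per window.
#' @return A list with `centers`, `n_windows`, `spring`, `ns_per_window`,
#'   `ns_burn_in`, `runs_per_window`, `burn_in_fraction`.
#' @export
umbrella_protocol <- function(xi_min = 3.0, xi_max = 14.5, spacing = 0.5,
                              spring = 239, ns_per_window = 5,
                              ns_burn_in = 2, runs_per_window = 4L) {
  centers <- seq(xi_min, xi_max, by = spacing)
  list(centers = centers,
       n_windows = length(centers),
       spring = spring,
       ns_per_window = ns_per_window,
       ns_burn_in = ns_burn_in,
       runs_per_window = as.integer(runs_per_window),
       burn_in_fraction = ns_burn_in / ns_per_window)
}

#' Total simulated time implied by the protocol
#'
#' `pairs x windows x ns_per_window x runs` nanoseconds: the bookkeeping
#' behind a full 20x20 contact-energy table (100,800 ns for the default
#' protocol over all 210 pairs).
#'
#' @param protocol A list from [umbrella_protocol()].
#' @param n_pairs Number of pairwise systems (default [residue_pair_count()]).
#' @return A list with `n_pairs`, `n_windows`, `runs_per_window`,
#'   `ns_per_window` and `total_ns`.
#' @export
protocol_summary <- function(protocol = umbrella_protocol(),
                             n_pairs = residue_pair_count()) {
  total <- n_pairs * protocol$n_windows * protocol$ns_per_window *
    protocol$runs_per_window
  list(n_pairs = n_pairs,
       n_windows = protocol$n_windows,
       runs_per_window = protocol$runs_per_window,
       ns_per_window = protocol$ns_per_window,
       total_ns = total)
}
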