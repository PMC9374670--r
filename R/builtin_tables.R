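#' Synthetic side-chain-style contact-energy table
#'
#' A deterministic, fully synthetic 20x20 contact free-energy table built
#' from simple physical ingredients, intended as a stand-in for MD-derived
#' side-chain contact energies in tests, examples and design demos.  It is
#' not fitted to any published matrix.  The construction encodes the
#' qualitative interaction pattern expected of side chains free of backbone
#' steric constraints:
#'
#' * electrostatic attraction between oppositely charged residues (R/K vs
#'   D/E), with arginine's bidentate guanidinium salt bridge slightly
#'   stronger than lysine's;
#' * cation-pi attraction of R (and more weakly K) toward F, W and Y, with
#'   R additionally pi-stacking through its planar guanidinium;
#' * stacking of the guanidinium pi face against polarizable side chains
#'   generally, which makes R the broadly strongest interactor;
#' * hydrophobic attraction between aliphatic/aromatic side chains;
#' * weak pi-pi stacking among aromatics;
#' * down-weighted interactions for the minimal side chains G and A.
#'
#' All additive offsets cancel in the relative-energy transform, so only
#' the multiplicative pair terms shape designs.
#'
#' @return A `contact_energy_table` with `source_tag = "md_side_chain"` and
#'   a label marking it as synthetic.
#' @examples
#' tab <- synthetic_md_table()
#' rel <- relative_energy_table(tab)
#' rel$energies["D", "R"]  # strongly favourable
#' @export
synthetic_md_table <- function() {
  ab <- aa_alphabet()
  zero <- stats::setNames(numeric(20L), ab)

  charge <- zero
  charge[c("R", "K")] <- 1
  charge[c("D", "E")] <- -1
  charge["H"] <- 0.25

  # salt-bridge strength factor (R bidentate > K monodentate)
  salt <- zero + 1
  salt["R"] <- 1.15
  salt["K"] <- 0.85

  # positive part of Kyte-Doolittle hydropathy, scaled to [0, 1]
  kd <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
          I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
          R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)
  hyd <- pmax(kd[ab], 0) / 4.5
  # W/Y rings are hydrophobic despite their polar atoms lowering hydropathy
  hyd["W"] <- 0.55
  hyd["Y"] <- 0.35

  aromatic <- zero
  aromatic[c("F", "W", "Y")] <- c(1, 1.2, 0.9)

  cation_pi <- zero
  cation_pi["R"] <- 1.0
  cation_pi["K"] <- 0.5

  # relative side-chain polarizability (roughly tracks heavy-atom count,
  # enhanced for pi systems); partner for guanidinium-pi stacking
  pol <- c(A = 0.25, C = 0.55, D = 0.45, E = 0.55, F = 0.95, G = 0.10,
           H = 0.70, I = 0.75, K = 0.60, L = 0.75, M = 0.80, N = 0.50,
           P = 0.50, Q = 0.60, R = 0.75, S = 0.30, T = 0.45, V = 0.60,
           W = 1.20, Y = 1.00)[ab]
  guanidinium <- zero
  guanidinium["R"] <- 1.0

  # side-chain size scale: G has essentially no side chain, A a methyl
  scale <- zero + 1
  scale["G"] <- 0.2
  scale["A"] <- 0.5

  w_el <- 2.5; w_h <- 1.5; w_cp <- 1.2; w_pp <- 0.6; w_g <- 0.5
  qq <- outer(charge * salt, charge * salt)
  hh <- -w_h * outer(hyd, hyd)
  cp <- -w_cp * (outer(cation_pi, aromatic) + outer(aromatic, cation_pi))
  pp <- -w_pp * outer(aromatic, aromatic)
  gp <- -w_g * (outer(guanidinium, pol) + outer(pol, guanidinium))
  e <- -1.0 + outer(scale, scale) * (w_el * qq + hh + cp + pp + gp)
  contact_energy_table(e, source_tag = "md_side_chain",
                       label = "synthetic side-chain-style table (not MD data)")
}

#' The Miyazawa-Jernigan 3D structure-based contact-energy table
#'
#' Loads the bundled transcription of the classic residue-residue contact
#' energies estimated from contact statistics of folded protein structures
#' (Miyazawa & Jernigan 1996, upper-triangle e_ij, RT units; converted to
#' kcal/mol at 298 K on load).  For this table the average-residue
#' reference energies are conventionally taken from the original
#' publication; [mean_energies()] accepts them via its `per_residue` /
#' `global` arguments, and otherwise recomputes them from the table.
#'
#' @return A `contact_energy_table` with `source_tag = "structure_3d"`.
#' @export
mj1996_table <- function() {
  path <- system.file("extdata", "mj1996_contact_energies.tsv",
                      package = "idrpep", mustWork = TRUE)
  load_energy_table(path, source_tag = "structure_3d")
}

#' Bundled p53 N-terminal IDR target sequences
#'
#' `p53_nt_target()` returns the p53 N-terminal disordered region
#' (residues 1-94 of human p53, UniProt P04637), the design target used
#' throughout the examples.  `p53_nt_fragment()` returns the shorter
#' fragment (residues 37-65) used as the labelled species in titration
#' experiments; its `numbering_offset` is 37 so that reported windows use
#' biological residue numbers.
#'
#' @return A `target_region` object.
#' @export
p53_nt_target <- function() {
  path <- system.file("extdata", "p53_nt.fasta", package = "idrpep",
                      mustWork = TRUE)
  read_fasta(path)[[1L]]
}

#' @rdname p53_nt_target
#' @export
p53_nt_fragment <- function() {
  path <- system.file("extdata", "p53_nt.fasta", package = "idrpep",
                      mustWork = TRUE)
  read_fasta(path)[[2L]]
}
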