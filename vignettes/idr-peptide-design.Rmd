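---
title: "Contact-energy-based peptide design for disordered regions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact-energy-based peptide design for disordered regions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idrpep)
```

# The problem

Intrinsically disordered regions (IDRs) drive liquid–liquid phase
separation of proteins such as p53, and a peptide that binds an IDR can
modulate that behaviour. Because an IDR has no fixed structure, docking
and structure-based design do not apply; what is available is the IDR
*sequence* and a model of how strongly pairs of amino-acid residues
attract each other in a flexible, solvent-exposed context. `idrpep`
implements that sequence-level design loop: a residue-pair contact-energy
model, a greedy complementary-sequence optimiser, the free-energy
estimator that such pair energies come from, and the binding assay model
used to validate designed peptides.

# Contact energies and the relative-energy transform

A contact-energy table assigns each unordered residue pair $(i, j)$ an
effective contact free energy $e_{ij}$ in kcal/mol (negative =
attractive); 210 unordered pairs over the 20 proteinogenic amino acids.
Raw $e_{ij}$ mix two things: a pair-specific preference and each
residue's overall stickiness. For design, what matters is the *relative*
energy against the "average residue" $r$:

$$\tilde e_{ij} = e_{ij} + e_{rr} - e_{ir} - e_{jr},
\qquad e_{ir} = \tfrac{1}{20}\sum_j e_{ij},
\qquad e_{rr} = \tfrac{1}{20}\sum_i e_{ir}.$$

Any additive component $e_{ij} = x_i + x_j$ cancels exactly in
$\tilde e$ (a property the tests assert), and when the means are computed
from the table itself the 400 ordered entries of $\tilde e$ average to
exactly zero. For structure-derived tables the reference energies are
conventionally taken from the original publication instead of recomputed;
`mean_energies()` accepts externally supplied values and records the mode,
and the zero-mean invariant is only asserted for computed means.

Two tables ship with the package. `mj1996_table()` is a transcription of
the classic Miyazawa–Jernigan contact energies estimated from contact
statistics in folded structures (RT units in the file; converted to
kcal/mol at 298 K on load). `synthetic_md_table()` is a deterministic,
fully synthetic stand-in for an MD-derived *side-chain* table — see below.
`table_correlation()` compares tables by Pearson correlation over the 210
unique pairs by default; a `"full"` option uses all 400 ordered entries.
For symmetric tables the two differ only by the weight the diagonal
carries, and the unique-pair form is the default because it matches how
such triangular tables are published.

# Greedy complementary design

A candidate peptide of length $L$ is aligned parallel (N→C) to a window
of the target starting at position $s$. The score of placing residue $c$
at peptide position $p$ is

* **OO (one-by-one):** $\tilde e(t_{s+p-1}, c)$ — the aligned target
  residue only;
* **OT (one-by-three):** $\tilde e(t_{s+p-2}, c) + \tilde e(t_{s+p-1}, c)
  + \tilde e(t_{s+p}, c)$ — the aligned residue plus its two sequence
  neighbours, modelling the fuzzy, multivalent contact of two extended
  chains.

Each position independently takes the candidate minimising its score.
Because no term couples peptide positions, this greedy per-position
argmin *is* the global optimum over all $20^L$ sequences of the window —
an equivalence the test suite verifies against exhaustive enumeration of
all $20^3$ sequences on 100 random instances. All admissible windows are
scanned and ranked by total energy.

Conventions, each chosen once and fixed:

* **Parallel register.** Peptide position $p$ pairs with target position
  $s + p - 1$. Nothing in the scoring model distinguishes chain
  orientation, so the simplest indexing is used and documented.
* **OT edges.** By default windows are restricted so every aligned
  target residue has both neighbours ($s \ge 2$,
  $s + L - 1 \le N - 1$); a 94-residue target therefore admits 85
  OO windows and 83 OT windows for $L = 10$. This avoids inventing an
  edge-truncation rule; a `truncate` variant (drop the missing neighbour
  term) is available behind the `ot_edge` flag for users who want edge
  windows.
* **Glycine.** With side-chain-derived energies a G entry describes a
  near-absent side chain, and emitting G would trade a designable contact
  for backbone flexibility. With `gly_to_ala = TRUE` (default) G is
  removed from the candidate set, so A is emitted wherever the bare
  argmin would have picked either. With `gly_to_ala = FALSE` both
  compete, and exact A/G ties still resolve to A through the tie-break
  rule.
* **Ties.** Exact score ties are broken by alphabetical one-letter
  order (the order `aa_alphabet()` returns). This makes every design
  fully deterministic.
* **Composition cap.** Minimum-energy design against a strongly acidic
  IDR collapses to poly-arginine: maximal charge complementarity, minimal
  specificity. `select_candidate()` optionally enforces that the most
  frequent residue not exceed `max_single_residue_fraction`, searching
  the scanned designs within `delta_e` kcal/mol of the minimum and
  flagging the result `constrained`. The cap is off by default (the raw
  algorithm), because any particular threshold is a judgement call; the
  near-minimum report (`top_k` candidates with composition statistics)
  gives the user the information that judgement needs. Relaxing
  `delta_e` or the cap never raises the selected energy (tested).

# Umbrella integration

The pair energies $e_{ij}$ in such tables are binding free energies
along a reaction coordinate $\xi$ (centre-of-mass distance between two
residues). The package implements the estimator that converts biased
samples into a profile $A(\xi)$, with a synthetic sampler replacing the
MD engine.

Sampling is performed in windows with harmonic bias
$w_i(\xi) = \tfrac{K}{2}(\xi - \xi_i^c)^2$. Under a normal approximation
to each window's biased distribution (mean $\bar\xi_i^b$, variance
$(\sigma_i^b)^2$), the unbiased profile derivative estimated from window
$i$ is

$$\frac{\partial A}{\partial \xi}
 = \frac{1}{\beta}\,\frac{\xi - \bar\xi_i^b}{(\sigma_i^b)^2}
 - K(\xi - \xi_i^c), \qquad \beta = 1/k_B T .$$

A note on the sign: written with the opposite sign on the first term the
expression fails the closed-form oracle below, so the package uses the
standard umbrella-integration form shown here. The per-window offset
constants of free-energy matching cancel in the derivative formulation
and have no representation in the code.

Per-grid-point, window derivatives are combined with weights
proportional to $n_i$ times the window's normal density (the standard
count-weighted combination), then integrated with the trapezoidal rule
and pinned to $A = 0$ at the largest grid $\xi$ — the dissociated state,
so a well depth reads directly as a binding free energy.
`binding_free_energy()` reports either that well depth
(`min_minus_reference`, default) or a Boltzmann-weighted bound-state
integral relative to the unbound region (`boltzmann_bound_state`, with a
configurable bound/unbound cutoff defaulting to the grid midpoint); a
profile with no well below the reference yields 0 with a warning.

Correctness anchors:

* **Gaussian exactness.** For a quadratic PMF $A = a(\xi-\mu_0)^2/2$
  under harmonic bias, the biased density is exactly normal with known
  moments; supplying those moments must return exactly $a(\xi-\mu_0)$,
  and does so to better than $10^{-10}$ relative. Doubling $K$ (moments
  updated) leaves the recovered derivative unchanged.
* **Double-well recovery.** The default window protocol — 24 windows
  centred 3.0–14.5 Å at 0.5 Å spacing, $K = 239$ kcal/mol/Å², 300 K,
  four independent runs per window — recovers a smooth synthetic
  double-well PMF (contact well at 4.5 Å, barrier near 8 Å) to better
  than 0.2 kcal/mol RMSD with $10^4$ samples per run. The four-run
  pooling matters: with this spring stiffness the per-window derivative
  error scales as $\sqrt{K k_B T / n}$, and single runs of $10^4$
  samples sit at the edge of that tolerance, which is an information
  limit of stiff-spring umbrella sampling rather than an estimator
  property.

Numerical choices: the synthetic sampler draws by inverse-CDF lookup on
an 8001-point grid spanning $\pm(8\sigma + 0.1\,\text{Å})$ of each
window, using a *trapezoidal* cumulative — a one-sided Riemann cumulative
shifts every sample by half a grid cell, and at $K = 239$ that
half-cell bias integrates into a visible profile drift. Burn-in is
fraction-based (default 0.4, mirroring protocols that keep the last
3 ns of 5-ns windows) because the estimator sees samples, not
trajectories; the synthetic sampler produces i.i.d. draws, so analyses
of synthetic data set `burn_in_fraction = 0`. Temperature defaults to
300 K with $k_B = 0.0019872041$ kcal/mol/K and is configurable
everywhere. Grid spacing defaults to 0.05 Å. A grid region where no
window carries numerically non-zero weight is reported as a coverage gap
rather than silently extrapolated.

# The 1:1 titration model

Fluorescence anisotropy of a dye-labelled species A (total
concentration $c_A$, fixed and known) titrated with B reports complex
formation through

$$r_{\text{obs}} = r_A\,\frac{c_A - c_{AB}}{c_A}
  + r_{AB}\,\frac{c_{AB}}{c_A},$$

with $c_{AB}$ the physical root of the 1:1 equilibrium quadratic
$(c_A - c_{AB})(c_B - c_{AB}) = K_D\,c_{AB}$. The root is evaluated as
$2 c_A c_B / (s + \sqrt{s^2 - 4 c_A c_B})$ with $s = c_A + c_B + K_D$,
which is immune to the catastrophic cancellation the textbook
$(s - \sqrt{\cdot})/2$ form suffers when $K_D \gg c_A, c_B$; the tests
confirm the identity to $10^{-12}$ relative over $10^5$ random inputs
spanning nine orders of magnitude.

Fitting floats $(r_A, r_{AB}, \log K_D)$ by Levenberg–Marquardt least
squares at fixed $c_A$: the label concentration is known experimentally,
and floating it would destroy identifiability in the common regime
$c_A \ll K_D$ where curve shape constrains only the ratio. The log
parameterisation enforces $K_D > 0$; its standard error is mapped back
by the delta method. Default initial values are $r_A$ from the first
point, $r_{AB}$ from the last, and $K_D$ from the concentration nearest
half-signal. A curve with no signal span raises an identifiability error
instead of returning nonsense.

# Synthetic data generators

Three generators make the full pipeline testable without simulations or
instruments; their defaults are the study conditions the rest of the
package assumes.

**Synthetic contact table.** `synthetic_md_table()` is built from fixed
physical ingredients: screened electrostatics between charged residues
(with arginine's bidentate guanidinium salt bridge slightly stronger
than lysine's), cation-π attraction of R and (weaker) K toward F/W/Y,
a moderate guanidinium-π stacking term toward polarizable side chains,
hydrophobic attraction from the positive part of Kyte–Doolittle
hydropathy, weak aromatic π–π terms, and down-scaled interactions for
the minimal side chains G and A. The weights were fixed against the
qualitative pattern expected of a side-chain energy matrix — after the
relative-energy transform, R is the most favourable partner for D, E,
F, W and Y — and not against any design output. What the table is *not*:
it is not MD data, and design results obtained with it (for example,
that the unconstrained OT 16-mer against p53's N-terminal IDR is
arginine at 15 of 16 positions, with a serine at one all-neutral
P-G-P neighbourhood) characterise the stand-in, not any published
energy set. Tests passing on this table demonstrate the algorithms,
not the real energetics.

**Biased sampler.** Draws i.i.d. samples from the exact biased density
of a user-supplied PMF, as described above. It does not emulate the
autocorrelation, equilibration transients or run-to-run drift of real
trajectories — which is precisely why burn-in handling is parametric
rather than baked in.

**Titration simulator.** Forward model plus i.i.d. Gaussian noise on
$r_{\text{obs}}$. The recovery checks use $c_A = 10$ nM, 12 titrant
points log-spaced 1 nM–10 µM, anisotropy endpoints 0.05/0.25, and noise
of 1% of the signal span (sd 0.002) — a clean-instrument scenario at the
strong-binder scale ($K_D = 35$ nM). Real curves have concentration
errors and correlated drift that this generator does not model.

# Problem sizes and determinism

The test suite runs the exhaustive-design oracle on 100 seeded random
instances, the double-well recovery at $4 \times 10^4$ samples per
window under the 24-window protocol, the binding quadratic on $10^5$
random triples, and 100 seeded noisy titration fits; the whole suite
completes in well under a minute on one core. Every stochastic
component takes an explicit seed, all tie-breaks are specified, and
identical inputs produce identical outputs, including byte-identical
CLI reports.

# Limitations

* Total contact energy is a *ranking* score. It correlates with binding
  strength across designs but is not a $K_D$ predictor in physical
  units; validation still needs titrations.
* The design model has no intra-peptide terms — no solubility, net
  charge, aggregation or synthesis constraints beyond the single
  composition cap.
* Umbrella integration relies on the per-window normal approximation;
  strongly anharmonic windows (soft springs over rugged profiles) bias
  the derivative. Error bars (e.g. bootstrap over runs) are not
  implemented.
* The bundled structure-derived table is a transcription of published
  values in RT units; the energy scale entering designs depends on the
  conversion temperature, though rankings and correlations do not.
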