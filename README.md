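# idrpep

Design peptide binders for intrinsically disordered protein regions (IDRs)
from residue–residue contact energies.

Liquid–liquid phase separation of proteins such as p53 is driven by their
IDRs, so short peptides that bind an IDR complementarily can act as
condensate regulators. `idrpep` implements the computational core of a
contact-energy-based design workflow for such peptides:

* **Contact-energy tables.** Load, validate and transform symmetric 20×20
  pair free-energy tables e<sub>ij</sub> (kcal/mol). The key transform is
  the *relative* contact energy referenced against the average residue r,

  &nbsp;&nbsp;&nbsp;&nbsp;ẽ<sub>ij</sub> = e<sub>ij</sub> + e<sub>rr</sub> − e<sub>ir</sub> − e<sub>jr</sub>,
  &nbsp;&nbsp; e<sub>ir</sub> = Σ<sub>j</sub> e<sub>ij</sub>/20,
  &nbsp;&nbsp; e<sub>rr</sub> = Σ<sub>i</sub> e<sub>ir</sub>/20,

  which removes additive per-residue stickiness and leaves only
  pair-specific preferences. A transcription of the Miyazawa–Jernigan
  structure-derived table and a synthetic side-chain-style table (labelled
  synthetic; not MD data) are bundled, and `table_correlation()` compares
  tables over the 210 unique pairs.

* **Greedy minimum-energy design.** A peptide aligned to a window of the
  target is optimised position by position: each position takes the
  residue minimising its score, either against the single aligned target
  residue (one-by-one, OO) or against that residue plus its two sequence
  neighbours (one-by-three, OT). Because positions are independent, the
  greedy argmin is the exact optimum over all 20^L sequences of that
  window. All registers along the target are scanned and ranked;
  an optional composition cap re-selects the best near-minimum design
  that is not dominated by a single residue type (homopolymer avoidance).

* **Umbrella integration.** `combine_and_integrate()` turns harmonically
  biased reaction-coordinate samples (window centre ξ<sub>c</sub>, spring
  K) into a potential of mean force using the per-window normal
  approximation,

  &nbsp;&nbsp;&nbsp;&nbsp;∂A/∂ξ = (1/β)(ξ − ξ̄<sub>b</sub>)/σ<sub>b</sub>² − K(ξ − ξ<sub>c</sub>),

  combining windows with count-weighted normal densities and integrating
  to a profile pinned to zero in the dissociated state. The well depth is
  the pairwise binding free energy that contact-energy tables are built
  from. A synthetic biased sampler stands in for molecular dynamics so
  the whole estimator is testable end to end.

* **Titration fitting.** The 1:1 fluorescence-anisotropy binding model:
  r<sub>obs</sub> = r<sub>A</sub>(c<sub>A</sub> − c<sub>AB</sub>)/c<sub>A</sub> + r<sub>AB</sub> c<sub>AB</sub>/c<sub>A</sub>
  with c<sub>AB</sub> the physical root of
  (c<sub>A</sub> − c<sub>AB</sub>)(c<sub>B</sub> − c<sub>AB</sub>) = K<sub>D</sub> c<sub>AB</sub>,
  fitted by Levenberg–Marquardt least squares with K<sub>D</sub> > 0
  enforced on the log scale.

The p53 N-terminal IDR (residues 1–94) and its titration fragment
(residues 37–65) are bundled as FASTA fixtures.

## Worked example

```r
library(idrpep)

rel    <- relative_energy_table(synthetic_md_table())
target <- p53_nt_target()                       # p53 residues 1-94

designs <- scan_designs(rel, target, design_spec(10, "OT"))
designs[[1]]
#> OT design RRRRRRRRRR vs target 48-57: total -41.542 kcal/mol

sel <- select_candidate(designs, design_spec(10, "OT",
         max_single_residue_fraction = 0.7, delta_e = 10, top_k = 3))
sel
#> OT design RRRSRRRREE vs target 56-65: total -35.601 kcal/mol [composition-constrained]
```

The raw minimum collapses onto the acidic stretch around residues 48–57
and is pure arginine — maximal charge complementarity, but a homopolymer
with poor specificity. The composition cap keeps the design within
10 kcal/mol of the minimum while forcing residue diversity
(`RRRSRRRREE`, residues 56–65). Validating a synthesised binder:

```r
params <- binding_parameters(r_A = 0.05, r_AB = 0.25, K_D = 3.5e-8, c_A = 1e-8)
curve  <- simulate_titration(params, 10^seq(-9, -5, length.out = 12),
                             noise_sd = 0.002, seed = 42)
fit_titration(curve)
#> 1:1 binding fit: K_D = 3.61e-08 +/- 1.2e-09 M, r_A = 0.0512 +/- 0.0012,
#>   r_AB = 0.2526 +/- 0.00091 (RSS 2.98e-05)
```

i.e. a 36 nM dissociation constant recovered from a noisy 12-point curve
of a 10 nM labelled fragment, with standard errors from the fit.

A command-line interface with the same functionality is installed at
`exec/idrpep` (subcommands `design`, `pmf`, `fitkd`, `matcorr`, `synth`);
every run writes a versioned JSON report embedding its configuration and
seed.

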