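---
title: "Models and methods in duplexmelt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in duplexmelt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duplexmelt)
```

# The two-state melting model

A short non-self-complementary RNA duplex is assumed to melt in a two-state
manner: duplex ⇌ two single strands, with no populated intermediates and no
heat-capacity change (ΔC~p~ = 0, the pure van't Hoff picture). The
association constant is

$$K(T) = \exp\!\left(\frac{\Delta S^\circ}{R} - \frac{\Delta H^\circ}{R\,T}\right),$$

with formation-signed parameters (ΔH°, ΔS° negative for duplex formation).
At total strand concentration $C_T$, mass balance $K = 2f/((1-f)^2 C_T)$
has the closed-form root in [0, 1]

$$f = \frac{a}{(a+1) + \sqrt{2a+1}}, \qquad a = K C_T,$$

which `fraction_duplex()` evaluates in this conjugate form because the
algebraically equivalent $((a+1)-\sqrt{2a+1})/a$ cancels catastrophically
as $a \to 0$. At the melting temperature $K(T_M) = 4/C_T$, so $f(T_M)=1/2$
exactly. Self-complementary duplexes would use $C_T$ in place of $C_T/4$;
the flag exists on `tm_at_concentration()` and `vant_hoff()` but the
duplexes studied here are all non-self-complementary.

An absorbance melting curve at 260 nm is modelled as the $f$-weighted
mixture of two independent linear baselines,

$$A(T) = (1-f)\,(m_{ss} T + b_{ss}) + f\,(m_{ds} T + b_{ds}),$$

so `fit_melt_curve()` estimates six parameters per curve. Conventions used
throughout: $R = 1.9872$ cal mol^-1^ K^-1^, 0 °C = 273.15 K, and
ΔG°~37~ = ΔH° − 310.15·ΔS°/1000 evaluated at 310.15 K — the combination
that reproduces the printed arithmetic of the packaged reference table.

## The two analysis routes

Per-curve fits are summarized two ways, mirroring standard practice:

* **Average of curve fits** — per-parameter mean and *sample* SD (n−1) over
  converged fits; ΔG°~37~ is averaged over per-curve values, **not**
  recomputed from the averaged ΔH°/ΔS°. The distinction matters because
  ΔH° and ΔS° are strongly correlated across curves; averaging the derived
  quantity gives a much tighter spread.
* **van't Hoff (concentration-dependence)** — ordinary least squares of
  $1/T_M$ on $\ln(C_T/4)$, with ΔH° = R/(1000·slope) kcal/mol and
  ΔS° = 1000·intercept·ΔH° eu. SDs for ΔH°, ΔS° and ΔG°~37~ are propagated
  from the regression coefficient covariance by the delta method.

The agreement of the two routes is the operational test of two-state
behaviour: `two_state_check()` passes when the enthalpies differ by at most
15%.

## Fitting: initialization, convergence, degeneracy

Minimization is Levenberg–Marquardt (`minpack.lm::nlsLM`), relative
cost-change tolerance 1e-10, at most 500 iterations. Initial values:
baselines from linear fits to the first and last 15% of points, ΔH° = −70
kcal/mol (a typical 9-mer), and the T~M~ guess at the maximum of the
smoothed dA/dT. A fit is reported `converged = FALSE` — with a diagnostic
message, never silent garbage — when the optimizer fails, when estimates
are non-finite or not formation-signed, when no physical melting
temperature exists, or when the fitted transition amplitude is below 5% of
the absorbance span (a featureless curve such as a pure line). An optional
temperature `window` truncates curves before fitting; truncation choices
are known to move fitted parameters by a few percent, which is why the
window is exposed rather than hard-coded.

The six parameters are identifiable only when both baselines are visible
inside the measured window; the round-trip tests therefore restrict their
parameter grid to combinations with T~M~ between 25 and 70 °C on the
0–90 °C grid.

## Extinction coefficients and concentrations

Single-strand concentrations follow Beer–Lambert using absorbance at 80 °C
and the nearest-neighbour extinction model
$\varepsilon = \sum_i 2\varepsilon(\text{pair}_i) - \sum_{\text{internal}} \varepsilon(\text{mono})$
over the standard packaged 260 nm monomer/dimer table. No published
coefficients exist for 7A, A^L^ or 7A^L^; they alias to adenosine, and the
package warns every time this approximation is used.

# Comparison statistics

ΔΔG°~37~ is the formation-signed difference to the unmodified reference
duplex sharing the same opposing residue (positive = destabilization), with
SD $\sqrt{sd_a^2 + sd_b^2}$ since the two measurements are independent.
Reference pairing is taken from an explicit map — never inferred from
sequence strings. ΔT~M~ compares melting temperatures at 10^-4^ M. The
predicted-versus-experimental Pearson correlation excludes the reference
duplexes' identically-zero pairs by default (the eight informative pairs);
`include_references = TRUE` keeps them. The packaged table reproduces
r = 0.96 at two decimals with the default; whether the published value
included the zero pairs is not stated in the source, so the choice that
reproduces it is the default and the switch is exposed.

One documented data inconsistency: in the concentration-plot block of the
packaged thermodynamic table, the A-U row's printed ΔH°/ΔS° imply
ΔG°~37~ ≈ 12.50 kcal/mol where 11.86 is printed — far outside what printed
rounding can explain. The row carries `vh_consistent = FALSE` and is
excluded from exact-match tests. More broadly, the printed ΔH°/ΔS° values
are rounded to one decimal, which alone propagates to roughly ±0.1 kcal/mol
in ΔG°~37~ and ±0.3 °C in T~M~; recomputed values should be compared
against the printed ones at those tolerances, not tighter.

# Conformational analysis

Glycosidic torsions use O4′–C1′–N9–C4 (N9 purines), O4′–C1′–N1–C2
(pyrimidines) and O4′–C1′–N7–C5 for the N7-linked adenosines. The N7
definition is a design choice by structural analogy with the N9 convention
(the base atom adjacent to the six-membered ring); no standard exists for
this linkage. Angles are reported in [−90°, 270°) and classified syn in
[−90°, 90°) and anti in [90°, 270°), IUPAC-style windows that fold
"high-anti" into anti.

Hydrogen bonds between the two middle residues use a donor–acceptor
heavy-atom distance cutoff of 3.5 Å and a D–H–A angle cutoff of 135° —
common MD-analysis defaults, both exposed as arguments since the original
analysis tool's thresholds are unstated. Only inter-strand base–base
donor/acceptor pairs are considered.

Clustering is the single-pass leader algorithm: frames in order, each
joining the first cluster whose *leader* frame is within 0.5 Å (inclusive)
superposed RMSD on the middle-pair heavy atoms (sugar + base, no
hydrogens), else seeding a new cluster. Superposition is least-squares
(Kabsch via SVD with the determinant correction). The algorithm is
order-dependent by construction; the frame order is recorded in the
object's provenance so runs are reproducible. Whether the original
in-house clustering superposed before RMSD, and its frame ordering, are
unstated — the choices here are documented conventions, not a
reimplementation of that code. Cluster-average structures superpose every
member onto the leader (transform fitted on the clustering subset, applied
to all atoms) and average per atom.

Before energetic and clustering analyses the terminal two base pairs are
removed (`trim_terminal_pairs()`), keeping fraying ends out of the
statistics.

# Energy aggregation

Per-frame components combine as
dG_rism = ⟨E_complex − E_strand1 − E_strand2⟩ and
dG_nmode likewise, with **dG_pred = dG_rism − dG_nmode** — the normal-mode
term enters with a minus sign exactly as defined, with no hidden re-signing.
Strand terms are taken from the same frames as the complex
(single-trajectory decomposition), the standard protocol for this style of
end-point free-energy pipeline; the aggregation accepts any grouping column
so per-cluster or all-frame averages are both possible (the source does not
state which was used). `global_minimum()` reports states within 2.5
kcal/mol of the minimum as co-populated alternates, matching the window
used when discussing near-degenerate cluster stabilities. The solvation
and normal-mode solvers themselves are out of scope: their outputs enter
as delimited tables.

# The synthetic-data generators

The generators define the test conditions; they are not tuning knobs.

* **Melting curves**: nine log-spaced concentrations spanning 1–100 μM
  (the dilution-series design), a 0–90 °C grid in 0.5° steps (the 1 °C/min
  heated-cell ramp sampled every 30 s), Gaussian absorbance noise of
  0.002 AU — the jitter a bench spectrophotometer shows on a ~0.2 AU
  transition. Baselines default to a gently sloping single-strand line
  above a duplex line with ~25% hyperchromicity.
* **Duplex frames**: an idealized 9-bp duplex with correct residue/atom
  naming (including the 7A/7A^L^ conventions), built from planar base
  templates on an internal-coordinate sugar, with the middle-pair χ set
  exactly per state and the opposing base placed by a constrained rigid-body
  optimization so that exactly the scheduled number of inter-strand
  hydrogen bonds forms (designed contacts at 2.9 Å/near-linear, all other
  donor–acceptor pairs pushed beyond 3.8 Å). Coordinate jitter defaults to
  0.05 Å. This is deliberately *not* an A-form builder: no helical twist,
  no backbone continuity between residues, no force-field realism. Every
  consuming operation (torsions, bond geometry, RMSD clustering) is purely
  geometric, so passing tests demonstrate correctness of the analysis
  code — not that the analysis would reach the same conclusions on real
  trajectories, whose state separations, bond-length distributions and
  autocorrelations are messier.
* **Energy tables**: strand components drawn around realistic magnitudes
  with the state-wise differences given prescribed means and 0.5 kcal/mol
  noise per difference, so recovery tolerances follow standard-error
  arithmetic.

All generators are deterministic given their seed and emit ground-truth
records alongside the data. Noise defaults were chosen once so that the
documented recovery tolerances (van't Hoff ΔH° within 5%, cluster
populations within ±0.02, mean bond counts within ±0.05) hold with large
margin at the default sizes; at 0.05 Å jitter the χ torsion itself spreads
with a standard deviation near 7° (positional noise through four ~1.4 Å
bonds), far from the ±90° state boundaries.

# Numerical choices and degenerate inputs

* `fraction_duplex` uses the cancellation-free conjugate form (above).
* Duplicate concentrations in `vant_hoff()` are collapsed by averaging
  1/T~M~, with a warning; fewer than three distinct concentrations is an
  error, as is a zero slope.
* Exact ties in modal loop-orientation labels are reported as ties
  (`"a | b"`, `tie = TRUE`), never broken silently.
* The leader threshold is inclusive (≤ 0.5 Å), verified at the boundary.
* The synthetic pairing optimizer carries a small quadratic pin to its
  constructive starting point, because rotation about the contact axis is
  otherwise nearly degenerate and would let equivalent states drift apart.
* Readers validate strictly (file, column and line context in every error);
  no silent coercion.

# Problem sizes

Default test and reproduction sizes: 20 seeded replicates of the
nine-concentration melting recovery, 300–400 frames for clustering and
bond-count recovery, 1000 frames per state for energy aggregation, and 100
random instances per geometry-oracle comparison. These sizes put the
standard errors an order of magnitude below the documented tolerances.

# Known limitations

* ΔC~p~ = 0 and strict two-state behaviour are assumed, not tested beyond
  the 15% consistency check; three-state or zipper models are out of scope.
* Modified-residue extinction coefficients are approximated by adenosine's.
* The leader clustering is order-dependent; a different trajectory
  concatenation order can change cluster identities (populations of
  well-separated states are stable).
* The synthetic duplex geometry validates analysis code, not biophysics;
  see above.
* The packaged reference tables inherit the printed precision (and the one
  flagged inconsistent row) of their source.
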