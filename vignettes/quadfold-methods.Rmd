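---
title: "Models and methods behind quadfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind quadfold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadfold)
```

quadfold analyses the folding landscape of intramolecular G-quadruplexes
built on a snapback-loop, G-vacancy architecture: a 5'-terminal GG tract one
guanine short of three tetrad layers, three complete GGG tracts, and a
3'-terminal segment whose last G folds back to fill the vacant tetrad
position. This vignette explains the geometric model behind the topology
enumeration, the additive stability model and its calibration, the two-state
melting analysis, and the numerical choices that matter; it closes with known
limitations. All quantities shown here are computed by the package itself.

## Sequence model

Sequences use an extended residue alphabet: `A C G T` plus inosine `I`
(hypoxanthine nucleoside, a purine), the abasic 1',2'-dideoxyribose site `X`
(no nucleobase), and 8-bromo-2'-deoxyguanosine `BrG` (a syn-favouring
guanosine analog), written in brackets in strings (`"[BrG]"`). Tract
detection counts `G` and `BrG` as tract-forming so that a bromo-substituted
core decomposes identically to its parent. `I` is deliberately *not*
tract-eligible: it is used here as a loop-purine substitute, and letting it
join tracts would silently change the loop architecture of mutants carrying
inosine adjacent to a tract (e.g. a 5A→5I substitution next to the second
tract), violating the requirement that loop-confined substitutions leave the
decomposition unchanged. `X` never joins a tract.

Core numbering is 1-based; a single added 5'-flanking residue takes internal
index 0 (kept contiguous) and may be *displayed* as "(-1)" for parity with
the common reporting convention for 5'-overhangs.

```{r}
qref <- parse_sequence("GG-CTA-GGG-TCA-GGG-T-GGG-TCA-G", "Qref")
decompose(qref)
```

## Topology enumeration

The four G-columns of an intramolecular fold occupy the corners of a square,
viewed from the 5' face; each column runs up or down, with the 5'-terminal
column fixed as the reference (corner 0, pointing toward the viewer). Loops
move between corners:

* a **propeller** loop (`p`) links two parallel columns along a groove; the
  right-handed helicity fixes its rotational progression (counter-clockwise
  along an up column, clockwise along a down column), so propeller signs are
  never free;
* a **lateral** loop (`l`) links antiparallel columns across a tetrad edge,
  in either rotational direction;
* a **diagonal** loop (`d`) crosses the core to the opposite corner.

Length gates default to lateral ≥ 2 nt and diagonal ≥ 4 nt, both
configurable because these empirical minima are tendencies rather than hard
rules; a 1-nt segment can only form a propeller in a three-layer fold. The
enumerator generates every (kind, sign) assignment, discards corner
collisions, resolves the layer occupancy of the deficient tract from the
loop that anchors its 3' end, and decides whether the snapback G can fill
the vacancy: a lateral snapback folds back around the face where the last
column exits, so filling succeeds only when the vacant layer coincides with
that face. Unfilled candidates are kept as vacancy-triad folds with
`4*(layers-1)+3` tetrad guanines. The candidates are labelled with the
standard compact descriptor (loop kinds plus rotational sign, snapback loop
omitted), e.g. `+(lpp)` for the hybrid and `-(ppp)` for the parallel fold.

Two-layer folds are admitted through a single exception — a 1-nt lateral
loop is possible when only two tetrads stack — and are generated *only* for
assignments that actually use that exception; any other two-layer fold
duplicates a three-layer candidate with strictly fewer tetrads. The relaxed
candidate set therefore contains, beyond the four architectures one would
sketch by hand, a handful of mixed two-layer arrangements (`+(lpl)`,
`-(pll)`, `-(ppl)`, `-(lll)`); they are reported rather than silently
dropped, and the missing-tetrad penalty keeps them marginal. Propeller-type
snapback loops are excluded by default (a structurally very unusual motif)
behind a configuration switch. A vacancy outside the 5'-terminal tract is
flagged by the decomposer but not resolved by the enumerator — the fill
geometry of an internally broken column is not constrained by this
architecture, and multi-vacancy register combinatorics is out of scope.

Groove widths follow column directions: medium between parallel columns;
between antiparallel columns the width follows the Hoogsteen donor direction
of the flanking columns, implemented as *narrow* when the clockwise-first
column of the groove runs up and *wide* when it runs down. This single rule
reproduces the narrow first-lateral groove, the wide snapback groove and the
medium propeller grooves of the hybrid fold, the all-medium parallel fold,
and the alternating narrow/wide grooves of two-layer chair folds.

```{r}
enumerate_topologies(decompose(qref))[, c("descriptor", "n_layers",
                                          "intact_tetrads", "filled")]
```

## Glycosidic variants

Each tetrad layer carries a polarity — the rotational direction of its
Hoogsteen donor progression. The glycosidic conformation of a core guanine
is *anti* when its strand direction agrees with its layer's polarity and
*syn* when it opposes it; the snapback fill-in residue enters with reversed
strand direction after turning around a face, which is why it is syn in an
otherwise all-anti parallel fold. This rule was chosen because it reproduces
all three experimentally characterised conformer patterns of this
architecture (the parallel fold with a lone syn fill-in, the heteropolar
hybrid with a `syn-syn-anti` broken column and three `syn-anti-anti`
columns, and the homopolar hybrid with an interrupted all-syn column); it is
a working rule validated by those observations, not a claimed mechanism.

Assigning a polarity to each of the three layers gives 2³ variants, halved
by the global flip symmetry (reversing every polarity swaps syn and anti
everywhere). Canonical variants have no more syn than anti residues, ties
broken lexicographically, so a three-layer topology yields at most four
variants. Tetrad-tetrad interfaces are *homopolar* when adjacent layers
share a polarity, *heteropolar* otherwise, and syn-syn steps are counted
within columns.

## The additive stability model

Candidates of one sequence are scored relative to each other (kcal/mol); an
intercept absorbs the common baseline, so scores are not absolute folding
energies. Increments, all configurable through `g4_energy_model()` or a YAML
file:

| increment | default | origin |
|---|---|---|
| `syn_syn_step_penalty` | +1.0 | unfavourable stacking of consecutive syn guanines |
| `anti_syn_step_penalty` | +1.0 | syn guanines sit at tract 5'-ends; a 5'-anti→syn-3' step within a tract is essentially unobserved (fill-in residue exempt) |
| `heteropolar_interface_penalty` | +0.3 | opposite-polarity tetrad stacking |
| `missing_tetrad_penalty` | +3.0 | per missing/incomplete layer; keeps two-tetrad and vacancy-triad folds marginal |
| `central_1nt_homopolar_bonus` | −4.5 | measured loop-shortening stabilization of homopolar folds |
| `central_1nt_heteropolar_bonus` | −3.2 | measured loop-shortening stabilization of the heteropolar hybrid |
| `lateral3_end_purine_bonus` | −1.8 | outer-tetrad stacking of a purine at the last position of a narrow-groove 3-nt lateral loop |
| `first_position_purine_penalty` | +0.3 | hydrophobic cost of a solvent-exposed purine at a loop 5'-end |
| `first_position_abasic_bonus` | −0.2 | converse gain for an abasic first position |
| `brg_anti_penalty` | +2.0 | steric cost of holding syn-favouring BrG anti at a tetrad position |
| `overhang5_fill_clash_penalty` | +2.0 | clash of a 5'-flanking residue with a fill-in G on the 5' face |
| `snapback_cap_bonus` | 0 | capping over the outer tetrad; common to filled folds and not separable from the data, hence zero |

Calibration uses printed anchors only: the two loop-shortening free energies
(−4.5 and −3.2 kcal/mol) enter directly as the central-1-nt-loop bonuses,
and the reported conformer molar ratios of the parent sequence (62% / 27% /
11%) fix the hybrid-vs-parallel gap at −RT·ln(62/27) ≈ −0.50 kcal/mol, which
the round defaults reproduce exactly (0.3 + 1.0 − 1.8 = −0.5). Per-mutation
free-energy bars that are only displayed graphically in the source study
were not used. One structural point deserves note: with only syn-syn steps
and heteropolar interfaces, the heteropolar hybrid is the exact feature
midpoint of the homopolar hybrid and the alternating-polarity variant, so no
additive choice of those two increments alone can make it the unique
minimum; the anti→syn step rule (a well-established conformational
regularity) is what breaks that tie, and with it the lowest-energy candidate
of the parent sequence is the observed heteropolar hybrid.

```{r}
sc <- score_candidates(enumerate_candidates(qref), qref)
head(sc[order(sc$dG_est), c("descriptor", "dG_est", "population")], 4)
```

Boltzmann populations use `p_i ∝ exp(-dG_i/RT)` with R = 1.987×10⁻³
kcal mol⁻¹ K⁻¹ at a reference temperature of 303.15 K; a stabilization of
−1 kcal/mol corresponds to a population-ratio factor of
`r round(population_ratio_factor(-1, 303.15), 2)`, i.e. about fivefold.

## Two-state melting analysis

UV melting curves (absorbance at 295 nm vs temperature, default 10–90 °C in
0.2 °C steps) are analysed under a two-state equilibrium with negligible
heat-capacity effects. The unfolding constant is `K(T) = (1-α)/α` with α
the folded fraction; reported ΔH°, ΔS°, ΔG° are *formation* quantities
(negative for a stable fold), so `ln K = ΔH°/R · (1/T − 1/Tm)` and the
regression of ln K on 1/T gives ΔH° as slope×R. For table parity, ΔS° is
taken as ΔH°/Tm (kelvin), which makes ΔG°(Tm) = 0 exact; the independent
entropy from the regression intercept is retained in diagnostics, and any
difference between the two is visible there rather than silently merged.

Numerical choices:

* **Baseline regions** default to the lowest and highest 15% of the
  temperature span. Fixed tail regions are *biased* whenever the tails still
  contain partially melted material — on an exact synthetic curve the
  recovered enthalpy is off by ~0.4%, and for a broad transition near the
  grid edge the tail fit can fail outright. `fit_two_state()` therefore
  initialises with the region pipeline and then re-estimates the four
  baseline parameters together with (ΔH°, Tm) by a global
  Levenberg–Marquardt fit of the full two-state signal
  (`method = "global"`, the default); the reported ΔH° is still the
  weighted van't Hoff regression, computed on the folded fraction implied by
  the refined baselines. Both enthalpy estimates (regression and global) are
  exposed via `glance()`. `method = "regions"` gives the plain pipeline.
* **Van't Hoff window**: α ∈ [0.15, 0.85], configurable and reported with
  every fit; points are weighted by (α(1−α))², the inverse variance of ln K
  under absorbance noise. α is clipped at ε = 10⁻⁶ before logs; saturated
  points are excluded with a warning.
* **Tm** is the linear interpolation of the α = 0.5 crossing. The exported
  `melting_temperature()` treats multiple crossings as a monotonicity
  violation and errors by default; the pipeline uses an isotonic
  (monotone-regression) smoothing that leaves noiseless data untouched and
  yields a single crossing on noisy data.
* **Replicates**: means and sample SDs over independent fits; with n = 1
  the SD is reported as `NA`, never 0. Only heating curves enter replicate
  summaries by default. Hysteresis is flagged when |Tm(heat) − Tm(cool)|
  exceeds 0.5 °C.
* **Display rounding** for table parity is one decimal, round half away
  from zero.

## The synthetic-data generator

`g4_sim_spec()` defines the ground truth: exact two-state α with
ΔS° = ΔH°/Tm, sloping linear baselines (defaults −5×10⁻⁴ and −1.5×10⁻³
a.u./°C, small and deliberately unequal so extrapolation is genuinely
exercised), i.i.d. Gaussian absorbance noise (default σ = 0.002 a.u., sized
so triplicate scatter is comparable to typical reported uncertainties of
±0.1–0.2 kcal/mol in ΔG°), and a 10–90 °C grid at 0.2 °C matching the usual
ramp. Hysteresis is emulated phenomenologically as a ±lag/2 shift of the
apparent transition on heating/cooling — a detector control, not a kinetic
model. Simulation is bit-reproducible from the spec seed and leaves the
session RNG untouched.

What passing the recovery tests shows — and does not show: the generator
emulates sigmoidal two-state transitions with linear baselines and white
noise. Real melting data can carry correlated drift, ramp-rate artefacts,
multi-state transitions and heat-capacity effects, none of which are
simulated; parameter-recovery results therefore validate the estimator
under the stated model, not the two-state assumption itself for any given
real curve.

Test problem sizes: recovery is exercised noiselessly at the parameters of
the reported parallel-fold row, and on a 3×3 grid of ΔH° ∈ {−40, −60, −80}
kcal/mol × Tm ∈ {35, 50, 70} °C with 25 seeds per cell at σ = 0.002 —
401-point curves throughout, medians per cell.

## Known limitations

* Scores are relative free energies among candidates of one sequence;
  absolute stabilities and cross-sequence ΔΔG require the melting module.
* The model slightly misorders the two *minor* conformers of the
  short-central-loop mutant (it places the homopolar hybrid below the
  heteropolar one once the −4.5/−3.2 bonuses apply, whereas the observed
  minor populations are 19% vs 27%); major-species calls are unaffected
  across the entire panel.
* Register isomers of tracts longer than the layer count, vacancies outside
  the 5'-terminal tract, bulged cores, V-shaped loops, left-handed folds and
  multimeric assemblies are out of scope.
* Melting analysis assumes monomolecular two-state behaviour; multi-transition
  deconvolution and ΔCp corrections are not implemented.
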