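# quadfold

Topology enumeration and melting thermodynamics of intramolecular
G-quadruplexes with a snapback-loop, G-vacancy architecture.

## The problem

G-rich DNA sequences fold into four-stranded G-quadruplexes (G4s): stacked
G-tetrads connected by propeller (`p`), lateral (`l`) or diagonal (`d`)
loops. A sequence with one GG tract (one guanine short of three layers),
three GGG tracts and a 3′-terminal `...TCA-G` tail can fill its vacant
tetrad position with the terminal G through a *snapback loop*, and such a
design is restricted to a small set of competing folds — typically a
hybrid-type `+(lpp)` and a parallel `-(ppp)` topology, distinguished by
whether the first 3-nt loop goes lateral or propeller. Which fold wins is
decided by surprisingly small free-energy differences contributed by
individual loop residues and by the glycosidic (syn/anti) pattern of the
G-core. quadfold is for structural-bioinformatics users who want to

* decompose modified G-rich sequences (with inosine `I`, abasic `X`,
  8-bromo-dG `[BrG]`) into tracts, loops and snapback architecture,
* enumerate the feasible topologies under loop-length and helicity
  constraints, with Webba da Silva descriptors, groove widths and
  glycosidic variants classified by tetrad stacking polarity,
* score competing folds with a configurable additive free-energy model and
  convert scores to Boltzmann populations, and
* run the complete two-state UV-melting workflow on real or synthetic
  curves.

## The core quantities

With folded fraction α(T) obtained from linear baseline extrapolation of a
295 nm melting curve, the unfolding constant is K(T) = (1−α)/α and

```
ln K(T) = ΔH°/R · (1/T − 1/Tm)        (van't Hoff; formation convention)
ΔS°     = ΔH°/Tm                       (so that ΔG°(Tm) = 0)
ΔG°(T)  = ΔH° − T·ΔS°
```

Competing folds are weighted by `p_i ∝ exp(−ΔG_i/RT)`; a stabilization of
−1 kcal/mol at 30 °C multiplies a population ratio by
`exp(1/(R·303.15)) ≈ 5.3` — about fivefold.

## Worked example

```r
library(quadfold)

qref <- parse_sequence("GG-CTA-GGG-TCA-GGG-T-GGG-TCA-G", "Qref")
decompose(qref)
#> <g4_decomposition> Qref
#>   tracts: 1-2, 6-8, 12-14, 16-18
#>   loops:  'CTA', 'TCA', 'T'
#>   vacancy: tract 1 (one G short of 3 layers)
#>   snapback: G22 preceded by 'TCA'

sc <- score_candidates(enumerate_candidates(qref), qref)
head(sc[order(sc$dG_est),
        c("descriptor", "n_syn_syn_steps", "n_heteropolar",
          "dG_est", "population")], 4)
#>   descriptor n_syn_syn_steps n_heteropolar dG_est population
#> 1 +(lpp)                   1             1   -0.5      0.489
#> 2 -(ppp)                   0             0    0        0.213
#> 3 +(lpp)                   2             0    0.2      0.153
#> 4 -(ppp)                   0             1    0.3      0.130
```

The lowest-energy candidate is the heteropolar `+(lpp)` hybrid (broken
`syn-syn-anti` column, one syn–syn step), 0.5 kcal/mol below the parallel
fold — a population ratio of about 49:21 at 30 °C — with the homopolar
all-syn-column hybrid third. That is the experimentally observed ranking of
the three coexisting conformers of this sequence.

```r
curve <- simulate_curve(g4_sim_spec(dH = -53.7, Tm = 44.1, seed = 7))
fit <- fit_two_state(curve)
fit
#> <g4_two_state_fit> (heating, global)
#>   Tm = 44.14 C  dH = -53.3 kcal/mol  dG(303.15 K) = -2.37 kcal/mol  r2 = 0.99611
tidy(fit)
#> # A tibble: 5 × 3
#>   term          estimate unit
#>   Tm              44.1   degC
#>   dH             -53.3   kcal/mol
#>   dS              -0.168 kcal/(mol K)
#>   minus_TdS_ref   50.9   kcal/mol
#>   dG_ref          -2.37  kcal/mol
```

A noisy synthetic melt (σ = 0.002 a.u.) generated at ΔH° = −53.7 kcal/mol,
Tm = 44.1 °C is recovered to within 1% / 0.05 °C; ΔG°₃₀ = −2.37 kcal/mol is
the 30 °C folding free energy. `autoplot(fit)` and `plot_vant_hoff(fit)`
draw the fitted curve and the ln K vs 1/T regression; `build_table1_panel()`
emits the full reference mutant panel and `predict_major_topology()` calls
the dominant fold for each member.

A thin command-line wrapper ships in `inst/cli/quadfold.R` with subcommands
`enumerate | score | meltfit | simulate | panel` (exit codes: 0 ok, 2 input
error, 3 constraints unsatisfiable).

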