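---
title: "Mechanistic inference of microbial carbon fluxes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic inference of microbial carbon fluxes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carbonflux)
```

## The problem

Amplicon sequencing tells us *who* is present in a marine microbial
community week by week, but not *who feeds whom*. This package estimates
the dissolved organic carbon (DOC) fluxes that connect phytoplankton taxa
to heterotrophic prokaryote taxa — and heterotrophic prokaryotes to each
other — by fitting a mass-balance ecosystem model to weekly time-series
observations (chlorophyll, 18S/16S rRNA read tables, flow-cytometric cell
counts, inorganic nutrients, temperature, light). The quantity of primary
interest is *internal recycling*: the share of heterotroph DOC consumption
that originates from DOC released by other heterotrophs (via mortality,
presumed mostly viral lysis) rather than from phytoplankton.

## The model

State variables are carbon concentrations (µmol C L⁻¹) of: many
phytoplankton taxa, many heterotrophic prokaryote taxa (each split into an
active and a dormant pool), many hypothetical DOM species, one particulate
organic matter (POM) pool, plus inorganic nutrients (NO₃, NH₄, PO₄,
silicate; µmol L⁻¹).

Phytoplankton growth is
$$\mu = \mu_{max}\, f_T\, f_I\, \min(f_N, f_P[, f_{Si}]),$$
with a Q10 temperature factor $f_T = \min(1, Q_{10}^{(T - T_{ref})/10})$,
a light factor $f_I = \frac{I}{I + k_I}\cdot\frac{daylength}{24}$, and
Monod factors for DIN, PO₄ and (for silicifiers) silicate combined by
Liebig's minimum. DOM release is basal exudation plus a fraction of
photosynthesis ($E = k_e B + f_e P$); respiration is analogous
($R = k_r B + f_r P$).

Heterotrophs grow only by DOM uptake (no exudation): uptake of DOM
species $j$ is $v_{max} f_T B_a w_j D_j/(D_j + K_j)$ with equal weights
over the species the taxon can use; a fraction *yield* becomes biomass and
the rest is respired. When net growth is negative, active cells become
dormant (rate `dorm_in`); dormant cells take up nothing, die slowly
(`kd * dorm_death_mult`) and reactivate when growth turns positive — this
is what prevents extinction over winter and supports coexistence.

Mortality is a single lumped process for both guilds, split between DOM
(`f_dom`, the lysis-like share) and POM. The realized rate is
$k_d + k_{d,quad} B$: the optional density-dependent term is a
kill-the-winner closure representing lytic pressure that rises with host
density. It is off (`kd_quad = 0`) in the plain process-rate operations
and worked examples, but the shipped synthetic community uses it, because
with purely linear mortality a multi-taxon Monod community collapses to
its single best competitor per resource — the closure is what lets five
phytoplankton and eight heterotroph taxa coexist realistically through
the seasons. It also concentrates DOM release at bloom peaks, which is
the viral-lysis phenomenology the DOM/POM ratio diagnostic probes.

POM dissolves into DOM (`k_dis`) and sinks out of the modeled volume
(`k_sink`); sinking and respiration are the only exports, balancing the
winter nutrient loadings.

### Stoichiometric closure

Every carbon flux carries nitrogen and phosphorus at the donor pool's
fixed quota (biomass: Redfield 16/106 and 1/106; DOM species: per-species
quotas constrained to be at most the biomass quotas). Quota mismatches at
organic-organic transfers are balanced against NH₄/PO₄, so heterotrophic
remineralization emerges from the bookkeeping: consuming N-rich DOM while
building Redfield biomass at 30 % yield releases NH₄, which in the
synthetic scenario is what relieves summer nitrogen limitation of the
phytoplankton after a bacterial bloom. Silicate is tracked only through
silicifier biomass. Nutrient loadings (from measured increases of the
nutrient totals, `derive_nutrient_loadings()`) enter as piecewise-constant
source rates.

### Integration and the source ledger

The system is integrated with fixed-step explicit Euler (default
`dt = 0.05` d). Before each update, the outflows of every pool are summed;
if they would overdraw the pool within the step, all of that pool's
outflows are scaled by the factor that empties it exactly. With that rule
the bookkeeping is exactly conservative — per step,
$\Delta(\text{organic C} + \text{exported C}) = \text{photosynthesis}\cdot dt$
to round-off — and the simulator verifies carbon, N, P, Si and ledger
closure at every step (`$balance` on the returned trajectory; the test
suite requires < 1e-9 relative over a year of steps, observed ~1e-13).

A *source ledger* records, for each DOM species and for POM, how much of
the standing mass each producing taxon contributed. Inflows credit the
producer; consumption and dissolution debit all producers proportionally
to their current share (dissolution carries POM attributions into the DOM
ledger). Attributing each consumer's uptake by the ledger fractions yields
the producer-by-consumer flux table (`pairwise_fluxes()`), whose row sums
reproduce total uptake exactly. Initial DOM/POM stocks are attributed to a
`background` producer; flux shares exclude it.

Euler was chosen over adaptive solvers because the per-step proportional
capping and ledger updates are themselves part of the model definition:
flux records are exact sums of what the integrator did. The closed-form
test (exponential growth at `dt = 0.01`, error < 1 %) and the
halving-`dt` convergence test characterize the first-order error.

## Calibration

The objective is a weighted sum of squared log10 residuals
(`eps = 1e-4` µmol C L⁻¹ keeps zeros finite) over all carbon series;
total-pool series get weight equal to their member count so totals and
composition carry comparable weight. Missing observations are skipped.
The optimizer is a greedy stochastic hill climb: perturb 1–3 random free
parameters multiplicatively (lognormal, `sigma = 0.25`), clip to
literature-scale bounds (`inst/extdata/parameter_bounds.yaml`), accept if
the score decreases. A simulated-annealing acceptance with geometric
cooling is available (`temperature > 0`) but off by default — at the
desk-scale problem sizes greedy search recovers parameters well and is
easier to audit. Years are calibrated separately (January-1 boundary),
with the year's initial state taken from the observations at the first
sample (`state_from_observations()`; DOM and POM are unobserved and start
at configurable seed values). `delump_taxa()` implements gradual
delumping in two stages: lumped taxa are replaced by their members, which
inherit the parent's parameters (with optional jitter) and split the
parent's carbon by the members' observed fractions.

Identifiability caveat: a heterotroph whose substrate supply is fully
consumed operates supply-limited, and its `v_max` is then only weakly
identified from concentration series (the objective is flat upward).
Recovery experiments therefore target parameters with clear curvature
(the spring diatom's `mu_max`, a mid-guild consumer's `v_max`).

## The synthetic scenario

The generator emulates the observation structure of a temperate coastal
weekly time series. Defaults (deliberately desk-scale): 5 phytoplankton
taxa (including a flow-cytometry-counted *Synechococcus*-like taxon),
8 heterotroph taxa, 6 DOM species, 2 simulated years. Forcing is
sinusoidal (temperature 13 ± 4 °C peaking in late August, PAR 26 ± 21
peaking at the solstice, daylength 8–16.5 h) with winter NO₃/PO₄/silicate
loadings that restock what sinking exports. DOM species have roles:
fresh exudate (1–2), phytoplankton lysate (3), heterotroph lysate (4–5,
usable only by warm-adapted specialists), dissolved POM (6).

The true parameter set was chosen — once, as the generator's contract —
so the run exhibits the canonical regime: a spring phytoplankton bloom
(February–May chlorophyll peak) when light returns to winter-replete
nutrients; a bacterial bloom (June–August) once temperature releases the
warm heterotroph guild onto the DOM accumulated since spring; a
late-summer phytoplankton bloom (July–August) fed by the NH₄ the
bacterial bloom remineralizes. Within the bacterial bloom the
internal-recycling share rises week over week as the lysate specialists
take over, and the bloom-mean share far exceeds the spring share.

Observations: weekly subsampling (52 dates/year); chlorophyll = eukaryote
phytoplankton carbon × 12.011/40 with lognormal noise (σ = 0.15); 18S and
16S reads are Dirichlet-multinomial draws (depth 20 000, concentration
200) around true carbon fractions, with each eukaryote taxon split over
two ASVs and contaminant ASVs (heterotrophic/unassigned 18S; chloroplast
and ammonia-oxidizer 16S) that the ingest filters must remove; cell
counts and nutrients get lognormal noise. What the generator does *not*
emulate: allochthonous DOM, sequencing batch effects, taxonomy
mis-annotation, irregular sampling gaps, and real interannual variability
— so green tests demonstrate the pipeline's internal consistency and
recoverability under its own assumptions, not field accuracy.

Chlorophyll maps to eukaryote phytoplankton carbon only (the
*Synechococcus*-like taxon is carried by cell counts), keeping the
OTU-carbon identity Σ OTU = chl-derived carbon exact; real chlorophyll
measurements would include the picocyanobacteria.

## Bloom windows and derived quantities

Bloom peaks are seasonal-window maxima (spring phytoplankton: Feb–May on
chlorophyll; summer phytoplankton: Jul–Aug; summer bacteria: Jun–Aug on
total heterotroph concentration). The start is the latest strict local
minimum within 28 d before the peak; since starts were assigned manually
in the motivating analyses, manual start and duration overrides (e.g. 34
or 42 d for persistent blooms) are first-class arguments. Blooms end 28 d
after the start unless the concentration falls below the starting value
earlier. With no local minimum (flat or monotone lead-in) the start falls
back to the window lead-in with a warning.

Derived quantities: bloom-mean and weekly producer-class fluxes
(`aggregate_bloom_fluxes()`), the internal-recycling share
(`hp_flux_share()`), GPP/NPP and gross/net heterotrophic production with
areal conversion (`production_metrics()`; the integration depth defaults
to 50 m and is flagged in reports — station-depth scale, configurable),
DOC-normalized heterotrophy rates (DOC = Σ model DOM pools; no
recalcitrant background), the DOM/POM release ratio (> 1 flags
lysis-dominated mortality), per-taxon limitation time series (recomputable
from states and verified against the simulator's records), and network
snapshots at the median bloom day with inflow/outflow/throughflow node
sizes.

## Problem sizes and reproducibility

All shipped analyses run on the desk-scale scenario: 2-year ground-truth
runs at `dt = 0.05` d; conservation verified over a year (7 300 steps);
two-parameter recovery with 2 000 hill-climb iterations × 5 observation
seeds; flux-share recovery with 250 iterations × 5 seeds on 13 free
parameters. All randomness flows from explicit integer seeds; simulations
are bitwise deterministic given configuration and forcing. The pipeline
orchestrator (`run_pipeline()`/`write_report()`) exposes the stages as R
functions with a JSON manifest (config hash, seed, timings) — the
package's users work in R, so no shell entry point is shipped.

## Known limitations

- Exact mortality partitioning (viruses vs grazers) is not modeled; only
  the DOM/POM split of a lumped death flux.
- The functional forms (Q10, Monod, Liebig, equal substrate weights) are
  one reasonable choice among several; all parameters sit behind
  constructors so alternative configurations are easy, but alternative
  *forms* require code changes.
- Nutrient loadings are piecewise-constant exogenous rates; there is no
  explicit mixing or advection.
- Weekly observations under-sample bloom rise times; calibration can
  therefore trade timing against magnitude, which is why recovery checks
  use medians over several observation seeds.
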