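# carbonflux

Mechanistic inference of carbon fluxes in microbial plankton communities.

Amplicon time series show *who* is present in a coastal microbial
community; they do not show *who feeds whom*. `carbonflux` estimates the
dissolved organic carbon (DOC) fluxes connecting phytoplankton taxa and
heterotrophic prokaryote taxa by calibrating a mass-balance ecosystem
model to weekly observations — chlorophyll, 18S/16S rRNA ASV read tables,
flow-cytometric cell counts, inorganic nutrients and physical forcing —
after converting them all to carbon units. The headline quantity is
**internal recycling**: the share of heterotroph DOC consumption that
comes from DOC released by *other heterotrophs* (mortality, mostly viral
lysis) rather than by phytoplankton.

It is aimed at microbial ecologists and biogeochemists working with
weekly coastal observatory data who want bloom-resolved, taxon-resolved
flux estimates rather than co-occurrence networks.

## The model in brief

Carbon is tracked in phytoplankton taxa, heterotroph taxa (active +
dormant pools), hypothetical DOM species, one POM pool and an export
term, alongside NO₃, NH₄, PO₄ and silicate. Phytoplankton grow as

```
mu = mu_max * f_T * f_I * min(f_N, f_P[, f_Si])
```

(Q10 temperature factor, Monod light x photoperiod, Liebig minimum over
Monod nutrient factors), exude DOM (`ke*B + fe*P`), respire
(`kr*B + fr*P`) and die (`kd + kd_quad*B`, split `f_dom` to DOM, rest to
POM). Heterotrophs take up DOM species `j` at
`v_max * f_T * B * w_j * D_j/(D_j + K_j)` with taxon-specific
affinities, grow with a fixed yield and respire the rest; dormancy
prevents winter extinction. POM dissolves into DOM and sinks out. Every
carbon flux carries N and P at fixed quotas, so remineralization — and
with it the nitrogen hand-off from bacterial blooms to late-summer
phytoplankton — emerges from the bookkeeping.

Integration is fixed-step explicit Euler with proportional outflow
capping, which makes the mass balance exact (carbon, N, P and
ledger-attribution closure are verified each step to ~1e-13 relative). A
*source ledger* tracks which taxon produced the standing mass of every
DOM species, so each uptake flux can be attributed to its producers —
that attribution is what turns a simulation into a flux network.

Calibration is a greedy stochastic hill climb in log-parameter space
within literature bounds, scored by weighted squared log10 residuals
against all carbon series, run separately per year, with gradual
delumping from lumped groups to full taxa.

## Worked example

Generate the shipped synthetic scenario (5 phytoplankton taxa, 8
heterotroph taxa, 6 DOM species, 2 years of daily dynamics), detect
blooms, and attribute fluxes:

```r
library(carbonflux)
sc    <- synthetic_scenario(seed = 1)
truth <- generate_ground_truth(sc)
truth$blooms
#>       bloom_type year      start       peak        end duration
#>     phyto_spring 2015 2015-02-24 2015-03-24 2015-03-24       28
#>  bacteria_summer 2015 2015-06-06 2015-07-04 2015-07-04       28
#>     phyto_summer 2015 2015-06-11 2015-07-08 2015-07-09       28
#>     phyto_spring 2016 2016-03-11 2016-04-08 2016-04-08       28
#>  bacteria_summer 2016 2016-06-13 2016-07-11 2016-07-11       28
#>     phyto_summer 2016 2016-06-15 2016-07-13 2016-07-13       28
```

The seasonal sequence — spring phytoplankton bloom, bacterial summer
bloom, late-summer phytoplankton bloom — emerges from the mechanisms:
light releases the spring bloom onto winter nutrients, rising temperature
releases the heterotrophs onto accumulated DOM, and the NH₄ they
remineralize feeds the second phytoplankton bloom.

```r
pw <- pairwise_fluxes(truth$trajectory)
w  <- subset(truth$blooms, bloom_type == "bacteria_summer" & year == 2015)
round(aggregate_bloom_fluxes(pw, w)$bloom_mean, 3)
#>     phyto_to_het        het_to_het background_to_het
#>            0.968             0.589             0.012
hp_flux_share(pw, w)
#> [1] 0.38
dom_pom_release_ratio(truth$trajectory)$ratio
#> [1] 1.14
```

During the 2015 bacterial summer bloom, heterotrophs drew 0.97 µmol C
L⁻¹ d⁻¹ from phytoplankton-derived DOC and 0.59 µmol C L⁻¹ d⁻¹ from DOC
released by other heterotrophs — an internal-recycling share of 0.38,
versus ~0.02 in the spring bloom — and the DOM/POM release ratio of 1.14
flags lysis-dominated mortality. `production_metrics()` converts the same
run into GPP/NPP and heterotrophic production (volumetric and areal):
whole-run GPP here is 0.76 µmol C L⁻¹ d⁻¹ (38 mmol C m⁻² d⁻¹ over 50 m).

To run the full observation pipeline (write synthetic weekly CSVs, read
them back, convert to carbon, simulate, attribute, report):

```r
run_pipeline("out", stages = c("synth", "ingest", "fluxes", "report"),
             scenario = synthetic_scenario(seed = 1))
```

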