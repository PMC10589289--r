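# phycopam

Photophysiology of macroalgae from PAM fluorometry and bio-optics: rapid
light curve (RLC) fitting, absorbance-spectrum decomposition partitioning
chlorophyll a between photosystem II and photosystem I, excitation-adjusted
chlorophyll-a emission ratios, and the season × tissue-age statistics —
plus a synthetic-data generator with known ground truth so the whole
pipeline is testable without instrument data.

**Who it is for.** Researchers analysing pulse-amplitude-modulated (PAM)
chlorophyll fluorescence and in-vivo optical spectra of seaweeds (e.g.
Arctic *Ulva*, *Palmaria palmata* and kelps across the Polar Night), and
anyone needing a tested reference implementation of the underlying
numerics.

## The models

**Rapid light curves.** From the dark reading, the maximum quantum yield of
PS II is F<sub>v</sub>/F<sub>m</sub> = (F<sub>m</sub> − F<sub>0</sub>)/F<sub>m</sub>.
At each actinic step the operational yield is
φ′ = (F′<sub>m</sub> − F)/F′<sub>m</sub> and the relative electron transport
rate is rETR = φ′ · E<sub>PAR</sub>. The rETR–irradiance curve is fitted
with the Webb (1974) saturating exponential

> rETR(E) = α · E<sub>K</sub> · (1 − e<sup>−E/E<sub>K</sub></sup>),

giving the photosynthetic efficiency α, the asymptote
rETR<sub>max</sub> = α·E<sub>K</sub>, and the light saturation parameter
E<sub>K</sub> = rETR<sub>max</sub>/α (µmol photons m⁻² s⁻¹). Fitting is
Nelder–Mead least squares on log-parameters.

**Absorbance decomposition.** Whole-tissue absorbance and the water-soluble
phycobiliprotein extract (the LHC II + PS II fraction of a red alga) are
baseline-zeroed at 800 nm, the extract is scaled to match the
phycoerythrin peak at 495 nm, and the difference spectrum estimates the
non-fluorescent LHC I + PS I fraction. Red Chl-a peaks (640–700 nm,
quadratic-refined) give the PS II share of red-peak absorbance and the
spectral shifts between the 676-nm (PS II), 681-nm (PS I) and emergent
~679-nm (total) peaks.

**Emission ratios.** The 685-nm PS II emission peak under green (525 nm)
vs blue (452 nm) excitation, divided by the instrument's excitation
intensity ratio (600/200 = 3), indicates the relative energy transfer to
PS II vs PS I.

**Statistics.** One-/two-way fixed-effects ANOVA (classical sums of
squares; Type II-style when unbalanced) with Tukey–Kramer post-hoc tests.

## Worked example

```r
library(phycopam)

# absorbance decomposition on the synthetic red-algal fixture
fx  <- make_palmaria_spectra()            # truth: PS II weight 0.40, 676/681 nm
dec <- decompose_absorbance(fx$total, fx$extract)
dec
#> <decomposition_result>
#>   red peaks (nm): total 679.03, a_PSII 676.00, PS I diff 681.00
#>   PS II red-peak fraction: 41.2%
#>   shifts (nm): PS I - a_PSII 5.00, total - a_PSII 3.03
#>   extract scale factor 2.002, PE mismatch at 2nd anchor 0.001

# Webb fit round trip on a noiseless simulated RLC
fit <- fit_rlc(simulate_rlc(rlc_sim_config(alpha = 0.30, E_K = 50)))
fit$params
#> <photo_params: alpha=0.3, rETR_max=15, E_K=50, Fv/Fm=0.700, sse=1.18e-13>

# excitation-adjusted green:blue emission ratio
g <- summarize_emission(make_emission_spectrum("green", peak685 = 750))
b <- summarize_emission(make_emission_spectrum("blue",  peak685 = 75))
raw <- green_blue_ratio(g, b)                      # 10.0
as.numeric(adjust_for_excitation(raw))             # 3.33

# season contrast on the synthetic pigment table
pt <- make_pigment_table(seed = 1)
ua <- pt[pt$species == "Ulva sp." & pt$pigment == "Chl a", ]
one_way_anova(ua$concentration, ua$season)
#> <anova_result>
#>    effect df      ss      ms      F          p
#>     group  1 2211658 2211658 119.86 0.00039541
#>  residual  4   73810   18452     NA         NA
```

Reading the numbers: the decomposition recovers the configured 40% PS II
share of red-peak absorbance to within 1.2 percentage points, the 5-nm
PS I↔PS II shift exactly, and the emergent 679-nm total peak produced by
summing the 676- and 681-nm bands. The noiseless Webb fit returns the
generating parameters to machine-level accuracy (with realistic noise,
E<sub>K</sub> from a single 13-step curve is poorly identified — see the
vignette's estimator-limitation section). The adjusted emission ratio ~3
corresponds to the published interpretation that roughly a third of Chl a
serves PS II in *P. palmata*. The pigment ANOVA flags the ~2.5× seasonal
Chl-a contrast in *Ulva* (F ≈ 120, p < 0.001).

## Command line

```sh
Rscript inst/cli/phycopam.R run --out-dir out --seed 1        # full pipeline
Rscript inst/cli/phycopam.R fit-rlc --rlc out/rlc01.csv
Rscript inst/cli/phycopam.R decompose --total out/absorbance_total.csv \
        --extract out/absorbance_extract.csv
```

## Layout

- `R/` — implementation: synthetic generators, RLC fitting, spectral
  decomposition, emission analysis, ANOVA/Tukey, text I/O, pipeline.
- `tests/testthat/` — unit, property and acceptance tests.
- `vignettes/macroalgal-photophysiology.Rmd` — models, assumptions,
  numerical choices, limitations.
- `inst/cli/phycopam.R` — command-line front end.
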