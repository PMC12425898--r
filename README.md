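# qwachron

Cellular-level dendroclimatology in R: from per-cell tracheid measurements
to intra-ring **sector chronologies**, chronology **signal statistics**,
**ring-width standardization**, and **climate-correlation screening**.

## The problem

Conifer tree rings archive climate not only in their width but in their
anatomy: the radial lumen diameter (LD) and tangential wall thickness (CWT)
of successive tracheids record conditions through the growing season. The
*tracheidogram* — the radial profile of cell measurements along one ring —
can be standardized by dividing each ring into S equidistant sectors
(sector I = earlywood at the ring start, sector S = latewood at the ring
end), turning rings with different cell counts into comparable S-point
profiles. Averaged over ≥ 10 radial files per ring and z-scored per tree,
each sector yields an annual site chronology whose common signal is
quantified by the classical statistics

- **Rbar** — mean pairwise Pearson correlation among tree series,
- **EPS** = n·r̄ / (n·r̄ + (1 − r̄)) — expressed population signal,
- **SNR** = n·r̄ / (1 − r̄), with EPS = SNR/(1 + SNR),
- **AR1** — lag-1 autocorrelation (persistence).

Ring widths are standardized conventionally: a variance-stabilizing power
transform, a cubic smoothing spline whose frequency response is 0.5 at a
wavelength of 0.66·n years ("66% spline, 50% cutoff"), ratio indices, and
a Tukey biweight robust site mean. Chronologies are then screened against
monthly climate (previous-year January through current-year December),
seasonal aggregates of 1–19 months (totals for precipitation, means for
temperature and drought indices), and gridded fields, with exact two-tailed
t-transform p-values on pairwise-complete years.

Because raw cellular datasets of this kind are rarely deposited, the
package ships a calibrated synthetic generator (`gen_climate()`,
`gen_anatomy()`, `gen_ringwidths()`) that emulates a semi-arid
East-Mediterranean juniper site — 6 trees, 1963–2019, a decreasing lumen
profile (≈ 22 → 4 µm), increasing wall profile (≈ 3 → 5 µm), a positive
May-precipitation and negative summer-temperature lumen response, weak
common signal in wall thickness, and a post-1992 warming-driven lumen
decline — so every stage of the pipeline is testable end to end.

## Worked example

```r
library(qwachron)
params  <- qwa_params(seed = 42)          # the emulated study conditions
climate <- gen_climate(params)
cells   <- gen_anatomy(climate, params)   # ~150k cells, 6 trees, 57 years

sm       <- build_sector_matrix(cells, n_sectors = 10, min_files = 10)
stats_ld <- chronology_stats(sm, "ld")
round(stats_ld[c(1, 10, 11), c("mean","sd","ar1","rbar","eps","snr")], 3)
#>      mean    sd   ar1  rbar   eps   snr
#> 1  22.339 4.158 0.312 0.371 0.779 3.534   (sector I)
#> 10  3.804 0.700 0.278 0.369 0.778 3.502   (sector X)
#> 11 15.049 2.755 0.296 0.366 0.776 3.464   (cross-sector mean)
```

Sector means fall from ≈ 22 µm (earlywood) to ≈ 3.8 µm (latewood); an Rbar
near 0.37 at n = 6 trees gives EPS ≈ 0.78 — a usable, if sub-0.85, common
signal, typical for wood-anatomical series.

```r
chron <- sector_chronology(sm, "ld")              # z-score site chronologies
x     <- chron[chron$sector == "X", ]
split_group_test(x$index, x$year, split_year = 1992)
#> sector X level shift: F = 9.7, p = 0.0029, means 0.26 / -0.27

best_season(seasonal_scan(data.frame(year = x$year, LD_X = x$index), climate))
#>   variable  window length          r            p
#> 1   precip     May      1  0.3843701 3.157715e-03
#> 2     spei     May      1  0.6608770 2.210185e-08
#> 3     tmax May-Sep      5 -0.7826543 6.419745e-13
critical_r(57)
#> 0.261
```

The screen recovers exactly the structure the generator injected: a
positive current-May precipitation optimum, a strong negative
May–September maximum-temperature window, a positive drought-index
correlation, and a significant post-1992 lumen decline. `run_pipeline()`
(see `?qwa_config`) executes the same flow from files on disk and writes
tidy CSV outputs plus a run manifest; `inst/scripts/qwa-run.R` wraps it for
the shell.

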