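# acoustoWMRS

Simulation and analysis of **wavelength-modulated Raman spectroscopy (WMRS)
time series from acoustically trapped bacterial aggregates**, for
spectroscopists and microbiologists who monitor live-cell biochemistry —
for example the lipid response of mycobacteria to the antibiotic isoniazid
(INH) — without labels and without immobilising the cells.

## The method

An acoustic half-wavelength resonator (8.07 MHz drive, ~120 µm channel)
levitates a bacterial aggregate at the pressure node while Raman spectra
are acquired. Because the fluorescence background of biological samples
dwarfs the Raman lines, the excitation laser is stepped over five
wavelengths spanning 1.5 nm around 785 nm (50 s integration each, 250 s per
differential spectrum): Raman bands shift with the excitation while the
background does not. The package reconstructs a **background-free
differential (WMR) spectrum** from each five-step modulation set by
per-detector-bin contrasts across steps — any additive component constant
across steps cancels exactly. In a differential spectrum a band centre is a
positive-to-negative **zero crossing**, and its intensity is the
**peak-to-valley value** of the flanking lobes; for an exact
Lorentzian-derivative profile of amplitude A and half-width γ this equals
(9/(4√3))·A/γ.

Thirteen fingerprint bands (600–1800 cm⁻¹; tyrosine, nucleic acids,
carbohydrates, lipids, carotenoids) are matched to a reference catalogue and
tracked over up to 8 h. Each band's series is classified as
increasing/stable/decreasing with the **Mann–Kendall test** (exact null
distribution for n ≤ 8) gated by the **Theil–Sen slope**, and the resulting
trend table is scored against the expected per-condition pattern.

The trap physics is modelled in the long-wavelength (Rayleigh) regime: the
acoustophoretic contrast factor Φ = f₁/3 + f₂/2 (polystyrene in water
≈ 0.224), the standing-wave radiation force F(z) = 4πΦka³·E_ac·sin(2kz),
and the levitation-balance calibration p_min = √(4ρ₀c₀²Δρg/(3Φk)) — the
smallest pressure amplitude whose radiation force balances a 10 µm test
bead's net weight. With the measured 18.2 kPa/Vpp ± 30 % transducer
calibration, the 3 Vpp holding drive (54.6 kPa) sits well above the
≈ 13.9 kPa threshold.

No measured spectra are distributed; the package ships a first-class
synthetic-data generator (Lorentzian fingerprint lines with
condition-specific trajectories, a smooth fluorescence background ~10× the
line amplitude, Poisson shot noise) so the entire chain is testable and
reproducible end to end.

## Worked example

```r
library(acoustoWMRS)

res <- runPipeline(file.path(tempdir(), "demo"), "inh_stress",
                   hours = 8, seed = 42)
print(res$trendTable)
#> TrendTable (inh_stress): 13 bands, agreement 1.00
#>    reference_cm1      label sen_slope  p_value   expected
#> 1            635 increasing   0.05968 3.97e-04 increasing
#> 2            783     stable  -0.00699 2.75e-01     stable
#> 3           1007     stable   0.00389 5.48e-01     stable
#> 4           1040 increasing   0.06910 4.96e-05 increasing
#> 5           1080 increasing   0.12787 4.96e-05 increasing
#> 6           1130 increasing   0.09238 4.96e-05 increasing
#> 7           1150 decreasing  -0.16475 1.67e-02 decreasing
#> 8           1303 increasing   0.13268 4.96e-05 increasing
#> 9           1443 increasing   0.13383 4.96e-05 increasing
#> 10          1523 decreasing  -0.11075 4.96e-05 decreasing
#> 11          1606 increasing   0.07481 4.96e-05 increasing
#> 12          1658 increasing   0.13165 4.96e-05 increasing
#> 13          1750 increasing   0.12861 4.96e-05 increasing
```

One simulated 8 h INH-stress run (hourly modulation sets, shot noise at a
band signal-to-noise ratio of about 20) recovers the full expected pattern:
lipid-associated bands (1080, 1303, 1443, 1658, 1750 cm⁻¹) rise — the
hallmark of the drug response — the tyrosine/carbohydrate rises are slowed
and delayed, and the carotenoid bands (1150, 1523 cm⁻¹) decay almost to
zero. `sen_slope` is the fractional change per hour of the renormalised
peak-to-valley series; `p_value` is the two-sided Mann–Kendall probability
(4.96e-05 = 2/8! is a perfectly monotone 8-point series).

```r
op <- trapOperatingPoint(3)
sprintf("hold pressure: %.1f kPa, levitation threshold: %.1f kPa",
        op$pA / 1e3, op$levitationThreshold / 1e3)
#> "hold pressure: 54.6 kPa, levitation threshold: 13.9 kPa"
```

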