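# lynxmonitor

Quantitative monitoring machinery for translocation-based reinforcement of
small, inbred carnivore populations, built around the data streams of the
Dinaric–Alpine Eurasian lynx (*Lynx lynx*) reinforcement: non-invasive
microsatellite genotypes, multi-year camera-trap capture histories, GPS
collar tracks, and tracking-period fates. Every stage is paired with a
seeded synthetic-data generator, so the whole pipeline can be exercised,
calibrated, and validated without access to any field data.

## What it computes

**Genetic monitoring.** Observed and Nei's unbiased expected
heterozygosity per microsatellite locus; *effective inbreeding* relative
to a source population, `Fe = 1 − H_focal / H_ref` (default reference
`H_ref = 0.592`); a 40-individual traveling window that tracks `Fe`
chronologically; and the lethal-equivalents projection of inbreeding
depression, `δ = 1 − exp(−(2B/2)·Fe)` with `2B = 12` diploid lethal
equivalents, giving remaining relative fitness `1 − δ`. Three nested
scenarios (remnant only; core-area reinforcement; fully connected system)
filter the genotype table before windowing. Immigrant offspring are
screened via private alleles, and parentage is assigned by simple allele
exclusion (single-parent and parent-pair tests with a configurable
mismatch tolerance).

**Density.** Maximum-likelihood multi-session spatial capture–recapture:
half-normal detection `p(d) = p0 · exp(−d²/2σ²)` with optional session,
sex, site-type, and local (trap-specific) behavioral-response effects on
`p0` (logit link) and sex on `σ` (log link); a state space of 2.5-km
cells within a 15-km buffer of the traps; conditional-on-detection
likelihood integrated over the state space; Horvitz–Thompson abundance
with lognormal CIs; density per 100 km²; AIC model ranking; a seasonal
closure filter (Aug 15 – Feb 15) and annual turnover.

**Predation.** GPS location-cluster (GLC) kill-site detection (200-m
radius, 2-day window, ≥2 fixes, sequential centroid sweep), inter-kill
intervals, time from release to first kill, feeding time, and
kleptoparasitism rates with exact binomial CIs.

**Survival.** Tracking periods with a six-category end status mapped to
right-censored records (disappeared animals excluded by default),
Kaplan–Meier curves with Greenwood errors, and the k-sample log-rank
test.

## Worked example

```r
library(lynxmonitor)

# projected inbreeding depression under the three scenarios
fe <- c(no_reinforcement = 0.32, core_only = 0.19, fully_connected = 0.08)
delta <- inbreeding_depression(fe, lethal_equivalents = 12)
round(delta, 2)
#> no_reinforcement        core_only  fully_connected
#>             0.85             0.68             0.38
round(relative_fitness(delta), 2)
#> no_reinforcement        core_only  fully_connected
#>             0.15             0.32             0.62
```

Without reinforcement the remnant population retains an expected 15% of
source-population fitness; the core-area reinforcement alone more than
doubles that, and the fully connected system quadruples it.

A full synthetic run:

```r
dir <- tempfile(); out <- tempfile()
generate_synthetic_inputs(seed = 11, out_dir = dir,
  drift = list(n_generations = 8, ne = 10,
               immigrants = list(generation = 5, n_dinaric = 4,
                                 n_alpine = 3, n_excluded = 0)),
  scr = list(n_sessions = 2, n_occasions = 6, density = 2),
  tracks = list(n_animals = 2, n_kills = 8),
  survival = list(n_per_group = 8))
res <- run_pipeline(list(
  inputs = list(genotypes = file.path(dir, "genotypes.csv"),
                traps = file.path(dir, "scr_traps.csv"),
                detections = file.path(dir, "scr_detections.csv"),
                tracks = file.path(dir, "tracks.csv"),
                periods = file.path(dir, "tracking_periods.csv")),
  popgen = list(window_width = 20, window_step = 5),
  scr = list(buffer = 7500)), out)
writeLines(res$summary_lines)
#> Monitoring pipeline summary
#> ===========================
#> [popgen] remnant_only: final-window He=0.472 Fe=0.202 delta=0.70 fitness=0.30
#> [popgen] dinaric_reinforcement: final-window He=0.576 Fe=0.027 delta=0.15 fitness=0.85
#> [popgen] fully_connected: final-window He=0.718 Fe=-0.213 delta=0.00 fitness=1.00
#> [scr] session Y1: N=13.4 (6.1-29.5), D=1.73/100km2
#> [scr] session Y2: N=15.6 (7.5-32.7), D=2.02/100km2
#> [scr] density change first-to-last session: +16.7%
#> [glc] 9 clusters; mean inter-kill interval 5.57 d; mean feeding time 2.00 d
#> [survival] f1: n=8, events=4, S(183d)=0.88
#> [survival] remnant: n=8, events=4, S(183d)=0.73
#> [survival] translocated: n=8, events=4, S(183d)=0.88
#> [survival] log-rank chi2=0.92 df=2 p=0.630
```

The three scenario series show the reinforcement signature: the remnant
counterfactual stays inbred (`Fe = 0.20`), the core reinforcement pulls
the final window near the source (`Fe = 0.03`), and the fully connected
system overshoots it (negative `Fe`, flagged, depression clamped at 0).

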