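# poremod

Site-level detection of RNA modifications in direct RNA nanopore sequencing
data, for people benchmarking therapeutic RNA chemistries (2′OMe, 2′MOE,
2′F, LNA, phosphorothioate backbones, m1Ψ, 5moU, m5C, ...) against canonical
controls. Direct RNA sequencing reads native RNA 3′→5′ through a protein
pore; a modification perturbs both what the basecaller writes and the ionic
current underneath it. `poremod` implements the two complementary detection
strategies that exploit this, plus the benchmarking and quantification
machinery around them, and a seeded synthetic-data generator so the whole
pipeline runs and is tested without sequencing data.

## The two statistics

**Total variation percentage** — per reference position, from a basecall
pileup:

```
TV = 100 × (mismatched base calls + deletion calls + insertion calls)
           ─────────────────────────────────────────────────────────
           (A + C + G + U calls + deletion calls + insertion calls)
```

Positions with zero denominator are *undefined*, never 0%. The per-type
breakdown (mismatch by base, deletion, insertion) shares the same
denominator and sums exactly to the total.

**Two-sample energy distance** — per position, from per-read signal features.
Each read contributes a 9-dimensional vector (log dwell time, current mean,
current SD at the position and its two neighbours, robustly scaled); with
X = {x₁…xₙ} from the modified sample and Y = {y₁…yₘ} from the control,

```
E(X, Y) = 2/(nm) Σᵢⱼ ‖xᵢ − yⱼ‖  −  1/n² Σᵢⱼ ‖xᵢ − xⱼ‖  −  1/m² Σᵢⱼ ‖yᵢ − yⱼ‖
```

a nonparametric multivariate statistic that is zero when the distributions
coincide and grows with any distributional difference — mean shift, variance
inflation, or dwell-time changes the basecaller silently absorbs.

Detection is scored against known modified positions with mid-rank AUROC,
step-wise average-precision AUPRC, thresholded confusion matrices and
proximity attribution of false positives; modification-aware basecaller
pileups (bedMethyl-like, as emitted by Modkit) are summarized with
canonical-call-denominator modified fractions and cumulative curves.

## Worked example

```r
library(poremod)

cfg <- sim_config(seed = 7)      # 120-nt reference, 9 modified sites,
sim <- simulate_dataset(cfg)     # 200 reads per sample
#> <mod_sim> 120-nt reference, 9 modified sites, 200/200 reads (control/modified)

tv <- total_variation(sim$pileup$modified)
summary(tv[sim$truth$position])
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   15.42   16.75   17.91   18.79   21.89   22.71

pre  <- preprocess_signals(coverage_filter(sim$signal$modified),
                           coverage_filter(sim$signal$control))
prof <- energy_profile(pre$modified, pre$control)
#> <energy_profile> 120 positions (118 defined), max E = 1.861 at position 71

sp_tv <- scored_positions(sim$pileup$modified$position, tv, sim$truth)
sp_ed <- scored_positions(prof$position, prof$energy_distance, sim$truth)
round(c(tv_auroc = auroc(sp_tv), tv_auprc = auprc(sp_tv),
        ed_auroc = auroc(sp_ed), ed_auprc = auprc(sp_ed)), 3)
#> tv_auroc tv_auprc ed_auroc ed_auprc
#>    0.985    0.824    0.918    0.332

confusion_at(sp_tv, 20)   # predict "modified" at >= 20% total variation
#>  tp  fp  tn  fn
#>   3   0 111   6
```

Modified sites (clusters at 33–37, 70–74, 107–111) carry ~15–23% total
variation against a ~4% background, and the energy profile peaks inside
each cluster (maximum at position 71). The profile also shows secondary
elevation ~10 nt downstream of each cluster — the dwell-time perturbation
offset the generator emulates — which costs the energy distance precision
(AUPRC 0.33) while it stays a strong ranker (AUROC 0.92): exactly the
broader-footprint behaviour that makes error-based and signal-based
detection complementary.

The same stages run file-to-file through `run_all()` (see
`?run_config`), or from a shell via `inst/scripts/poremod.R simulate|run`.

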