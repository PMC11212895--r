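# memdyn

Quantifying the population dynamics of circulating memory CD4 T cells —
central memory (T<sub>CM</sub>) and effector memory (T<sub>EM</sub>) — from
BrdU/Ki67 dual-labelling timecourses in busulfan bone-marrow-chimeric mice.
The package is aimed at quantitative immunologists who want to estimate
division, loss and influx rates of kinetically heterogeneous lymphocyte
populations, compare competing models of that heterogeneity, and test the
fitted dynamics against independent fate-mapping experiments.

## The model

Each memory subset, stratified by host/donor lineage and mouse age cohort,
is described as one or two subpopulations whose cells divide (rate α),
die or differentiate away (rate δ), and receive a constitutive influx of
new cells (per-capita rate *f*, total φ = *f·N*). Cells are classified by
Ki67 (expressed for *T* = 1/β days after division) and by BrdU content
(each division during the labelling pulse marks both daughters with
probability ε). Four topologies of kinetic heterogeneity are implemented:

- **branched** — new cells split between independent fast and slow pools;
- **linear** — all influx enters a fast pool that matures into a slow pool (rate γ);
- **burst** — quiescent cells are triggered (rate *a*) into a fast-dividing
  state and revert (rate *r*);
- **temporal** — a single pool in which only the loss rate differs between
  Ki67-high and Ki67-low cells (the model the data reject).

The labelling dynamics are linear ODEs over compartments
{pool} × {Ki67 stage} × {BrdU±}, solved exactly by matrix exponentials
under the quasi-equilibrium assumption (loss rates are closed so each pool
is stationary). Fits are Bayesian: beta likelihoods on the four observed
fractions (BrdU⁺, BrdU⁺ within Ki67-high/low, Ki67-high), adaptive
Metropolis sampling initialised at the posterior mode, and priors on the
influx rate derived from fits to donor-chimerism replacement curves,
`dX/dt = rate·(source − X)`. Topologies are ranked by PSIS-LOO ELPD
(differences below 4 treated as indistinguishable). Derived summaries
include the net loss rate λ = δ − α, the clonal half-life ln 2/λ,
size-weighted mean lifespans 1/(Σ Nᵢδᵢ/Σ Nᵢ), and the two closed-form
lifespan approximations 2ε/p (BrdU upslope) and −T/ln(1 − k/2) (Ki67
occupancy k).

## Worked example

Simulate one stratum, derive an influx prior from a chimerism fit, and fit
the branched model:

```r
library(memdyn)
truth  <- paper_like_truth(strata = "young.TCM.host")
design <- experiment_design()                      # 21-day pulse, 35-day assay
obs    <- generate_labelling_dataset(truth, design, seed = 1)

chi   <- generate_chimerism_dataset(truth, seed = 2)
rfit  <- fit_replacement(chi[chi$subset == "TCM", ], seed = 3)
prior <- influx_prior_from_replacement(rfit)
prior
#> Influx prior: rate ~ lognormal(-4.609, 0.057) (median 0.009963/day);
#>   source chimerism ~ beta(568.42, 186.57)

fit <- fit_labelling_model(obs, "branched", influx_prior = prior,
                           design = design, seed = 4)
fit
#> Labelling model fit (branched topology), 8000 posterior draws
#>   max split-Rhat: 1.029; min ESS: 144
#>   PSIS-LOO elpd: 309.3 (SE 7.6)
#>      parameter         q2.5          q50        q97.5
#> 1            f 8.773444e-03 9.894337e-03 1.101606e-02
#> 2      epsilon 5.630556e-01 6.010092e-01 6.378202e-01
#> 3         beta 3.014891e-01 3.242109e-01 3.508997e-01
#> ...
```

The posterior recovers the generating parameters (ε = 0.6, Ki67 lifetime
1/β = 3.1 d, fast fraction ν = 0.45). Lifespan summaries follow directly
from the draws:

```r
lifespan_summary(fit$draws[complete.cases(fit$draws), ])
#>         quantity       median           lo           hi frac_infinite
#> 1    lambda_fast  0.011050983  0.009331573   0.01272966             0
#> 2    lambda_slow  0.008917698  0.006180722   0.01184568             0
#> 3 half_life_fast 62.722673606 54.451348510  74.23430602             0
#> 4 half_life_slow 77.727140444 58.514772402 112.14664282             0
#> 5  mean_lifespan 12.303104908 11.383683962  13.24563636             0
```

`half_life_*` are clonal half-lives in days (ln 2/λ: how long a cohort of
cells — and the TCR clones it carries — takes to halve); `mean_lifespan`
is the size-weighted mean cell lifespan of the stratum. The closed-form
population average from Ki67 occupancy alone:

```r
k <- weighted_subset_average(0.4, 0.2, 7.5)   # Ki67-high, weighted TEM:TCM
lifespan_from_ki67(k, 3.1)
#> [1] 26.15623
```

`run_full_analysis(pipeline_config(...))` chains every stage — input
tables, replacement fits, per-stratum fits of all four topologies, LOO
comparison, derived quantities, transfer predictions — into one seeded,
resumable run writing CSV outputs and a manifest.
`predict_label_dilution()` and `predict_transfer_ki67()` reproduce the two
fate-mapping validation experiments (reporter dilution along the
naive → T<sub>CM</sub> → T<sub>EM</sub> pathway; Ki67 trajectories of
transferred division-marked cohorts).

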