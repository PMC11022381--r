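# msncm

Ecosystem-level microbiome comparisons between benthic holobiont
communities and their surrounding sediment along an ocean-acidification
gradient, built around two statistics:

* **Distinctness** — the percentage of features (16S ASVs or metabolite
  features) present in a unit's holobiont community microbiome that are
  absent from the paired sediment microbiome, modelled against ordinal pH
  with a hierarchical linear mixed model and a likelihood-ratio test.
* **The mixture Sloan neutral community model (MSNCM)** — occurrence
  frequencies of taxa across the holobiont community samples of one pH
  regime modelled as a two-source neutral mixture.

Under the Sloan model a taxon with metacommunity relative abundance *p*
occurs in a sample with probability
`F(p) = 1 - I_d(Nmp, Nm(1-p))` — the upper tail of the stationary beta
distribution of its local abundance, with `N` reads per sample, detection
limit `d = 1/N`, and migration parameter `m`. The mixture extension fits

```
F_mix(i) = mix * F(p_holo_i; m_holo) + (1 - mix) * F(p_env_i; m_env)
```

by bounded multi-start non-linear least squares, and reports the
mixture-weighted parameters `mix * m_holo` and `(1 - mix) * m_env` and
their ratio — the summary used to compare source contributions across pH
regimes. The package also provides the directly computed community
metrics (rarefaction to even depth, plug-in Shannon diversity, phylum
aggregation, unclamped Morisita dissimilarity matrices for external
ordination) and seeded generators that make every estimator checkable by
parameter recovery. It is aimed at microbial ecologists analysing paired
host-associated/environmental community tables from standardized
settlement units (ARMS) or comparable designs.

## Worked example

Simulate 60 holobiont-community samples from a known two-source mixture
and refit it:

```r
library(msncm)

meta_holo <- simulate_metacommunity(500, seed = 1)
meta_env  <- simulate_metacommunity(500, seed = 2)
tbl <- simulate_mixture_table(meta_holo, meta_env, n_samples = 60,
                              N = 10000, m_holo = 0.3, m_env = 0.1,
                              mix = 0.6, seed = 3)
fit <- fit_msncm(tbl, meta_holo, meta_env, N = 10000)
fit
#> <msncm_fit> m_holo = 0.2971, m_env = 0.1035, mix = 0.591, R^2 = 0.928
#>   weighted: m_holo = 0.1757, m_env = 0.04228, ratio = 4.154
```

The generating values were `m_holo = 0.3`, `m_env = 0.1`, `mix = 0.6`
(mixture-weighted: 0.18 and 0.04), all recovered within a few percent;
`R^2 = 0.928` says the neutral mixture explains most of the variation in
occurrence frequencies. `weighted_report(fit)` returns the same summary as
a data frame with the ratio also rounded to two decimals, the convention
of published model-comparison tables.

Distinctness inference on a simulated 18-ARMS study (2 localities × 3 pH
levels × 3 units, true slope −5 points per pH step):

```r
sc <- simulate_distinctness_scenario(seed = 4)
dm <- fit_distinctness_model(sc$records, "community")
#> slope -7.29, CI [-8.95, -5.63], LRT p < 1e-4
```

The slope is percentage points of distinctness per ordinal pH step
(control = 0, medium = 1, low = 2); a negative slope means holobiont
community microbiomes become less distinct from sediment as pH drops.

## Analysis workflow

The `analysis/` scripts run the pipeline end to end on a synthetic study
and validate the estimators; each writes tables under `results/`:

1. `01_simulate_study.R` — generates the 18-ARMS paired-fraction study
   (partially disjoint holobiont/sediment metacommunities, mixture share
   of the holobiont source declining with pH).
2. `02_run_pipeline.R` — `run_pipeline()` over that study: distinctness
   records + mixed model, one MSNCM fit per pH regime, Shannon and
   Morisita outputs.
3. `03_parameter_recovery.R` — replicated simulate-and-refit for both
   neutral models.
4. `04_inference_calibration.R` — size and coverage of the distinctness
   inference at the study design.

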