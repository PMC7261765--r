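# ebmseq

Event-based modelling of biomarker progression from cross-sectional data.

## The problem

In progressive neurological diseases such as amyotrophic lateral sclerosis,
longitudinal imaging is hard to collect — fast progression, attrition, and
non-random missingness bias any longitudinal analysis. An **event-based model
(EBM)** extracts temporal information from a *single cross-sectional* table
instead: it treats the disease as a fixed sequence of *events*, each the
transition of one biomarker from a healthy to a diseased distribution, and
infers the most likely event ordering, its uncertainty, and a per-subject
disease stage, directly from patient/control data.

`ebmseq` implements this pipeline for tabular biomarker panels — one row per
subject, one numeric column per marker — with first-class support for regional
white-matter fractional anisotropy (FA) from diffusion MRI, including the
canonical 11-region (hemispheres combined) and 19-region (hemispheres split)
white-matter sets with corticospinal-tract segment boundaries as metadata.

## The model

For biomarker $i$ and subject $j$, two-component Gaussian mixtures supply the
event densities $P(x_{ij}\mid E_i)$ and $P(x_{ij}\mid \neg E_i)$. The healthy
component is constrained to the 95% confidence box of a control-only Gaussian
fit (projected EM); fits are robustified by refitting on 1000 bootstrap
resamples, dropping replicates whose mixing proportion collapsed to 0 or 1,
and taking the median of the rest. The likelihood of an ordering $S$
marginalizes a uniform stage prior per patient:

$$P(X\mid S)=\prod_j \frac{1}{N+1}\sum_{k=0}^{N}\prod_{i\le k}P(x_{s(i)j}\mid E)\prod_{i>k}P(x_{s(i)j}\mid \neg E)$$

A Metropolis chain over permutations (swap proposal, uniform prior, greedy
initialization) samples $P(S\mid X)$ on patient data only; uncertainty is
displayed as a grayscale **positional variance diagram** (PVD). Bootstrap
cross-validation (10,000 replicates, direct mixture refits under weak
constraints) gives a deliberately more conservative PVD. Finally every subject
gets a maximum-likelihood stage, and a stage-threshold rule yields
sensitivity/specificity.

A synthetic-cohort generator with known ground truth (`simulate_cohort()`)
makes the whole pipeline testable by parameter recovery.

## A worked example

```r
library(ebmseq)

co  <- simulate_cohort(n_patients = 150, n_controls = 130, seed = 7)
run <- run_ebm_pipeline(co$data, out_dir = "ebm-run",
                        mixture_B = 200, n_iter = 20000, burn_in = 2000,
                        cv_B = 100, seed = 7)
run
#> Event-based model run (ebm-run)
#> MAP ordering: CST_inf > CST_mid > CST_sup > CC_genu > CC_body > CC_splenium > Cingulum > ILF > SLF > IFOF > UF
#> Sensitivity 0.893 / specificity 0.862 at stage cut-off 1

kendall_distance(run$posterior$map, co$ordering)
#> [1] 0.01818182
```

The MAP ordering is the inferred event sequence — here the simulated disease
affects the corticospinal tract first, the corpus callosum next, association
fibres last, and the inference recovers the generator's ground truth up to
one adjacent swap among the weakly-ordered association fibres (normalized
Kendall distance 0.018, i.e. 1 discordant pair of 55). The
sensitivity/specificity line is the stage-1 cutoff rule: subjects staged 0
are called healthy, stage ≥ 1 diseased; at the generator's default 2.5-SD
separation the groups overlap, so the rule is imperfect by construction. The run directory
contains the fitted mixtures, the MCMC and cross-validation PVD matrices
(CSV), per-subject stages, stage proportions and a JSON manifest that
reproduces the run bit-for-bit; `render_ebm_reports("ebm-run")` draws the
grayscale PVD heatmaps and the per-group stage-proportion bar chart, and
`autoplot()` / `tidy()` / `glance()` methods cover the intermediate objects.

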