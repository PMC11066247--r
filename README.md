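# afpheno — autofluorescence stress phenotyping

`afpheno` quantifies drought stress in plants from top-view autofluorescence
image sequences, the kind produced daily by high-throughput phenotyping (HTPP)
conveyor platforms. Healthy leaf tissue is dominated by red chlorophyll
fluorescence; as drought kills tissue and depletes chlorophyll, the emission
of other metabolites becomes visible and the affected pixels change colour.
The package turns that contrast into per-plant, per-day stress numbers that
can separate drought-tolerant from drought-susceptible genotypes.

It is aimed at plant-phenomics researchers who have (or can simulate) a
manifest of plant images across days after germination (DAG) and want
reproducible stress trajectories per genotype.

## The method

For plant *i* on day *j*, a pixel-level classifier **C** maps the fluorescence
image to a binary stress image,

    C : I[i,j](x, y)  →  Is[i,j](x, y) ∈ {0, 1},

where 1 marks stressed (browned, chlorophyll-depleted) and 0 marks healthy
tissue, evaluated only inside the segmented plant region. The pipeline is:

1. **Segmentation** — colour-threshold extraction of the plant region with
   age-dependent channel selection (HSV bounds for small pale seedlings, red
   dominance for grown plants), then morphological opening and 8-connected
   small-component removal.
2. **Ground truth** — elliptical patches placed on visually healthy and dried
   leaf regions; every patch pixel inside the plant mask contributes one
   labelled (r, g, b) row to the ground-truth set G = V_normal ∪ V_stress.
3. **Classifier comparison** — six families (bagged-trees ensemble, 25-unit
   neural network, quadratic-kernel SVM, ≤ 20-split decision tree, logistic
   regression, Gaussian naive Bayes) trained on a stratified 60/20/20
   train/validation/test split; the family with the best test accuracy
   becomes C.
4. **Phenotypes** — per plant and day,

       average percentage stress = 100 · |stressed plant pixels| / |plant pixels|,

   and its *moving average* over the n most recent imaging days (default
   n = 3). Genotype values are replicate means ± standard error; genotypes are
   compared per day with Welch's two-sample t-test.

A seeded synthetic-image generator renders rosette plants on a soil/pot
background with separable stressed/non-stressed pixel populations and
multi-genotype drought time series (a plateauing tolerant genotype versus
continuously increasing susceptible ones), with per-pixel truth masks — so the
whole pipeline can be validated without camera hardware.

## Worked example

```r
library(afpheno)

cfg <- default_pipeline_config()   # 3 genotypes x 6 replicates x days 5..30
cfg$seed <- 1

ds  <- simulate_dataset(cfg, out_dir = "experiment")
res <- run_pipeline(ds$manifest, root = "experiment", config = cfg,
                    out_dir = "experiment/out", truth = ds$truth)

tidy(res$bundle)
dplyr::filter(res$summary, dag == 30)
autoplot(res$phenotypes)
```

`tidy(res$bundle)` prints the classifier comparison (all six families separate
the synthetic pixel classes essentially perfectly; the tie resolves to the
bagged-trees ensemble):

```
  family                validation_accuracy test_accuracy selected
1 ensemble_bagged_trees                   1             1 TRUE
2 neural_network                          1             1 FALSE
3 svm_quadratic                           1             1 FALSE
4 decision_tree                           1             1 FALSE
5 logistic_regression                     1             1 FALSE
6 naive_bayes                             1             1 FALSE
```

and the day-30 genotype summary shows the drought-tolerant genotype (R500)
plateauing near 15 % stressed tissue while the susceptible genotypes keep
climbing — the separation is significant from the early twenties DAG onward
(Welch p < 1e-5 in `res$comparisons`):

```
  genotype   dag  mean stderr n_replicates
1 CC          30  48.8  0.718            6
2 R500        30  15.4  0.545            6
3 VT          30  53.0  0.454            6
```

Numbers are means ± SE of `average percentage stress` over 6 replicate
plants. `experiment/out/` holds `accuracy_report.csv`, `phenotypes.csv`,
`genotype_summary.csv`, `comparisons.csv` and `run.json`.

A thin command-line interface wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/afpheno.R", package="afpheno"))')" \
    simulate --seed 1 --out experiment
```

with subcommands `simulate`, `segment`, `ground-truth`, `train`, `classify`,
`phenotype`, `compare` and `run`.

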