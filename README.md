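# spvs — sensor-failure-tolerant classification for e-nose arrays

Electronic noses assess food quality from an array of gas sensors (here 11
MQ-series metal-oxide channels) by classifying each time-stamped reading
into an ordinal quality label: 1 excellent, 2 good, 3 acceptable,
4 spoiled. Sensors drift and fail in deployment, and a classifier trained
on the joint feature vector has no good answer to a missing channel.

This package implements a **single plurality voting system (SPVS)**: one
univariate base classifier per sensor; a test sample is labelled by the
plurality of votes

```
ŷ(x, a) = argmax_c Σ_{j: a_j = 1} 1[ h_j(x_j) = c ]
```

over exactly the sensors `j` whose availability bit `a_j` is set. Failed
sensors are skipped, never imputed, so losing channels only shrinks the
electorate. Three base families are implemented from scratch behind one
train/predict contract — k-nearest neighbours (Euclidean / Manhattan /
Minkowski / cosine distances), CART-style Gini decision trees, and LDA with
Bayes-rule classification — along with the joint-classifier baseline,
seeded sensor-failure simulation (the ten-tier 10% × 0–9 failures and
five-tier 20% × 0–4 mixtures), stratified 5-fold cross-validated evaluation
(CA, macro sensitivity, macro specificity), CSV I/O with configurable
column mapping, and a seeded synthetic e-nose generator so everything is
benchmarkable without external data.

## Worked example

```r
library(spvs)

# a synthetic spoilage run: 2200 minutes, 11 sensors, 9 of them informative
frame <- generate_enose(preset_benchmark("redundant_informative"), seed = 1)

# the full benchmark: 3 families x {single, SPVS} x {clean, ten-tier failures}
report <- run_experiment(frame, families = c("knn", "lda", "tree"),
                         k = 5, profile = ten_tier_profile(), seed = 7)
print(report)
```

```
SPVS benchmark: 5 folds, seed 7, imputation 'mean', macro averaging
Base   Method                  CA   Sens   Spec
knn    Single CL           1.0000 1.0000 1.0000
knn    Missing:Single CL   0.6895 0.6895 0.8965
knn    SPVS                0.9959 0.9959 0.9986
knn    Missing:SPVS        0.9400 0.9400 0.9800
lda    Single CL           1.0000 1.0000 1.0000
lda    Missing:Single CL   0.7023 0.7023 0.9008
lda    SPVS                0.9995 0.9995 0.9998
lda    Missing:SPVS        0.9618 0.9618 0.9873
tree   Single CL           0.9832 0.9832 0.9944
tree   Missing:Single CL   0.6609 0.6609 0.8870
tree   SPVS                0.9964 0.9964 0.9988
tree   Missing:SPVS        0.9382 0.9382 0.9794
```

Reading the table: on clean data the joint classifiers are at or near
ceiling on this easy synthetic benchmark. Under the ten-tier failure
mixture (on average 4.5 of 11 sensors lost per sample) they collapse by
30–32 accuracy points despite mean imputation, while the voting ensembles
lose only 4–6 points — the failure tolerance the method exists for.
Sensitivity equals CA here because the synthetic classes are exactly
balanced.

Single samples work the same way:

```r
model <- spvs_fit(frame, family = "tree")
x <- frame$features[1500, ]
available <- rep(c(TRUE, FALSE), c(6, 5))   # five failed sensors
spvs_predict(model, x, available)
#> $label      [1] 3
#> $votes      [1] 0 0 6 0
#> $n_votes    [1] 6
```

A thin command-line wrapper (`inst/cli/spvs-cli.R`) exposes `generate`,
`train`, `predict` and `evaluate` for shell pipelines; models round-trip
through versioned JSON archives (`spvs_save()` / `spvs_load()`). Real
datasets are read with `read_sensor_csv()`, whose `sensor_mapping()` binds
arbitrary CSV headers to the 11-sensor schema.

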