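# brute-force per-class confusion-cell oracle
metrics_oracle <- function(cm) {
  C <- nrow(cm)
  total <- sum(cm)
  sens <- spec <- numeric(0)
  for (c in seq_len(C)) {
    tp <- cm[c, c]
    fn <- sum(cm[c, -c])
    fp <- sum(cm[-c, c])
    tn <- total - tp - fn - fp
    if (tp + fn > 0) {  # class present in the truth
      sens <- c(sens, tp / (tp + fn))
      spec <- c(spec, tn / (tn + fp))
    }
  }
  c(ca = sum(diag(cm)) / total, sensitivity = mean(sens),
    specificity = mean(spec))
}

test_that("kfold_split partitions the data into near-equal stratified folds", {
  fr <- sensor_frame(matrix(seq_len(20) / 3, 10, 2), rep(1:2, 5))
  folds <- kfold_split(fr, 5, seed = 2)
  tests <- lapply(folds, `[[`, "test")
  expect_identical(lengths(tests), rep(2L, 5))
  expect_identical(sort(unlist(tests)), 1:10)
  for (f in folds) {
    expect_identical(sort(c(f$train, f$test)), 1:10)
    expect_length(intersect(f$train, f$test), 0)
  }

  # stratification: fold class counts differ by at most one per class,
  # and overall fold sizes by at most one
  fr2 <- random_frame(n = 103, d = 2, n_classes = 4, seed = 3)
  folds2 <- kfold_split(fr2, 5, seed = 4)
  sizes <- lengths(lapply(folds2, `[[`, "test"))
  expect_lte(diff(range(sizes)), 1)
  for (c in 1:4) {
    per_fold <- vapply(folds2, function(f) sum(fr2$labels[f$test] == c),
                       integer(1))
    expect_lte(diff(range(per_fold)), 1)
  }

  expect_identical(kfold_split(fr, 5, seed = 2), folds)  # same seed
  expect_false(identical(kfold_split(fr, 5, seed = 3), folds))
  expect_error(kfold_split(fr, 1), class = "spvs_config_error")
})

test_that("a class rarer than k falls back to unstratified folds", {
  labels <- c(rep(1L, 20), 2L, 2L)
  fr <- sensor_frame(matrix(rnorm(44), 22, 2), labels)
  expect_warning(folds <- kfold_split(fr, 5, seed = 1), "fewer samples")
  expect_identical(sort(unlist(lapply(folds, `[[`, "test"))), 1:22)
})

test_that("compute_metrics reproduces closed forms and the cell oracle", {
  perfect <- diag(c(5L, 3L, 7L, 2L))
  expect_equal(compute_metrics(perfect),
               c(ca = 1, sensitivity = 1, specificity = 1))

  # everything predicted class 1, balanced truth over 4 classes
  all1 <- matrix(0L, 4, 4)
  all1[, 1] <- 10L
  m <- compute_metrics(all1)
  expect_equal(m[["ca"]], 0.25)
  expect_equal(m[["sensitivity"]], 0.25)
  expect_equal(m[["specificity"]], 0.75)

  expect_error(compute_metrics(matrix(0L, 4, 4)), class = "spvs_empty_input")

  withr::with_seed(111, {
    for (rep in 1:300) {
      cm <- matrix(rpois(16, 3), 4, 4)
      if (sum(cm) == 0) next
      expect_equal(compute_metrics(cm), metrics_oracle(cm))
    }
  })
})

test_that("micro averaging pools the per-class counts", {
  cm <- matrix(c(8L, 2L, 1L, 9L), 2, 2, byrow = TRUE)
  micro <- compute_metrics(cm, averaging = "micro")
  expect_equal(micro[["sensitivity"]], (8 + 9) / 20)
  expect_equal(micro[["specificity"]], (9 + 8) / 20)
})

test_that("confusion_matrix counts truth rows against prediction columns", {
  cm <- confusion_matrix(c(1, 1, 2, 3), c(1, 2, 2, 3), 4)
  expect_identical(sum(cm), 4L)
  expect_identical(cm[1, 2], 1L)
  expect_identical(cm[2, 2], 1L)
  expect_identical(cm[4, 4], 0L)
})

test_that("single-classifier evaluation imputes only failed cells", {
  fr <- gaussian_frame(n_per_class = 40, d = 3, n_classes = 3, seed = 121)
  test <- gaussian_frame(n_per_class = 15, d = 3, n_classes = 3, seed = 122)

  cm_clean <- evaluate_single(fr, test, NULL, "lda")
  expect_identical(sum(cm_clean), 45L)
  expect_gt(compute_metrics(cm_clean)[["ca"]], 0.9)

  masks <- matrix(TRUE, 45, 3)
  masks[1:20, 1] <- FALSE
  cm_mean <- evaluate_single(fr, test, masks, "lda", imputation = "mean")
  cm_zero <- evaluate_single(fr, test, masks, "lda", imputation = "zero")
  cm_skip <- evaluate_single(fr, test, masks, "lda", imputation = "skip")
  expect_identical(sum(cm_skip), 25L)  # listwise skip drops 20 rows
  expect_identical(sum(cm_mean), 45L)
  expect_false(identical(cm_mean, cm_zero))
})

test_that("clean-mask evaluation equals the explicit no-failure profile", {
  fr <- random_frame(n = 120, d = 4, n_classes = 3, seed = 123)
  folds <- kfold_split(fr, 4, seed = 5)
  tr <- frame_rows(fr, folds[[1]]$train)
  te <- frame_rows(fr, folds[[1]]$test)
  none <- generate_masks(nrow(te$features), 4, failure_profile(1, 0), 1)
  expect_identical(evaluate_spvs(tr, te, NULL, "tree"),
                   evaluate_spvs(tr, te, none$mask, "tree"))
})

test_that("run_experiment covers the requested grid deterministically", {
  fr <- generate_enose(synthetic_config(n_samples = 300), seed = 9)
  rep1 <- run_experiment(fr, families = "tree", k = 5, seed = 17)
  expect_identical(nrow(as.data.frame(rep1)), 4L * 5L)
  expect_setequal(unique(rep1$condition), c("clean", "missing"))
  expect_setequal(unique(rep1$method), c("single", "spvs"))
  expect_true(all(rep1$ca >= 0 & rep1$ca <= 1))

  s <- summary(rep1)
  expect_identical(nrow(s), 4L)
  # summary means equal the arithmetic fold means
  for (i in seq_len(nrow(s))) {
    sel <- rep1$family == s$family[i] & rep1$method == s$method[i] &
      rep1$condition == s$condition[i]
    expect_equal(s$ca[i], mean(rep1$ca[sel]), tolerance = 1e-12)
  }

  rep2 <- run_experiment(fr, families = "tree", k = 5, seed = 17)
  expect_identical(as.data.frame(rep1), as.data.frame(rep2))
})

test_that("reports round-trip through the report files", {
  fr <- generate_enose(synthetic_config(n_samples = 200), seed = 10)
  rep <- run_experiment(fr, families = "lda", k = 4, seed = 3)
  dir <- withr::local_tempdir()
  write_report(rep, dir)
  expect_true(all(file.exists(file.path(dir, c("report_folds.csv",
                                               "report_mean.csv",
                                               "report.txt",
                                               "run_config.txt")))))
  folds_back <- read.csv(file.path(dir, "report_folds.csv"))
  expect_equal(folds_back$ca, rep$ca)
  mean_back <- read.csv(file.path(dir, "report_mean.csv"))
  expect_equal(mean_back$ca, summary(rep)$ca)
})
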