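# independent counting oracle for plurality voting
vote_oracle <- function(votes, n_classes, tie = "smallest") {
  tab <- table(factor(votes, levels = seq_len(n_classes)))
  winners <- as.integer(names(tab)[tab == max(tab)])
  if (tie == "smallest") min(winners) else max(winners)
}

test_that("plurality_vote matches the exhaustive counting oracle", {
  expect_identical(plurality_vote(c(3, 3, 1)), 3L)
  expect_identical(plurality_vote(c(1, 2, 1, 2)), 1L)
  expect_identical(plurality_vote(c(1, 2, 1, 2), tie = "largest"), 2L)
  expect_error(plurality_vote(integer()), class = "spvs_empty_input")

  # all vote multisets of length <= 6 over 4 labels
  for (len in 1:6) {
    grid <- as.matrix(expand.grid(rep(list(1:4), len)))
    got <- apply(grid, 1L, plurality_vote, n_classes = 4L)
    want <- apply(grid, 1L, vote_oracle, n_classes = 4L)
    expect_identical(got, want)
  }
})

test_that("spvs_fit builds one univariate model per sensor", {
  fr <- random_frame(n = 60, d = 5, seed = 71)
  m <- spvs_fit(fr, "tree")
  expect_identical(length(m$models), 5L)
  for (bm in m$models) expect_identical(length(bm$sensor_names), 1L)
  expect_identical(m$majority_label,
                   which.max(tabulate(fr$labels, fr$n_classes)))

  masked <- fr
  masked$mask[3, 2] <- FALSE
  expect_error(spvs_fit(masked, "tree"), class = "spvs_masked_training")
})

test_that("a one-sensor ensemble degenerates to its base classifier", {
  fr <- random_frame(n = 50, d = 1, seed = 72)
  test_x <- matrix(withr::with_seed(73, rnorm(30, mean = 3, sd = 2)), ncol = 1)
  for (family in c("knn", "tree", "lda")) {
    ens <- spvs_fit(fr, family)
    base <- switch(family, knn = knn_fit(fr, sensors = 1),
                   tree = tree_fit(fr, sensors = 1),
                   lda = lda_fit(fr, sensors = 1))
    expect_identical(spvs_predict(ens, test_x)$label, predict(base, test_x),
                     info = family)
  }
})

test_that("spvs_predict tallies exactly the available sensors' votes", {
  fr <- random_frame(n = 80, d = 6, n_classes = 4, seed = 74)
  m <- spvs_fit(fr, "tree")
  # per-sensor predictions, computed independently
  q <- withr::with_seed(75, matrix(rnorm(40 * 6, mean = 6, sd = 4), 40, 6))
  per_sensor <- vapply(1:6, function(j)
    predict(m$models[[j]], q[, j, drop = FALSE]), integer(40))

  withr::with_seed(76, {
    for (rep in 1:25) {
      avail <- matrix(runif(40 * 6) > 0.4, 40, 6)
      avail[rowSums(avail) == 0, 1] <- TRUE  # keep at least one sensor
      res <- spvs_predict(m, q, avail)
      expect_identical(res$n_votes, rowSums(avail))
      for (i in 1:40) {
        expect_identical(res$label[i],
                         vote_oracle(per_sensor[i, avail[i, ]], 4L))
        expect_equal(sum(res[i, paste0("votes_", 1:4)]), sum(avail[i, ]))
      }
    }
  })
})

test_that("failed sensors' classifiers are never invoked", {
  fr <- random_frame(n = 40, d = 3, seed = 77)
  m <- spvs_fit(fr, "tree")
  q <- fr$features[1:10, ]
  q[, 2] <- NaN  # poison the failed channel
  avail <- cbind(TRUE, FALSE, TRUE)[rep(1, 10), ]
  res <- spvs_predict(m, q, avail)
  expect_false(anyNA(res$label))
  expect_identical(res$n_votes, rep(2, 10))
})

test_that("sensor order permutation never changes the prediction", {
  fr <- random_frame(n = 60, d = 5, seed = 78)
  m <- spvs_fit(fr, "lda")
  q <- withr::with_seed(79, matrix(rnorm(10 * 5, 5, 3), 10, 5))
  avail <- withr::with_seed(80, matrix(runif(50) > 0.3, 10, 5))
  avail[rowSums(avail) == 0, 1] <- TRUE
  base <- spvs_predict(m, q, avail)$label
  perm <- c(4, 1, 5, 3, 2)
  fr_p <- sensor_frame(fr$features[, perm], fr$labels,
                       sensor_names = fr$sensor_names[perm],
                       n_classes = fr$n_classes)
  m_p <- spvs_fit(fr_p, "lda")
  expect_identical(spvs_predict(m_p, q[, perm], avail[, perm])$label, base)
})

test_that("the all-sensors-failed fallback follows the configured policy", {
  fr <- random_frame(n = 30, d = 2, seed = 81)
  q <- fr$features[1:3, ]
  none <- matrix(FALSE, 3, 2)
  m_err <- spvs_fit(fr, "tree")
  expect_error(spvs_predict(m_err, q, none), class = "spvs_all_failed")
  m_fb <- spvs_fit(fr, "tree", fallback = "majority")
  res <- spvs_predict(m_fb, q, none)
  expect_true(all(res$fallback))
  expect_true(all(res$label == m_fb$majority_label))
  expect_true(all(res$n_votes == 0))
})

test_that("probability-weighted voting is available behind a flag", {
  fr <- gaussian_frame(n_per_class = 30, d = 4, n_classes = 3, seed = 82)
  m <- spvs_fit(fr, "lda")
  q <- fr$features[c(1, 40, 75), ]
  hard <- spvs_predict(m, q)
  soft <- spvs_predict(m, q, vote_type = "prob")
  expect_identical(hard$label, soft$label)  # easy points: both agree
  expect_equal(rowSums(as.matrix(soft[paste0("votes_", 1:3)])), rep(4, 3),
               tolerance = 1e-9)  # prob votes sum to the sensors cast
})

test_that("a saved model archive round-trips predictions exactly", {
  fr <- random_frame(n = 50, d = 4, n_classes = 4, seed = 83)
  q <- withr::with_seed(84, matrix(rnorm(25 * 4, 5, 3), 25, 4))
  avail <- withr::with_seed(85, matrix(runif(100) > 0.3, 25, 4))
  avail[rowSums(avail) == 0, 1] <- TRUE
  for (family in c("knn", "tree", "lda")) {
    m <- spvs_fit(fr, family)
    path <- withr::local_tempfile(fileext = ".json")
    spvs_save(m, path)
    m2 <- spvs_load(path)
    expect_identical(spvs_predict(m2, q, avail), spvs_predict(m, q, avail),
                     info = family)
  }
})
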