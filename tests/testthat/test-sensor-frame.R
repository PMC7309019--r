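test_that("sensor_frame enforces its invariants", {
  x <- matrix(1:6 / 2, 3, 2)
  fr <- sensor_frame(x, c(1, 2, 4), sensor_names = c("a", "b"))
  expect_s3_class(fr, "sensor_frame")
  expect_identical(dim(fr), c(3L, 2L))
  expect_identical(fr$n_classes, 4L)
  expect_true(all(fr$mask))

  expect_error(sensor_frame(x, 1:2), class = "spvs_invalid_frame")
  expect_error(sensor_frame(x, c(1, 2, 0)), class = "spvs_invalid_frame")
  expect_error(sensor_frame(x, 1:3, sensor_names = c("a", "a")),
               class = "spvs_invalid_frame")
  expect_error(sensor_frame(x, 1:3, mask = matrix(TRUE, 2, 2)),
               class = "spvs_invalid_frame")
  expect_error(sensor_frame(x, c(1, 2, 5), n_classes = 4),
               class = "spvs_invalid_frame")
})

test_that("read_sensor_csv parses a clean file and masks bad cells", {
  path <- withr::local_tempfile(fileext = ".csv")
  sensors <- mq_sensor_names()
  df <- as.data.frame(matrix(round(rnorm(33), 3), 3, 11,
                             dimnames = list(NULL, sensors)))
  df$label <- c(1L, 2L, 4L)
  write.csv(df, path, row.names = FALSE)

  fr <- read_sensor_csv(path)
  expect_identical(dim(fr), c(3L, 11L))
  expect_true(all(fr$mask))
  expect_identical(fr$labels, c(1L, 2L, 4L))
  expect_equal(fr$features[2, "MQ3"], df$MQ3[2], ignore_attr = TRUE)

  # blank a single cell -> exactly one masked entry, with a warning
  lines <- readLines(path)
  fields <- strsplit(lines[3], ",")[[1]]
  fields[5] <- ""
  lines[3] <- paste(fields, collapse = ",")
  writeLines(lines, path)
  expect_warning(fr2 <- read_sensor_csv(path), "masked 1")
  expect_identical(sum(!fr2$mask), 1L)
  expect_false(fr2$mask[2, 5])
  expect_equal(fr2$features[-2, ], fr$features[-2, ], ignore_attr = TRUE)
})

test_that("read_sensor_csv rejects bad configurations", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1, b = 2), path, row.names = FALSE)
  expect_error(read_sensor_csv(path, sensor_mapping(c("a", "b"), label = "quality")),
               class = "spvs_config_error")
  expect_error(read_sensor_csv(path, sensor_mapping(c("x", "y"), label = "a")),
               class = "spvs_config_error")
  expect_error(read_sensor_csv(withr::local_tempfile(fileext = ".csv")),
               class = "spvs_io_error")
})

test_that("write/read round-trips features, labels and mask", {
  fr <- random_frame(n = 25, d = 4, seed = 11)
  fr$mask[cbind(c(3, 9, 20), c(1, 4, 2))] <- FALSE
  path <- withr::local_tempfile(fileext = ".csv")
  write_sensor_csv(fr, path, sensor_mapping(fr$sensor_names))
  expect_warning(back <- read_sensor_csv(path, sensor_mapping(fr$sensor_names)),
                 "masked 3")
  expect_identical(back$labels, fr$labels)
  expect_identical(back$mask, fr$mask)
  expect_equal(back$features[back$mask], fr$features[fr$mask],
               tolerance = 1e-12)

  # masked cells appear as empty fields in the file
  expect_match(readLines(path)[4], "^,")

  # degenerate n = 0 frame -> header-only file
  empty <- sensor_frame(matrix(numeric(), 0, 2), integer(),
                        sensor_names = c("a", "b"), n_classes = 4)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_sensor_csv(empty, p2, sensor_mapping(c("a", "b")))
  expect_identical(length(readLines(p2)), 1L)
})
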