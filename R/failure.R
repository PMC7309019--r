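#' Specify a sensor-failure mixture for a test set
#'
#' A failure profile is an ordered list of tiers, each a fraction of the
#' test samples and the number of sensors that fail for samples in that
#' tier. Which samples land in which tier and which sensors fail are drawn
#' from a seeded RNG by [generate_masks()].
#'
#' @param fractions Numeric vector of tier fractions, summing to 1.
#' @param counts Integer vector of failed-sensor counts, same length.
#' @param assignment `"random"` (default; samples are randomly interleaved
#'   across tiers) or `"contiguous"` (tier blocks in row order, for
#'   debugging).
#' @return An object of class `failure_profile`.
#' @export
failure_profile <- function(fractions, counts,
                            assignment = c("random", "contiguous")) {
  assignment <- match.arg(assignment)
  stopifnot(length(fractions) == length(counts), length(fractions) >= 1L)
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9)
    spvs_stop("tier fractions must be non-negative and sum to 1",
              "spvs_config_error")
  counts <- as.integer(counts)
  if (any(counts < 0))
    spvs_stop("failure counts must be non-negative", "spvs_config_error")
  structure(list(fractions = fractions, counts = counts,
                 assignment = assignment),
            class = "failure_profile")
}

#' The ten-tier failure mixture (10% of samples at each count 0-9)
#'
#' The default benchmark condition: one tenth of the test samples have no
#' failed sensor, one tenth one failed sensor, and so on up to nine failed
#' sensors.
#'
#' @param assignment Passed to [failure_profile()].
#' @return A [failure_profile()].
#' @export
ten_tier_profile <- function(assignment = "random") {
  failure_profile(rep(0.1, 10L), 0:9, assignment)
}

#' The five-tier failure mixture (20% of samples at each count 0-4)
#'
#' @param assignment Passed to [failure_profile()].
#' @return A [failure_profile()].
#' @export
five_tier_profile <- function(assignment = "random") {
  failure_profile(rep(0.2, 5L), 0:4, assignment)
}

#' Generate per-sample sensor-availability masks from a failure profile
#'
#' Tier sizes are `fraction * n` rounded by the largest-remainder method so
#' they sum exactly to `n`; the assignment of samples to tiers and the
#' identity of the failed sensors are drawn from R's Mersenne-Twister RNG
#' seeded with `seed`, so masks are a pure function of
#' `(n, d, profile, seed)`.
#'
#' @param n Number of samples.
#' @param d Number of sensors.
#' @param profile A [failure_profile()]; every count must be `<= d`.
#' @param seed Integer RNG seed.
#' @return A list with `mask` (logical `n x d`, `TRUE` = available) and
#'   `n_failed` (integer vector of per-sample failure counts).
#' @export
#' @examples
#' m <- generate_masks(100, 11, ten_tier_profile(), seed = 1)
#' table(m$n_failed)  # exactly 10 samples at each count 0..9
generate_masks <- function(n, d, profile, seed) {
  stopifnot(inherits(profile, "failure_profile"))
  n <- as.integer(n); d <- as.integer(d)
  if (any(profile$counts > d))
    spvs_stop(sprintf("failure count %d exceeds d = %d",
                      max(profile$counts), d), "spvs_config_error")
  sizes <- largest_remainder(profile$fractions, n)
  tier_of_sorted <- rep.int(seq_along(sizes), sizes)
  withr::with_seed(seed, {
    tier_of <- if (profile$assignment == "random") {
      sample(tier_of_sorted)
    } else tier_of_sorted
    n_failed <- profile$counts[tier_of]
    mask <- matrix(TRUE, n, d)
    for (i in seq_len(n)) {
      if (n_failed[i] > 0L) mask[i, sample.int(d, n_failed[i])] <- FALSE
    }
  })
  list(mask = mask, n_failed = n_failed)
}

# internal: integer tier sizes summing exactly to n (largest remainder;
# remainder ties go to the earliest tier)
largest_remainder <- function(fractions, n) {
  exact <- fractions * n
  base <- floor(exact)
  shortfall <- n - sum(base)
  if (shortfall > 0L) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(shortfall)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}
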