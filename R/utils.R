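#' Derive a component sub-seed from a master seed
#'
#' Hashes a component name together with the master seed so that every
#' randomised stage of a pipeline (fold shuffling, per-fold failure masks,
#' data generation) draws from its own stream. Adding a new named component
#' never perturbs the streams of existing ones.
#'
#' @param seed Master seed, a single integer.
#' @param name Character scalar naming the component.
#' @return A single integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(42, "fold-1")
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name), length(name) == 1L)
  h <- 0
  for (v in utf8ToInt(name)) h <- (h * 131 + v) %% 2147483629
  as.integer((abs(seed) + h) %% 2147483629)
}

# internal: stop() with a classed condition so callers can test error categories
spvs_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "spvs_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
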