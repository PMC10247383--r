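#' Derive a reproducible sub-stream seed from a master seed and a name
#'
#' All stochastic components of the package draw from sub-streams derived
#' deterministically from one master seed and the component's name. Adding a
#' new component (for example, one more taxon) therefore never perturbs the
#' draws of existing components.
#'
#' @param seed master integer seed.
#' @param name character scalar naming the sub-generator.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @keywords internal
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  m <- 2147483647 # 2^31 - 1, keeps arithmetic exact in doubles
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% m
  as.integer((h + (abs(seed) %% m) * 7919) %% (m - 1) + 1)
}

#' Evaluate an expression under a named RNG sub-stream
#'
#' Saves and restores the caller's RNG state so that sub-generators do not
#' interfere with each other or with user code.
#'
#' @inheritParams substream_seed
#' @param expr expression to evaluate.
#' @keywords internal
with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name))
  expr
}
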