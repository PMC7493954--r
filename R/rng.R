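#' Derive a reproducible sub-seed from a master seed and a named key
#'
#' Every stochastic artifact in the package draws from its own RNG stream,
#' seeded by a deterministic hash of the master seed and a short label.
#' Adding a new draw to a pipeline therefore never perturbs existing ones.
#'
#' @param master integer master seed.
#' @param key character label naming the artifact (e.g. "scene/2017").
#' @return an integer seed in [0, 2^31 - 2].
#' @export
derive_seed <- function(master, key) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(key))
  h <- 0
  for (cp in utf8ToInt(paste(key, collapse = "/"))) {
    h <- (h * 131 + cp) %% 2147483647
  }
  as.integer((abs(master) * 2654435761 + h * 40503 + 17) %% 2147483647)
}

# Evaluate `expr` under a local RNG state seeded from (master, key),
# restoring the caller's RNG afterwards.
with_substream <- function(master, key, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(master, key))
  expr
}
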