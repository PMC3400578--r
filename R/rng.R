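#' Derive a child RNG seed from a root seed and a stream label
#'
#' All generators in featherkit consume one root seed and derive independent
#' per-component streams from it, so that e.g. the feather renderer and the
#' cross simulator driven by the same root seed do not share a stream. The
#' derivation is a fixed integer hash of the label mixed with the root seed,
#' reduced modulo 2^31 - 1; it is deterministic across platforms.
#'
#' @param seed integer root seed.
#' @param label character stream label, e.g. "feather", "gene", "cross".
#' @return An integer seed in `[0, 2^31 - 2]`, suitable for [set.seed()].
#' @examples
#' child_seed(1, "feather")
#' @export
child_seed <- function(seed, label) {
  fk_assert(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
            "InvalidSpec", "seed must be a single finite number")
  h <- 0
  for (k in utf8ToInt(as.character(label))) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) %% 1048576 * 2039 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
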