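# Seed plumbing. All randomness in the package flows from one root seed via
# derive_seed(), so adding sampling levels or repeats never perturbs the
# draws of existing ones, and every operation is reproducible in isolation.

#' Derive a deterministic child seed from a root seed and a context key
#'
#' A small string hash (Horner polynomial, base 31, modulo 2^31 - 1) over
#' the root seed and the context components. Platform-independent and
#' stable across sessions; collisions are harmless for this use (they
#' would only correlate two unrelated sampling draws).
#'
#' @param root Integer root seed.
#' @param ... Context components (coerced to character), e.g. a sampling
#'   fraction, repeat index and library ID.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(root, ...) {
  key <- paste(c(format(root, scientific = FALSE),
                 vapply(list(...), function(x) paste(format(x, scientific = FALSE),
                                                     collapse = ","), "")),
               collapse = "|")
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% 2147483647
  as.integer(h + 1)
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.
local_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}
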