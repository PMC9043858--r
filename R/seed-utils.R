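#' Derive a reproducible sub-seed from a master seed
#'
#' Every randomized operation in the package consumes a seed derived
#' deterministically from a master seed and a short string key, so a
#' single master seed reproduces an entire pipeline run while distinct
#' stages draw from independent streams. The derivation is a fixed
#' integer hash: `(master * 69069 + hash(key)) mod (2^31 - 1)`, with
#' `hash` a polynomial rolling hash of the key's characters.
#'
#' @param master integer master seed.
#' @param key character scalar naming the consumer (e.g. `"split"`,
#'   `"run3"`).
#' @return Integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, key) {
  m <- 2147483647 # 2^31 - 1, a prime
  h <- 0
  for (ch in utf8ToInt(as.character(key))) h <- (h * 131 + ch) %% m
  as.integer((abs(as.numeric(master)) %% m * 69069 + h) %% m)
}

# evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller-visible state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
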