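# Reproducibility helpers: one user-facing seed, per-unit substreams derived
# by stable string hashing so each sample/stage can be regenerated in
# isolation without replaying the whole stream.

#' Derive a deterministic substream seed
#'
#' Combines a base seed with a character key (e.g. a sample id) by a stable
#' polynomial string hash, yielding an integer seed below 2^31.
#'
#' @param seed Integer base seed.
#' @param key Character scalar naming the substream.
#' @return Integer seed in [0, 2^31 - 1].
#' @export
substream_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(key), length(key) == 1)
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.numeric(seed) %% m
  for (cp in utf8ToInt(key)) h <- (h * 131 + cp) %% m
  as.integer(h)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
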