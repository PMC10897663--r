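# Unit conversions. Internals work in SI (m, s, Pa, m^3/s); user-facing
# values are mmHg, L/min, cm, mm as customary in the field.

MMHG_PA <- 133.322
LMIN_M3S <- 1 / 60000

mmhg_to_pa <- function(p) p * MMHG_PA
pa_to_mmhg <- function(p) p / MMHG_PA
lmin_to_m3s <- function(q) q * LMIN_M3S
m3s_to_lmin <- function(q) q / LMIN_M3S

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the
#' previous RNG state, so that seeded helpers do not disturb the caller's
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Derive a deterministic sub-stream seed
#'
#' Maps a master seed plus up to three stream indices to a reproducible
#' 31-bit seed, so each sample and acquisition gets its own independent,
#' logged random stream.
#'
#' @param master Master integer seed.
#' @param i,j,k Non-negative stream indices.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
substream_seed <- function(master, i = 0L, j = 0L, k = 0L) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- (abs(as.numeric(master)) %% m)
  for (x in c(i, j, k)) {
    s <- (s * 48271 + as.numeric(x) * 16807 + 12345) %% m
  }
  as.integer(s %% (m - 2) + 1)
}
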