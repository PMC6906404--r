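#' Derive a deterministic child seed
#'
#' All stochastic operations in radcell take explicit integer seeds. Child
#' streams (per stage, per cell, per dose, per copy) are derived from a master
#' seed with a splitmix64-based mixer, so any single stream can be replayed in
#' isolation. The returned value is an integer-valued double below 2^31 and
#' can itself be used as a seed.
#'
#' @param seed master seed (non-negative integer-valued scalar).
#' @param a,b stream labels (integer-valued scalars), e.g. a stage code and a
#'   cell id.
#' @return a non-negative integer-valued double < 2^31.
#' @examples
#' child_seed(1, 2, 3)
#' @export
child_seed <- function(seed, a = 0, b = 0) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed), seed >= 0)
  .cpp_mix_seed(as.double(seed), as.double(a), as.double(b))
}

# stage codes used by the fused damage kernel (kept in one place)
.STAGE_TRACKS <- 0
.STAGE_CLUSTER <- 1
.STAGE_LESIONS <- 2
.STAGE_THIN <- 3

# uniform deviates from the package RNG (used where an R-level operation must
# consume exactly the same stream as the compiled kernels)
.u01 <- function(n, seed) {
  if (n == 0) return(numeric(0))
  .cpp_u01(as.integer(n), as.double(seed))
}
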