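#' @importFrom rlang abort warn .data
#' @importFrom stats as.formula coef lm model.matrix na.omit optimize pchisq
#'   pnorm predict qnorm rbinom rnorm rpois runif sd setNames terms var
#' @importFrom utils head tail
NULL

# round half away from zero (clock and TIB arithmetic; base round() is
# round-half-even, which would make 0.5-minute boundaries direction-dependent)
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# derive a 32-bit sub-seed from a master seed and a stream index, so each
# participant/replicate gets an independent, reproducible stream
sub_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483629)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
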