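#' @keywords internal
#' @importFrom stats predict coef
#' @importFrom utils head tail
"_PACKAGE"

# gravity in m/s^2; trial metadata records the unit so downstream magnitude
# computations stay unit-agnostic
GRAVITY <- 9.81

stop_imbfall <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "imbfall_error")))
}

assert_scalar_pos <- function(x, name, class) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_imbfall(sprintf("`%s` must be a single positive finite number", name),
                 class)
  }
}

# Deterministic child-seed derivation: a fixed affine hash modulo a Mersenne
# prime keeps every derived seed a valid 32-bit integer and makes corpora
# reproducible from a single master seed. Exact in double arithmetic
# (products stay far below 2^53).
derive_seed <- function(master_seed, index) {
  s <- (abs(as.numeric(master_seed)) %% 2147483647) * 1000003 +
    as.numeric(index) * 7919
  as.integer(s %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
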