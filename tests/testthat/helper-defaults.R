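# Reference parameter set used by the figure panels: d_E0 = d_A0 = r_0 = 0.5,
# b = 100, n = 5.
fig_defaults <- function(...) {
  args <- list(...)
  do.call(life_history_params, args)
}

# Hand-evaluated fitness chain at the reference parameters, unconstrained
# allocations (c = 0.5; m = 0.5 where the trait exists). Frozen from an
# independent evaluation of the closed forms:
#   d_A(S1) = 1 - 0.5 exp(-1),   d_E = 0.5 exp(-0.5),  r(S1) = 0.5
#   R(S1) = 0.5 * 100 * (1 - 0.5 exp(-0.5)) = 34.83673...
#   W = R * (1 + sum_{i=0}^{5} i dA (1-dA)^i)
hand_W <- c(S1 = 42.68052, S2 = 59.47400, S3 = 54.63924, S4 = 63.99698)

# random valid parameter set for property-style loops
random_params <- function() {
  life_history_params(
    d_E0 = runif(1), d_A0 = runif(1), r_0 = runif(1),
    b = sample(0:300, 1), n = sample(0:10, 1)
  )
}

clone_with <- function(params, ...) {
  args <- unclass(params)
  new <- list(...)
  args[names(new)] <- new
  do.call(life_history_params, args)
}

set_b <- function(params, b) clone_with(params, b = b)
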