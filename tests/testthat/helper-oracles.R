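# Independent quadratic evaluator used as an oracle against the package's
# prediction path (same term order as quadratic_model, written out by hand).
oracle_quad <- function(b, T, t, C) {
  b[[1]] + b[[2]] * T + b[[3]] * t + b[[4]] * C +
    b[[5]] * T^2 + b[[6]] * t^2 + b[[7]] * C^2 +
    b[[8]] * T * t + b[[9]] * T * C + b[[10]] * t * C
}

# Random 10-term coefficient vector on assorted scales.
random_coefs <- function() {
  stats::rnorm(10) * c(10, 1, 0.1, 0.5, 0.01, 0.001, 0.01, 0.001, 0.001, 0.0005)
}

ref_space <- od_factor_space()
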