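# Shared fixtures: the study-condition phantom and a noise-free variant.
default_spec <- function(...) phantom_spec(...)

noise_free_spec <- function(...) phantom_spec(noise_sd_velocity = 0, ...)

# Brute-force quadratic least squares via explicit normal equations,
# independent of the package's qr-based fit.
normal_equations_parabola <- function(t, y) {
  X <- cbind(1, t, t^2)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(c = beta[1], b = beta[2], a = beta[3])
}
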