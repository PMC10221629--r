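# Shared fixture builders and independent oracles.

# single- or multi-channel recording holding pure sinusoids
sine_recording <- function(freq, fs = 128, duration = 8, amplitude = 1) {
  t <- (0:(fs * duration - 1)) / fs
  data <- do.call(rbind, lapply(seq_along(freq), function(i) {
    amplitude * sin(2 * pi * freq[i] * t)
  }))
  eeg_recording(data, fs)
}

# independent ridge oracle: numerical minimization of the penalized loss
# on already centered/scaled data (never calls the package's solver)
ridge_optim_oracle <- function(X, y, alpha) {
  loss <- function(b) sum((y - X %*% b)^2) + alpha * sum(b^2)
  grad <- function(b) -2 * drop(crossprod(X, y - X %*% b)) + 2 * alpha * b
  optim(rep(0, ncol(X)), loss, grad, method = "BFGS",
        control = list(maxit = 1000, reltol = 1e-14))$par
}

# sessions x channels matrix with two orthogonal latent sources, strongest
# on channels 2 and 5 (population correlations rmain/rside with the source)
planted_two_factor <- function(seed, n = 1000,
                               rmain = c(0.85, 0.80),
                               rside = c(0.55, 0.50)) {
  set.seed(seed)
  mk <- function(r, f) {
    l <- r / sqrt(1 - r^2)
    (l * f + rnorm(n)) / sqrt(1 + l^2)
  }
  f1 <- rnorm(n)
  f2 <- rnorm(n)
  cbind(mk(rside[1], f1), mk(rmain[1], f1), mk(rside[1], f1),
        mk(rside[2], f2), mk(rmain[2], f2), mk(rside[2], f2))
}

# toy design with an exact linear response, for recovery/CV identities
toy_linear_data <- function(n = 20, seed = 42) {
  set.seed(seed)
  tibble::tibble(
    x1 = rnorm(n), x2 = runif(n, -2, 2), x3 = rnorm(n, sd = 2)
  ) |>
    dplyr::mutate(fss = 1.5 + 2 * x1 - 0.5 * x2 + 0.25 * x3)
}
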