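# Independent numerical oracles for the eigen-based solvers.

# brute-force Rayleigh-quotient maximizer over a dense grid of unit vectors
# in 2-D
rayleigh_grid_2d <- function(S, Q) {
  theta <- seq(0, pi, length.out = 200001)
  W <- rbind(cos(theta), sin(theta))
  num <- colSums(W * (S %*% W))
  den <- colSums(W * (Q %*% W))
  W[, which.max(num / den)]
}

# multi-start numerical maximization of the Rayleigh quotient (any dim)
rayleigh_optim <- function(S, Q, n_starts = 20, seed = 1) {
  f <- function(w) -drop(t(w) %*% S %*% w) / drop(t(w) %*% Q %*% w)
  set.seed(seed)
  best <- NULL; bestval <- Inf
  for (s in seq_len(n_starts)) {
    r <- stats::optim(rnorm(nrow(S)), f, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
    if (r$value < bestval) { bestval <- r$value; best <- r$par }
  }
  best / sqrt(sum(best^2))
}

subspace_angle <- function(a, b) acos(min(1, abs(sum(a * b)) /
                                            sqrt(sum(a^2) * sum(b^2))))
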