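test_that("positional encoding follows the sinusoidal definition", {
  pe <- positional_encoding(50, 8)
  expect_equal(pe[1, ], rep(c(0, 1), 4))          # pos 0: sin 0 / cos 0
  expect_equal(pe[2, 1], sin(1))                  # PE(1, 0) = sin(1)
  pe2 <- positional_encoding(50, 32)
  expect_equal(pe2[2, 1], sin(1))
  # all rows pairwise distinct
  expect_equal(nrow(unique(round(pe2, 12))), 50)
  expect_error(positional_encoding(10, 7), "even")
})

test_that("scaled dot-product attention matches hand-computed cases", {
  # singleton key/value: softmax of a single score is 1
  out <- scaled_dot_attention(matrix(rnorm(4), 2, 2),
                              matrix(c(1, 0), 1, 2),
                              matrix(5, 1, 1))
  expect_equal(out$output, matrix(5, 2, 1))
  # identical value rows: convex combination returns that row
  out2 <- scaled_dot_attention(matrix(rnorm(6), 3, 2),
                               matrix(rnorm(8), 4, 2),
                               matrix(rep(c(2, -1), each = 4), 4, 2))
  expect_equal(out2$output,
               matrix(rep(c(2, -1), each = 3), 3, 2), tolerance = 1e-12)
  # 2x2 worked example: scores (1/sqrt(2), 0) -> weight exp(2^-0.5)/(exp(2^-0.5)+1)
  r <- scaled_dot_attention(matrix(c(1, 0), 1, 2),
                            matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE),
                            matrix(c(1, 0), 2, 1))
  w1 <- exp(2^-0.5) / (exp(2^-0.5) + 1)
  expect_equal(r$output[1, 1], w1, tolerance = 1e-6)
  expect_equal(r$output[1, 1], 0.6698, tolerance = 1e-4)
  expect_equal(rowSums(r$weights), 1)
  expect_error(scaled_dot_attention(matrix(0, 1, 2), matrix(0, 2, 3),
                                    matrix(0, 2, 1)), "d_k")
})

test_that("multihead attention collapses to single-head and is equivariant", {
  set.seed(8)
  d <- 6; n <- 5
  X <- matrix(rnorm(n * d), n, d)
  id <- diag(d)
  mh <- multihead_attention(X, 1, list(Wq = id, Wk = id, Wv = id, Wo = id))
  sd1 <- scaled_dot_attention(X, X, X)
  expect_equal(mh$output, sd1$output, tolerance = 1e-12)
  # shape contract for any valid head count
  proj <- list(Wq = matrix(rnorm(d * d), d), Wk = matrix(rnorm(d * d), d),
               Wv = matrix(rnorm(d * d), d), Wo = matrix(rnorm(d * d), d))
  for (h in c(1, 2, 3))
    expect_equal(dim(multihead_attention(X, h, proj)$output), c(n, d))
  # permutation equivariance (no positional encoding involved here)
  perm <- sample(n)
  a <- multihead_attention(X, 2, proj)$output
  b <- multihead_attention(X[perm, ], 2, proj)$output
  expect_equal(b, a[perm, ], tolerance = 1e-12)
})

test_that("spatial fully connected filter behaves like tanh(Wx + b)", {
  x <- matrix(0.01 * rnorm(4 * 10), 4, 10)
  W0 <- matrix(0, 6, 4)
  expect_equal(spatial_fc_forward(x, W0), matrix(0, 6, 10))
  # near-identity in the tanh linear regime
  Wi <- diag(4)
  err <- max(abs(spatial_fc_forward(x, Wi) - x))
  expect_lt(err, 1e-3)   # |tanh(u)-u| <= |u|^3/3 for |u| < 0.05
  # codomain
  big <- spatial_fc_forward(100 * x, matrix(rnorm(24), 6, 4))
  expect_true(all(big > -1 & big < 1))
  expect_error(spatial_fc_forward(x, matrix(0, 6, 3)), "mismatch")
})

test_that("frequency convolution is a faithful 'same' convolution", {
  set.seed(3)
  s <- abs(matrix(rnorm(3 * 30), 3, 30))       # nonnegative input
  # delta kernel at the aligned center tap reproduces the input
  L <- 7; pl <- floor((L - 1) / 2)
  delta <- matrix(0, 1, L); delta[1, pl + 1] <- 1
  out <- freq_conv_forward(s, delta)
  expect_equal(out[1, , ], s, tolerance = 1e-12)
  # output shape [N_fr x N_sp x N_s]
  k8 <- matrix(rnorm(8 * 5), 8, 5)
  expect_equal(dim(freq_conv_forward(matrix(rnorm(16 * 125), 16, 125), k8)),
               c(8, 16, 125))
  # moving average against a direct-convolution oracle (interior samples)
  x <- matrix(sin(2 * pi * 5 * (0:99) / 100), 1, 100)
  ker <- matrix(rep(1 / 5, 5), 1, 5)
  y <- freq_conv_forward(x, ker, activation = FALSE)[1, 1, ]
  oracle <- vapply(3:98, function(t2)
    sum(ker[1, ] * x[1, (t2 - 2):(t2 + 2)]), numeric(1))
  expect_equal(y[3:98], oracle, tolerance = 1e-10)
  # matches the kernel's frequency response in steady state
  H <- abs(sum(ker[1, ] * exp(-1i * 2 * pi * 5 / 100 * (0:4))))
  expect_equal(sqrt(mean(y[10:90]^2)) / sqrt(mean(x[1, 10:90]^2)), H,
               tolerance = 1e-2)
  expect_error(freq_conv_forward(s, matrix(0, 1, 31)), "longer")
})

test_that("the full forward pass honours its shape and determinism contracts", {
  cfg <- aetf_config(n_channels = 8, n_samples = 125, n_classes = 12,
                     fs = 250, dropout = 0)
  expect_equal(cfg$n_spatial, 16)
  expect_equal(cfg$d_model, 128)
  expect_equal(cfg$kernel_len, 125)
  m <- aetf_init(cfg, seed = 1)
  x <- matrix(rnorm(8 * 125), 8, 125)
  l1 <- aetf_forward(m, x)
  expect_length(l1, 12)
  expect_identical(l1, aetf_forward(m, x))
  # attention rows sum to 1 in every layer and head
  lg <- aetf_forward(m, x, collect_attention = TRUE)
  at <- attr(lg, "attention")
  expect_length(at, 2)
  for (layer in at) for (A in layer) {
    expect_equal(dim(A), c(125, 125))
    expect_lt(max(abs(rowSums(A) - 1)), 1e-6)
    expect_true(all(A >= 0))
  }
})

test_that("the encoder-less ablation still maps trials to class logits", {
  cfg <- aetf_config(n_channels = 4, n_samples = 30, n_classes = 5, fs = 50,
                     n_freq_filters = 4, encoder = FALSE)
  m <- aetf_init(cfg, seed = 2)
  x <- matrix(rnorm(4 * 30), 4, 30)
  expect_length(aetf_forward(m, x), 5)
})

test_that("backpropagation matches finite differences", {
  cfg <- aetf_config(n_channels = 3, n_samples = 10, n_classes = 4, fs = 16,
                     n_spatial = 4, n_freq_filters = 2, n_layers = 2,
                     n_heads = 2, dropout = 0)
  m <- aetf_init(cfg, seed = 3)
  set.seed(1)
  B <- 3
  X <- array(rnorm(B * 3 * 10), dim = c(B, 3, 10))
  y <- c(0L, 1L, 2L); yp <- c(1L, 2L, 0L); lam <- c(0.3, 0.8, 1.0)
  fwb <- ssvepmix:::aetf_forward_batch(m, X, training = TRUE,
                                       keep_cache = TRUE)
  gr <- ssvepmix:::mixed_ce_grad(fwb$logits, y, yp, lam)
  grads <- ssvepmix:::aetf_backward_batch(m, fwb$cache, gr$dlogits)
  lossfun <- function(model) {
    f <- ssvepmix:::aetf_forward_batch(model, X, training = TRUE)
    ssvepmix:::mixed_ce_grad(f$logits, y, yp, lam)$loss
  }
  eps <- 1e-5
  for (nm in names(grads)) {
    ix <- sample(length(m$w[[nm]]), min(3, length(m$w[[nm]])))
    for (k in ix) {
      mp <- m; mp$w[[nm]][k] <- mp$w[[nm]][k] + eps
      mm2 <- m; mm2$w[[nm]][k] <- mm2$w[[nm]][k] - eps
      num <- (lossfun(mp) - lossfun(mm2)) / (2 * eps)
      ana <- grads[[nm]][k]
      if (abs(num) < 1e-7 && abs(ana) < 1e-7) next  # both vanish
      rel <- abs(num - ana) / max(abs(num) + abs(ana), 1e-6)
      expect_lt(rel, 1e-4)
    }
  }
})

test_that("the student halves the hidden size and shrinks the model", {
  teacher_cfg <- aetf_config(n_channels = 8, n_samples = 125, n_classes = 12,
                             fs = 250)                    # d_model 128
  s_cfg <- make_student(teacher_cfg)
  expect_equal(s_cfg$n_layers, 1)
  expect_equal(s_cfg$d_model, 64)
  expect_equal(s_cfg$d_model %% s_cfg$n_heads, 0)
  teacher <- aetf_init(teacher_cfg, 1)
  student <- aetf_init(s_cfg, 1)
  expect_lt(aetf_n_params(student), aetf_n_params(teacher))
  x <- matrix(rnorm(8 * 125), 8, 125)
  expect_length(aetf_forward(student, x), 12)
})
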