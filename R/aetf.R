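#' AETF architecture configuration
#'
#' The decoder stacks a spatial fully connected filter (tanh), a
#' frequency-domain convolution (kernel length `floor(fs/2)`, 'same'
#' zero padding, ELU, batch norm over filter maps), sinusoidal positional
#' encoding, and `n_layers` Transformer encoder layers over the `n_samples`
#' time points treated as tokens with embedding dimension
#' `d_model = n_spatial * n_freq_filters`, followed by a flattening linear
#' classification head.
#'
#' @param n_channels,n_samples,n_classes input channel count, samples per
#'   trial, and number of stimulus classes.
#' @param fs sampling rate in Hz (fixes the convolution kernel length).
#' @param n_spatial number of spatial filters (default twice the electrode
#'   count).
#' @param n_freq_filters number of frequency filter maps (default 8).
#' @param n_layers number of encoder layers (default 2).
#' @param n_heads attention heads (default = `n_freq_filters`, mimicking a
#'   filter bank); must divide `d_model`.
#' @param ff_dim position-wise feed-forward width (default `2 * d_model`).
#' @param dropout dropout rate inside encoder layers.
#' @param encoder set `FALSE` for the ablation variant without positional
#'   encoding and encoder stack (spatial + frequency filters straight into
#'   the classification head).
#' @param leaky_slope negative slope of the leaky-ReLU feed-forward
#'   activation.
#' @return an object of class `aetf_config`.
#' @export
aetf_config <- function(n_channels, n_samples, n_classes, fs,
                        n_spatial = 2L * n_channels,
                        n_freq_filters = 8L, n_layers = 2L,
                        n_heads = n_freq_filters, ff_dim = NULL,
                        dropout = 0.1, encoder = TRUE, leaky_slope = 0.01) {
  d_model <- n_spatial * n_freq_filters
  if (is.null(ff_dim)) ff_dim <- 2L * d_model
  if (d_model %% n_heads != 0)
    stop(sprintf("d_model (%d) must be divisible by n_heads (%d)",
                 d_model, n_heads))
  if (ff_dim < d_model) stop("ff_dim must be >= d_model")
  kernel_len <- floor(fs / 2)
  if (kernel_len > n_samples) {
    warning(sprintf(
      "conv kernel length floor(fs/2) = %d exceeds n_samples = %d; clipping",
      kernel_len, n_samples))
    kernel_len <- n_samples
  }
  structure(list(n_channels = as.integer(n_channels),
                 n_samples = as.integer(n_samples),
                 n_classes = as.integer(n_classes), fs = fs,
                 n_spatial = as.integer(n_spatial),
                 n_freq_filters = as.integer(n_freq_filters),
                 n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads),
                 d_model = as.integer(d_model), ff_dim = as.integer(ff_dim),
                 dropout = dropout, encoder = isTRUE(encoder),
                 leaky_slope = leaky_slope,
                 kernel_len = as.integer(kernel_len)),
            class = "aetf_config")
}

#' Derive the distilled student configuration
#'
#' The student keeps a single encoder layer and halves the hidden dimension
#' (by halving the number of frequency filter maps, so
#' `d_model = n_spatial * n_freq_filters` halves) and the feed-forward
#' width; the head count follows the halved filter count, reduced further if
#' needed to keep `d_model` divisible.
#'
#' @param cfg a teacher [aetf_config()].
#' @return an `aetf_config` for the student.
#' @export
make_student <- function(cfg) {
  stopifnot(inherits(cfg, "aetf_config"))
  n_fr <- max(1L, cfg$n_freq_filters %/% 2L)
  d_new <- cfg$n_spatial * n_fr
  heads <- n_fr
  if (d_new %% heads != 0) {
    heads <- max(which(d_new %% seq_len(heads) == 0))
    warning(sprintf("head count reduced to %d to divide d_model = %d",
                    heads, d_new))
  }
  aetf_config(cfg$n_channels, cfg$n_samples, cfg$n_classes, cfg$fs,
              n_spatial = cfg$n_spatial, n_freq_filters = n_fr,
              n_layers = 1L, n_heads = heads,
              ff_dim = max(d_new, cfg$ff_dim %/% 2L),
              dropout = cfg$dropout, encoder = cfg$encoder,
              leaky_slope = cfg$leaky_slope)
}

#' Sinusoidal positional encoding
#'
#' `PE(pos, 2i) = sin(pos / 10000^(2i/d_model))`,
#' `PE(pos, 2i+1) = cos(same argument)`, positions 0-based.
#'
#' @param n_pos number of positions (rows).
#' @param d_model embedding dimension (must be even).
#' @return matrix `[n_pos x d_model]`.
#' @export
positional_encoding <- function(n_pos, d_model) {
  if (d_model %% 2 != 0) stop("d_model must be even")
  pos <- seq_len(n_pos) - 1
  i <- seq_len(d_model / 2) - 1
  ang <- outer(pos, 1 / 10000^(2 * i / d_model))
  pe <- matrix(0, n_pos, d_model)
  pe[, seq(1, d_model, by = 2)] <- sin(ang)
  pe[, seq(2, d_model, by = 2)] <- cos(ang)
  pe
}

softmax_rows <- function(m) {
  m <- m - apply(m, 1, max)
  e <- exp(m)
  e / rowSums(e)
}

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V` with the softmax taken row-wise.
#'
#' @param Q queries `[m x d_k]`.
#' @param K keys `[n x d_k]`.
#' @param V values `[n x d_v]`.
#' @return list with `output` `[m x d_v]` and the attention `weights`
#'   `[m x n]` (each row sums to 1).
#' @export
scaled_dot_attention <- function(Q, K, V) {
  if (ncol(Q) != ncol(K)) stop("Q and K must share d_k")
  if (nrow(K) != nrow(V)) stop("K and V must share their row count")
  A <- softmax_rows(Q %*% t(K) / sqrt(ncol(Q)))
  list(output = A %*% V, weights = A)
}

#' Multihead self-attention (single sequence)
#'
#' Projects `X` into per-head queries, keys and values, applies scaled
#' dot-product attention per head, concatenates the heads and applies the
#' output projection.
#'
#' @param X input sequence `[n x d_model]`.
#' @param h number of heads (`d_model` must be divisible by `h`).
#' @param proj list with projection matrices `Wq`, `Wk`, `Wv`, `Wo`
#'   (`[d_model x d_model]`) and optional bias vectors `bq`, `bk`, `bv`,
#'   `bo`.
#' @return list with `output` `[n x d_model]` and per-head attention
#'   `weights`.
#' @export
multihead_attention <- function(X, h, proj) {
  d <- ncol(X)
  if (d %% h != 0) stop("d_model must be divisible by h")
  dk <- d %/% h
  zb <- numeric(d)
  Q <- addb(X %*% proj$Wq, proj$bq %||% zb)
  K <- addb(X %*% proj$Wk, proj$bk %||% zb)
  V <- addb(X %*% proj$Wv, proj$bv %||% zb)
  O <- matrix(0, nrow(X), d)
  weights <- vector("list", h)
  for (head in seq_len(h)) {
    cols <- ((head - 1L) * dk + 1L):(head * dk)
    att <- scaled_dot_attention(Q[, cols, drop = FALSE],
                                K[, cols, drop = FALSE],
                                V[, cols, drop = FALSE])
    O[, cols] <- att$output
    weights[[head]] <- att$weights
  }
  list(output = addb(O %*% proj$Wo, proj$bo %||% zb), weights = weights)
}

#' Spatial fully connected filter
#'
#' Per-time-point affine map across channels followed by tanh; the time
#' axis is untouched. Each output row is a learned nonlinear combination of
#' all electrodes, i.e. a spatial filter.
#'
#' @param x input `[N_c x N_s]`.
#' @param W weights `[N_sp x N_c]`.
#' @param b bias `[N_sp]` (default zeros).
#' @return matrix `[N_sp x N_s]` with entries in (-1, 1).
#' @export
spatial_fc_forward <- function(x, W, b = numeric(nrow(W))) {
  if (ncol(W) != nrow(x)) stop("weight/input shape mismatch")
  tanh(W %*% x + b)
}

#' Frequency-filter convolution
#'
#' One-input-channel 2-D convolution along time with `nrow(kernels)` output
#' maps and 'same' zero padding (even kernel lengths place the extra zero on
#' the right), optionally followed by ELU. Batch normalization over maps is
#' applied when `bn` (list with `gamma`, `beta`, `mean`, `var`) is supplied.
#'
#' @param s input `[N_sp x N_s]`.
#' @param kernels `[N_fr x L]` filter kernels.
#' @param bias per-map bias (default zeros).
#' @param activation apply ELU when `TRUE`.
#' @param bn optional batch-norm parameters.
#' @return array `[N_fr x N_sp x N_s]`.
#' @export
freq_conv_forward <- function(s, kernels, bias = numeric(nrow(kernels)),
                              activation = TRUE, bn = NULL) {
  n_sp <- nrow(s); n_s <- ncol(s); L <- ncol(kernels)
  if (L > n_s) stop("kernel longer than the signal")
  x3 <- array(s, dim = c(n_sp, 1L, n_s))
  cm <- im2col(x3, L)
  y <- kernels %*% cm + bias
  if (activation) y <- elu(y)
  if (!is.null(bn))
    y <- (y - bn$mean) / sqrt(bn$var + 1e-5) * bn$gamma + bn$beta
  out <- array(0, dim = c(nrow(kernels), n_sp, n_s))
  for (f in seq_len(nrow(kernels)))
    out[f, , ] <- array(y[f, ], dim = c(n_sp, n_s))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

addb <- function(M, b) M + matrix(b, nrow(M), length(b), byrow = TRUE)

elu <- function(x) ifelse(x > 0, x, exp(x) - 1)

leaky <- function(x, slope) ifelse(x > 0, x, slope * x)

# im2col for 1-D 'same' convolution along the last axis of [n_sp, B, n_s]:
# returns [L x (n_sp*B*n_s)], column order (sp, b, t), with zero padding
# split floor((L-1)/2) left / remainder right.
im2col <- function(x3, L) {
  n_sp <- dim(x3)[1]; B <- dim(x3)[2]; n_s <- dim(x3)[3]
  pl <- floor((L - 1) / 2)
  pad <- array(0, dim = c(n_sp, B, n_s + L - 1L))
  pad[, , (pl + 1L):(pl + n_s)] <- x3
  cm <- matrix(0, L, n_sp * B * n_s)
  for (k in seq_len(L))
    cm[k, ] <- as.vector(pad[, , k:(k + n_s - 1L), drop = FALSE])
  cm
}

col2im <- function(dcm, n_sp, B, n_s, L) {
  pl <- floor((L - 1) / 2)
  dpad <- array(0, dim = c(n_sp, B, n_s + L - 1L))
  for (k in seq_len(L))
    dpad[, , k:(k + n_s - 1L)] <- dpad[, , k:(k + n_s - 1L), drop = FALSE] +
      array(dcm[k, ], dim = c(n_sp, B, n_s))
  dpad[, , (pl + 1L):(pl + n_s), drop = FALSE]
}

xavier <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize AETF weights
#'
#' Glorot-uniform initialization of all projection matrices, zero biases,
#' unit batch-norm scale. The returned object carries the configuration,
#' the parameter list and the batch-norm running statistics.
#'
#' @param cfg an [aetf_config()].
#' @param seed integer seed.
#' @return an object of class `aetf_model`.
#' @export
aetf_init <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "aetf_config"))
  w <- with_seed(seed, {
    d <- cfg$d_model
    w <- list(
      W_sp = xavier(cfg$n_spatial, cfg$n_channels),
      b_sp = numeric(cfg$n_spatial),
      K = xavier(cfg$n_freq_filters, cfg$kernel_len) / sqrt(cfg$kernel_len),
      b_conv = numeric(cfg$n_freq_filters),
      bn_gamma = rep(1, cfg$n_freq_filters),
      bn_beta = numeric(cfg$n_freq_filters),
      W_out = xavier(cfg$n_samples * d, cfg$n_classes),
      b_out = numeric(cfg$n_classes))
    if (cfg$encoder) {
      for (l in seq_len(cfg$n_layers)) {
        p <- function(nm) paste0("L", l, "_", nm)
        w[[p("Wq")]] <- xavier(d, d); w[[p("bq")]] <- numeric(d)
        w[[p("Wk")]] <- xavier(d, d); w[[p("bk")]] <- numeric(d)
        w[[p("Wv")]] <- xavier(d, d); w[[p("bv")]] <- numeric(d)
        w[[p("Wo")]] <- xavier(d, d); w[[p("bo")]] <- numeric(d)
        w[[p("g1")]] <- rep(1, d); w[[p("be1")]] <- numeric(d)
        w[[p("W1")]] <- xavier(d, cfg$ff_dim)
        w[[p("bf1")]] <- numeric(cfg$ff_dim)
        w[[p("W2")]] <- xavier(cfg$ff_dim, d)
        w[[p("bf2")]] <- numeric(d)
        w[[p("g2")]] <- rep(1, d); w[[p("be2")]] <- numeric(d)
      }
    }
    w
  })
  structure(list(cfg = cfg, w = w,
                 bn_mean = numeric(cfg$n_freq_filters),
                 bn_var = rep(1, cfg$n_freq_filters)),
            class = "aetf_model")
}

#' @export
print.aetf_model <- function(x, ...) {
  cat(sprintf(
    "aetf_model: %d ch x %d samples -> %d classes | d_model %d, %d layer(s), %d head(s)%s | %d parameters\n",
    x$cfg$n_channels, x$cfg$n_samples, x$cfg$n_classes, x$cfg$d_model,
    x$cfg$n_layers, x$cfg$n_heads,
    if (x$cfg$encoder) "" else " [encoder ablated]", aetf_n_params(x)))
  invisible(x)
}

#' Number of trainable parameters
#' @param model an `aetf_model`.
#' @return integer count.
#' @export
aetf_n_params <- function(model) sum(vapply(model$w, length, integer(1)))

layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  list(out = addb(sweep(xhat, 2, g, "*"), b),
       xhat = xhat, istd = istd)
}

layernorm_bwd <- function(dout, cache, g) {
  xhat <- cache$xhat; istd <- cache$istd
  dg <- colSums(dout * xhat)
  db <- colSums(dout)
  dxhat <- sweep(dout, 2, g, "*")
  dX <- istd * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dX, dg = dg, db = db)
}

# Batched forward pass. X: [B x N_c x N_s]. Returns logits [B x N_f] and,
# when requested, a cache for backprop and/or the attention matrices.
aetf_forward_batch <- function(model, X, training = FALSE,
                               keep_cache = FALSE, collect_attention = FALSE) {
  cfg <- model$cfg; w <- model$w
  B <- dim(X)[1]; nc <- cfg$n_channels; ns <- cfg$n_samples
  nsp <- cfg$n_spatial; nfr <- cfg$n_freq_filters; d <- cfg$d_model
  stopifnot(dim(X)[2] == nc, dim(X)[3] == ns)

  Xm <- matrix(aperm(X, c(2, 1, 3)), nrow = nc)        # [nc x B*ns], col (b,t)
  S_pre <- w$W_sp %*% Xm + w$b_sp
  S <- tanh(S_pre)
  S3 <- array(S, dim = c(nsp, B, ns))
  Cm <- im2col(S3, cfg$kernel_len)                     # [L x nsp*B*ns]
  Ypre <- w$K %*% Cm + w$b_conv                        # [nfr x M], col (sp,b,t)
  Ye <- elu(Ypre)
  if (training) {
    mu <- rowMeans(Ye)
    vv <- rowMeans((Ye - mu)^2)
  } else {
    mu <- model$bn_mean
    vv <- model$bn_var
  }
  istd_bn <- 1 / sqrt(vv + 1e-5)
  xhat_bn <- (Ye - mu) * istd_bn
  Ybn <- xhat_bn * w$bn_gamma + w$bn_beta

  A4 <- array(Ybn, dim = c(nfr, nsp, B, ns))
  Tok <- matrix(aperm(A4, c(4, 3, 1, 2)), nrow = ns * B)  # row (b,t), t fastest

  cache <- if (keep_cache)
    list(Xm = Xm, S_pre = S_pre, S = S, Cm = Cm, Ypre = Ypre, Ye = Ye,
         mu = mu, vv = vv, istd_bn = istd_bn, xhat_bn = xhat_bn, B = B,
         layers = vector("list", cfg$n_layers), training = training)
  else NULL
  attn_out <- if (collect_attention) vector("list", cfg$n_layers) else NULL

  M <- Tok
  if (cfg$encoder) {
    pe <- positional_encoding(ns, d)
    M <- M + pe[rep(seq_len(ns), B), , drop = FALSE]
    h <- cfg$n_heads; dk <- d %/% h
    keep <- 1 - cfg$dropout
    for (l in seq_len(cfg$n_layers)) {
      p <- function(nm) w[[paste0("L", l, "_", nm)]]
      Q <- addb(M %*% p("Wq"), p("bq"))
      K <- addb(M %*% p("Wk"), p("bk"))
      V <- addb(M %*% p("Wv"), p("bv"))
      O <- matrix(0, nrow(M), d)
      Alist <- vector("list", B)
      for (b in seq_len(B)) {
        rb <- ((b - 1L) * ns + 1L):(b * ns)
        Ab <- vector("list", h)
        for (hd in seq_len(h)) {
          cols <- ((hd - 1L) * dk + 1L):(hd * dk)
          sc <- Q[rb, cols, drop = FALSE] %*%
            t(K[rb, cols, drop = FALSE]) / sqrt(dk)
          A <- softmax_rows(sc)
          O[rb, cols] <- A %*% V[rb, cols, drop = FALSE]
          Ab[[hd]] <- A
        }
        Alist[[b]] <- Ab
      }
      attn <- addb(O %*% p("Wo"), p("bo"))
      mask1 <- NULL
      if (training && cfg$dropout > 0) {
        mask1 <- matrix(stats::rbinom(length(attn), 1, keep) / keep,
                        nrow(attn), ncol(attn))
        attn <- attn * mask1
      }
      R1 <- M + attn
      ln1 <- layernorm_fwd(R1, p("g1"), p("be1"))
      X1 <- ln1$out
      H <- addb(X1 %*% p("W1"), p("bf1"))
      Ha <- leaky(H, cfg$leaky_slope)
      F2 <- addb(Ha %*% p("W2"), p("bf2"))
      mask2 <- NULL
      if (training && cfg$dropout > 0) {
        mask2 <- matrix(stats::rbinom(length(F2), 1, keep) / keep,
                        nrow(F2), ncol(F2))
        F2 <- F2 * mask2
      }
      R2 <- X1 + F2
      ln2 <- layernorm_fwd(R2, p("g2"), p("be2"))
      if (keep_cache)
        cache$layers[[l]] <- list(Min = M, Q = Q, K = K, V = V, O = O,
                                  A = Alist, mask1 = mask1, ln1 = ln1,
                                  X1 = X1, H = H, Ha = Ha, mask2 = mask2,
                                  ln2 = ln2)
      if (collect_attention)
        attn_out[[l]] <- Alist
      M <- ln2$out
    }
  }
  Flat <- matrix(aperm(array(M, dim = c(ns, B, d)), c(2, 1, 3)), nrow = B)
  logits <- addb(Flat %*% w$W_out, w$b_out)
  if (keep_cache) {
    cache$Mfinal <- M
    cache$Flat <- Flat
  }
  list(logits = logits, cache = cache, attention = attn_out)
}

# Backward pass matching aetf_forward_batch(keep_cache = TRUE).
aetf_backward_batch <- function(model, cache, dlogits) {
  cfg <- model$cfg; w <- model$w
  B <- cache$B; ns <- cfg$n_samples; d <- cfg$d_model
  nsp <- cfg$n_spatial; nfr <- cfg$n_freq_filters
  g <- list()
  g$W_out <- t(cache$Flat) %*% dlogits
  g$b_out <- colSums(dlogits)
  dFlat <- dlogits %*% t(w$W_out)
  dM <- matrix(aperm(array(dFlat, dim = c(B, ns, d)), c(2, 1, 3)),
               nrow = ns * B)
  if (cfg$encoder) {
    h <- cfg$n_heads; dk <- d %/% h
    for (l in rev(seq_len(cfg$n_layers))) {
      lc <- cache$layers[[l]]
      p <- function(nm) w[[paste0("L", l, "_", nm)]]
      nm2 <- function(nm) paste0("L", l, "_", nm)
      b2 <- layernorm_bwd(dM, lc$ln2, p("g2"))
      g[[nm2("g2")]] <- b2$dg; g[[nm2("be2")]] <- b2$db
      dR2 <- b2$dX
      dX1 <- dR2
      dF2 <- dR2
      if (!is.null(lc$mask2)) dF2 <- dF2 * lc$mask2
      g[[nm2("W2")]] <- t(lc$Ha) %*% dF2
      g[[nm2("bf2")]] <- colSums(dF2)
      dHa <- dF2 %*% t(p("W2"))
      dH <- dHa * ifelse(lc$H > 0, 1, cfg$leaky_slope)
      g[[nm2("W1")]] <- t(lc$X1) %*% dH
      g[[nm2("bf1")]] <- colSums(dH)
      dX1 <- dX1 + dH %*% t(p("W1"))
      b1 <- layernorm_bwd(dX1, lc$ln1, p("g1"))
      g[[nm2("g1")]] <- b1$dg; g[[nm2("be1")]] <- b1$db
      dR1 <- b1$dX
      dMin <- dR1
      dattn <- dR1
      if (!is.null(lc$mask1)) dattn <- dattn * lc$mask1
      g[[nm2("Wo")]] <- t(lc$O) %*% dattn
      g[[nm2("bo")]] <- colSums(dattn)
      dO <- dattn %*% t(p("Wo"))
      dQ <- matrix(0, nrow(dM), d)
      dK <- matrix(0, nrow(dM), d)
      dV <- matrix(0, nrow(dM), d)
      for (b in seq_len(B)) {
        rb <- ((b - 1L) * ns + 1L):(b * ns)
        for (hd in seq_len(h)) {
          cols <- ((hd - 1L) * dk + 1L):(hd * dk)
          A <- lc$A[[b]][[hd]]
          dOb <- dO[rb, cols, drop = FALSE]
          Vb <- lc$V[rb, cols, drop = FALSE]
          dA <- dOb %*% t(Vb)
          dV[rb, cols] <- t(A) %*% dOb
          dSc <- A * (dA - rowSums(dA * A))
          dQ[rb, cols] <- dSc %*% lc$K[rb, cols, drop = FALSE] / sqrt(dk)
          dK[rb, cols] <- t(dSc) %*% lc$Q[rb, cols, drop = FALSE] / sqrt(dk)
        }
      }
      g[[nm2("Wq")]] <- t(lc$Min) %*% dQ; g[[nm2("bq")]] <- colSums(dQ)
      g[[nm2("Wk")]] <- t(lc$Min) %*% dK; g[[nm2("bk")]] <- colSums(dK)
      g[[nm2("Wv")]] <- t(lc$Min) %*% dV; g[[nm2("bv")]] <- colSums(dV)
      dMin <- dMin + dQ %*% t(p("Wq")) + dK %*% t(p("Wk")) + dV %*% t(p("Wv"))
      dM <- dMin
    }
  }
  # positional encoding is additive: gradient passes through unchanged
  dA4 <- aperm(array(dM, dim = c(ns, B, nfr, nsp)), c(3, 4, 2, 1))
  dYbn <- matrix(dA4, nrow = nfr)
  g$bn_gamma <- rowSums(dYbn * cache$xhat_bn)
  g$bn_beta <- rowSums(dYbn)
  dxhat <- dYbn * w$bn_gamma
  if (cache$training) {
    dYe <- cache$istd_bn *
      (dxhat - rowMeans(dxhat) - cache$xhat_bn * rowMeans(dxhat * cache$xhat_bn))
  } else {
    dYe <- dxhat * cache$istd_bn
  }
  dYpre <- dYe * ifelse(cache$Ypre > 0, 1, cache$Ye + 1)
  g$K <- dYpre %*% t(cache$Cm)
  g$b_conv <- rowSums(dYpre)
  dCm <- t(w$K) %*% dYpre
  dS3 <- col2im(dCm, nsp, B, ns, cfg$kernel_len)
  dS <- matrix(dS3, nrow = nsp)
  dSpre <- dS * (1 - cache$S^2)
  g$W_sp <- dSpre %*% t(cache$Xm)
  g$b_sp <- rowSums(dSpre)
  g
}

#' Forward pass of the AETF decoder
#'
#' @param model an `aetf_model`.
#' @param x a single trial `[N_c x N_s]` or a batch `[B x N_c x N_s]`.
#' @param collect_attention also return the per-layer, per-head attention
#'   matrices (`[N_s x N_s]`, rows summing to 1).
#' @return for a single trial, the logits vector of length `N_f` (with
#'   attribute `"attention"` when requested); for a batch, a `[B x N_f]`
#'   logits matrix.
#' @export
aetf_forward <- function(model, x, collect_attention = FALSE) {
  stopifnot(inherits(model, "aetf_model"))
  single <- is.matrix(x)
  if (single) x <- array(x, dim = c(1L, nrow(x), ncol(x)))
  out <- aetf_forward_batch(model, x, training = FALSE,
                            collect_attention = collect_attention)
  if (single) {
    lg <- drop(out$logits)
    if (collect_attention)
      attr(lg, "attention") <- lapply(out$attention, function(layer)
        layer[[1L]])
    lg
  } else out$logits
}

#' @export
predict.aetf_model <- function(object, newdata, type = c("label", "logits"),
                               ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "epoched_eeg")) newdata$data else newdata
  if (is.matrix(X)) X <- array(X, dim = c(1L, nrow(X), ncol(X)))
  logits <- aetf_forward_batch(object, X)$logits
  if (type == "logits") return(logits)
  max.col(logits, ties.method = "first") - 1L
}

# Cross-entropy pieces shared by the training loop ------------------------

# dlogits and loss for mixed-label cross-entropy (Eq-style two-term loss).
mixed_ce_grad <- function(logits, y, y_prime, lam) {
  B <- nrow(logits)
  P <- softmax_rows(logits)
  iy <- cbind(seq_len(B), y + 1L)
  iyp <- cbind(seq_len(B), y_prime + 1L)
  eps <- 1e-12
  loss <- mean(lam * (-log(P[iy] + eps)) + (1 - lam) * (-log(P[iyp] + eps)))
  target <- matrix(0, B, ncol(logits))
  target[iy] <- target[iy] + lam
  target[iyp] <- target[iyp] + (1 - lam)
  list(loss = loss, dlogits = (P - target) / B)
}

ce_loss <- function(logits, y) {
  P <- softmax_rows(logits)
  mean(-log(P[cbind(seq_len(nrow(logits)), y + 1L)] + 1e-12))
}
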