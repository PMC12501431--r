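# eTRCA and TDCA filter-bank decoders.

# leading generalized eigenvector of (S, Q); ridge-regularizes Q when it is
# numerically singular (eps = 1e-8 * trace/dim, logged via message).
geigen_leading <- function(S, Q, k = 1L) {
  d <- nrow(Q)
  solveQ <- tryCatch(solve(Q, S), error = function(e) NULL)
  if (is.null(solveQ) || !all(is.finite(solveQ)) || rcond(Q) < 1e-12) {
    eps <- 1e-8 * sum(diag(Q)) / d
    if (eps <= 0) eps <- 1e-8
    message(sprintf("singular matrix in generalized eigensolve: ridge %g added",
                    eps))
    solveQ <- solve(Q + diag(eps, d), S)
  }
  ei <- eigen(solveQ)
  V <- Re(ei$vectors[, seq_len(k), drop = FALSE])
  # normalize columns and fix sign: largest-magnitude entry positive
  for (j in seq_len(k)) {
    v <- V[, j]
    v <- v / sqrt(sum(v^2))
    if (v[which.max(abs(v))] < 0) v <- -v
    V[, j] <- v
  }
  list(vectors = V, values = Re(ei$values[seq_len(k)]))
}

#' TRCA spatial filter for one class
#'
#' Maximizes the inter-trial covariance of the spatially filtered signal
#' subject to a variance constraint: `w` is the leading generalized
#' eigenvector of `(S, Q)` with `S` the summed cross-trial covariance (over
#' ordered trial pairs h1 != h2) and `Q` the pooled within-trial covariance.
#' Trials are channel-mean-centered first. The returned filter has unit
#' norm with its largest-magnitude entry positive.
#'
#' @param class_trials array `[N_t x N_c x N_s]`, `N_t >= 2`.
#' @return numeric weight vector of length `N_c`.
#' @export
trca_spatial_filter <- function(class_trials) {
  stopifnot(length(dim(class_trials)) == 3L)
  nt <- dim(class_trials)[1]; nc <- dim(class_trials)[2]
  if (nt < 2L) stop("TRCA needs at least 2 trials")
  Xs <- lapply(seq_len(nt), function(h) {
    X <- class_trials[h, , , drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, nrow = nc)
    X - rowMeans(X)
  })
  Xsum <- Reduce(`+`, Xs)
  Q <- Reduce(`+`, lapply(Xs, function(X) X %*% t(X)))
  S <- Xsum %*% t(Xsum) - Q        # = sum over ordered pairs h1 != h2
  drop(geigen_leading(S, Q)$vectors)
}

# default filter-bank sub-band weights a(m) = m^-1.25 + 0.25
fb_weights <- function(n_bands, scheme = c("standard", "uniform")) {
  scheme <- match.arg(scheme)
  m <- seq_len(n_bands)
  if (scheme == "standard") m^(-1.25) + 0.25 else rep(1, n_bands)
}

# default SSVEP filter bank: sub-band m spans (m*8, 90) Hz
default_bank <- function(n_bands, fs) {
  if (90 >= fs / 2)
    stop(sprintf(paste0(
      "default filter bank (m*8-90 Hz) needs fs > 180 Hz (fs = %g); ",
      "pass a custom `bank`"), fs))
  lapply(seq_len(n_bands), function(m) {
    if (m * 8 >= 90) stop("sub-band lower edge reaches 90 Hz; reduce n_bands")
    c(m * 8, 90)
  })
}

apply_bank_filter <- function(e, band) {
  bandpass(e, filter_spec(band[1], band[2]))
}

filter_trial <- function(x, band, fs) {
  filt <- design_cheby(filter_spec(band[1], band[2]), fs)
  t(apply(x, 1, function(ch) signal::filtfilt(filt, ch)))
}

#' Fit the ensemble TRCA (eTRCA) decoder
#'
#' Per filter-bank sub-band (defaults: sub-band m spans m*8 to 90 Hz), one
#' TRCA spatial filter is computed per class and assembled into the
#' ensemble matrix `W = [w_1 ... w_Nf]`; per-class trial-average templates
#' are stored alongside. Sub-band scores are combined with weights
#' `a(m) = m^-1.25 + 0.25` (or uniform).
#'
#' @param train an `epoched_eeg` with >= 2 trials per class.
#' @param n_bands number of sub-bands (default 3).
#' @param bank optional list of custom `c(low, high)` passbands (Hz),
#'   overriding the default bank (required when `fs <= 180` Hz).
#' @param weight_scheme `"standard"` or `"uniform"` sub-band weights.
#' @return an object of class `etrca_model`.
#' @export
etrca_fit <- function(train, n_bands = 3L, bank = NULL,
                      weight_scheme = c("standard", "uniform")) {
  stopifnot(inherits(train, "epoched_eeg"))
  weight_scheme <- match.arg(weight_scheme)
  if (is.null(bank)) bank <- default_bank(n_bands, train$fs)
  classes <- sort(unique(train$labels))
  counts <- vapply(classes, function(k) sum(train$labels == k), integer(1))
  if (any(counts < 2L)) stop("eTRCA needs >= 2 trials per class")
  bands <- lapply(bank, function(band) {
    filt <- apply_bank_filter(train, band)
    W <- matrix(0, n_channels(train), length(classes))
    templates <- vector("list", length(classes))
    for (ci in seq_along(classes)) {
      ix <- which(filt$labels == classes[ci])
      W[, ci] <- trca_spatial_filter(filt$data[ix, , , drop = FALSE])
      templates[[ci]] <- compute_template(filt$data[ix, , , drop = FALSE])
    }
    list(W = W, templates = templates, band = band)
  })
  structure(list(bands = bands, bank = bank,
                 bank_weights = fb_weights(length(bank), weight_scheme),
                 classes = classes, fs = train$fs,
                 n_channels = n_channels(train),
                 n_samples = n_samples(train)),
            class = "etrca_model")
}

# correlation that treats a zero-variance input as contributing 0
safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

#' Classify a trial with a fitted eTRCA model
#'
#' Per sub-band, the trial is band-passed, projected by the ensemble filter
#' `W`, and correlated with every projected class template; weighted
#' sub-band correlations are summed and the highest-scoring class wins
#' (ties go to the lowest class index).
#'
#' @param model an `etrca_model`.
#' @param x a single trial `[N_c x N_s]`.
#' @return list with 0-based `label` and the per-class `scores`.
#' @export
etrca_predict <- function(model, x) {
  stopifnot(inherits(model, "etrca_model"), is.matrix(x))
  K <- length(model$classes)
  scores <- numeric(K)
  for (bi in seq_along(model$bands)) {
    b <- model$bands[[bi]]
    xf <- filter_trial(x, b$band, model$fs)
    proj <- as.vector(t(b$W) %*% xf)
    for (k in seq_len(K)) {
      tk <- as.vector(t(b$W) %*% b$templates[[k]])
      scores[k] <- scores[k] + model$bank_weights[bi] * safe_cor(proj, tk)
    }
  }
  list(label = model$classes[which.max(scores)], scores = scores)
}

#' @export
predict.etrca_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "epoched_eeg")) newdata$data else newdata
  if (is.matrix(X)) X <- array(X, dim = c(1L, nrow(X), ncol(X)))
  vapply(seq_len(dim(X)[1]),
         function(i) etrca_predict(object, X[i, , ])$label, integer(1))
}

#' Delay embedding of a trial
#'
#' Stacks `l` left-shifted copies of the trial below the original
#' (`(l+1) * N_c` rows); columns vacated by the shift are zero-filled, so
#' no access ever reads past the trial end.
#'
#' @param X trial matrix `[N_c x N_s]`.
#' @param l number of delays (`0 <= l < N_s`).
#' @param is_test kept for interface symmetry; epoched trials carry no
#'   post-window samples, so training and test trials are both zero-padded.
#' @return matrix `[(l+1)N_c x N_s]`.
#' @export
tdca_delay_embed <- function(X, l, is_test = FALSE) {
  stopifnot(is.matrix(X), l >= 0)
  ns <- ncol(X); nc <- nrow(X)
  if (l >= ns) stop("l must be smaller than the number of samples")
  out <- matrix(0, (l + 1) * nc, ns)
  for (d in 0:l) {
    rows <- d * nc + seq_len(nc)
    if (d == 0) out[rows, ] <- X
    else out[rows, seq_len(ns - d)] <- X[, (d + 1):ns, drop = FALSE]
  }
  out
}

#' Sinusoidal reference projector of one stimulus class
#'
#' Builds the reference matrix `Y_i` of sines and cosines at harmonics
#' `1..N_h` of `f_i`, orthonormalizes it by QR decomposition and returns the
#' projector `P_i = Q Q'` onto the spanned subspace (symmetric and
#' idempotent).
#'
#' @param f_i stimulus frequency (Hz).
#' @param N_h number of harmonics (`N_h * f_i < fs/2`).
#' @param N_s samples per trial.
#' @param fs sampling rate (Hz).
#' @return projector matrix `[N_s x N_s]`.
#' @export
tdca_reference_projection <- function(f_i, N_h, N_s, fs) {
  if (N_h * f_i >= fs / 2)
    stop(sprintf("harmonic %d of %g Hz aliases at fs = %g", N_h, f_i, fs))
  t <- seq_len(N_s) / fs
  Y <- do.call(rbind, lapply(seq_len(N_h), function(k)
    rbind(sin(2 * pi * k * f_i * t), cos(2 * pi * k * f_i * t))))
  qrd <- qr(t(Y))
  Q <- qr.Q(qrd)[, seq_len(qrd$rank), drop = FALSE]
  Q %*% t(Q)
}

# secondary augmentation: [X_tilde, X_tilde P]
tdca_augment <- function(X, l, P) {
  Xt <- tdca_delay_embed(X, l)
  cbind(Xt, Xt %*% P)
}

#' Fit the TDCA decoder
#'
#' Every training trial is delay-embedded (`l` delays), augmented with its
#' projection onto the class's sinusoidal reference subspace
#' (`X_a = [X~, X~ P_i]`, width `2 N_s`), and the class centers, the
#' between-class difference matrix `H_b` and within-class difference matrix
#' `H_w` are assembled; the discriminant directions are the top `K_dims`
#' generalized eigenvectors of `(S_b, S_w) = (H_b H_b', H_w H_w')` (Fisher
#' criterion). Applied per filter-bank sub-band by default, as for eTRCA.
#'
#' @param train an `epoched_eeg` with >= 2 trials per class.
#' @param stim_freqs stimulus frequency (Hz) per class, in class order.
#' @param l delay count (default 5).
#' @param N_h reference harmonics (default 5).
#' @param K_dims number of discriminant directions (default 8).
#' @param n_bands,bank,weight_scheme filter-bank settings as in
#'   [etrca_fit()]; set `use_bank = FALSE` to fit on the broadband signal
#'   only.
#' @param use_bank apply the filter bank (default TRUE).
#' @return an object of class `tdca_model`.
#' @export
tdca_fit <- function(train, stim_freqs, l = 5L, N_h = 5L, K_dims = 8L,
                     n_bands = 3L, bank = NULL,
                     weight_scheme = c("standard", "uniform"),
                     use_bank = TRUE) {
  stopifnot(inherits(train, "epoched_eeg"))
  weight_scheme <- match.arg(weight_scheme)
  classes <- sort(unique(train$labels))
  if (length(stim_freqs) != length(classes))
    stop("need one stimulus frequency per class")
  counts <- vapply(classes, function(k) sum(train$labels == k), integer(1))
  if (any(counts < 2L)) stop("TDCA needs >= 2 trials per class")
  ns <- n_samples(train)
  P <- lapply(stim_freqs, tdca_reference_projection, N_h = N_h, N_s = ns,
              fs = train$fs)
  if (!use_bank) bank <- list(NULL)
  else if (is.null(bank)) bank <- default_bank(n_bands, train$fs)

  bands <- lapply(bank, function(band) {
    filt <- if (is.null(band)) train else apply_bank_filter(train, band)
    K <- length(classes)
    centers <- vector("list", K)
    Xa_all <- vector("list", K)
    for (ci in seq_len(K)) {
      ix <- which(filt$labels == classes[ci])
      Xa_all[[ci]] <- lapply(ix, function(i)
        tdca_augment(filt$data[i, , ], l, P[[ci]]))
      centers[[ci]] <- Reduce(`+`, Xa_all[[ci]]) / length(ix)
    }
    grand <- Reduce(`+`, centers) / K
    Hb <- do.call(cbind, lapply(centers, function(C) C - grand)) / sqrt(K)
    Hw <- do.call(cbind, lapply(seq_len(K), function(ci) {
      do.call(cbind, lapply(Xa_all[[ci]], function(Xa)
        Xa - centers[[ci]]))
    })) / sqrt(K * min(counts))
    Sb <- Hb %*% t(Hb)
    Sw <- Hw %*% t(Hw)
    Wl <- geigen_leading(Sb, Sw, k = min(K_dims, nrow(Sb)))$vectors
    list(W = Wl, centers = centers, band = band)
  })
  structure(list(bands = bands, bank = bank,
                 bank_weights = if (is.null(bank[[1]])) 1
                                else fb_weights(length(bank), weight_scheme),
                 classes = classes, P = P, l = l, N_h = N_h,
                 fs = train$fs, n_samples = ns),
            class = "tdca_model")
}

#' Classify a trial with a fitted TDCA model
#'
#' The test trial is delay-embedded with zero padding, secondarily
#' augmented with each candidate class's projector `P_k`, projected by the
#' discriminant directions and correlated with that class's center;
#' sub-band scores are combined as in eTRCA.
#'
#' @param model a `tdca_model`.
#' @param x a single trial `[N_c x N_s]`.
#' @return list with 0-based `label` and per-class `scores`.
#' @export
tdca_predict <- function(model, x) {
  stopifnot(inherits(model, "tdca_model"), is.matrix(x))
  K <- length(model$classes)
  scores <- numeric(K)
  for (bi in seq_along(model$bands)) {
    b <- model$bands[[bi]]
    xf <- if (is.null(b$band)) x else filter_trial(x, b$band, model$fs)
    wgt <- model$bank_weights[bi]
    for (k in seq_len(K)) {
      Xa <- tdca_augment(xf, model$l, model$P[[k]])
      scores[k] <- scores[k] + wgt *
        safe_cor(as.vector(t(b$W) %*% Xa),
                 as.vector(t(b$W) %*% b$centers[[k]]))
    }
  }
  list(label = model$classes[which.max(scores)], scores = scores)
}

#' @export
predict.tdca_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "epoched_eeg")) newdata$data else newdata
  if (is.matrix(X)) X <- array(X, dim = c(1L, nrow(X), ncol(X)))
  vapply(seq_len(dim(X)[1]),
         function(i) tdca_predict(object, X[i, , ])$label, integer(1))
}
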