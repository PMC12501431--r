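#' Per-class averaged template
#'
#' The task-related component of a stimulus class is estimated as the
#' elementwise mean over trials: averaging N phase-locked trials leaves the
#' stimulus-locked response intact while shrinking the background EEG.
#'
#' @param trials array `[n x N_c x N_s]` (or a single `[N_c x N_s]` matrix).
#' @return template matrix `[N_c x N_s]`.
#' @export
compute_template <- function(trials) {
  if (is.matrix(trials)) return(trials)
  if (!is.array(trials) || length(dim(trials)) != 3L || dim(trials)[1L] < 1L)
    stop("`trials` must be a non-empty [n x N_c x N_s] array")
  apply(trials, c(2, 3), mean)
}

#' Background EEG of a trial
#'
#' The residual after subtracting the class template: the task-unrelated
#' component that BGMix swaps between classes. When the template averages
#' all trials of the class, residuals of that class sum to zero elementwise.
#'
#' @param trial matrix `[N_c x N_s]`.
#' @param template matrix `[N_c x N_s]`.
#' @return residual matrix `[N_c x N_s]`.
#' @export
compute_background <- function(trial, template) {
  if (!identical(dim(trial), dim(template)))
    stop("trial and template dimensions differ")
  trial - template
}

#' BGMix augmentation configuration
#'
#' @param passes list of `c(n, factor)` pairs: each pass uses `n` trials to
#'   build both the target template and the donor background, and emits
#'   `factor` generated samples per original training sample.
#' @param lam_alpha,lam_beta parameters of the Beta distribution the label
#'   mixing weight lambda is drawn from (default Beta(1,1) = uniform).
#' @param template_scope `"subset"` (templates built from the n drawn trials,
#'   the operational description) or `"all"` (templates from all class
#'   trials).
#' @param seed integer seed.
#' @return an object of class `bgmix_config`.
#' @export
bgmix_config <- function(passes = list(c(2, 40), c(3, 40)),
                         lam_alpha = 1, lam_beta = 1,
                         template_scope = c("subset", "all"), seed = 1L) {
  template_scope <- match.arg(template_scope)
  for (p in passes) {
    if (length(p) != 2L || p[1] < 2 || p[2] < 1)
      stop("each pass must be c(n >= 2, factor >= 1)")
  }
  structure(list(passes = passes, lam_alpha = lam_alpha, lam_beta = lam_beta,
                 template_scope = template_scope, seed = as.integer(seed)),
            class = "bgmix_config")
}

# Container for generated samples: data [N x N_c x N_s] plus the label pair
# and the per-sample mixing weight.
mixed_set <- function(data, y_template, y_background, lambda, fs,
                      channel_names = NULL) {
  structure(list(data = data, y_template = as.integer(y_template),
                 y_background = as.integer(y_background),
                 lambda = as.numeric(lambda), fs = fs,
                 channel_names = channel_names),
            class = "mixed_set")
}

#' @export
print.mixed_set <- function(x, ...) {
  cat(sprintf("mixed_set: %d generated samples [%d ch x %d samples]\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3]))
  invisible(x)
}

#' Generate augmented samples by background-EEG swapping
#'
#' For every original training sample (target class y) and every pass
#' `(n, factor)`: draw `n` trials of class y and average them into a
#' template; draw a donor class y' != y uniformly and `n` of its trials;
#' subtract the donor template from the donor trials to obtain `n`
#' background residuals; emit template + residual for each residual. Draws
#' repeat until `factor` samples per original trial are collected, so the
#' per-class balance of the output equals `factor x` the input balance and
#' the total generated:original ratio equals the sum of pass factors. Each
#' emitted sample carries the label pair (y, y') and a weight
#' `lambda ~ Beta(lam_alpha, lam_beta)` that enters only the training loss
#' (the waveform itself is never lambda-scaled, unlike Mixup).
#'
#' @param train an `epoched_eeg` with >= 2 classes and at least `max(n)`
#'   trials per class.
#' @param cfg a [bgmix_config()].
#' @return a `mixed_set`.
#' @export
bgmix_generate <- function(train, cfg) {
  stopifnot(inherits(train, "epoched_eeg"), inherits(cfg, "bgmix_config"))
  classes <- sort(unique(train$labels))
  if (length(classes) < 2L) stop("BGMix requires at least 2 classes")
  idx_by_class <- lapply(classes, function(k) which(train$labels == k))
  names(idx_by_class) <- as.character(classes)
  counts <- lengths(idx_by_class)
  max_n <- max(vapply(cfg$passes, function(p) p[1], numeric(1)))
  if (any(counts < max_n))
    stop(sprintf("every class needs >= %d trials for the configured passes",
                 max_n))
  nt <- n_trials(train); nc <- n_channels(train); ns <- n_samples(train)
  total <- nt * sum(vapply(cfg$passes, function(p) p[2], numeric(1)))
  out <- array(0, dim = c(total, nc, ns))
  y_t <- integer(total); y_b <- integer(total); lam <- numeric(total)

  all_templates <- NULL
  if (cfg$template_scope == "all")
    all_templates <- lapply(idx_by_class, function(ix)
      compute_template(train$data[ix, , , drop = FALSE]))

  with_seed(cfg$seed, {
    pos <- 0L
    for (p in cfg$passes) {
      n <- as.integer(p[1]); factor <- as.integer(p[2])
      for (i in seq_len(nt)) {
        y <- train$labels[i]
        made <- 0L
        while (made < factor) {
          tgt_ix <- sample(idx_by_class[[as.character(y)]], n)
          tmpl <- if (cfg$template_scope == "all") all_templates[[as.character(y)]]
                  else compute_template(train$data[tgt_ix, , , drop = FALSE])
          yp <- sample(setdiff(classes, y), 1L)
          don_ix <- sample(idx_by_class[[as.character(yp)]], n)
          don_tmpl <- if (cfg$template_scope == "all")
                        all_templates[[as.character(yp)]]
                      else compute_template(train$data[don_ix, , , drop = FALSE])
          for (j in seq_len(n)) {
            if (made >= factor) break
            res <- train$data[don_ix[j], , ] - don_tmpl
            pos <- pos + 1L; made <- made + 1L
            out[pos, , ] <- tmpl + res
            y_t[pos] <- y; y_b[pos] <- yp
            lam[pos] <- stats::rbeta(1, cfg$lam_alpha, cfg$lam_beta)
          }
        }
      }
    }
  })
  mixed_set(out, y_t, y_b, lam, train$fs, train$channel_names)
}

#' Label-mixed loss combination
#'
#' Fuses the losses of a generated sample's two labels:
#' `lam * loss_y + (1 - lam) * loss_y_prime`.
#'
#' @param loss_y,loss_y_prime scalar losses under the template label and the
#'   background-donor label.
#' @param lam mixing weight in `[0, 1]`.
#' @return scalar mixed loss.
#' @export
mixed_loss <- function(loss_y, loss_y_prime, lam) {
  if (!is.numeric(lam) || lam < 0 || lam > 1)
    stop("lam must lie in [0, 1]")
  lam * loss_y + (1 - lam) * loss_y_prime
}

#' Mixup comparator
#'
#' Classical Mixup on epoched trials: `x = lam * x_i + (1 - lam) * x_j` for
#' cross-class pairs with `lam ~ Beta(alpha, alpha)`; the same lambda mixes
#' the labels in the loss. Provided as the baseline BGMix is compared
#' against.
#'
#' @param train an `epoched_eeg` with >= 2 classes.
#' @param alpha Beta concentration parameter.
#' @param factor generated samples per original sample.
#' @param seed integer seed.
#' @return a `mixed_set`.
#' @export
mixup_generate <- function(train, alpha = 1, factor = 1L, seed = 1L) {
  stopifnot(inherits(train, "epoched_eeg"))
  classes <- sort(unique(train$labels))
  if (length(classes) < 2L) stop("Mixup requires at least 2 classes")
  nt <- n_trials(train); nc <- n_channels(train); ns <- n_samples(train)
  total <- nt * factor
  out <- array(0, dim = c(total, nc, ns))
  y_t <- integer(total); y_b <- integer(total); lam <- numeric(total)
  with_seed(seed, {
    pos <- 0L
    for (i in seq_len(nt)) {
      for (r in seq_len(factor)) {
        j <- sample(which(train$labels != train$labels[i]), 1L)
        l <- stats::rbeta(1, alpha, alpha)
        pos <- pos + 1L
        out[pos, , ] <- l * train$data[i, , ] + (1 - l) * train$data[j, , ]
        y_t[pos] <- train$labels[i]; y_b[pos] <- train$labels[j]
        lam[pos] <- l
      }
    }
  })
  mixed_set(out, y_t, y_b, lam, train$fs, train$channel_names)
}
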