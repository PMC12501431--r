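#' Training configuration
#'
#' @param lr Adam learning rate.
#' @param weight_decay decoupled weight decay applied to matrix weights.
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience: training stops once the
#'   validation loss has failed to improve for more than `patience` epochs.
#' @param seed integer seed governing shuffling, dropout and initialization.
#' @param distill optional list `(temperature, hard_weight)` enabling
#'   knowledge distillation from a teacher model (defaults temperature 5,
#'   hard/soft ratio 0.7:0.3).
#' @return an object of class `train_config`.
#' @export
train_config <- function(lr = 1e-3, weight_decay = 1e-2, batch_size = 64L,
                         max_epochs = 500L, patience = 20L, seed = 1L,
                         distill = NULL) {
  if (patience < 1L) stop("patience must be >= 1")
  if (!is.null(distill)) {
    distill$temperature <- distill$temperature %||% 5
    distill$hard_weight <- distill$hard_weight %||% 0.7
    if (distill$temperature <= 0) stop("distill temperature must be > 0")
    if (distill$hard_weight < 0 || distill$hard_weight > 1)
      stop("distill hard_weight must lie in [0, 1]")
  }
  structure(list(lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 distill = distill),
            class = "train_config")
}

#' Early-stopping rule
#'
#' Stops once the running minimum of the validation loss has not improved
#' for more than `patience` epochs; the best epoch is the first occurrence
#' of the minimum.
#'
#' @param val_losses numeric vector of per-epoch validation losses.
#' @param patience allowed epochs without improvement.
#' @return list with `stop` (flag) and `best` (epoch index of the minimum).
#' @export
early_stop_check <- function(val_losses, patience) {
  if (length(val_losses) == 0L) stop("val_losses must be nonempty")
  best <- which.min(val_losses)
  list(stop = (length(val_losses) - best) > patience, best = best)
}

#' Knowledge-distillation loss
#'
#' `hard_weight * CE(student, hard_label) + (1 - hard_weight) * T^2 *
#' KL(softmax(teacher/T) || softmax(student/T))`. The `T^2` factor keeps the
#' soft-gradient magnitude comparable across temperatures.
#'
#' @param student_logits,teacher_logits numeric logit vectors.
#' @param hard_label 0-based true class.
#' @param temperature softening temperature (> 0), default 5.
#' @param hard_weight weight of the hard-label term in `[0,1]`, default 0.7.
#' @return scalar loss.
#' @export
distill_loss <- function(student_logits, teacher_logits, hard_label,
                         temperature = 5, hard_weight = 0.7) {
  if (temperature <= 0) stop("temperature must be > 0")
  if (hard_weight < 0 || hard_weight > 1)
    stop("hard_weight must lie in [0, 1]")
  sm <- function(z) { z <- z - max(z); exp(z) / sum(exp(z)) }
  ps <- sm(student_logits)
  hard <- -log(ps[hard_label + 1L] + 1e-12)
  pt_T <- sm(teacher_logits / temperature)
  ps_T <- sm(student_logits / temperature)
  kl <- sum(pt_T * (log(pt_T + 1e-12) - log(ps_T + 1e-12)))
  hard_weight * hard + (1 - hard_weight) * temperature^2 * kl
}

# gradient of the batched distillation loss wrt student logits
distill_grad <- function(student_logits, teacher_logits, y, temperature,
                         hard_weight) {
  B <- nrow(student_logits)
  P <- softmax_rows(student_logits)
  iy <- cbind(seq_len(B), y + 1L)
  hard_loss <- mean(-log(P[iy] + 1e-12))
  tgt <- matrix(0, B, ncol(student_logits)); tgt[iy] <- 1
  dhard <- (P - tgt) / B
  psT <- softmax_rows(student_logits / temperature)
  ptT <- softmax_rows(teacher_logits / temperature)
  soft_loss <- mean(rowSums(ptT * (log(ptT + 1e-12) - log(psT + 1e-12)))) *
    temperature^2
  dsoft <- temperature * (psT - ptT) / B
  list(loss = hard_weight * hard_loss + (1 - hard_weight) * soft_loss,
       dlogits = hard_weight * dhard + (1 - hard_weight) * dsoft)
}

adam_init <- function(w)
  list(m = lapply(w, function(x) x * 0), v = lapply(w, function(x) x * 0),
       t = 0L)

adam_step <- function(w, g, st, lr, weight_decay, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(g)) {
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g[[nm]]
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g[[nm]]^2
    mhat <- st$m[[nm]] / (1 - b1^st$t)
    vhat <- st$v[[nm]] / (1 - b2^st$t)
    upd <- mhat / (sqrt(vhat) + eps)
    if (weight_decay > 0 && is.matrix(w[[nm]]))
      upd <- upd + weight_decay * w[[nm]]
    w[[nm]] <- w[[nm]] - lr * upd
  }
  list(w = w, st = st)
}

# Assemble (X, y, y', lam) training arrays from an epoched_eeg or mixed_set.
as_training_set <- function(train) {
  if (inherits(train, "mixed_set")) {
    list(X = train$data, y = train$y_template, yp = train$y_background,
         lam = train$lambda)
  } else if (inherits(train, "epoched_eeg")) {
    list(X = train$data, y = train$labels, yp = train$labels,
         lam = rep(1, n_trials(train)))
  } else stop("train must be an epoched_eeg or mixed_set")
}

#' Train an AETF model
#'
#' Minibatch Adam with the two-term mixed-label cross-entropy (generated
#' samples contribute `lam * CE(y) + (1-lam) * CE(y')`), per-epoch
#' validation loss on original (non-augmented) trials, early stopping, and
#' restoration of the best-validation-loss weights. When `teacher` is given
#' together with `cfg$distill`, the loss becomes the distillation
#' combination of hard labels and temperature-softened teacher targets.
#'
#' @param model an initialized `aetf_model` (its weights are the starting
#'   point, enabling fine-tuning).
#' @param train an `epoched_eeg` or a `mixed_set` of generated samples.
#' @param val an `epoched_eeg` used for validation loss.
#' @param cfg a [train_config()].
#' @param teacher optional teacher `aetf_model` for distillation.
#' @param verbose print per-epoch losses.
#' @return the trained `aetf_model`, with a `history` element (per-epoch
#'   train/val losses and the best epoch).
#' @export
train_aetf <- function(model, train, val, cfg = train_config(),
                       teacher = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "aetf_model"), inherits(cfg, "train_config"))
  ts <- as_training_set(train)
  n <- dim(ts$X)[1]
  st <- adam_init(model$w)
  best_w <- model$w
  best_bn <- list(mean = model$bn_mean, var = model$bn_var)
  tr_hist <- numeric(0); va_hist <- numeric(0)
  momentum <- 0.1
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        Xb <- ts$X[idx, , , drop = FALSE]
        fw <- aetf_forward_batch(model, Xb, training = TRUE,
                                 keep_cache = TRUE)
        model$bn_mean <- (1 - momentum) * model$bn_mean +
          momentum * fw$cache$mu
        model$bn_var <- (1 - momentum) * model$bn_var +
          momentum * fw$cache$vv
        if (!is.null(teacher) && !is.null(cfg$distill)) {
          tlog <- aetf_forward_batch(teacher, Xb)$logits
          gr <- distill_grad(fw$logits, tlog, ts$y[idx],
                             cfg$distill$temperature,
                             cfg$distill$hard_weight)
        } else {
          gr <- mixed_ce_grad(fw$logits, ts$y[idx], ts$yp[idx], ts$lam[idx])
        }
        grads <- aetf_backward_batch(model, fw$cache, gr$dlogits)
        upd <- adam_step(model$w, grads, st, cfg$lr, cfg$weight_decay)
        model$w <- upd$w; st <- upd$st
        ep_loss <- ep_loss + gr$loss; nb <- nb + 1L
      }
      vlog <- aetf_forward_batch(model, val$data)$logits
      vloss <- ce_loss(vlog, val$labels)
      tr_hist <- c(tr_hist, ep_loss / nb)
      va_hist <- c(va_hist, vloss)
      es <- early_stop_check(va_hist, cfg$patience)
      if (es$best == epoch) {
        best_w <- model$w
        best_bn <- list(mean = model$bn_mean, var = model$bn_var)
      }
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                        ep_loss / nb, vloss))
      if (es$stop) break
    }
  })
  model$w <- best_w
  model$bn_mean <- best_bn$mean
  model$bn_var <- best_bn$var
  model$history <- list(train_loss = tr_hist, val_loss = va_hist,
                        best_epoch = which.min(va_hist))
  model
}

#' Two-stage training protocol
#'
#' Stage 1 trains a single intersubject model on data pooled from all
#' subjects (no augmentation). Stage 2 clones its weights for each subject
#' and fine-tunes on that subject's trials; BGMix augmentation, if
#' requested, is applied only here: the fine-tuning training set consists of
#' samples generated from the subject's original train + validation trials,
#' while the concatenated original train + validation trials become the new
#' validation set. The best-validation-loss checkpoint is kept at both
#' stages.
#'
#' @param model_factory function `(n_channels, n_samples, n_classes, fs)`
#'   returning a fresh `aetf_model` (initialization included).
#' @param all_subjects list of `epoched_eeg`, one per subject.
#' @param splits list of fold definitions (one per subject), each with
#'   `train` and `val` trial indices — e.g. one fold of
#'   [kfold_trial_split()].
#' @param cfg a [train_config()].
#' @param aug optional [bgmix_config()]; BGMix runs only in stage 2.
#' @param stage1_epochs optional cap on stage-1 epochs (defaults to
#'   `cfg$max_epochs`).
#' @return list with `intersubject` (the stage-1 model) and `subjects`
#'   (one fine-tuned `aetf_model` per subject; weights not shared).
#' @export
train_two_stage <- function(model_factory, all_subjects, splits,
                            cfg = train_config(), aug = NULL,
                            stage1_epochs = NULL) {
  if (length(all_subjects) == 0L) stop("empty subject list")
  stopifnot(length(splits) == length(all_subjects))
  e1 <- all_subjects[[1L]]
  pooled_train <- do.call(rbind3, lapply(seq_along(all_subjects), function(i)
    subset_trials(all_subjects[[i]], splits[[i]]$train)))
  pooled_val <- do.call(rbind3, lapply(seq_along(all_subjects), function(i)
    subset_trials(all_subjects[[i]], splits[[i]]$val)))
  model <- model_factory(n_channels(e1), n_samples(e1), e1$n_classes, e1$fs)
  cfg1 <- cfg
  if (!is.null(stage1_epochs)) cfg1$max_epochs <- as.integer(stage1_epochs)
  inter <- train_aetf(model, pooled_train, pooled_val, cfg1)
  subjects <- lapply(seq_along(all_subjects), function(i) {
    subj <- all_subjects[[i]]
    tr <- subset_trials(subj, splits[[i]]$train)
    va <- subset_trials(subj, splits[[i]]$val)
    m <- inter                      # weight copy; R lists are copy-on-write
    m$history <- NULL
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i
    if (is.null(aug)) {
      train_aetf(m, tr, va, cfg_i)
    } else {
      trva <- concat_epochs(tr, va)
      gen <- bgmix_generate(trva, aug)
      train_aetf(m, gen, trva, cfg_i)
    }
  })
  list(intersubject = inter, subjects = subjects)
}

# Concatenate two epoched sets with identical geometry.
#' Concatenate epoched sets trial-wise
#' @param a,b `epoched_eeg` objects with identical channel/sample geometry.
#' @return an `epoched_eeg` holding the trials of `a` then `b`.
#' @export
concat_epochs <- function(a, b) {
  stopifnot(inherits(a, "epoched_eeg"), inherits(b, "epoched_eeg"),
            n_channels(a) == n_channels(b), n_samples(a) == n_samples(b),
            a$fs == b$fs)
  dat <- array(0, dim = c(n_trials(a) + n_trials(b), n_channels(a),
                          n_samples(a)))
  dat[seq_len(n_trials(a)), , ] <- a$data
  dat[n_trials(a) + seq_len(n_trials(b)), , ] <- b$data
  epoched_eeg(dat, c(a$labels, b$labels), a$fs, a$channel_names,
              a$subject_id, n_classes = max(a$n_classes, b$n_classes))
}

rbind3 <- function(...) Reduce(concat_epochs, list(...))
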