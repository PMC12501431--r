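test_that("early stopping triggers after patience epochs without improvement", {
  # strictly decreasing: never stops, best = last
  r <- early_stop_check(c(5, 4, 3, 2), patience = 2)
  expect_false(r$stop); expect_equal(r$best, 4)
  # worked trace: [3,2,4,4,4], patience 2 -> still going at epoch 4,
  # stops at epoch 5, best epoch 2
  expect_false(early_stop_check(c(3, 2, 4, 4), 2)$stop)
  r2 <- early_stop_check(c(3, 2, 4, 4, 4), 2)
  expect_true(r2$stop); expect_equal(r2$best, 2)
  # constant losses: best is the first epoch; stops p+1 epochs after it
  p <- 3
  expect_false(early_stop_check(rep(1, p + 1), p)$stop)
  rc <- early_stop_check(rep(1, p + 2), p)
  expect_true(rc$stop); expect_equal(rc$best, 1)
  expect_error(early_stop_check(numeric(0), 2), "nonempty")
})

test_that("distillation loss combines hard and temperature-softened terms", {
  sl <- c(2, -1); tl <- c(1.5, 0.5)
  # hard_weight 1: plain cross-entropy
  expect_equal(distill_loss(sl, tl, 0, temperature = 2, hard_weight = 1),
               -log(exp(2) / (exp(2) + exp(-1))), tolerance = 1e-9)
  # teacher == student: soft term vanishes
  expect_equal(distill_loss(sl, sl, 0, temperature = 5, hard_weight = 0), 0,
               tolerance = 1e-9)
  # 2-class hand computation at T = 2
  sm <- function(z) exp(z - max(z)) / sum(exp(z - max(z)))
  ps <- sm(sl); psT <- sm(sl / 2); ptT <- sm(tl / 2)
  hand <- 0.7 * (-log(ps[1])) +
    0.3 * 4 * sum(ptT * (log(ptT) - log(psT)))
  expect_equal(distill_loss(sl, tl, 0, temperature = 2, hard_weight = 0.7),
               hand, tolerance = 1e-6)
  expect_error(distill_loss(sl, tl, 0, temperature = 0), "temperature")
  expect_error(distill_loss(sl, tl, 0, hard_weight = 1.2), "hard_weight")
})

test_that("balanced accuracy averages per-class recalls", {
  expect_equal(balanced_accuracy(diag(5) * 3), 1.0)
  cm <- rbind(c(1, 1), c(0, 4))          # recalls 0.5 and 1.0
  expect_equal(balanced_accuracy(cm), 0.75)
  # everything predicted into one class with balanced truth -> 1/K
  K <- 4
  cm2 <- matrix(0, K, K); cm2[, 1] <- 5
  expect_equal(balanced_accuracy(cm2), 1 / K)
  cm3 <- diag(3); cm3[2, ] <- 0
  expect_error(balanced_accuracy(cm3), "test sample")
})

test_that("ITR follows the closed form with its boundary conventions", {
  # chance accuracy gives exactly zero bits
  for (N in c(2, 12, 40)) expect_equal(itr(N, 1 / N, 1), 0)
  # perfect accuracy: 60/T * log2(N)
  expect_equal(itr(40, 1, 1), 60 * log2(40), tolerance = 1e-12)
  expect_equal(itr(40, 1, 1), 319.3, tolerance = 0.05)
  # 12 targets, 90% accuracy, 0.7 s per selection
  expect_equal(itr(12, 0.9, 0.7), 237.43, tolerance = 0.05)
  # below-chance floored to zero
  expect_equal(itr(12, 0.01, 1), 0)
  # monotone: increasing in P on (1/N, 1], decreasing in T
  ps <- seq(0.2, 1, by = 0.05)
  vals <- vapply(ps, function(p) itr(5, p, 1), numeric(1))
  expect_true(all(diff(vals) > 0))
  ts <- seq(0.3, 3, by = 0.1)
  vt <- vapply(ts, function(T2) itr(5, 0.9, T2), numeric(1))
  expect_true(all(diff(vt) < 0))
  expect_error(itr(1, 0.5, 1), "N")
  expect_error(itr(12, 0.5, 0), "T_sec")
})

test_that("evaluate accumulates fold confusions into BA and ITR", {
  e <- tiny_epochs(n_classes = 3, trials_per_class = 4, n_samples = 50,
                   fs = 100)
  sp <- kfold_trial_split(e, seed = 2)
  # a mock perfect classifier (predicts the hidden label by lookup)
  perfect <- structure(list(truth = e$labels), class = "mock_perfect")
  registerS3method("predict", "mock_perfect",
                   function(object, newdata, ...) newdata$labels)
  models <- rep(list(perfect), length(sp$folds))
  rep1 <- evaluate(models, sp, e, selection_time_overhead = 0.5)
  expect_equal(rep1$balanced_accuracy, 1.0)
  expect_equal(rep1$selection_time, 1.0)       # 0.5 s window + 0.5 s overhead
  expect_equal(rep1$itr, 60 * log2(3))
  # confusion row sums equal per-class test counts (one per class per fold)
  expect_equal(rowSums(rep1$confusion), rep(length(sp$folds), 3))
  # a fixed classifier always answering class 0 scores 1/K
  fixed <- structure(list(), class = "mock_fixed")
  registerS3method("predict", "mock_fixed",
                   function(object, newdata, ...) rep(0L, n_trials(newdata)))
  rep2 <- evaluate(rep(list(fixed), length(sp$folds)), sp, e)
  expect_equal(rep2$balanced_accuracy, 1 / 3)
  expect_equal(rep2$itr, 0)
  expect_error(evaluate(models[1:2], sp, e), "folds")
})

test_that("training is deterministic and restores the best checkpoint", {
  e <- synth_dataset(synth_config(n_classes = 3,
                                  stim_freqs = c(9, 11, 13),
                                  stim_phases = c(0, pi / 2, pi),
                                  n_harmonics = 2, n_channels = 3,
                                  n_trials_per_class = 4, fs = 100,
                                  trial_len = 0.5, snr_db = 5))
  tr <- subset_trials(e, which(seq_len(12) %% 4 != 0))
  va <- subset_trials(e, which(seq_len(12) %% 4 == 0))
  acfg <- aetf_config(3, 50, 3, 100, n_spatial = 4, n_freq_filters = 2,
                      n_layers = 1, n_heads = 2, dropout = 0.1)
  tcfg <- train_config(max_epochs = 5, patience = 3, batch_size = 4, seed = 2)
  m1 <- train_aetf(aetf_init(acfg, 1), tr, va, tcfg)
  m2 <- train_aetf(aetf_init(acfg, 1), tr, va, tcfg)
  expect_identical(m1$w, m2$w)
  expect_equal(m1$history$val_loss, m2$history$val_loss)
  expect_equal(m1$history$best_epoch, which.min(m1$history$val_loss))
  expect_true(all(is.finite(m1$history$train_loss)))
})

test_that("two-stage training clones intersubject weights per subject", {
  mk_subj <- function(seed) synth_dataset(synth_config(
    n_classes = 3, stim_freqs = c(9, 11, 13),
    stim_phases = c(0, pi / 2, pi), n_harmonics = 2, n_channels = 3,
    n_trials_per_class = 4, fs = 100, trial_len = 0.5, snr_db = 5,
    mixing_seed = seed, noise_seed = seed + 50))
  subs <- list(mk_subj(1), mk_subj(2))
  splits <- lapply(subs, function(s) kfold_trial_split(s, 1)$folds[[1]])
  factory <- function(nc, ns, nk, fs)
    aetf_init(aetf_config(nc, ns, nk, fs, n_spatial = 4,
                          n_freq_filters = 2, n_layers = 1, n_heads = 2,
                          dropout = 0), seed = 7)
  cfg <- train_config(max_epochs = 3, patience = 3, batch_size = 8, seed = 3)
  # lr = 0 in stage 2 leaves the intersubject weights untouched: the
  # subject models must then equal the stage-1 model exactly
  cfg0 <- cfg; cfg0$lr <- 0
  out0 <- train_two_stage(factory, subs, splits, cfg0)
  expect_identical(out0$subjects[[1]]$w, out0$intersubject$w)
  expect_identical(out0$subjects[[2]]$w, out0$intersubject$w)
  # with a real learning rate the subjects adapt independently
  out <- train_two_stage(factory, subs, splits, cfg)
  expect_false(identical(out$subjects[[1]]$w, out$subjects[[2]]$w))
  # mutating one model leaves the other unchanged (no shared storage)
  w2 <- out$subjects[[2]]$w$W_sp
  out$subjects[[1]]$w$W_sp[] <- 0
  expect_identical(out$subjects[[2]]$w$W_sp, w2)
  # augmentation only in stage 2: generated training set has
  # sum(factors) * |train + val| samples per subject (checked via bgmix)
  aug <- bgmix_config(passes = list(c(2, 3)), seed = 1)
  trva <- concat_epochs(subset_trials(subs[[1]], splits[[1]]$train),
                        subset_trials(subs[[1]], splits[[1]]$val))
  expect_equal(dim(bgmix_generate(trva, aug)$data)[1],
               3 * n_trials(trva))
  out_aug <- train_two_stage(factory, subs, splits, cfg, aug = aug)
  expect_length(out_aug$subjects, 2)
  expect_error(train_two_stage(factory, list(), list(), cfg), "empty")
})

test_that("a distilled student learns from teacher logits", {
  e <- synth_dataset(synth_config(n_classes = 3, stim_freqs = c(9, 11, 13),
                                  stim_phases = c(0, pi / 2, pi),
                                  n_harmonics = 2, n_channels = 3,
                                  n_trials_per_class = 4, fs = 100,
                                  trial_len = 0.5, snr_db = 5))
  tr <- subset_trials(e, 1:9); va <- subset_trials(e, 10:12)
  tcfg_cls <- aetf_config(3, 50, 3, 100, n_spatial = 4, n_freq_filters = 2,
                          n_layers = 2, n_heads = 2, dropout = 0)
  teacher <- train_aetf(aetf_init(tcfg_cls, 1), tr, va,
                        train_config(max_epochs = 3, patience = 3,
                                     batch_size = 4, seed = 1))
  scfg <- make_student(tcfg_cls)
  dcfg <- train_config(max_epochs = 3, patience = 3, batch_size = 4,
                       seed = 2, distill = list())
  expect_equal(dcfg$distill$temperature, 5)
  expect_equal(dcfg$distill$hard_weight, 0.7)
  student <- train_aetf(aetf_init(scfg, 2), tr, va, dcfg, teacher = teacher)
  expect_lt(aetf_n_params(student), aetf_n_params(teacher))
  expect_length(predict(student, va), 3)
  expect_true(all(is.finite(student$history$train_loss)))
})
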