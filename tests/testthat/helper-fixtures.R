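# Shared fixtures, built in code.

# Tiny deterministic epoched set with arbitrary (non-SSVEP) content.
tiny_epochs <- function(n_classes = 3L, trials_per_class = 4L,
                        n_channels = 4L, n_samples = 20L, fs = 100,
                        seed = 42L) {
  n <- n_classes * trials_per_class
  dat <- array(0, dim = c(n, n_channels, n_samples))
  set.seed(seed)
  dat[] <- rnorm(length(dat))
  labels <- rep(seq_len(n_classes) - 1L, each = trials_per_class)
  epoched_eeg(dat, labels, fs)
}

# Confusion matrix from 0-based truth/prediction vectors.
confusion_from <- function(truth, pred, K) {
  cm <- matrix(0L, K, K)
  for (i in seq_along(truth))
    cm[truth[i] + 1L, pred[i] + 1L] <- cm[truth[i] + 1L, pred[i] + 1L] + 1L
  cm
}

# Small synthetic SSVEP set shared by decoder tests (fs high enough for the
# default filter bank).
decoder_synth <- function(snr_db = 10, n_classes = 12L,
                          trials_per_class = 6L, seed = 1L) {
  synth_dataset(synth_config(
    n_classes = n_classes, n_trials_per_class = trials_per_class,
    snr_db = snr_db, mixing_seed = seed, noise_seed = seed + 1L))
}

# Balanced per-class assignment used by the AETF experiments:
# 3 train + 1 val per class, remainder test.
split_3_1_rest <- function(e, seed) {
  set.seed(seed)
  tr <- c(); va <- c(); te <- c()
  for (k in sort(unique(e$labels))) {
    ix <- sample(which(e$labels == k))
    tr <- c(tr, ix[1:3]); va <- c(va, ix[4]); te <- c(te, ix[-(1:4)])
  }
  list(train = tr, val = va, test = te)
}

# One run of the small-sample AETF experiment: tiny 1-layer model
# (d_model 32) on 6-class synthetic data, 3 training trials per class,
# with or without BGMix. Returns held-out balanced accuracy.
small_sample_aetf_run <- function(seed, use_bgmix, encoder = TRUE) {
  scfg <- synth_config(
    n_classes = 6L, stim_freqs = seq(8, by = 1.2, length.out = 6),
    stim_phases = (seq(0, by = 0.5 * pi, length.out = 6)) %% (2 * pi),
    n_harmonics = 2L, n_channels = 4L, n_trials_per_class = 8L,
    fs = 100, trial_len = 0.5, snr_db = -2,
    mixing_seed = 100L + seed, noise_seed = 200L + seed)
  e <- synth_dataset(scfg)
  sp <- split_3_1_rest(e, seed)
  trn <- subset_trials(e, sp$train)
  val <- subset_trials(e, sp$val)
  te <- subset_trials(e, sp$test)
  acfg <- aetf_config(4L, 50L, 6L, 100, n_spatial = 8L, n_freq_filters = 4L,
                      n_layers = 1L, n_heads = 4L, dropout = 0.1,
                      encoder = encoder)
  model <- aetf_init(acfg, seed = seed)
  tcfg <- train_config(lr = 1e-3, weight_decay = 1e-2, batch_size = 32L,
                       max_epochs = 40L, patience = 6L, seed = seed)
  fit <- if (use_bgmix) {
    trva <- concat_epochs(trn, val)
    gen <- bgmix_generate(trva, bgmix_config(passes = list(c(2, 10)),
                                             seed = seed))
    train_aetf(model, gen, trva, tcfg)
  } else {
    train_aetf(model, trn, val, tcfg)
  }
  pred <- predict(fit, te)
  balanced_accuracy(confusion_from(te$labels, pred, 6L))
}
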