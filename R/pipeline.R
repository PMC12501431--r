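# YAML-configured pipeline: synth -> preprocess -> split -> fit -> evaluate.

pipeline_schema <- list(
  seed = c("integer"),
  data = c("synth", "path", "format"),
  filter = c("low_hz", "high_hz", "order", "ripple_db", "zero_phase"),
  window = c("t_start", "t_len"),
  channels = NULL,                 # plain list of names
  method = c("type", "n_bands", "l", "n_h", "k_dims", "use_bank",
             "n_spatial", "n_freq_filters", "n_layers", "dropout",
             "encoder"),
  augment = c("method", "passes", "alpha", "factor", "lam_alpha",
              "lam_beta", "template_scope"),
  training = c("lr", "weight_decay", "batch_size", "max_epochs", "patience"),
  evaluation = c("selection_time_overhead")
)

validate_config <- function(cfg) {
  unknown <- setdiff(names(cfg), names(pipeline_schema))
  if (length(unknown))
    stop(sprintf("unknown config section(s): %s",
                 paste(unknown, collapse = ", ")))
  for (sec in names(cfg)) {
    allowed <- pipeline_schema[[sec]]
    if (is.null(allowed)) next
    if (sec == "data" && !is.null(cfg$data$synth)) next  # nested synth keys
    bad <- setdiff(names(cfg[[sec]]), allowed)
    if (length(bad))
      stop(sprintf("unknown key(s) in section '%s': %s", sec,
                   paste(bad, collapse = ", ")))
  }
  if (is.null(cfg$data))
    stop("config must contain a 'data' section")
  if (is.null(cfg$method$type) ||
      !cfg$method$type %in% c("etrca", "tdca", "aetf"))
    stop("method.type must be one of etrca / tdca / aetf")
  invisible(TRUE)
}

load_pipeline_data <- function(dcfg, seed) {
  if (!is.null(dcfg$synth)) {
    s <- dcfg$synth
    args <- s[setdiff(names(s), c())]
    args$mixing_seed <- s$mixing_seed %||% seed
    args$noise_seed <- s$noise_seed %||% (seed + 1L)
    cfg <- do.call(synth_config, args)
    list(epochs = synth_dataset(cfg), synth_cfg = cfg)
  } else {
    list(epochs = load_epochs(dcfg$path, dcfg$format %||% "auto"),
         synth_cfg = NULL)
  }
}

#' Run the full decoding pipeline from a YAML config
#'
#' Loads or synthesizes epoched data, optionally band-passes / crops /
#' selects channels, builds the trial-level K-fold plan, fits the requested
#' decoder per fold (eTRCA, TDCA or AETF, the latter optionally with BGMix
#' or Mixup augmentation), and evaluates balanced accuracy and ITR on the
#' held-out trials. The report, the echoed config and the seed are written
#' to `out_dir` as JSON, so a run directory is self-describing and
#' reproducible.
#'
#' @param config_path path to the YAML run configuration.
#' @param out_dir directory for the report and config echo (default: a
#'   fresh temporary directory).
#' @param dry_run validate the configuration and return without computing.
#' @return the `eval_report` (invisibly `NULL` for dry runs).
#' @export
run_pipeline <- function(config_path, out_dir = NULL, dry_run = FALSE) {
  cfg <- yaml::read_yaml(config_path)
  validate_config(cfg)
  if (dry_run) return(invisible(NULL))
  seed <- as.integer(cfg$seed %||% 1L)
  if (is.null(out_dir)) out_dir <- tempfile("ssvepmix-run-")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  dat <- load_pipeline_data(cfg$data, seed)
  e <- dat$epochs
  if (!is.null(cfg$channels)) e <- select_channels(e, unlist(cfg$channels))
  if (!is.null(cfg$filter))
    e <- bandpass(e, do.call(filter_spec, cfg$filter))
  if (!is.null(cfg$window))
    e <- crop_window(e, cfg$window$t_start %||% 0, cfg$window$t_len)

  split <- kfold_trial_split(e, seed = seed)
  m <- cfg$method
  models <- lapply(seq_along(split$folds), function(f) {
    fold <- split$folds[[f]]
    tr <- subset_trials(e, sort(c(fold$train, fold$val)))
    if (m$type == "etrca") {
      etrca_fit(tr, n_bands = m$n_bands %||% 3L)
    } else if (m$type == "tdca") {
      freqs <- dat$synth_cfg$stim_freqs
      if (is.null(freqs)) stop("tdca requires synthetic data (known freqs)")
      tdca_fit(tr, freqs, l = m$l %||% 5L, N_h = m$n_h %||% 5L,
               K_dims = m$k_dims %||% 8L, n_bands = m$n_bands %||% 3L,
               use_bank = m$use_bank %||% TRUE)
    } else {
      acfg <- aetf_config(
        n_channels(e), n_samples(e), e$n_classes, e$fs,
        n_spatial = m$n_spatial %||% (2L * n_channels(e)),
        n_freq_filters = m$n_freq_filters %||% 8L,
        n_layers = m$n_layers %||% 2L,
        dropout = m$dropout %||% 0.1,
        encoder = m$encoder %||% TRUE)
      model <- aetf_init(acfg, seed = seed + f)
      tcfg <- do.call(train_config,
                      c(cfg$training %||% list(), list(seed = seed + f)))
      trn <- subset_trials(e, fold$train)
      val <- subset_trials(e, fold$val)
      if (!is.null(cfg$augment)) {
        trva <- concat_epochs(trn, val)
        gen <- if ((cfg$augment$method %||% "bgmix") == "mixup") {
          mixup_generate(trva, alpha = cfg$augment$alpha %||% 1,
                         factor = cfg$augment$factor %||% 10L,
                         seed = seed + f)
        } else {
          passes <- lapply(cfg$augment$passes %||% list(c(2, 10)), unlist)
          bgmix_generate(trva, bgmix_config(
            passes = passes,
            lam_alpha = cfg$augment$lam_alpha %||% 1,
            lam_beta = cfg$augment$lam_beta %||% 1,
            template_scope = cfg$augment$template_scope %||% "subset",
            seed = seed + f))
        }
        train_aetf(model, gen, trva, tcfg)
      } else {
        train_aetf(model, trn, val, tcfg)
      }
    }
  })
  report <- evaluate(models, split, e,
                     cfg$evaluation$selection_time_overhead %||% 0.5)
  jsonlite::write_json(
    list(balanced_accuracy = report$balanced_accuracy, itr = report$itr,
         selection_time = report$selection_time,
         fold_accuracy = report$fold_accuracy,
         confusion = report$confusion, seed = seed,
         config = cfg, package_version = as.character(
           utils::packageVersion("ssvepmix"))),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  report
}
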