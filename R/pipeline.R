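#' Pipeline run configuration
#'
#' Serializable configuration bundling every stage's settings. Two
#' presets are provided: `"replication"` pins the full-scale settings
#' (69 subjects, 90 epochs, batch 240, 9000 hidden ELM neurons) and
#' `"desk"` scales the cohort and training down for interactive use
#' (8 subjects, 20 epochs, 1000 hidden neurons).
#'
#' @param preset `"replication"` or `"desk"`.
#' @param ... Named overrides of any field.
#' @return An object of class `run_config`.
#' @export
run_config <- function(preset = c("replication", "desk"), ...) {
  preset <- match.arg(preset)
  base <- list(
    preset = preset,
    n_subjects = 69, n_sessions = 3,
    signature = "strong", noise_scale = 1, subject_gain_spread = 0.25,
    sampler = "gaussian",
    epochs = 90, batch_size = 240, learning_rate = 1e-3,
    grad_decay = 0.99, dropout_p = 0.5,
    elm_hidden = 9000,
    protocol = "splits", n_repeats = 3, band = "broadband",
    master_seed = 1
  )
  if (preset == "desk") {
    base$n_subjects <- 8; base$epochs <- 20; base$elm_hidden <- 1000
    base$n_repeats <- 1; base$batch_size <- 60
  }
  over <- list(...)
  bad <- setdiff(names(over), names(base))
  if (length(bad) > 0) stop("unknown config field(s): ",
                            paste(bad, collapse = ", "))
  cfg <- modifyList(base, over)
  valid_bands <- c("broadband", names(RHYTHM_BANDS))
  if (!cfg$band %in% valid_bands) {
    stop("invalid band '", cfg$band, "'; choose one of ",
         paste(valid_bands, collapse = ", "))
  }
  if (!cfg$protocol %in% c("splits", "loso")) {
    stop("protocol must be 'splits' or 'loso'")
  }
  structure(cfg, class = "run_config")
}

#' Save / load a run configuration
#'
#' YAML round-trip: `load_run_config(save_run_config(cfg, f))` equals
#' `cfg`.
#'
#' @param config A `run_config`.
#' @param path File path.
#' @return `save_run_config` returns `path` invisibly;
#'   `load_run_config` returns the `run_config`.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

config_hash <- function(config) {
  s <- paste(names(config), vapply(config, paste, character(1),
                                   collapse = ","),
             sep = "=", collapse = ";")
  # small stable polynomial hash, hex-encoded
  h <- 0
  for (ch in utf8ToInt(s)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Run the full pipeline
#'
#' Orchestrates simulate -> preprocess -> balance -> evaluate for a
#' `run_config`, writing stage artifacts (cohort and dataset caches,
#' metrics JSON, run manifest) under `out_dir`. Completed stages are
#' skipped on re-run when the config hash matches, unless
#' `force = TRUE`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @param force Recompute all stages even if cached.
#' @return Invisibly, a list with the `protocol_result` and paths of
#'   the written artifacts.
#' @export
run_pipeline <- function(config, out_dir, force = FALSE) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- function(name) file.path(out_dir, paste0(name, "-", hash,
                                                    ".rds"))
  log_msg <- function(...) message("[memoraffect] ", ...)

  ds_path <- stamp("dataset")
  if (!force && file.exists(ds_path)) {
    log_msg("stage preprocess: cached, skipping")
    dataset <- readRDS(ds_path)
  } else {
    log_msg("stage simulate: ", config$n_subjects, " subjects")
    protocol <- protocol_config(n_subjects = config$n_subjects,
                                n_sessions = config$n_sessions)
    sig <- signature_preset(config$signature,
                            noise_scale = config$noise_scale,
                            subject_gain_spread = config$subject_gain_spread)
    cohort <- generate_cohort(protocol, sig,
                              master_seed = config$master_seed,
                              sampler = config$sampler)
    log_msg("stage preprocess")
    dataset <- preprocess_cohort(cohort)
    dataset <- balance_classes(dataset, seed = config$master_seed)
    if (config$band != "broadband") {
      dataset <- rhythm_datasets(dataset, config$band)[[config$band]]
    }
    saveRDS(dataset, ds_path)
  }

  res_path <- stamp("result")
  if (!force && file.exists(res_path)) {
    log_msg("stage evaluate: cached, skipping")
    result <- readRDS(res_path)
  } else {
    log_msg("stage evaluate: protocol ", config$protocol)
    cfg <- crnn_config(epochs = config$epochs,
                       batch_size = config$batch_size,
                       learning_rate = config$learning_rate,
                       grad_decay = config$grad_decay,
                       dropout_p = config$dropout_p,
                       seed = config$master_seed)
    result <- if (config$protocol == "splits") {
      random_split_protocol(dataset, cfg, elm_hidden = config$elm_hidden,
                            n_repeats = config$n_repeats,
                            seed = config$master_seed)
    } else {
      loso_protocol(dataset, cfg, elm_hidden = config$elm_hidden,
                    seed = config$master_seed)
    }
    saveRDS(result, res_path)
  }

  metrics_path <- file.path(out_dir, "metrics.json")
  jsonlite::write_json(list(
    config_hash = hash,
    config = unclass(config),
    protocol = result$protocol,
    runs = result$runs,
    mean_accuracy = result$mean_accuracy,
    sd_accuracy = result$sd_accuracy
  ), metrics_path, auto_unbox = TRUE, digits = NA)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(config_hash = hash,
                            artifacts = c(ds_path, res_path,
                                          metrics_path)),
                       manifest_path, auto_unbox = TRUE)
  log_msg("done: mean accuracy ", signif(result$mean_accuracy, 4))
  invisible(list(result = result,
                 paths = c(dataset = ds_path, result = res_path,
                           metrics = metrics_path,
                           manifest = manifest_path)))
}

#' Verify the architecture bookkeeping
#'
#' Recomputes every shape and parameter count of the replication
#' architecture and checks it against the expected value: 144
#' convolution parameters, 32 batch-norm parameters, flattened length
#' 28,672, 3,674,240 LSTM parameters, convolution output lengths 121
#' (unpadded) and 128 (padded by 7), and max-pool unpadded length 127.
#'
#' @param config A [crnn_config()] (defaults to the replication
#'   architecture).
#' @return A tibble with columns `check`, `expected`, `actual`,
#'   `pass`; attribute `all_pass` summarises it.
#' @export
#' @examples
#' verify_architecture()
verify_architecture <- function(config = crnn_config()) {
  pc <- count_parameters(config)
  v <- config$input_length; k <- config$kernel_size
  checks <- tibble::tribble(
    ~check, ~expected, ~actual,
    "conv parameters", 144, pc$conv,
    "batch-norm parameters", 32, pc$bn,
    "flattened feature length", 28672, pc$flatten,
    "lstm parameters", 3674240, pc$lstm,
    "conv output length (unpadded)", 121,
    output_length(v, 0, k, config$stride),
    "conv output length (padded k-1)", 128,
    output_length(v, k - 1, k, config$stride),
    "max-pool output length (unpadded)", 127,
    output_length(v, 0, config$pool_size, config$pool_stride)
  )
  checks$pass <- checks$expected == checks$actual
  attr(checks, "all_pass") <- all(checks$pass)
  checks
}
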