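#' Read and write run configuration files
#'
#' A flat, human-editable key/value format with `[section]` headers:
#'
#' ```
#' [data]
#' n = 4000
#' labeled_fraction = 0.3
#' [training]
#' epochs = 30
#' ```
#'
#' Values parse as numbers when they look numeric, `TRUE`/`FALSE` as
#' logicals, otherwise strings. Unknown sections or keys are errors, not
#' warnings, so silent typos cannot change a run.
#'
#' @param path file path.
#' @return A named list of sections, each a named list of values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_field("path", paste("no such file:", path))
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- out[[section]] %||% list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(section)) abort_field("config", "key before any [section]")
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = "="))
      num <- suppressWarnings(as.numeric(val))
      out[[section]][[key]] <-
        if (!is.na(num)) num
        else if (val %in% c("TRUE", "FALSE")) as.logical(val)
        else val
    } else {
      abort_field("config", paste("unparseable line:", ln))
    }
  }
  out
}

#' @rdname read_run_config
#' @param config named list of sections.
#' @export
write_run_config <- function(config, path) {
  lines <- unlist(lapply(names(config), function(sec) {
    c(sprintf("[%s]", sec),
      vapply(names(config[[sec]]), function(k) {
        sprintf("%s = %s", k, format(config[[sec]][[k]], digits = 12))
      }, ""))
  }))
  writeLines(as.character(lines %||% character(0)), path)
  invisible(path)
}

PIPELINE_KEYS <- list(
  data = c("n", "d", "n_modes", "radius", "mode_sd", "noise_sd",
           "prevalence", "labeled_fraction", "dataset"),
  training = c("batch_size", "epochs", "lr_g", "lr_d", "noise_size",
               "n_layers", "hidden_width", "activation", "dropout_rate",
               "lambda_r", "lambda_consistency", "lambda_pseudo", "tau",
               "aug_sigma", "use_attention", "oversample"),
  tuning = c("num_bees", "max_cycles", "limit", "F", "budget_epochs"),
  evaluation = c("slices", "k")
)

check_config_keys <- function(config) {
  for (sec in names(config)) {
    if (!sec %in% names(PIPELINE_KEYS)) {
      abort_field("config", paste("unknown section:", sec))
    }
    bad <- setdiff(names(config[[sec]]), PIPELINE_KEYS[[sec]])
    if (length(bad)) {
      abort_field("config", sprintf("unknown key(s) in [%s]: %s", sec,
                                    paste(bad, collapse = ", ")))
    }
  }
  invisible(config)
}

config_mixture_spec <- function(dc) {
  ring_mixture_spec(
    n_modes = dc$n_modes %||% 8, d = dc$d %||% 16,
    radius = dc$radius %||% 4, mode_sd = dc$mode_sd %||% 0.5,
    noise_sd = dc$noise_sd %||% 0.1, prevalence = dc$prevalence %||% 0.3
  )
}

config_training <- function(tc, seed) {
  spec <- mlp_spec(
    n_layers = tc$n_layers %||% 2,
    hidden_width = tc$hidden_width %||% 64,
    activation = tc$activation %||% "relu",
    dropout_rate = tc$dropout_rate %||% 0
  )
  training_config(
    batch_size = tc$batch_size %||% 64,
    epochs = tc$epochs %||% 30,
    lr_g = tc$lr_g %||% 1e-3, lr_d = tc$lr_d %||% 1e-3,
    noise_size = tc$noise_size %||% 16,
    g_spec = spec, d_spec = spec,
    weights = loss_weights(
      lambda_r = tc$lambda_r %||% 0.42,
      lambda_consistency = tc$lambda_consistency %||% 0.28,
      lambda_pseudo = tc$lambda_pseudo %||% 0.41,
      tau = tc$tau %||% 0.9
    ),
    aug_sigma = tc$aug_sigma %||% 0.1,
    use_attention = tc$use_attention %||% TRUE,
    oversample = tc$oversample %||% TRUE,
    seed = seed
  )
}

pipeline_dataset <- function(config, out_dir, seed) {
  dc <- config$data %||% list()
  path <- dc$dataset %||% file.path(out_dir, "dataset.tsv")
  if (file.exists(path)) return(read_feature_tsv(path))
  spec <- config_mixture_spec(dc)
  data <- simulate_features(spec, n = dc$n %||% 4000,
                            seed = derive_seed(seed, 21)) |>
    assign_splits(seed = derive_seed(seed, 22)) |>
    split_semisupervised(dc$labeled_fraction %||% 0.3,
                         seed = derive_seed(seed, 23))
  write_feature_tsv(data, path)
  data
}

#' Run an end-to-end pipeline command
#'
#' Ties the modules together behind five commands:
#' * `simulate` — draw the configured mixture dataset, tag splits, mask
#'   labels, and write `dataset.tsv`;
#' * `train` — train the SS-GAN, writing `generator.json`,
#'   `discriminator.json` and `history.tsv`;
#' * `evaluate` — classification metrics on the test split plus generator
#'   distribution metrics, written to `metrics.tsv` / `gan_metrics.tsv`;
#' * `tune` — short-budget ML-ABC search, writing `best_config.ini` and
#'   `tuning_history.tsv`;
#' * `ablate` — the six-row configuration-only ablation table
#'   (`ablation.tsv`).
#'
#' The effective configuration (including the seed) is serialized back into
#' the output directory so every run directory is a reproducibility record.
#'
#' @param command one of `simulate`, `train`, `tune`, `evaluate`, `ablate`.
#' @param config named config list (see [read_run_config()]) or a path to a
#'   config file; `NULL` uses defaults throughout.
#' @param out_dir output directory, created if needed.
#' @param seed global seed; fanned out to per-stage streams.
#' @param quiet suppress progress messages.
#' @return The primary result of the command, invisibly.
#' @export
run_pipeline <- function(command = c("simulate", "train", "tune",
                                     "evaluate", "ablate"),
                         config = NULL, out_dir = "melanogan-run",
                         seed = 1, quiet = FALSE) {
  command <- match.arg(command)
  if (is.character(config)) config <- read_run_config(config)
  config <- check_config_keys(config %||% list())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  write_run_config(config, file.path(out_dir, "config_used.ini"))
  writeLines(sprintf("seed = %d", as.integer(seed)),
             file.path(out_dir, "seed.txt"))

  data <- pipeline_dataset(config, out_dir, seed)
  if (command == "simulate") {
    say("wrote %s (%d rows)", file.path(out_dir, "dataset.tsv"), nrow(data))
    return(invisible(data))
  }

  tc <- config_training(config$training %||% list(), seed = derive_seed(seed, 31))

  if (command == "train") {
    fit <- train_ssgan(data, tc)
    write_checkpoint(fit$generator, file.path(out_dir, "generator.json"))
    write_checkpoint(fit$discriminator,
                     file.path(out_dir, "discriminator.json"))
    readr::write_tsv(fit$history, file.path(out_dir, "history.tsv"))
    say("trained %d epochs; final val F-measure %.3f", tc$epochs,
        dplyr::last(fit$history$val_f_measure) %||% NA_real_)
    return(invisible(fit))
  }

  if (command == "tune") {
    tn <- config$tuning %||% list()
    fit <- tune_ssgan(
      data,
      config = colony_config(
        num_bees = tn$num_bees %||% 6, max_cycles = tn$max_cycles %||% 5,
        limit = tn$limit %||% 5, F = tn$F %||% 1,
        seed = derive_seed(seed, 41)
      ),
      budget_epochs = tn$budget_epochs %||% 5,
      base_config = tc
    )
    readr::write_tsv(fit$history, file.path(out_dir, "tuning_history.tsv"))
    best <- fit$best_config
    write_run_config(list(training = best[!vapply(best, is.null, TRUE)]),
                     file.path(out_dir, "best_config.ini"))
    say("best fitness (val F-measure): %.3f", fit$best$fitness)
    return(invisible(fit))
  }

  if (command == "evaluate") {
    gen_path <- file.path(out_dir, "generator.json")
    dsc_path <- file.path(out_dir, "discriminator.json")
    if (!file.exists(dsc_path)) {
      abort_field("out_dir", "no discriminator checkpoint; run `train` first")
    }
    dsc <- read_checkpoint(dsc_path)
    test_idx <- if ("split" %in% names(data)) which(data$split == "test")
                else seq_len(nrow(data))
    truth <- (data$label_true %||% data$label)[test_idx]
    pred <- discriminator_predict(dsc, data[test_idx, ])
    mt <- classification_metrics(confusion_counts(truth, pred$.pred_class))
    mt$auc <- auc_score(pred$.pred_melanoma, truth)
    readr::write_tsv(mt, file.path(out_dir, "metrics.tsv"))
    gm <- NULL
    if (file.exists(gen_path)) {
      g <- read_checkpoint(gen_path)
      ev <- config$evaluation %||% list()
      withr::with_seed(derive_seed(seed, 51), {
        z <- matrix(stats::rnorm(length(test_idx) * g$noise_size),
                    length(test_idx))
        fake <- generator_forward(g, z)
      })
      gm <- distribution_metrics(
        feature_matrix(data[test_idx, ]), fake,
        spec = config_mixture_spec(config$data %||% list()),
        slices = ev$slices %||% 64, k = ev$k %||% 5,
        seed = derive_seed(seed, 52)
      )
      readr::write_tsv(gm, file.path(out_dir, "gan_metrics.tsv"))
    }
    say("test F-measure %.3f, AUC %.3f", mt$f_measure, mt$auc)
    return(invisible(list(metrics = mt, gan_metrics = gm)))
  }

  # ablate
  tab <- ablate_ssgan(data, tc)
  readr::write_tsv(tab, file.path(out_dir, "ablation.tsv"))
  say("wrote %s (%d rows)", file.path(out_dir, "ablation.tsv"), nrow(tab))
  invisible(tab)
}
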