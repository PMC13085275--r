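# End-to-end orchestration of the four experimental settings:
#   1  end-to-end CNN classification (softmax head) per backbone
#   2  per-layer deep features (pooling / attention) -> classifier battery
#   3  DWT-fused dual-layer features per backbone -> classifier battery
#   4  cross-network concatenation -> ANOVA top-k sweep -> classifier battery
# Every stage is deterministic given the config seed; artifacts (features,
# metrics, rankings, ANOVA tables) are persisted under output_dir.

.cfg_keys <- c("setting", "dataset_dir", "fixture", "feature_fixture",
               "backbones", "dwt_level", "k_grid", "classifiers", "n_folds",
               "n_repeats", "seed", "output_dir", "training", "augment",
               "train_fraction")
.fixture_keys <- c("n_classes", "per_class_counts", "image_size", "seed")
.feature_fixture_keys <- c("n_samples", "p_features", "k_informative",
                           "effect_size", "noise_sd", "n_classes", "seed")
.training_keys <- c("minibatch", "epochs", "learning_rate", "momentum",
                    "weight_decay", "validation_frequency")

#' Validate a raw run configuration
#'
#' Fills defaults (training hyperparameters: mini-batch 5, 50 epochs, learning
#' rate 0.001, momentum 0.9, weight decay 1e-4; 5-fold CV; the full
#' seven-classifier battery; top-k grid 100..1500 step 100) and rejects
#' unknown keys with a field-level message.
#'
#' @param raw a named list, or a path to a YAML file.
#' @return A validated `run_config` list.
#' @export
validate_config <- function(raw) {
  if (is.character(raw) && length(raw) == 1) raw <- yaml::read_yaml(raw)
  stop_if_not(is.list(raw), "config must be a list or a YAML file path")
  unknown <- setdiff(names(raw), .cfg_keys)
  stop_if_not(length(unknown) == 0,
              paste("unknown config keys:", paste(unknown, collapse = ", ")))
  if (!is.null(raw$fixture)) {
    bad <- setdiff(names(raw$fixture), .fixture_keys)
    stop_if_not(length(bad) == 0,
                paste("unknown fixture keys:", paste(bad, collapse = ", ")))
  }
  if (!is.null(raw$training)) {
    bad <- setdiff(names(raw$training), .training_keys)
    stop_if_not(length(bad) == 0,
                paste("unknown training keys:", paste(bad, collapse = ", ")))
  }
  if (!is.null(raw$feature_fixture)) {
    bad <- setdiff(names(raw$feature_fixture), .feature_fixture_keys)
    stop_if_not(length(bad) == 0,
                paste("unknown feature_fixture keys:", paste(bad, collapse = ", ")))
  }
  cfg <- raw
  cfg$setting <- as.integer(cfg$setting %||% 4L)
  stop_if_not(cfg$setting %in% 1:4, "setting must be 1, 2, 3 or 4")
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$backbones <- cfg$backbones %||% "toy_cnn"
  stop_if_not(all(cfg$backbones %in% c("efficientnetb0", "mobilenet",
                                       "resnet18", "toy_cnn")),
              "backbones must be among efficientnetb0/mobilenet/resnet18/toy_cnn")
  cfg$classifiers <- cfg$classifiers %||% classifier_names()
  stop_if_not(all(cfg$classifiers %in% classifier_names()),
              "unknown classifier name(s)")
  cfg$dwt_level <- as.integer(cfg$dwt_level %||% 2L)
  stop_if_not(cfg$dwt_level %in% 1:2, "dwt_level must be 1 or 2")
  cfg$n_folds <- as.integer(cfg$n_folds %||% 5L)
  cfg$n_repeats <- as.integer(cfg$n_repeats %||% 5L)
  cfg$train_fraction <- cfg$train_fraction %||% 0.7
  stop_if_not(cfg$train_fraction > 0 && cfg$train_fraction < 1,
              "train_fraction must be in (0, 1)")
  cfg$augment <- isTRUE(cfg$augment %||% TRUE)
  cfg$k_grid <- as.integer(cfg$k_grid %||% seq(100L, 1500L, by = 100L))
  tr <- cfg$training %||% list()
  cfg$training <- training_config(
    minibatch = tr$minibatch %||% 5L,
    epochs = tr$epochs %||% 50L,
    learning_rate = tr$learning_rate %||% 0.001,
    momentum = tr$momentum %||% 0.9,
    weight_decay = tr$weight_decay %||% 1e-4,
    validation_frequency = tr$validation_frequency %||% 10L,
    seed = cfg$seed)
  if (is.null(cfg$dataset_dir) && is.null(cfg$fixture) &&
      is.null(cfg$feature_fixture)) {
    stop("config needs a dataset_dir, fixture or feature_fixture", call. = FALSE)
  }
  stop_if_not(is.null(cfg$feature_fixture) || cfg$setting == 4L,
              "feature_fixture input only applies to setting 4")
  class(cfg) <- "run_config"
  cfg
}

pipeline_dataset <- function(cfg) {
  if (!is.null(cfg$dataset_dir) && dir.exists(cfg$dataset_dir)) {
    return(load_image_dataset(cfg$dataset_dir))
  }
  fx <- cfg$fixture
  spec <- fixture_spec(n_classes = fx$n_classes,
                       per_class_counts = fx$per_class_counts,
                       image_size = fx$image_size %||% c(48L, 48L),
                       seed = fx$seed %||% cfg$seed)
  imgs <- list(); labels <- integer(0)
  for (k in seq_len(spec$n_classes)) {
    for (i in seq_len(spec$per_class_counts[k])) {
      imgs[[length(imgs) + 1L]] <-
        generate_cell_image(k - 1L, spec, seed = derive_seed(spec$seed, k, i))
      labels <- c(labels, k - 1L)
    }
  }
  list(images = imgs, labels = labels,
       class_names = sprintf("class%d", seq_len(spec$n_classes) - 1L))
}

stratified_split <- function(labels, fraction, seed) {
  with_seed(seed, {
    train <- integer(0)
    for (g in sort(unique(labels))) {
      idx <- sample(which(labels == g))
      n_tr <- max(1L, round(fraction * length(idx)))
      train <- c(train, idx[seq_len(n_tr)])
    }
    sort(train)
  })
}

train_backbones <- function(cfg, ds, train_idx) {
  ranges <- if (cfg$augment) augmentation_ranges() else identity_ranges()
  n_classes <- length(unique(ds$labels))
  models <- list()
  for (bb in cfg$backbones) {
    model <- build_attention_model(bb, n_classes,
                                   seed = derive_seed(cfg$seed, match(bb,
                                     c("efficientnetb0", "mobilenet",
                                       "resnet18", "toy_cnn"))))
    tr <- train_model(model, ds$images[train_idx], ds$labels[train_idx],
                      tcfg = cfg$training, ranges = ranges)
    models[[bb]] <- tr
  }
  models
}

extract_all <- function(models, ds) {
  feats <- list()
  for (bb in names(models)) {
    m <- models[[bb]]$model
    feats[[bb]] <- list(
      pooling = extract_pooling_features(m, ds$images, ds$labels),
      attention = extract_attention_features(m, ds$images, ds$labels))
  }
  feats
}

#' Run one experimental setting end-to-end
#'
#' Trains (or reuses) the attention CNNs, derives the features the setting
#' needs, evaluates, and persists artifacts under `cfg$output_dir`. A shared
#' `state` (trained models / extracted features from an earlier call) can be
#' passed so settings 2-4 reuse setting-1 training; reruns from cached state
#' are bit-identical to fresh runs with the same seed.
#'
#' @param cfg a [validate_config()] run configuration.
#' @param state optional list with `models` and/or `features` from a
#'   previous call.
#' @return A list with the setting's results plus the updated `state`.
#' @export
run_setting <- function(cfg, state = NULL) {
  if (!inherits(cfg, "run_config")) cfg <- validate_config(cfg)
  out_dir <- cfg$output_dir %||% tempfile("cytodx_run")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  env <- environment()
  get_ds <- function() {
    if (is.null(env$state$dataset)) env$state$dataset <- pipeline_dataset(cfg)
    env$state$dataset
  }
  get_train_idx <- function() {
    if (is.null(env$state$train_idx)) {
      env$state$train_idx <- stratified_split(get_ds()$labels,
                                              cfg$train_fraction,
                                              derive_seed(cfg$seed, 99))
    }
    env$state$train_idx
  }
  ensure_models <- function() {
    if (is.null(env$state$models)) {
      env$state$models <- train_backbones(cfg, get_ds(), get_train_idx())
    }
    env$state$models
  }
  ensure_features <- function() {
    if (is.null(env$state$features)) {
      env$state$features <- extract_all(ensure_models(), get_ds())
    }
    env$state$features
  }
  ensure_fused <- function() {
    if (is.null(env$state$fused)) {
      env$state$fused <- lapply(ensure_features(), function(f) {
        dwt_fuse(concat_dual(f$pooling, f$attention), cfg$dwt_level)
      })
    }
    env$state$fused
  }
  jsonlite::write_json(
    list(setting = cfg$setting, seed = cfg$seed, backbones = cfg$backbones,
         package = "cytodx",
         version = as.character(utils::packageVersion("cytodx"))),
    file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE)

  result <- switch(as.character(cfg$setting),
    "1" = {
      models <- ensure_models()
      ds <- get_ds(); train_idx <- get_train_idx()
      test_idx <- setdiff(seq_along(ds$images), train_idx)
      acc <- vapply(names(models), function(bb) {
        probs <- predict_model(models[[bb]]$model, ds$images[test_idx])
        mean(max.col(probs) - 1L == ds$labels[test_idx])
      }, numeric(1))
      for (bb in names(models)) {
        utils::write.csv(models[[bb]]$history,
                         file.path(out_dir, sprintf("history_%s.csv", bb)),
                         row.names = FALSE)
      }
      jsonlite::write_json(as.list(acc), file.path(out_dir, "accuracy.json"),
                           auto_unbox = TRUE, digits = NA)
      list(accuracy = acc,
           history = lapply(models, function(m) m$history))
    },
    "2" = {
      features <- ensure_features()
      reports <- list()
      for (bb in names(features)) {
        for (layer in c("pooling", "attention")) {
          fm <- features[[bb]][[layer]]
          write_feature_csv(fm, file.path(out_dir,
                                          sprintf("features_%s_%s.csv", bb, layer)))
          rep <- cv_evaluate(fm, cfg$classifiers, cfg$n_folds, cfg$n_repeats,
                             seed = derive_seed(cfg$seed, 2))
          write_report(rep, file.path(out_dir, sprintf("%s_%s", bb, layer)))
          reports[[paste(bb, layer, sep = "_")]] <- rep
        }
      }
      list(reports = reports)
    },
    "3" = {
      features <- ensure_features()
      reports <- list(); fused <- list()
      for (bb in names(features)) {
        cc <- concat_dual(features[[bb]]$pooling, features[[bb]]$attention)
        fs <- dwt_fuse(cc, cfg$dwt_level)
        fused[[bb]] <- fs
        write_fused_csv(fs, file.path(out_dir, sprintf("fused_%s.csv", bb)))
        rep <- cv_evaluate(fs$matrix, cfg$classifiers, cfg$n_folds,
                           cfg$n_repeats, seed = derive_seed(cfg$seed, 3))
        write_report(rep, file.path(out_dir, bb))
        reports[[bb]] <- rep
      }
      state$fused <- fused
      list(reports = reports, fused = fused)
    },
    "4" = {
      ens <- if (!is.null(cfg$feature_fixture)) {
        ff <- cfg$feature_fixture
        gen <- generate_feature_matrix(synthetic_feature_spec(
          n_samples = ff$n_samples, p_features = ff$p_features,
          k_informative = ff$k_informative,
          effect_size = ff$effect_size %||% 1,
          noise_sd = ff$noise_sd %||% 1,
          n_classes = ff$n_classes %||% 2L,
          seed = ff$seed %||% cfg$seed))
        feature_matrix(gen$features$values, gen$labels, source = "ensemble",
                       network = "synthetic",
                       feature_names = gen$features$feature_names)
      } else {
        concat_networks(unname(ensure_fused()))
      }
      sw <- sweep_k(ens, cfg$classifiers, cfg$k_grid, cfg$n_folds,
                    n_repeats = 1L, seed = derive_seed(cfg$seed, 4))
      write_ranking_csv(sw$ranking, file.path(out_dir, "ranking.csv"))
      best_k <- sw$best_k[which.max(apply(sw$accuracy, 1L, max))]
      idx <- select_top_k(sw$ranking, best_k)
      sel <- feature_matrix(ens$values[, idx, drop = FALSE], ens$labels,
                            source = "ensemble", network = "ensemble",
                            feature_names = ens$feature_names[idx])
      rep <- cv_evaluate(sel, cfg$classifiers, cfg$n_folds, cfg$n_repeats,
                         seed = derive_seed(cfg$seed, 5))
      write_report(rep, out_dir)
      jsonlite::write_json(list(selected_k = unname(best_k),
                                best_k_per_classifier = as.list(sw$best_k)),
                           file.path(out_dir, "selected_k.json"),
                           auto_unbox = TRUE)
      utils::write.csv(sw$accuracy, file.path(out_dir, "sweep_accuracy.csv"))
      list(report = rep, sweep = sw, selected_k = best_k, ensemble = ens,
           selected = sel)
    })
  list(setting = cfg$setting, result = result, state = state,
       output_dir = out_dir)
}

#' Run settings 1 through 4 sharing trained models
#'
#' @param cfg a [validate_config()] configuration (its `setting` is ignored).
#' @return Named list `setting1`..`setting4` of [run_setting()] results.
#' @export
run_all_settings <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- validate_config(cfg)
  state <- NULL
  out <- list()
  base_dir <- cfg$output_dir %||% tempfile("cytodx_run")
  for (s in 1:4) {
    cfg$setting <- s
    cfg$output_dir <- file.path(base_dir, sprintf("setting%d", s))
    r <- run_setting(cfg, state)
    state <- r$state
    out[[sprintf("setting%d", s)]] <- r
  }
  out
}
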