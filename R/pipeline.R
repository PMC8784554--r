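#' Configure an end-to-end benchmark experiment
#'
#' Bundles every stage parameter of the simulate - preprocess - train -
#' predict - evaluate - compare pipeline. The default desk preset (10
#' subjects on a 64 x 64 x 8 grid, tiny networks) completes on one CPU
#' core; the cohort is split into training, validation and unseen test
#' subjects in the 400/100/234 proportions of the full-scale design.
#'
#' @param n_subjects cohort size.
#' @param spec a [phantom_spec()] describing the synthetic subjects.
#' @param out_dir artifact directory.
#' @param seed master seed for the run (data, weight init, shuffling).
#' @param val_fraction fraction of training subjects held out for
#'   validation (default 100/500).
#' @param epochs_2d,epochs_3d training epoch caps per family.
#' @param learning_rate Adam learning rate used at desk scale (larger than
#'   the full-scale 1e-4 because desk runs take two orders of magnitude
#'   fewer gradient steps).
#' @param patience early-stopping patience (epochs) for both families. The
#'   desk default equals the epoch cap, i.e. early stopping is inactive:
#'   with a single validation subject the stopping signal is
#'   noise-dominated. Full-scale runs should lower it (the
#'   [train_config()] default is 8).
#' @param batch_size_2d slice batch size (published value 16; 8 at desk
#'   scale where an epoch holds few slices).
#' @param batch_size_3d patch batch size.
#' @param patch_shape_3d,patch_step_3d sliding-window geometry for the 3D
#'   family; defaults tile a 64 x 64 x 8 volume into 3 x 3 x 1 = 9
#'   half-overlapping patches, mirroring the acquisition-scale
#'   128/64 tiling.
#' @param depth,base_filters U-Net size shared by both families.
#' @param folds 1 trains a single model per family on the train/val
#'   split; k > 1 runs [cv_train()] and averages the fold models'
#'   probabilities at prediction time.
#' @param resume reuse an existing simulated dataset and saved models in
#'   `out_dir` when present.
#' @param verbose print stage progress.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(n_subjects = 10L,
                              spec = phantom_spec(),
                              out_dir = tempfile("ctsegbench_"),
                              seed = 1L,
                              val_fraction = 0.2,
                              epochs_2d = 40L, epochs_3d = 20L,
                              learning_rate = 3e-3, patience = 40L,
                              batch_size_2d = 8L, batch_size_3d = 4L,
                              patch_shape_3d = c(32L, 32L, 8L),
                              patch_step_3d = c(16L, 16L, 8L),
                              depth = 3L, base_filters = 6L,
                              folds = 1L, resume = FALSE,
                              verbose = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"), n_subjects >= 4)
  if (val_fraction <= 0 || val_fraction >= 1)
    stopf("val_fraction must be in (0, 1)")
  structure(as.list(environment()), class = "experiment_config")
}

exp_log <- function(cfg, fmt, ...) {
  if (cfg$verbose)
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
}

load_subject <- function(row) {
  ct <- read_ct_volume(row$ct_path)
  lab <- read_label_volume(row$label_path)
  list(ct = window_hu(ct), lab = lab)
}

# slices + per-class mask targets for the 2D single-task family
slices_for_class <- function(subjects, code) {
  x <- list(); y <- list()
  for (s in subjects) {
    xs <- extract_slices(s$ct$data)
    ys <- extract_slices(class_mask(s$lab, code))
    x <- c(x, xs); y <- c(y, ys)
  }
  list(x = x, y = y)
}

# patches + one-hot targets for the 3D multitask family
patches_for_3d <- function(subjects, patch_shape, step) {
  grid <- plan_grid(dim(subjects[[1]]$ct$data), patch_shape, step)
  x <- list(); y <- list()
  for (s in subjects) {
    x <- c(x, extract_patches(s$ct$data, grid))
    y <- c(y, extract_patches(to_categorical(s$lab), grid))
  }
  list(x = x, y = y, grid = grid)
}

ensemble_predict_2d <- function(model_sets, ct) {
  preds <- lapply(model_sets, predict_2d, ct = ct)
  out <- preds[[1]]
  if (length(preds) > 1) {
    for (k in 2:length(preds))
      for (nm in names(out)) out[[nm]] <- out[[nm]] + preds[[k]][[nm]]
    for (nm in names(out)) out[[nm]] <- out[[nm]] / length(preds)
  }
  out
}

ensemble_predict_3d <- function(models, ct, step) {
  preds <- lapply(models, predict_3d, ct = ct, step = step)
  Reduce(`+`, preds) / length(preds)
}

#' Run the full 2D-versus-3D benchmark experiment
#'
#' Simulates (or reuses) a synthetic cohort, windows the CT volumes,
#' trains the three single-task 2D U-Nets and the multitask 3D U-Net,
#' predicts every unseen test subject, writes per-tissue probability maps
#' as NIfTI, evaluates both families with the published metric suite and
#' emits `metrics.csv`, `summary.csv` (the benchmark-report layout) and
#' `comparison.csv` (per-subject Dice and volume pairs for box-plot
#' comparison). Reruns with an identical config and seed reproduce the
#' CSVs bit-identically.
#'
#' @param config an [experiment_config()].
#' @return invisibly, a list with `manifest`, `metrics`, `summary`,
#'   `comparison`, `histories` and `out_dir`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  data_dir <- file.path(cfg$out_dir, "data")
  manifest_path <- file.path(data_dir, "manifest.csv")
  if (cfg$resume && file.exists(manifest_path)) {
    exp_log(cfg, "reusing simulated cohort in %s", data_dir)
    manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE,
                                colClasses = c(subject_id = "character"))
  } else {
    exp_log(cfg, "simulating %d subjects", cfg$n_subjects)
    manifest <- make_dataset(cfg$n_subjects, cfg$spec, data_dir,
                             seed = cfg$seed)
  }
  train_rows <- manifest[manifest$split == "train", ]
  test_rows <- manifest[manifest$split == "test", ]
  if (nrow(train_rows) < 2L || nrow(test_rows) < 1L)
    stopf("cohort too small: %d train / %d test subjects",
          nrow(train_rows), nrow(test_rows))
  n_val <- max(1L, round(nrow(train_rows) * cfg$val_fraction))
  val_rows <- utils::tail(train_rows, n_val)
  fit_rows <- utils::head(train_rows, nrow(train_rows) - n_val)
  exp_log(cfg, "loading %d train / %d val / %d test subjects",
          nrow(fit_rows), nrow(val_rows), nrow(test_rows))
  fit_sub <- lapply(seq_len(nrow(fit_rows)),
                    function(i) load_subject(fit_rows[i, ]))
  val_sub <- lapply(seq_len(nrow(val_rows)),
                    function(i) load_subject(val_rows[i, ]))
  test_sub <- lapply(seq_len(nrow(test_rows)),
                     function(i) load_subject(test_rows[i, ]))
  grid_shape <- dim(fit_sub[[1]]$ct$data)

  model_path <- file.path(cfg$out_dir, "models.rds")
  if (cfg$resume && file.exists(model_path)) {
    exp_log(cfg, "reusing trained models")
    trained <- readRDS(model_path)
  } else {
    cfg2 <- unet_config(dims = 2L, input_shape = grid_shape[1:2],
                        out_channels = 1L, depth = cfg$depth,
                        base_filters = cfg$base_filters)
    cfg3 <- unet_config(dims = 3L, input_shape = cfg$patch_shape_3d,
                        out_channels = 4L, depth = cfg$depth,
                        base_filters = cfg$base_filters)
    trained <- list(m2d = list(), m3d = NULL, histories = list())
    for (tis in names(TISSUES)) {
      exp_log(cfg, "training 2D U-Net for %s", toupper(tis))
      tc <- train_config(learning_rate = cfg$learning_rate,
                         batch_size = cfg$batch_size_2d,
                         max_epochs = cfg$epochs_2d,
                         early_stopping_patience = cfg$patience,
                         lr_reduce_patience = max(2L, cfg$patience %/% 2L),
                         folds = max(cfg$folds, 2L),
                         seed = cfg$seed + TISSUES[[tis]])
      tr <- slices_for_class(fit_sub, TISSUES[[tis]])
      va <- slices_for_class(val_sub, TISSUES[[tis]])
      if (cfg$folds > 1L) {
        cvr <- cv_train(cfg2, c(tr$x, va$x), c(tr$y, va$y), tc)
        trained$m2d[[tis]] <- cvr$models
        trained$histories[[paste0("2d_", tis)]] <- cvr$history
      } else {
        m <- build_unet(cfg2, seed = cfg$seed + TISSUES[[tis]])
        m <- train_unet(m, tr$x, tr$y, tc, va$x, va$y)
        trained$m2d[[tis]] <- list(m)
        trained$histories[[paste0("2d_", tis)]] <- m$history
      }
    }
    exp_log(cfg, "training multitask 3D U-Net")
    tc3 <- train_config(learning_rate = cfg$learning_rate,
                        batch_size = cfg$batch_size_3d,
                        max_epochs = cfg$epochs_3d,
                        early_stopping_patience = cfg$patience,
                        lr_reduce_patience = max(2L, cfg$patience %/% 2L),
                        folds = max(cfg$folds, 2L),
                        seed = cfg$seed + 7L)
    tr3 <- patches_for_3d(fit_sub, cfg$patch_shape_3d, cfg$patch_step_3d)
    va3 <- patches_for_3d(val_sub, cfg$patch_shape_3d, cfg$patch_step_3d)
    if (cfg$folds > 1L) {
      cvr <- cv_train(cfg3, c(tr3$x, va3$x), c(tr3$y, va3$y), tc3)
      trained$m3d <- cvr$models
      trained$histories[["3d"]] <- cvr$history
    } else {
      m3 <- build_unet(cfg3, seed = cfg$seed + 7L)
      m3 <- train_unet(m3, tr3$x, tr3$y, tc3, va3$x, va3$y)
      trained$m3d <- list(m3)
      trained$histories[["3d"]] <- m3$history
    }
    saveRDS(trained, model_path)
  }

  pred2_dir <- file.path(cfg$out_dir, "pred_2d")
  pred3_dir <- file.path(cfg$out_dir, "pred_3d")
  ref_dir <- file.path(cfg$out_dir, "ref")
  for (d in c(pred2_dir, pred3_dir, ref_dir))
    dir.create(d, showWarnings = FALSE)
  m2d_named <- function(k) list(gm = trained$m2d$gm[[k]],
                                wm = trained$m2d$wm[[k]],
                                csf = trained$m2d$csf[[k]])
  n_folds_2d <- length(trained$m2d$gm)
  for (i in seq_len(nrow(test_rows))) {
    id <- test_rows$subject_id[i]
    s <- test_sub[[i]]
    exp_log(cfg, "predicting subject %s", id)
    p2 <- ensemble_predict_2d(lapply(seq_len(n_folds_2d), m2d_named), s$ct)
    p3 <- ensemble_predict_3d(trained$m3d, s$ct, cfg$patch_step_3d)
    sp <- s$ct$spacing_mm
    for (tis in names(TISSUES)) {
      write_volume(ct_volume(p2[[tis]], sp),
                   file.path(pred2_dir, sprintf("prob_%s_%s.nii.gz", id, tis)))
      write_volume(ct_volume(p3[, , , TISSUES[[tis]] + 1L], sp),
                   file.path(pred3_dir, sprintf("prob_%s_%s.nii.gz", id, tis)))
    }
    write_volume(s$lab, file.path(ref_dir, sprintf("labels_%s.nii.gz", id)))
  }
  exp_log(cfg, "evaluating")
  met2 <- evaluate_testset(pred2_dir, ref_dir, "2D")
  met3 <- evaluate_testset(pred3_dir, ref_dir, "3D")
  metrics <- rbind(met2, met3)
  summary_tab <- summarize_metrics(metrics)
  comparison <- metrics[, c("subject_id", "tissue", "model_tag", "d_c",
                            "v_ct_liters", "v_ref_liters")]
  utils::write.csv(metrics, file.path(cfg$out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(summary_tab, file.path(cfg$out_dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(comparison, file.path(cfg$out_dir, "comparison.csv"),
                   row.names = FALSE)
  invisible(list(manifest = manifest, metrics = metrics,
                 summary = summary_tab, comparison = comparison,
                 histories = trained$histories, out_dir = cfg$out_dir))
}
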