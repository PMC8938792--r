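#' @title End-to-end pipeline
#' @description Wires the modules together: phantom cohort generation,
#'   labelled/unlabelled split, supervised warm-up, pseudo-label
#'   self-training, segmentation of the test pool, volumetry and
#'   Lund-Mackay scoring, and summary statistics, with every artifact
#'   listed (with MD5 hashes) in a manifest. One top-level seed
#'   deterministically derives every stage seed.
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param n_subjects cohort size.
#' @param n_labeled subjects treated as having manual annotations.
#' @param grid_shape,spacing_mm phantom grid.
#' @param seg tiny-model [seg_config()] used for training.
#' @param labeled_ratio,selftrain_fraction split parameters.
#' @param tau,lambda,rounds self-training parameters.
#' @param warmup_epochs,epochs_per_round,batch_size,lr training schedule.
#' @param hu_threshold air/disease intensity cut (HU).
#' @param tlms_partial_low,tlms_complete_high automated TLMs ratio cut-offs.
#' @param seed top-level seed.
#' @param out_dir output directory.
#' @return A `pipeline_config` list (validated).
#' @export
pipeline_config <- function(n_subjects = 12, n_labeled = 6,
                            grid_shape = c(32, 32, 32),
                            spacing_mm = c(3, 3, 3),
                            seg = seg_config(base_width = 8, depth = 3,
                                             se_reduction = 4,
                                             atrous_rates = c(1, 2, 3)),
                            labeled_ratio = 0.8, selftrain_fraction = 0.5,
                            tau = 0.9, lambda = 0, rounds = 2,
                            warmup_epochs = 6, epochs_per_round = 3,
                            batch_size = 8, lr = 1e-3,
                            hu_threshold = -400,
                            tlms_partial_low = 0.05,
                            tlms_complete_high = 0.95,
                            seed = 1L, out_dir = tempfile("sinusct_run_")) {
  if (!is.numeric(hu_threshold) || length(hu_threshold) != 1 ||
      !is.finite(hu_threshold))
    stop("hu_threshold must be a finite number")
  if (n_labeled >= n_subjects) stop("need unlabeled subjects")
  if (n_labeled < 2) stop("need at least 2 labeled subjects")
  if (!(tau > 0 && tau <= 1)) stop("tau must be in (0, 1]")
  if (rounds < 1) stop("rounds must be >= 1")
  stopifnot(inherits(seg, "seg_config"))
  structure(as.list(environment()), class = "pipeline_config")
}

stage_seed <- function(seed, stage) {
  # deterministic per-stage seeds derived from the top-level seed
  offsets <- c(cohort = 1L, split = 2L, model = 3L, warmup = 4L,
               selftrain = 5L)
  (as.integer(seed) * 97L + offsets[[stage]]) %% .Machine$integer.max
}

subject_slices <- function(phantom) {
  sl <- reslice_coronal(phantom$volume, phantom$labels)
  list(images = sl$images, labels = sl$labels)
}

#' Run the full pipeline
#'
#' @param config a [pipeline_config()].
#' @return List with `scores` (per-subject score table), `metrics`
#'   (test-pool segmentation metrics), `manifest` (files written), and the
#'   trained `model`; artifacts are written under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  emit <- function(path) manifest <<- c(manifest, path)
  stage <- "cohort"
  result <- tryCatch({
    cohort <- generate_cohort(config$n_subjects,
                              grid_shape = config$grid_shape,
                              spacing_mm = config$spacing_mm,
                              seed = stage_seed(config$seed, "cohort"))
    phantoms <- lapply(cohort$specs, generate_phantom)
    cohort_csv <- file.path(config$out_dir, "cohort.csv")
    write_cohort_csv(cohort, cohort_csv); emit(cohort_csv)

    stage <- "split"
    ids <- cohort$records$subject_id
    labeled_ids <- ids[seq_len(config$n_labeled)]
    unlabeled_ids <- setdiff(ids, labeled_ids)
    split <- make_split(labeled_ids, unlabeled_ids,
                        labeled_ratio = config$labeled_ratio,
                        selftrain_fraction = config$selftrain_fraction,
                        seed = stage_seed(config$seed, "split"))
    split_json <- file.path(config$out_dir, "split.json")
    write_split_json(split, split_json); emit(split_json)

    slices_of <- function(sel_ids) {
      idx <- match(sel_ids, ids)
      out <- list(images = list(), labels = list())
      for (i in idx) {
        s <- subject_slices(phantoms[[i]])
        out$images <- c(out$images, s$images)
        out$labels <- c(out$labels, s$labels)
      }
      out
    }

    stage <- "warmup"
    tr <- slices_of(split$labeled_train)
    va <- slices_of(split$labeled_val)
    model <- build_segnet(config$seg,
                          seed = stage_seed(config$seed, "model"))
    hist <- train_segnet(model, tr$images, tr$labels,
                         epochs = config$warmup_epochs,
                         batch_size = config$batch_size, lr = config$lr,
                         val = va, seed = stage_seed(config$seed, "warmup"))
    curve_csv <- file.path(config$out_dir, "warmup_curve.csv")
    write.csv(hist, curve_csv, row.names = FALSE); emit(curve_csv)

    stage <- "selftrain"
    st_pool <- slices_of(split$unlabeled_selftrain)
    state <- self_train(model, labeled = tr,
                        unlabeled = list(images = st_pool$images),
                        val = va, rounds = config$rounds, tau = config$tau,
                        lambda = config$lambda,
                        epochs_per_round = config$epochs_per_round,
                        batch_size = config$batch_size, lr = config$lr / 2,
                        seed = stage_seed(config$seed, "selftrain"))
    rounds_csv <- file.path(config$out_dir, "selftrain_rounds.csv")
    write.csv(state$history, rounds_csv, row.names = FALSE); emit(rounds_csv)
    ckpt <- file.path(config$out_dir, "model.rds")
    save_segnet(model, ckpt); emit(ckpt); emit(paste0(ckpt, ".json"))

    stage <- "segment"
    test_idx <- match(split$unlabeled_test, ids)
    scores <- list()
    all_pred <- integer(0); all_ref <- integer(0)
    for (i in test_idx) {
      ph <- phantoms[[i]]
      sl <- reslice_coronal(ph$volume)
      pred <- lapply(sl$images, function(s) predict_slice(model, s)$labels)
      seg3d <- stack_segmentations(pred, ph$volume$spacing_mm)
      rep_i <- suppressWarnings(
        region_volumes(seg3d, ph$volume, hu_threshold = config$hu_threshold))
      v <- vmlms(rep_i)
      t <- tlms(rep_i, config$tlms_partial_low, config$tlms_complete_high)
      truth_v <- vmlms(ph$truth)
      scores[[length(scores) + 1]] <- data.frame(
        subject_id = ids[i], vmlms = v$total, tlms = t$total,
        vmlms_truth = truth_v$total,
        tlms_truth = sum(ph$truth$tlms_sub))
      all_pred <- c(all_pred, as.vector(seg3d$data))
      all_ref <- c(all_ref, as.vector(ph$labels$data))
    }
    scores <- do.call(rbind, scores)
    scores_csv <- file.path(config$out_dir, "scores.csv")
    write.csv(scores, scores_csv, row.names = FALSE); emit(scores_csv)

    stage <- "evaluate"
    metrics <- seg_metrics(all_pred, all_ref)
    metrics_json <- file.path(config$out_dir, "metrics.json")
    jsonlite::write_json(
      list(pixel_accuracy = metrics$pixel_accuracy,
           mean_dice = metrics$mean_dice, miou = metrics$miou,
           vmlms_mae = mean(abs(scores$vmlms - scores$vmlms_truth))),
      metrics_json, auto_unbox = TRUE, digits = NA)
    emit(metrics_json)

    list(scores = scores, metrics = metrics, model = model, split = split,
         cohort = cohort)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  manifest_df <- data.frame(path = manifest,
                            md5 = unname(tools::md5sum(manifest)),
                            stringsAsFactors = FALSE)
  manifest_csv <- file.path(config$out_dir, "manifest.csv")
  write.csv(manifest_df, manifest_csv, row.names = FALSE)
  result$manifest <- manifest_df
  result
}
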