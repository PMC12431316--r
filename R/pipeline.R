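#' Full-run configuration
#'
#' Collects every stage's configuration — synthesis, selection/segmentation,
#' signal fusion, superlet transform, network, training, decision fusion,
#' energy constants — under one seed.  The defaults describe a desk-scale
#' smoke study on synthetic data; the full-scale settings of the method
#' (224 x 224 images, T = 6, 150/160 epochs) are reachable by overriding
#' the respective fields.
#'
#' @param synth a [synth_config()].
#' @param min_length,trim_start,trim_end record selection rule
#'   ([select_and_trim()]).
#' @param window_seconds segment window; `step_normal`/`step_abnormal` are
#'   the class-dependent hops ([segment_step_for_label()]).
#' @param test_fraction,n_folds record-level split ([make_split()]).
#' @param fusion a [fusion_config()].
#' @param aslt an [aslt_config()]; `downsample_to` optionally decimates
#'   each segment to this rate (Hz) before the transform (the integer
#'   decimation factor `fs / downsample_to`), which caps the analysable
#'   band at `downsample_to / 2` and speeds the transform up accordingly.
#' @param image_size,image_scale spectrogram rendering ([render_image()]).
#' @param net an [scnn_config()]; its `in_size` must equal `image_size`.
#' @param train_ecg,train_epcg per-branch [train_config()]s (the method
#'   trains the ECG branch 150 epochs and the EPCG branch 160 at full
#'   scale).
#' @param cdd a [cdd_config()].
#' @param modalities the two model branches, primary first (default
#'   `c("ecg", "epcg")`; `"pcg"` is also accepted).
#' @param folds_to_run folds held out during training (default 0 — one
#'   validation fold; `0:4` runs the full cross-validation).
#' @param seed global seed; all stage seeds derive from it.
#' @param out_dir run directory for artifacts, or `NULL` for in-memory only.
#' @return a `run_config` list.
#' @export
run_config <- function(synth = synth_config(),
                       min_length = 40000, trim_start = 4000, trim_end = 40000,
                       window_seconds = 6, step_normal = 2, step_abnormal = 6,
                       test_fraction = 0.1, n_folds = 5,
                       fusion = fusion_config(),
                       aslt = aslt_config(f_min = 3, f_max = 400, n_freqs = 32,
                                          o_min = 1, o_max = 8, c1 = 3,
                                          fs = 1000),
                       downsample_to = 1000,
                       image_size = 64, image_scale = "log1p",
                       net = scnn_config(in_size = 64, T_steps = 2, alpha = 1),
                       train_ecg = train_config(lr = 0.002, epochs = 5),
                       train_epcg = train_config(lr = 0.002, epochs = 5),
                       cdd = cdd_config(),
                       modalities = c("ecg", "epcg"),
                       folds_to_run = 0L,
                       seed = 1L, out_dir = NULL) {
  modalities <- tolower(modalities)
  bad <- setdiff(modalities, c("ecg", "pcg", "epcg"))
  if (length(bad)) {
    stop_invalid("unknown modality: %s", paste(bad, collapse = ", "))
  }
  if (length(modalities) != 2) stop_invalid("exactly two modalities required")
  if (net$in_size != image_size) {
    stop_invalid("net$in_size (%d) must equal image_size (%d)",
                 net$in_size, image_size)
  }
  if (!is.null(downsample_to)) {
    q <- synth$sampling_rate / downsample_to
    if (abs(q - round(q)) > 1e-9 || q < 1) {
      stop_invalid("downsample_to must divide the sampling rate")
    }
    if (aslt$fs != downsample_to) {
      stop_invalid("aslt$fs (%g) must equal downsample_to (%g)",
                   aslt$fs, downsample_to)
    }
  } else if (aslt$fs != synth$sampling_rate) {
    stop_invalid("aslt$fs must equal the sampling rate when not downsampling")
  }
  structure(list(
    synth = synth, min_length = min_length, trim_start = trim_start,
    trim_end = trim_end, window_seconds = window_seconds,
    step_normal = step_normal, step_abnormal = step_abnormal,
    test_fraction = test_fraction, n_folds = n_folds, fusion = fusion,
    aslt = aslt, downsample_to = downsample_to, image_size = image_size,
    image_scale = image_scale, net = net, train_ecg = train_ecg,
    train_epcg = train_epcg, cdd = cdd, modalities = modalities,
    folds_to_run = folds_to_run, seed = as.integer(seed), out_dir = out_dir
  ), class = "run_config")
}

# Extract the requested channel of a segment as a 1-D signal.
segment_channel <- function(seg, modality, fusion_cfg) {
  switch(modality,
    ecg = seg$ecg,
    pcg = seg$pcg,
    epcg = differential_fuse(seg$ecg, seg$pcg, fusion_cfg)
  )
}

# Transform one segment channel into a rendered grayscale image.
segment_to_image <- function(x, cfg) {
  if (!is.null(cfg$downsample_to)) {
    q <- round(cfg$synth$sampling_rate / cfg$downsample_to)
    if (q > 1) x <- as.numeric(signal::decimate(x, q))
  }
  s <- aslt_transform(x, cfg$aslt)
  render_image(s, size = cfg$image_size, scale = cfg$image_scale)
}

# Stack a list of segments into an (H, W, N) image array for one modality.
segments_to_images <- function(segments, modality, cfg) {
  n <- length(segments)
  out <- array(0, c(cfg$image_size, cfg$image_size, n))
  for (i in seq_len(n)) {
    x <- segment_channel(segments[[i]], modality, cfg$fusion)
    out[, , i] <- segment_to_image(x, cfg)
  }
  out
}

write_artifact <- function(obj, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(out_dir, name)
  if (is.data.frame(obj)) data.table::fwrite(obj, path)
  else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Run the full detection pipeline
#'
#' simulate -> select/trim -> record-level split -> class-balanced
#' sliding-window segmentation (independently within train and test) ->
#' superlet spectrogram images per modality -> one spiking-network branch
#' per modality -> confidence-based decision fusion -> metrics and energy
#' report.  Deterministic for a fixed config: two invocations produce
#' identical manifests, predictions and metrics.
#'
#' @param cfg a [run_config()].
#' @param verbose log stage progress and per-epoch training lines.
#' @return a `pipeline_result` list: `manifest` (segment manifest),
#'   `branches` (per modality: training history, test predictions, metrics,
#'   spike-rate report, energy report), `fusion` (fused predictions, usage
#'   fraction, metrics), and `config`.
#' @export
run_pipeline <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_invalid("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  say("stage simulate: %d records", cfg$synth$n_records)
  records <- stage("simulate", generate_dataset(cfg$synth))

  say("stage preprocess")
  kept <- stage("preprocess", {
    out <- lapply(records, select_and_trim, min_length = cfg$min_length,
                  trim_start = cfg$trim_start, trim_end = cfg$trim_end)
    out[!vapply(out, is.null, logical(1))]
  })
  if (length(kept) < 2) stop_invalid("too few records pass selection")
  plan <- stage("split", make_split(kept, cfg$test_fraction, cfg$n_folds,
                                    seed = derive_seed(cfg$seed, 2L)))

  seg_of <- function(ids) {
    segs <- list()
    for (rec in kept) {
      if (!rec$record_id %in% ids) next
      step <- segment_step_for_label(rec$label, cfg$step_normal,
                                     cfg$step_abnormal)
      segs <- c(segs, segment_recording(rec, cfg$window_seconds, step))
    }
    segs
  }
  train_segs <- stage("segment", seg_of(plan$train_record_ids))
  test_segs <- stage("segment", seg_of(plan$test_record_ids))
  say("segments: %d train / %d test", length(train_segs), length(test_segs))

  manifest <- rbind(
    cbind(segment_manifest(train_segs, plan)),
    cbind(segment_manifest(test_segs, plan))
  )
  write_artifact(manifest, cfg$out_dir, "segment_manifest.csv")

  seg_labels <- function(segs) vapply(segs, `[[`, integer(1), "label")
  train_fold <- vapply(train_segs, function(s) {
    unname(plan$fold_assignments[s$record_id])
  }, integer(1))

  branches <- list()
  for (m in cfg$modalities) {
    say("stage transform (%s): %d + %d images", m,
        length(train_segs), length(test_segs))
    tr_img <- stage("transform", segments_to_images(train_segs, m, cfg))
    te_img <- stage("transform", segments_to_images(test_segs, m, cfg))
    tr_cfg <- if (m == "epcg") cfg$train_epcg else cfg$train_ecg
    tr_cfg$seed <- derive_seed(cfg$seed, 10L + match(m, cfg$modalities))
    say("stage train (%s): %d epochs", m, tr_cfg$epochs)
    cvres <- stage("train", scnn_train_cv(
      tr_img, seg_labels(train_segs), train_fold, cfg$net, tr_cfg,
      folds_to_run = cfg$folds_to_run, verbose = verbose))
    # model of the last run fold (single-fold smoke: the only one)
    net <- cvres[[length(cvres)]]$net
    history <- do.call(rbind, lapply(cvres, function(r) {
      cbind(fold = r$fold, r$history)
    }))
    say("stage predict (%s)", m)
    pred <- stage("predict", scnn_predict(net, te_img, collect_trace = TRUE))
    rates <- layer_spike_rates(pred$trace, cfg$net$T_steps)
    cnt <- count_ann_ops(cfg$net)
    branches[[m]] <- list(
      history = history, pred = pred,
      metrics = compute_metrics(
        confusion_counts(pred$pred_label, seg_labels(test_segs)),
        scores = pred$probs[2, ], labels = seg_labels(test_segs)),
      spike_rates = rates,
      energy = energy_report(cnt$total, rates$overall)
    )
    write_artifact(history, cfg$out_dir, sprintf("train_log_%s.csv", m))
  }

  say("stage fuse")
  fused <- stage("fuse", fuse_batch(branches[[cfg$modalities[1]]]$pred,
                                    branches[[cfg$modalities[2]]]$pred,
                                    cfg$cdd))
  truth <- seg_labels(test_segs)
  fusion <- list(
    fused = fused,
    metrics = compute_metrics(confusion_counts(fused$pred_label, truth),
                              scores = fused$probs[2, ], labels = truth),
    usage_fraction = fused$usage_fraction
  )

  pred_table <- data.table::data.table(
    record_id = vapply(test_segs, `[[`, "", "record_id"),
    start_sample = vapply(test_segs, `[[`, numeric(1), "start_sample"),
    label = truth,
    p_abnormal_m1 = branches[[cfg$modalities[1]]]$pred$probs[2, ],
    p_abnormal_m2 = branches[[cfg$modalities[2]]]$pred$probs[2, ],
    p_abnormal_fused = fused$probs[2, ],
    predicted = fused$pred_label,
    used_model2 = fused$used_model2
  )
  write_artifact(pred_table, cfg$out_dir, "predictions.csv")
  write_artifact(
    list(
      fused = unclass(fusion$metrics),
      per_branch = lapply(branches, function(b) unclass(b$metrics)),
      overall_spike_rates = lapply(branches, function(b) b$spike_rates$overall),
      usage_fraction = fusion$usage_fraction
    ),
    cfg$out_dir, "metrics.json")

  structure(list(manifest = manifest, plan = plan, branches = branches,
                 fusion = fusion, predictions = pred_table, config = cfg),
            class = "pipeline_result")
}
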