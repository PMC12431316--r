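#' Read a dataset written in the two-column CSV layout
#'
#' Reads every record listed in `REFERENCE.csv` under `dir` (columns
#' `record_id,label`, labels in {-1,+1}), each from `<record_id>.csv` with
#' columns `ecg,pcg`.
#'
#' @param dir dataset directory.
#' @param fs sampling rate in Hz of the stored waveforms (default 2000).
#' @return list of `recording` objects.
#' @export
read_dataset <- function(dir, fs = 2000) {
  ref_path <- file.path(dir, "REFERENCE.csv")
  if (!file.exists(ref_path)) stop_invalid("no REFERENCE.csv under %s", dir)
  ref <- data.table::fread(ref_path)
  lapply(seq_len(nrow(ref)), function(i) {
    d <- data.table::fread(file.path(dir, paste0(ref$record_id[i], ".csv")))
    structure(list(record_id = as.character(ref$record_id[i]),
                   ecg = as.numeric(d$ecg), pcg = as.numeric(d$pcg),
                   fs = fs, label = as.integer(ref$label[i])),
              class = "recording")
  })
}

#' Length selection and fixed-window trimming
#'
#' Applies the study's record-selection rule: records shorter than
#' `min_length` samples are rejected; accepted records are cut to the
#' half-open sample range `[trim_start, trim_end)` (0-based) on both
#' channels.  The defaults keep samples 4000..39,999, i.e. a 36,000-sample
#' excerpt that skips the unstable start of an acquisition.
#'
#' @param rec a `recording`.
#' @param min_length minimum record length in samples (default 40,000).
#' @param trim_start first retained sample, 0-based inclusive.
#' @param trim_end one past the last retained sample, 0-based exclusive.
#' @return the trimmed `recording`, or `NULL` if the record is rejected.
#' @export
select_and_trim <- function(rec, min_length = 40000,
                            trim_start = 4000, trim_end = 40000) {
  stopifnot(inherits(rec, "recording"))
  if (!(trim_end > trim_start && trim_start >= 0)) {
    stop_invalid("need trim_end > trim_start >= 0")
  }
  n <- length(rec$ecg)
  if (n < min_length) return(NULL)
  idx <- (trim_start + 1):min(trim_end, n)
  rec$ecg <- rec$ecg[idx]
  rec$pcg <- rec$pcg[idx]
  rec
}

#' Sliding-window segmentation of one recording
#'
#' Windows of `window_seconds` starting at 0, `step`, 2*`step`, ... samples
#' while the full window fits; the segment count is
#' `floor((L - W) / S) + 1` in samples.  The label is inherited from the
#' record.
#'
#' @param rec a `recording`.
#' @param window_seconds window length in seconds (default 6).
#' @param step_seconds hop between window starts in seconds.
#' @param strict if `TRUE`, a window longer than the record is an error;
#'   otherwise an empty list is returned with a warning.
#' @return list of `segment` objects (`record_id`, `start_sample` 0-based,
#'   `ecg`, `pcg`, `fs`, `label`).
#' @export
segment_recording <- function(rec, window_seconds = 6, step_seconds,
                              strict = FALSE) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$fs
  W <- round(window_seconds * fs)
  S <- round(step_seconds * fs)
  L <- length(rec$ecg)
  if (W > L) {
    msg <- sprintf("window (%d samples) longer than record %s (%d samples)",
                   W, rec$record_id, L)
    if (strict) stop_invalid("%s", msg)
    warning(msg, call. = FALSE)
    return(list())
  }
  if (S <= 0) stop_invalid("step must be positive")
  n_seg <- floor((L - W) / S) + 1
  lapply(seq_len(n_seg), function(k) {
    s0 <- (k - 1) * S
    structure(list(record_id = rec$record_id, start_sample = s0,
                   ecg = rec$ecg[(s0 + 1):(s0 + W)],
                   pcg = rec$pcg[(s0 + 1):(s0 + W)],
                   fs = fs, label = rec$label),
              class = "segment")
  })
}

#' Class-dependent augmentation step
#'
#' The sliding-window augmentation uses a denser hop for the normal class
#' (2 s) than for the abnormal class (6 s) to counter class imbalance.
#'
#' @param label -1 (normal) or +1 (abnormal).
#' @param step_normal,step_abnormal hops in seconds.
#' @return step in seconds.
#' @export
segment_step_for_label <- function(label, step_normal = 2, step_abnormal = 6) {
  if (label > 0) step_abnormal else step_normal
}

#' Record-level train/test split with stratified cross-validation folds
#'
#' The split is performed at the record level before any augmentation, so no
#' segment of a test record can leak into training.  Both the test subset
#' and the fold assignment are stratified by label and deterministic under
#' `seed`.
#'
#' @param records list of `recording` objects.
#' @param test_fraction fraction of records held out for testing.
#' @param n_folds number of cross-validation folds over the training ids.
#' @param seed integer seed.
#' @return a `split_plan`: list with `train_record_ids`, `test_record_ids`,
#'   and `fold_assignments` (named integer vector, folds 0..n_folds-1).
#' @export
make_split <- function(records, test_fraction = 0.1, n_folds = 5, seed = 1L) {
  ids <- vapply(records, `[[`, "", "record_id")
  labels <- vapply(records, `[[`, integer(1), "label")
  if (anyDuplicated(ids)) stop_invalid("record ids must be unique")
  with_seed(seed, {
    test_ids <- character(0)
    train_ids <- character(0)
    folds <- integer(0)
    for (cl in sort(unique(labels))) {
      cl_ids <- sample(ids[labels == cl])
      n_test <- round(test_fraction * length(cl_ids))
      test_ids <- c(test_ids, cl_ids[seq_len(n_test)])
      tr <- cl_ids[setdiff(seq_along(cl_ids), seq_len(n_test))]
      train_ids <- c(train_ids, tr)
      if (length(tr)) {
        f <- rep_len(0:(n_folds - 1), length(tr))
        names(f) <- tr
        folds <- c(folds, f)
      }
    }
    if (length(train_ids) < n_folds) {
      stop_invalid("too few training records (%d) for %d folds",
                   length(train_ids), n_folds)
    }
    structure(list(train_record_ids = sort(train_ids),
                   test_record_ids = sort(test_ids),
                   fold_assignments = folds[sort(names(folds))]),
              class = "split_plan")
  })
}

#' Segment manifest as a data.table
#'
#' @param segments list of `segment` objects.
#' @param plan optional `split_plan` used to annotate split membership and
#'   fold index.
#' @return data.table with columns `record_id`, `start_sample`, `label`,
#'   and, when `plan` is given, `split` and `fold`.
#' @export
segment_manifest <- function(segments, plan = NULL) {
  m <- data.table::data.table(
    record_id = vapply(segments, `[[`, "", "record_id"),
    start_sample = vapply(segments, `[[`, numeric(1), "start_sample"),
    label = vapply(segments, `[[`, integer(1), "label")
  )
  if (!is.null(plan)) {
    m$split <- ifelse(m$record_id %in% plan$test_record_ids, "test", "train")
    m$fold <- ifelse(m$record_id %in% names(plan$fold_assignments),
                     plan$fold_assignments[m$record_id], NA_integer_)
  }
  m
}
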