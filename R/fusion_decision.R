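#' Confidence-based dynamic decision (CDD) fusion configuration
#'
#' @param threshold confidence threshold tau in `[0, 1]` (default 0.5).
#' @param w1,w2 non-negative fusion weights for model 1 (primary) and
#'   model 2; the weighted average is normalised by `w1 + w2`.
#' @param comparison `"strict_greater"` (default; model 1 is accepted when
#'   its confidence strictly exceeds tau) or `"greater_equal"`.  For binary
#'   softmax outputs `max(p) >= 0.5` always, so the boundary behaviour at
#'   `tau = 0.5` is operationally meaningful and both modes are exposed.
#' @return a `cdd_config` list.
#' @export
cdd_config <- function(threshold = 0.5, w1 = 0.5, w2 = 0.5,
                       comparison = c("strict_greater", "greater_equal")) {
  comparison <- match.arg(comparison)
  if (threshold < 0 || threshold > 1) stop_invalid("threshold must be in [0, 1]")
  if (w1 < 0 || w2 < 0 || w1 + w2 <= 0) {
    stop_invalid("weights must be >= 0 with w1 + w2 > 0")
  }
  structure(list(threshold = threshold, w1 = w1, w2 = w2,
                 comparison = comparison), class = "cdd_config")
}

check_distribution <- function(p, tol = 1e-6) {
  if (any(p < -tol) || abs(sum(p) - 1) > tol) {
    stop_invalid("probability vector must be non-negative and sum to 1 (got sum %g)",
                 sum(p))
  }
}

#' Fuse one pair of class-probability vectors
#'
#' The confidence of the primary model is `max(p1)`.  If it exceeds the
#' threshold (strictly, by default) the primary prediction is accepted
#' unchanged; otherwise the fused distribution is the normalised weighted
#' average `(w1 * p1 + w2 * p2) / (w1 + w2)`.  The predicted class is the
#' argmax of the fused distribution, ties broken toward the lower class
#' index.
#'
#' @param p1,p2 probability vectors of equal length from models 1 and 2.
#' @param cfg a [cdd_config()].
#' @return list with `fused` (probability vector), `pred_class` (1-based
#'   index), and `used_model2` (logical).
#' @export
cdd_fuse <- function(p1, p2, cfg = cdd_config()) {
  if (length(p1) != length(p2)) stop_invalid("p1 and p2 differ in length")
  check_distribution(p1)
  check_distribution(p2)
  conf <- max(p1)
  accept <- if (cfg$comparison == "strict_greater") conf > cfg$threshold
            else conf >= cfg$threshold
  if (accept) {
    fused <- p1
    used2 <- FALSE
  } else {
    fused <- (cfg$w1 * p1 + cfg$w2 * p2) / (cfg$w1 + cfg$w2)
    used2 <- TRUE
  }
  list(fused = fused, pred_class = which.max(fused), used_model2 = used2)
}

#' Fuse two aligned prediction sets
#'
#' Applies [cdd_fuse()] segment by segment over two `prediction_set`s (or
#' bare probability matrices, classes in rows) that must describe the same
#' segments in the same order.
#'
#' @param preds1,preds2 `prediction_set`s or `n_classes x N` probability
#'   matrices from the primary and secondary model.
#' @param cfg a [cdd_config()].
#' @return list with `probs` (fused `n_classes x N`), `pred_class`,
#'   `pred_label` ({-1, +1} for binary problems), `used_model2` (logical
#'   per segment), and `usage_fraction` (share of segments where model 2
#'   was consulted).
#' @export
fuse_batch <- function(preds1, preds2, cfg = cdd_config()) {
  P1 <- if (inherits(preds1, "prediction_set")) preds1$probs else preds1
  P2 <- if (inherits(preds2, "prediction_set")) preds2$probs else preds2
  if (!all(dim(P1) == dim(P2))) {
    stop_invalid("prediction sets are not aligned: %dx%d vs %dx%d",
                 nrow(P1), ncol(P1), nrow(P2), ncol(P2))
  }
  N <- ncol(P1)
  fused <- matrix(0, nrow(P1), N)
  used2 <- logical(N)
  cls <- integer(N)
  for (j in seq_len(N)) {
    r <- cdd_fuse(P1[, j], P2[, j], cfg)
    fused[, j] <- r$fused
    used2[j] <- r$used_model2
    cls[j] <- r$pred_class
  }
  list(probs = fused, pred_class = cls,
       pred_label = ifelse(cls == 2, 1L, -1L),
       used_model2 = used2, usage_fraction = mean(used2))
}
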