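# ROC/AUC by exact pair counting, per-class accuracy, boundary sensitivity.

#' ROC curve and AUC by exact pair counting
#'
#' The AUC equals the Mann-Whitney probability that a random positive
#' outscores a random negative, with ties counted one half; the curve itself
#' is reported at every unique score threshold.
#'
#' @param scores Numeric prediction scores (higher = more coding-like).
#' @param labels Logical (or 0/1): `TRUE` for positives.
#' @return An object of class `roc_curve`: data.frame components
#'   `thresholds`, `fpr`, `tpr`, plus `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    cp_stop("codingpot_eval_error", "ROC needs both classes present")
  }
  r <- rank(scores)  # midranks handle ties as 1/2
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thresholds, function(t) mean(scores[labels] >= t), numeric(1L))
  fpr <- vapply(thresholds, function(t) mean(scores[!labels] >= t), numeric(1L))
  structure(list(
    curve = data.frame(threshold = thresholds, fpr = fpr, tpr = tpr),
    auc = auc, n_positive = n1, n_negative = n0
  ), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: AUC = %.4f (%d positives, %d negatives, %d thresholds)\n",
    x$auc, x$n_positive, x$n_negative, nrow(x$curve)))
  invisible(x)
}

#' Plot a ROC curve
#'
#' @param x A `roc_curve`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(c(0, x$curve$fpr, 1), c(0, x$curve$tpr, 1), type = "l",
    xlab = "false positive rate", ylab = "true positive rate", ...)
  graphics::abline(0, 1, lty = 3, col = "grey60")
}

#' Accuracy stratified by sequence class and length variant
#'
#' A prediction is correct when its call is `coding` for the coding classes
#' (`long_coding`, `sorf`) and `noncoding` for the noncoding classes
#' (`ncrna`, `intergenic`).
#'
#' @param preds Prediction data.frame from [predict.coding_model()] (needs
#'   `id` and `call`).
#' @param labels Labels data.frame with columns `id`, `klass` and `variant`.
#' @return A data.frame with one row per (klass, variant) stratum plus
#'   macro/micro overall rows: columns `klass`, `variant`, `n`, `correct`,
#'   `accuracy`.
#' @export
accuracy_by_class <- function(preds, labels) {
  idx <- match(preds$id, labels$id)
  if (anyNA(idx)) {
    missing <- preds$id[is.na(idx)]
    cp_stop("codingpot_eval_error", "prediction ids missing from labels: %s",
      paste(utils::head(missing, 5L), collapse = ", "))
  }
  klass <- labels$klass[idx]
  variant <- labels$variant[idx]
  expected <- ifelse(klass %in% CODING_KLASSES, "coding", "noncoding")
  ok <- preds$call == expected
  strata <- unique(data.frame(klass = klass, variant = variant,
    stringsAsFactors = FALSE))
  strata <- strata[order(match(strata$klass, KLASSES), strata$variant), ,
    drop = FALSE]
  rows <- lapply(seq_len(nrow(strata)), function(i) {
    sel <- klass == strata$klass[[i]] & variant == strata$variant[[i]]
    data.frame(klass = strata$klass[[i]], variant = strata$variant[[i]],
      n = sum(sel), correct = sum(ok[sel]), accuracy = mean(ok[sel]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  micro <- data.frame(klass = "overall", variant = "micro", n = length(ok),
    correct = sum(ok), accuracy = mean(ok), stringsAsFactors = FALSE)
  macro <- data.frame(klass = "overall", variant = "macro", n = length(ok),
    correct = sum(out$correct), accuracy = mean(out$accuracy),
    stringsAsFactors = FALSE)
  rbind(out, micro, macro)
}

#' Accuracy under controlled boundary perturbation
#'
#' For each requested keep fraction and extension amount, regenerates
#' perturbed variants of a labeled corpus (seeded), predicts, and reports
#' per-class accuracy — quantifying how much performance depends on seeing
#' the precise gene boundary.
#'
#' @param m A `coding_model`.
#' @param corpus Data.frame with columns `id`, `klass`, `seq` (exact-length
#'   sequences) and optionally `gc` per row (default 0.5 background for the
#'   extensions).
#' @param keep_fractions Numeric vector of fixed keep fractions.
#' @param extensions Integer vector of fixed per-side extension lengths.
#' @param seed Integer seed for the perturbation draws.
#' @return A data.frame with one row per (klass, keep_fraction, extension):
#'   `n`, `correct`, `accuracy`.
#' @export
boundary_sensitivity <- function(m, corpus, keep_fractions = c(1, 0.9, 0.75, 0.5),
                                 extensions = 0L, seed = 1L) {
  set.seed(as.integer(seed))
  gc_bg <- if (!is.null(corpus$gc)) corpus$gc else rep(0.5, nrow(corpus))
  rows <- list()
  for (kf in keep_fractions) {
    for (ext in extensions) {
      pol <- varied_length_policy(keep_fraction = c(kf, kf),
        extension = c(ext, ext))
      seqs <- vapply(seq_len(nrow(corpus)), function(i) {
        vary_length(corpus$seq[[i]], pol, gc = gc_bg[[i]])
      }, character(1L))
      names(seqs) <- corpus$id
      preds <- stats::predict(m, seqs)
      expected <- ifelse(corpus$klass %in% CODING_KLASSES, "coding", "noncoding")
      ok <- preds$call == expected
      for (kl in unique(corpus$klass)) {
        sel <- corpus$klass == kl
        rows[[length(rows) + 1L]] <- data.frame(
          klass = kl, keep_fraction = kf, extension = ext,
          n = sum(sel), correct = sum(ok[sel]), accuracy = mean(ok[sel]),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
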