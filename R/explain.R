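# Exact Shapley attribution on the probability scale. With p features the
# value function is evaluated on all 2^p coalitions; p is capped at 16.

coalition_masks <- function(p) {
  # 2^p x p logical matrix; row i is the binary expansion of i-1
  m <- matrix(FALSE, nrow = 2^p, ncol = p)
  for (j in seq_len(p)) {
    m[, j] <- bitwAnd(seq_len(2^p) - 1L, bitwShiftL(1L, j - 1L)) > 0L
  }
  m
}

#' Exact Shapley feature attribution for one prediction
#'
#' Attributes the difference between the model's output at `x` and its
#' baseline output (all features drawn from the background) to the
#' individual features, by exact enumeration of all feature coalitions. The
#' value of a coalition S is the mean model output over background rows with
#' the features in S replaced by their values in `x`. Attribution is on the
#' probability scale, i.e. on the logistic output the user sees.
#'
#' @param m A `coding_model`.
#' @param x Raw feature vector (canonical order).
#' @param background Feature matrix of background rows (>= 1 row), e.g. a
#'   seeded subsample of the training features.
#' @return List with `values` (named per-feature Shapley values),
#'   `base_value` (mean output over the background) and `explained_output`
#'   (output at `x`). The values sum to `explained_output - base_value`
#'   (efficiency) to within 1e-9.
#' @export
shapley_values <- function(m, x, background) {
  if (!is.matrix(background)) {
    background <- matrix(background, nrow = 1L,
      dimnames = list(NULL, names(background)))
  }
  p <- length(x)
  if (p > 16L) {
    cp_stop("codingpot_unsupported_error",
      "exact Shapley enumeration supports at most 16 features (got %d); use a sampling approximation", p)
  }
  nb <- nrow(background)
  masks <- coalition_masks(p)
  nc <- nrow(masks)
  # batch all hybrid vectors through one forward pass
  big <- background[rep(seq_len(nb), times = nc), , drop = FALSE]
  sel <- masks[rep(seq_len(nc), each = nb), , drop = FALSE]
  xrep <- matrix(x, nrow = nb * nc, ncol = p, byrow = TRUE)
  big[sel] <- xrep[sel]
  out <- forward(m, big)
  v <- colMeans(matrix(out, nrow = nb))  # one value per coalition
  sizes <- rowSums(masks)
  # Shapley kernel weight for adding feature i to a coalition of size s
  wts <- exp(lfactorial(0:(p - 1L)) + lfactorial(p - 1L - 0:(p - 1L)) - lfactorial(p))
  phi <- numeric(p)
  for (j in seq_len(p)) {
    without <- which(!masks[, j])
    with_j <- without + 2^(j - 1L)
    phi[[j]] <- sum(wts[sizes[without] + 1L] * (v[with_j] - v[without]))
  }
  names(phi) <- names(x)
  list(values = phi, base_value = v[[1L]], explained_output = v[[nc]])
}

#' Mean absolute Shapley importance of each feature
#'
#' @param m A `coding_model`.
#' @param data Feature matrix of examples to explain.
#' @param background Background feature matrix (see [shapley_values()]).
#' @return A data.frame with columns `feature` and `importance` (mean
#'   absolute Shapley value), sorted by descending importance; ties broken by
#'   canonical feature order.
#' @export
feature_importance <- function(m, data, background) {
  if (!is.matrix(data)) {
    data <- matrix(data, nrow = 1L, dimnames = list(NULL, names(data)))
  }
  if (nrow(data) == 0L) {
    cp_stop("codingpot_config_error", "feature_importance needs at least one example")
  }
  abs_sum <- numeric(ncol(data))
  for (i in seq_len(nrow(data))) {
    sv <- shapley_values(m, data[i, ], background)
    abs_sum <- abs_sum + abs(sv$values)
  }
  imp <- abs_sum / nrow(data)
  ord <- order(-imp, seq_along(imp))
  data.frame(feature = colnames(data)[ord], importance = imp[ord],
    row.names = NULL, stringsAsFactors = FALSE)
}
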