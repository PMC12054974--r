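# --- Standardization -------------------------------------------------------

#' Estimate per-feature standardization parameters
#'
#' @param x Feature matrix (rows = examples).
#' @param sd_floor Lower bound applied to each standard deviation so constant
#'   features cannot produce non-finite standardized values.
#' @return List with `mean` and `sd` vectors (canonical feature order).
#' @export
standardization_params <- function(x, sd_floor = 1e-8) {
  list(mean = colMeans(x), sd = pmax(apply(x, 2L, stats::sd), sd_floor))
}

#' Standardize a feature vector or matrix
#'
#' @param x Named numeric vector or matrix in canonical feature order.
#' @param p Parameters from [standardization_params()].
#' @return `(x - mean) / sd`, elementwise.
#' @export
standardize <- function(x, p) {
  if (is.matrix(x)) {
    if (!identical(colnames(x), names(p$mean))) {
      cp_stop("codingpot_config_error", "feature order mismatch in standardize()")
    }
    sweep(sweep(x, 2L, p$mean, "-"), 2L, p$sd, "/")
  } else {
    if (!identical(names(x), names(p$mean))) {
      cp_stop("codingpot_config_error", "feature order mismatch in standardize()")
    }
    (x - p$mean) / p$sd
  }
}

# --- Feed-forward network (rectifier hidden units, logistic output) --------

mlp_init <- function(sizes) {
  lapply(seq_len(length(sizes) - 1L), function(l) {
    fan_in <- sizes[[l]]
    list(W = matrix(stats::rnorm(fan_in * sizes[[l + 1L]], sd = sqrt(2 / fan_in)),
      nrow = fan_in),
      b = numeric(sizes[[l + 1L]]))
  })
}

# X: n x p standardized matrix; returns n-vector of probabilities
mlp_forward <- function(layers, X) {
  A <- X
  nl <- length(layers)
  for (l in seq_len(nl)) {
    Z <- A %*% layers[[l]]$W
    Z <- sweep(Z, 2L, layers[[l]]$b, "+")
    A <- if (l < nl) pmax(Z, 0) else Z
  }
  as.numeric(1 / (1 + exp(-A)))
}

# one forward+backward pass; returns gradients and weighted BCE loss
mlp_backprop <- function(layers, X, y, w) {
  nl <- length(layers)
  As <- vector("list", nl + 1L)
  As[[1L]] <- X
  for (l in seq_len(nl)) {
    Z <- sweep(As[[l]] %*% layers[[l]]$W, 2L, layers[[l]]$b, "+")
    As[[l + 1L]] <- if (l < nl) pmax(Z, 0) else Z
  }
  p <- 1 / (1 + exp(-As[[nl + 1L]]))
  eps <- 1e-12
  loss <- -sum(w * (y * log(p + eps) + (1 - y) * log(1 - p + eps))) / sum(w)
  # gradient of weighted BCE wrt logits
  delta <- (p - y) * w / sum(w)
  grads <- vector("list", nl)
  for (l in rev(seq_len(nl))) {
    grads[[l]] <- list(W = crossprod(As[[l]], delta), b = colSums(delta))
    if (l > 1L) {
      delta <- (delta %*% t(layers[[l]]$W)) * (As[[l]] > 0)
    }
  }
  list(grads = grads, loss = loss)
}

weighted_bce <- function(p, y, w) {
  eps <- 1e-12
  -sum(w * (y * log(p + eps) + (1 - y) * log(1 - p + eps))) / sum(w)
}

#' Training configuration for the classifier network
#'
#' @param hidden Hidden layer sizes (rectifier units).
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param validation_fraction Fraction of examples held out (stratified) for
#'   early stopping.
#' @return List of hyperparameters.
#' @export
mlp_control <- function(hidden = c(32L, 16L), learning_rate = 1e-3,
                        batch_size = 64L, max_epochs = 500L, patience = 20L,
                        validation_fraction = 0.1) {
  list(hidden = as.integer(hidden), learning_rate = learning_rate,
    batch_size = as.integer(batch_size), max_epochs = as.integer(max_epochs),
    patience = as.integer(patience), validation_fraction = validation_fraction)
}

# Adam on standardized X (n x p), labels y in {0,1}, example weights w.
# Deterministic given the current RNG state.
mlp_train <- function(X, y, w, control) {
  sizes <- c(ncol(X), control$hidden, 1L)
  layers <- mlp_init(sizes)
  mom <- lapply(layers, function(l) list(
    mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0))
  n <- nrow(X)
  # stratified validation split
  pos <- which(y == 1); neg <- which(y == 0)
  nv_pos <- max(1L, round(length(pos) * control$validation_fraction))
  nv_neg <- max(1L, round(length(neg) * control$validation_fraction))
  val_idx <- c(sample(pos, nv_pos), sample(neg, nv_neg))
  tr_idx <- setdiff(seq_len(n), val_idx)
  Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]; wtr <- w[tr_idx]
  Xval <- X[val_idx, , drop = FALSE]; yval <- y[val_idx]; wval <- w[val_idx]

  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; lr <- control$learning_rate
  t <- 0L
  best_val <- Inf; best_layers <- layers; best_epoch <- 0L; wait <- 0L
  history <- data.frame(epoch = integer(0L), train_loss = numeric(0L),
    val_loss = numeric(0L))
  for (epoch in seq_len(control$max_epochs)) {
    ord <- sample(length(tr_idx))
    batches <- split(ord, ceiling(seq_along(ord) / control$batch_size))
    epoch_loss <- 0
    for (bi in batches) {
      bp <- mlp_backprop(layers, Xtr[bi, , drop = FALSE], ytr[bi], wtr[bi])
      if (!is.finite(bp$loss)) {
        cp_stop("codingpot_training_error",
          "non-finite training loss at epoch %d; check feature values", epoch)
      }
      epoch_loss <- epoch_loss + bp$loss * length(bi)
      t <- t + 1L
      for (l in seq_along(layers)) {
        g <- bp$grads[[l]]
        mom[[l]]$mW <- b1 * mom[[l]]$mW + (1 - b1) * g$W
        mom[[l]]$vW <- b2 * mom[[l]]$vW + (1 - b2) * g$W^2
        mom[[l]]$mb <- b1 * mom[[l]]$mb + (1 - b1) * g$b
        mom[[l]]$vb <- b2 * mom[[l]]$vb + (1 - b2) * g$b^2
        mhW <- mom[[l]]$mW / (1 - b1^t); vhW <- mom[[l]]$vW / (1 - b2^t)
        mhb <- mom[[l]]$mb / (1 - b1^t); vhb <- mom[[l]]$vb / (1 - b2^t)
        layers[[l]]$W <- layers[[l]]$W - lr * mhW / (sqrt(vhW) + eps)
        layers[[l]]$b <- layers[[l]]$b - lr * mhb / (sqrt(vhb) + eps)
      }
    }
    val_loss <- weighted_bce(mlp_forward(layers, Xval), yval, wval)
    history <- rbind(history, data.frame(epoch = epoch,
      train_loss = epoch_loss / length(tr_idx), val_loss = val_loss))
    if (val_loss < best_val - 1e-9) {
      best_val <- val_loss; best_layers <- layers; best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= control$patience) break
    }
  }
  best_layers <- lapply(best_layers, function(l) {
    list(W = unname(l$W), b = unname(l$b))
  })
  list(layers = best_layers, best_epoch = best_epoch, best_val = best_val,
    history = history, sizes = sizes)
}

# --- The fitted-model interface -------------------------------------------

#' Train a coding-potential classifier
#'
#' Fits a small feed-forward neural network (rectifier hidden units, logistic
#' output) to the coding-potential feature panel. Features are standardized
#' with parameters estimated on the training data; class imbalance is handled
#' by inverse-frequency example weights in the binary cross-entropy loss;
#' training uses adaptive-moment stochastic gradient descent with a seeded
#' stratified validation split and early stopping. For robustness to
#' imprecise transcript boundaries, train on a corpus that includes
#' length-varied (truncated/extended) variants; see [vary_length()] and
#' [generate_benchmark()].
#'
#' @param x Either a named character vector of training sequences or a
#'   precomputed feature matrix from [feature_matrix()].
#' @param y Logical (or 0/1) labels, `TRUE` = coding.
#' @param refs A `reference_tables` bundle. Required when `x` is a feature
#'   matrix; when `x` is sequences and `refs` is `NULL`, tables are built
#'   from the training sequences themselves, coding side vs. noncoding side.
#'   Build the tables from exact-boundary sequences (not length-varied
#'   variants) when those are available, since the codon table reads its
#'   input in frame 0.
#' @param control Hyperparameters from [mlp_control()].
#' @param threshold Decision threshold on the coding probability.
#' @param seed Integer seed; training is reproducible given (data, control,
#'   seed).
#' @return An object of class `coding_model`.
#' @export
train_classifier <- function(x, y, refs = NULL, control = mlp_control(),
                             threshold = 0.5, seed = 1L) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) {
    cp_stop("codingpot_config_error", "training data must contain both classes")
  }
  if (length(y) < 20L) {
    cp_stop("codingpot_config_error", "need at least 20 training examples")
  }
  if (is.character(x)) {
    if (is.null(refs)) {
      refs <- reference_tables(x[y == 1], x[y == 0])
    }
    X <- feature_matrix(x, refs)
  } else {
    # refs may stay NULL for matrix training; predict() on raw sequences
    # then has no reference tables and accepts only feature matrices
    X <- x
    if (is.null(colnames(X))) {
      colnames(X) <- paste0("f", seq_len(ncol(X)))
    }
  }
  if (any(!is.finite(X))) {
    cp_stop("codingpot_input_error", "non-finite feature values in training data")
  }
  std <- standardization_params(X)
  Xs <- standardize(X, std)
  # inverse-frequency class weights, mean 1
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  w <- ifelse(y == 1, length(y) / (2 * n1), length(y) / (2 * n0))
  set.seed(as.integer(seed))
  fit <- mlp_train(Xs, y, w, control)
  structure(list(
    standardization = std,
    layers = fit$layers,
    layer_sizes = fit$sizes,
    feature_names = colnames(X),
    threshold = threshold,
    seed = as.integer(seed),
    control = control,
    references = refs,
    history = fit$history,
    best_epoch = fit$best_epoch,
    format_version = "codingpot-model-1"
  ), class = "coding_model")
}

#' Forward pass of a fitted classifier
#'
#' @param m A `coding_model`.
#' @param x Raw (unstandardized) feature vector or matrix in the model's
#'   feature order.
#' @return Coding probability (or vector of them), in `(0, 1)`.
#' @export
forward <- function(m, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L, dimnames = list(NULL, names(x)))
  if (any(!is.finite(x))) {
    cp_stop("codingpot_input_error", "non-finite feature values")
  }
  colnames(x) <- names(m$standardization$mean)
  mlp_forward(m$layers, standardize(x, m$standardization))
}

#' Predict coding probability for sequences
#'
#' Runs feature extraction, standardization and the network forward pass for
#' each input sequence, preserving input order.
#'
#' @param object A `coding_model`.
#' @param seqs Named character vector of sequences (or a raw feature matrix,
#'   in which case extraction is skipped).
#' @param threshold Decision threshold; defaults to the model's stored value.
#' @param ... Unused.
#' @return A data.frame with columns `id`, `length`, `probability_coding`,
#'   `call` and the feature panel (one column per feature).
#' @export
predict.coding_model <- function(object, seqs, threshold = object$threshold, ...) {
  if (length(seqs) == 0L) {
    out <- data.frame(id = character(0L), length = integer(0L),
      probability_coding = numeric(0L), call = character(0L))
    for (f in object$feature_names) out[[f]] <- numeric(0L)
    return(out)
  }
  if (is.matrix(seqs)) {
    X <- seqs
    ids <- rownames(X)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
    lens <- rep(NA_integer_, nrow(X))
  } else {
    if (is.null(object$references)) {
      cp_stop("codingpot_config_error",
        "model has no reference tables; pass a feature matrix instead of sequences")
    }
    X <- feature_matrix(seqs, object$references)
    ids <- names(seqs)
    if (is.null(ids)) ids <- as.character(seq_along(seqs))
    lens <- nchar(seqs)
  }
  p <- forward(object, X)
  out <- data.frame(id = ids, length = lens, probability_coding = p,
    call = ifelse(p >= threshold, "coding", "noncoding"),
    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(X, row.names = seq_len(nrow(X))))
}

#' @export
print.coding_model <- function(x, ...) {
  cat("Coding-potential classifier (feed-forward network)\n")
  cat(sprintf("  architecture: %s (rectifier hidden, logistic output)\n",
    paste(x$layer_sizes, collapse = " -> ")))
  cat(sprintf("  features:     %s\n", paste(x$feature_names, collapse = ", ")))
  cat(sprintf("  threshold:    %.3f   seed: %d   best epoch: %d\n",
    x$threshold, x$seed, x$best_epoch))
  invisible(x)
}

#' @export
summary.coding_model <- function(object, ...) {
  res <- list(
    layer_sizes = object$layer_sizes,
    n_parameters = sum(vapply(object$layers,
      function(l) length(l$W) + length(l$b), numeric(1L))),
    feature_names = object$feature_names,
    threshold = object$threshold,
    best_epoch = object$best_epoch,
    final_val_loss = object$history$val_loss[[object$best_epoch]],
    epochs_run = nrow(object$history)
  )
  class(res) <- "summary.coding_model"
  res
}

#' @export
print.summary.coding_model <- function(x, ...) {
  cat("Coding-potential classifier\n")
  cat(sprintf("  architecture      %s\n", paste(x$layer_sizes, collapse = " -> ")))
  cat(sprintf("  parameters        %d\n", x$n_parameters))
  cat(sprintf("  epochs run        %d (best validation loss %.4f at epoch %d)\n",
    x$epochs_run, x$final_val_loss, x$best_epoch))
  cat(sprintf("  decision threshold %.3f\n", x$threshold))
  invisible(x)
}

#' @export
coef.coding_model <- function(object, ...) {
  stats::setNames(object$layers,
    paste0("layer", seq_along(object$layers)))
}

#' Plot the training history of a fitted classifier
#'
#' @param x A `coding_model`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.coding_model <- function(x, ...) {
  graphics::matplot(x$history$epoch,
    cbind(x$history$train_loss, x$history$val_loss),
    type = "l", lty = 1, col = c("grey40", "firebrick"),
    xlab = "epoch", ylab = "weighted cross-entropy", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("training", "validation"),
    lty = 1, col = c("grey40", "firebrick"), bty = "n")
}

# --- Serialization ---------------------------------------------------------

#' Save a fitted classifier to a structured-text (JSON) model file
#'
#' The file embeds the feature order, standardization parameters, network
#' weights, codon table, hexamer log-odds, Fickett constants version tag,
#' pKa set, decision threshold, training seed and a format version string.
#'
#' @param m A `coding_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(m, path) {
  if (is.null(m$references)) {
    cp_stop("codingpot_config_error",
      "model has no reference tables; only sequence-trained models are serializable")
  }
  doc <- list(
    format_version = m$format_version,
    feature_names = m$feature_names,
    layer_sizes = m$layer_sizes,
    threshold = m$threshold,
    seed = m$seed,
    best_epoch = m$best_epoch,
    standardization = m$standardization,
    layers = lapply(m$layers, function(l) list(W = l$W, b = l$b)),
    control = m$control,
    references = list(
      codon_counts = as.list(m$references$codon_table$counts),
      codon_pseudocount = m$references$codon_table$pseudocount,
      hexamer_log_odds = unname(m$references$hexamer_model$log_odds),
      hexamer_pseudocount = m$references$hexamer_model$pseudocount,
      pka = as.list(m$references$pka$pka),
      pka_sign = as.list(m$references$pka$sign),
      fickett_version = m$references$fickett_version,
      min_codons = m$references$min_codons
    )
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a classifier from a model file
#'
#' @param path Path to a file written by [save_model()].
#' @return A `coding_model`; the forward pass of the loaded model is
#'   identical to that of the saved one.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) {
    cp_stop("codingpot_input_error", "model file not found: %s", path)
  }
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) cp_stop("codingpot_load_error",
      "corrupted model file: %s (%s)", path, conditionMessage(e)))
  required <- c("format_version", "feature_names", "layer_sizes", "threshold",
    "seed", "standardization", "layers", "references")
  for (f in required) {
    if (is.null(doc[[f]])) {
      cp_stop("codingpot_load_error", "model file missing field '%s'", f)
    }
  }
  if (!identical(doc$format_version, "codingpot-model-1")) {
    cp_stop("codingpot_load_error", "unsupported model format_version '%s'",
      doc$format_version)
  }
  sizes <- as.integer(doc$layer_sizes)
  layers <- lapply(seq_len(length(sizes) - 1L), function(l) {
    W <- doc$layers$W[[l]]
    if (is.null(dim(W))) W <- matrix(W, nrow = sizes[[l]])
    list(W = W, b = as.numeric(doc$layers$b[[l]]))
  })
  counts <- unlist(doc$references$codon_counts)
  ct <- build_codon_table_from_counts(counts, doc$references$codon_pseudocount)
  hx <- structure(list(
    log_odds = stats::setNames(as.numeric(doc$references$hexamer_log_odds),
      ALL_HEXAMERS),
    pseudocount = doc$references$hexamer_pseudocount
  ), class = "hexamer_model")
  refs <- structure(list(
    codon_table = ct,
    hexamer_model = hx,
    pka = list(pka = unlist(doc$references$pka),
      sign = unlist(doc$references$pka_sign)),
    fickett_version = doc$references$fickett_version,
    min_codons = as.integer(doc$references$min_codons)
  ), class = "reference_tables")
  std <- list(mean = stats::setNames(as.numeric(doc$standardization$mean),
    doc$feature_names),
    sd = stats::setNames(as.numeric(doc$standardization$sd), doc$feature_names))
  structure(list(
    standardization = std,
    layers = layers,
    layer_sizes = sizes,
    feature_names = doc$feature_names,
    threshold = doc$threshold,
    seed = as.integer(doc$seed),
    control = doc$control,
    references = refs,
    history = doc$history,
    best_epoch = doc$best_epoch,
    format_version = doc$format_version
  ), class = "coding_model")
}

# rebuild relative adaptiveness from stored raw counts
build_codon_table_from_counts <- function(counts, pseudocount) {
  counts <- counts[names(CODON_TABLE)]
  smoothed <- counts + pseudocount
  w <- structure(numeric(length(SENSE_CODONS)), names = SENSE_CODONS)
  for (fam in SYNONYMOUS_FAMILY) w[fam] <- smoothed[fam] / max(smoothed[fam])
  structure(list(counts = counts, w = w, pseudocount = pseudocount),
    class = "codon_table")
}
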