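# Shared fixtures, built once per test session and cached.

fixture_cache <- new.env(parent = emptyenv())

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small multi-genome benchmark + reference tables + trained model
small_benchmark <- function() {
  if (is.null(fixture_cache$bm)) {
    fixture_cache$bm <- generate_benchmark(n_genomes = 4L, holdout_genomes = 1L,
      n_per_class = 40L, seed = 7L)
  }
  fixture_cache$bm
}

small_refs <- function() {
  if (is.null(fixture_cache$refs)) {
    tr <- small_benchmark()$train
    exact <- tr[tr$variant == "exact", ]
    fixture_cache$refs <- reference_tables(exact$seq[exact$is_coding],
      exact$seq[!exact$is_coding])
  }
  fixture_cache$refs
}

small_model <- function() {
  if (is.null(fixture_cache$model)) {
    tr <- small_benchmark()$train
    X <- feature_matrix(stats::setNames(tr$seq, tr$id), small_refs())
    fixture_cache$model <- train_classifier(X, tr$is_coding,
      refs = small_refs(), seed = 11L)
  }
  fixture_cache$model
}

# hand-assembled model with given layers and identity standardization
manual_model <- function(layers, feature_names) {
  p <- nrow(layers[[1L]]$W)
  sizes <- c(p, vapply(layers, function(l) ncol(l$W), integer(1L)))
  structure(list(
    standardization = list(
      mean = stats::setNames(rep(0, p), feature_names),
      sd = stats::setNames(rep(1, p), feature_names)),
    layers = layers, layer_sizes = sizes, feature_names = feature_names,
    threshold = 0.5, seed = 0L, references = NULL,
    format_version = "codingpot-model-1"
  ), class = "coding_model")
}

write_tmp_fasta <- function(seqs) {
  path <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}
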