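# Shared fixtures, generated in code at test time.

# Small synthetic image directory, created once per test run.
tiny_synth_dir <- local({
  dir <- NULL
  function(n_per_class = 5L, image_size = c(32L, 32L), seed = 1L) {
    key <- file.path(tempdir(),
                     sprintf("amdnet-synth-%d-%d-%d", n_per_class,
                             image_size[1], seed))
    if (!dir.exists(key))
      generate_synthetic(synthetic_spec(n_per_class = n_per_class,
                                        image_size = image_size, seed = seed),
                         key)
    key
  }
})

# A dataset index built directly from label counts (no files on disk);
# used for split arithmetic that never touches images.
index_from_counts <- function(counts, class_names = names(counts)) {
  if (is.null(class_names)) class_names <- paste0("class", seq_along(counts))
  amdnet:::new_dataset_index(
    path = sprintf("mem://%s/%d", rep(class_names, counts),
                   unlist(lapply(counts, seq_len))),
    class_index = rep(seq_along(counts) - 1L, counts),
    class_name = rep(class_names, counts),
    class_names = class_names)
}

# Reference confusion matrices used across metric tests.
private_cm <- function()
  amdnet:::as_confusion(rbind(c(98, 1, 5), c(0, 133, 0), c(1, 0, 109)),
                        class_names = c("dry_amd", "normal", "wet_amd"))

noor_cm <- function()
  amdnet:::as_confusion(diag(c(248, 243, 158)),
                        class_names = c("amd", "normal", "dme"))

# Brute-force one-vs-rest metrics: the independent oracle used against the
# metrics module.
brute_force_metrics <- function(m) {
  K <- nrow(m)
  pr <- re <- numeric(K)
  for (k in seq_len(K)) {
    tp <- m[k, k]
    fp <- sum(m[-k, k])
    fn <- sum(m[k, -k])
    pr[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
    re[k] <- if (tp + fn > 0) tp / (tp + fn) else 0
  }
  list(accuracy = sum(diag(m)) / sum(m), precision = pr, recall = re)
}
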