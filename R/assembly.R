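#' Full-model configuration
#'
#' Every hyperparameter of the proposed network, stated and unstated. Stated
#' values: 224x224x3 input, 32 stem filters, one Inception stage with 64
#' filters per branch, a 3x3/128 convolution after it, 64 DSEB filters, and a
#' ConvMixer stage with hidden dim `cm_h = 256`, depth `cm_d = 16`, kernel
#' `cm_k = 5` and patch size `cm_p = 2`, followed by global average pooling,
#' fully connected layers and a 3-class softmax. Unstated values (SE ratio,
#' hidden head widths, batch-norm placement) default to the reconciliation
#' ledger's choices and can be searched with [reconcile_config()].
#'
#' @param input_shape Input [tensor_shape()].
#' @param stem_filters Stem pointwise/conv filter count.
#' @param mim_branch_filters Filters per Inception branch.
#' @param mim_repeats How many times the modified Inception module is applied.
#' @param post_mim_filters,post_mim_kernel The standard convolution applied
#'   after the Inception stage.
#' @param dseb_filters DSEB pointwise filter count.
#' @param se_ratio SE bottleneck reduction ratio.
#' @param cm_h,cm_d,cm_k,cm_p ConvMixer hidden dim, depth, kernel, patch size.
#' @param head_hidden_units Integer vector of hidden fully connected widths
#'   between global average pooling and the classifier (may be empty).
#' @param n_classes Number of output classes.
#' @param bias Use bias terms on conv/dense layers.
#' @param bn_variant `"stem_only"` (batch normalization where explicitly
#'   stated: stem and ConvMixer) or `"post_mim"` (additionally after the
#'   post-Inception convolution).
#' @return An object of class `model_config`.
#' @export
model_config <- function(input_shape = tensor_shape(224, 224, 3),
                         stem_filters = 32L, mim_branch_filters = 64L,
                         mim_repeats = 1L, post_mim_filters = 128L,
                         post_mim_kernel = 3L, dseb_filters = 64L,
                         se_ratio = 16L, cm_h = 256L, cm_d = 16L, cm_k = 5L,
                         cm_p = 2L, head_hidden_units = 256L, n_classes = 3L,
                         bias = TRUE, bn_variant = "stem_only") {
  bn_variant <- match.arg(bn_variant, c("stem_only", "post_mim"))
  if (n_classes < 2) stop("n_classes must be at least 2", call. = FALSE)
  cfg <- list(input_shape = input_shape, stem_filters = as.integer(stem_filters),
              mim_branch_filters = as.integer(mim_branch_filters),
              mim_repeats = as.integer(mim_repeats),
              post_mim_filters = as.integer(post_mim_filters),
              post_mim_kernel = as.integer(post_mim_kernel),
              dseb_filters = as.integer(dseb_filters),
              se_ratio = as.integer(se_ratio), cm_h = as.integer(cm_h),
              cm_d = as.integer(cm_d), cm_k = as.integer(cm_k),
              cm_p = as.integer(cm_p),
              head_hidden_units = as.integer(head_hidden_units),
              n_classes = as.integer(n_classes), bias = isTRUE(bias),
              bn_variant = bn_variant)
  structure(cfg, class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config>\n")
  cat("  input:", format(x$input_shape), " classes:", x$n_classes, "\n")
  cat("  stem:", x$stem_filters, " mim:", x$mim_branch_filters, "x4 (x",
      x$mim_repeats, ") conv:", x$post_mim_kernel, "x", x$post_mim_kernel,
      "/", x$post_mim_filters, "\n", sep = "")
  cat("  dseb:", x$dseb_filters, " se_ratio:", x$se_ratio, "\n")
  cat("  convmixer: h=", x$cm_h, " d=", x$cm_d, " k=", x$cm_k, " p=", x$cm_p,
      "\n", sep = "")
  cat("  head: [", paste(x$head_hidden_units, collapse = ", "),
      "] bias:", x$bias, " bn:", x$bn_variant, "\n")
  invisible(x)
}

set_bias <- function(node, bias) {
  if (inherits(node, "conv_spec")) {
    node$bias <- bias
    return(node)
  }
  node$nodes <- lapply(node$nodes, set_bias, bias = bias)
  node
}

head_spec <- function(cin, hidden, n_classes, bias) {
  nodes <- list(conv_spec("gap", name = "gap"))
  i <- 0L
  for (w in hidden) {
    i <- i + 1L
    nodes[[length(nodes) + 1L]] <-
      conv_spec("dense", filters = w, bias = bias, activation = "relu",
                name = sprintf("fc%d", i))
  }
  nodes[[length(nodes) + 1L]] <-
    conv_spec("dense", filters = n_classes, bias = bias,
              activation = "softmax", name = "fc_out")
  block_spec(nodes, name = "head")
}

#' Block specification of the full model
#'
#' Assembles stem, Inception stage, post-Inception convolution, DSEB,
#' ConvMixer stage and classification head into one [block_spec()],
#' propagating shapes and raising a configuration error naming the stage if
#' the patch size does not divide the spatial dimensions that reach the
#' ConvMixer.
#'
#' @param config A [model_config()].
#' @param components Character subset of `c("mim", "dseb", "cm")`; used by
#'   [build_ablation()]. Stem and head are always present, and the
#'   post-Inception convolution is included iff `"mim"` is.
#' @return A [block_spec()].
#' @export
pm_spec <- function(config = model_config(),
                    components = c("mim", "dseb", "cm")) {
  stopifnot(inherits(config, "model_config"))
  s <- config$input_shape
  nodes <- list(build_stem(s))
  s <- spec_out_shape(nodes[[1]], s)
  if ("mim" %in% components) {
    for (i in seq_len(config$mim_repeats)) {
      mim <- build_mim(s, config$mim_branch_filters)
      nodes[[length(nodes) + 1L]] <- mim
      s <- spec_out_shape(mim, s)
    }
    pk <- config$post_mim_kernel
    post <- conv_spec("standard", c(pk, pk), config$post_mim_filters,
                      activation = "relu",
                      batchnorm = config$bn_variant == "post_mim",
                      name = "post_mim_conv")
    nodes[[length(nodes) + 1L]] <- post
    s <- spec_out_shape(post, s)
  }
  if ("dseb" %in% components) {
    dseb <- build_dseb(s, config$dseb_filters, config$se_ratio)
    nodes[[length(nodes) + 1L]] <- dseb
    s <- spec_out_shape(dseb, s)
  }
  if ("cm" %in% components) {
    if (s$height %% config$cm_p != 0L || s$width %% config$cm_p != 0L)
      stop(sprintf(paste0("configuration error at ConvMixer stage: patch size",
                          " %d does not divide the %d x %d feature map"),
                   config$cm_p, s$height, s$width), call. = FALSE)
    cm <- build_convmixer(s, config$cm_h, config$cm_d, config$cm_k, config$cm_p)
    nodes[[length(nodes) + 1L]] <- cm
    s <- spec_out_shape(cm, s)
  }
  nodes[[length(nodes) + 1L]] <-
    head_spec(s$channels, config$head_hidden_units, config$n_classes,
              config$bias)
  spec <- block_spec(nodes, topology = "sequential", name = "pm")
  if (!config$bias) spec <- set_bias(spec, FALSE)
  spec
}

#' Build the full executable model
#'
#' @param config A [model_config()].
#' @param seed Weight-initialization seed.
#' @return An `amdnet_model` mapping `(H, W, C, N)` batches to `(K, N)`
#'   class-probability matrices whose columns sum to 1.
#' @export
build_pm <- function(config = model_config(), seed = 42L)
  build_model(pm_spec(config), config$input_shape, seed = seed)

#' Ablation component flags
#'
#' Maps an ablation id (1-7) to the component triple it enables: 1 = MIM
#' only, 2 = DSEB only, 3 = ConvMixer only, 4 = DSEB + ConvMixer,
#' 5 = MIM + ConvMixer, 6 = MIM + DSEB, 7 = all three (the full model).
#'
#' @param id Integer in 1..7.
#' @return Named logical vector `c(mim=, dseb=, cm=)`.
#' @export
ablation_flags <- function(id) {
  if (!id %in% 1:7) stop("ablation id must be in 1..7", call. = FALSE)
  flags <- list(c(TRUE, FALSE, FALSE), c(FALSE, TRUE, FALSE),
                c(FALSE, FALSE, TRUE), c(FALSE, TRUE, TRUE),
                c(TRUE, FALSE, TRUE), c(TRUE, TRUE, FALSE),
                c(TRUE, TRUE, TRUE))[[id]]
  stats::setNames(flags, c("mim", "dseb", "cm"))
}

#' Build an ablation variant
#'
#' Chains exactly the flagged components in full-model order; the stem and
#' the GAP/FC/softmax head are always retained, and the post-Inception
#' convolution accompanies the Inception stage.
#'
#' @param id Ablation id in 1..7 (7 is the full model).
#' @param config A [model_config()].
#' @param seed Weight-initialization seed.
#' @return An `amdnet_model` with the same I/O contract as [build_pm()].
#' @export
build_ablation <- function(id, config = model_config(), seed = 42L) {
  fl <- ablation_flags(id)
  build_model(pm_spec(config, components = names(fl)[fl]),
              config$input_shape, seed = seed)
}

#' Default reconciliation search space
#'
#' The finite space of unstated hyperparameters searched when reconciling
#' the model against a published parameter total: SE reduction ratio,
#' hidden fully connected widths, bias usage, and batch-norm placement.
#'
#' @return Named list of candidate sets.
#' @export
default_search_space <- function() {
  list(se_ratio = c(2L, 4L, 8L, 16L),
       head_hidden_units = list(integer(0), 256L, 128L, 512L),
       bias = TRUE,
       bn_variant = c("stem_only", "post_mim"))
}

config_distance <- function(cfg, ref) {
  d <- 0L
  for (f in c("se_ratio", "bias", "bn_variant"))
    d <- d + as.integer(!identical(cfg[[f]], ref[[f]]))
  d + as.integer(!identical(cfg$head_hidden_units, ref$head_hidden_units))
}

#' Reconcile unstated hyperparameters against a target parameter total
#'
#' Exhaustively enumerates the finite search space, computes the analytic
#' trainable-parameter total of each resulting configuration, and returns
#' every configuration matching `target`, sorted by distance from the
#' package defaults. If none matches, the result carries a nearest-miss
#' report (configuration, count, delta) instead.
#'
#' @param search_space Named list as in [default_search_space()].
#' @param target Target trainable-parameter total.
#' @param base A [model_config()] supplying all non-searched fields.
#' @return A `reconcile_result`: list with `matches` (list of
#'   [model_config()]), `table` (data.frame of every candidate and count),
#'   and `nearest_miss` (`NULL` when matches exist).
#' @export
reconcile_config <- function(search_space = default_search_space(),
                             target = 1650020L, base = model_config()) {
  hh <- search_space$head_hidden_units
  if (!is.list(hh)) hh <- list(hh)
  grid <- expand.grid(se = seq_along(search_space$se_ratio),
                      hd = seq_along(hh),
                      bi = seq_along(search_space$bias),
                      bn = seq_along(search_space$bn_variant))
  cfgs <- vector("list", nrow(grid))
  counts <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- base
    cfg$se_ratio <- search_space$se_ratio[grid$se[i]]
    cfg$head_hidden_units <- as.integer(hh[[grid$hd[i]]])
    cfg$bias <- search_space$bias[grid$bi[i]]
    cfg$bn_variant <- search_space$bn_variant[grid$bn[i]]
    cfgs[[i]] <- cfg
    counts[i] <- block_params(pm_spec(cfg), cfg$input_shape)
  }
  tab <- data.frame(
    se_ratio = vapply(cfgs, `[[`, integer(1), "se_ratio"),
    head_hidden_units = vapply(cfgs, function(c)
      paste(c$head_hidden_units, collapse = "+"), character(1)),
    bias = vapply(cfgs, `[[`, logical(1), "bias"),
    bn_variant = vapply(cfgs, `[[`, character(1), "bn_variant"),
    params = counts, delta = counts - as.integer(target),
    stringsAsFactors = FALSE)
  hit <- which(counts == target)
  if (length(hit)) {
    ord <- order(vapply(cfgs[hit], config_distance, integer(1), ref = base))
    res <- list(matches = cfgs[hit][ord], table = tab, nearest_miss = NULL,
                target = target)
  } else {
    j <- which.min(abs(counts - target))
    res <- list(matches = list(), table = tab,
                nearest_miss = list(config = cfgs[[j]], count = counts[j],
                                    delta = counts[j] - as.integer(target)),
                target = target)
  }
  structure(res, class = "reconcile_result")
}

#' @export
print.reconcile_result <- function(x, ...) {
  cat("<reconcile_result> target:", format(x$target, big.mark = ","), "\n")
  if (length(x$matches)) {
    cat(length(x$matches), "matching configuration(s); closest to defaults:\n")
    print(x$matches[[1]])
  } else {
    nm <- x$nearest_miss
    cat("no exact match;", nrow(x$table), "configurations searched\n")
    cat("nearest miss:", format(nm$count, big.mark = ","),
        sprintf("(delta %+d, %.2f%%)\n", nm$delta, 100 * nm$delta / x$target))
    print(nm$config)
  }
  invisible(x)
}

## config <-> YAML

config_to_list <- function(cfg) {
  out <- unclass(cfg)
  out$input_shape <- unclass(cfg$input_shape)
  out$head_hidden_units <- as.list(cfg$head_hidden_units)
  out
}

#' Read / write model configurations as YAML
#'
#' Omitted fields take the package defaults.
#'
#' @param config A [model_config()].
#' @param path File path.
#' @return `write_config_yaml` returns `path` invisibly; `read_config_yaml`
#'   returns a [model_config()].
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(x$input_shape))
    args$input_shape <- tensor_shape(x$input_shape$height, x$input_shape$width,
                                     x$input_shape$channels)
  for (f in c("stem_filters", "mim_branch_filters", "mim_repeats",
              "post_mim_filters", "post_mim_kernel", "dseb_filters",
              "se_ratio", "cm_h", "cm_d", "cm_k", "cm_p", "n_classes",
              "bias", "bn_variant"))
    if (!is.null(x[[f]])) args[[f]] <- x[[f]]
  if (!is.null(x$head_hidden_units))
    args$head_hidden_units <- as.integer(unlist(x$head_hidden_units))
  do.call(model_config, args)
}
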