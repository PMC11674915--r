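#' Tensor shape
#'
#' Height x width x channels descriptor for a feature map.
#'
#' @param height,width,channels Positive integers.
#' @return An object of class `tensor_shape`.
#' @export
tensor_shape <- function(height, width, channels) {
  for (v in c(height, width, channels)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 || v != round(v))
      stop("tensor_shape fields must be positive integers", call. = FALSE)
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 channels = as.integer(channels)),
            class = "tensor_shape")
}

#' @export
format.tensor_shape <- function(x, ...)
  sprintf("%d x %d x %d", x$height, x$width, x$channels)

#' @export
print.tensor_shape <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

CONV_KINDS <- c("standard", "depthwise", "pointwise", "maxpool", "dense", "gap")
ACTIVATIONS <- c("none", "relu", "gelu", "sigmoid", "softmax")

#' Convolutional layer specification
#'
#' Declarative description of a single layer: the unit of parameter auditing
#' and of executable-model construction. `pointwise` layers are constrained
#' to 1x1 kernels; `depthwise` layers have no independent filter count
#' (output channels equal input channels); `maxpool` and `gap` carry no
#' trainable parameters.
#'
#' @param kind One of `"standard"`, `"depthwise"`, `"pointwise"`,
#'   `"maxpool"`, `"dense"`, `"gap"`.
#' @param kernel Integer vector of length 2 `(kh, kw)`; ignored for
#'   `dense`/`gap`.
#' @param filters Output channel count; must be `NA` for `depthwise`,
#'   `maxpool` and `gap`.
#' @param stride Positive integer stride.
#' @param padding `"same"` or `"valid"`.
#' @param bias Logical; include additive bias terms.
#' @param activation Activation applied after the layer.
#' @param batchnorm Logical; append batch normalization (2 trainable
#'   parameters per output channel).
#' @param name Layer name used in audits.
#' @return An object of class `conv_spec`.
#' @export
conv_spec <- function(kind, kernel = c(1L, 1L), filters = NA, stride = 1L,
                      padding = "same", bias = TRUE, activation = "none",
                      batchnorm = FALSE, name = kind) {
  kind <- match.arg(kind, CONV_KINDS)
  activation <- match.arg(activation, ACTIVATIONS)
  padding <- match.arg(padding, c("same", "valid"))
  kernel <- as.integer(kernel)
  if (length(kernel) == 1L) kernel <- c(kernel, kernel)
  if (any(kernel < 1L)) stop("kernel dimensions must be positive", call. = FALSE)
  if (kind == "pointwise" && !all(kernel == 1L))
    stop("pointwise convolutions require a 1x1 kernel", call. = FALSE)
  if (kind %in% c("depthwise", "maxpool", "gap") && !is.na(filters))
    stop(sprintf("invalid spec: %s layers have no independent filter count", kind),
         call. = FALSE)
  if (kind %in% c("standard", "pointwise", "dense")) {
    if (is.na(filters) || filters < 1)
      stop(sprintf("%s layers require a positive filter count", kind), call. = FALSE)
    filters <- as.integer(filters)
  }
  structure(list(kind = kind, kernel = kernel, filters = filters,
                 stride = as.integer(stride), padding = padding,
                 bias = isTRUE(bias), activation = activation,
                 batchnorm = isTRUE(batchnorm), name = name),
            class = "conv_spec")
}

#' Composite block specification
#'
#' An ordered collection of [conv_spec()] layers and/or nested blocks, with a
#' topology describing how they are wired:
#' * `sequential` - nodes applied in order;
#' * `parallel_concat` - all nodes consume the same input and their outputs
#'   are concatenated along the channel axis;
#' * `residual` - the (sequential) node chain output is added to the block
#'   input, which requires identical input and output shapes;
#' * `se_scale` - squeeze-and-excitation gating: the two dense nodes form the
#'   bottleneck, and the resulting per-channel weights rescale the input.
#'
#' @param nodes List of `conv_spec` or `block_spec` objects.
#' @param topology Wiring of the nodes.
#' @param name Block name used in audits.
#' @return An object of class `block_spec`.
#' @export
block_spec <- function(nodes, topology = "sequential", name = "block") {
  topology <- match.arg(topology,
                        c("sequential", "parallel_concat", "residual", "se_scale"))
  ok <- vapply(nodes, function(n) inherits(n, c("conv_spec", "block_spec")),
               logical(1))
  if (!length(nodes) || !all(ok))
    stop("nodes must be conv_spec or block_spec objects", call. = FALSE)
  structure(list(nodes = nodes, topology = topology, name = name),
            class = "block_spec")
}

#' Trainable parameter count of a single layer
#'
#' Analytic count of the trainable scalars of a layer given its input
#' channel count, biases included. Batch normalization contributes two
#' trainable parameters (scale and shift) per output channel; moving
#' statistics are not trainable and are excluded.
#'
#' @param spec A [conv_spec()].
#' @param in_channels Positive integer input channel count.
#' @return Non-negative integer.
#' @examples
#' param_count(conv_spec("standard", c(1, 1), 64), 3)   # 256
#' param_count(conv_spec("depthwise", c(3, 3)), 3)      # 30
#' @export
param_count <- function(spec, in_channels) {
  stopifnot(inherits(spec, "conv_spec"))
  if (!is.numeric(in_channels) || in_channels < 1 || in_channels != round(in_channels))
    stop("in_channels must be a positive integer", call. = FALSE)
  cin <- as.integer(in_channels)
  kh <- spec$kernel[1]; kw <- spec$kernel[2]
  b <- as.integer(spec$bias)
  n <- switch(spec$kind,
    standard  = (kh * kw * cin + b) * spec$filters,
    pointwise = (cin + b) * spec$filters,
    depthwise = kh * kw * cin + b * cin,
    dense     = (cin + b) * spec$filters,
    maxpool   = 0L,
    gap       = 0L)
  if (spec$batchnorm) n <- n + 2L * spec_out_channels(spec, cin)
  as.integer(n)
}

#' Output channel count of a layer
#' @param spec A [conv_spec()].
#' @param in_channels Input channel count.
#' @return Integer.
#' @keywords internal
spec_out_channels <- function(spec, in_channels) {
  switch(spec$kind,
    standard = , pointwise = , dense = spec$filters,
    depthwise = , maxpool = , gap = as.integer(in_channels))
}

# Spatial output size for one dimension under same/valid padding.
out_dim <- function(n, k, stride, padding) {
  if (padding == "same") as.integer(ceiling(n / stride))
  else as.integer(floor((n - k) / stride) + 1L)
}

# Leading padding (top/left) mirroring the usual same-padding convention.
pad_before <- function(n, k, stride, padding) {
  if (padding == "valid") return(0L)
  o <- out_dim(n, k, stride, padding)
  total <- max((o - 1L) * stride + k - n, 0L)
  as.integer(total %/% 2L)
}

#' Shape propagation through a layer or block
#'
#' @param spec A [conv_spec()] or [block_spec()].
#' @param in_shape A [tensor_shape()].
#' @return The output [tensor_shape()]. `dense` and `gap` layers collapse the
#'   spatial dimensions to 1x1.
#' @export
spec_out_shape <- function(spec, in_shape) {
  stopifnot(inherits(in_shape, "tensor_shape"))
  if (inherits(spec, "block_spec")) return(block_out_shape(spec, in_shape))
  if (spec$kind == "gap")
    return(tensor_shape(1L, 1L, in_shape$channels))
  if (spec$kind == "dense")
    return(tensor_shape(1L, 1L, spec$filters))
  h <- out_dim(in_shape$height, spec$kernel[1], spec$stride, spec$padding)
  w <- out_dim(in_shape$width, spec$kernel[2], spec$stride, spec$padding)
  tensor_shape(h, w, spec_out_channels(spec, in_shape$channels))
}

block_out_shape <- function(block, in_shape) {
  switch(block$topology,
    sequential = {
      s <- in_shape
      for (nd in block$nodes) s <- spec_out_shape(nd, s)
      s
    },
    parallel_concat = {
      shapes <- lapply(block$nodes, spec_out_shape, in_shape = in_shape)
      hw <- unique(vapply(shapes, function(s) c(s$height, s$width), integer(2)),
                   MARGIN = 2)
      if (ncol(hw) != 1L)
        stop("parallel_concat branches disagree on output spatial dims",
             call. = FALSE)
      tensor_shape(shapes[[1]]$height, shapes[[1]]$width,
                   sum(vapply(shapes, function(s) s$channels, integer(1))))
    },
    residual = {
      s <- in_shape
      for (nd in block$nodes) s <- spec_out_shape(nd, s)
      if (!identical(unclass(s), unclass(in_shape)))
        stop("residual block requires identical input and output shapes",
             call. = FALSE)
      s
    },
    se_scale = in_shape)
}

#' Per-layer audit of a block specification
#'
#' Walks a [block_spec()] and produces one audit row per parameterized
#' layer (plus zero-parameter pooling rows) in the classical
#' layer / input / kernel_size-filter / parameter-count layout. Batch
#' normalization attached to a layer is reported as its own row.
#'
#' @param block A [block_spec()] or single [conv_spec()].
#' @param in_shape Input [tensor_shape()].
#' @param input_name Label of the input feeding the block.
#' @return A `layer_audit`: list with `rows` (data.frame with columns
#'   `layer`, `input`, `kernel_filter`, `params`) and `total`.
#' @export
audit_block <- function(block, in_shape, input_name = "Input") {
  rows <- audit_walk(block, in_shape, input_name)
  structure(list(rows = rows, total = sum(rows$params)), class = "layer_audit")
}

audit_walk <- function(node, in_shape, input_name) {
  if (inherits(node, "conv_spec")) {
    kf <- switch(node$kind,
      dense = sprintf("dense/%d", node$filters),
      gap = "global_avg_pool",
      sprintf("%d x %d%s", node$kernel[1], node$kernel[2],
              if (!is.na(node$filters)) sprintf("/%d", node$filters) else ""))
    bn_params <- if (node$batchnorm)
      2L * spec_out_channels(node, in_shape$channels) else 0L
    df <- data.frame(layer = node$name, input = input_name,
                     kernel_filter = kf,
                     params = param_count(node, in_shape$channels) - bn_params,
                     stringsAsFactors = FALSE)
    if (node$batchnorm)
      df <- rbind(df, data.frame(layer = paste0(node$name, "_bn"),
                                 input = node$name, kernel_filter = "batchnorm",
                                 params = bn_params, stringsAsFactors = FALSE))
    return(df)
  }
  stopifnot(inherits(node, "block_spec"))
  out <- list()
  if (node$topology %in% c("sequential", "residual")) {
    prev <- input_name
    s <- in_shape
    for (nd in node$nodes) {
      df <- audit_walk(nd, s, prev)
      out[[length(out) + 1L]] <- df
      prev <- df$layer[nrow(df)]
      s <- spec_out_shape(nd, s)
    }
  } else if (node$topology == "parallel_concat") {
    for (nd in node$nodes)
      out[[length(out) + 1L]] <- audit_walk(nd, in_shape, input_name)
  } else { # se_scale: dense bottleneck operating on pooled channels
    prev <- paste0(input_name, "_gap")
    s <- tensor_shape(1L, 1L, in_shape$channels)
    for (nd in node$nodes) {
      df <- audit_walk(nd, s, prev)
      out[[length(out) + 1L]] <- df
      prev <- df$layer[nrow(df)]
      s <- spec_out_shape(nd, s)
    }
  }
  do.call(rbind, out)
}

#' Total trainable parameters of a block specification
#'
#' @inheritParams audit_block
#' @return Non-negative integer: the analytic trainable-parameter total.
#' @export
block_params <- function(block, in_shape, input_name = "Input") {
  audit_block(block, in_shape, input_name)$total
}

#' @export
print.layer_audit <- function(x, ...) {
  print(x$rows, row.names = FALSE)
  cat("Total number of parameters:", format(x$total, big.mark = ","), "\n")
  invisible(x)
}

#' Write an audit table as CSV
#'
#' Columns `layer,input,kernel_filter,params` with a final `total` row.
#'
#' @param audit A `layer_audit`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_audit_csv <- function(audit, path) {
  stopifnot(inherits(audit, "layer_audit"))
  df <- rbind(audit$rows,
              data.frame(layer = "total", input = "", kernel_filter = "",
                         params = audit$total, stringsAsFactors = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

## YAML serialization mirroring the layer/input/kernel_size-filter/params schema

spec_to_list <- function(node) {
  if (inherits(node, "conv_spec")) {
    list(layer = node$name, kind = node$kind,
         kernel_size = paste(node$kernel, collapse = "x"),
         filters = if (is.na(node$filters)) NULL else node$filters,
         stride = node$stride, padding = node$padding, bias = node$bias,
         activation = node$activation, batchnorm = node$batchnorm)
  } else {
    list(block = node$name, topology = node$topology,
         nodes = lapply(node$nodes, spec_to_list))
  }
}

list_to_spec <- function(x) {
  if (!is.null(x$block)) {
    block_spec(lapply(x$nodes, list_to_spec), topology = x$topology,
               name = x$block)
  } else {
    k <- as.integer(strsplit(x$kernel_size, "x")[[1]])
    conv_spec(x$kind, kernel = k,
              filters = if (is.null(x$filters)) NA else x$filters,
              stride = x$stride, padding = x$padding, bias = x$bias,
              activation = x$activation, batchnorm = x$batchnorm,
              name = x$layer)
  }
}

#' Serialize / deserialize block specifications as YAML
#'
#' @param block A [block_spec()].
#' @param path File path.
#' @return `write_block_yaml` returns `path` invisibly; `read_block_yaml`
#'   returns the reconstructed [block_spec()].
#' @export
write_block_yaml <- function(block, path) {
  yaml::write_yaml(spec_to_list(block), path)
  invisible(path)
}

#' @rdname write_block_yaml
#' @export
read_block_yaml <- function(path) list_to_spec(yaml::read_yaml(path))
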