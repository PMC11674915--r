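#' Network stem
#'
#' Entry block applied to the raw B-scan: a 5x5 standard convolution with 32
#' filters, a 3x3 depthwise convolution, a 1x1 pointwise convolution with 32
#' filters followed by batch normalization, and a 3x3 max-pooling layer. The
#' pooling uses stride 2, halving the spatial resolution before the Inception
#' stage; all convolutions use stride 1 and same padding with ReLU.
#'
#' @param in_shape Input [tensor_shape()] (224x224x3 by default in the full
#'   model; any valid shape is accepted).
#' @return A sequential [block_spec()] with 32 output channels.
#' @export
build_stem <- function(in_shape) {
  stopifnot(inherits(in_shape, "tensor_shape"))
  block_spec(list(
    conv_spec("standard", c(5, 5), 32, activation = "relu", name = "stem_conv"),
    conv_spec("depthwise", c(3, 3), activation = "relu", name = "stem_dconv"),
    conv_spec("pointwise", c(1, 1), 32, activation = "relu", batchnorm = TRUE,
              name = "stem_pconv"),
    conv_spec("maxpool", c(3, 3), stride = 2L, name = "stem_maxpool")
  ), topology = "sequential", name = "stem")
}

#' Standard Inception module
#'
#' Four parallel branches on a common input: a 1x1 convolution; a 3x3
#' convolution followed by a 1x1 convolution; a 5x5 convolution followed by
#' a 1x1 convolution; and a 3x3 max-pooling followed by a 1x1 convolution.
#' The branch outputs are concatenated, so the module emits
#' `4 * branch_filters` channels. The spatial convolution precedes the 1x1
#' convolution in the 3x3 and 5x5 branches, the ordering that the reference
#' per-layer parameter table implies. All layers use stride 1, same padding
#' and ReLU.
#'
#' @param in_shape Input [tensor_shape()].
#' @param branch_filters Filters per branch (64 in the reference module).
#' @return A `parallel_concat` [block_spec()].
#' @export
build_inception_standard <- function(in_shape, branch_filters = 64L) {
  stopifnot(inherits(in_shape, "tensor_shape"), branch_filters >= 1)
  f <- as.integer(branch_filters)
  cv <- function(k, name) conv_spec("standard", c(k, k), f, activation = "relu",
                                    name = name)
  block_spec(list(
    cv(1, "im_conv1"),
    block_spec(list(cv(3, "im_conv2"), cv(1, "im_conv3")), name = "im_branch3"),
    block_spec(list(cv(5, "im_conv4"), cv(1, "im_conv5")), name = "im_branch5"),
    block_spec(list(conv_spec("maxpool", c(3, 3), name = "im_maxpool"),
                    cv(1, "im_conv6")), name = "im_branchpool")
  ), topology = "parallel_concat", name = "inception")
}

#' Modified Inception module (MIM)
#'
#' The Inception variant in which the 3x3 and 5x5 standard convolutions are
#' replaced by depthwise separable pairs: a 3x3 depthwise convolution
#' followed by a 1x1 pointwise convolution, and a 5x5 depthwise convolution
#' followed by a 1x1 pointwise convolution. The 1x1 branch and the
#' maxpool+1x1 branch are unchanged. This cuts the module's parameter count
#' roughly thirteen-fold at 64 filters per branch on a 3-channel input.
#'
#' @inheritParams build_inception_standard
#' @return A `parallel_concat` [block_spec()] emitting `4 * branch_filters`
#'   channels.
#' @export
build_mim <- function(in_shape, branch_filters = 64L) {
  stopifnot(inherits(in_shape, "tensor_shape"), branch_filters >= 1)
  f <- as.integer(branch_filters)
  pw <- function(name) conv_spec("pointwise", c(1, 1), f, activation = "relu",
                                 name = name)
  block_spec(list(
    conv_spec("standard", c(1, 1), f, activation = "relu", name = "mim_conv1"),
    block_spec(list(conv_spec("depthwise", c(3, 3), activation = "relu",
                              name = "mim_dconv1"), pw("mim_pconv1")),
               name = "mim_branch3"),
    block_spec(list(conv_spec("depthwise", c(5, 5), activation = "relu",
                              name = "mim_dconv2"), pw("mim_pconv2")),
               name = "mim_branch5"),
    block_spec(list(conv_spec("maxpool", c(3, 3), name = "mim_maxpool"),
                    conv_spec("standard", c(1, 1), f, activation = "relu",
                              name = "mim_conv6")),
               name = "mim_branchpool")
  ), topology = "parallel_concat", name = "mim")
}

#' Squeeze-and-excitation block
#'
#' Channel attention: global average pooling squeezes each channel to a
#' scalar, a bottleneck pair of dense layers (C -> C/ratio with ReLU, then
#' C/ratio -> C with a logistic gate) produces per-channel weights in (0,1),
#' and the input feature map is rescaled channel-wise. Output shape equals
#' input shape.
#'
#' @param channels Input channel count.
#' @param ratio Bottleneck reduction ratio; the bottleneck width is
#'   `max(1, floor(channels / ratio))`.
#' @return An `se_scale` [block_spec()].
#' @export
build_se <- function(channels, ratio = 16L) {
  if (!is.numeric(channels) || channels < 1)
    stop("channels must be a positive integer", call. = FALSE)
  bott <- max(1L, as.integer(channels) %/% as.integer(ratio))
  block_spec(list(
    conv_spec("dense", filters = bott, activation = "relu", name = "se_reduce"),
    conv_spec("dense", filters = as.integer(channels), activation = "sigmoid",
              name = "se_expand")
  ), topology = "se_scale", name = "se")
}

#' Depthwise squeeze-and-excitation block (DSEB)
#'
#' Two depthwise separable convolutions followed by channel attention: a 5x5
#' depthwise convolution with a 1x1 pointwise convolution (`filters`
#' outputs), then a 3x3 depthwise convolution with a 1x1 pointwise
#' convolution (`filters` outputs), then an SE block. Stride 1 and same
#' padding throughout, so spatial dimensions are preserved and the output
#' has `filters` channels.
#'
#' @param in_shape Input [tensor_shape()].
#' @param filters Pointwise filter count (64 in the full model).
#' @param se_ratio SE bottleneck reduction ratio.
#' @return A sequential [block_spec()].
#' @export
build_dseb <- function(in_shape, filters = 64L, se_ratio = 16L) {
  stopifnot(inherits(in_shape, "tensor_shape"), filters >= 1)
  f <- as.integer(filters)
  block_spec(list(
    conv_spec("depthwise", c(5, 5), activation = "relu", name = "dseb_dconv1"),
    conv_spec("pointwise", c(1, 1), f, activation = "relu", name = "dseb_pconv1"),
    conv_spec("depthwise", c(3, 3), activation = "relu", name = "dseb_dconv2"),
    conv_spec("pointwise", c(1, 1), f, activation = "relu", name = "dseb_pconv2"),
    build_se(f, se_ratio)
  ), topology = "sequential", name = "dseb")
}

#' ConvMixer stage
#'
#' Patch embedding followed by depth-wise/point-wise mixing blocks. The
#' embedding is a standard convolution with kernel and stride equal to the
#' patch size `p` and `h` filters, followed by GELU and batch normalization,
#' mapping an `n x n` input to an `h x n/p x n/p` feature map. Each of the
#' `d` mixer blocks applies a residual depthwise convolution (kernel `k`,
#' same padding, GELU, batch normalization) and then a pointwise convolution
#' with `h` filters (GELU, batch normalization); every block preserves the
#' `(n/p, n/p, h)` shape.
#'
#' @param in_shape Input [tensor_shape()]; `p` must divide both spatial dims.
#' @param h Hidden dimension (filters of the embedding and mixing layers).
#' @param d Depth: number of mixer blocks (`d = 0` leaves only the
#'   embedding).
#' @param k Depthwise kernel size.
#' @param p Patch size.
#' @return A sequential [block_spec()].
#' @export
build_convmixer <- function(in_shape, h = 256L, d = 16L, k = 5L, p = 2L) {
  stopifnot(inherits(in_shape, "tensor_shape"))
  if (in_shape$height %% p != 0L || in_shape$width %% p != 0L)
    stop(sprintf(
      "invalid config: patch size %d does not divide spatial dims %d x %d",
      p, in_shape$height, in_shape$width), call. = FALSE)
  nodes <- list(conv_spec("standard", c(p, p), as.integer(h), stride = as.integer(p),
                          padding = "valid", activation = "gelu",
                          batchnorm = TRUE, name = "cm_embed"))
  if (d > 0) for (i in seq_len(d)) {
    nodes[[length(nodes) + 1L]] <- block_spec(list(
      conv_spec("depthwise", c(k, k), activation = "gelu", batchnorm = TRUE,
                name = sprintf("cm%d_dconv", i))
    ), topology = "residual", name = sprintf("cm%d_res", i))
    nodes[[length(nodes) + 1L]] <-
      conv_spec("pointwise", c(1, 1), as.integer(h), activation = "gelu",
                batchnorm = TRUE, name = sprintf("cm%d_pconv", i))
  }
  block_spec(nodes, topology = "sequential", name = "convmixer")
}
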