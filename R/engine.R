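# Executable-model engine.
#
# Compiled networks are trees of environments. Node kinds:
#   layer    - a parameterized or elementwise operation
#   chain    - sequential list of nodes
#   concat   - parallel branches joined along the channel axis
#   residual - body output added to the node input
# Batched feature maps are column-major arrays with dim (H, W, C, N);
# post-pooling features are (C, N) matrices.

new_node <- function(kind, ...) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  for (nm in names(list(...))) assign(nm, list(...)[[nm]], envir = e)
  e
}

# broadcast a per-channel vector (length C, or C*N matrix) over (H,W,C,N)
bc_channel <- function(v, hw) rep(as.vector(v), each = hw)

channel_sum <- function(a, hw, C, N)
  rowSums(matrix(.colSums(matrix(a, hw, C * N), hw, C * N), C, N))

he_init <- function(nr, nc, fan_in)
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)

## ---- layer construction -----------------------------------------------

make_conv_layer <- function(spec, cin) {
  kh <- spec$kernel[1]; kw <- spec$kernel[2]
  w <- he_init(kh * kw * cin, spec$filters, kh * kw * cin)
  params <- list(w = w)
  if (spec$bias) params$b <- numeric(spec$filters)
  new_node("layer", type = "conv", kh = kh, kw = kw, stride = spec$stride,
           padding = spec$padding, cin = cin, f = spec$filters,
           params = params, grads = NULL, name = spec$name)
}

make_dwconv_layer <- function(spec, cin) {
  kh <- spec$kernel[1]; kw <- spec$kernel[2]
  params <- list(w = he_init(kh * kw, cin, kh * kw))
  if (spec$bias) params$b <- numeric(cin)
  new_node("layer", type = "dwconv", kh = kh, kw = kw, stride = spec$stride,
           padding = spec$padding, cin = cin, params = params, grads = NULL,
           name = spec$name)
}

make_dense_layer <- function(spec, cin) {
  params <- list(w = he_init(cin, spec$filters, cin))
  if (spec$bias) params$b <- numeric(spec$filters)
  new_node("layer", type = "dense", cin = cin, f = spec$filters,
           params = params, grads = NULL, name = spec$name)
}

make_bn_layer <- function(channels, name) {
  new_node("layer", type = "bn", c = channels,
           params = list(gamma = rep(1, channels), beta = numeric(channels)),
           grads = NULL, momentum = 0.9, eps = 1e-5,
           state = list(rm = numeric(channels), rv = rep(1, channels)),
           name = name)
}

make_se_layer <- function(block, cin) {
  bott <- block$nodes[[1]]$filters
  cout <- block$nodes[[2]]$filters
  if (cout != cin)
    stop("SE block expansion width must equal the input channel count",
         call. = FALSE)
  new_node("layer", type = "se", cin = cin, bott = bott,
           params = list(w1 = he_init(cin, bott, cin), b1 = numeric(bott),
                         w2 = he_init(bott, cin, bott), b2 = numeric(cin)),
           grads = NULL, name = block$name)
}

# compile one conv_spec into its layer (+activation, +batchnorm) sequence
compile_conv_spec <- function(spec, in_shape) {
  cin <- in_shape$channels
  main <- switch(spec$kind,
    standard  = , pointwise = make_conv_layer(spec, cin),
    depthwise = make_dwconv_layer(spec, cin),
    dense     = make_dense_layer(spec, cin),
    maxpool   = new_node("layer", type = "maxpool", kh = spec$kernel[1],
                         kw = spec$kernel[2], stride = spec$stride,
                         padding = spec$padding, params = list(),
                         name = spec$name),
    gap       = new_node("layer", type = "gap", params = list(),
                         name = spec$name))
  items <- list(main)
  if (spec$activation != "none")
    items[[length(items) + 1L]] <-
      new_node("layer", type = spec$activation, params = list(),
               name = paste0(spec$name, "_", spec$activation))
  if (spec$batchnorm)
    items[[length(items) + 1L]] <-
      make_bn_layer(spec_out_channels(spec, cin), paste0(spec$name, "_bn"))
  items
}

compile_node <- function(node, in_shape) {
  if (inherits(node, "conv_spec"))
    return(new_node("chain", items = compile_conv_spec(node, in_shape)))
  stopifnot(inherits(node, "block_spec"))
  switch(node$topology,
    sequential = {
      items <- list(); s <- in_shape
      for (nd in node$nodes) {
        items[[length(items) + 1L]] <- compile_node(nd, s)
        s <- spec_out_shape(nd, s)
      }
      new_node("chain", items = items)
    },
    parallel_concat = {
      branches <- lapply(node$nodes, compile_node, in_shape = in_shape)
      new_node("concat", branches = branches)
    },
    residual = {
      items <- list(); s <- in_shape
      for (nd in node$nodes) {
        items[[length(items) + 1L]] <- compile_node(nd, s)
        s <- spec_out_shape(nd, s)
      }
      new_node("residual", body = new_node("chain", items = items))
    },
    se_scale = make_se_layer(node, in_shape$channels))
}

#' Compile a block specification into an executable model
#'
#' Instantiates weights for every layer of `spec` and returns a model that
#' can be run forward (and trained) on batches of `in_shape` inputs.
#'
#' @param spec A [block_spec()].
#' @param in_shape Input [tensor_shape()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `amdnet_model`.
#' @export
build_model <- function(spec, in_shape, seed = 42L) {
  stopifnot(inherits(spec, "block_spec"), inherits(in_shape, "tensor_shape"))
  out_shape <- spec_out_shape(spec, in_shape)  # validates wiring
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  net <- compile_node(spec, in_shape)
  structure(list(net = net, spec = spec, in_shape = in_shape,
                 out_shape = out_shape, seed = seed),
            class = "amdnet_model")
}

## ---- forward ----------------------------------------------------------

pads_for <- function(n, k, stride, padding) {
  c(out = out_dim(n, k, stride, padding), pad = pad_before(n, k, stride, padding))
}

layer_fwd <- function(l, x, training) {
  switch(l$type,
    conv = {
      d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
      if (l$kh == 1L && l$kw == 1L && l$stride == 1L) {
        xm <- matrix(aperm(x, c(1, 2, 4, 3)), H * W * N, C)
        y <- xm %*% l$params$w
        if (!is.null(l$params$b)) y <- y + rep(l$params$b, each = nrow(y))
        l$cache <- list(x = x, d = d)
        aperm(array(y, c(H, W, N, l$f)), c(1, 2, 4, 3))
      } else {
        ph <- pads_for(H, l$kh, l$stride, l$padding)
        pw <- pads_for(W, l$kw, l$stride, l$padding)
        cols <- im2col_cpp(x, H, W, C, N, l$kh, l$kw, l$stride,
                           ph[["pad"]], pw[["pad"]], ph[["out"]], pw[["out"]])
        y <- cols %*% l$params$w
        if (!is.null(l$params$b)) y <- y + rep(l$params$b, each = nrow(y))
        l$cache <- list(x = x, d = d, ph = ph, pw = pw)
        aperm(array(y, c(ph[["out"]], pw[["out"]], N, l$f)), c(1, 2, 4, 3))
      }
    },
    dwconv = {
      d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
      ph <- pads_for(H, l$kh, l$stride, l$padding)
      pw <- pads_for(W, l$kw, l$stride, l$padding)
      l$cache <- list(x = x, d = d, ph = ph, pw = pw)
      dwconv_fwd_cpp(x, H, W, C, N, l$params$w,
                     if (is.null(l$params$b)) numeric(0) else l$params$b,
                     l$kh, l$kw, l$stride, ph[["pad"]], pw[["pad"]],
                     ph[["out"]], pw[["out"]])
    },
    maxpool = {
      d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
      ph <- pads_for(H, l$kh, l$stride, l$padding)
      pw <- pads_for(W, l$kw, l$stride, l$padding)
      r <- maxpool_fwd_cpp(x, H, W, C, N, l$kh, l$kw, l$stride,
                           ph[["pad"]], pw[["pad"]], ph[["out"]], pw[["out"]])
      l$cache <- list(argmax = r$argmax, d = d)
      r$out
    },
    bn = {
      d <- dim(x); hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
      if (training) {
        mu <- channel_sum(x, hw, C, N) / (hw * N)
        ex2 <- channel_sum(x * x, hw, C, N) / (hw * N)
        v <- pmax(ex2 - mu^2, 0)
        l$state$rm <- l$momentum * l$state$rm + (1 - l$momentum) * mu
        l$state$rv <- l$momentum * l$state$rv + (1 - l$momentum) * v
      } else {
        mu <- l$state$rm; v <- l$state$rv
      }
      ivar <- 1 / sqrt(v + l$eps)
      xhat <- (x - bc_channel(mu, hw)) * bc_channel(ivar, hw)
      l$cache <- list(xhat = xhat, ivar = ivar, d = d, training = training)
      xhat * bc_channel(l$params$gamma, hw) + bc_channel(l$params$beta, hw)
    },
    gap = {
      d <- dim(x); hw <- d[1] * d[2]
      l$cache <- list(d = d)
      matrix(.colMeans(matrix(x, hw, d[3] * d[4]), hw, d[3] * d[4]), d[3], d[4])
    },
    dense = {
      l$cache <- list(x = x)
      y <- crossprod(l$params$w, x)
      if (!is.null(l$params$b)) y <- y + l$params$b
      y
    },
    relu = {
      mask <- x > 0
      l$cache <- list(mask = mask)
      x * mask
    },
    gelu = {
      l$cache <- list(x = x)
      x * stats::pnorm(x)
    },
    sigmoid = {
      y <- stats::plogis(x)
      l$cache <- list(y = y)
      y
    },
    softmax = {
      z <- exp(sweep(x, 2, apply(x, 2, max)))
      y <- sweep(z, 2, colSums(z), "/")
      l$cache <- list(y = y)
      y
    },
    se = {
      d <- dim(x); hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
      s <- matrix(.colMeans(matrix(x, hw, C * N), hw, C * N), C, N)
      pre1 <- crossprod(l$params$w1, s) + l$params$b1
      mask1 <- pre1 > 0
      z1 <- pre1 * mask1
      g <- stats::plogis(crossprod(l$params$w2, z1) + l$params$b2)
      l$cache <- list(x = x, s = s, z1 = z1, mask1 = mask1, g = g, d = d)
      x * bc_channel(g, hw)
    },
    stop("unknown layer type: ", l$type))
}

nn_forward <- function(node, x, training = FALSE) {
  switch(node$kind,
    layer = layer_fwd(node, x, training),
    chain = {
      for (it in node$items) x <- nn_forward(it, x, training)
      x
    },
    concat = {
      ys <- lapply(node$branches, nn_forward, x = x, training = training)
      chs <- vapply(ys, function(y) dim(y)[3], numeric(1))
      d <- dim(ys[[1]])
      y <- array(0, c(d[1], d[2], sum(chs), d[4]))
      off <- 0L
      for (i in seq_along(ys)) {
        y[, , (off + 1L):(off + chs[i]), ] <- ys[[i]]
        off <- off + chs[i]
      }
      node$cache <- list(chs = chs)
      y
    },
    residual = x + nn_forward(node$body, x, training))
}

## ---- backward ---------------------------------------------------------

acc_grad <- function(l, name, g) {
  if (is.null(l$grads[[name]])) l$grads[[name]] <- g
  else l$grads[[name]] <- l$grads[[name]] + g
}

layer_bwd <- function(l, dy) {
  switch(l$type,
    conv = {
      cc <- l$cache
      d <- cc$d; H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
      if (l$kh == 1L && l$kw == 1L && l$stride == 1L) {
        dym <- matrix(aperm(dy, c(1, 2, 4, 3)), H * W * N, l$f)
        xm <- matrix(aperm(cc$x, c(1, 2, 4, 3)), H * W * N, C)
        acc_grad(l, "w", crossprod(xm, dym))
        if (!is.null(l$params$b)) acc_grad(l, "b", colSums(dym))
        dxm <- tcrossprod(dym, l$params$w)
        aperm(array(dxm, c(H, W, N, C)), c(1, 2, 4, 3))
      } else {
        ph <- cc$ph; pw <- cc$pw
        dym <- matrix(aperm(dy, c(1, 2, 4, 3)), ph[["out"]] * pw[["out"]] * N, l$f)
        cols <- im2col_cpp(cc$x, H, W, C, N, l$kh, l$kw, l$stride,
                           ph[["pad"]], pw[["pad"]], ph[["out"]], pw[["out"]])
        acc_grad(l, "w", crossprod(cols, dym))
        if (!is.null(l$params$b)) acc_grad(l, "b", colSums(dym))
        dcols <- tcrossprod(dym, l$params$w)
        col2im_cpp(dcols, H, W, C, N, l$kh, l$kw, l$stride,
                   ph[["pad"]], pw[["pad"]], ph[["out"]], pw[["out"]])
      }
    },
    dwconv = {
      cc <- l$cache
      d <- cc$d
      r <- dwconv_bwd_cpp(cc$x, dy, d[1], d[2], d[3], d[4], l$params$w,
                          l$kh, l$kw, l$stride, cc$ph[["pad"]], cc$pw[["pad"]],
                          cc$ph[["out"]], cc$pw[["out"]], !is.null(l$params$b))
      acc_grad(l, "w", r$dw)
      if (!is.null(l$params$b)) acc_grad(l, "b", r$db)
      r$dx
    },
    maxpool = {
      d <- l$cache$d
      maxpool_bwd_cpp(l$cache$argmax, dy, d[1], d[2], d[3], d[4])
    },
    bn = {
      cc <- l$cache
      d <- cc$d; hw <- d[1] * d[2]; C <- d[3]; N <- d[4]; m <- hw * N
      acc_grad(l, "gamma", channel_sum(dy * cc$xhat, hw, C, N))
      acc_grad(l, "beta", channel_sum(dy, hw, C, N))
      dxhat <- dy * bc_channel(l$params$gamma, hw)
      if (cc$training) {
        s1 <- channel_sum(dxhat, hw, C, N)
        s2 <- channel_sum(dxhat * cc$xhat, hw, C, N)
        (dxhat - bc_channel(s1 / m, hw) - cc$xhat * bc_channel(s2 / m, hw)) *
          bc_channel(cc$ivar, hw)
      } else {
        dxhat * bc_channel(cc$ivar, hw)
      }
    },
    gap = {
      d <- l$cache$d; hw <- d[1] * d[2]
      array(rep(as.vector(dy), each = hw) / hw, d)
    },
    dense = {
      x <- l$cache$x
      acc_grad(l, "w", x %*% t(dy))
      if (!is.null(l$params$b)) acc_grad(l, "b", rowSums(dy))
      l$params$w %*% dy
    },
    relu = dy * l$cache$mask,
    gelu = {
      x <- l$cache$x
      dy * (stats::pnorm(x) + x * stats::dnorm(x))
    },
    sigmoid = dy * l$cache$y * (1 - l$cache$y),
    softmax = {
      y <- l$cache$y
      s <- colSums(dy * y)
      y * (dy - rep(s, each = nrow(y)))
    },
    se = {
      cc <- l$cache
      d <- cc$d; hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
      dgmat <- matrix(.colSums(matrix(dy * cc$x, hw, C * N), hw, C * N), C, N)
      dpre2 <- dgmat * cc$g * (1 - cc$g)
      acc_grad(l, "w2", cc$z1 %*% t(dpre2))
      acc_grad(l, "b2", rowSums(dpre2))
      dz1 <- l$params$w2 %*% dpre2
      dpre1 <- dz1 * cc$mask1
      acc_grad(l, "w1", cc$s %*% t(dpre1))
      acc_grad(l, "b1", rowSums(dpre1))
      ds <- l$params$w1 %*% dpre1
      dy * bc_channel(cc$g, hw) + array(rep(as.vector(ds), each = hw) / hw, d)
    },
    stop("unknown layer type: ", l$type))
}

nn_backward <- function(node, dy) {
  switch(node$kind,
    layer = layer_bwd(node, dy),
    chain = {
      for (it in rev(node$items)) dy <- nn_backward(it, dy)
      dy
    },
    concat = {
      chs <- node$cache$chs
      off <- 0L
      dx <- NULL
      for (i in seq_along(node$branches)) {
        dyi <- dy[, , (off + 1L):(off + chs[i]), , drop = FALSE]
        off <- off + chs[i]
        dxi <- nn_backward(node$branches[[i]], dyi)
        dx <- if (is.null(dx)) dxi else dx + dxi
      }
      dx
    },
    residual = dy + nn_backward(node$body, dy))
}

## ---- parameter plumbing ----------------------------------------------

collect_layers <- function(node, acc = list()) {
  switch(node$kind,
    layer = if (length(node$params)) c(acc, node) else acc,
    chain = {
      for (it in node$items) acc <- collect_layers(it, acc)
      acc
    },
    concat = {
      for (b in node$branches) acc <- collect_layers(b, acc)
      acc
    },
    residual = collect_layers(node$body, acc))
}

#' Count trainable parameters of an executable model
#'
#' Counts every trainable scalar actually allocated in the compiled network:
#' convolution and dense weights and biases, and batch-normalization scale
#' and shift. Moving statistics are state, not parameters, and are excluded.
#' This count is independent of the analytic [audit()] total and the two are
#' checked against each other in the test suite.
#'
#' @param model An `amdnet_model`, or `NULL` (an empty model), which counts 0.
#' @return Non-negative integer.
#' @export
count_trainable <- function(model) {
  if (is.null(model)) return(0L)
  stopifnot(inherits(model, "amdnet_model"))
  layers <- collect_layers(model$net)
  as.integer(sum(vapply(layers, function(l) sum(lengths(l$params)), numeric(1))))
}

zero_grads <- function(model) {
  for (l in collect_layers(model$net)) l$grads <- NULL
  invisible(model)
}

get_weights <- function(model)
  lapply(collect_layers(model$net), function(l) l$params)

set_weights <- function(model, weights) {
  layers <- collect_layers(model$net)
  stopifnot(length(layers) == length(weights))
  for (i in seq_along(layers)) layers[[i]]$params <- weights[[i]]
  invisible(model)
}

get_bn_state <- function(model)
  lapply(collect_layers(model$net), function(l) l$state)

set_bn_state <- function(model, states) {
  layers <- collect_layers(model$net)
  for (i in seq_along(layers))
    if (!is.null(states[[i]])) layers[[i]]$state <- states[[i]]
  invisible(model)
}

clear_caches <- function(node) {
  switch(node$kind,
    layer = node$cache <- NULL,
    chain = for (it in node$items) clear_caches(it),
    concat = {
      node$cache <- NULL
      for (b in node$branches) clear_caches(b)
    },
    residual = clear_caches(node$body))
  invisible(NULL)
}

adam_init <- function(model) {
  lapply(get_weights(model), function(p) list(m = lapply(p, function(x) x * 0),
                                              v = lapply(p, function(x) x * 0)))
}

adam_step <- function(model, opt, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  layers <- collect_layers(model$net)
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      if (is.null(g)) next
      opt[[i]]$m[[nm]] <- beta1 * opt[[i]]$m[[nm]] + (1 - beta1) * g
      opt[[i]]$v[[nm]] <- beta2 * opt[[i]]$v[[nm]] + (1 - beta2) * g * g
      mhat <- opt[[i]]$m[[nm]] / (1 - beta1^t)
      vhat <- opt[[i]]$v[[nm]] / (1 - beta2^t)
      l$params[[nm]] <- l$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  opt
}

#' Run a model forward on a batch
#'
#' @param object An `amdnet_model`.
#' @param x Array of dim `(H, W, C, N)` (a single `(H, W, C)` image is
#'   promoted to a batch of one).
#' @param training Logical; use batch statistics and record caches.
#' @param ... Unused.
#' @return The network output: class-probability matrix `(K, N)` for models
#'   ending in softmax, otherwise the output feature map.
#' @export
predict.amdnet_model <- function(object, x, training = FALSE, ...) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  y <- nn_forward(object$net, x, training = training)
  if (!training) clear_caches(object$net)
  y
}

#' @export
print.amdnet_model <- function(x, ...) {
  cat("<amdnet_model> input", format(x$in_shape), "->", format(x$out_shape),
      "|", format(count_trainable(x), big.mark = ","),
      "trainable parameters\n")
  invisible(x)
}

#' Audit a model or block specification
#'
#' Produces the per-layer parameter table (layer, input, kernel/filters,
#' parameter count) and the total, mirroring the classical layer-audit
#' layout.
#'
#' @param x An `amdnet_model` or [block_spec()].
#' @param ... For `block_spec`: `in_shape` (required) and optional
#'   `input_name`.
#' @return A `layer_audit`.
#' @export
audit <- function(x, ...) UseMethod("audit")

#' @export
audit.amdnet_model <- function(x, ...)
  audit_block(x$spec, x$in_shape, input_name = "Input")

#' @export
audit.block_spec <- function(x, in_shape, input_name = "Input", ...)
  audit_block(x, in_shape, input_name)
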