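# Correctness of the executable-model engine against independent oracles.

naive_conv2d <- function(x, w, b, kh, kw) {
  # direct same-padding stride-1 convolution, one sample; w: (kh*kw*C, F)
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  Fo <- ncol(w)
  pt <- (kh - 1) %/% 2; pl <- (kw - 1) %/% 2
  y <- array(0, c(H, W, Fo))
  for (f in seq_len(Fo)) {
    for (oh in seq_len(H)) for (ow in seq_len(W)) {
      acc <- b[f]
      for (c in seq_len(C)) for (j in seq_len(kw)) for (i in seq_len(kh)) {
        hs <- oh - pt + i - 1L; ws <- ow - pl + j - 1L
        if (hs >= 1 && hs <= H && ws >= 1 && ws <= W) {
          row <- (c - 1L) * kh * kw + (j - 1L) * kh + i
          acc <- acc + w[row, f] * x[hs, ws, c]
        }
      }
      y[oh, ow, f] <- acc
    }
  }
  y
}

test_that("GEMM convolution agrees with a direct convolution oracle", {
  set.seed(10)
  spec <- block_spec(list(conv_spec("standard", c(3, 3), 2, name = "c")))
  m <- build_model(spec, tensor_shape(6, 7, 3), seed = 5)
  l <- amdnet:::collect_layers(m$net)[[1]]
  x <- array(rnorm(6 * 7 * 3), c(6, 7, 3, 1))
  got <- predict(m, x)[, , , 1]
  want <- naive_conv2d(x[, , , 1, drop = FALSE][, , , 1], l$params$w,
                       l$params$b, 3, 3)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("depthwise convolution agrees with per-channel direct convolution", {
  set.seed(11)
  spec <- block_spec(list(conv_spec("depthwise", c(3, 3), name = "d")))
  m <- build_model(spec, tensor_shape(5, 5, 2), seed = 6)
  l <- amdnet:::collect_layers(m$net)[[1]]
  x <- array(rnorm(5 * 5 * 2), c(5, 5, 2, 1))
  got <- predict(m, x)[, , , 1]
  for (c in 1:2) {
    wfull <- matrix(0, 9 * 2, 1)
    wfull[(c - 1) * 9 + 1:9, 1] <- l$params$w[, c]
    want <- naive_conv2d(x[, , , 1], wfull, l$params$b[c], 3, 3)
    expect_equal(got[, , c], want[, , 1], tolerance = 1e-12)
  }
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(3)
  spec <- block_spec(list(
    conv_spec("standard", c(3, 3), 4, activation = "relu", batchnorm = TRUE,
              name = "c1"),
    block_spec(list(
      conv_spec("pointwise", c(1, 1), 4, activation = "gelu", name = "b1"),
      block_spec(list(conv_spec("depthwise", c(3, 3), activation = "gelu",
                                batchnorm = TRUE, name = "b2")),
                 topology = "residual", name = "res")
    ), topology = "parallel_concat", name = "par"),
    conv_spec("maxpool", c(3, 3), stride = 2, name = "mp"),
    build_se(8, 2),
    conv_spec("gap", name = "gap"),
    conv_spec("dense", filters = 3, activation = "softmax", name = "out")
  ), name = "tiny")
  m <- build_model(spec, tensor_shape(8, 8, 2), seed = 7)
  x <- array(rnorm(8 * 8 * 2 * 3), c(8, 8, 2, 3))
  y <- c(0L, 2L, 1L)
  loss_of <- function() {
    p <- amdnet:::nn_forward(m$net, x, training = TRUE)
    -mean(log(pmax(p[cbind(y + 1L, 1:3)], 1e-12)))
  }
  amdnet:::zero_grads(m)
  p <- amdnet:::nn_forward(m$net, x, training = TRUE)
  g <- matrix(0, 3, 3)
  ix <- cbind(y + 1L, 1:3)
  g[ix] <- -1 / (3 * pmax(p[ix], 1e-12))
  amdnet:::nn_backward(m$net, g)
  eps <- 1e-6
  for (l in amdnet:::collect_layers(m$net)) {
    for (nm in names(l$params)) {
      picks <- sample(length(l$params[[nm]]), min(3, length(l$params[[nm]])))
      for (k in picks) {
        orig <- l$params[[nm]][k]
        l$params[[nm]][k] <- orig + eps; lp <- loss_of()
        l$params[[nm]][k] <- orig - eps; lm <- loss_of()
        l$params[[nm]][k] <- orig
        num <- (lp - lm) / (2 * eps)
        expect_equal(l$grads[[nm]][k], num, tolerance = 1e-3,
                     label = sprintf("grad %s/%s[%d]", l$name, nm, k))
      }
    }
  }
})

test_that("batchnorm normalizes batch statistics and tracks running ones", {
  spec <- block_spec(list(conv_spec("standard", c(1, 1), 3, batchnorm = TRUE,
                                    bias = FALSE, name = "c")))
  m <- build_model(spec, tensor_shape(4, 4, 3), seed = 2)
  layers <- amdnet:::collect_layers(m$net)
  conv <- layers[[1]]; bn <- layers[[2]]
  conv$params$w <- diag(3)  # identity mixing: BN sees the raw input
  x <- array(rnorm(4 * 4 * 3 * 5, mean = 2, sd = 3), c(4, 4, 3, 5))
  y <- predict(m, x, training = TRUE)
  for (c in 1:3) {
    expect_equal(mean(y[, , c, ]), 0, tolerance = 1e-8)
    expect_equal(stats::sd(as.vector(y[, , c, ])) *
                   sqrt(79 / 80), 1, tolerance = 1e-3)
  }
  expect_true(all(bn$state$rm != 0))
})

test_that("maxpool picks window maxima and routes gradients to them", {
  spec <- block_spec(list(conv_spec("maxpool", c(2, 2), stride = 2,
                                    name = "mp")))
  m <- build_model(spec, tensor_shape(4, 4, 1), seed = 1)
  x <- array(1:16, c(4, 4, 1, 1)) * 1.0
  y <- predict(m, x)
  expect_equal(as.vector(y), c(6, 8, 14, 16))
})

test_that("bilinear resize preserves constants and value range", {
  x <- array(0.6, c(10, 12, 1))
  y <- bilinear_resize_cpp(x, 10, 12, 1, 7, 5)
  expect_equal(dim(y), c(7L, 5L, 1L))
  expect_true(all(abs(y - 0.6) < 1e-12))
})

test_that("count_trainable handles the empty model and matches audits", {
  expect_equal(count_trainable(NULL), 0L)
  s <- tensor_shape(16, 16, 3)
  mim <- build_mim(s, 8)
  m <- build_model(mim, s, seed = 3)
  expect_equal(count_trainable(m), block_params(mim, s))
  expect_equal(audit(m)$total, count_trainable(m))
})
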