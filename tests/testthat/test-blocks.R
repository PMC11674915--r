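s224 <- tensor_shape(224, 224, 3)

test_that("param_count reproduces the published per-layer values", {
  # standard Inception rows on a 3-channel input
  expect_equal(param_count(conv_spec("standard", c(1, 1), 64), 3), 256L)
  expect_equal(param_count(conv_spec("standard", c(3, 3), 64), 3), 1792L)
  expect_equal(param_count(conv_spec("standard", c(1, 1), 64), 64), 4160L)
  expect_equal(param_count(conv_spec("standard", c(5, 5), 64), 3), 4864L)
  expect_equal(param_count(conv_spec("maxpool", c(3, 3)), 3), 0L)
  # depthwise-separable rows
  expect_equal(param_count(conv_spec("depthwise", c(3, 3)), 3), 30L)
  expect_equal(param_count(conv_spec("depthwise", c(5, 5)), 3), 78L)
  expect_equal(param_count(conv_spec("pointwise", c(1, 1), 64), 3), 256L)
  # degenerate standard conv
  expect_equal(param_count(conv_spec("standard", c(1, 1), 1), 1), 2L)
})

test_that("param_count covers bias, batchnorm and invalid specs", {
  # bias off drops one term per filter (or per channel for depthwise)
  expect_equal(param_count(conv_spec("standard", c(3, 3), 8, bias = FALSE), 4),
               9L * 4L * 8L)
  expect_equal(param_count(conv_spec("depthwise", c(3, 3), bias = FALSE), 5),
               45L)
  # batchnorm adds 2 trainable scalars per output channel
  expect_equal(param_count(conv_spec("pointwise", c(1, 1), 8, batchnorm = TRUE),
                           4), (4L + 1L) * 8L + 16L)
  # a depthwise spec with an explicit filter count is invalid
  expect_error(conv_spec("depthwise", c(3, 3), filters = 64),
               "no independent filter count")
  expect_error(conv_spec("pointwise", c(3, 3), 64), "1x1")
  expect_error(param_count(conv_spec("standard", c(1, 1), 4), 0),
               "positive integer")
})

test_that("standard Inception module matches its published audit", {
  im <- build_inception_standard(s224, 64)
  a <- audit_block(im, s224, "Input_Image")
  expect_equal(a$total, 15488L)
  expect_equal(a$rows$params, c(256L, 1792L, 4160L, 4864L, 4160L, 0L, 256L))
  expect_equal(spec_out_shape(im, s224)$channels, 256L)
})

test_that("modified Inception module matches its published audit", {
  mim <- build_mim(s224, 64)
  a <- audit_block(mim, s224, "Input_Image")
  expect_equal(a$total, 1132L)
  expect_equal(a$rows$params, c(256L, 30L, 256L, 78L, 256L, 0L, 256L))
  expect_equal(spec_out_shape(mim, s224)$channels, 256L)
  # the depthwise substitution buys at least a 13x reduction here
  expect_gte(15488 / 1132, 13)
})

test_that("Inception/MIM totals equal independent hand summation elsewhere", {
  # independent oracle: direct arithmetic over the 7 rows, away from the
  # published input shape
  hand_im <- function(cin, f)
    (1 * cin + 1) * f + (9 * cin + 1) * f + (f + 1) * f +
    (25 * cin + 1) * f + (f + 1) * f + 0 + (cin + 1) * f
  hand_mim <- function(cin, f)
    (1 * cin + 1) * f + (9 * cin + cin) + (cin + 1) * f +
    (25 * cin + cin) + (cin + 1) * f + 0 + (cin + 1) * f
  s8 <- tensor_shape(8, 8, 1)
  expect_equal(block_params(build_inception_standard(s8, 1), s8), hand_im(1, 1))
  s32 <- tensor_shape(32, 32, 32)
  expect_equal(block_params(build_mim(s32, 64), s32), hand_mim(32, 64))
  expect_equal(block_params(build_inception_standard(s32, 16), s32),
               hand_im(32, 16))
  # MIM is always cheaper for identical input and filters
  expect_lt(block_params(build_mim(s32, 64), s32),
            block_params(build_inception_standard(s32, 64), s32))
})

test_that("SE block parameters and shape contract", {
  se <- build_se(64, 16)
  s <- tensor_shape(8, 8, 64)
  expect_equal(block_params(se, s), 64L * 4L + 4L + 4L * 64L + 64L)  # 580
  expect_equal(unclass(spec_out_shape(se, s)), unclass(s))
  # bottleneck floors at one unit
  expect_equal(block_params(build_se(4, 16), tensor_shape(2, 2, 4)),
               (4L + 1L) * 1L + (1L + 1L) * 4L)
  expect_error(build_se(0, 16), "positive")
})

test_that("DSEB layer arithmetic and contracts", {
  s <- tensor_shape(14, 14, 128)
  ds <- build_dseb(s, 64, 16)
  a <- audit_block(ds, s)
  # first separable pair: 25*128+128 + (128+1)*64
  expect_equal(sum(a$rows$params[1:2]), 11584L)
  expect_equal(a$total, 11584L + 640L + 4160L + 580L)
  expect_equal(spec_out_shape(ds, s)$channels, 64L)
  # parameter totals are invariant to spatial input size
  s2 <- tensor_shape(112, 112, 128)
  expect_equal(block_params(ds, s2), a$total)
})

test_that("ConvMixer stage shapes and per-block parameters", {
  s <- tensor_shape(224, 224, 64)
  cm <- build_convmixer(s, h = 256, d = 16, k = 5, p = 2)
  expect_equal(unclass(spec_out_shape(cm, s)),
               unclass(tensor_shape(112, 112, 256)))
  a <- audit_block(cm, s)
  embed <- 65792L + 512L
  per_block <- 6656L + 512L + 65792L + 512L
  expect_equal(a$total, embed + 16L * per_block)
  # d = 0 leaves the patch embedding alone
  cm0 <- build_convmixer(s, h = 256, d = 0, k = 5, p = 2)
  expect_equal(block_params(cm0, s), embed)
  expect_error(build_convmixer(tensor_shape(15, 15, 8), h = 16, d = 1, p = 2),
               "does not divide")
})

test_that("stem arithmetic and zero-parameter pooling", {
  st <- build_stem(s224)
  a <- audit_block(st, s224)
  expect_equal(a$total, 2432L + 320L + 1056L + 64L)
  expect_equal(a$rows$params[a$rows$layer == "stem_maxpool"], 0L)
  expect_equal(spec_out_shape(st, s224)$channels, 32L)
  # stride-2 pooling halves spatial dims
  expect_equal(spec_out_shape(st, s224)$height, 112L)
})

test_that("parallel branches must agree on spatial dims; residual on shape", {
  bad <- block_spec(list(conv_spec("standard", c(3, 3), 4),
                         conv_spec("maxpool", c(2, 2), stride = 2)),
                    topology = "parallel_concat")
  expect_error(spec_out_shape(bad, tensor_shape(8, 8, 3)), "disagree")
  bad_res <- block_spec(list(conv_spec("standard", c(3, 3), 4)),
                        topology = "residual")
  expect_error(spec_out_shape(bad_res, tensor_shape(8, 8, 3)), "identical")
})

test_that("block specs round-trip through YAML", {
  mim <- build_mim(s224, 64)
  path <- tempfile(fileext = ".yaml")
  write_block_yaml(mim, path)
  back <- read_block_yaml(path)
  expect_equal(back, mim)
  expect_equal(block_params(back, s224), 1132L)
})
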