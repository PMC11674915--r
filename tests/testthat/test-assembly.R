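test_that("analytic audit, executable count and hand summation agree", {
  # three-way oracle agreement on every standalone block
  cases <- list(
    list(spec = build_stem(tensor_shape(64, 64, 3)),
         shape = tensor_shape(64, 64, 3)),
    list(spec = build_inception_standard(tensor_shape(32, 32, 3), 16),
         shape = tensor_shape(32, 32, 3)),
    list(spec = build_mim(tensor_shape(32, 32, 3), 16),
         shape = tensor_shape(32, 32, 3)),
    list(spec = build_se(16, 4), shape = tensor_shape(8, 8, 16)),
    list(spec = build_dseb(tensor_shape(16, 16, 24), 16, 4),
         shape = tensor_shape(16, 16, 24)),
    list(spec = build_convmixer(tensor_shape(16, 16, 8), 16, 2, 3, 2),
         shape = tensor_shape(16, 16, 8)))
  for (cs in cases) {
    m <- build_model(cs$spec, cs$shape, seed = 1)
    analytic <- block_params(cs$spec, cs$shape)
    expect_equal(count_trainable(m), analytic)
    expect_equal(audit(m)$total, analytic)
  }
})

test_that("standalone Inception/MIM executable counts match published totals", {
  s <- tensor_shape(224, 224, 3)
  expect_equal(count_trainable(build_model(build_inception_standard(s, 64), s)),
               15488L)
  expect_equal(count_trainable(build_model(build_mim(s, 64), s)), 1132L)
})

test_that("the default full model is internally consistent", {
  cfg <- model_config()
  m <- build_pm(cfg)
  a <- audit(m)
  expect_equal(count_trainable(m), a$total)
  expect_equal(a$total, sum(a$rows$params))
  expect_equal(block_params(pm_spec(cfg), cfg$input_shape), a$total)
  # parameter total is invariant under spatial resizing of the input
  cfg2 <- model_config(input_shape = tensor_shape(112, 112, 3))
  expect_equal(block_params(pm_spec(cfg2), cfg2$input_shape), a$total)
})

test_that("full-model forward emits probability simplex points", {
  cfg <- model_config(input_shape = tensor_shape(32, 32, 3), cm_h = 32L,
                      cm_d = 2L, head_hidden_units = integer(0))
  m <- build_pm(cfg, seed = 4)
  set.seed(20)
  x <- array(runif(32 * 32 * 3 * 5), c(32, 32, 3, 5))
  p <- predict(m, x)
  expect_equal(dim(p), c(3L, 5L))
  expect_true(all(p > 0))
  expect_equal(colSums(p), rep(1, 5), tolerance = 1e-6)
})

test_that("ablation variants contain exactly the flagged components", {
  cfg <- model_config(input_shape = tensor_shape(64, 64, 3), cm_h = 16L,
                      cm_d = 2L, head_hidden_units = integer(0))
  for (id in 1:7) {
    fl <- ablation_flags(id)
    spec <- pm_spec(cfg, components = names(fl)[fl])
    nm <- audit_block(spec, cfg$input_shape)$rows$layer
    expect_equal(any(grepl("^mim_", nm)), unname(fl["mim"]), label = id)
    expect_equal(any(grepl("^dseb_", nm)), unname(fl["dseb"]), label = id)
    expect_equal(any(grepl("^cm", nm)), unname(fl["cm"]), label = id)
    # post-Inception conv travels with the Inception stage
    expect_equal(any(nm == "post_mim_conv"), unname(fl["mim"]), label = id)
    # stem and head always present
    expect_true(any(grepl("^stem_", nm)))
    expect_true(any(nm == "fc_out"))
    # executable count equals analytic audit for every variant
    m <- build_ablation(id, cfg, seed = 2)
    expect_equal(count_trainable(m), block_params(spec, cfg$input_shape))
  }
  # id 7 is the full model
  expect_equal(pm_spec(cfg, components = c("mim", "dseb", "cm")),
               pm_spec(cfg))
  expect_error(ablation_flags(0), "1..7")
})

test_that("single-component ablation has strictly fewer parameters than full", {
  cfg <- model_config()
  expect_lt(count_trainable(build_ablation(1, cfg)),
            count_trainable(build_ablation(7, cfg)))
})

test_that("reconcile_config finds a self-consistent target and reports misses", {
  base <- model_config(input_shape = tensor_shape(32, 32, 3), cm_h = 16L,
                       cm_d = 2L)
  space <- list(se_ratio = c(8L, 16L), head_hidden_units = list(integer(0), 32L),
                bias = TRUE, bn_variant = c("stem_only", "post_mim"))
  known <- model_config(input_shape = tensor_shape(32, 32, 3), cm_h = 16L,
                        cm_d = 2L, se_ratio = 8L, head_hidden_units = 32L)
  target <- block_params(pm_spec(known), known$input_shape)
  r <- reconcile_config(space, target, base)
  expect_gt(length(r$matches), 0)
  counts <- vapply(r$matches, function(c) block_params(pm_spec(c), c$input_shape),
                   numeric(1))
  expect_true(all(counts == target))
  expect_true(any(vapply(r$matches, function(c)
    c$se_ratio == 8L && identical(c$head_hidden_units, 32L), logical(1))))
  # impossible target: empty match list plus a populated nearest miss
  r2 <- reconcile_config(space, 1L, base)
  expect_length(r2$matches, 0)
  expect_false(is.null(r2$nearest_miss))
  expect_equal(r2$nearest_miss$count,
               r2$table$params[which.min(abs(r2$table$delta))])
})

test_that("configuration errors name the offending stage", {
  bad <- model_config(input_shape = tensor_shape(50, 50, 3), cm_p = 4L)
  expect_error(pm_spec(bad), "ConvMixer")
})

test_that("model configurations round-trip through YAML", {
  cfg <- model_config(se_ratio = 8L, head_hidden_units = c(128L, 64L),
                      bn_variant = "post_mim")
  path <- tempfile(fileext = ".yaml")
  write_config_yaml(cfg, path)
  expect_equal(read_config_yaml(path), cfg)
  # omitted fields take defaults
  yaml::write_yaml(list(se_ratio = 4), path)
  partial <- read_config_yaml(path)
  expect_equal(partial$se_ratio, 4L)
  expect_equal(partial$cm_h, 256L)
})
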