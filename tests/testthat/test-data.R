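test_that("split sizes reproduce the reference partitions and sum to n", {
  expect_equal(split_sizes(2316), c(train = 1621L, val = 348L, test = 347L))
  expect_equal(split_sizes(4326)[["test"]], 649L)
  expect_equal(split_sizes(100), c(train = 70L, val = 15L, test = 15L))
  for (n in c(4L, 7L, 50L, 101L, 999L, 2316L, 4326L))
    expect_equal(sum(split_sizes(n)), n)
  expect_error(split_sizes(2), "at least 3")
  # n = 3 rounds the test share to zero: an empty partition is an error
  expect_error(split_sizes(3), "empty partition")
})

test_that("split_spec validates its fractions", {
  expect_error(split_spec(0.5, 0.2, 0.2), "sum to 1")
  expect_error(split_spec(1.2, -0.1, -0.1), "in \\(0, 1\\)")
})

test_that("dataset splitting is a deterministic disjoint partition", {
  idx <- index_from_counts(c(dry_amd = 653L, normal = 920L, wet_amd = 743L))
  sp <- split_spec(shuffle_seed = 3L)
  parts <- split_dataset(idx, sp)
  expect_equal(nrow(parts$test), 347L)
  expect_equal(nrow(parts$train), 1621L)
  expect_equal(nrow(parts$val), 348L)
  all_paths <- c(parts$train$path, parts$val$path, parts$test$path)
  expect_setequal(all_paths, idx$path)
  expect_equal(anyDuplicated(all_paths), 0L)
  # identical seed, identical partitions (byte-identical manifests)
  f1 <- tempfile(); f2 <- tempfile()
  write_manifest_csv(parts, f1)
  write_manifest_csv(split_dataset(idx, sp), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # a different seed moves entries between partitions
  parts2 <- split_dataset(idx, split_spec(shuffle_seed = 4L))
  expect_false(identical(parts$test$path, parts2$test$path))
})

test_that("test-partition class supports match hypergeometric expectation", {
  # draw the reference test split repeatedly from the reference class mix;
  # each class support should fall inside the central 99% hypergeometric
  # band in at least 95% of seeded trials
  counts <- c(dry_amd = 653L, normal = 920L, wet_amd = 743L)
  idx <- index_from_counts(counts)
  n <- sum(counts); k <- 347L
  trials <- 200L
  inside <- logical(trials)
  for (s in seq_len(trials)) {
    te <- split_dataset(idx, split_spec(shuffle_seed = s))$test
    supp <- table(factor(te$class_name, levels = names(counts)))
    ok <- TRUE
    for (j in seq_along(counts)) {
      lo <- qhyper(0.005, counts[j], n - counts[j], k)
      hi <- qhyper(0.995, counts[j], n - counts[j], k)
      ok <- ok && supp[j] >= lo && supp[j] <= hi
    }
    inside[s] <- ok
  }
  expect_gte(mean(inside), 0.95)
})

test_that("load_dataset indexes class directories and flags bad layouts", {
  root <- tiny_synth_dir()
  idx <- load_dataset(root)
  expect_equal(nrow(idx), 15L)
  expect_equal(attr(idx, "class_names"), c("dry_amd", "normal", "wet_amd"))
  expect_equal(sort(unique(idx$class_index)), 0:2)
  expect_true(all(file.exists(idx$path)))
  # an empty class subdirectory is an error naming the class
  root2 <- tempfile()
  dir.create(file.path(root2, "empty_class"), recursive = TRUE)
  expect_error(load_dataset(root2), "empty_class")
  expect_error(load_dataset(tempfile()), "not found")
})

test_that("synthetic generation is a pure function of its spec", {
  spec <- synthetic_spec(n_per_class = 2L, image_size = c(48L, 48L), seed = 9L)
  d1 <- tempfile(); d2 <- tempfile()
  i1 <- generate_synthetic(spec, d1)
  i2 <- generate_synthetic(spec, d2)
  expect_equal(nrow(i1), 6L)
  for (k in seq_len(nrow(i1))) {
    b1 <- readBin(i1$path[k], "raw", file.size(i1$path[k]))
    b2 <- readBin(i2$path[k], "raw", file.size(i2$path[k]))
    expect_identical(b1, b2)
  }
})

test_that("generated images have the declared size and replicated channels", {
  idx <- load_dataset(tiny_synth_dir())
  x <- read_image(idx$path[1])
  expect_equal(dim(x), c(32L, 32L, 3L))
  expect_equal(x[, , 1], x[, , 2])
  expect_equal(x[, , 1], x[, , 3])
  expect_true(all(x >= 0 & x <= 1))
})

test_that("zero lesion amplitudes and zero speckle erase the class signal", {
  spec <- synthetic_spec(n_per_class = 1L, image_size = c(48L, 48L), seed = 5L,
                         drusen_amplitude = 0, fluid_radius = 0,
                         speckle_sigma = 0)
  d <- tempfile()
  idx <- generate_synthetic(spec, d)
  imgs <- lapply(idx$path, read_image)
  expect_equal(imgs[[1]], imgs[[2]])
  expect_equal(imgs[[2]], imgs[[3]])
})

test_that("classes are visibly distinct under default lesion amplitudes", {
  idx <- load_dataset(tiny_synth_dir())
  by_class <- split(idx$path, idx$class_name)
  m <- lapply(by_class, function(p) read_image(p[[1]])[, , 1])
  expect_gt(mean(abs(m$dry_amd - m$normal)), 1e-3)
  expect_gt(mean(abs(m$wet_amd - m$normal)), 1e-3)
})
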