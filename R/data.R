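IMAGE_EXT <- "\\.(png|jpg|jpeg|tif|tiff)$"

new_dataset_index <- function(path, class_index, class_name, class_names) {
  df <- data.frame(path = path, class_index = as.integer(class_index),
                   class_name = class_name, stringsAsFactors = FALSE)
  structure(df, class = c("dataset_index", "data.frame"),
            class_names = class_names)
}

#' Index a class-labelled image directory
#'
#' Expects one subdirectory per class under `root`, each containing at least
#' one readable image (PNG, JPEG or TIFF). Class names are the sorted
#' subdirectory names; class indices are 0-based in that order.
#'
#' @param root Dataset root directory.
#' @return A `dataset_index`: data.frame with columns `path`, `class_index`,
#'   `class_name` and attribute `class_names`.
#' @export
load_dataset <- function(root) {
  if (!dir.exists(root)) stop("dataset root not found: ", root, call. = FALSE)
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (!length(classes))
    stop("no class subdirectories under ", root, call. = FALSE)
  paths <- list(); idx <- list(); nms <- list()
  for (i in seq_along(classes)) {
    files <- sort(list.files(file.path(root, classes[i]),
                             pattern = IMAGE_EXT, ignore.case = TRUE,
                             full.names = TRUE))
    readable <- file.access(files, mode = 4) == 0
    if (any(!readable)) {
      warning("skipping unreadable file(s): ",
              paste(files[!readable], collapse = ", "), call. = FALSE)
      files <- files[readable]
    }
    if (!length(files))
      stop("class subdirectory contains no readable images: ", classes[i],
           call. = FALSE)
    paths[[i]] <- files
    idx[[i]] <- rep(i - 1L, length(files))
    nms[[i]] <- rep(classes[i], length(files))
  }
  new_dataset_index(unlist(paths), unlist(idx), unlist(nms), classes)
}

#' Train/validation/test split specification
#'
#' @param train_fraction,val_fraction,test_fraction Fractions in (0,1)
#'   summing to 1; defaults 0.70/0.15/0.15.
#' @param shuffle_seed Integer seed for the partition shuffle.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.70, val_fraction = 0.15,
                       test_fraction = 0.15, shuffle_seed = 1L) {
  fr <- c(train_fraction, val_fraction, test_fraction)
  if (any(fr <= 0) || any(fr >= 1))
    stop("fractions must lie in (0, 1)", call. = FALSE)
  if (abs(sum(fr) - 1) > 1e-9)
    stop("fractions must sum to 1", call. = FALSE)
  structure(list(train_fraction = train_fraction,
                 val_fraction = val_fraction,
                 test_fraction = test_fraction,
                 shuffle_seed = as.integer(shuffle_seed)),
            class = "split_spec")
}

#' Partition sizes under the 70/15/15 rule
#'
#' `n_train = floor(train_fraction * n)`, `n_test` rounded half-up from
#' `test_fraction * n`, and `n_val` the remainder - the unique simple
#' rounding rule consistent with the reference partitions (2316 ->
#' 1621/348/347 and 4326 -> test 649).
#'
#' @param n_total Total sample count (at least 3).
#' @param spec A [split_spec()].
#' @return Named integer vector `c(train=, val=, test=)` summing to
#'   `n_total`.
#' @export
split_sizes <- function(n_total, spec = split_spec()) {
  if (n_total < 3) stop("need at least 3 samples to split", call. = FALSE)
  n_train <- as.integer(floor(spec$train_fraction * n_total))
  n_test <- as.integer(floor(spec$test_fraction * n_total + 0.5))
  n_val <- as.integer(n_total) - n_train - n_test
  sizes <- c(train = n_train, val = n_val, test = n_test)
  if (any(sizes <= 0))
    stop("empty partition for n_total = ", n_total, call. = FALSE)
  sizes
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Split a dataset index into train/validation/test partitions
#'
#' Image-level, unstratified partition: entries are shuffled with the
#' spec's seed and cut into sizes given by [split_sizes()]. The same index
#' and seed always produce identical partitions.
#'
#' @param index A [load_dataset()] index.
#' @param spec A [split_spec()].
#' @return Named list of three `dataset_index` objects (`train`, `val`,
#'   `test`), disjoint and covering `index`.
#' @export
split_dataset <- function(index, spec = split_spec()) {
  stopifnot(inherits(index, "dataset_index"))
  n <- nrow(index)
  sizes <- split_sizes(n, spec)
  perm <- with_seed(spec$shuffle_seed, sample.int(n))
  cuts <- list(train = perm[seq_len(sizes["train"])],
               val = perm[sizes["train"] + seq_len(sizes["val"])],
               test = perm[sizes["train"] + sizes["val"] + seq_len(sizes["test"])])
  lapply(cuts, function(ix) {
    part <- index[sort(ix), , drop = FALSE]
    rownames(part) <- NULL
    structure(part, class = class(index),
              class_names = attr(index, "class_names"))
  })
}

#' Write / read a partition manifest
#'
#' CSV with columns `path,class_name,partition`.
#'
#' @param parts A [split_dataset()] result.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_manifest_csv <- function(parts, path) {
  rows <- do.call(rbind, lapply(names(parts), function(p)
    data.frame(path = parts[[p]]$path, class_name = parts[[p]]$class_name,
               partition = p, stringsAsFactors = FALSE)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Synthetic OCT B-scan generator specification
#'
#' Parameters of the desk-scale synthetic dataset that emulates the three
#' B-scan morphologies: smooth horizontal retinal bands (normal), bright
#' bumpy hyperreflective deposits on the brightest band (drusen, dry AMD),
#' and a dark sub-band fluid pocket with local band elevation (wet AMD),
#' all under multiplicative speckle noise.
#'
#' @param n_per_class Images generated per class.
#' @param seed Integer seed; generation is a pure function of the spec.
#' @param image_size `(height, width)` in pixels.
#' @param band_count Number of retinal layer bands.
#' @param drusen_count Number of drusen bumps (dry class).
#' @param drusen_amplitude Drusen bump height in pixels (dry class).
#' @param fluid_radius Fluid-pocket radius in pixels (wet class).
#' @param speckle_sigma Multiplicative speckle scale (0 disables noise).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class = 40L, seed = 1L,
                           image_size = c(224L, 224L), band_count = 5L,
                           drusen_count = 10L, drusen_amplitude = 8,
                           fluid_radius = 16, speckle_sigma = 0.12) {
  if (drusen_amplitude > image_size[1] || 2 * fluid_radius > image_size[1])
    stop("lesion geometry does not fit inside image_size", call. = FALSE)
  structure(list(n_per_class = as.integer(n_per_class), seed = as.integer(seed),
                 image_size = as.integer(image_size),
                 band_count = as.integer(band_count),
                 drusen_count = as.integer(drusen_count),
                 drusen_amplitude = drusen_amplitude,
                 fluid_radius = fluid_radius,
                 speckle_sigma = speckle_sigma),
            class = "synthetic_spec")
}

# Render one scene. The random geometry (band phases, lesion positions,
# speckle field) is drawn identically for every class so that, with zero
# lesion amplitudes and zero speckle, the three class renderings are
# pixel-identical: the class signal is carried only by the amplitude
# parameters.
render_bscan <- function(spec, scene_seed, class_name) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  img <- with_seed(scene_seed, {
    xs <- seq_len(W); ys <- seq_len(H)
    phase <- stats::runif(1, 0, 2 * pi)
    tilt <- stats::runif(1, -0.05, 0.05)
    amp <- stats::runif(1, 0.01, 0.03) * H
    band_gain <- stats::runif(spec$band_count, 0.45, 0.95)
    band_gain[1] <- 1  # brightest band: the RPE line
    druse_x <- stats::runif(spec$drusen_count, 0.1 * W, 0.9 * W)
    druse_w <- stats::runif(spec$drusen_count, 0.02 * W, 0.045 * W)
    fluid_x <- stats::runif(1, 0.3 * W, 0.7 * W)
    speckle <- matrix(stats::rnorm(H * W), H, W)

    base_y <- 0.45 * H + tilt * (xs - W / 2) + amp * sin(2 * pi * xs / W + phase)
    spacing <- 0.05 * H
    sigma_b <- 0.012 * H

    # per-column deformation of the brightest band
    druse_bump <- numeric(W)
    if (class_name == "dry_amd" && spec$drusen_amplitude > 0)
      for (j in seq_len(spec$drusen_count))
        druse_bump <- druse_bump + spec$drusen_amplitude *
          exp(-(xs - druse_x[j])^2 / (2 * druse_w[j]^2))
    elev <- numeric(W)
    if (class_name == "wet_amd" && spec$fluid_radius > 0)
      elev <- spec$fluid_radius *
        exp(-(xs - fluid_x)^2 / (2 * (2 * spec$fluid_radius)^2))

    img <- matrix(0.06, H, W)
    ymat <- matrix(ys, H, W)
    for (b in seq_len(spec$band_count)) {
      # bands sit below the RPE line; band 1 carries the lesions
      deform <- if (b == 1) druse_bump + elev else numeric(W)
      center <- matrix(base_y + (b - 1) * spacing - deform, H, W, byrow = TRUE)
      img <- img + band_gain[b] * exp(-(ymat - center)^2 / (2 * sigma_b^2))
    }
    if (class_name == "dry_amd" && spec$drusen_amplitude > 0) {
      # hyperreflective material on top of the deformed band
      center <- matrix(base_y - druse_bump, H, W, byrow = TRUE)
      blob <- matrix(pmin(druse_bump / max(spec$drusen_amplitude, 1e-9), 1),
                     H, W, byrow = TRUE)
      img <- img + 0.6 * blob *
        exp(-(ymat - center)^2 / (2 * (2.2 * sigma_b)^2))
    }
    if (class_name == "wet_amd" && spec$fluid_radius > 0) {
      # dark fluid pocket beneath the elevated band
      cy <- matrix(base_y + 0.8 * spec$fluid_radius, H, W, byrow = TRUE)
      cxm <- matrix(fluid_x, H, W, byrow = TRUE)
      xmat <- matrix(xs, H, W, byrow = TRUE)
      ell <- ((xmat - cxm) / (2 * spec$fluid_radius))^2 +
        ((ymat - cy) / spec$fluid_radius)^2
      img <- img * (1 - 0.85 * exp(-ell)) + 0.25 * exp(-ell)
    }
    if (spec$speckle_sigma > 0)
      img <- img * (1 + spec$speckle_sigma * speckle)
    pmin(pmax(img, 0), 1)
  })
  img
}

#' Generate the synthetic OCT dataset
#'
#' Writes `n_per_class` 8-bit PNG images per class (`dry_amd`, `normal`,
#' `wet_amd`) into class subdirectories of `out`. Images are grayscale
#' replicated to 3 channels. Generation is fully determined by the spec:
#' rerunning with the same spec produces bit-identical files. With
#' `speckle_sigma = 0`, `drusen_amplitude = 0` and `fluid_radius = 0` the
#' three classes render pixel-identically (the degenerate, signal-free
#' configuration).
#'
#' @param spec A [synthetic_spec()].
#' @param out Output directory (created if missing).
#' @return The [load_dataset()] index of the generated directory.
#' @export
generate_synthetic <- function(spec = synthetic_spec(), out) {
  stopifnot(inherits(spec, "synthetic_spec"))
  classes <- c("dry_amd", "normal", "wet_amd")
  for (cl in classes)
    dir.create(file.path(out, cl), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(spec$n_per_class)) {
    scene_seed <- (spec$seed + 7919L * i) %% .Machine$integer.max
    for (cl in classes) {
      img <- render_bscan(spec, scene_seed, cl)
      rgb <- array(img, c(dim(img), 3L))
      png::writePNG(rgb, file.path(out, cl, sprintf("bscan_%04d.png", i)))
    }
  }
  load_dataset(out)
}

#' Read an image file as an (H, W, C) array in [0, 1]
#'
#' PNG files are decoded natively; JPEG and TIFF are decoded through EBImage
#' when available.
#'
#' @param path Image file path.
#' @return Numeric array `(H, W, C)` with C = 1 or 3.
#' @export
read_image <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    x <- png::readPNG(path)
  } else {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("EBImage is required to read non-PNG images", call. = FALSE)
    e <- EBImage::readImage(path)
    x <- EBImage::imageData(e)
    # EBImage uses (x, y[, c]); transpose to (row, col[, c])
    x <- if (length(dim(x)) == 2L) t(x) else aperm(x, c(2, 1, 3))
  }
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  if (dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]  # drop alpha
  if (max(x) > 1) x <- x / 255
  x
}
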