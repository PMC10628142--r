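#' Specification for a synthetic leaf-image dataset
#'
#' Describes a deterministic, class-separable synthetic dataset emulating the
#' structure of public plant-leaf collections: one directory per class, one
#' "healthy" class, and disease classes distinguished by lesion motifs. Each
#' class is rendered as a leaf of a distinct base hue carrying a class-specific
#' lesion pattern (spot count, size, placement), so that at `noise_level = 0`
#' classes are separable by a nearest-class-template rule, and difficulty grows
#' with `noise_level`.
#'
#' @param name Dataset label (free text).
#' @param n_classes Number of classes, >= 2. Ignored when `class_names` is
#'   given.
#' @param images_per_class Images generated per class, >= 1.
#' @param image_size Integer `(height, width)`, both >= 8.
#' @param noise_level Amplitude of uniform pixel noise in `[0, 1]`; 0 renders
#'   noise-free images.
#' @param seed Integer seed; identical specs (including seed) render
#'   bit-identical datasets.
#' @param class_names Optional character vector of class labels; its length
#'   overrides `n_classes`. A class named (case-insensitively) "healthy" is
#'   rendered lesion-free; if none matches, the last class is the healthy one.
#' @return An object of class `leaf_dataset_spec`.
#' @seealso [make_dataset()], [dataset_preset()]
#' @export
dataset_spec <- function(name = "synthetic", n_classes = 4L,
                         images_per_class = 30L, image_size = c(32L, 32L),
                         noise_level = 0.1, seed = 1L, class_names = NULL) {
  if (!is.null(class_names)) {
    class_names <- as.character(class_names)
    n_classes <- length(class_names)
  }
  n_classes <- .check_count(n_classes, "n_classes", min = 2L)
  images_per_class <- .check_count(images_per_class, "images_per_class", min = 1L)
  if (length(image_size) != 2L) .fl_stop("`image_size` must be (height, width)")
  h <- .check_count(image_size[1], "image_size[height]", min = 8L)
  w <- .check_count(image_size[2], "image_size[width]", min = 8L)
  if (!is.numeric(noise_level) || length(noise_level) != 1L ||
      is.na(noise_level) || noise_level < 0 || noise_level > 1) {
    .fl_stop("`noise_level` must be a single number in [0, 1]")
  }
  seed <- .check_count(seed, "seed", min = 0L)
  if (is.null(class_names)) {
    class_names <- c(paste0("disease_", seq_len(n_classes - 1L)), "Healthy")
  }
  structure(
    list(name = as.character(name)[1], n_classes = n_classes,
         images_per_class = images_per_class, image_size = c(h, w),
         noise_level = as.numeric(noise_level), seed = seed,
         class_names = class_names),
    class = "leaf_dataset_spec"
  )
}

#' Preset specs mirroring the four public plant-leaf datasets
#'
#' Returns a [dataset_spec()] whose class labels mirror the four PlantVillage
#' collections commonly used for leaf-disease benchmarks: grape, apple and
#' corn with 4 classes each and tomato with 10, one healthy class per dataset.
#' The default scale is small ("desk") so full federated sweeps run on one
#' CPU; `scale = "published"` sizes each balanced synthetic set to approximately
#' the published image counts (grape 4062, apple 3161, corn 3852,
#' tomato 18160).
#'
#' @param name One of `"grape"`, `"apple"`, `"corn"`, `"tomato"`.
#' @param scale `"desk"` (default, `images_per_class` images per class) or
#'   `"published"` (per-class count = published total / number of classes,
#'   rounded).
#' @param images_per_class Per-class count used at desk scale.
#' @param ... Further arguments passed to [dataset_spec()] (`image_size`,
#'   `noise_level`, `seed`).
#' @return A `leaf_dataset_spec`.
#' @export
dataset_preset <- function(name = c("grape", "apple", "corn", "tomato"),
                           scale = c("desk", "published"),
                           images_per_class = 30L, ...) {
  name <- match.arg(name)
  scale <- match.arg(scale)
  presets <- list(
    grape  = list(classes = c("Black_rot", "Black_Measles", "Leaf_blight", "Healthy"),
                  total = 4062L),
    apple  = list(classes = c("Apple_scab", "Black_rot", "Cedar_apple_rust", "Healthy"),
                  total = 3161L),
    corn   = list(classes = c("Leaf_spot", "Common_rust", "Healthy", "Leaf_blight"),
                  total = 3852L),
    tomato = list(classes = c("Bacterial_Spot", "Early_Blight", "Late_Blight",
                              "Leaf_Mold", "Septoria_leaf_spot",
                              "Two_Spotted_Spider_Mite", "Target_Spot",
                              "Yellow_Leaf_Curl_Virus", "Mosaic_Virus", "Healthy"),
                  total = 18160L)
  )
  p <- presets[[name]]
  ipc <- if (scale == "published") as.integer(round(p$total / length(p$classes))) else images_per_class
  dataset_spec(name = name, images_per_class = ipc, class_names = p$classes, ...)
}

# per-class rendering parameters: distinct base hue; disease classes get a
# class-specific lesion motif (spot count, radius, color, placement spread)
.class_render_params <- function(k, n_classes, healthy) {
  hue <- 0.95 * (k - 1) / n_classes
  leaf_rgb <- grDevices::col2rgb(grDevices::hsv(hue, 0.55, 0.60))[, 1] / 255
  if (healthy) {
    return(list(leaf = leaf_rgb, n_spots = 0L, radius = 0, spot = c(0, 0, 0),
                spread = 0))
  }
  spot_hue <- (hue + 0.45) %% 1
  list(
    leaf = leaf_rgb,
    n_spots = 2L + (k * 2L) %% 5L,
    radius = 0.05 + 0.03 * (k %% 3L),        # fraction of min(h, w)
    spot = grDevices::col2rgb(grDevices::hsv(spot_hue, 0.85, 0.35))[, 1] / 255,
    spread = 0.15 + 0.1 * (k %% 2L)          # placement sd around leaf center
  )
}

# render one leaf image: dark background, elliptical leaf of the class hue,
# lesion spots with soft edges, then uniform pixel noise of the given amplitude
.render_leaf <- function(h, w, params, noise_level) {
  yc <- (seq_len(h) - 0.5) / h - 0.5
  xc <- (seq_len(w) - 0.5) / w - 0.5
  # mild per-image shape jitter so images within a class are not identical
  cy <- stats::runif(1, -0.04, 0.04)
  cx <- stats::runif(1, -0.04, 0.04)
  ry <- stats::runif(1, 0.36, 0.44)
  rx <- stats::runif(1, 0.30, 0.38)
  ell <- outer((yc - cy)^2 / ry^2, (xc - cx)^2 / rx^2, `+`)
  leaf_mask <- ell <= 1

  bg <- c(0.16, 0.12, 0.07)
  img <- array(0, dim = c(h, w, 3L))
  for (ch in 1:3) {
    plane <- matrix(bg[ch], h, w)
    plane[leaf_mask] <- params$leaf[ch]
    img[, , ch] <- plane
  }

  if (params$n_spots > 0L) {
    r_px <- params$radius * min(h, w)
    for (s in seq_len(params$n_spots)) {
      sy <- cy + stats::rnorm(1, 0, params$spread) * ry
      sx <- cx + stats::rnorm(1, 0, params$spread) * rx
      r_s <- r_px * stats::runif(1, 0.7, 1.3)
      d2 <- outer(((yc - sy) * h)^2, ((xc - sx) * w)^2, `+`) # squared distance in px
      alpha <- pmax(0, 1 - d2 / r_s^2) # soft-edged disc
      alpha[!leaf_mask] <- 0
      for (ch in 1:3) {
        img[, , ch] <- img[, , ch] * (1 - alpha) + params$spot[ch] * alpha
      }
    }
  }

  if (noise_level > 0) {
    img <- img + stats::runif(length(img), -noise_level, noise_level)
    img[img < 0] <- 0
    img[img > 1] <- 1
  }
  img
}

#' Generate a synthetic labeled leaf-image dataset
#'
#' Renders `n_classes * images_per_class` images according to a
#' [dataset_spec()]: class `k` is a leaf of a distinct base hue with a
#' class-specific lesion motif; the healthy class carries no lesions. Labels
#' are balanced by construction and the output is bit-identical for identical
#' specs.
#'
#' @param spec A [dataset_spec()].
#' @return A [image_set()] in class-major order (all images of class 1 first).
#' @examples
#' d <- make_dataset(dataset_spec(n_classes = 4, images_per_class = 5, seed = 7))
#' table(d$labels)
#' @export
make_dataset <- function(spec) {
  if (!inherits(spec, "leaf_dataset_spec")) {
    .fl_stop("`spec` must be created with dataset_spec()")
  }
  h <- spec$image_size[1]; w <- spec$image_size[2]
  healthy_idx <- grep("healthy", spec$class_names, ignore.case = TRUE)
  healthy_idx <- if (length(healthy_idx)) healthy_idx[1] else spec$n_classes

  set.seed(spec$seed)
  images <- vector("list", spec$n_classes * spec$images_per_class)
  labels <- integer(length(images))
  i <- 0L
  for (k in seq_len(spec$n_classes)) {
    params <- .class_render_params(k, spec$n_classes, healthy = (k == healthy_idx))
    for (j in seq_len(spec$images_per_class)) {
      i <- i + 1L
      images[[i]] <- .render_leaf(h, w, params, spec$noise_level)
      labels[i] <- k
    }
  }
  image_set(images, labels, spec$class_names)
}

#' Stratified train/test split
#'
#' Splits a labeled image set into train and test subsets, sampling
#' `round(test_fraction * n_k)` test images per class (within one image of the
#' exact proportion), uniformly at random under the given seed. Train and test
#' are disjoint and together recover the input.
#'
#' @param data A [image_set()].
#' @param test_fraction Fraction of each class assigned to the test set, in
#'   `(0, 1)`.
#' @param seed Integer seed; identical inputs and seed give identical splits.
#' @return A list with elements `train` and `test`, both `leaf_image_set`.
#' @export
stratified_split <- function(data, test_fraction = 0.2, seed = 1L) {
  stopifnot(inherits(data, "leaf_image_set"))
  test_fraction <- .check_fraction(test_fraction, "test_fraction")
  seed <- .check_count(seed, "seed", min = 0L)
  counts <- table(factor(data$labels, levels = seq_along(data$class_names)))
  present <- which(counts > 0)
  if (any(counts[present] < 2L)) {
    bad <- data$class_names[present[counts[present] < 2L]][1]
    .fl_stop(sprintf("class '%s' has fewer than 2 examples; cannot split", bad))
  }
  set.seed(seed)
  test_idx <- integer(0)
  for (k in present) {
    idx_k <- which(data$labels == k)
    n_test <- as.integer(round(test_fraction * length(idx_k)))
    n_test <- min(max(n_test, 0L), length(idx_k))
    if (n_test > 0L) test_idx <- c(test_idx, sample(idx_k, n_test))
  }
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_along(data$labels), test_idx)
  list(train = subset_images(data, train_idx),
       test = subset_images(data, test_idx))
}

#' Write a labeled image set to a class-per-directory tree of PNG files
#'
#' Lays the dataset out in the de facto convention of public leaf-image
#' repositories: `<root>/<class_name>/<image>.png`, 3-channel 8-bit PNG.
#'
#' @param data A [image_set()].
#' @param root Target directory; must be absent or empty.
#' @return Invisibly, `root`.
#' @export
write_dataset <- function(data, root) {
  stopifnot(inherits(data, "leaf_image_set"))
  if (dir.exists(root) && length(list.files(root, all.files = TRUE, no.. = TRUE))) {
    .fl_stop(sprintf("`root` '%s' exists and is not empty", root))
  }
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  counter <- integer(length(data$class_names))
  for (i in seq_along(data$images)) {
    k <- data$labels[i]
    cls_dir <- file.path(root, data$class_names[k])
    if (!dir.exists(cls_dir)) dir.create(cls_dir)
    counter[k] <- counter[k] + 1L
    img <- data$images[[i]]
    img[img < 0] <- 0; img[img > 1] <- 1
    png::writePNG(img, file.path(cls_dir, sprintf("img_%05d.png", counter[k])))
  }
  invisible(root)
}

#' Read a class-per-directory image dataset from disk
#'
#' Reads `<root>/<class>/<image>.png`; class names are the subdirectory names
#' in lexicographic order, and labels index that order. Non-PNG files are
#' skipped with a warning; an empty class directory is an error.
#'
#' @param root Directory containing one subdirectory per class.
#' @return A [image_set()].
#' @export
read_dataset <- function(root) {
  if (!dir.exists(root)) .fl_stop(sprintf("dataset root '%s' does not exist", root))
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE),
                  method = "radix")
  if (!length(classes)) .fl_stop(sprintf("'%s' contains no class directories", root))
  images <- list(); labels <- integer(0)
  for (k in seq_along(classes)) {
    cls_dir <- file.path(root, classes[k])
    files <- sort(list.files(cls_dir, full.names = TRUE), method = "radix")
    kept <- 0L
    for (f in files) {
      if (tolower(tools::file_ext(f)) != "png") {
        warning(sprintf("skipping non-image file '%s'", f), call. = FALSE)
        next
      }
      im <- png::readPNG(f)
      im <- .as_rgb_array(im)
      images[[length(images) + 1L]] <- im
      labels <- c(labels, k)
      kept <- kept + 1L
    }
    if (kept == 0L) {
      .fl_stop(sprintf("class directory '%s' contains no readable images", cls_dir))
    }
  }
  image_set(images, labels, classes)
}

# coerce grayscale (h x w) and RGBA (h x w x 4) PNG data to h x w x 3
.as_rgb_array <- function(im) {
  if (is.matrix(im)) {
    array(rep(im, 3L), dim = c(dim(im), 3L))
  } else if (length(dim(im)) == 3L && dim(im)[3] >= 3L) {
    im[, , 1:3, drop = FALSE]
  } else {
    .fl_stop("unsupported image channel layout")
  }
}
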