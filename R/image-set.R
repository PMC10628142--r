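#' Labeled image set
#'
#' In-memory form of a class-per-directory image dataset: a list of 3-channel
#' real-valued image arrays together with integer class labels. This is the
#' container every pipeline stage (preprocessing, partitioning, training,
#' evaluation) consumes and produces.
#'
#' @param images List of numeric `height x width x 3` arrays with values in
#'   `[0, 1]` (or standardized values after [normalize_images()]).
#' @param labels Integer vector, one label per image, each in
#'   `1..length(class_names)`.
#' @param class_names Character vector of class labels; position `k` names
#'   label `k`.
#' @return An object of class `leaf_image_set` with fields `images`, `labels`
#'   and `class_names`.
#' @seealso [make_dataset()], [read_dataset()], [stratified_split()]
#' @export
image_set <- function(images, labels, class_names) {
  if (!is.list(images)) .fl_stop("`images` must be a list of arrays")
  labels <- as.integer(labels)
  if (length(images) != length(labels)) {
    .fl_stop("`images` and `labels` must have the same length")
  }
  class_names <- as.character(class_names)
  if (length(class_names) < 1L) .fl_stop("`class_names` must be non-empty")
  if (length(labels) > 0L) {
    if (anyNA(labels) || any(labels < 1L) || any(labels > length(class_names))) {
      .fl_stop("every label must index `class_names` (1..", length(class_names), ")")
    }
    dims <- vapply(images, function(im) {
      d <- dim(im)
      if (is.null(d) || length(d) != 3L || d[3] != 3L) {
        .fl_stop("every image must be a height x width x 3 array")
      }
      d[1:2]
    }, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
      .fl_stop("all images must share the same height and width")
    }
  }
  structure(
    list(images = images, labels = labels, class_names = class_names),
    class = "leaf_image_set"
  )
}

#' @export
print.leaf_image_set <- function(x, ...) {
  d <- if (length(x$images)) dim(x$images[[1]]) else c(0L, 0L, 3L)
  cat(sprintf("<leaf_image_set> %d images (%dx%dx%d), %d classes\n",
              length(x$images), d[1], d[2], d[3], length(x$class_names)))
  tab <- table(factor(x$class_names[x$labels], levels = x$class_names))
  for (k in seq_along(x$class_names)) {
    cat(sprintf("  %-28s %d\n", x$class_names[k], tab[[k]]))
  }
  invisible(x)
}

#' @export
length.leaf_image_set <- function(x) length(x$images)

#' Subset a labeled image set by image index
#'
#' @param data A [image_set()] object.
#' @param idx Integer indices of images to keep.
#' @return A `leaf_image_set` with the selected images; `class_names` kept as is.
#' @export
subset_images <- function(data, idx) {
  stopifnot(inherits(data, "leaf_image_set"))
  idx <- as.integer(idx)
  if (length(idx) && (min(idx) < 1L || max(idx) > length(data$images))) {
    .fl_stop("`idx` out of range")
  }
  image_set(data$images[idx], data$labels[idx], data$class_names)
}

# stack images into a h x w x 3 x B array for vectorized batch computation
.stack_images <- function(images) {
  d <- dim(images[[1]])
  array(unlist(images, use.names = FALSE), dim = c(d, length(images)))
}
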