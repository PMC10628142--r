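#' Resize every image in a set to a fixed target shape
#'
#' Bilinear resize (via EBImage) of all images to `target = (height, width)`,
#' the "consistent shape" step applied before standardization. Labels are
#' unchanged. When the target equals the current shape the images are returned
#' untouched.
#'
#' @param data A [image_set()].
#' @param target Integer `(height, width)`, both >= 1.
#' @return A `leaf_image_set` of resized images.
#' @export
resize_images <- function(data, target) {
  stopifnot(inherits(data, "leaf_image_set"))
  if (length(target) != 2L) .fl_stop("`target` must be (height, width)")
  th <- .check_count(target[1], "target[height]")
  tw <- .check_count(target[2], "target[width]")
  if (!length(data$images)) return(data)
  d <- dim(data$images[[1]])
  if (d[1] == th && d[2] == tw) return(data)
  resized <- lapply(data$images, function(im) {
    # EBImage resizes the first two array dimensions; axis naming is
    # immaterial as long as it is consistent, so (h, w, c) passes straight in
    out <- EBImage::resize(EBImage::Image(im, colormode = "Color"),
                           w = th, h = tw, filter = "bilinear")
    array(EBImage::imageData(out), dim = c(th, tw, 3L))
  })
  image_set(resized, data$labels, data$class_names)
}

#' Per-channel mean and standard deviation of an image set
#'
#' Computes, over all pixels of all images, the empirical mean `m` and the
#' population standard deviation `sigma` of each of the three channels. These
#' are the statistics of the standardization `Z = (X - m) / sigma`; they are
#' intended to be computed on the training subset and applied unchanged to
#' test data so both share the same distribution.
#'
#' @param data A non-empty [image_set()].
#' @return An object of class `channel_stats`: list with numeric length-3
#'   fields `mean` and `sd`.
#' @export
compute_channel_stats <- function(data) {
  stopifnot(inherits(data, "leaf_image_set"))
  if (!length(data$images)) .fl_stop("cannot compute channel stats of an empty dataset")
  n_px <- sum(vapply(data$images, function(im) prod(dim(im)[1:2]), numeric(1)))
  s <- numeric(3); ss <- numeric(3)
  for (im in data$images) {
    for (ch in 1:3) {
      v <- im[, , ch]
      s[ch] <- s[ch] + sum(v)
      ss[ch] <- ss[ch] + sum(v * v)
    }
  }
  m <- s / n_px
  var_pop <- ss / n_px - m^2
  var_pop[var_pop < 0] <- 0 # guard tiny negative rounding
  sd_pop <- sqrt(var_pop)
  if (any(sd_pop == 0)) {
    .fl_stop(sprintf("channel %d has zero variance; standardization requires sigma > 0",
                     which(sd_pop == 0)[1]))
  }
  structure(list(mean = m, sd = sd_pop), class = "channel_stats")
}

#' @export
print.channel_stats <- function(x, ...) {
  cat("<channel_stats>\n  mean:", format(x$mean, digits = 4),
      "\n  sd:  ", format(x$sd, digits = 4), "\n")
  invisible(x)
}

#' Standardize an image set with fixed channel statistics
#'
#' Applies `Z = (X - m) / sigma` channel-wise, with `m` and `sigma` taken from
#' a [compute_channel_stats()] result (normally computed on the training
#' split). Labels are unchanged.
#'
#' @param data A [image_set()].
#' @param stats A `channel_stats` object.
#' @return A `leaf_image_set` of standardized images (values no longer in
#'   `[0, 1]`).
#' @export
normalize_images <- function(data, stats) {
  stopifnot(inherits(data, "leaf_image_set"), inherits(stats, "channel_stats"))
  if (length(stats$mean) != 3L || length(stats$sd) != 3L) {
    .fl_stop("`stats` must carry exactly 3 channels to match 3-channel images")
  }
  if (any(stats$sd <= 0)) .fl_stop("`stats$sd` must be strictly positive")
  out <- lapply(data$images, function(im) {
    for (ch in 1:3) im[, , ch] <- (im[, , ch] - stats$mean[ch]) / stats$sd[ch]
    im
  })
  image_set(out, data$labels, data$class_names)
}

#' Invert the channel standardization
#'
#' Recovers `X = Z * sigma + m`, the inverse of [normalize_images()].
#'
#' @inheritParams normalize_images
#' @return A `leaf_image_set` on the original scale.
#' @export
denormalize_images <- function(data, stats) {
  stopifnot(inherits(data, "leaf_image_set"), inherits(stats, "channel_stats"))
  out <- lapply(data$images, function(im) {
    for (ch in 1:3) im[, , ch] <- im[, , ch] * stats$sd[ch] + stats$mean[ch]
    im
  })
  image_set(out, data$labels, data$class_names)
}
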