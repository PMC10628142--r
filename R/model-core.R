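.ARCHITECTURES <- c("tiny_cnn", "resnet50", "densenet121", "vgg16",
                    "mobilenet_v2", "inception_v3", "vit_b16", "vit_b32")

#' Specification of a trainable classifier
#'
#' Names the architecture and its head/input configuration. `tiny_cnn` — two
#' 3x3 convolution blocks (8 and 16 filters, each ReLU + 2x2 max pooling),
#' global average pooling and a linear head — is the desk-scale reference
#' backend implemented in this package and accepts any input of at least
#' 16x16 pixels. The seven large published architectures are registered names
#' that require an external deep-learning backend; building them without one
#' raises an informative error.
#'
#' @param architecture One of `"tiny_cnn"`, `"resnet50"`, `"densenet121"`,
#'   `"vgg16"`, `"mobilenet_v2"`, `"inception_v3"`, `"vit_b16"`, `"vit_b32"`.
#' @param n_classes Number of output classes, >= 2.
#' @param input_size Integer `(height, width)` the model expects.
#' @param pretrained Logical; `tiny_cnn` has no published pretrained weights,
#'   so only `FALSE` is accepted for it.
#' @param init_seed Integer seed fully determining the random initialization.
#' @return An object of class `fl_model_spec`.
#' @export
model_spec <- function(architecture = "tiny_cnn", n_classes = 4L,
                       input_size = c(32L, 32L), pretrained = FALSE,
                       init_seed = 1L) {
  architecture <- match.arg(architecture, .ARCHITECTURES)
  n_classes <- .check_count(n_classes, "n_classes", min = 2L)
  if (length(input_size) != 2L) .fl_stop("`input_size` must be (height, width)")
  h <- .check_count(input_size[1], "input_size[height]")
  w <- .check_count(input_size[2], "input_size[width]")
  if (architecture == "tiny_cnn" && (h < 16L || w < 16L)) {
    .fl_stop("tiny_cnn requires input_size of at least 16x16")
  }
  stopifnot(is.logical(pretrained), length(pretrained) == 1L)
  init_seed <- .check_count(init_seed, "init_seed", min = 0L)
  structure(
    list(architecture = architecture, n_classes = n_classes,
         input_size = c(h, w), pretrained = pretrained, init_seed = init_seed),
    class = "fl_model_spec"
  )
}

#' Build a classifier from a model specification
#'
#' For `tiny_cnn`, initializes all parameters (He-scaled Gaussian weights,
#' zero biases) deterministically from `init_seed`. The other registered
#' architectures need a deep-learning backend and raise an error naming the
#' architecture.
#'
#' @param spec A [model_spec()].
#' @return An object of class `fl_model`: list with fields `spec`, `params`
#'   (named list of parameter arrays) and `layout`.
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "fl_model_spec"))
  if (spec$architecture != "tiny_cnn") {
    .fl_stop(sprintf(
      "architecture '%s' requires an external deep-learning backend, which is not available; use 'tiny_cnn'",
      spec$architecture))
  }
  if (isTRUE(spec$pretrained)) {
    .fl_stop("no pretrained weights exist for 'tiny_cnn'; set pretrained = FALSE")
  }
  f1 <- 8L; f2 <- 16L; k2 <- .KSIZE^2
  set.seed(spec$init_seed)
  params <- list(
    conv1.W = matrix(stats::rnorm(k2 * 3L * f1, sd = sqrt(2 / (k2 * 3L))), k2 * 3L, f1),
    conv1.b = numeric(f1),
    conv2.W = matrix(stats::rnorm(k2 * f1 * f2, sd = sqrt(2 / (k2 * f1))), k2 * f1, f2),
    conv2.b = numeric(f2),
    head.W = matrix(stats::rnorm(f2 * spec$n_classes, sd = sqrt(1 / f2)),
                    f2, spec$n_classes),
    head.b = numeric(spec$n_classes)
  )
  layout <- lapply(params, function(p) if (is.matrix(p)) dim(p) else length(p))
  structure(list(spec = spec, params = params, layout = layout),
            class = "fl_model")
}

#' @export
print.fl_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, 1L))
  cat(sprintf("<fl_model> %s: %d classes, input %dx%d, %d parameters\n",
              x$spec$architecture, x$spec$n_classes,
              x$spec$input_size[1], x$spec$input_size[2], n_par))
  invisible(x)
}

#' Flat weight vector of a model
#'
#' Serializes all trainable parameters into one flat numeric vector plus a
#' layout manifest (ordered parameter names and shapes). The flat vector is
#' the unit of client-to-server transfer and of federated averaging; two
#' weight vectors are aggregation-compatible exactly when their layouts are
#' identical.
#'
#' @param model An [build_model()] object.
#' @return An object of class `weight_vector`: list with numeric `values` and
#'   named list `layout` of shapes.
#' @export
get_weights <- function(model) {
  stopifnot(inherits(model, "fl_model"))
  structure(
    list(values = unlist(lapply(model$params, as.numeric), use.names = FALSE),
         layout = model$layout),
    class = "weight_vector"
  )
}

#' @export
print.weight_vector <- function(x, ...) {
  cat(sprintf("<weight_vector> %d values over %d parameters\n",
              length(x$values), length(x$layout)))
  invisible(x)
}

#' Load a flat weight vector into a model
#'
#' Inverse of [get_weights()]: checks that the layout matches the model's and
#' unflattens the values into the parameter arrays. After
#' `set_weights(m, get_weights(m))` the model's predictions are unchanged.
#'
#' @param model An `fl_model`.
#' @param weights A `weight_vector` with a layout identical to the model's.
#' @return The model carrying the new parameter values.
#' @export
set_weights <- function(model, weights) {
  stopifnot(inherits(model, "fl_model"), inherits(weights, "weight_vector"))
  .check_layout(model$layout, weights$layout)
  total <- sum(vapply(model$layout, prod, 1))
  if (length(weights$values) != total) {
    .fl_stop(sprintf("weight vector has %d values but layout requires %d",
                     length(weights$values), total))
  }
  offset <- 0L
  for (nm in names(model$layout)) {
    sh <- model$layout[[nm]]
    n <- prod(sh)
    vals <- weights$values[(offset + 1L):(offset + n)]
    model$params[[nm]] <- if (length(sh) > 1L) {
      matrix(vals, sh[1], sh[2])
    } else {
      as.numeric(vals)
    }
    offset <- offset + as.integer(n)
  }
  model
}

.check_layout <- function(ref, other) {
  if (!identical(names(ref), names(other))) {
    n_min <- min(length(ref), length(other))
    first <- which(names(ref)[seq_len(n_min)] != names(other)[seq_len(n_min)])
    bad <- if (length(first)) {
      names(ref)[first[1]]
    } else {
      c(names(ref), names(other))[n_min + 1L]
    }
    .fl_stop(sprintf("weight layout mismatch at parameter '%s'", bad))
  }
  for (nm in names(ref)) {
    if (!identical(as.integer(ref[[nm]]), as.integer(other[[nm]]))) {
      .fl_stop(sprintf("weight layout mismatch at parameter '%s'", nm))
    }
  }
  invisible(TRUE)
}

#' Class-score logits for a batch of images
#'
#' @param model A built `fl_model`.
#' @param data A [image_set()] (labels are ignored).
#' @return A numeric matrix, one row per image, one column per class.
#' @export
predict_logits <- function(model, data) {
  stopifnot(inherits(model, "fl_model"), inherits(data, "leaf_image_set"))
  if (!length(data$images)) .fl_stop("`data` is empty")
  X <- .stack_images(data$images)
  X <- aperm(X, c(1, 2, 3, 4)) # (h, w, C, B) already
  .tiny_cnn_forward(model$params, X)$logits
}

#' @export
predict.fl_model <- function(object, data, ...) {
  logits <- predict_logits(object, data)
  max.col(logits, ties.method = "first")
}

#' Train a model locally by mini-batch stochastic gradient descent
#'
#' Runs `epochs` full passes of plain SGD with cross-entropy loss over the
#' data. Each epoch visits a fresh seeded shuffle of the items in mini-batches
#' of `batch_size` (the final batch may be smaller); the epoch shuffle seed is
#' derived from `seed` and the epoch index, so training is deterministic per
#' (initial weights, data, seed).
#'
#' @param model A built `fl_model` carrying the initial weights.
#' @param data A non-empty [image_set()] of preprocessed images.
#' @param epochs Number of full passes, >= 1.
#' @param batch_size Mini-batch size, >= 1.
#' @param lr Learning rate, >= 0 (0 leaves the weights untouched).
#' @param seed Integer seed for the per-epoch batch shuffles.
#' @return A list: `model` (trained), `weights` (its [get_weights()]),
#'   `epoch_losses` (mean training loss per epoch).
#' @export
local_train <- function(model, data, epochs = 1L, batch_size = 16L,
                        lr = 0.01, seed = 1L) {
  stopifnot(inherits(model, "fl_model"), inherits(data, "leaf_image_set"))
  n <- length(data$images)
  if (n == 0L) .fl_stop("`data` is empty; cannot train")
  epochs <- .check_count(epochs, "epochs")
  batch_size <- .check_count(batch_size, "batch_size")
  if (!is.numeric(lr) || length(lr) != 1L || is.na(lr) || lr < 0) {
    .fl_stop("`lr` must be a single non-negative number")
  }
  seed <- .check_count(seed, "seed", min = 0L)

  K <- model$spec$n_classes
  if (any(data$labels > K)) .fl_stop("data labels exceed the model's class count")
  Xall <- .stack_images(data$images)
  Yall <- matrix(0, n, K)
  Yall[cbind(seq_len(n), data$labels)] <- 1

  params <- model$params
  epoch_losses <- numeric(epochs)
  for (e in seq_len(epochs)) {
    set.seed(derive_seed(seed, e))
    perm <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    loss_sum <- 0
    for (s in starts) {
      ids <- perm[s:min(s + batch_size - 1L, n)]
      lg <- .tiny_cnn_loss_grad(params, Xall[, , , ids, drop = FALSE],
                                Yall[ids, , drop = FALSE])
      if (lr > 0) {
        for (nm in names(params)) params[[nm]] <- params[[nm]] - lr * lg$grads[[nm]]
      }
      loss_sum <- loss_sum + lg$loss * length(ids)
    }
    epoch_losses[e] <- loss_sum / n
  }
  model$params <- params
  list(model = model, weights = get_weights(model), epoch_losses = epoch_losses)
}
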