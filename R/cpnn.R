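# Counter-propagation neural network (CPNN): an unsupervised Kohonen
# codebook grid coupled to a supervised output layer that stores, per
# neuron, a value in [0, 1] per class.  The winning neuron for an input
# is the codebook vector at minimal Euclidean distance (ties broken by
# the lowest row-major index); during training the winner's grid
# neighborhood is pulled toward the input and, with the same factors,
# the output layer toward the one-hot class target, so output weights
# stay convex combinations of 0/1 targets and their initial value.

#' Initialize a counter-propagation network
#'
#' The codebook is drawn uniformly at random per feature within the
#' min-max range of `reference` (or in `[0, 1]` when no reference data
#' are given); output weights start at `1/n_classes`.
#'
#' @param grid `c(rows, cols)` of the Kohonen map (default `c(10, 10)`).
#' @param n_features Descriptor length (default 210).
#' @param seed Integer seed; initialization and training are fully
#'   reproducible given the seed.
#' @param reference Optional numeric matrix whose per-column ranges
#'   bound the random initialization.
#' @param classes Class labels (default `c("nonTM", "TM")`).
#' @return An object of class `cpnn`.
#' @export
cpnn_init <- function(grid = c(10L, 10L), n_features = 210L, seed = 1L,
                      reference = NULL, classes = c("nonTM", "TM")) {
  stopifnot(length(grid) == 2L)
  if (any(grid < 1L)) abort("grid dimensions must be >= 1")
  if (n_features < 1L) abort("n_features must be >= 1")
  n_neurons <- grid[1L] * grid[2L]
  if (!is.null(reference)) {
    lo <- apply(reference, 2L, min)
    hi <- apply(reference, 2L, max)
  } else {
    lo <- rep(0, n_features); hi <- rep(1, n_features)
  }
  set.seed(seed)
  codebook <- matrix(runif(n_neurons * n_features), n_neurons, n_features)
  codebook <- sweep(sweep(codebook, 2L, hi - lo, `*`), 2L, lo, `+`)
  output <- matrix(1 / length(classes), n_neurons, length(classes),
                   dimnames = list(NULL, classes))
  structure(
    list(grid = as.integer(grid), codebook = codebook, output = output,
         classes = classes, seed = as.integer(seed), trained = FALSE,
         hyper = NULL, quantization_error = numeric(0),
         center = NULL, scale = NULL,
         encoding = "adj210/sym/norm"),
    class = "cpnn")
}

# apply the model's stored autoscaling, if any
scale_input <- function(model, x) {
  if (is.null(model$center)) return(x)
  sweep(sweep(x, 2L, model$center), 2L, model$scale, `/`)
}

#' Winning neuron of the Kohonen layer
#'
#' @param model A `cpnn` object.
#' @param x A descriptor vector, or a matrix with one descriptor per row.
#' @return Integer vector of 1-based flat (row-major) neuron indices;
#'   ties go to the lowest index.
#' @export
cpnn_winner <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != ncol(model$codebook)) {
    abort(sprintf("descriptor length %d does not match model (%d features)",
                  ncol(x), ncol(model$codebook)))
  }
  cpnn_winner_cpp(model$codebook, scale_input(model, x))
}

#' Train a counter-propagation network
#'
#' Per epoch the examples are visited in a seed-determined shuffled
#' order; the learning rate and the Gaussian neighborhood radius decay
#' linearly from their initial to final values.  The per-epoch mean
#' distance of each example to its winner (quantization error) is
#' logged in the returned model.
#'
#' @param model A `cpnn` object from [cpnn_init()].
#' @param x Descriptor matrix (rows = examples).
#' @param labels Character or factor class labels matching
#'   `model$classes`; at least two classes must be present.
#' @param epochs Training epochs (default 100).
#' @param eta Initial/final learning rate (default `c(0.5, 0.01)`).
#' @param radius Initial/final neighborhood radius; default
#'   `max(grid)/2` down to 1.
#' @return The trained `cpnn` model.
#' @export
cpnn_train <- function(model, x, labels, epochs = 100L,
                       eta = c(0.5, 0.01), radius = NULL) {
  stopifnot(inherits(model, "cpnn"), epochs >= 1L)
  if (nrow(x) != length(labels)) abort("x and labels have different lengths")
  cls <- match(as.character(labels), model$classes)
  if (anyNA(cls)) abort("labels contain classes unknown to the model")
  if (length(unique(cls)) < 2L) {
    abort("training data must contain at least two classes")
  }
  if (is.null(radius)) radius <- c(max(model$grid) / 2, 1)
  set.seed(model$seed + 1L)
  fit <- cpnn_train_cpp(x, cls, length(model$classes),
                        model$grid[1L], model$grid[2L], as.integer(epochs),
                        eta[1L], eta[2L], radius[1L], radius[2L],
                        model$codebook + 0, model$output + 0)
  model$codebook <- fit$codebook
  model$output <- fit$output
  colnames(model$output) <- model$classes
  model$quantization_error <- as.numeric(fit$quantization_error)
  model$hyper <- list(epochs = as.integer(epochs), eta = eta, radius = radius)
  model$trained <- TRUE
  model
}

#' Fit a CPNN classifier to encoded windows
#'
#' Convenience wrapper: initializes from the data range and trains.
#'
#' @inheritParams cpnn_train
#' @param encoded Tibble from [encode_windows()] with a logical `tm`
#'   column, or a descriptor matrix (then `labels` is required).
#' @param labels Optional explicit labels.
#' @param grid,seed Passed to [cpnn_init()].
#' @param standardize Autoscale each descriptor feature to zero mean
#'   and unit variance over the training set before training (default
#'   `TRUE`)?  The centering/scaling is stored in the model and applied
#'   to every later input, so winner search stays Euclidean in the
#'   model's feature space.  Autoscaling stops the handful of
#'   high-count common pairs from dominating the distance.
#' @return A trained `cpnn` model.
#' @export
cpnn <- function(encoded, labels = NULL, grid = c(10L, 10L), seed = 1L,
                 epochs = 100L, eta = c(0.5, 0.01), radius = NULL,
                 standardize = TRUE) {
  if (is.data.frame(encoded)) {
    x <- descriptor_matrix(encoded)
    if (is.null(labels)) {
      stopifnot("tm" %in% names(encoded))
      labels <- ifelse(encoded$tm, "TM", "nonTM")
    }
  } else {
    x <- encoded
    if (is.null(labels)) abort("labels are required with a matrix input")
  }
  center <- scale_sd <- NULL
  if (standardize) {
    center <- colMeans(x)
    scale_sd <- pmax(apply(x, 2L, sd), 1e-8)
    x <- sweep(sweep(x, 2L, center), 2L, scale_sd, `/`)
  }
  model <- cpnn_init(grid = grid, n_features = ncol(x), seed = seed,
                     reference = x)
  model <- cpnn_train(model, x, labels, epochs = epochs, eta = eta,
                      radius = radius)
  model$center <- center
  model$scale <- scale_sd
  model
}

#' Predict class labels with a trained CPNN
#'
#' The confidence is the winning neuron's output weight for the `TM`
#' class; the label is `TM` iff confidence is greater than or equal to
#' the threshold (inclusive, so an exact tie is called `TM`).
#'
#' @param object A trained `cpnn` model.
#' @param newdata Descriptor matrix or tibble from [encode_windows()].
#' @param threshold Decision threshold on the TM confidence (default 0.5).
#' @param ... Unused.
#' @return A tibble with columns `label` and `confidence` (plus the
#'   window columns when `newdata` is an encoded tibble).
#' @export
predict.cpnn <- function(object, newdata, threshold = 0.5, ...) {
  tbl <- NULL
  if (is.data.frame(newdata)) {
    tbl <- dplyr::select(newdata, -"descriptor")
    newdata <- descriptor_matrix(newdata)
  }
  if (!object$trained ||
      all(abs(object$output - 1 / length(object$classes)) < 1e-12)) {
    warn("model output layer appears untrained; predictions are uninformative")
  }
  w <- cpnn_winner(object, newdata)
  conf <- unname(object$output[w, "TM"])
  res <- tibble::tibble(
    label = ifelse(conf >= threshold, "TM", "nonTM"),
    confidence = as.numeric(conf))
  if (!is.null(tbl)) res <- dplyr::bind_cols(tbl, res)
  res
}

#' Evaluate a CPNN against labelled data
#'
#' @param model A trained `cpnn` model.
#' @param encoded Encoded window tibble with a logical `tm` column, or a
#'   descriptor matrix (then `labels` required).
#' @param labels Optional explicit labels (`"TM"`/`"nonTM"`).
#' @param threshold Decision threshold.
#' @return A one-row tibble: `tp`, `fp`, `tn`, `fn`, `n`, `accuracy`.
#' @export
cpnn_evaluate <- function(model, encoded, labels = NULL, threshold = 0.5) {
  if (is.data.frame(encoded) && is.null(labels)) {
    stopifnot("tm" %in% names(encoded))
    labels <- ifelse(encoded$tm, "TM", "nonTM")
  }
  if (length(labels) == 0L) abort("evaluation requires a non-empty dataset")
  pred <- predict(model, encoded, threshold = threshold)$label
  truth <- as.character(labels)
  tibble::tibble(
    tp = sum(pred == "TM" & truth == "TM"),
    fp = sum(pred == "TM" & truth == "nonTM"),
    tn = sum(pred == "nonTM" & truth == "nonTM"),
    fn = sum(pred == "nonTM" & truth == "TM"),
    n = length(truth),
    accuracy = mean(pred == truth))
}

#' @export
print.cpnn <- function(x, ...) {
  cat(sprintf("Counter-propagation network: %d x %d grid, %d features\n",
              x$grid[1L], x$grid[2L], ncol(x$codebook)))
  cat(sprintf("  classes: %s; seed %d; %s\n",
              paste(x$classes, collapse = ", "), x$seed,
              if (x$trained) sprintf("trained %d epochs (final QE %.4g)",
                                     x$hyper$epochs,
                                     utils::tail(x$quantization_error, 1))
              else "untrained"))
  invisible(x)
}

#' Tidy a CPNN into a per-neuron tibble
#'
#' @param x A `cpnn` model.
#' @param ... Unused.
#' @return A tibble with one row per neuron: grid `row`/`col`, the flat
#'   index `neuron`, and one output-weight column per class.
#' @export
tidy.cpnn <- function(x, ...) {
  n <- nrow(x$codebook)
  idx <- seq_len(n)
  out <- tibble::tibble(
    neuron = idx,
    row = (idx - 1L) %/% x$grid[2L] + 1L,
    col = (idx - 1L) %% x$grid[2L] + 1L)
  dplyr::bind_cols(out, tibble::as_tibble(x$output))
}

#' One-row summary of a CPNN fit
#'
#' @param x A `cpnn` model.
#' @param ... Unused.
#' @return A one-row tibble with grid size, feature count, epochs, seed
#'   and final quantization error.
#' @export
glance.cpnn <- function(x, ...) {
  tibble::tibble(
    rows = x$grid[1L], cols = x$grid[2L], n_features = ncol(x$codebook),
    epochs = if (x$trained) x$hyper$epochs else 0L,
    seed = x$seed,
    final_qe = if (x$trained) utils::tail(x$quantization_error, 1) else NA_real_)
}

#' Save / load a CPNN model as JSON
#'
#' The file stores the grid, hyperparameters, seed, codebook, output
#' weights and the descriptor encoding id.
#'
#' @param model A `cpnn` model.
#' @param path File path.
#' @return `path` invisibly / the restored `cpnn` model.
#' @export
write_cpnn <- function(model, path) {
  obj <- list(grid = model$grid, classes = model$classes, seed = model$seed,
              trained = model$trained, hyper = model$hyper,
              encoding = model$encoding,
              quantization_error = model$quantization_error,
              center = model$center, scale = model$scale,
              codebook = model$codebook, output = unname(model$output))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cpnn
#' @export
read_cpnn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(m) {
    m <- as.matrix(m)
    dimnames(m) <- NULL
    m
  }
  model <- structure(
    list(grid = as.integer(obj$grid),
         codebook = as_mat(obj$codebook),
         output = matrix(as_mat(obj$output), nrow = prod(obj$grid),
                         dimnames = list(NULL, obj$classes)),
         classes = obj$classes, seed = as.integer(obj$seed),
         trained = isTRUE(obj$trained), hyper = obj$hyper,
         quantization_error = as.numeric(obj$quantization_error),
         center = if (!is.null(obj$center)) as.numeric(obj$center),
         scale = if (!is.null(obj$scale)) as.numeric(obj$scale),
         encoding = obj$encoding),
    class = "cpnn")
  model
}
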