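#' Network architecture specification
#'
#' The architecture is: a length-preserving 1-D convolution over the one-hot
#' input (`kernels` filters of width `kernel_size`, stride 1, zero "same"
#' padding so the feature map is `L x kernels`), ReLU, flatten, a fully
#' connected layer of `fc_units` with ReLU, dropout, and a fully connected
#' softmax output of `n_classes`.
#'
#' @param L Input window length (even).
#' @param n_conv_layers Number of convolutional layers (default 1).
#' @param kernels Convolution filters per layer (default 50).
#' @param kernel_size Filter width in nucleotides (default 9).
#' @param stride Convolution stride; fixed at 1.
#' @param fc_units Hidden fully connected units (default 100).
#' @param dropout_rate Fraction of hidden activations masked during training
#'   (default 0.30).
#' @param n_classes 3 for the donor/acceptor/non-splice model, 2 for the
#'   binary filter variants.
#' @param conv_relu Apply ReLU after the convolution (default `TRUE`).
#' @return A `model_spec` list.
#' @export
model_spec <- function(L = 400L, n_conv_layers = 1L, kernels = 50L,
                       kernel_size = 9L, stride = 1L, fc_units = 100L,
                       dropout_rate = 0.30, n_classes = 3L,
                       conv_relu = TRUE) {
  if (stride != 1L) stop("spec error: stride is fixed at 1")
  if (n_conv_layers != 1L)
    stop("spec error: this implementation builds one convolutional layer")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("spec error: dropout_rate must be in [0, 1)")
  if (kernel_size > L) stop("spec error: kernel_size > L")
  if (L %% 2L != 0L) stop("spec error: L must be even")
  if (!n_classes %in% c(2L, 3L)) stop("spec error: n_classes must be 2 or 3")
  structure(list(L = as.integer(L), n_conv_layers = 1L,
                 kernels = as.integer(kernels),
                 kernel_size = as.integer(kernel_size), stride = 1L,
                 fc_units = as.integer(fc_units),
                 dropout_rate = dropout_rate,
                 n_classes = as.integer(n_classes),
                 conv_relu = isTRUE(conv_relu)),
            class = "model_spec")
}

#' Training configuration
#'
#' Cross-entropy loss minimized with Adam.
#'
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param epochs Training epochs (default 40).
#' @param batch_size Minibatch size (default 50).
#' @param seed Integer seed controlling weight initialization, shuffling and
#'   dropout.
#' @param class_weights Optional per-class loss weights in label order
#'   (default all 1 = unweighted).
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 40L,
                         batch_size = 50L, seed = 1L, class_weights = NULL) {
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate > 0)
  structure(list(loss = "cross_entropy", optimizer = "adam",
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 class_weights = class_weights),
            class = "train_config")
}

#' Closed-form trainable parameter count
#'
#' conv: `kernels * (kernel_size * 4 + 1)`; hidden:
#' `(L * kernels) * fc_units + fc_units`; output:
#' `fc_units * n_classes + n_classes`.
#'
#' @param spec A [model_spec()].
#' @return Integer parameter count.
#' @export
count_parameters <- function(spec) {
  with(spec, kernels * (kernel_size * 4L + 1L) +
         (L * kernels) * fc_units + fc_units +
         fc_units * n_classes + n_classes)
}

.model_labels <- function(n_classes, positive_class = NULL) {
  if (n_classes == 3L) LABEL_ORDER
  else c(positive_class %||% "positive", "non_splice")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Build an (untrained) network
#'
#' Weights are Glorot-uniform initialized, biases zero; the initialization is
#' deterministic given `seed`.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for weight initialization.
#' @param label_order Class labels in output-column order; defaults to
#'   `acceptor, donor, non_splice` for 3 classes.
#' @return A `splice_cnn` model handle.
#' @export
build_model <- function(spec, seed = 1L, label_order = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  label_order <- label_order %||% .model_labels(spec$n_classes)
  if (length(label_order) != spec$n_classes)
    stop("label_order length must equal n_classes")
  set.seed(seed)
  flat <- spec$L * spec$kernels
  params <- list(
    Wc = .glorot(spec$kernel_size * 4L, spec$kernels),
    bc = numeric(spec$kernels),
    W1 = .glorot(flat, spec$fc_units),
    b1 = numeric(spec$fc_units),
    W2 = .glorot(spec$fc_units, spec$n_classes),
    b2 = numeric(spec$n_classes))
  structure(list(spec = spec, params = params, label_order = label_order,
                 history = NULL, trained = FALSE),
            class = "splice_cnn")
}

#' @export
print.splice_cnn <- function(x, ...) {
  cat("splice_cnn: L=", x$spec$L, ", ", x$spec$kernels, " kernels of size ",
      x$spec$kernel_size, ", fc=", x$spec$fc_units, ", classes=",
      paste(x$label_order, collapse = "/"), "\n",
      "parameters: ", count_parameters(x$spec),
      if (x$trained) " (trained)" else " (untrained)", "\n", sep = "")
  invisible(x)
}

.dataset_xy <- function(dataset_or_windows, label_order) {
  if (inherits(dataset_or_windows, "splice_dataset"))
    w <- dataset_or_windows$windows
  else w <- dataset_or_windows
  y <- match(w$label, label_order) - 1L
  if (anyNA(y))
    stop("data error: label outside model label order (",
         paste(label_order, collapse = ", "), ")")
  list(x = .encode_cube(w$sequence), y = as.integer(y))
}

#' Train a network
#'
#' Minibatch Adam on the cross-entropy loss, with inverted dropout on the
#' hidden layer during training only. The validation set is used for
#' per-epoch monitoring, never for weight updates or stopping.
#'
#' @param model A `splice_cnn` from [build_model()].
#' @param train_set,validation_set `splice_dataset`s (validation may be
#'   `NULL`).
#' @param config A [train_config()].
#' @param fresh_init Re-initialize weights from `config$seed` before training
#'   (default `TRUE`); set `FALSE` to continue from the handle's weights.
#' @return The trained `splice_cnn`; `$history` is a data.frame with one row
#'   per epoch (`epoch`, `train_loss`, `train_acc`, `val_loss`, `val_acc`).
#' @export
train_model <- function(model, train_set, validation_set = NULL, config,
                        fresh_init = TRUE) {
  stopifnot(inherits(model, "splice_cnn"), inherits(config, "train_config"))
  if (fresh_init)
    model <- build_model(model$spec, seed = config$seed,
                         label_order = model$label_order)
  tr <- .dataset_xy(train_set, model$label_order)
  if (!is.null(validation_set)) {
    va <- .dataset_xy(validation_set, model$label_order)
  } else {
    va <- list(x = array(0, dim = c(model$spec$L, 4L, 0L)), y = integer())
  }
  cw <- config$class_weights %||% rep(1, model$spec$n_classes)
  fit <- .cnn_train_cpp(tr$x, tr$y, va$x, va$y, model$params,
                        epochs = config$epochs,
                        batch_size = config$batch_size,
                        lr = config$learning_rate,
                        dropout = model$spec$dropout_rate,
                        conv_relu = model$spec$conv_relu,
                        seed = config$seed, class_weights = cw)
  model$params <- fit$params
  h <- fit$history
  model$history <- data.frame(epoch = seq_len(nrow(h)), train_loss = h[, 1],
                              train_acc = h[, 2], val_loss = h[, 3],
                              val_acc = h[, 4])
  model$trained <- TRUE
  model
}

#' Class probabilities for windows
#'
#' Dropout is inactive; rows sum to 1.
#'
#' @param model A `splice_cnn`.
#' @param windows Character vector of length-`L` sequences, a
#'   `splice_dataset`, or an `(n, L, 4)` encoded array.
#' @return `n x n_classes` matrix with columns named by the model's label
#'   order.
#' @export
predict_proba <- function(model, windows) {
  x <- .windows_to_cube(model, windows)
  p <- .cnn_forward_cpp(x, model$params, training = FALSE, dropout = 0,
                        conv_relu = model$spec$conv_relu, seed = 0L)$probs
  colnames(p) <- model$label_order
  p
}

.windows_to_cube <- function(model, windows) {
  if (inherits(windows, "splice_dataset")) windows <- windows$windows$sequence
  if (is.character(windows)) {
    if (any(nchar(windows) != model$spec$L))
      stop("shape error: window length != model L (", model$spec$L, ")")
    .encode_cube(windows)
  } else if (is.array(windows) && length(dim(windows)) == 3L) {
    if (dim(windows)[2L] != model$spec$L || dim(windows)[3L] != 4L)
      stop("shape error: encoded array must be (n, L, 4) with L = ",
           model$spec$L)
    aperm(windows, c(2L, 3L, 1L))
  } else stop("windows must be sequences, a splice_dataset or an array")
}

# forward pass exposing dropout behavior; used by diagnostics and tests
.forward_debug <- function(model, windows, training = FALSE, seed = 1L) {
  x <- .windows_to_cube(model, windows)
  .cnn_forward_cpp(x, model$params, training = training,
                   dropout = model$spec$dropout_rate,
                   conv_relu = model$spec$conv_relu, seed = seed)
}

#' Empirical dropout mask rate of a model's hidden layer
#'
#' Runs forward passes in training mode and reports the fraction of hidden
#' dropout-layer units that were masked to zero, over at least `min_draws`
#' unit draws. In inference mode the fraction is exactly 0.
#'
#' @param model A `splice_cnn`.
#' @param min_draws Minimum number of unit draws (default 1e6).
#' @param seed Integer seed.
#' @return list with `fraction`, `n_draws`.
#' @export
dropout_mask_rate <- function(model, min_draws = 1e6, seed = 1L) {
  L <- model$spec$L
  n <- ceiling(min_draws / model$spec$fc_units)
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1L))
  masked <- 0; total <- 0
  chunk <- 2000L
  for (s0 in seq(1L, n, by = chunk)) {
    s1 <- min(n, s0 + chunk - 1L)
    f <- .forward_debug(model, seqs[s0:s1], training = TRUE,
                        seed = seed + s0)
    masked <- masked + f$n_masked
    total <- total + f$n_units
  }
  list(fraction = masked / total, n_draws = total)
}

#' Save a model to a directory
#'
#' Writes a JSON sidecar (`spec.json`: format version, architecture, label
#' order, training history) and the weights in R's native serialization
#' (`weights.rds`).
#'
#' @param model A `splice_cnn`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(format_version = 1L, spec = unclass(model$spec),
               label_order = model$label_order, trained = model$trained)
  jsonlite::write_json(meta, file.path(path, "spec.json"), auto_unbox = TRUE,
                       digits = NA)
  saveRDS(model$params, file.path(path, "weights.rds"))
  if (!is.null(model$history))
    utils::write.table(model$history, file.path(path, "history.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path Model directory.
#' @param expect_classes Optional class count to assert (e.g. 3 when a
#'   3-class scanner model is required).
#' @return A `splice_cnn`.
#' @export
load_model <- function(path, expect_classes = NULL) {
  meta_path <- file.path(path, "spec.json")
  if (!file.exists(meta_path)) stop("model not found at ", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$format_version) || meta$format_version != 1L)
    stop("model load error: format version ",
         meta$format_version %||% "<missing>", " (this build reads 1)")
  if (!is.null(expect_classes) && meta$spec$n_classes != expect_classes)
    stop("model class-count error: expected ", expect_classes,
         " classes, found ", meta$spec$n_classes)
  spec <- do.call(model_spec, meta$spec[c("L", "n_conv_layers", "kernels",
                                          "kernel_size", "stride",
                                          "fc_units", "dropout_rate",
                                          "n_classes", "conv_relu")])
  params <- readRDS(file.path(path, "weights.rds"))
  hist_path <- file.path(path, "history.tsv")
  history <- if (file.exists(hist_path))
    utils::read.table(hist_path, sep = "\t", header = TRUE) else NULL
  structure(list(spec = spec, params = params,
                 label_order = meta$label_order, history = history,
                 trained = isTRUE(meta$trained)),
            class = "splice_cnn")
}
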