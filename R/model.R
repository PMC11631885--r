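#' Configuration of the large-kernel 1D convolutional sequence labeller
#'
#' The network judges each disc space relative to its neighbours, so its
#' receptive field is made large: a stem convolution lifting the single
#' binary input channel to `channels`, then `n_intermediate_layers` residual
#' blocks (conv kernel `kernel_size` -> batch norm -> ReLU, identity added),
#' then a width-1 convolution to `n_classes` logits with a per-position
#' softmax. Stride is 1 with zero padding, so output length equals input
#' length; the receptive field of the default configuration is
#' `1 + 6 * (151 - 1) = 901` positions.
#'
#' @param kernel_size odd convolution kernel length (default 151).
#' @param channels feature channels (default 64).
#' @param n_intermediate_layers residual blocks after the stem (default 5).
#' @param n_classes output classes (default 3: no / normal / narrowed disc
#'   space).
#' @param input_length sequence length (default 1024).
#' @return an object of class `model_config`.
#' @export
model_config <- function(kernel_size = 151L, channels = 64L,
                         n_intermediate_layers = 5L, n_classes = 3L,
                         input_length = 1024L) {
  kernel_size <- stopifnot_scalar_count(kernel_size, "kernel_size")
  if (kernel_size %% 2L == 0L)
    stop("'kernel_size' must be odd (length-preserving padding)", call. = FALSE)
  structure(list(
    kernel_size = kernel_size,
    channels = stopifnot_scalar_count(channels, "channels"),
    n_intermediate_layers = stopifnot_scalar_count(n_intermediate_layers,
                                                   "n_intermediate_layers"),
    n_classes = stopifnot_scalar_count(n_classes, "n_classes", min = 2L),
    input_length = stopifnot_scalar_count(input_length, "input_length")
  ), class = "model_config")
}

#' Combined cross-entropy + focal loss configuration
#'
#' Per position with one-hot truth `y` and predicted probabilities `p`, the
#' class-c cross entropy is `L_c = -y_c log p_c` and the combined loss is
#' `sum_c [ alpha_c (1 - p_c)^gamma L_c + L_c ]`. The focal term down-weights
#' easy positions, countering the heavy class imbalance between background,
#' normal and narrowed rows.
#'
#' @param alpha balancing factor, a scalar or one value per class
#'   (default 0.25).
#' @param gamma focusing factor (default 2).
#' @param n_classes number of classes (default 3).
#' @param clip_eps probability floor before logarithms (default 1e-7).
#' @return an object of class `loss_config`.
#' @export
loss_config <- function(alpha = 0.25, gamma = 2.0, n_classes = 3L,
                        clip_eps = 1e-7) {
  if (any(alpha <= 0)) stop("'alpha' must be positive", call. = FALSE)
  if (gamma < 0) stop("'gamma' must be >= 0", call. = FALSE)
  structure(list(alpha = alpha, gamma = gamma,
                 n_classes = as.integer(n_classes), clip_eps = clip_eps),
            class = "loss_config")
}

#' Training configuration
#'
#' Defaults follow the reference training regime (Adam, learning rate 1e-5,
#' 50 epochs, batch 16, 80:20 train/validation split by image, early stopping
#' on validation loss with patience 10). Small synthetic runs on a CPU budget
#' need a larger learning rate and fewer epochs; pass them here.
#'
#' @param learning_rate Adam step size (default 1e-5).
#' @param epochs maximum epochs (default 50).
#' @param batch_size minibatch size (default 16).
#' @param seed RNG seed for split, shuffling and initialization.
#' @param validation_fraction held-out fraction for model selection
#'   (default 0.2).
#' @param patience early-stopping patience in epochs (default 10).
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-5, epochs = 50L, batch_size = 16L,
                         seed = 1L, validation_fraction = 0.2, patience = 10L) {
  if (learning_rate <= 0) stop("'learning_rate' must be > 0", call. = FALSE)
  if (validation_fraction < 0 || validation_fraction >= 1)
    stop("'validation_fraction' must be in [0,1)", call. = FALSE)
  structure(list(learning_rate = learning_rate,
                 epochs = stopifnot_scalar_count(epochs, "epochs"),
                 batch_size = stopifnot_scalar_count(batch_size, "batch_size"),
                 seed = as.integer(seed),
                 validation_fraction = validation_fraction,
                 patience = stopifnot_scalar_count(patience, "patience")),
            class = "train_config")
}

#' Build an untrained sequence-labelling network
#'
#' He-style random initialization of all convolution weights; batch-norm
#' scales start at 1 with running statistics at the standard normal, biases
#' at zero.
#'
#' @param config a [model_config()].
#' @param seed integer RNG seed for the weight draw.
#' @return an object of class `ivd_cnn`.
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  net <- cpp_nn_init(config$kernel_size, config$channels,
                     config$n_intermediate_layers, config$n_classes,
                     as.integer(seed))
  structure(list(net = net, config = config, trained = FALSE, history = NULL),
            class = "ivd_cnn")
}

#' Combined cross-entropy + focal loss (reference implementation)
#'
#' Direct R evaluation of the printed formula, averaged over positions.
#' This is the package's ground-truth definition of the loss; the C++
#' training path must agree with it.
#'
#' @param y_true one-hot matrix (positions x classes) or an integer class
#'   vector (0-based).
#' @param y_pred probability matrix (positions x classes).
#' @param cfg a [loss_config()].
#' @return mean combined loss (scalar).
#' @export
combined_loss <- function(y_true, y_pred, cfg = loss_config()) {
  stopifnot(inherits(cfg, "loss_config"))
  if (!is.matrix(y_pred)) y_pred <- matrix(y_pred, nrow = 1)
  if (!is.matrix(y_true)) {
    if (length(y_true) == ncol(y_pred) && nrow(y_pred) == 1) {
      y_true <- matrix(y_true, nrow = 1)
    } else {
      oh <- matrix(0, length(y_true), ncol(y_pred))
      oh[cbind(seq_along(y_true), as.integer(y_true) + 1L)] <- 1
      y_true <- oh
    }
  }
  if (!identical(dim(y_true), dim(y_pred)))
    stop("y_true and y_pred shapes differ", call. = FALSE)
  p <- pmin(pmax(y_pred, cfg$clip_eps), 1 - cfg$clip_eps)
  alpha <- rep_len(cfg$alpha, ncol(p))
  Lcc <- -y_true * log(p)
  focal <- sweep((1 - p)^cfg$gamma * Lcc, 2, alpha, `*`)
  mean(rowSums(focal + Lcc))
}

#' Train the sequence labeller on quantified-vector data
#'
#' Minimizes the combined loss with Adam over an 80:20 (by default)
#' image-level train/validation split; the checkpoint with the best
#' validation loss is retained and early stopping uses `patience`.
#' A fixed seed reproduces the weight trajectory on one machine.
#'
#' @param dataset an `ivd_vector_dataset` from [generate_vector_dataset()],
#'   or a list of `list(vector, labels)` pairs.
#' @param model an `ivd_cnn` from [build_model()]; built fresh when `NULL`.
#' @param tcfg a [train_config()].
#' @param lcfg a [loss_config()].
#' @return the trained `ivd_cnn`, with `history` (per-epoch train/validation
#'   loss) and `best_epoch`.
#' @export
train_ivd_cnn <- function(dataset, model = NULL, tcfg = train_config(),
                          lcfg = loss_config()) {
  stopifnot(inherits(tcfg, "train_config"), inherits(lcfg, "loss_config"))
  if (inherits(dataset, "ivd_vector_dataset")) {
    mats <- dataset_matrices(dataset)
  } else if (is.list(dataset) && length(dataset) &&
             all(vapply(dataset, function(d) !is.null(d$vector) &&
                          !is.null(d$labels), logical(1)))) {
    n <- length(dataset)
    mats <- list(X = matrix(0, n, PHANTOM_H), Y = matrix(0L, n, PHANTOM_H))
    for (i in seq_len(n)) {
      mats$X[i, ] <- dataset[[i]]$vector
      mats$Y[i, ] <- dataset[[i]]$labels
    }
  } else stop("empty or malformed training dataset", call. = FALSE)
  if (nrow(mats$X) < 1L) stop("empty training dataset", call. = FALSE)
  if (is.null(model)) model <- build_model(seed = tcfg$seed)
  stopifnot(inherits(model, "ivd_cnn"))
  Y <- mats$Y
  storage.mode(Y) <- "integer"
  if (any(Y < 0L | Y >= model$config$n_classes))
    stop("labels outside 0..n_classes-1", call. = FALSE)
  # the C++ loss uses a single alpha (all classes share 0.25 by default)
  alpha <- if (length(lcfg$alpha) > 1) mean(lcfg$alpha) else lcfg$alpha
  res <- cpp_nn_train(model$net, mats$X, Y, list(
    epochs = tcfg$epochs, batch_size = tcfg$batch_size,
    learning_rate = tcfg$learning_rate, alpha = alpha, gamma = lcfg$gamma,
    clip_eps = lcfg$clip_eps, validation_fraction = tcfg$validation_fraction,
    patience = tcfg$patience, seed = tcfg$seed))
  model$net <- res$net
  model$trained <- TRUE
  model$history <- list(train_loss = as.numeric(res$train_loss),
                        val_loss = as.numeric(res$val_loss))
  model$best_epoch <- res$best_epoch
  model$n_train <- res$n_train
  model$n_val <- res$n_val
  model
}

#' Classify a quantified vector position by position
#'
#' Per-position argmax of the predicted probability triples; ties break
#' toward the lower class index.
#'
#' @param model a trained `ivd_cnn`.
#' @param vector binary vector of length 1024 (or a matrix, one row per
#'   image).
#' @return for a single vector, a list of class `position_labels` with
#'   `values` (integer 0/1/2 per position) and `probs` (1024 x n_classes);
#'   for a matrix input, a list of such objects.
#' @export
classify_vector <- function(model, vector) {
  stopifnot(inherits(model, "ivd_cnn"))
  single <- !is.matrix(vector)
  X <- if (single) matrix(as.numeric(vector), nrow = 1) else vector
  if (ncol(X) != model$config$input_length)
    stop(sprintf("vector length %d != configured input length %d",
                 ncol(X), model$config$input_length), call. = FALSE)
  probs <- cpp_nn_forward(model$net, X)
  out <- lapply(seq_len(nrow(X)), function(i) {
    p <- matrix(probs[i, , ], ncol = model$config$n_classes)
    structure(list(values = max.col(p, ties.method = "first") - 1L, probs = p),
              class = "position_labels")
  })
  if (single) out[[1]] else out
}

#' Per-gap narrowing decision from per-position labels
#'
#' Each measured gap is labelled by majority vote among its rows' predicted
#' classes restricted to normal/narrowed (background votes are ignored);
#' an exact tie is called narrowed (conservative screening) and a gap whose
#' rows carry no disc-space votes at all is `"unassigned"`.
#'
#' @param labels a `position_labels` object (or its integer `values`).
#' @param gaps gap table from [measure_gaps()] on the same vector.
#' @return the gap table with `label` filled in.
#' @export
detect_narrowed <- function(labels, gaps) {
  v <- if (inherits(labels, "position_labels")) labels$values else as.integer(labels)
  stopifnot(length(v) == PHANTOM_H, is.data.frame(gaps))
  lab <- character(nrow(gaps))
  for (i in seq_len(nrow(gaps))) {
    rows <- seq(gaps$start_row[i] + 1L, gaps$end_row[i])
    n_normal <- sum(v[rows] == 1L)
    n_narrow <- sum(v[rows] == 2L)
    lab[i] <- if (n_normal + n_narrow == 0L) "unassigned"
              else if (n_narrow >= n_normal) "narrowed" else "normal"
  }
  gaps$label <- lab
  gaps
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint embeds the `model_config` and a hash of it; loading a
#' checkpoint into a pipeline with a different configuration is a hard error
#' before any inference happens.
#'
#' @param model an `ivd_cnn`.
#' @param path checkpoint file path (RDS).
#' @export
save_ivd_cnn <- function(model, path) {
  stopifnot(inherits(model, "ivd_cnn"))
  model$config_hash <- config_hash(unclass(model$config))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_ivd_cnn
#' @param config optional `model_config` the checkpoint must match.
#' @export
load_ivd_cnn <- function(path, config = NULL) {
  model <- readRDS(path)
  if (!inherits(model, "ivd_cnn")) stop("not an ivd_cnn checkpoint", call. = FALSE)
  if (!is.null(config) &&
      !identical(config_hash(unclass(config)), config_hash(unclass(model$config))))
    stop("checkpoint model configuration does not match the requested configuration",
         call. = FALSE)
  model
}

#' @export
print.ivd_cnn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "large-kernel 1D-CNN: kernel %d, %d channels, %d residual blocks, %d classes\n",
    cfg$kernel_size, cfg$channels, cfg$n_intermediate_layers, cfg$n_classes))
  cat(sprintf("  receptive field: %d positions; %s\n",
              1L + (cfg$n_intermediate_layers + 1L) * (cfg$kernel_size - 1L),
              if (x$trained) sprintf("trained (best epoch %s)",
                                     x$best_epoch %||% NA) else "untrained"))
  invisible(x)
}
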