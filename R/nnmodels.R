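#' Configuration for a PolyaID or PolyaStrength model
#'
#' PolyaID is a dual-head network: a convolutional layer (window 8) followed
#' by a bidirectional LSTM feeds a dense trunk, from which a sigmoid head
#' emits the site classification probability and a 50-way softmax head emits
#' the cleavage probability vector.  PolyaStrength shares the trunk
#' architecture but has a single linear head predicting log2-odds usage.
#'
#' @param task `"polyaid"` or `"polyastrength"`.
#' @param conv_window Convolution window (nt); default 8.
#' @param conv_filters Number of convolution filters.
#' @param rnn_units LSTM units per direction.
#' @param dense_units Width of the dense trunk.
#' @param dropout Dropout fraction applied to the trunk during training.
#' @param learning_rate Nadam learning rate; default 0.001.
#' @param batch_size Minibatch size; default 100.
#' @param max_epochs Training epochs (4 for PolyaID, 9 for PolyaStrength by
#'   default, matching the epoch counts at which validation loss bottomed
#'   out for the full-scale models).
#' @param seed Integer seed controlling weight initialisation, shuffling and
#'   dropout.
#' @param trunk `"flatten"` keeps the full per-position biLSTM output
#'   (needed by the position-sensitive cleavage head; PolyaID default);
#'   `"pool"` summarises it by global mean+max pooling, giving a
#'   translation-invariant trunk that generalises better for the strength
#'   regression (PolyaStrength default).
#' @return A `polya_model_config` list.
#' @export
polya_model_config <- function(task = c("polyaid", "polyastrength"),
                               conv_window = 8L, conv_filters = 64L,
                               rnn_units = 32L, dense_units = 64L,
                               dropout = 0.3, learning_rate = 0.001,
                               batch_size = 100L,
                               max_epochs = NULL, seed = 1L,
                               trunk = NULL) {
  task <- match.arg(task)
  stopifnot(conv_window >= 1, learning_rate > 0, batch_size >= 1,
            dropout >= 0, dropout < 1)
  if (is.null(max_epochs)) max_epochs <- if (task == "polyaid") 4L else 9L
  if (is.null(trunk)) trunk <- if (task == "polyaid") "flatten" else "pool"
  trunk <- match.arg(trunk, c("flatten", "pool"))
  structure(list(
    task = task,
    task_id = if (task == "polyaid") 0L else 1L,
    trunk = trunk,
    pool_id = if (trunk == "flatten") 0L else 1L,
    conv_window = as.integer(conv_window),
    conv_filters = as.integer(conv_filters),
    rnn_units = as.integer(rnn_units),
    dense_units = as.integer(dense_units),
    dropout = dropout,
    learning_rate = learning_rate,
    batch_size = as.integer(batch_size),
    max_epochs = as.integer(max_epochs),
    seed = as.integer(seed)
  ), class = "polya_model_config")
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

#' Build an untrained model from a configuration
#'
#' Initialises all weights (Glorot uniform, forget-gate biases at 1) under
#' the configuration seed so that construction is reproducible.
#'
#' @param config A [polya_model_config()].
#' @return A `polya_model` object (untrained).
#' @export
build_polya_model <- function(config) {
  stopifnot(inherits(config, "polya_model_config"))
  Tlen <- 240L - config$conv_window + 1L
  F <- config$conv_filters; U <- config$rnn_units; D <- config$dense_units
  d_in <- if (config$trunk == "flatten") 2L * U * Tlen else 4L * U
  w <- with_seed(config$seed, {
    w <- list(
      Wc = glorot(F, 4L * config$conv_window), bc = numeric(F),
      Wxf = glorot(4L * U, F), Whf = glorot(4L * U, U),
      bf = c(numeric(U), rep(1, U), numeric(2L * U)),
      Wxb = glorot(4L * U, F), Whb = glorot(4L * U, U),
      bb = c(numeric(U), rep(1, U), numeric(2L * U)),
      Wd = glorot(D, d_in), bd = numeric(D),
      Wcls = glorot(1L, D), bcls = numeric(1)
    )
    if (config$task == "polyaid") {
      w$Wclv <- glorot(50L, D)
      w$bclv <- numeric(50)
    }
    w
  })
  structure(list(config = config, weights = w, trained = FALSE,
                 history = NULL, best_epoch = NA_integer_),
            class = "polya_model")
}

#' @export
print.polya_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<polya_model: %s>\n", cfg$task))
  cat(sprintf("  conv %d filters (window %d), biLSTM %d units/dir, dense %d\n",
              cfg$conv_filters, cfg$conv_window, cfg$rnn_units,
              cfg$dense_units))
  if (isTRUE(x$trained)) {
    cat(sprintf("  trained; best epoch %d (validation loss %.4f)\n",
                x$best_epoch, x$best_val_loss))
  } else {
    cat("  untrained\n")
  }
  invisible(x)
}

#' One-hot encode a set of 240-nt windows into a model input array
#'
#' @param seqs Character vector of 240-nt sequences.
#' @return A `4 x 240 x N` numeric array (rows A, C, G, T; N columns zero).
#' @export
encode_seqs <- function(seqs) {
  n <- length(seqs)
  if (any(nchar(seqs) != 240L)) stop("all sequences must be 240 nt")
  ints <- vapply(toupper(seqs), utf8ToInt, integer(240), USE.NAMES = FALSE)
  X <- array(0, dim = c(4L, 240L, n))
  codes <- c(A = 65L, C = 67L, G = 71L, T = 84L)
  for (b in 1:4) {
    X[b, , ] <- (ints == codes[b]) * 1
  }
  X
}

# assemble (X, y, yclv) from an example tibble
prepare_dataset <- function(examples, task) {
  X <- encode_seqs(examples$seq)
  if (task == "polyaid") {
    y <- as.numeric(examples$label_class)
    yclv <- vapply(examples$label_cleavage, identity, numeric(50))
    list(X = X, y = y, yclv = yclv)
  } else {
    list(X = X, y = as.numeric(examples$label_usage),
         yclv = matrix(0, 1, 1))
  }
}

#' Train a PolyaID or PolyaStrength model
#'
#' Optimises the equally weighted classification (binary cross-entropy) and
#' cleavage (Kullback-Leibler) losses for PolyaID, or the mean squared error
#' on log2-odds usage for PolyaStrength, with the Nadam optimizer
#' (learning rate 0.001, batch size 100 by default).  The weights from the
#' epoch with minimum validation loss are retained.
#'
#' @param model An untrained (or previously trained) `polya_model`.
#' @param train,valid Example tibbles.  For PolyaID they need columns
#'   `seq`, `label_class` and `label_cleavage` (list of length-50 vectors);
#'   for PolyaStrength, `seq` and `label_usage`.
#' @param epochs Override `config$max_epochs`.
#' @param verbose Print per-epoch losses.
#' @return The fitted `polya_model` with `history`, `best_epoch`,
#'   `best_val_loss` filled in.
#' @export
train_polya_model <- function(model, train, valid, epochs = NULL,
                              verbose = FALSE) {
  stopifnot(inherits(model, "polya_model"))
  cfg <- model$config
  if (is.null(epochs)) epochs <- cfg$max_epochs
  tr <- prepare_dataset(train, cfg$task)
  va <- prepare_dataset(valid, cfg$task)
  fit <- nn_train_cpp(model$weights, unclass(cfg),
                      tr$X, tr$y, tr$yclv,
                      va$X, va$y, va$yclv,
                      as.integer(epochs), cfg$batch_size,
                      cfg$learning_rate, cfg$dropout, cfg$seed,
                      verbose)
  hist <- fit$history
  colnames(hist) <- if (cfg$task == "polyaid") {
    c("train_classification", "train_cleavage",
      "val_classification", "val_cleavage")
  } else {
    c("train_mse", "train_unused", "val_mse", "val_unused")
  }
  model$weights <- fit$weights
  model$trained <- TRUE
  model$history <- tibble::as_tibble(hist) |>
    dplyr::mutate(epoch = dplyr::row_number(), .before = 1)
  model$best_epoch <- fit$best_epoch
  model$best_val_loss <- fit$best_val_loss
  model
}

# low-level batched forward pass; x is seqs, array, or matrix
predict_raw <- function(model, x, chunk = 512L) {
  if (is.character(x)) x <- encode_seqs(x)
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  nn_predict_cpp(model$weights, unclass(model$config), x, chunk)
}

#' Predict with a PolyaID / PolyaStrength model
#'
#' @param object A `polya_model`.
#' @param newdata Character vector of 240-nt sequences, a `4 x 240 x N`
#'   array, or a tibble with a `seq` column.
#' @param ... Unused.
#' @return For PolyaID, a tibble with `p_class` and a `cleavage` list-column
#'   of length-50 probability vectors (each summing to 1); for
#'   PolyaStrength, a tibble with `score`.
#' @export
predict.polya_model <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- newdata$seq
  out <- predict_raw(object, newdata)
  if (object$config$task == "polyaid") {
    tibble::tibble(
      p_class = as.numeric(out$p_class),
      cleavage = lapply(seq_len(ncol(out$cleavage)),
                        function(j) out$cleavage[, j])
    )
  } else {
    tibble::tibble(score = as.numeric(out$score))
  }
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training history of a fitted model
#'
#' @param x A trained `polya_model`.
#' @param ... Unused.
#' @return A tibble with one row per epoch and the per-branch losses.
#' @export
tidy.polya_model <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble::tibble(epoch = integer()))
  }
  x$history
}

#' One-row summary of a fitted model
#'
#' @param x A trained `polya_model`.
#' @param ... Unused.
#' @export
glance.polya_model <- function(x, ...) {
  tibble::tibble(
    task = x$config$task,
    trained = isTRUE(x$trained),
    epochs = if (is.null(x$history)) 0L else nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_loss = if (is.null(x$best_val_loss)) NA_real_ else x$best_val_loss,
    n_parameters = sum(vapply(x$weights, length, integer(1)))
  )
}

#' Binary cross-entropy classification loss
#'
#' Mean over the batch of \eqn{-[y \log p + (1-y)\log(1-p)]}, with
#' predictions clipped to `(1e-7, 1 - 1e-7)`.
#'
#' @param y Numeric vector of 0/1 labels.
#' @param p Numeric vector of predicted probabilities.
#' @return Scalar loss.
#' @export
loss_classification <- function(y, p) {
  eps <- 1e-7
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Kullback-Leibler cleavage loss
#'
#' \eqn{\sum_j c_{obs,j} \log(c_{obs,j} / c_{pred,j})} over the 50-position
#' cleavage vector, with `0 log(0/x) := 0` and predictions clipped at 1e-7.
#'
#' @param observed,predicted Length-50 probability vectors.
#' @return Scalar loss (non-negative; 0 iff the vectors agree).
#' @export
loss_cleavage <- function(observed, predicted) {
  eps <- 1e-7
  predicted <- pmax(predicted, eps)
  nz <- observed > 0
  sum(observed[nz] * log(observed[nz] / predicted[nz]))
}

#' Mean squared error usage loss
#'
#' @param u Observed log2-odds usage values.
#' @param v Predicted values.
#' @return Scalar mean squared error.
#' @export
loss_usage <- function(u, v) mean((u - v)^2)
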