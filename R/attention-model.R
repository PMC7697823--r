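#' Model configuration for the attention recurrent classifier
#'
#' Defaults follow the reference training setup: Adam with learning rate
#' 0.001, beta1 0.9, beta2 0.999, epsilon 1e-8; an LSTM of 128 units over at
#' most 15 day-steps; 0.7/0.15/0.15 train/validation/test fractions; batch
#' size 64 and 10 epochs (a 256/20 preset is used for larger cohorts).
#'
#' @param lstm_units Hidden units of the recurrent layer.
#' @param max_len Maximum timesteps the model accepts.
#' @param learning_rate,beta1,beta2,epsilon Adam optimizer settings.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs; the history has exactly this many entries.
#' @param split_fractions Train/validation/test fractions (must sum to 1).
#' @param seed Seed governing initialization and shuffling.
#' @param attention_weight_sharing `"per-timestep"` learns a separate
#'   attention matrix `W_k` for every timestep `k` (the literal reading of
#'   `a_k = softmax(W_k x_k)`); `"shared"` uses one matrix for all steps.
#' @param cell `"lstm"` (default) or `"rnn"` (plain tanh recurrence,
#'   provided as a baseline).
#' @param standardize Standardize each feature to zero mean / unit variance
#'   using statistics of the training split's unmasked days.
#' @param f1_threshold Decision threshold for the F1 metric.
#' @return A `model_config` list.
#' @export
model_config <- function(lstm_units = 128L, max_len = 15L,
                         learning_rate = 0.001, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-8, batch_size = 64L, epochs = 10L,
                         split_fractions = c(0.7, 0.15, 0.15), seed = 1L,
                         attention_weight_sharing = c("per-timestep",
                                                      "shared"),
                         cell = c("lstm", "rnn"), standardize = TRUE,
                         f1_threshold = 0.5) {
  attention_weight_sharing <- match.arg(attention_weight_sharing)
  cell <- match.arg(cell)
  if (length(split_fractions) != 3L || any(split_fractions <= 0) ||
      abs(sum(split_fractions) - 1) > 1e-8)
    stop("split_fractions must be three positive numbers summing to 1",
         call. = FALSE)
  structure(list(
    lstm_units = as.integer(lstm_units), max_len = as.integer(max_len),
    learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
    epsilon = epsilon, batch_size = as.integer(batch_size),
    epochs = as.integer(epochs), split_fractions = split_fractions,
    seed = as.integer(seed),
    attention_weight_sharing = attention_weight_sharing, cell = cell,
    standardize = standardize, f1_threshold = f1_threshold),
    class = "model_config")
}

#' Train the attention recurrent outcome classifier
#'
#' The network is, per sample: a per-timestep attention layer
#' `a_k = softmax(W_k x_k)` whose weights rescale the inputs elementwise
#' (`x_k * a_k`), a masking step that freezes the recurrent state across
#' zero-padded days, a recurrent layer (LSTM with forget/input/output gates,
#' or a plain tanh recurrence for the baseline cell), and a dense sigmoid
#' output on the last unmasked hidden state. Trained with minibatch Adam on
#' binary cross-entropy; all randomness (initialization, shuffling) flows
#' from `config$seed`. Padded days never influence the prediction: inputs
#' are masked before the attention layer and the state carries through
#' masked steps unchanged.
#'
#' @param train Labeled `feature_tensor` with both classes present.
#' @param val Optional validation `feature_tensor`; per-epoch validation
#'   loss is recorded and final metrics are computed on it.
#' @param config A [model_config()].
#' @return A `trained_model`: list with `params` (learned weights including
#'   the attention matrices), `config`, `scaler`, `feature_index`,
#'   `history` (data.frame with one row per epoch), `metrics` (`auroc`,
#'   `f1` on `val`, or `NA` when absent).
#' @export
train_model <- function(train, val = NULL, config = model_config()) {
  stopifnot(inherits(train, "feature_tensor"),
            inherits(config, "model_config"))
  y <- train$labels
  if (is.null(y) || length(unique(y)) < 2L)
    stop("training labels must contain both classes", call. = FALSE)
  T_ <- train$T
  if (T_ > config$max_len)
    stop(sprintf("tensor has %d timesteps but config$max_len is %d",
                 T_, config$max_len), call. = FALSE)
  F_ <- train$F
  H <- config$lstm_units

  scaler <- NULL
  if (config$standardize) scaler <- fit_scaler(train)
  Xs <- apply_scaler(train, scaler)

  with_seed(config$seed, {
    params <- init_params(T_, F_, H, config)
    opt <- adam_init(params)
    n <- length(y)
    history <- data.frame(epoch = seq_len(config$epochs),
                          train_loss = NA_real_, val_loss = NA_real_)
    Xv <- if (!is.null(val)) apply_scaler(val, scaler)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (b in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
        fb <- net_forward(Xs$values[b, , , drop = FALSE],
                          Xs$mask[b, , drop = FALSE], params, config,
                          cache = TRUE)
        yb <- y[b]
        p <- pmin(pmax(fb$p, 1e-12), 1 - 1e-12)
        losses <- c(losses, -mean(yb * log(p) + (1 - yb) * log(1 - p)))
        grads <- net_backward(fb, yb, params, config)
        opt <- adam_step(params, grads, opt, config)
        params <- opt$params
      }
      history$train_loss[ep] <- mean(losses)
      if (!is.null(val)) {
        fv <- net_forward(Xv$values, Xv$mask, params, config, cache = FALSE)
        pv <- pmin(pmax(fv$p, 1e-12), 1 - 1e-12)
        history$val_loss[ep] <- -mean(val$labels * log(pv) +
                                        (1 - val$labels) * log(1 - pv))
      }
    }
  })
  model <- structure(list(params = params, config = config, scaler = scaler,
                          feature_index = train$feature_index,
                          history = history,
                          metrics = list(auroc = NA_real_, f1 = NA_real_)),
                     class = "trained_model")
  if (!is.null(val) && length(unique(val$labels)) == 2L)
    model$metrics <- evaluate_model(model, val)
  model
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("attention %s classifier: %d units, %d feature(s), %d epoch(s)\n",
              toupper(x$config$cell), x$config$lstm_units,
              length(x$feature_index), nrow(x$history)))
  if (!is.na(x$metrics$auroc))
    cat(sprintf("validation auroc %.4f, f1 %.4f\n",
                x$metrics$auroc, x$metrics$f1))
  invisible(x)
}

#' Predict outcome probabilities
#'
#' @param object A `trained_model`.
#' @param tensor A `feature_tensor` with the same feature set as the model.
#' @param ... Unused.
#' @return Numeric vector of probabilities in `[0, 1]`, one per sample.
#' @export
predict.trained_model <- function(object, tensor, ...) {
  stopifnot(inherits(tensor, "feature_tensor"))
  if (tensor$F != length(object$feature_index) ||
      !identical(names(tensor$feature_index),
                 names(object$feature_index)))
    stop("tensor feature set does not match the model's", call. = FALSE)
  if (tensor$T != dim_T(object))
    stop(sprintf("tensor has %d timesteps but the model expects %d",
                 tensor$T, dim_T(object)), call. = FALSE)
  Xs <- apply_scaler(tensor, object$scaler)
  as.numeric(net_forward(Xs$values, Xs$mask, object$params, object$config,
                         cache = FALSE)$p)
}

dim_T <- function(model) {
  if (model$config$attention_weight_sharing == "per-timestep")
    length(model$params$Wa) else model$params$T
}

#' Evaluate a model on a held-out tensor
#'
#' AUROC is the rank-based probability that a random positive outscores a
#' random negative, with ties counted one half (midrank formula); F1 is
#' computed at the configured decision threshold (default 0.5).
#'
#' @param model A `trained_model`.
#' @param test Labeled `feature_tensor` containing both classes.
#' @return List with `auroc` and `f1`.
#' @export
evaluate_model <- function(model, test) {
  if (is.null(test$labels) || length(unique(test$labels)) < 2L)
    stop("AUROC is undefined on a single-class test set", call. = FALSE)
  p <- predict(model, test)
  list(auroc = auroc_score(p, test$labels),
       f1 = f1_score(p, test$labels, model$config$f1_threshold))
}

#' Rank-based AUROC and thresholded F1
#'
#' `auroc_score` uses midranks, so tied scores contribute one half;
#' `f1_score` classifies at `threshold` and returns 0 when precision and
#' recall are both undefined or zero.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @param threshold Decision threshold for F1.
#' @return A number in `[0, 1]`.
#' @export
auroc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUROC is undefined without both classes", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname auroc_score
#' @export
f1_score <- function(scores, labels, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  labels <- as.integer(labels)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Extract per-sample attention maps
#'
#' Runs the forward pass and returns the attention weights `a_k` of every
#' sample: nonnegative, summing to one over features at each unmasked
#' timestep, and exactly zero at masked (padded) timesteps.
#'
#' @param model A `trained_model`.
#' @param tensor A compatible `feature_tensor`.
#' @return An `attention_map`: list with `weights` (`n x T x F` array),
#'   `mask`, `feature_index`, `keys`.
#' @export
extract_attention <- function(model, tensor) {
  stopifnot(inherits(model, "trained_model"),
            inherits(tensor, "feature_tensor"))
  Xs <- apply_scaler(tensor, model$scaler)
  fw <- net_forward(Xs$values, Xs$mask, model$params, model$config,
                    cache = TRUE)
  A <- fw$attention
  for (t in seq_len(tensor$T)) A[, t, ] <- A[, t, ] * tensor$mask[, t]
  structure(list(weights = A, mask = tensor$mask,
                 feature_index = tensor$feature_index, keys = tensor$keys),
            class = "attention_map")
}

#' @export
print.attention_map <- function(x, ...) {
  d <- dim(x$weights)
  cat(sprintf("attention map: %d sample(s) x %d timestep(s) x %d feature(s)\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Save / load a trained model
#'
#' The checkpoint is a JSON document holding the configuration, scaler,
#' feature index, flattened parameter arrays, and training history.
#'
#' @param model A `trained_model`.
#' @param path File path.
#' @return `save_model`: `path`, invisibly. `load_model`: the
#'   `trained_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  ser_mat <- function(m) list(dim = dim(m), data = as.numeric(m))
  params <- model$params
  payload <- list(
    config = unclass(model$config),
    scaler = model$scaler,
    feature_index = as.list(model$feature_index),
    history = as.list(model$history),
    T = if (model$config$attention_weight_sharing == "per-timestep")
      length(params$Wa) else params$T,
    params = list(
      Wa = if (is.list(params$Wa)) lapply(params$Wa, ser_mat)
           else ser_mat(params$Wa),
      Wx = ser_mat(params$Wx), Wh = ser_mat(params$Wh),
      b = as.numeric(params$b), wo = as.numeric(params$wo),
      bo = as.numeric(params$bo)),
    metrics = model$metrics)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE,
                                 simplifyMatrix = FALSE)
  cfg <- payload$config
  config <- model_config(
    lstm_units = cfg$lstm_units, max_len = cfg$max_len,
    learning_rate = cfg$learning_rate, beta1 = cfg$beta1, beta2 = cfg$beta2,
    epsilon = cfg$epsilon, batch_size = cfg$batch_size, epochs = cfg$epochs,
    split_fractions = cfg$split_fractions, seed = cfg$seed,
    attention_weight_sharing = cfg$attention_weight_sharing,
    cell = cfg$cell, standardize = cfg$standardize,
    f1_threshold = cfg$f1_threshold)
  de_mat <- function(m) array(m$data, dim = m$dim)
  p <- payload$params
  Wa <- if (config$attention_weight_sharing == "per-timestep") {
    lapply(p$Wa, de_mat)
  } else de_mat(p$Wa)
  params <- list(Wa = Wa, Wx = de_mat(p$Wx), Wh = de_mat(p$Wh),
                 b = as.numeric(p$b), wo = matrix(p$wo, ncol = 1),
                 bo = as.numeric(p$bo), T = payload$T)
  scaler <- payload$scaler
  if (!is.null(scaler)) scaler <- list(mean = as.numeric(scaler$mean),
                                       sd = as.numeric(scaler$sd))
  structure(list(params = params, config = config, scaler = scaler,
                 feature_index = unlist(payload$feature_index),
                 history = as.data.frame(payload$history),
                 metrics = as.list(payload$metrics)),
            class = "trained_model")
}
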