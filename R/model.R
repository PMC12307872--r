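# Sequence model: BiLSTM -> self-attention -> 1D CNN, optionally fused with a
# dense encoder of baseline variables, ending in a sigmoid regressor on
# min-max-scaled glucose. All layers are implemented directly (base R matrix
# algebra) together with their exact backward passes; see model-engine.R.

#' Model configuration
#'
#' Hyperparameters of the unimodal/multimodal forecaster. Defaults follow the
#' reference architecture: a kernel of 3 with 100 filters in the convolutional
#' stage, 10% dropout after the CNN (a 20% rate for stacked configurations is
#' carried in `dropout_stacked`), Glorot-uniform initialisation, and 50
#' training epochs. The LSTM width, dense widths, optimizer settings and batch
#' size are documented package defaults (the architecture description leaves
#' them open).
#'
#' @param lstm_hidden LSTM units per direction.
#' @param cnn_filters,cnn_kernel,cnn_stride convolution stage shape.
#' @param dropout_cnn dropout rate applied to the flattened CNN features
#'   during training.
#' @param dropout_stacked alternative rate for stacked configurations.
#' @param baseline_hidden integer widths of the dense baseline encoder.
#' @param fusion_hidden width of the fusion network's hidden layer.
#' @param loss `"mse"` (default) or `"eq14"` (the log-likelihood objective;
#'   see [loss_eq14()]).
#' @param epochs,batch_size,learning_rate Adam training loop settings.
#' @param lr_decay_factor per-stage multiplier of a step-decay learning-rate
#'   schedule (1 = constant rate).
#' @param lr_decay_stages number of equal-length decay stages over the run.
#' @param adam_beta2 second-moment decay rate of Adam.
#' @param clip_norm global gradient-norm clipping threshold (`Inf` = off).
#' @param seed integer seed controlling initialisation, shuffling and dropout.
#' @param mode `"unimodal"` (CGM only) or `"multimodal"` (fused with baseline
#'   record).
#' @param variable_set baseline variable set (0..6) used in multimodal mode.
#' @param input_len input window length in samples (6).
#' @return list of class `model_config`.
#' @export
model_config <- function(lstm_hidden = 64L, cnn_filters = 100L,
                         cnn_kernel = 3L, cnn_stride = 1L,
                         dropout_cnn = 0.10, dropout_stacked = 0.20,
                         baseline_hidden = c(32L, 16L), fusion_hidden = 64L,
                         loss = c("mse", "eq14"), epochs = 50L,
                         batch_size = 64L, learning_rate = 1e-3,
                         lr_decay_factor = 1, lr_decay_stages = 3L,
                         adam_beta2 = 0.999, clip_norm = Inf, seed = 1L,
                         mode = c("unimodal", "multimodal"),
                         variable_set = 0L, input_len = 6L) {
  loss <- match.arg(loss)
  mode <- match.arg(mode)
  .assert(lstm_hidden >= 1 && cnn_filters >= 1 && fusion_hidden >= 1 &&
            all(baseline_hidden >= 1), "all layer widths must be positive")
  .assert(dropout_cnn >= 0 && dropout_cnn < 1 &&
            dropout_stacked >= 0 && dropout_stacked < 1,
          "dropout rates must lie in [0, 1)")
  .assert(cnn_kernel <= input_len, "kernel cannot exceed the input length")
  .assert(variable_set %in% 0:6, "variable_set must be in 0..6")
  structure(list(lstm_hidden = as.integer(lstm_hidden),
                 cnn_filters = as.integer(cnn_filters),
                 cnn_kernel = as.integer(cnn_kernel),
                 cnn_stride = as.integer(cnn_stride),
                 dropout_cnn = dropout_cnn,
                 dropout_stacked = dropout_stacked,
                 baseline_hidden = as.integer(baseline_hidden),
                 fusion_hidden = as.integer(fusion_hidden),
                 loss = loss, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_stages = as.integer(lr_decay_stages),
                 adam_beta2 = adam_beta2, clip_norm = clip_norm,
                 seed = as.integer(seed),
                 mode = mode, variable_set = as.integer(variable_set),
                 input_len = as.integer(input_len)),
            class = "model_config")
}

# convolution output length: floor((l - m)/d) + 1
.conv_out_len <- function(l, m, d) floor((l - m) / d) + 1L

#' Glorot-uniform limit
#'
#' @param f_in,f_out fan-in and fan-out of the layer.
#' @return `sqrt(6 / (f_in + f_out))`.
#' @export
glorot_limit <- function(f_in, f_out) sqrt(6 / (f_in + f_out))

.glorot <- function(nr, nc, f_in = nr, f_out = nc) {
  l <- glorot_limit(f_in, f_out)
  matrix(runif(nr * nc, -l, l), nr, nc)
}

#' Initialise model parameters
#'
#' Weights are drawn Glorot-uniform, `U(-limit, limit)` with
#' `limit = sqrt(6/(f_in + f_out))` (for the convolution, `f_in` is kernel
#' size x input channels and `f_out` the number of filters); all biases start
#' at zero. Deterministic given `seed`.
#'
#' @param config a [model_config()].
#' @param seed seed used for the draws (defaults to `config$seed`).
#' @return nested list of parameter matrices (class `model_params`):
#'   `fwd`/`bwd` LSTM weights (`W` is `(H + 1) x 4H`, gate column blocks in
#'   the order forget, input, output, candidate), `conv`, optional `base` and
#'   `fus` (multimodal), and the sigmoid regressor `reg`.
#' @export
init_params <- function(config, seed = config$seed) {
  set.seed(seed)
  H <- config$lstm_hidden
  D <- 2L * H
  Fn <- config$cnn_filters
  m <- config$cnn_kernel
  out_len <- .conv_out_len(config$input_len, m, config$cnn_stride)
  p <- list()
  p$fwd <- list(W = .glorot(H + 1L, 4L * H), b = numeric(4L * H))
  p$bwd <- list(W = .glorot(H + 1L, 4L * H), b = numeric(4L * H))
  p$conv <- list(W = .glorot(m * D, Fn, f_in = m * D, f_out = Fn),
                 b = numeric(Fn))
  z1_dim <- out_len * Fn
  if (config$mode == "multimodal") {
    widths <- c(length(variable_set_names(config$variable_set)),
                config$baseline_hidden)
    p$base <- lapply(seq_len(length(widths) - 1L), function(i)
      list(W = .glorot(widths[i], widths[i + 1L]), b = numeric(widths[i + 1L])))
    p$fus <- list(W = .glorot(z1_dim + widths[length(widths)],
                              config$fusion_hidden),
                  b = numeric(config$fusion_hidden))
    p$reg <- list(W = .glorot(config$fusion_hidden, 1L), b = 0)
  } else {
    p$reg <- list(W = .glorot(z1_dim, 1L), b = 0)
  }
  class(p) <- "model_params"
  p
}

.as_row <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1)

#' One LSTM cell step
#'
#' Standard gated update: forget/input/output gates are logistic sigmoids of
#' `[h_prev, x] %*% W + b`, the candidate state is a tanh, the new cell state
#' is `f * c_prev + i * candidate` (elementwise) and the hidden state is
#' `o * tanh(c)`.
#'
#' @param x input at this step: vector of length d, or N x d matrix for a
#'   batch.
#' @param h_prev,c_prev previous hidden/cell state (length H or N x H).
#' @param params list with `W` (`(H + d) x 4H`, gate column order f, i, o,
#'   candidate; rows ordered `[h_prev, x]`) and `b` (length 4H).
#' @return list with `h` and `c` (same shape as `h_prev`).
#' @export
lstm_step <- function(x, h_prev, c_prev, params) {
  xm <- .as_row(x); hm <- .as_row(h_prev); cm <- .as_row(c_prev)
  H <- ncol(hm)
  .assert(nrow(params$W) == H + ncol(xm) && ncol(params$W) == 4L * H,
          "lstm_step: weight shape inconsistent with states")
  st <- .lstm_cell(cbind(hm, xm), cm, params$W, params$b, H)
  if (is.matrix(h_prev)) list(h = st$h, c = st$c)
  else list(h = drop(st$h), c = drop(st$c))
}

#' Bidirectional LSTM encoding of one window
#'
#' Runs the forward stream over t0..t5 and the backward stream over t5..t0
#' and concatenates both hidden states at each step.
#'
#' @param window numeric vector of length 6 (one scaled input window).
#' @param params list with `fwd` and `bwd` LSTM parameter sets (see
#'   [init_params()]).
#' @return matrix 6 x 2H: columns 1..H forward stream, H+1..2H backward
#'   stream.
#' @export
bilstm_forward <- function(window, params) {
  .assert(is.numeric(window) && is.null(dim(window)),
          "window must be a plain numeric vector")
  X <- matrix(window, nrow = 1)
  Y <- .bilstm_batch(X, params)$Y
  t(vapply(Y, function(m) m[1, ], numeric(ncol(Y[[1]]))))
}

#' Self-attention over a hidden sequence
#'
#' Scaled-free dot-product self-attention in which the sequence acts as its
#' own query and value: row `t` of the output is the softmax-weighted (over
#' t') combination of all rows, with weights `softmax(y_t . y_t')`. Every
#' weight row sums to 1.
#'
#' @param y_seq numeric matrix (l x d), finite.
#' @return attended matrix (l x d) with the l x l weight matrix in
#'   `attr(, "weights")`.
#' @export
self_attention <- function(y_seq) {
  .assert(is.matrix(y_seq) && all(is.finite(y_seq)),
          "y_seq must be a finite numeric matrix")
  l <- nrow(y_seq)
  S <- y_seq %*% t(y_seq)
  S <- S - apply(S, 1, max)
  W <- exp(S) / rowSums(exp(S))
  out <- W %*% y_seq
  attr(out, "weights") <- W
  out
}

#' 1D convolution + ReLU over an attended sequence
#'
#' Slides a kernel of `m` steps (stride `d`) along the time axis of an l x d
#' input, producing `floor((l - m)/d) + 1` feature rows of `n_filters`
#' ReLU-activated features.
#'
#' @param attended l x d numeric matrix.
#' @param params list with `W` (`(m * d_channels) x n_filters`; kernel rows
#'   grouped by time offset, then channel) and `b`.
#' @param kernel,stride kernel length and step size.
#' @return out_len x n_filters matrix.
#' @export
conv1d_relu <- function(attended, params, kernel = 3L, stride = 1L) {
  .assert(is.matrix(attended), "attended must be a matrix")
  l <- nrow(attended)
  .assert(kernel <= l, "kernel longer than the input sequence")
  out_len <- .conv_out_len(l, kernel, stride)
  d <- ncol(attended)
  .assert(nrow(params$W) == kernel * d, "conv weight shape mismatch")
  out <- matrix(0, out_len, ncol(params$W))
  for (i in seq_len(out_len)) {
    s <- (i - 1L) * stride + 1L
    # rows of W are grouped by time offset, then channel
    slice <- as.numeric(t(attended[s:(s + kernel - 1L), , drop = FALSE]))
    out[i, ] <- pmax(0, slice %*% params$W + params$b)
  }
  out
}

#' Dense encoder of baseline variables
#'
#' Stacked dense + ReLU layers applied to the (unscaled) ordered baseline
#' vector of the configured variable set.
#'
#' @param record numeric vector (length p) or N x p matrix; all values must
#'   be present and finite.
#' @param params list of layers, each `list(W, b)` (see [init_params()]).
#' @return encoded features (vector or matrix, width = last layer).
#' @export
baseline_encoder <- function(record, params) {
  Rm <- .as_row(record)
  .assert(all(is.finite(Rm)),
          "baseline record contains absent values; filter the variable set first")
  for (ly in params) Rm <- pmax(0, sweep(Rm %*% ly$W, 2, ly$b, `+`))
  if (is.matrix(record)) Rm else drop(Rm)
}

#' Fuse CGM and baseline representations
#'
#' Feature-axis concatenation of the flattened CNN features `Z1` and the
#' baseline encoding `Z2`, followed by one dense + ReLU layer.
#'
#' @param z1,z2 numeric vectors (or N x . matrices).
#' @param params list with `W` and `b` of the fusion layer.
#' @return fused features `Z3`.
#' @export
fuse <- function(z1, z2, params) {
  C <- cbind(.as_row(z1), .as_row(z2))
  out <- pmax(0, sweep(C %*% params$W, 2, params$b, `+`))
  if (is.matrix(z1)) out else drop(out)
}

#' Full forward pass
#'
#' Pipeline: BiLSTM -> self-attention -> 1D CNN (+ dropout in training) ->
#' optional fusion with the baseline encoder -> dense regressor -> sigmoid.
#' The scaled prediction is strictly inside (0, 1). In unimodal mode the
#' record argument is ignored and the regressor reads the CNN features
#' directly.
#'
#' @param window scaled input window: numeric vector of length 6 or N x 6
#'   matrix.
#' @param record baseline vector/matrix (multimodal mode) or `NULL`.
#' @param params [init_params()] output.
#' @param config [model_config()].
#' @param training if `TRUE`, dropout is active (stochastic output).
#' @return numeric vector of scaled predictions in (0, 1).
#' @export
nn_forward <- function(window, record = NULL, params, config,
                       training = FALSE) {
  X <- if (is.matrix(window)) window else matrix(window, nrow = 1)
  .assert(ncol(X) == config$input_len, "wrong window length")
  Rm <- NULL
  if (config$mode == "multimodal") {
    .assert(!is.null(record), "multimodal mode needs a baseline record")
    Rm <- .as_row(record)
    .assert(nrow(Rm) == nrow(X), "record/window batch sizes differ")
  }
  yhat <- .forward_batch(X, Rm, params, config, training = training)$yhat
  if (is.matrix(window)) yhat else drop(yhat)
}

#' Mean squared error on scaled predictions
#'
#' @param yhat,y scaled predictions and targets (equal length).
#' @return mean of squared differences.
#' @export
loss_mse <- function(yhat, y) {
  .assert(length(yhat) == length(y) && length(y) > 0,
          "predictions and targets must be equal-length and non-empty")
  mean((yhat - y) ^ 2)
}

#' Log-likelihood objective over horizon candidate sets
#'
#' For each subject's candidate set `x` the contribution is
#' `sum_i (x_i - log(sum_j exp(x_j)))`, evaluated with a numerically stable
#' log-sum-exp. A singleton set contributes 0; a set of `n` equal values
#' contributes `-n log n`. The candidate set over which `j` ranges is
#' under-determined for scalar regression, so when this objective is selected
#' for training the set is taken as the same-subject predictions within the
#' current mini-batch.
#'
#' @param x numeric vector (one subject's candidate set) or a list of such
#'   vectors (one per subject).
#' @return scalar log-likelihood.
#' @export
loss_eq14 <- function(x) {
  if (is.list(x)) return(sum(vapply(x, loss_eq14, numeric(1))))
  .assert(is.numeric(x) && length(x) > 0, "empty candidate set")
  m <- max(x)
  lse <- m + log(sum(exp(x - m)))
  sum(x) - length(x) * lse
}
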