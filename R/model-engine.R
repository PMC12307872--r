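# Batch forward/backward engine, parameter flattening, Adam, training loop.
# Everything is plain matrix algebra over a batch of windows; the backward
# pass is the exact gradient of the forward pass (finite-difference checked
# in the test suite).

.sig <- function(z) 1 / (1 + exp(-z))

.addbias <- function(Z, b) Z + rep(b, each = nrow(Z))

.lstm_cell <- function(inp, c_prev, W, b, H) {
  z <- .addbias(inp %*% W, b)
  s <- .sig(z[, 1:(3 * H), drop = FALSE])
  f <- s[, 1:H, drop = FALSE]
  i <- s[, (H + 1):(2 * H), drop = FALSE]
  o <- s[, (2 * H + 1):(3 * H), drop = FALSE]
  g <- tanh(z[, (3 * H + 1):(4 * H), drop = FALSE])
  cc <- f * c_prev + i * g
  tc <- tanh(cc)
  list(h = o * tc, c = cc, f = f, i = i, o = o, g = g, tanh_c = tc,
       c_prev = c_prev, inp = inp)
}

# one direction over a list of time-ordered N x 1 inputs
.lstm_run <- function(xs, W, b, H, N) {
  h <- cc <- matrix(0, N, H)
  Tn <- length(xs)
  cache <- vector("list", Tn)
  hs <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    st <- .lstm_cell(cbind(h, xs[[t]]), cc, W, b, H)
    cache[[t]] <- st
    h <- st$h; cc <- st$c
    hs[[t]] <- h
  }
  list(hs = hs, cache = cache)
}

.lstm_bptt <- function(dhs, cache, W, H) {
  Tn <- length(dhs)
  dW <- matrix(0, nrow(W), ncol(W))
  db <- numeric(ncol(W))
  Wh_t <- t(W[1:H, , drop = FALSE])
  dh_carry <- dc_carry <- 0
  for (t in rev(seq_len(Tn))) {
    st <- cache[[t]]
    dh <- dhs[[t]] + dh_carry
    do_ <- dh * st$tanh_c
    dc <- dc_carry + dh * st$o * (1 - st$tanh_c ^ 2)
    df <- dc * st$c_prev
    di <- dc * st$g
    dg <- dc * st$i
    dz <- cbind(df * st$f * (1 - st$f), di * st$i * (1 - st$i),
                do_ * st$o * (1 - st$o), dg * (1 - st$g ^ 2))
    dW <- dW + crossprod(st$inp, dz)
    db <- db + colSums(dz)
    dh_carry <- dz %*% Wh_t
    dc_carry <- dc * st$f
  }
  list(dW = dW, db = db)
}

.bilstm_batch <- function(X, params) {
  N <- nrow(X)
  Tn <- ncol(X)
  H <- ncol(params$fwd$W) / 4L
  xs <- lapply(seq_len(Tn), function(t) X[, t, drop = FALSE])
  fw <- .lstm_run(xs, params$fwd$W, params$fwd$b, H, N)
  bw <- .lstm_run(rev(xs), params$bwd$W, params$bwd$b, H, N)
  Y <- lapply(seq_len(Tn), function(t)
    cbind(fw$hs[[t]], bw$hs[[Tn + 1L - t]]))
  list(Y = Y, fw = fw, bw = bw, H = H)
}

.attention_batch <- function(Y) {
  Tn <- length(Y)
  N <- nrow(Y[[1]])
  dots <- vector("list", Tn)
  for (t in seq_len(Tn)) dots[[t]] <- matrix(0, N, Tn)
  for (t in seq_len(Tn)) for (t2 in t:Tn) {
    d <- rowSums(Y[[t]] * Y[[t2]])
    dots[[t]][, t2] <- d
    dots[[t2]][, t] <- d
  }
  A <- vector("list", Tn)
  O <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    M <- dots[[t]]
    mx <- M[, 1]
    for (j in 2:Tn) mx <- pmax(mx, M[, j])
    E <- exp(M - mx)
    At <- E / rowSums(E)
    A[[t]] <- At
    out <- 0
    for (t2 in seq_len(Tn)) out <- out + At[, t2] * Y[[t2]]
    O[[t]] <- out
  }
  list(O = O, A = A)
}

.attention_backward <- function(dO, Y, A) {
  Tn <- length(Y)
  dY <- lapply(Y, function(m) m * 0)
  for (t in seq_len(Tn)) {
    At <- A[[t]]
    dA <- matrix(0, nrow(At), Tn)
    for (t2 in seq_len(Tn)) {
      # value path
      dY[[t2]] <- dY[[t2]] + At[, t2] * dO[[t]]
      dA[, t2] <- rowSums(dO[[t]] * Y[[t2]])
    }
    dS <- At * (dA - rowSums(At * dA))
    for (t2 in seq_len(Tn)) {
      # score path: s_{t,t2} = y_t . y_t2
      dY[[t]] <- dY[[t]] + dS[, t2] * Y[[t2]]
      dY[[t2]] <- dY[[t2]] + dS[, t2] * Y[[t]]
    }
  }
  dY
}

.dense_fwd <- function(A, W, b, relu = TRUE) {
  Z <- .addbias(A %*% W, b)
  if (relu) pmax(Z, 0) else Z
}

.forward_batch <- function(X, R, params, config, training = FALSE) {
  N <- nrow(X)
  m <- config$cnn_kernel
  stride <- config$cnn_stride
  bl <- .bilstm_batch(X, params)
  at <- .attention_batch(bl$Y)
  out_len <- .conv_out_len(config$input_len, m, stride)
  D <- ncol(bl$Y[[1]])
  Fn <- config$cnn_filters
  Xp <- vector("list", out_len)
  P <- vector("list", out_len)
  for (p in seq_len(out_len)) {
    s <- (p - 1L) * stride + 1L
    Xp[[p]] <- do.call(cbind, at$O[s:(s + m - 1L)])
    P[[p]] <- .dense_fwd(Xp[[p]], params$conv$W, params$conv$b)
  }
  Z1 <- do.call(cbind, P)
  dropmask <- NULL
  if (training && config$dropout_cnn > 0) {
    keep <- 1 - config$dropout_cnn
    dropmask <- matrix((runif(length(Z1)) < keep) / keep, nrow(Z1), ncol(Z1))
    Z1d <- Z1 * dropmask
  } else Z1d <- Z1
  base_in <- NULL; Cc <- NULL; Z3 <- NULL
  if (config$mode == "multimodal") {
    base_in <- vector("list", length(params$base) + 1L)
    base_in[[1]] <- R
    for (i in seq_along(params$base))
      base_in[[i + 1L]] <- .dense_fwd(base_in[[i]], params$base[[i]]$W,
                                      params$base[[i]]$b)
    Z2 <- base_in[[length(base_in)]]
    Cc <- cbind(Z1d, Z2)
    Z3 <- .dense_fwd(Cc, params$fus$W, params$fus$b)
    top <- Z3
  } else top <- Z1d
  s_pre <- drop(.dense_fwd(top, params$reg$W, params$reg$b, relu = FALSE))
  yhat <- plogis(s_pre)
  list(yhat = yhat,
       cache = list(bl = bl, at = at, Xp = Xp, P = P, Z1 = Z1, Z1d = Z1d,
                    dropmask = dropmask, base_in = base_in, Cc = Cc, Z3 = Z3,
                    top = top, s_pre = s_pre, yhat = yhat, N = N,
                    out_len = out_len, D = D, Fn = Fn))
}

# ds: dL/d s_pre (pre-sigmoid), length N
.backward_batch <- function(ds, cache, params, config) {
  N <- cache$N
  g <- list()
  dsm <- matrix(ds, ncol = 1)
  g$reg <- list(W = crossprod(cache$top, dsm), b = sum(ds))
  dtop <- dsm %*% t(params$reg$W)
  if (config$mode == "multimodal") {
    dZ3 <- dtop * (cache$Z3 > 0)
    g$fus <- list(W = crossprod(cache$Cc, dZ3), b = colSums(dZ3))
    dC <- dZ3 %*% t(params$fus$W)
    nz1 <- ncol(cache$Z1d)
    dZ1d <- dC[, seq_len(nz1), drop = FALSE]
    dZ2 <- dC[, -seq_len(nz1), drop = FALSE]
    g$base <- vector("list", length(params$base))
    dcur <- dZ2
    for (i in rev(seq_along(params$base))) {
      act <- cache$base_in[[i + 1L]]
      dact <- dcur * (act > 0)
      g$base[[i]] <- list(W = crossprod(cache$base_in[[i]], dact),
                          b = colSums(dact))
      dcur <- dact %*% t(params$base[[i]]$W)
    }
  } else {
    dZ1d <- dtop
  }
  dZ1 <- if (is.null(cache$dropmask)) dZ1d else dZ1d * cache$dropmask
  m <- config$cnn_kernel
  stride <- config$cnn_stride
  Fn <- cache$Fn
  D <- cache$D
  Tn <- config$input_len
  dO <- lapply(seq_len(Tn), function(t) matrix(0, N, D))
  dWc <- matrix(0, nrow(params$conv$W), ncol(params$conv$W))
  dbc <- numeric(Fn)
  for (p in seq_len(cache$out_len)) {
    cols <- ((p - 1L) * Fn + 1L):(p * Fn)
    dP <- dZ1[, cols, drop = FALSE] * (cache$P[[p]] > 0)
    dWc <- dWc + crossprod(cache$Xp[[p]], dP)
    dbc <- dbc + colSums(dP)
    dXp <- dP %*% t(params$conv$W)
    s <- (p - 1L) * stride + 1L
    for (k in seq_len(m)) {
      ck <- ((k - 1L) * D + 1L):(k * D)
      dO[[s + k - 1L]] <- dO[[s + k - 1L]] + dXp[, ck, drop = FALSE]
    }
  }
  g$conv <- list(W = dWc, b = dbc)
  dY <- .attention_backward(dO, cache$bl$Y, cache$at$A)
  H <- cache$bl$H
  dhf <- lapply(dY, function(m2) m2[, 1:H, drop = FALSE])
  dhb_time <- lapply(dY, function(m2) m2[, (H + 1):(2 * H), drop = FALSE])
  gf <- .lstm_bptt(dhf, cache$bl$fw$cache, params$fwd$W, H)
  gb <- .lstm_bptt(rev(dhb_time), cache$bl$bw$cache, params$bwd$W, H)
  g$fwd <- list(W = gf$dW, b = gf$db)
  g$bwd <- list(W = gb$dW, b = gb$db)
  g[names(params)]
}

# ---- parameter flattening -------------------------------------------------

.flatten_params <- function(p) unlist(p, use.names = FALSE)

.unflatten_params <- function(vec, skeleton) {
  pos <- 0L
  walk <- function(x) {
    if (is.list(x)) return(lapply(x, walk))
    n <- length(x)
    out <- vec[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (!is.null(dim(x))) dim(out) <- dim(x)
    out
  }
  out <- walk(skeleton)
  class(out) <- class(skeleton)
  out
}

# ---- loss gradients -------------------------------------------------------

# returns list(loss, dyhat)
.loss_grad <- function(yhat, y, pid, config) {
  if (config$loss == "mse") {
    list(loss = mean((yhat - y) ^ 2),
         dyhat = 2 * (yhat - y) / length(y))
  } else {
    # maximise the log-likelihood objective: minimise its negative; candidate
    # set = same-subject predictions within the batch
    if (is.null(pid)) pid <- rep("all", length(yhat))
    groups <- split(seq_along(yhat), pid)
    loss <- 0
    dyhat <- numeric(length(yhat))
    for (gi in groups) {
      x <- yhat[gi]
      n <- length(x)
      mx <- max(x)
      w <- exp(x - mx)
      sm <- w / sum(w)
      lse <- mx + log(sum(w))
      loss <- loss - (sum(x) - n * lse)
      dyhat[gi] <- n * sm - 1
    }
    list(loss = loss / length(yhat), dyhat = dyhat / length(yhat))
  }
}

# full-objective gradient for one batch (used by training and the
# finite-difference check)
.nn_gradients <- function(X, y, R, pid, params, config, training = FALSE) {
  fwd <- .forward_batch(X, R, params, config, training = training)
  lg <- .loss_grad(fwd$yhat, y, pid, config)
  ds <- lg$dyhat * fwd$yhat * (1 - fwd$yhat)
  grads <- .backward_batch(ds, fwd$cache, params, config)
  list(loss = lg$loss, grads = grads, yhat = fwd$yhat)
}

# ---- Adam -----------------------------------------------------------------

.adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

.adam_step <- function(theta, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad ^ 2
  mhat <- state$m / (1 - beta1 ^ state$t)
  vhat <- state$v / (1 - beta2 ^ state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}

# ---- training loop --------------------------------------------------------

# X: N x 6 scaled inputs; y: scaled targets; R: N x p records or NULL;
# pid: patient ids (needed for the eq14 objective). Deterministic given
# config$seed.
.train_network <- function(X, y, R = NULL, pid = NULL, config,
                           params = NULL) {
  .assert(nrow(X) > 0, "empty training set")
  set.seed(config$seed)
  if (is.null(params)) params <- init_params(config, seed = config$seed)
  theta <- .flatten_params(params)
  ad <- .adam_init(length(theta))
  N <- nrow(X)
  trace <- numeric(config$epochs)
  decay <- config$lr_decay_factor %||% 1
  stages <- config$lr_decay_stages %||% 3L
  beta2 <- config$adam_beta2 %||% 0.999
  for (ep in seq_len(config$epochs)) {
    lr_ep <- config$learning_rate *
      decay ^ floor(stages * (ep - 1) / config$epochs)
    ord <- sample.int(N)
    bs <- min(config$batch_size, N)
    nb <- ceiling(N / bs)
    ep_loss <- 0
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1L) * bs + 1L):min(b * bs, N)]
      params <- .unflatten_params(theta, params)
      gr <- .nn_gradients(X[idx, , drop = FALSE], y[idx],
                          if (is.null(R)) NULL else R[idx, , drop = FALSE],
                          if (is.null(pid)) NULL else pid[idx],
                          params, config, training = TRUE)
      if (!is.finite(gr$loss))
        stop("non-finite training loss at epoch ", ep, ", batch ", b,
             call. = FALSE)
      if (config$learning_rate > 0) {
        gvec <- .flatten_params(gr$grads)
        clip <- config$clip_norm %||% Inf
        if (is.finite(clip)) {
          gn <- sqrt(sum(gvec ^ 2))
          if (gn > clip) gvec <- gvec * (clip / gn)
        }
        st <- .adam_step(theta, gvec, ad, lr_ep, beta2 = beta2)
        theta <- st$theta
        ad <- st$state
      }
      ep_loss <- ep_loss + gr$loss * length(idx)
    }
    trace[ep] <- ep_loss / N
  }
  list(params = .unflatten_params(theta, params), trace = trace)
}
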