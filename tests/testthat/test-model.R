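# Network layers against independent brute-force oracles (helper-fixtures.R),
# initialisation, training behaviour and exactness of the analytic gradients.

test_that("Glorot initialisation respects limits, zero biases, determinism", {
  cfg <- tiny_config(seed = 8)
  p1 <- init_params(cfg)
  p2 <- init_params(cfg)
  expect_identical(p1, p2)
  expect_true(all(p1$fwd$b == 0) && all(p1$conv$b == 0) && p1$reg$b == 0)
  # single-channel kernel example: f_in = 3, f_out = 100
  cfg1 <- model_config(lstm_hidden = 1, cnn_filters = 100, seed = 2)
  # conv input channels = 2 * H = 2 here; check against its own fan
  pc <- init_params(cfg1)
  lim <- glorot_limit(3 * 2, 100)
  expect_true(all(abs(pc$conv$W) <= lim))
  expect_equal(glorot_limit(3, 100), sqrt(6 / 103))
})

test_that("lstm_step matches hand-evaluated gate recurrences", {
  # all-zero parameters: gates 0.5, candidate 0 -> h = c = 0
  p0 <- const_lstm_params(w = 0)
  st <- lstm_step(1, 0, 0, p0)
  expect_equal(st$h, 0); expect_equal(st$c, 0)
  # single unit, all weights 0.5: hand-computed oracle
  p <- const_lstm_params(w = 0.5)
  st <- lstm_step(1, 0, 0, p)
  g <- plogis(0.5); cand <- tanh(0.5)
  c_exp <- g * 0 + g * cand
  expect_equal(st$c, c_exp, tolerance = 1e-12)
  expect_equal(st$h, g * tanh(c_exp), tolerance = 1e-12)
  # saturating input: gates -> 1, h -> tanh(c)
  st_inf <- lstm_step(50, 0, 0.3, p)
  expect_equal(st_inf$h, tanh(st_inf$c), tolerance = 1e-6)
  expect_equal(st_inf$c, plogis(25) * (0.3 + tanh(25)), tolerance = 1e-9)
  # batched call agrees with per-row calls
  set.seed(2)
  W <- matrix(rnorm(3 * 8), 3, 8)
  pb <- list(W = W, b = rnorm(8))
  X <- matrix(rnorm(10), 5, 2)
  H2 <- matrix(rnorm(10), 5, 2); C2 <- matrix(rnorm(10), 5, 2)
  stb <- lstm_step(X[, 1, drop = FALSE], H2, C2, pb)
  for (i in 1:5) {
    sti <- lstm_step(X[i, 1], H2[i, ], C2[i, ], pb)
    expect_equal(unname(stb$h[i, ]), unname(sti$h), tolerance = 1e-12)
  }
  expect_error(lstm_step(1, c(0, 0), c(0, 0), p0), "shape")
})

test_that("BiLSTM runs the two streams in opposite directions", {
  cfg <- tiny_config(seed = 3)
  p <- init_params(cfg)
  w <- c(0.2, 0.5, 0.9, 0.1, 0.4, 0.7)
  H <- cfg$lstm_hidden
  out <- bilstm_forward(w, p)
  expect_identical(dim(out), c(6L, 2L * H))
  # shared parameters: reversing the window swaps the streams
  ps <- p; ps$bwd <- p$fwd
  a <- bilstm_forward(w, ps)
  b <- bilstm_forward(rev(w), ps)
  expect_equal(a[, 1:H], b[6:1, (H + 1):(2 * H)], tolerance = 1e-12)
  # zero parameters give a zero hidden sequence
  pz <- ps
  pz$fwd$W[] <- 0; pz$bwd$W[] <- 0
  expect_true(all(bilstm_forward(w, pz) == 0))
})

test_that("self-attention equals the brute-force oracle and normalises", {
  set.seed(10)
  for (r in 1:100) {
    d <- sample(2:8, 1)
    y <- matrix(rnorm(6 * d, sd = runif(1, 0.1, 2)), 6, d)
    a <- self_attention(y)
    expect_lt(max(abs(a - brute_attention(y))), 1e-6)
    expect_lt(max(abs(rowSums(attr(a, "weights")) - 1)), 1e-6)
  }
  # identical rows: uniform weights, output equals input
  y0 <- matrix(rep(c(1, 2, 3), each = 6), 6, 3)
  a0 <- self_attention(y0)
  expect_equal(unclass(a0), y0, ignore_attr = TRUE)
  expect_true(all(abs(attr(a0, "weights") - 1 / 6) < 1e-12))
  expect_error(self_attention(matrix(c(1, NA, 3, 4), 2, 2)), "finite")
})

test_that("1D convolution matches nested loops; ReLU and shapes behave", {
  set.seed(11)
  for (r in 1:100) {
    d <- sample(2:6, 1); Fn <- sample(2:7, 1)
    a <- matrix(rnorm(6 * d), 6, d)
    pw <- list(W = matrix(rnorm(3 * d * Fn), 3 * d, Fn), b = rnorm(Fn))
    got <- conv1d_relu(a, pw)
    expect_identical(dim(got), c(4L, Fn))
    expect_lt(max(abs(got - brute_conv(a, pw$W, pw$b))), 1e-6)
  }
  # centre pass-through kernel on a single channel
  a1 <- matrix(c(5, 1, 4, 2, 8, 3), 6, 1)
  id <- list(W = matrix(c(0, 1, 0), 3, 1), b = 0)
  expect_equal(drop(conv1d_relu(a1, id)), c(1, 4, 2, 8))
  # all-negative pre-activations are zeroed
  neg <- list(W = matrix(-1, 3, 1), b = 0)
  expect_true(all(conv1d_relu(abs(a1), neg) == 0))
  expect_error(conv1d_relu(matrix(1, 2, 1), id), "longer")
})

test_that("baseline encoder dimensions follow the variable sets", {
  expect_length(variable_set_names(0), 2)
  expect_length(variable_set_names(2), 5)
  cfg <- tiny_config(mode = "multimodal", variable_set = 2, seed = 5)
  p <- init_params(cfg)
  expect_identical(nrow(p$base[[1]]$W), 5L)
  z <- baseline_encoder(c(67, 1, 7.4, 80, 1.6), p$base)
  expect_length(z, cfg$baseline_hidden[length(cfg$baseline_hidden)])
  # zero weights: output is ReLU of the biases
  pz <- p$base
  pz[[1]]$W[] <- 0; pz[[1]]$b <- rep(-1, length(pz[[1]]$b))
  expect_true(all(baseline_encoder(c(1, 2, 3, 4, 5), pz[1]) == 0))
  expect_error(baseline_encoder(c(67, NA), p$base), "absent")
})

test_that("fusion concatenates along the feature axis", {
  set.seed(6)
  pf <- list(W = matrix(rnorm(10 * 4), 10, 4), b = rnorm(4))
  z1 <- rnorm(7); z2 <- rnorm(3)
  expect_equal(fuse(z1, z2, pf),
               pmax(0, drop(c(z1, z2) %*% pf$W) + pf$b))
  # zeroed baseline features leave only the CGM contribution
  f0 <- fuse(z1, numeric(3), pf)
  pf2 <- pf; pf2$W[8:10, ] <- 100
  expect_equal(fuse(z1, numeric(3), pf2), f0)
})

test_that("forward pass is bounded, deterministic in eval mode, unimodal ignores records", {
  cfg <- tiny_config(seed = 12)
  p <- init_params(cfg)
  w <- runif(6)
  y1 <- nn_forward(w, NULL, p, cfg)
  expect_true(y1 > 0 && y1 < 1)
  expect_identical(y1, nn_forward(w, NULL, p, cfg))
  expect_identical(y1, nn_forward(w, c(1, 2), p, cfg))
  cfgm <- tiny_config(mode = "multimodal", variable_set = 0, seed = 12)
  pm <- init_params(cfgm)
  expect_error(nn_forward(w, NULL, pm, cfgm), "record")
  ym <- nn_forward(w, c(67, 1), pm, cfgm)
  expect_true(ym > 0 && ym < 1)
})

test_that("the log-likelihood objective matches its closed forms and a naive evaluation", {
  expect_equal(loss_eq14(0.37), 0)
  expect_equal(loss_eq14(c(1.2, 1.2)), -2 * log(2))
  set.seed(13)
  for (r in 1:20) {
    x <- rnorm(sample(2:10, 1), sd = 2)
    naive <- sum(x - log(sum(exp(x))))
    expect_equal(loss_eq14(x), naive, tolerance = 1e-6)
  }
  expect_equal(loss_eq14(list(c(1, 1), 2)), -2 * log(2))
  expect_error(loss_eq14(numeric(0)), "empty")
  # stability at magnitudes where the naive form overflows
  expect_equal(loss_eq14(c(800, 800)), -2 * log(2))
})

test_that("training descends, reproduces bit-identically, and freezes at lr 0", {
  set.seed(14)
  co <- tiny_cohort(n_patients = 2, n_sensor1 = 0, days = 2, seed = 33)
  ds <- thin_windows(prepare_windows(co$series, 15), 3)
  cfg0 <- tiny_config(learning_rate = 0, epochs = 2, seed = 20)
  f0 <- glucast(ds, control = cfg0)
  expect_identical(glucast:::.flatten_params(f0$params),
                   glucast:::.flatten_params(init_params(cfg0, seed = 20L)))
  cfg <- tiny_config(epochs = 4, learning_rate = 5e-3, seed = 21)
  f1 <- glucast(ds, control = cfg)
  f2 <- glucast(ds, control = cfg)
  expect_identical(f1$params, f2$params)
  # loss decreases over training in at least 4 of 5 seeds
  drops <- sapply(1:5, function(s) {
    f <- glucast(ds, control = tiny_config(epochs = 4, learning_rate = 5e-3,
                                           seed = s))
    tail(f$loss_trace, 1) < f$loss_trace[1]
  })
  expect_gte(sum(drops), 4)
})

test_that("analytic gradients match central finite differences", {
  for (mode in c("unimodal", "multimodal")) {
    cfg <- model_config(lstm_hidden = 3, cnn_filters = 4,
                        baseline_hidden = c(3), fusion_hidden = 4,
                        dropout_cnn = 0, mode = mode, variable_set = 1,
                        seed = 3)
    p <- init_params(cfg)
    set.seed(9)
    X <- matrix(runif(5 * 6), 5, 6)
    yt <- runif(5)
    R <- if (mode == "multimodal")
      cbind(runif(5, 60, 80), rbinom(5, 1, 0.5), runif(5, 6, 9)) else NULL
    gr <- glucast:::.nn_gradients(X, yt, R, NULL, p, cfg)
    theta <- glucast:::.flatten_params(p)
    gvec <- glucast:::.flatten_params(gr$grads)
    eps <- 1e-5
    fobj <- function(v) {
      pp <- glucast:::.unflatten_params(v, p)
      yh <- glucast:::.forward_batch(X, R, pp, cfg)$yhat
      mean((yh - yt)^2)
    }
    num <- vapply(seq_along(theta), function(i) {
      up <- theta; up[i] <- up[i] + eps
      dn <- theta; dn[i] <- dn[i] - eps
      (fobj(up) - fobj(dn)) / (2 * eps)
    }, numeric(1))
    rel <- max(abs(num - gvec) / pmax(1e-6, abs(num) + abs(gvec)))
    expect_lt(rel, 1e-4)
  }
})
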