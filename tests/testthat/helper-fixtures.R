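# Shared fixtures, built in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# small deterministic cohort for pipeline tests
tiny_cohort <- function(n_patients = 3, n_sensor1 = 1, days = 3, seed = 5,
                        missing_fraction = 0.05, effect_scale = 1) {
  simulate_cohort(cohort_config(n_patients = n_patients,
                                n_sensor1 = n_sensor1,
                                duration_days = c(days, days),
                                missing_fraction = missing_fraction,
                                baseline_effect_scale = effect_scale,
                                seed = seed))
}

# a fully observed 5-min series with given values starting at midnight UTC
series_5min <- function(values, patient_id = "PX", start_day = "2023-03-01") {
  cgm_series(patient_id,
             as.POSIXct(paste(start_day, "00:00:00"), tz = "UTC") +
               (seq_along(values) - 1) * 300,
             values, native_interval = 5)
}

# a quiet single-unit LSTM parameter set with all weights equal
const_lstm_params <- function(H = 1, d = 1, w = 0.5, b = 0) {
  list(W = matrix(w, H + d, 4 * H), b = rep(b, 4 * H))
}

# small model config for fast training tests
tiny_config <- function(epochs = 3, learning_rate = 5e-3, ...) {
  model_config(lstm_hidden = 4, cnn_filters = 8, baseline_hidden = c(4),
               fusion_hidden = 8, epochs = epochs, batch_size = 64,
               learning_rate = learning_rate, ...)
}

# independent ray-casting point-in-polygon oracle (even-odd rule)
point_in_polygon <- function(px, py, poly_x, poly_y) {
  n <- length(poly_x)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((poly_y[i] > py) != (poly_y[j] > py)) {
      xint <- poly_x[i] + (py - poly_y[i]) / (poly_y[j] - poly_y[i]) *
        (poly_x[j] - poly_x[i])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# closed polygons of the worse-than-or-equal regions of the type 2 grid:
# everything strictly above the upper boundary of zone Z (or below the lower
# one), closed through the plot corners. Used by the geometric oracle.
parkes_region_polygons <- function() {
  v <- parkes_vertices()
  seg <- function(zone, side) v[v$zone == zone & v$side == side, c("x", "y")]
  up <- function(zone) {
    p <- seg(zone, "upper")
    list(x = c(p$x, p$x[nrow(p)], 0),
         y = c(p$y, 550, 550))
  }
  lo <- function(zone) {
    p <- seg(zone, "lower")
    list(x = c(p$x, 550, p$x[1]),
         y = c(p$y, 0, 0))
  }
  list(upB = up("B"), upC = up("C"), upD = up("D"), upE = up("E"),
       loB = lo("B"), loC = lo("C"), loD = lo("D"))
}

# oracle zone of a single point via polygon membership of the worse-regions
parkes_zone_oracle <- function(x, y, polys = parkes_region_polygons()) {
  inreg <- function(p) point_in_polygon(x, y, p$x, p$y)
  if (y > x) {                       # above diagonal: check upper regions
    if (inreg(polys$upE)) return("E")
    if (inreg(polys$upD)) return("D")
    if (inreg(polys$upC)) return("C")
    if (inreg(polys$upB)) return("B")
    return("A")
  }
  if (inreg(polys$loD)) return("D")
  if (inreg(polys$loC)) return("C")
  if (inreg(polys$loB)) return("B")
  "A"
}

# independent brute-force implementations of the sequence layers
brute_attention <- function(y) {
  l <- nrow(y)
  out <- matrix(0, l, ncol(y))
  for (t in seq_len(l)) {
    sc <- sapply(seq_len(l), function(t2) sum(y[t, ] * y[t2, ]))
    w <- exp(sc - max(sc)); w <- w / sum(w)
    for (t2 in seq_len(l)) out[t, ] <- out[t, ] + w[t2] * y[t2, ]
  }
  out
}

brute_conv <- function(a, W, b, kernel = 3, stride = 1) {
  l <- nrow(a); d <- ncol(a)
  out_len <- floor((l - kernel) / stride) + 1
  Fn <- ncol(W)
  out <- matrix(0, out_len, Fn)
  for (i in seq_len(out_len)) for (f in seq_len(Fn)) {
    acc <- b[f]
    for (k in seq_len(kernel)) for (ch in seq_len(d)) {
      row <- (k - 1) * d + ch
      acc <- acc + a[(i - 1) * stride + k, ch] * W[row, f]
    }
    out[i, f] <- max(0, acc)
  }
  out
}

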