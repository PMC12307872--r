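# Clinical evaluation: Parkes (consensus) error grid for type 2 diabetes and
# ambulatory glucose profile (AGP) summary statistics.

.parkes_env <- new.env(parent = emptyenv())

#' Parkes type-2 consensus grid vertices
#'
#' Returns the boundary polylines of the type 2 consensus error grid over the
#' (reference, predicted) plane in mg/dL, axes `[0, 550]`. The grid itself
#' comes from the consensus survey of Parkes et al. (Diabetes Care, 2000); the
#' vertex coordinates shipped in `inst/extdata/parkes_vertices_t2.csv` are the
#' widely used digitisation published by Pfutzner et al. (J Diabetes Sci
#' Technol, 2013). The file is versioned data: swap it to use another
#' digitisation.
#'
#' @param path optional alternative vertex CSV (columns zone, side, x, y).
#' @return data.frame of boundary vertices.
#' @export
parkes_vertices <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.parkes_env$vertices)) return(.parkes_env$vertices)
    path <- system.file("extdata", "parkes_vertices_t2.csv",
                        package = "glucast")
    .assert(nzchar(path), "shipped vertex file not found")
    v <- read.csv(path, stringsAsFactors = FALSE)
    .parkes_env$vertices <- v
    return(v)
  }
  read.csv(path, stringsAsFactors = FALSE)
}

# boundary polyline as a function of reference x; beyond the polyline's last
# x the adjoining worse region no longer exists (+Inf for upper boundaries,
# -Inf for lower); duplicated x (vertical segments) collapse to the extreme y
.boundary_fun <- function(verts, zone, side) {
  p <- verts[verts$zone == zone & verts$side == side, ]
  fill <- if (side == "upper") Inf else -Inf
  agg <- if (side == "upper") max else max   # top of a vertical segment
  keep_y <- tapply(p$y, p$x, agg)
  xs <- as.numeric(names(keep_y))
  ys <- as.numeric(keep_y)
  o <- order(xs)
  xs <- xs[o]; ys <- ys[o]
  function(x) {
    y <- approx(xs, ys, xout = x, rule = 1)$y
    y[x > xs[length(xs)]] <- fill
    y[x < xs[1]] <- fill
    y
  }
}

.parkes_boundaries <- function() {
  if (!is.null(.parkes_env$bounds)) return(.parkes_env$bounds)
  v <- parkes_vertices()
  b <- list(upB = .boundary_fun(v, "B", "upper"),
            upC = .boundary_fun(v, "C", "upper"),
            upD = .boundary_fun(v, "D", "upper"),
            upE = .boundary_fun(v, "E", "upper"),
            loB = .boundary_fun(v, "B", "lower"),
            loC = .boundary_fun(v, "C", "lower"),
            loD = .boundary_fun(v, "D", "lower"))
  .parkes_env$bounds <- b
  b
}

#' Parkes error-grid zone of prediction pairs
#'
#' Classifies (reference, predicted) glucose pairs into the five consensus
#' zones A-E of the type 2 grid: A = clinically accurate (the identity
#' diagonal always lies in A), through E = clinically dangerous confusion.
#' Classification is against the embedded published vertex coordinates
#' ([parkes_vertices()]); points exactly on a boundary are assigned to the
#' better (more accurate) zone. Values outside `[0, 550]` mg/dL are clamped
#' with a warning.
#'
#' @param reference,predicted mg/dL vectors (recycled to common length).
#' @return factor with levels A, B, C, D, E.
#' @export
#' @examples
#' parkes_zone(100, 100)  # A
#' parkes_zone(c(100, 100), c(140, 350))
parkes_zone <- function(reference, predicted) {
  n <- max(length(reference), length(predicted))
  x <- rep_len(as.numeric(reference), n)
  y <- rep_len(as.numeric(predicted), n)
  if (any(x < 0 | x > 550 | y < 0 | y > 550, na.rm = TRUE)) {
    warning("values outside [0, 550] mg/dL clamped for zone classification")
    x <- pmin(550, pmax(0, x))
    y <- pmin(550, pmax(0, y))
  }
  b <- .parkes_boundaries()
  # lower boundaries: a -Inf fill means the region below does not exist there
  loB <- b$loB(x); loC <- b$loC(x); loD <- b$loD(x)
  upB <- b$upB(x); upC <- b$upC(x); upD <- b$upD(x); upE <- b$upE(x)
  z <- rep("A", n)
  z[y > upB] <- "B"; z[y > upC] <- "C"; z[y > upD] <- "D"; z[y > upE] <- "E"
  z[y < loB] <- "B"; z[y < loC] <- "C"; z[y < loD] <- "D"
  factor(z, levels = c("A", "B", "C", "D", "E"))
}

#' Zone distribution of prediction pairs
#'
#' @param reference,predicted mg/dL vectors (non-empty).
#' @return named numeric vector of percentages over zones A-E (sums to 100).
#' @export
zone_distribution <- function(reference, predicted) {
  .assert(length(reference) > 0, "empty pair list")
  z <- parkes_zone(reference, predicted)
  100 * table(z) / length(z)
}

#' Plot predictions on the Parkes type-2 grid
#'
#' @param reference,predicted mg/dL vectors.
#' @param ... passed to [points()].
#' @return invisibly, the zone factor.
#' @export
plot_parkes <- function(reference, predicted, ...) {
  v <- parkes_vertices()
  plot(NA, xlim = c(0, 550), ylim = c(0, 550),
       xlab = "reference glucose (mg/dL)", ylab = "predicted glucose (mg/dL)",
       main = "Parkes consensus error grid (type 2)")
  for (key in split(v, paste(v$zone, v$side)))
    lines(key$x, key$y, col = "grey40")
  abline(0, 1, col = "grey70", lty = 2)
  z <- parkes_zone(reference, predicted)
  cols <- c(A = "#2c7fb8", B = "#41ab5d", C = "#fe9929", D = "#e31a1c",
            E = "#6a0dad")
  points(reference, predicted, col = adjustcolor(cols[as.character(z)], 0.6),
         pch = 16, cex = 0.6, ...)
  legend("topleft", legend = sprintf("%s: %.1f%%", names(table(z)),
                                     100 * table(z) / length(z)),
         pch = 16, col = cols, bty = "n")
  invisible(z)
}

# observed (non-imputed) glucose values of a series or plain vector
.observed_values <- function(x) {
  if (inherits(x, "cgm_series")) {
    v <- x$glucose
    imp <- attr(x, "imputed")
    if (!is.null(imp)) v <- v[!imp]
    v[!is.na(v)]
  } else as.numeric(x[!is.na(x)])
}

#' Time in clinical glucose ranges
#'
#' Percent of observed (non-imputed) samples in the standard AGP ranges, with
#' the cumulative convention: "low" counts every value below 70 mg/dL
#' (including the very-low values below 54) and "high" every value above
#' 180 mg/dL (including above 250). Hence `target + low + high = 100`.
#'
#' @param x a [cgm_series()] or numeric vector of mg/dL values.
#' @return named numeric vector: `very_low` (<54), `low` (<70), `target`
#'   (70-180), `high` (>180), `very_high` (>250), in percent.
#' @export
#' @examples
#' time_in_ranges(c(50, 60, rep(100, 6), 200, 300))
time_in_ranges <- function(x) {
  v <- .observed_values(x)
  .assert(length(v) > 0, "empty series")
  c(very_low = 100 * mean(v < 54),
    low = 100 * mean(v < 70),
    target = 100 * mean(v >= 70 & v <= 180),
    high = 100 * mean(v > 180),
    very_high = 100 * mean(v > 250))
}

#' Mean glucose of a series
#' @param x a [cgm_series()] or numeric vector (mg/dL).
#' @return mean of observed values, mg/dL.
#' @export
mean_glucose <- function(x) {
  v <- .observed_values(x)
  .assert(length(v) > 0, "empty series")
  mean(v)
}

#' Glucose management indicator
#'
#' HbA1c-scale summary of mean CGM glucose via the standard ADAG-derived
#' relation `GMI(%) = 3.31 + 0.02392 * mean_glucose`.
#'
#' @param mean_glucose mean glucose in mg/dL (> 0).
#' @return GMI in percent.
#' @export
#' @examples
#' round(gmi(146.1), 1)  # 6.8
gmi <- function(mean_glucose) {
  .assert(all(mean_glucose > 0), "mean glucose must be positive")
  3.31 + 0.02392 * mean_glucose
}

#' Glucose variability (%CV)
#'
#' `100 * sd / mean` over observed samples (sample standard deviation). A
#' constant series has CV 0.
#'
#' @param x a [cgm_series()] or numeric vector (mg/dL); needs >= 2 observed
#'   samples.
#' @return percent coefficient of variation.
#' @export
glucose_cv <- function(x) {
  v <- .observed_values(x)
  .assert(length(v) >= 2, "need at least 2 observed samples")
  100 * sd(v) / mean(v)
}

#' Ambulatory glucose profile report
#'
#' Bundles the AGP summary statistics of one series: time in ranges, mean
#' glucose, GMI and %CV.
#'
#' @param x a [cgm_series()] or numeric vector (mg/dL).
#' @return list of class `agp_report`.
#' @export
agp_report <- function(x) {
  tir <- time_in_ranges(x)
  mg <- mean_glucose(x)
  structure(list(time_in_ranges = tir, mean_glucose = mg, gmi = gmi(mg),
                 cv = glucose_cv(x)), class = "agp_report")
}

#' @export
print.agp_report <- function(x, ...) {
  t <- x$time_in_ranges
  cat("AGP summary\n")
  cat(sprintf("  mean glucose: %.1f mg/dL   GMI: %.1f%%   CV: %.1f%%\n",
              x$mean_glucose, x$gmi, x$cv))
  cat(sprintf("  time in ranges: very low (<54) %.2f%% | low (<70) %.2f%% | target (70-180) %.2f%% | high (>180) %.2f%% | very high (>250) %.2f%%\n",
              t["very_low"], t["low"], t["target"], t["high"], t["very_high"]))
  invisible(x)
}
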