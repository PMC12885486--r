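#' Binned probability density of TI values
#'
#' Bins TI values into `nbins` equal-width bins spanning `[0, max]` and
#' normalises counts to probabilities. Zero-valued windows (rest periods) are
#' data and are binned like any other value. A shared `ti_max` lets two hands
#' be binned on one comparable grid.
#'
#' @param values non-negative finite TI values (valid windows only).
#' @param nbins number of bins (default 20).
#' @param ti_max upper edge of the grid; defaults to `max(values)`. Values
#'   above `ti_max` land in the top bin.
#' @return a `binned_pdf`: `edges` (length `nbins + 1`), `centers`,
#'   `probabilities` (sum to 1), `counts`, `n`.
#' @export
ti_histogram <- function(values, nbins = 20, ti_max = NULL) {
  if (length(values) == 0L) stop("no TI values to bin", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("TI values must be finite and non-negative", call. = FALSE)
  }
  if (is.null(ti_max)) ti_max <- max(values)
  if (ti_max <= 0) ti_max <- 1  # all-zero input: single occupied bottom bin
  edges <- seq(0, ti_max, length.out = nbins + 1L)
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > nbins] <- nbins
  counts <- tabulate(idx, nbins)
  structure(list(edges = edges, centers = (edges[-1L] + edges[-(nbins + 1L)]) / 2,
                 probabilities = counts / length(values), counts = counts,
                 n = length(values), nbins = nbins),
            class = "binned_pdf")
}

#' @export
print.binned_pdf <- function(x, ...) {
  cat(sprintf("<binned_pdf> %d bins over [0, %.4g], n=%d, %d occupied\n",
              x$nbins, x$edges[x$nbins + 1L], x$n, sum(x$probabilities > 0)))
  invisible(x)
}

#' Log-log linearisation of a binned PDF
#'
#' Ordinary least squares of `log10(probability)` on `log10(bin centre)`,
#' dropping empty bins and the zero-centre bin. Long-tailed TI distributions
#' linearise well in this scale; the slope and intercept summarise them.
#'
#' @param pdf a `binned_pdf`.
#' @return a `loglog_fit`: `slope`, `intercept` (log10 probability at TI = 1),
#'   `r_squared`, `n_bins`.
#' @export
loglog_regression <- function(pdf) {
  stopifnot(inherits(pdf, "binned_pdf"))
  use <- pdf$probabilities > 0 & pdf$centers > 0
  if (sum(use) < 2L) {
    stop("degenerate fit: fewer than 2 usable (occupied, positive-centre) bins",
         call. = FALSE)
  }
  lx <- log10(pdf$centers[use])
  ly <- log10(pdf$probabilities[use])
  fit <- stats::lm(ly ~ lx)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = summary(fit)$r.squared,
                 n_bins = sum(use)),
            class = "loglog_fit")
}

#' Kurtosis and skewness of a TI distribution
#'
#' Standardized third and fourth central moments, bias-uncorrected, with the
#' Pearson kurtosis convention (a normal distribution gives 3, not 0).
#'
#' @param values numeric vector, at least 4 values with nonzero variance.
#' @return a `shape_moments` list: `kurtosis`, `skewness`, `n`.
#' @export
shape_moments <- function(values) {
  n <- length(values)
  if (n < 4L) stop("need at least 4 values for shape moments", call. = FALSE)
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 <= 0) stop("undefined moments: zero variance", call. = FALSE)
  structure(list(kurtosis = mean((values - m)^4) / m2^2,
                 skewness = mean((values - m)^3) / m2^1.5,
                 n = n),
            class = "shape_moments")
}

#' Per-hand, per-frequency distribution summary table
#'
#' Pools valid TI windows across all kept days of each hand and tabulates
#' the log-log fit and shape moments per hand and frequency -- the summary
#' used to compare the most and least tremor-affected hands.
#'
#' @param profiles named list of TI profiles (as from [ti_profile()]), one
#'   element per hand, e.g. `list(T = ..., nT = ...)`.
#' @param nbins histogram bins for the log-log fit (default 20).
#' @return data.frame with columns `hand`, `f_hz`, `n_windows`, `slope`,
#'   `intercept`, `r_squared`, `kurtosis`, `skewness` (NA where degenerate).
#' @export
distribution_summary <- function(profiles, nbins = 20) {
  rows <- list()
  for (hand in names(profiles)) {
    for (nm in names(profiles[[hand]])) {
      tis <- profiles[[hand]][[nm]]
      v <- valid_ti(tis)
      fit <- tryCatch(loglog_regression(ti_histogram(v, nbins)),
                      error = function(e) NULL)
      mom <- tryCatch(shape_moments(v), error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        hand = hand, f_hz = attr(tis, "f"), n_windows = length(v),
        slope = if (is.null(fit)) NA_real_ else fit$slope,
        intercept = if (is.null(fit)) NA_real_ else fit$intercept,
        r_squared = if (is.null(fit)) NA_real_ else fit$r_squared,
        kurtosis = if (is.null(mom)) NA_real_ else mom$kurtosis,
        skewness = if (is.null(mom)) NA_real_ else mom$skewness)
    }
  }
  do.call(rbind, rows)
}
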