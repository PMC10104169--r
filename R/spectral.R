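# Multitaper spectral estimation and band-power quantification.

#' Canonical band scheme
#'
#' Default frequency bands for band-specific analyses: delta (2-5 Hz), slow
#' theta (4-8), theta (8-12), low gamma (30-48), high gamma (52-100), HFO
#' (100-200). The slow-theta/theta pair overlaps at 8 Hz by construction; a
#' combined 4-12 Hz "theta frequencies" range is available as
#' `theta_wide`.
#'
#' @param ... named length-2 numeric vectors overriding or adding bands.
#' @return named list of `c(low_hz, high_hz)` pairs, class `band_scheme`.
#' @export
band_scheme <- function(...) {
  bands <- list(delta = c(2, 5), slow_theta = c(4, 8), theta = c(8, 12),
                low_gamma = c(30, 48), high_gamma = c(52, 100),
                hfo = c(100, 200), theta_wide = c(4, 12))
  dots <- list(...)
  for (nm in names(dots)) bands[[nm]] <- dots[[nm]]
  for (b in bands) stopifnot(length(b) == 2L, b[1] < b[2])
  structure(bands, class = "band_scheme")
}

# DPSS (Slepian) tapers: top-k eigenvectors of the standard symmetric
# tridiagonal matrix that commutes with the concentration operator, found by
# Sturm-sequence bisection plus inverse iteration (the classic LAPACK-style
# route; no installed R package exposes DPSS or a tridiagonal eigensolver).
# Cached per (n, nw, k).
.dpss_cache <- new.env(parent = emptyenv())

# number of eigenvalues of the symmetric tridiagonal (d, e) below x
sturm_count <- function(d, e, x) {
  n <- length(d)
  cnt <- 0L
  q <- d[1] - x
  if (q < 0) cnt <- 1L
  for (i in 2:n) {
    if (q == 0) q <- 1e-300
    q <- (d[i] - x) - e[i - 1]^2 / q
    if (q < 0) cnt <- cnt + 1L
  }
  cnt
}

# k largest eigenvalues by bisection on the Sturm count
tridiag_top_eigenvalues <- function(d, e, k, tol = 1e-11) {
  n <- length(d)
  rad <- c(abs(e[1]), abs(e[-(n - 1)]) + abs(e[-1]), abs(e[n - 1]))
  lo0 <- min(d - rad); hi0 <- max(d + rad)
  scale <- max(abs(lo0), abs(hi0))
  vapply(seq_len(k), function(j) {
    lo <- lo0; hi <- hi0
    while (hi - lo > tol * scale) {
      mid <- (lo + hi) / 2
      if (sturm_count(d, e, mid) <= n - j) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}

# solve (T - s I) x = b for tridiagonal T, Gaussian elimination with
# partial pivoting (one extra superdiagonal of fill-in)
tridiag_solve <- function(d, e, s, b) {
  n <- length(d)
  a <- d - s; l <- e; u <- e
  w <- numeric(n)
  x <- b
  for (i in 1:(n - 1)) {
    if (abs(l[i]) > abs(a[i])) {           # pivot rows i, i+1
      t1 <- a[i]; a[i] <- l[i]; l[i] <- t1
      t1 <- u[i]; u[i] <- a[i + 1]; a[i + 1] <- t1
      if (i < n - 1) { w[i] <- u[i + 1]; u[i + 1] <- 0 } else w[i] <- 0
      t1 <- x[i]; x[i] <- x[i + 1]; x[i + 1] <- t1
    } else w[i] <- 0
    if (a[i] == 0) a[i] <- 1e-300
    m <- l[i] / a[i]
    a[i + 1] <- a[i + 1] - m * u[i]
    if (i < n - 1) u[i + 1] <- u[i + 1] - m * w[i]
    x[i + 1] <- x[i + 1] - m * x[i]
  }
  if (a[n] == 0) a[n] <- 1e-300
  x[n] <- x[n] / a[n]
  x[n - 1] <- (x[n - 1] - u[n - 1] * x[n]) / a[n - 1]
  for (i in (n - 2):1) {
    x[i] <- (x[i] - u[i] * x[i + 1] - w[i] * x[i + 2]) / a[i]
  }
  x
}

#' Discrete prolate spheroidal sequence tapers
#'
#' @param n taper length, samples.
#' @param nw time-bandwidth product (default 3).
#' @param k number of tapers (default `2 * nw - 1`).
#' @return n x k matrix; columns are unit-energy tapers ordered by
#'   concentration.
#' @export
dpss_tapers <- function(n, nw = 3, k = 2 * nw - 1) {
  key <- sprintf("n%d_nw%g_k%d", n, nw, k)
  if (!is.null(.dpss_cache[[key]])) return(.dpss_cache[[key]])
  if (n > 8192) {
    # long windows: solve at a base length and interpolate (the standard
    # low-memory construction), then re-orthonormalize
    base <- dpss_tapers(8192, nw, k)
    v <- apply(base, 2, function(col) {
      stats::spline(seq(0, 1, length.out = 8192), col, n = n)$y
    })
    v <- qr.Q(qr(v))
    for (j in seq_len(k)) {
      if (j %% 2 == 1 && sum(v[, j]) < 0) v[, j] <- -v[, j]
    }
    .dpss_cache[[key]] <- v
    return(v)
  }
  w <- nw / n
  i <- 0:(n - 1)
  d <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  e <- as.numeric(1:(n - 1)) * as.numeric((n - 1):1) / 2
  vals <- tridiag_top_eigenvalues(d, e, k)
  v <- matrix(0, n, k)
  for (j in seq_len(k)) {
    vec <- sin((1:n) * j * 0.7)            # deterministic start vector
    for (it in 1:4) {
      if (j > 1) {
        prev <- v[, 1:(j - 1), drop = FALSE]
        vec <- vec - prev %*% crossprod(prev, vec)
      }
      vec <- tridiag_solve(d, e, vals[j], vec)
      vec <- vec / sqrt(sum(vec^2))
    }
    if (j > 1) {
      prev <- v[, 1:(j - 1), drop = FALSE]
      vec <- vec - prev %*% crossprod(prev, vec)
      vec <- vec / sqrt(sum(vec^2))
    }
    if (j %% 2 == 1 && sum(vec) < 0) vec <- -vec
    v[, j] <- vec
  }
  .dpss_cache[[key]] <- v
  v
}

#' Multitaper power spectral density over epochs
#'
#' DPSS-tapered PSD per epoch, averaged over tapers and epochs. Epochs
#' shorter than the analysis window are skipped with a warning; all retained
#' epochs are truncated to a common window length so they share one frequency
#' grid.
#'
#' @param lfp an `lfp_signal` (or `recording`).
#' @param epochs an `epoch_set`; `NULL` uses the whole signal as one epoch.
#' @param channel channel index.
#' @param nw time-bandwidth product.
#' @param k number of tapers.
#' @return object of class `power_spectrum`: list with `freqs` (Hz), `psd`
#'   (microvolt^2/Hz, one-sided), and method metadata. The half-bandwidth
#'   resolution `nw / T` Hz is recorded in `meta`.
#' @export
multitaper_psd <- function(lfp, epochs = NULL, channel = 1L, nw = 3, k = 5) {
  fs <- lfp$fs
  x <- lfp$signals[channel, ]
  if (is.null(epochs)) {
    segs <- list(x)
  } else {
    segs <- epoch_segments(x, fs, epochs)
  }
  lens <- vapply(segs, length, integer(1))
  n_win <- min(lens[lens >= fs])           # require >= 1 s of samples
  if (any(lens < n_win)) {
    warning(sprintf("%d epoch(s) shorter than the analysis window skipped",
                    sum(lens < n_win)))
    segs <- segs[lens >= n_win]
  }
  tapers <- dpss_tapers(n_win, nw, k)
  n_freq <- floor(n_win / 2) + 1L
  freqs <- (0:(n_freq - 1)) * fs / n_win
  acc <- numeric(n_freq)
  for (s in segs) {
    s <- s[seq_len(n_win)] - mean(s[seq_len(n_win)])
    ft <- stats::mvfft(tapers * s)
    p <- rowMeans(Mod(ft[seq_len(n_freq), , drop = FALSE])^2)
    acc <- acc + p
  }
  psd <- acc / length(segs) / fs
  scale <- rep(2, n_freq); scale[1] <- 1
  if (n_win %% 2 == 0) scale[n_freq] <- 1
  psd <- psd * scale
  structure(list(freqs = freqs, psd = psd,
                 meta = list(nw = nw, k = k, window_s = n_win / fs,
                             half_bandwidth_hz = nw / (n_win / fs),
                             n_epochs = length(segs), channel = channel)),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf(
    "<power_spectrum> %d frequencies to %.1f Hz, %d epoch(s), NW=%g, %d tapers\n",
    length(x$freqs), max(x$freqs), x$meta$n_epochs, x$meta$nw, x$meta$k))
  invisible(x)
}

#' @export
plot.power_spectrum <- function(x, xlim = c(0, 200), log = "y", ...) {
  sel <- x$freqs >= xlim[1] & x$freqs <= xlim[2] & x$psd > 0
  graphics::plot(x$freqs[sel], x$psd[sel], type = "l", log = log,
                 xlab = "Frequency (Hz)",
                 ylab = expression(PSD ~ (mu * V^2 / Hz)), ...)
  invisible(x)
}

#' Spectrogram by consecutive Fourier transforms
#'
#' Magnitude-squared short-time Fourier transform with a Hanning window.
#'
#' @param lfp an `lfp_signal` (or `recording`).
#' @param window_s window length, seconds.
#' @param step_s hop between consecutive windows, seconds (default:
#'   `window_s`, i.e. non-overlapping consecutive transforms).
#' @param channel channel index.
#' @return object of class `spectrogram`: list with `time_s` (window
#'   centers), `freqs` (Hz) and `power` (freq x time, microvolt^2/Hz).
#' @export
spectrogram <- function(lfp, window_s = 1, step_s = window_s, channel = 1L) {
  fs <- lfp$fs
  x <- lfp$signals[channel, ]
  n_win <- round(window_s * fs)
  hop <- max(1L, round(step_s * fs))
  starts <- seq(1L, length(x) - n_win + 1L, by = hop)
  h <- 0.5 - 0.5 * cos(2 * pi * (0:(n_win - 1)) / (n_win - 1))
  u <- sum(h^2)
  n_freq <- floor(n_win / 2) + 1L
  segmat <- vapply(starts,
                   function(s) h * (x[s:(s + n_win - 1L)] -
                                      mean(x[s:(s + n_win - 1L)])),
                   numeric(n_win))
  ft <- stats::mvfft(segmat)
  pow <- Mod(ft[seq_len(n_freq), , drop = FALSE])^2 / (u * fs)
  pow[-1, ] <- 2 * pow[-1, ]
  structure(list(time_s = (starts - 1L + n_win / 2) / fs,
                 freqs = (0:(n_freq - 1)) * fs / n_win,
                 power = pow,
                 meta = list(window_s = window_s, step_s = step_s)),
            class = "spectrogram")
}

#' @export
plot.spectrogram <- function(x, ylim = c(0, 120), ...) {
  sel <- x$freqs >= ylim[1] & x$freqs <= ylim[2]
  graphics::image(x$time_s, x$freqs[sel], t(log10(x$power[sel, ] + 1e-12)),
                  xlab = "Time (s)", ylab = "Frequency (Hz)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Band power from a power spectrum
#'
#' Integrates the PSD over `[low, high)` by the trapezoidal rule, with linear
#' interpolation at the exact band edges so the result is independent of grid
#' alignment.
#'
#' @param ps a `power_spectrum`.
#' @param scheme a `band_scheme` (default [band_scheme()]).
#' @param band_name band name in `scheme`, or a numeric `c(low, high)` pair.
#' @return band power in microvolt^2.
#' @export
band_power <- function(ps, scheme = band_scheme(), band_name) {
  band <- if (is.numeric(band_name)) band_name else scheme[[band_name]]
  if (is.null(band)) stop(sprintf("unknown band '%s'", band_name))
  lo <- band[1]; hi <- band[2]
  if (lo < min(ps$freqs) || hi > max(ps$freqs)) {
    stop("band outside the spectrum's frequency range")
  }
  inside <- ps$freqs > lo & ps$freqs < hi
  f <- c(lo, ps$freqs[inside], hi)
  p <- c(stats::approx(ps$freqs, ps$psd, lo)$y,
         ps$psd[inside],
         stats::approx(ps$freqs, ps$psd, hi)$y)
  sum(diff(f) * (p[-1] + p[-length(p)]) / 2)
}
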