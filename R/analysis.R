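#' Population firing-rate series
#'
#' Spike counts in sliding half-open windows `[t, t + T)`, divided by the
#' window length. By default the count is further divided by the
#' population size, giving a per-neuron rate in Hz that is comparable
#' across differently sized populations; `per_neuron = FALSE` reproduces
#' the raw population-summed convention. The reporting grid uses
#' `T = 50` ms; spectral analysis uses a finer 2 ms grid so beta/gamma
#' content stays below Nyquist.
#'
#' @param record A `spike_record` (or a data.frame of events with a
#'   `sizes` attribute supplied via `size`).
#' @param population Population name.
#' @param window_ms Window length T (ms).
#' @param stride_ms Step between window starts (ms), `<= window_ms`.
#' @param window Analysis interval `(start, end)` ms; defaults to the
#'   record's analysis window.
#' @param per_neuron Divide by population size (default `TRUE`).
#' @return data.frame of class `"firing_rate_series"` with `time_ms`
#'   (window centres) and `rate_hz`; attributes `population`,
#'   `window_ms`, `stride_ms`, `n_runs`.
#' @export
firing_rate <- function(record, population, window_ms = 50,
                        stride_ms = window_ms, window = NULL,
                        per_neuron = TRUE) {
  stopifnot(window_ms > 0, stride_ms > 0, stride_ms <= window_ms)
  if (!population %in% names(record$sizes))
    stop("unknown population: ", population)
  if (is.null(window)) window <- record$record_window
  ev <- record$events
  ts <- ev$time_ms[ev$population == population &
                     ev$time_ms >= window[1] & ev$time_ms < window[2]]
  starts <- seq(window[1], window[2] - window_ms, by = stride_ms)
  counts <- vapply(starts, function(s)
    sum(ts >= s & ts < s + window_ms), numeric(1))
  denom <- (window_ms / 1000) *
    (if (per_neuron) record$sizes[[population]] else 1)
  out <- data.frame(time_ms = starts + window_ms / 2,
                    rate_hz = counts / denom)
  structure(out, population = population, window_ms = window_ms,
            stride_ms = stride_ms, n_runs = 1L,
            class = c("firing_rate_series", "data.frame"))
}

#' Average firing-rate series across repetitions
#'
#' Pointwise mean of series sharing one population and window grid; the
#' result records the number of runs averaged.
#'
#' @param series List of [firing_rate()] outputs.
#' @return A `firing_rate_series`.
#' @export
average_rates <- function(series) {
  stopifnot(length(series) >= 1)
  ref <- series[[1]]
  for (s in series[-1]) {
    if (!isTRUE(all.equal(s$time_ms, ref$time_ms)) ||
        !identical(attr(s, "population"), attr(ref, "population")) ||
        !identical(attr(s, "window_ms"), attr(ref, "window_ms")))
      stop("series have mismatched grids or populations")
  }
  out <- data.frame(time_ms = ref$time_ms,
                    rate_hz = rowMeans(vapply(series,
                                              function(s) s$rate_hz,
                                              numeric(nrow(ref)))))
  structure(out, population = attr(ref, "population"),
            window_ms = attr(ref, "window_ms"),
            stride_ms = attr(ref, "stride_ms"),
            n_runs = sum(vapply(series, function(s)
                         attr(s, "n_runs"), integer(1))),
            class = c("firing_rate_series", "data.frame"))
}

#' Classify a frequency into the standard bands
#'
#' Half-open bands: theta `[4, 8)`, alpha `[8, 13)`, beta `[13, 30)`,
#' gamma `[30, 150)` Hz, so 13 Hz is beta and 30 Hz gamma. Frequencies
#' outside the covered range return `NA`.
#'
#' @param freq_hz Frequency (vectorised).
#' @return Character band label(s) or `NA`.
#' @export
band_of <- function(freq_hz) {
  vapply(freq_hz, function(f) {
    if (!is.finite(f)) return(NA_character_)
    for (b in names(FREQ_BANDS))
      if (f >= FREQ_BANDS[[b]][1] && f < FREQ_BANDS[[b]][2]) return(b)
    NA_character_
  }, character(1))
}

#' Short-time spectral summary of a firing-rate series
#'
#' Hann-windowed, linearly detrended short-time Fourier transform
#' (spectrogram), its time-averaged one-sided power histogram, the
#' dominant (non-DC) frequency, its band label, and the fraction of
#' non-DC power concentrated in the dominant band. The power scale is
#' chosen so the histogram bins sum to the variance of the detrended
#' series (Parseval, within estimator tolerance). A near-constant series
#' yields a flagged undefined dominant frequency.
#'
#' @param rate A [firing_rate()] series on a stride fine enough for the
#'   requested band content (Nyquist check enforced).
#' @param segment_ms Segment length (ms), default 1000.
#' @param overlap Fractional overlap between segments, default 0.5.
#' @param max_freq_hz Upper frequency of interest; the series' Nyquist
#'   frequency must exceed it.
#' @return List of class `"spectral_summary"`.
#' @export
spectral_summary <- function(rate, segment_ms = 1000, overlap = 0.5,
                             max_freq_hz = 150) {
  stride <- attr(rate, "stride_ms")
  fs <- 1000 / stride
  if (fs / 2 < max_freq_hz)
    stop("stride of ", stride, " ms caps analysis at ", fs / 2,
         " Hz; use a finer rate grid for content up to ", max_freq_hz,
         " Hz")
  L <- round(segment_ms / stride)
  x <- rate$rate_hz
  if (length(x) < L) stop("series shorter than one segment")
  hop <- max(1, round(L * (1 - overlap)))
  starts <- seq(1, length(x) - L + 1, by = hop)
  h <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))
  spec <- vapply(starts, function(s) {
    seg <- x[s:(s + L - 1)]
    tt <- seq_along(seg)
    seg <- seg - stats::fitted(stats::lm(seg ~ tt))
    X <- fft(seg * h)
    (Mod(X)^2 / (L * sum(h^2)))[seq_len(floor(L / 2) + 1)]
  }, numeric(floor(L / 2) + 1))
  freqs <- (seq_len(floor(L / 2) + 1) - 1) * fs / L
  onesided <- spec * 2
  onesided[1, ] <- spec[1, ]
  if (L %% 2 == 0) onesided[nrow(onesided), ] <- spec[nrow(onesided), ]
  hist_power <- rowMeans(onesided)
  nz <- hist_power[-1]
  keep <- freqs <= max_freq_hz
  dominant <- NA_real_
  if (sum(nz) > 1e-12 * max(1, mean(x)^2)) {
    cand <- which.max(hist_power[-1][keep[-1]])
    dominant <- freqs[-1][keep[-1]][cand]
  }
  band <- band_of(dominant)
  band_frac <- NA_real_
  if (is.finite(dominant) && !is.na(band)) {
    rng <- FREQ_BANDS[[band]]
    inband <- freqs >= rng[1] & freqs < rng[2]
    band_frac <- sum(hist_power[inband]) / sum(hist_power[-1])
  }
  structure(list(population = attr(rate, "population"),
                 frequencies = freqs,
                 spectrogram = t(spec),
                 segment_times_ms = rate$time_ms[starts] +
                   segment_ms / 2,
                 power_histogram = hist_power,
                 dominant_frequency = dominant,
                 band = band, band_power_fraction = band_frac,
                 fs_hz = fs),
            class = "spectral_summary")
}

#' @export
print.spectral_summary <- function(x, ...) {
  cat("<spectral_summary> ", x$population %||% "?", ": dominant ",
      signif(x$dominant_frequency, 4), " Hz (", x$band %||% "NA",
      "), band power fraction ", signif(x$band_power_fraction, 3), "\n",
      sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Pairwise spike-count synchrony
#'
#' Mean pairwise Pearson correlation of binned spike counts across all
#' neurons of the listed populations (pooled). Silent neurons are
#' excluded; if everything is silent the index is flagged undefined. The
#' raw mean correlation is clipped to `[0, 1]` for reporting (anti-phase
#' structure shows up as a negative raw value, returned in the
#' attributes).
#'
#' @param record A `spike_record`.
#' @param populations Character vector of population names.
#' @param bin_ms Count bin width (ms).
#' @param window Analysis interval; defaults to the record window.
#' @return Clipped synchrony index in `[0, 1]` with attributes `raw` and
#'   `n_neurons`; `NA` (flagged) if undefined.
#' @export
synchrony_index <- function(record, populations, bin_ms = 5,
                            window = NULL) {
  stopifnot(length(populations) >= 1)
  if (is.null(window)) window <- record$record_window
  breaks <- seq(window[1], window[2], by = bin_ms)
  counts <- list()
  for (p in populations) {
    ev <- record$events
    ev <- ev[ev$population == p & ev$time_ms >= window[1] &
               ev$time_ms < max(breaks), ] # whole bins only
    m <- matrix(0L, length(breaks) - 1, record$sizes[[p]])
    if (nrow(ev)) {
      bi <- findInterval(ev$time_ms, breaks, rightmost.closed = FALSE)
      for (r in seq_len(nrow(ev))) m[bi[r], ev$neuron[r]] <-
          m[bi[r], ev$neuron[r]] + 1L
    }
    counts[[p]] <- m
  }
  M <- do.call(cbind, counts)
  active <- apply(M, 2, sd) > 0
  if (sum(active) < 2)
    return(structure(NA_real_, raw = NA_real_, n_neurons = sum(active)))
  cm <- cor(M[, active])
  raw <- mean(cm[upper.tri(cm)])
  structure(min(max(raw, 0), 1), raw = raw, n_neurons = sum(active))
}

#' Burst structure of a population's spike trains
#'
#' A burst is a run of consecutive spikes of one neuron with inter-spike
#' intervals at most `max_isi_ms`; a rebound burst additionally requires
#' a quiescent gap of at least `min_gap_ms` before its first spike.
#' Used to detect tremor-like thalamic rebound bursting.
#'
#' @param record A `spike_record`.
#' @param population Population name.
#' @param max_isi_ms Maximum within-burst inter-spike interval (ms);
#'   the default matches the 40-55 Hz intra-burst rate of the relay-cell
#'   rebound response.
#' @param min_gap_ms Minimum pre-burst silence (ms) for the rebound
#'   count.
#' @param window Analysis interval; defaults to the record window.
#' @return List: `max_burst_len` (longest burst over all neurons),
#'   `n_rebound_bursts` (bursts of >= 3 spikes preceded by silence),
#'   `per_neuron_max` (vector).
#' @export
burst_stats <- function(record, population, max_isi_ms = 25,
                        min_gap_ms = 50, window = NULL) {
  if (is.null(window)) window <- record$record_window
  ev <- record$events
  ev <- ev[ev$population == population & ev$time_ms >= window[1] &
             ev$time_ms < window[2], ]
  per_max <- integer(record$sizes[[population]])
  n_rebound <- 0L
  if (nrow(ev)) {
    by_n <- split(ev$time_ms, ev$neuron)
    for (nm in names(by_n)) {
      ts <- sort(by_n[[nm]])
      isi <- diff(ts)
      runs <- rle(isi <= max_isi_ms)
      idx <- 1L
      best <- 1L
      for (r in seq_along(runs$lengths)) {
        if (runs$values[r]) {
          len <- runs$lengths[r] + 1L
          best <- max(best, len)
          first <- ts[idx]
          gap <- if (idx == 1L) first - window[1] else first - ts[idx - 1L]
          if (len >= 3L && gap >= min_gap_ms) n_rebound <- n_rebound + 1L
        }
        idx <- idx + runs$lengths[r]
      }
      per_max[as.integer(nm)] <- best
    }
  }
  list(max_burst_len = max(per_max, 0L), n_rebound_bursts = n_rebound,
       per_neuron_max = per_max)
}

#' VAR fit and partial directed coherence
#'
#' Fits a vector autoregressive model of the given order to the
#' multivariate firing-rate series by least squares and derives the
#' partial directed coherence (PDC) and generalised PDC per frequency
#' and directed pair. PDC from source j to sink i at frequency f is the
#' magnitude of element (i, j) of `Abar(f) = I - sum_k A_k exp(-2 pi i f
#' k dt)`, normalised by the Euclidean norm of column j, so each source
#' column's squared magnitudes sum to 1 at every frequency.
#'
#' @param rates List of [firing_rate()] series on one common grid.
#' @param model_order VAR order (lags); `"aic"` selects 1..20 by AIC.
#' @param freqs_hz Frequencies at which to evaluate (defaults to 0 to
#'   Nyquist in 1 Hz steps).
#' @return List of class `"var_pdc"`: `A` (array order x n x n), `pdc`
#'   and `gpdc` arrays (freq x n x n, sink x source), `freqs_hz`,
#'   `populations`, `sigma` (residual covariance).
#' @export
var_pdc <- function(rates, model_order = 10, freqs_hz = NULL) {
  stopifnot(length(rates) >= 2)
  X <- vapply(rates, function(r) r$rate_hz,
              numeric(nrow(rates[[1]])))
  if (any(vapply(rates, function(r) !isTRUE(all.equal(r$time_ms,
        rates[[1]]$time_ms)), logical(1))))
    stop("rate series are not on a common grid")
  stride <- attr(rates[[1]], "stride_ms")
  X <- scale(X, center = TRUE, scale = FALSE)
  n <- ncol(X); Tn <- nrow(X)
  fit_order <- function(p) {
    Y <- X[(p + 1):Tn, , drop = FALSE]
    Z <- do.call(cbind, lapply(1:p, function(k)
      X[(p + 1 - k):(Tn - k), , drop = FALSE]))
    qrz <- qr(Z)
    if (qrz$rank < ncol(Z))
      stop("rank-deficient VAR regression; try a lower model order")
    B <- qr.coef(qrz, Y)              # (n*p) x n
    E <- Y - Z %*% B
    Sig <- crossprod(E) / (nrow(Y) - ncol(Z))
    list(B = B, Sig = Sig, p = p,
         aic = nrow(Y) * determinant(Sig)$modulus[1] + 2 * p * n * n)
  }
  fit <- if (identical(model_order, "aic")) {
    fits <- lapply(1:20, function(p) tryCatch(fit_order(p),
                                              error = function(e) NULL))
    fits <- Filter(Negate(is.null), fits)
    fits[[which.min(vapply(fits, `[[`, numeric(1), "aic"))]]
  } else fit_order(as.integer(model_order))
  p <- fit$p
  A <- array(0, c(p, n, n))
  for (k in 1:p) A[k, , ] <- t(fit$B[((k - 1) * n + 1):(k * n), ,
                                     drop = FALSE])
  if (is.null(freqs_hz)) freqs_hz <- seq(0, 1000 / stride / 2, by = 1)
  lam <- freqs_hz * stride / 1000   # cycles per sample
  nf <- length(freqs_hz)
  pdc <- array(NA_real_, c(nf, n, n))
  gpdc <- array(NA_real_, c(nf, n, n))
  sdi <- sqrt(diag(fit$Sig))
  for (fi in seq_len(nf)) {
    Abar <- diag(n) + 0i
    for (k in 1:p) Abar <- Abar - A[k, , ] * exp(-2i * pi * lam[fi] * k)
    for (j in 1:n) {
      col <- Abar[, j]
      pdc[fi, , j] <- Mod(col) / sqrt(sum(Mod(col)^2))
      gcol <- Mod(col) / sdi
      gpdc[fi, , j] <- gcol / sqrt(sum(gcol^2))
    }
  }
  structure(list(A = A, pdc = pdc, gpdc = gpdc, freqs_hz = freqs_hz,
                 populations = vapply(rates, attr, "",
                                      which = "population"),
                 sigma = fit$Sig, order = p),
            class = "var_pdc")
}
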