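#' Static functional connectivity
#'
#' Pairwise product-moment correlation matrix of the regional signals.
#' Constant columns make a correlation undefined; those entries are set to 0
#' with a warning and the diagonal is forced to 1.
#'
#' @param s A `regional_signals` object with at least 3 time points.
#' @return An object of class `static_fc` with elements `values` (symmetric
#'   correlation matrix, unit diagonal) and `labels`.
#' @export
static_fc <- function(s) {
  stopifnot(inherits(s, "regional_signals"))
  x <- s$data
  if (nrow(x) < 3L) stop("need at least 3 time points")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("constant signal column(s); their correlations set to 0")
    r <- suppressWarnings(stats::cor(x))
    r[!is.finite(r)] <- 0
  } else {
    r <- stats::cor(x)
  }
  diag(r) <- 1
  new_static_fc(r, s$labels)
}

new_static_fc <- function(values, labels) {
  values <- as.matrix(values)
  dimnames(values) <- list(labels, labels)
  structure(list(values = values, labels = labels), class = "static_fc")
}

#' @export
print.static_fc <- function(x, ...) {
  ut <- upper_vals(x$values)
  cat("Static FC: ", length(x$labels), " regions; mean off-diagonal r = ",
      formatC(mean(ut), digits = 3, format = "f"), "\n", sep = "")
  invisible(x)
}

#' Group-average functional connectivity
#'
#' Fisher z-transforms each subject-level FC matrix, averages, and transforms
#' back. Off-diagonal entries at exactly +/-1 are clipped to +/-(1 - 1e-7)
#' before the transform; the diagonal is forced back to 1.
#'
#' @param fcs List of `static_fc` objects with identical shape and labels.
#' @return A `static_fc`.
#' @export
group_average_fc <- function(fcs) {
  stopifnot(length(fcs) >= 1L, all(vapply(fcs, inherits, TRUE, "static_fc")))
  labels <- fcs[[1]]$labels
  for (f in fcs)
    if (!identical(f$labels, labels)) stop("FC matrices differ in labels/shape")
  zs <- lapply(fcs, function(f) {
    v <- pmin(pmax(f$values, -1 + 1e-7), 1 - 1e-7)
    atanh(v)
  })
  zbar <- Reduce(`+`, zs) / length(zs)
  out <- tanh(zbar)
  diag(out) <- 1
  new_static_fc(out, labels)
}

#' Similarity between two FC matrices
#'
#' Product-moment correlation over the strictly-upper-triangle entries, the
#' measure used to compare simulated against reference FC.
#'
#' @param a,b `static_fc` objects of the same shape.
#' @return Correlation scalar in `[-1, 1]`.
#' @export
fc_similarity <- function(a, b) {
  stopifnot(inherits(a, "static_fc"), inherits(b, "static_fc"))
  if (!all(dim(a$values) == dim(b$values))) stop("FC shape mismatch")
  va <- upper_vals(a$values); vb <- upper_vals(b$values)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("degenerate (constant) FC upper triangle")
  stats::cor(va, vb)
}

#' Newman modularity of an FC matrix over a fixed partition
#'
#' \deqn{Q = \frac{1}{v} \sum_{i,j} \left(w_{ij} -
#'   \frac{s_i s_j}{v}\right) \delta_{ij}} with nodal strength
#' \eqn{s_i = \sum_j w_{ij}} and total weight \eqn{v = \sum_{ij} w_{ij}}. The
#' double sum runs over all ordered pairs including `i == j` (with
#' `w_ii := 0`). The formula assumes nonnegative weights, so negative FC
#' entries are clipped to 0 first. The modules are the fixed functional
#' systems of the partition, not the result of community detection.
#'
#' @param fc A `static_fc` (or a plain symmetric matrix).
#' @param partition System identifier per node.
#' @return Modularity scalar Q.
#' @export
fc_modularity <- function(fc, partition) {
  w <- if (inherits(fc, "static_fc")) fc$values else as.matrix(fc)
  if (length(partition) != nrow(w)) stop("partition must cover every node")
  w <- pmax(w, 0)
  diag(w) <- 0
  v <- sum(w)
  if (v == 0) stop("total weight is zero")
  s <- rowSums(w)
  delta <- outer(partition, partition, "==")
  sum((w - outer(s, s) / v) * delta) / v
}

#' Instantaneous phases via the analytic signal
#'
#' Computes each region's analytic signal (Hilbert transform of the demeaned
#' column) and takes the four-quadrant arctangent of imaginary over real part,
#' giving phases in \eqn{(-\pi, \pi]}. Because the analytic signal is
#' distorted near the series ends, a fraction `trim` of time points is dropped
#' from each end by default before any phase-based metric is computed.
#'
#' @param s A `regional_signals` object with >= 8 time points.
#' @param trim Fraction of time points dropped from each end (default 0.05).
#' @return An object of class `phase_series` with elements `phases`
#'   (time x node matrix in \eqn{(-\pi, \pi]}) and `tr`.
#' @export
hilbert_phases <- function(s, trim = 0.05) {
  stopifnot(inherits(s, "regional_signals"))
  x <- s$data
  n <- nrow(x)
  if (n < 8L) stop("need at least 8 time points")
  if (any(apply(x, 2, stats::sd) == 0)) stop("constant signal column")
  ph <- apply(x, 2, function(col) Arg(analytic_signal(col - mean(col))))
  keep <- seq_len(n)
  if (trim > 0) {
    k <- floor(trim * n)
    if (n - 2 * k < 2L) stop("`trim` leaves fewer than 2 time points")
    keep <- (k + 1L):(n - k)
  }
  structure(list(phases = ph[keep, , drop = FALSE], tr = s$tr,
                 labels = s$labels),
            class = "phase_series")
}

# Analytic signal by the FFT method: zero the negative frequencies and double
# the positive ones (DC and Nyquist kept once).
analytic_signal <- function(x) {
  n <- length(x)
  f <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(f * h, inverse = TRUE) / n
}

#' Instantaneous phase-coherence FC at one time point
#'
#' Entry \eqn{(i, j)} is \eqn{1 - |\sin(\theta_i - \theta_j)|}: 1 for
#' in-phase (or anti-phase) pairs, 0 at quadrature.
#'
#' @param p A `phase_series`.
#' @param t Time index into the series.
#' @return Symmetric N x N matrix with unit diagonal, entries in `[0, 1]`.
#' @export
instantaneous_fc <- function(p, t) {
  stopifnot(inherits(p, "phase_series"))
  if (t < 1L || t > nrow(p$phases)) stop("time index out of range")
  th <- p$phases[t, ]
  1 - abs(sin(outer(th, th, "-")))
}

#' Distribution of dynamic-FC similarities
#'
#' For every unordered pair of distinct time points, the cosine similarity
#' between the half-vectorized (strict upper triangle) instantaneous FC
#' matrices of the two time points. When the number of pairs exceeds
#' `max_pairs`, a seeded uniform subsample of `max_pairs` pairs is used; the
#' result is exhaustive and seed-independent otherwise.
#'
#' @param p A `phase_series` with >= 2 time points.
#' @param max_pairs Cap on the number of time-point pairs (default 250000).
#' @param seed Integer seed used only when subsampling.
#' @return An object of class `similarity_distribution` holding `samples`
#'   (cosine similarities in `[-1, 1]`; here all nonnegative since
#'   instantaneous FC entries are in `[0, 1]`).
#' @export
dfc_similarity_distribution <- function(p, max_pairs = 250000L, seed = 1L) {
  stopifnot(inherits(p, "phase_series"))
  tt <- nrow(p$phases)
  if (tt < 2L) stop("need at least 2 time points")
  u <- instantaneous_fc_rows(p)
  norms <- sqrt(rowSums(u^2))
  if (any(norms == 0)) stop("zero-norm instantaneous FC vector")
  un <- u / norms
  n_pairs <- tt * (tt - 1) / 2
  if (n_pairs <= max_pairs) {
    cs <- tcrossprod(un)
    samples <- cs[upper.tri(cs)]
  } else {
    seed_rng(seed)
    idx <- sample(n_pairs, max_pairs)
    ij <- pair_from_index(idx, tt)
    samples <- rowSums(un[ij[, 1], , drop = FALSE] *
                         un[ij[, 2], , drop = FALSE])
  }
  structure(list(samples = pmin(pmax(samples, -1), 1)),
            class = "similarity_distribution")
}

# time x pair matrix of half-vectorized instantaneous FC
instantaneous_fc_rows <- function(p) {
  th <- p$phases
  n <- ncol(th)
  ut <- which(upper.tri(diag(n)))
  ij <- arrayInd(ut, c(n, n))
  1 - abs(sin(th[, ij[, 1], drop = FALSE] - th[, ij[, 2], drop = FALSE]))
}

# map linear indices 1..T(T-1)/2 of the upper triangle (column-major over
# pairs i < j) back to (i, j)
pair_from_index <- function(k, tt) {
  j <- ceiling((1 + sqrt(1 + 8 * k)) / 2)
  # guard against floating-point rounding at exact column boundaries
  j <- j - (k <= (j - 1) * (j - 2) / 2)
  j <- j + (k > (j - 1) * j / 2)
  i <- k - (j - 1) * (j - 2) / 2
  cbind(as.integer(i), as.integer(j))
}

#' @export
print.similarity_distribution <- function(x, ...) {
  cat("dFC similarity distribution: ", length(x$samples),
      " samples, median ", formatC(stats::median(x$samples), digits = 3,
                                   format = "f"), "\n", sep = "")
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov distance
#'
#' Supremum absolute difference between the empirical CDFs of the two sample
#' sets; used to compare dynamic-FC similarity distributions.
#'
#' @param a,b `similarity_distribution` objects or plain numeric vectors.
#' @return Scalar in `[0, 1]`.
#' @export
ks_distance <- function(a, b) {
  xa <- if (inherits(a, "similarity_distribution")) a$samples else as.numeric(a)
  xb <- if (inherits(b, "similarity_distribution")) b$samples else as.numeric(b)
  if (length(xa) == 0L || length(xb) == 0L) stop("empty sample set")
  pooled <- sort(unique(c(xa, xb)))
  fa <- stats::ecdf(xa)(pooled)
  fb <- stats::ecdf(xb)(pooled)
  max(abs(fa - fb))
}

#' Kuramoto order parameter, synchrony and metastability
#'
#' At each time point the order parameter is the magnitude of the mean
#' resultant phase vector \eqn{r(t) = |\frac{1}{N}\sum_j e^{i\theta_j(t)}|}
#' with ensemble phase \eqn{\phi(t)} its argument. The time-mean of `r` is
#' the global synchrony, its time-SD the global metastability.
#'
#' @param p A `phase_series`.
#' @return An object of class `coherence_series` with elements `r`, `phi`,
#'   `synchrony`, `metastability`.
#' @export
order_parameter <- function(p) {
  stopifnot(inherits(p, "phase_series"))
  zbar <- rowMeans(exp(1i * p$phases))
  r <- Mod(zbar)
  structure(list(r = r, phi = Arg(zbar), synchrony = mean(r),
                 metastability = stats::sd(r)),
            class = "coherence_series")
}

#' @export
print.coherence_series <- function(x, ...) {
  cat("Order parameter over ", length(x$r), " samples: synchrony = ",
      formatC(x$synchrony, digits = 3, format = "f"), ", metastability = ",
      formatC(x$metastability, digits = 4, format = "f"), "\n", sep = "")
  invisible(x)
}

#' Estimate intrinsic angular frequencies from multi-subject signals
#'
#' Per subject and region, the in-band frequency of maximal Welch power
#' spectral density; per region, the median across subjects, returned as an
#' angular frequency \eqn{2\pi f} (rad/s). This is how the intrinsic drive
#' `omega0` of each oscillator is estimated from reference signals.
#'
#' @param subject_signals List of `regional_signals` (same regions, same tr).
#' @param band Frequency band `(low, high)` in Hz, inside `(0, Nyquist)`.
#' @param nperseg Welch segment length in samples (default
#'   `min(256, floor(T/2))`), 50% overlap, Hann window.
#' @return Named numeric vector of angular frequencies (rad/s), one per
#'   region.
#' @export
estimate_intrinsic_frequencies <- function(subject_signals,
                                           band = c(0.02, 0.12),
                                           nperseg = NULL) {
  stopifnot(length(subject_signals) >= 1L,
            all(vapply(subject_signals, inherits, TRUE, "regional_signals")))
  tr <- subject_signals[[1]]$tr
  fs <- 1 / tr
  if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2])
    stop("`band` must lie within (0, Nyquist)")
  peaks <- sapply(subject_signals, function(s) {
    apply(s$data, 2, function(col) {
      w <- welch_psd(col, fs = fs, nperseg = nperseg)
      inb <- w$freq >= band[1] & w$freq <= band[2]
      if (!any(inb)) stop("band empty after discretization")
      w$freq[inb][which.max(w$psd[inb])]
    })
  })
  peaks <- matrix(peaks, ncol = length(subject_signals))
  f_med <- apply(peaks, 1, stats::median)
  stats::setNames(2 * pi * f_med, subject_signals[[1]]$labels)
}

#' Welch power spectral density estimate
#'
#' Mean periodogram over Hann-windowed, 50%-overlapping, per-segment demeaned
#' segments.
#'
#' @param x Numeric vector.
#' @param fs Sampling frequency (Hz).
#' @param nperseg Segment length; default `min(256, floor(length(x)/2))`.
#' @return List with `freq` (Hz, one-sided) and `psd`.
#' @export
welch_psd <- function(x, fs, nperseg = NULL) {
  n <- length(x)
  if (is.null(nperseg)) nperseg <- min(256L, max(8L, floor(n / 2)))
  nperseg <- min(nperseg, n)
  step <- max(1L, floor(nperseg / 2))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, nperseg - 1) / (nperseg - 1)))
  scale <- fs * sum(w^2)
  nfreq <- floor(nperseg / 2) + 1L
  acc <- numeric(nfreq)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    px <- Mod(stats::fft(seg))^2 / scale
    acc <- acc + px[seq_len(nfreq)]
  }
  list(freq = (seq_len(nfreq) - 1) * fs / nperseg, psd = acc / length(starts))
}
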