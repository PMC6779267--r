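#' Model parameters for the adaptive Stuart-Landau whole-brain model
#'
#' Each region \eqn{j} is a Stuart-Landau oscillator near a supercritical Hopf
#' bifurcation with state \eqn{z_j = r e^{i\theta}} and a free-running angular
#' frequency \eqn{\omega_j} that relaxes towards its intrinsic drive
#' \eqn{\omega^0_j} with lethargy \eqn{\lambda} and is modulated (coefficient
#' \eqn{m}) by the connectivity-weighted net phase of its structural
#' neighbours. The bifurcation parameter `a` selects noise-driven fluctuations
#' (`a < 0`) versus a limit cycle of radius \eqn{\sqrt{a}} (`a > 0`).
#'
#' @param a Bifurcation parameter; scalar (shared by all regions) or one value
#'   per region.
#' @param omega0 Intrinsic angular frequency drive (rad/s); scalar or one per
#'   region. A spectral peak `f` in Hz corresponds to `2 * pi * f`.
#' @param G Global coupling scaling the structural weights.
#' @param lam Frequency lethargy \eqn{\lambda} (1/s); must be positive
#'   whenever `m != 0` or any `omega0 != 0`, so the frequency dynamics stay
#'   bounded.
#' @param m Frequency modulation coefficient.
#' @param beta Noise amplitude (standard deviation of the Wiener process);
#'   `>= 0`. The value used throughout the reference analyses is 0.02.
#' @param n_nodes Number of regions; needed only to recycle scalar `a` /
#'   `omega0`.
#' @return An object of class `wbm_parameters`.
#' @export
model_parameters <- function(a, omega0, G, lam, m, beta = 0.02,
                             n_nodes = NULL) {
  if (is.null(n_nodes)) n_nodes <- max(length(a), length(omega0))
  if (length(a) == 1L) a <- rep(a, n_nodes)
  if (length(omega0) == 1L) omega0 <- rep(omega0, n_nodes)
  if (length(a) != n_nodes || length(omega0) != n_nodes)
    stop("`a` and `omega0` must be scalars or length ", n_nodes)
  vals <- c(a, omega0, G, lam, m, beta)
  if (!all(is.finite(vals))) stop("all parameters must be finite")
  if (beta < 0) stop("`beta` must be >= 0")
  if ((m != 0 || any(omega0 != 0)) && lam <= 0)
    stop("`lam` must be > 0 when `m != 0` or `omega0 != 0` (bounded frequency dynamics)")
  structure(list(a = a, omega0 = omega0, G = G, lam = lam, m = m,
                 beta = beta),
            class = "wbm_parameters")
}

#' @export
print.wbm_parameters <- function(x, ...) {
  fmt <- function(v) if (length(unique(v)) == 1L) format(v[1]) else
    paste0("per-node [", format(min(v)), ", ", format(max(v)), "]")
  cat("Whole-brain model parameters (", length(x$a), " regions)\n",
      "  a      = ", fmt(x$a), "\n",
      "  omega0 = ", fmt(x$omega0), " rad/s\n",
      "  G      = ", format(x$G), "   lambda = ", format(x$lam),
      "   m = ", format(x$m), "   beta = ", format(x$beta), "\n", sep = "")
  invisible(x)
}

#' Simulation configuration
#'
#' Integration and recording settings for [simulate_model()]. The defaults
#' (Euler-Maruyama step `dt = 0.01` s, 60 s burn-in, 1190 output samples at
#' `tr = 0.72` s) mirror a single resting-state fMRI run after discarding the
#' initial transient. `dt` is adjusted to the nearest exact divisor of `tr` so
#' output instants fall on integration steps.
#'
#' @param dt Integrator step (s), `0 < dt <= tr`.
#' @param tr Output sampling interval (s).
#' @param n_samples Number of recorded samples (>= 2); alternatively give
#'   `duration`.
#' @param burn_in Discarded initial time (s).
#' @param duration Total simulated time (s); overrides `n_samples`.
#' @param seed Integer seed controlling initial conditions and noise.
#' @param record_frequencies Record the free-running frequencies
#'   \eqn{\omega_j(t)}.
#' @param record_psi Record the neighbour-ensemble phase drive
#'   \eqn{\psi_j(t)}.
#' @return An object of class `wbm_config`.
#' @export
simulation_config <- function(dt = 0.01, tr = 0.72, n_samples = 1190,
                              burn_in = 60, duration = NULL, seed = 1L,
                              record_frequencies = TRUE, record_psi = FALSE) {
  if (dt <= 0 || dt > tr) stop("need 0 < dt <= tr")
  if (!is.null(duration)) {
    if (duration <= burn_in) stop("`duration` must exceed `burn_in`")
    n_samples <- floor((duration - burn_in) / tr) + 1L
  }
  if (n_samples < 2L) stop("need at least 2 output samples")
  steps_per_sample <- max(1L, as.integer(round(tr / dt)))
  dt_eff <- tr / steps_per_sample
  burn_steps <- as.integer(round(burn_in / dt_eff))
  structure(list(dt = dt_eff, tr = tr, n_samples = as.integer(n_samples),
                 burn_in = burn_steps * dt_eff, seed = as.integer(seed),
                 steps_per_sample = steps_per_sample,
                 burn_steps = burn_steps,
                 record_frequencies = isTRUE(record_frequencies),
                 record_psi = isTRUE(record_psi)),
            class = "wbm_config")
}

#' Integrate the coupled whole-brain oscillator model
#'
#' Euler-Maruyama integration of
#' \deqn{\dot z_j = (a_j + i\omega_j - |z_j|^2) z_j +
#'       G \sum_i C_{ij} (z_i - z_j) + \beta \eta_j}
#' \deqn{\dot\omega_j = \omega^0_j - \lambda \omega_j + m \psi_j, \quad
#'       \psi_j = \sum_i C_{ij} \theta_i}
#' where \eqn{\theta_i} is the two-quadrant arctangent of
#' \eqn{\mathrm{Im}\,z_i / \mathrm{Re}\,z_i} in \eqn{[-\pi/2, \pi/2]} and
#' \eqn{\eta_j} are independent complex Wiener increments (independent real
#' and imaginary components, each of variance `dt` per step). Initial states
#' are drawn uniformly on the complex disk of radius
#' `max(sqrt(max(a, 0)), 0.1)` and \eqn{\omega_j(0) = \omega^0_j/\lambda}, so
#' the system starts near its attracting set. Fixed `cfg$seed` gives bitwise
#' reproducible trajectories.
#'
#' @param c A `structural_connectome` (its weights are the coupling matrix).
#' @param p A `wbm_parameters` object with per-node vectors of length
#'   `nrow(c$weights)`.
#' @param cfg A `wbm_config`.
#' @return An object of class `wbm_trajectory` with elements `times`
#'   (s, relative to simulation start), `z` (complex `n_samples x N` matrix),
#'   `omega` (when recorded), `psi` (when recorded), `labels`, `tr`, `config`.
#' @export
simulate_model <- function(c, p, cfg = simulation_config()) {
  stopifnot(inherits(c, "structural_connectome"),
            inherits(p, "wbm_parameters"), inherits(cfg, "wbm_config"))
  n <- nrow(c$weights)
  if (length(p$a) != n)
    stop("parameter vectors are length ", length(p$a),
         " but the connectome has ", n, " regions")
  seed_rng(cfg$seed)
  r0 <- pmax(sqrt(pmax(p$a, 0)), 0.1)
  rad <- r0 * sqrt(stats::runif(n))
  ang <- stats::runif(n, 0, 2 * pi)
  z0re <- rad * cos(ang)
  z0im <- rad * sin(ang)
  w0 <- if (p$lam > 0) p$omega0 / p$lam else p$omega0

  raw <- .sl_integrate(c$weights, p$a, p$omega0, p$G, p$lam, p$m, p$beta,
                       z0re, z0im, w0, cfg$dt, cfg$burn_steps,
                       cfg$n_samples, cfg$steps_per_sample,
                       cfg$record_frequencies, cfg$record_psi)
  times <- cfg$burn_in + (seq_len(cfg$n_samples) - 1) * cfg$tr
  out <- list(times = times,
              z = matrix(complex(real = raw$z_re, imaginary = raw$z_im),
                         nrow = cfg$n_samples,
                         dimnames = list(NULL, c$labels)),
              labels = c$labels, tr = cfg$tr, config = cfg)
  if (cfg$record_frequencies) out$omega <- raw$omega
  if (cfg$record_psi) out$psi <- raw$psi
  class(out) <- "wbm_trajectory"
  out
}

#' @export
print.wbm_trajectory <- function(x, ...) {
  cat("Whole-brain model trajectory: ", ncol(x$z), " regions x ",
      nrow(x$z), " samples (tr = ", x$tr, " s, burn-in ",
      x$config$burn_in, " s discarded)\n", sep = "")
  invisible(x)
}

#' @export
plot.wbm_trajectory <- function(x, nodes = seq_len(min(5L, ncol(x$z))), ...) {
  graphics::matplot(x$times, Re(x$z[, nodes, drop = FALSE]), type = "l",
                    lty = 1, xlab = "time (s)", ylab = "Re z (signal)", ...)
  invisible(x)
}

#' Extract BOLD-like regional signals from a trajectory
#'
#' The real part of the oscillator state, \eqn{r\cos\theta}, is read out as
#' the measurable regional activity; the imaginary part is the hidden state.
#'
#' @param t A `wbm_trajectory`.
#' @return An object of class `regional_signals` with elements `data`
#'   (time x region real matrix), `tr`, `labels`.
#' @export
extract_bold <- function(t) {
  stopifnot(inherits(t, "wbm_trajectory"))
  if (nrow(t$z) == 0L) stop("empty trajectory")
  regional_signals(Re(t$z), tr = t$tr, labels = t$labels)
}

#' Regional signal container
#'
#' @param data Time x region numeric matrix (>= 2 time points, finite).
#' @param tr Sampling interval in seconds.
#' @param labels Region identifiers.
#' @return An object of class `regional_signals`.
#' @export
regional_signals <- function(data, tr, labels = NULL) {
  data <- as.matrix(data)
  if (nrow(data) < 2L) stop("need at least 2 time points")
  if (!all(is.finite(data))) stop("signals must be finite")
  if (tr <= 0) stop("`tr` must be positive")
  if (is.null(labels)) labels <- colnames(data)
  if (is.null(labels)) labels <- default_labels(ncol(data))
  colnames(data) <- labels
  structure(list(data = data, tr = tr, labels = labels),
            class = "regional_signals")
}

#' @export
print.regional_signals <- function(x, ...) {
  cat("Regional signals: ", ncol(x$data), " regions x ", nrow(x$data),
      " samples (tr = ", x$tr, " s)\n", sep = "")
  invisible(x)
}

#' Lesion regions by shifting their dynamical regime
#'
#' Returns a copy of the parameters with the bifurcation parameter of the
#' target regions set to `a_lesion`. With the default `a_lesion = -2` a
#' lesioned region leaves the oscillatory domain and produces noise-driven
#' fluctuations around the stable fixed point at the origin.
#'
#' @param p A `wbm_parameters` object.
#' @param targets Integer indices of the regions to lesion (may be empty).
#' @param a_lesion Bifurcation parameter assigned to the targets.
#' @return A `wbm_parameters` object.
#' @export
apply_perturbation <- function(p, targets, a_lesion = -2) {
  stopifnot(inherits(p, "wbm_parameters"))
  targets <- as.integer(targets)
  if (length(targets) &&
      (any(targets < 1L) || any(targets > length(p$a))))
    stop("lesion target out of range")
  p$a[targets] <- a_lesion
  p
}
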