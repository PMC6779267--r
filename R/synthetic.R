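#' Specification of a synthetic reference study
#'
#' Describes the fully synthetic stand-in for an empirical resting-state
#' study: subject-level structural connectomes plus band-limited oscillatory
#' regional signals. Defaults mirror the acquisition the model was built
#' for -- 68 cortical regions in 6 functional systems, 0.72 s sampling, 1190
#' time points, a 0.02-0.12 Hz band -- with 20 subjects as a desk-scale
#' cohort. Ground-truth dynamics use the fitted working point
#' `a = 0.038, G = 0.01, lambda = 0.4, m = 0.14, beta = 0.02`.
#'
#' @param n_nodes,n_subjects,n_systems Counts.
#' @param tr Sampling interval (s).
#' @param n_timepoints Samples per subject (>= 2).
#' @param freq_band `(low, high)` in Hz, within `(0, 1/(2 tr))`.
#' @param signal_noise SD of additive white Gaussian observation noise on the
#'   extracted signals.
#' @param density,dropout Passed to [generate_subject_connectomes()].
#' @param params Named list of ground-truth `a`, `G`, `lam`, `m`, `beta`.
#' @param dt Integrator step (s).
#' @param burn_in Discarded initial time (s).
#' @param seed Master integer seed; all outputs are deterministic in it.
#' @return An object of class `study_spec`.
#' @export
synthetic_study_spec <- function(n_nodes = 68L, n_subjects = 20L,
                                 n_systems = 6L, tr = 0.72,
                                 n_timepoints = 1190L,
                                 freq_band = c(0.02, 0.12),
                                 signal_noise = 0.01, density = 0.3,
                                 dropout = 0.2,
                                 params = list(a = 0.038, G = 0.01,
                                               lam = 0.4, m = 0.14,
                                               beta = 0.02),
                                 dt = 0.01, burn_in = 60, seed = 1L) {
  if (n_nodes < 4L || n_subjects < 1L || n_systems < 1L || n_timepoints < 2L)
    stop("counts must be positive (n_nodes >= 4, n_timepoints >= 2)")
  if (freq_band[1] <= 0 || freq_band[2] >= 1 / (2 * tr) ||
      freq_band[1] >= freq_band[2])
    stop("`freq_band` must lie within (0, Nyquist)")
  if (signal_noise < 0) stop("`signal_noise` must be >= 0")
  structure(list(n_nodes = as.integer(n_nodes),
                 n_subjects = as.integer(n_subjects),
                 n_systems = as.integer(n_systems), tr = tr,
                 n_timepoints = as.integer(n_timepoints),
                 freq_band = freq_band, signal_noise = signal_noise,
                 density = density, dropout = dropout, params = params,
                 dt = dt, burn_in = burn_in, seed = as.integer(seed)),
            class = "study_spec")
}

#' Generate a fully synthetic reference study
#'
#' Produces everything an empirical study would provide: a stack of
#' subject-level structural connectomes, the group-representative connectome
#' (60% consistency rule, then rank-based Gaussian resampling with mu = 0.5,
#' sigma = 0.15), per-node ground-truth spectral peaks drawn uniformly in the
#' frequency band, and per-subject regional signals simulated from the model
#' at the ground-truth parameters with subject-specific seeds plus additive
#' observation noise. The intrinsic drive is set to
#' `omega0 = lam * 2 * pi * f_peak` so that the post-relaxation free-running
#' frequency `omega0 / lam` sits at the drawn spectral peak.
#'
#' @param spec A `study_spec`.
#' @return An object of class `synthetic_study`: list with `stack`
#'   (`connectome_stack`), `connectome` (group `structural_connectome`,
#'   resampled), `signals` (list of `regional_signals`, one per subject),
#'   `partition`, `ground_truth` (params and per-node `f_peak_hz`,
#'   `omega0`), and `spec`.
#' @export
generate_reference_study <- function(spec) {
  stopifnot(inherits(spec, "study_spec"))
  stack <- generate_subject_connectomes(
    n_nodes = spec$n_nodes, n_subjects = spec$n_subjects,
    n_systems = spec$n_systems, density = spec$density,
    dropout = spec$dropout, seed = derive_seed(spec$seed, 1L))
  group <- build_group_connectome(stack, consistency = 0.6)
  conn <- gaussian_resample_weights(group, mu = 0.5, sigma = 0.15)

  seed_rng(derive_seed(spec$seed, 2L))
  f_peak <- stats::runif(spec$n_nodes, spec$freq_band[1], spec$freq_band[2])
  omega_target <- 2 * pi * f_peak
  pars <- spec$params
  omega0 <- pars$lam * omega_target
  p_true <- model_parameters(a = pars$a, omega0 = omega0, G = pars$G,
                             lam = pars$lam, m = pars$m, beta = pars$beta,
                             n_nodes = spec$n_nodes)
  signals <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    cfg_s <- simulation_config(dt = spec$dt, tr = spec$tr,
                               n_samples = spec$n_timepoints,
                               burn_in = spec$burn_in,
                               seed = derive_seed(spec$seed, 100L + s),
                               record_frequencies = FALSE)
    sig <- extract_bold(simulate_model(conn, p_true, cfg_s))
    if (spec$signal_noise > 0) {
      seed_rng(derive_seed(spec$seed, 10000L + s))
      sig$data <- sig$data + matrix(
        stats::rnorm(length(sig$data), sd = spec$signal_noise),
        nrow(sig$data))
    }
    signals[[s]] <- sig
  }
  structure(list(stack = stack, connectome = conn, signals = signals,
                 partition = conn$partition,
                 ground_truth = list(params = pars, f_peak_hz = f_peak,
                                     omega0 = omega0),
                 spec = spec),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic reference study: ", x$spec$n_subjects, " subjects, ",
      x$spec$n_nodes, " regions, ", x$spec$n_timepoints,
      " samples @ tr = ", x$spec$tr, " s (seed ", x$spec$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Build reference summaries from multi-subject signals
#'
#' Computes the fitting target from per-subject regional signals: the
#' Fisher-z group average of the subject FC matrices, its modularity over
#' the partition, the pooled (concatenated across subjects) dFC similarity
#' distribution, and the across-subject means of synchrony and
#' metastability. Per-subject summaries are retained for the AIC comparison.
#'
#' @param signals List of `regional_signals`, one per subject.
#' @param partition System identifiers.
#' @param max_pairs,dfc_seed Passed to [dfc_similarity_distribution()].
#' @param trim Passed to [hilbert_phases()].
#' @return A `reference_summaries` object.
#' @export
make_reference_summaries <- function(signals, partition,
                                     max_pairs = 250000L, dfc_seed = 1L,
                                     trim = 0.05) {
  stopifnot(length(signals) >= 1L)
  per_subject <- lapply(signals, function(s) {
    ph <- hilbert_phases(s, trim = trim)
    coh <- order_parameter(ph)
    list(fc = static_fc(s),
         dfc = dfc_similarity_distribution(ph, max_pairs = max_pairs,
                                           seed = dfc_seed),
         synchrony = coh$synchrony, metastability = coh$metastability)
  })
  group_fc <- group_average_fc(lapply(per_subject, `[[`, "fc"))
  pooled <- structure(
    list(samples = unlist(lapply(per_subject,
                                 function(s) s$dfc$samples))),
    class = "similarity_distribution")
  reference_summaries(
    fc = group_fc,
    modularity_ref = fc_modularity(group_fc, partition),
    dfc = pooled,
    synchrony_ref = mean(vapply(per_subject, `[[`, numeric(1), "synchrony")),
    metastability_ref = mean(vapply(per_subject, `[[`, numeric(1),
                                    "metastability")),
    per_subject = per_subject)
}
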