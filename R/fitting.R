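#' Reference summaries used as the fitting target
#'
#' The signal-level summaries a model working point is scored against:
#' group-level static FC, its modularity over the functional-system
#' partition, the pooled dynamic-FC similarity distribution, and the mean
#' synchrony and metastability. Usually produced by
#' [make_reference_summaries()]; this constructor just validates the pieces.
#'
#' @param fc Group-level `static_fc`.
#' @param modularity_ref Modularity Q of the reference FC.
#' @param dfc `similarity_distribution` of reference dFC similarities.
#' @param synchrony_ref,metastability_ref Reference scalars.
#' @param per_subject Optional list of per-subject summaries (each a list
#'   with `fc`, `dfc`, `synchrony`, `metastability`) kept for AIC model
#'   comparison.
#' @return An object of class `reference_summaries`.
#' @export
reference_summaries <- function(fc, modularity_ref, dfc, synchrony_ref,
                                metastability_ref, per_subject = NULL) {
  stopifnot(inherits(fc, "static_fc"),
            inherits(dfc, "similarity_distribution"),
            length(dfc$samples) >= 1L,
            is.finite(modularity_ref), is.finite(synchrony_ref),
            is.finite(metastability_ref))
  structure(list(fc = fc, modularity_ref = modularity_ref, dfc = dfc,
                 synchrony_ref = synchrony_ref,
                 metastability_ref = metastability_ref,
                 per_subject = per_subject),
            class = "reference_summaries")
}

#' Evaluate one parameter set against reference summaries
#'
#' Simulates the model, extracts BOLD-like signals, and computes the five
#' fitting metrics: correlation between simulated and reference static FC,
#' modularity of the simulated FC, Kolmogorov-Smirnov distance between the
#' dFC similarity distributions, and the absolute synchrony and metastability
#' differences. Near-constant (sub-threshold, noise-free) signals or a
#' simulation blow-up flag the bundle as degenerate instead of erroring, so a
#' grid sweep can continue past pathological cells.
#'
#' @param c A `structural_connectome`.
#' @param p A `wbm_parameters` object.
#' @param cfg A `wbm_config` (its seed makes the evaluation deterministic).
#' @param ref A `reference_summaries`.
#' @param partition System identifiers (defaults to the connectome's).
#' @param max_pairs,dfc_seed Passed to [dfc_similarity_distribution()].
#' @param trim Passed to [hilbert_phases()].
#' @return A list (metric bundle) with `fc_corr`, `modularity`, `ks_dfc`,
#'   `synchrony_diff`, `metastability_diff`, `degenerate`.
#' @export
evaluate_point <- function(c, p, cfg, ref, partition = c$partition,
                           max_pairs = 250000L, dfc_seed = 1L, trim = 0.05) {
  degenerate_bundle <- function()
    list(fc_corr = NA_real_, modularity = NA_real_, ks_dfc = NA_real_,
         synchrony_diff = NA_real_, metastability_diff = NA_real_,
         degenerate = TRUE)
  sig <- tryCatch({
    extract_bold(simulate_model(c, p, cfg))
  }, error = function(e) NULL)
  if (is.null(sig)) return(degenerate_bundle())
  if (any(apply(sig$data, 2, stats::sd) < 1e-10)) return(degenerate_bundle())
  fc <- static_fc(sig)
  ph <- hilbert_phases(sig, trim = trim)
  coh <- order_parameter(ph)
  dfc <- dfc_similarity_distribution(ph, max_pairs = max_pairs,
                                     seed = dfc_seed)
  list(fc_corr = fc_similarity(fc, ref$fc),
       modularity = fc_modularity(fc, partition),
       ks_dfc = ks_distance(dfc, ref$dfc),
       synchrony_diff = abs(coh$synchrony - ref$synchrony_ref),
       metastability_diff = abs(coh$metastability - ref$metastability_ref),
       degenerate = FALSE)
}

#' Composite unity-normalized score over a grid of metric bundles
#'
#' Converts each bundle into five distances -- `(1 - fc_corr)/2`,
#' `|modularity - modularity_ref|`, `ks_dfc`, `synchrony_diff`,
#' `metastability_diff` -- unity-normalizes each distance across all grid
#' cells, and averages the five normalized distances. Lower is better. A
#' metric that is identical across the whole grid contributes 0 everywhere;
#' degenerate cells receive the worst (1) normalized distance for every
#' metric.
#'
#' @param bundles List of metric bundles from [evaluate_point()].
#' @param ref The `reference_summaries` the bundles were computed against.
#' @return Numeric vector of per-cell scores in `[0, 1]`.
#' @export
composite_score <- function(bundles, ref) {
  if (length(bundles) < 2L) stop("need at least 2 grid cells")
  d <- cbind(
    fc = vapply(bundles, function(b) (1 - b$fc_corr) / 2, numeric(1)),
    modularity = vapply(bundles, function(b)
      abs(b$modularity - ref$modularity_ref), numeric(1)),
    ks = vapply(bundles, function(b) b$ks_dfc, numeric(1)),
    synchrony = vapply(bundles, function(b) b$synchrony_diff, numeric(1)),
    metastability = vapply(bundles, function(b) b$metastability_diff,
                           numeric(1)))
  norm <- apply(d, 2, function(col) {
    ok <- is.finite(col)
    if (!any(ok)) return(rep(1, length(col)))
    rng <- range(col[ok])
    out <- if (rng[2] == rng[1]) rep(0, length(col))
           else (col - rng[1]) / (rng[2] - rng[1])
    out[!ok] <- 1
    out
  })
  rowMeans(norm)
}

#' Grid-search identification of the model working point
#'
#' Simulates the model at every cell of an `(a, G, lambda, m)` grid with one
#' common seed, scores each cell with the composite unity-normalized distance
#' to the reference summaries, and returns the argmin cell as the fitted
#' working point. Cells are evaluated in deterministic lexicographic order.
#' Two-stage (coarse then fine) searches are obtained by calling this twice
#' with different grids. The reference analysis used a fine grid of 71 values
#' of `a` (-0.07 to 0.07), 15 of `G` (0.002 to 0.03), 5 of `lambda` (0.2 to
#' 1) and 11 of `m` (0.1 to 0.2); desk-scale grids are much smaller.
#'
#' @param c A `structural_connectome`.
#' @param cfg A `wbm_config`; `seed` (or the `seed` argument) is used for
#'   every cell so that cell differences are attributable to parameters, not
#'   noise realizations.
#' @param ref A `reference_summaries`.
#' @param grid Named list with numeric vectors `a`, `G`, `lam`, `m`.
#' @param omega0 Per-node intrinsic angular frequency (rad/s) used at every
#'   cell (estimate with [estimate_intrinsic_frequencies()]).
#' @param partition System identifiers (defaults to the connectome's).
#' @param beta Noise amplitude used at every cell.
#' @param seed Optional override of `cfg$seed`.
#' @param scale_omega0_by_lambda If `TRUE`, each cell uses
#'   `omega0 * lam` so the post-relaxation free-running frequency
#'   `omega0 * lam / lam` equals the supplied spectral peak; by default the
#'   supplied `omega0` enters the frequency drive verbatim.
#' @param n_reps Stochastic realizations averaged per cell (default 1, with
#'   sub-seeds derived from the common seed).
#' @param ... Passed to [evaluate_point()].
#' @return An object of class `wbm_fit`; see [print.wbm_fit()],
#'   [summary.wbm_fit()], [coef.wbm_fit()], [plot.wbm_fit()].
#' @export
fit_working_point <- function(c, cfg, ref, grid, omega0,
                              partition = c$partition, beta = 0.02,
                              seed = NULL, scale_omega0_by_lambda = FALSE,
                              n_reps = 1L, ...) {
  stopifnot(inherits(c, "structural_connectome"),
            inherits(cfg, "wbm_config"),
            inherits(ref, "reference_summaries"))
  for (ax in c("a", "G", "lam", "m"))
    if (is.null(grid[[ax]]) || length(grid[[ax]]) == 0L)
      stop("grid axis `", ax, "` is empty")
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cells <- expand.grid(a = grid$a, G = grid$G, lam = grid$lam, m = grid$m,
                       KEEP.OUT.ATTRS = FALSE)
  n <- nrow(c$weights)
  bundles <- vector("list", nrow(cells))
  for (k in seq_len(nrow(cells))) {
    om0 <- if (scale_omega0_by_lambda) omega0 * cells$lam[k] else omega0
    p <- model_parameters(a = cells$a[k], omega0 = om0, G = cells$G[k],
                          lam = cells$lam[k], m = cells$m[k], beta = beta,
                          n_nodes = n)
    reps <- lapply(seq_len(n_reps), function(r) {
      cfg_r <- cfg
      if (n_reps > 1L) cfg_r$seed <- derive_seed(cfg$seed, r)
      evaluate_point(c, p, cfg_r, ref, partition = partition, ...)
    })
    bundles[[k]] <- average_bundles(reps)
  }
  score <- if (nrow(cells) >= 2L) composite_score(bundles, ref)
           else as.numeric(!vapply(bundles, `[[`, TRUE, "degenerate")) * 0
  best <- which.min(score)
  om0_best <- if (scale_omega0_by_lambda) omega0 * cells$lam[best] else omega0
  best_params <- model_parameters(a = cells$a[best], omega0 = om0_best,
                                  G = cells$G[best], lam = cells$lam[best],
                                  m = cells$m[best], beta = beta,
                                  n_nodes = n)
  structure(list(grid = grid, cells = cells, bundles = bundles,
                 composite = score, optimum = best,
                 best_params = best_params, omega0 = omega0,
                 scale_omega0_by_lambda = scale_omega0_by_lambda,
                 seed = cfg$seed, cfg = cfg, connectome = c,
                 partition = partition, ref = ref, call = match.call()),
            class = "wbm_fit")
}

average_bundles <- function(reps) {
  if (length(reps) == 1L) return(reps[[1]])
  fields <- c("fc_corr", "modularity", "ks_dfc", "synchrony_diff",
              "metastability_diff")
  out <- lapply(fields, function(f)
    mean(vapply(reps, `[[`, numeric(1), f), na.rm = FALSE))
  names(out) <- fields
  out$degenerate <- any(vapply(reps, `[[`, TRUE, "degenerate"))
  out
}

#' @export
print.wbm_fit <- function(x, ...) {
  b <- x$cells[x$optimum, ]
  cat("Whole-brain model working point (grid search over ",
      nrow(x$cells), " cells, seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  a = %g, G = %g, lambda = %g, m = %g  (composite score %.4f)\n",
              b$a, b$G, b$lam, b$m, x$composite[x$optimum]))
  invisible(x)
}

#' @export
coef.wbm_fit <- function(object, ...) {
  b <- object$cells[object$optimum, ]
  c(a = b$a, G = b$G, lam = b$lam, m = b$m)
}

#' @export
summary.wbm_fit <- function(object, ...) {
  b <- object$bundles[[object$optimum]]
  structure(list(fit = object, best_bundle = b,
                 n_degenerate = sum(vapply(object$bundles, `[[`, TRUE,
                                           "degenerate"))),
            class = "summary.wbm_fit")
}

#' @export
print.summary.wbm_fit <- function(x, ...) {
  print(x$fit)
  b <- x$best_bundle
  cat(sprintf(paste0("  at optimum: FC corr %.3f, modularity %.3f, KS(dFC)",
                     " %.3f,\n              |d synchrony| %.4f,",
                     " |d metastability| %.4f\n"),
              b$fc_corr, b$modularity, b$ks_dfc, b$synchrony_diff,
              b$metastability_diff))
  if (x$n_degenerate > 0)
    cat("  ", x$n_degenerate, " degenerate grid cell(s)\n", sep = "")
  invisible(x)
}

#' Composite-score landscape over the (a, G) plane
#'
#' Image of the composite score for the grid slice at the fitted `lambda`
#' and `m`, with the optimum marked.
#'
#' @param x A `wbm_fit`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.wbm_fit <- function(x, ...) {
  b <- x$cells[x$optimum, ]
  sl <- x$cells$lam == b$lam & x$cells$m == b$m
  a_vals <- sort(unique(x$cells$a))
  g_vals <- sort(unique(x$cells$G))
  z <- matrix(NA_real_, length(a_vals), length(g_vals))
  idx <- cbind(match(x$cells$a[sl], a_vals), match(x$cells$G[sl], g_vals))
  z[idx] <- x$composite[sl]
  graphics::image(a_vals, g_vals, z, xlab = "bifurcation parameter a",
                  ylab = "global coupling G",
                  main = sprintf("composite score (lambda = %g, m = %g)",
                                 b$lam, b$m), ...)
  graphics::points(b$a, b$G, pch = 8, col = "white", cex = 1.5)
  invisible(x)
}

#' Simulate regional signals at the fitted working point
#'
#' @param object A `wbm_fit`.
#' @param nsim Number of simulated runs.
#' @param seed Master seed (defaults to the fit's seed).
#' @param ... Ignored.
#' @return A `regional_signals` object, or a list of them when `nsim > 1`.
#' @export
simulate.wbm_fit <- function(object, nsim = 1, seed = object$seed, ...) {
  runs <- lapply(seq_len(nsim), function(r) {
    cfg <- object$cfg
    cfg$seed <- if (nsim == 1L) as.integer(seed) else derive_seed(seed, r)
    extract_bold(simulate_model(object$connectome, object$best_params, cfg))
  })
  if (nsim == 1L) runs[[1]] else runs
}

#' Per-subject composite scores at a fixed parameter set
#'
#' Recomputes the composite similarity score separately against each
#' subject's signals: the model is simulated once at `p`, and for every
#' subject the five raw distances to that subject's own summaries are
#' averaged (no grid normalization, since there is only one cell). Feeds
#' [aic_compare()].
#'
#' @param c A `structural_connectome`.
#' @param p A `wbm_parameters` (e.g. `fit$best_params`).
#' @param cfg A `wbm_config`.
#' @param subject_signals List of `regional_signals`, one per subject.
#' @param partition System identifiers.
#' @param max_pairs,dfc_seed,trim Passed through to the observables.
#' @return Numeric vector of per-subject scores.
#' @export
per_subject_scores <- function(c, p, cfg, subject_signals,
                               partition = c$partition,
                               max_pairs = 250000L, dfc_seed = 1L,
                               trim = 0.05) {
  sig <- extract_bold(simulate_model(c, p, cfg))
  fc <- static_fc(sig)
  ph <- hilbert_phases(sig, trim = trim)
  coh <- order_parameter(ph)
  dfc <- dfc_similarity_distribution(ph, max_pairs = max_pairs,
                                     seed = dfc_seed)
  q_sim <- fc_modularity(fc, partition)
  vapply(subject_signals, function(s) {
    sfc <- static_fc(s)
    sph <- hilbert_phases(s, trim = trim)
    scoh <- order_parameter(sph)
    sdfc <- dfc_similarity_distribution(sph, max_pairs = max_pairs,
                                        seed = dfc_seed)
    mean(c((1 - fc_similarity(fc, sfc)) / 2,
           abs(q_sim - fc_modularity(sfc, partition)),
           ks_distance(dfc, sdfc),
           abs(coh$synchrony - scoh$synchrony),
           abs(coh$metastability - scoh$metastability)))
  }, numeric(1))
}

#' AIC comparison of two models from per-subject score samples
#'
#' Fits a Gaussian by maximum likelihood (MLE mean and variance) to each
#' model's per-subject composite scores, computes the maximized
#' log-likelihood, and returns `AIC = 2k - 2 log L` for both models together
#' with their difference. Used to compare the adaptive frequency-modulated
#' model (k = 4 parameters) with the classic coupled Stuart-Landau model
#' (`m = 0`, k = 2).
#'
#' @param scores_a,scores_b Numeric score samples (>= 2 each).
#' @param k_a,k_b Parameter counts of the two models.
#' @return List with `aic_a`, `aic_b`, `delta` (= `aic_a - aic_b`),
#'   `loglik_a`, `loglik_b`.
#' @export
aic_compare <- function(scores_a, k_a, scores_b, k_b) {
  ll <- function(x) {
    n <- length(x)
    if (n < 2L) stop("need at least 2 scores per model")
    s2 <- mean((x - mean(x))^2)
    if (s2 == 0) stop("zero-variance score sample")
    -n / 2 * log(2 * pi * s2) - n / 2
  }
  la <- ll(scores_a); lb <- ll(scores_b)
  list(aic_a = 2 * k_a - 2 * la, aic_b = 2 * k_b - 2 * lb,
       delta = (2 * k_a - 2 * la) - (2 * k_b - 2 * lb),
       loglik_a = la, loglik_b = lb)
}
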