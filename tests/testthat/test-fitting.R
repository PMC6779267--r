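# A small self-contained study used by several fitting tests: signals
# generated by the model itself, so the fitting target is known exactly.
fit_fixture <- function(seed = 5, beta = 0, n_subjects = 1) {
  spec <- synthetic_study_spec(n_nodes = 12, n_subjects = n_subjects,
                               n_systems = 2, n_timepoints = 180,
                               signal_noise = 0, dt = 0.02, burn_in = 15,
                               params = list(a = 0.04, G = 0.01, lam = 0.4,
                                             m = 0.14, beta = beta),
                               seed = seed)
  study <- generate_reference_study(spec)
  list(study = study,
       ref = make_reference_summaries(study$signals, study$partition),
       cfg = simulation_config(dt = 0.02, tr = 0.72, n_samples = 180,
                               burn_in = 15,
                               seed = derive_seed(seed, 101L)))
}

test_that("evaluating against summaries of the identical run gives perfect scores", {
  c6 <- random_connectome(6, seed = 2)
  p <- model_parameters(a = 0.04, omega0 = 0.3, G = 0.02, lam = 0.4,
                        m = 0.14, beta = 0.02, n_nodes = 6)
  cfg <- tiny_cfg(seed = 9, n_samples = 150)
  sig <- extract_bold(simulate_model(c6, p, cfg))
  fc <- static_fc(sig)
  ph <- hilbert_phases(sig)
  coh <- order_parameter(ph)
  ref <- reference_summaries(fc, fc_modularity(fc, c6$partition),
                             dfc_similarity_distribution(ph),
                             coh$synchrony, coh$metastability)
  b <- evaluate_point(c6, p, cfg, ref, partition = c6$partition)
  expect_false(b$degenerate)
  expect_equal(b$fc_corr, 1)
  expect_equal(b$ks_dfc, 0)
  expect_equal(b$synchrony_diff, 0)
  expect_equal(b$metastability_diff, 0)
  # deterministic across repeated calls
  expect_identical(b, evaluate_point(c6, p, cfg, ref,
                                     partition = c6$partition))
})

test_that("sub-threshold noise-free cells are flagged degenerate, not fatal", {
  c4 <- random_connectome(4, seed = 3)
  p_dead <- model_parameters(a = -1, omega0 = 0.3, G = 0, lam = 0.4, m = 0,
                             beta = 0, n_nodes = 4)
  ref <- local({
    p <- model_parameters(a = 0.04, omega0 = 0.3, G = 0.01, lam = 0.4,
                          m = 0.14, beta = 0.02, n_nodes = 4)
    sig <- extract_bold(simulate_model(c4, p, tiny_cfg(seed = 1,
                                                       n_samples = 120)))
    ph <- hilbert_phases(sig)
    coh <- order_parameter(ph)
    reference_summaries(static_fc(sig), 0.1,
                        dfc_similarity_distribution(ph), coh$synchrony,
                        coh$metastability)
  })
  # by 40 s of burn-in the noise-free sub-threshold state has decayed to
  # numerically constant signals
  b <- evaluate_point(c4, p_dead,
                      tiny_cfg(seed = 1, n_samples = 120, burn_in = 40), ref)
  expect_true(b$degenerate)
})

test_that("composite score unity-normalizes each distance over the grid", {
  mkb <- function(fc_corr, q, ks, ds, dm)
    list(fc_corr = fc_corr, modularity = q, ks_dfc = ks,
         synchrony_diff = ds, metastability_diff = dm, degenerate = FALSE)
  ref <- list(modularity_ref = 0.3)
  # a cell attaining every minimum scores 0; every maximum scores 1
  b <- list(mkb(1, 0.3, 0, 0, 0), mkb(0, 0.8, 0.4, 0.2, 0.1))
  expect_equal(composite_score(b, ref), c(0, 1))
  # a constant metric contributes zero everywhere (so the worst cell of the
  # remaining four distances scores 4/5)
  b2 <- list(mkb(0.5, 0.3, 0, 0, 0), mkb(0.5, 0.8, 0.4, 0.2, 0.1))
  expect_equal(composite_score(b2, ref), c(0, 0.8))
  # degenerate cells get the worst distance on every metric
  b3 <- list(mkb(1, 0.3, 0, 0, 0), mkb(0.9, 0.35, 0.1, 0.01, 0.01),
             list(fc_corr = NA_real_, modularity = NA_real_,
                  ks_dfc = NA_real_, synchrony_diff = NA_real_,
                  metastability_diff = NA_real_, degenerate = TRUE))
  sc <- composite_score(b3, ref)
  expect_equal(sc[3], 1)
  expect_true(sc[1] < sc[2])
  # invariant under monotone rescaling of one distance preserving min & max
  b4 <- list(mkb(1, 0.3, 0, 0, 0), mkb(0.5, 0.3, 0.2, 0, 0),
             mkb(0, 0.3, 0.4, 0, 0))
  b5 <- b4
  b5[[2]]$ks_dfc <- 0.2   # already min-max preserving (identity case)
  expect_equal(composite_score(b4, ref), composite_score(b5, ref))
})

test_that("a single-cell grid is trivially optimal and the fit object is coherent", {
  fx <- fit_fixture(seed = 3)
  om <- fx$study$ground_truth$omega0
  fit <- fit_working_point(fx$study$connectome, fx$cfg, fx$ref,
                           grid = list(a = 0.04, G = 0.01, lam = 0.4,
                                       m = 0.14),
                           omega0 = om, beta = 0)
  expect_s3_class(fit, "wbm_fit")
  expect_equal(fit$optimum, 1L)
  expect_equal(unname(coef(fit)), c(0.04, 0.01, 0.4, 0.14))
  expect_output(print(fit), "working point")
  expect_output(print(summary(fit)), "FC corr")
  sim <- simulate(fit)
  expect_s3_class(sim, "regional_signals")
})

test_that("grid search recovers the generating parameters on a grid containing them", {
  fx <- fit_fixture(seed = 5, beta = 0)
  om <- fx$study$ground_truth$omega0
  grid <- list(a = c(0.01, 0.04, 0.07), G = c(0.002, 0.01, 0.03),
               lam = 0.4, m = 0.14)
  fit <- fit_working_point(fx$study$connectome, fx$cfg, fx$ref, grid, om,
                           beta = 0)
  expect_equal(unname(coef(fit)[c("a", "G")]), c(0.04, 0.01))
  expect_equal(nrow(fit$cells), 9L)
  # deterministic under the same seed
  fit2 <- fit_working_point(fx$study$connectome, fx$cfg, fx$ref, grid, om,
                            beta = 0)
  expect_identical(fit$composite, fit2$composite)
})

test_that("AIC comparison uses the Gaussian MLE likelihood", {
  res <- aic_compare(c(0, 0.2), k_a = 4, c(0, 0.2), k_b = 4)
  expect_equal(res$loglik_a, 1.7672, tolerance = 1e-4)
  expect_equal(res$aic_a, 4.4657, tolerance = 1e-3)
  # identical samples with different k differ by 2 * delta_k
  s <- c(0.1, 0.25, 0.4)
  res2 <- aic_compare(s, 4, s, 2)
  expect_equal(res2$delta, 4)
  # location invariance
  res3 <- aic_compare(s + 0.5, 4, s, 4)
  expect_equal(res3$delta, 0, tolerance = 1e-12)
  expect_error(aic_compare(c(0.1, 0.1, 0.1), 4, s, 2), "variance")
  expect_error(aic_compare(0.1, 4, s, 2), "at least 2")
})

test_that("per-subject scores feed the adaptive-vs-classic AIC comparison", {
  fx <- fit_fixture(seed = 7, beta = 0.02, n_subjects = 4)
  p_opt <- model_parameters(a = 0.04, omega0 = fx$study$ground_truth$omega0,
                            G = 0.01, lam = 0.4, m = 0.14, beta = 0.02,
                            n_nodes = 12)
  s_adapt <- per_subject_scores(fx$study$connectome, p_opt, fx$cfg,
                                fx$study$signals,
                                partition = fx$study$partition)
  expect_length(s_adapt, 4)
  expect_true(all(is.finite(s_adapt) & s_adapt >= 0))
  p_classic <- model_parameters(a = 0.04,
                                omega0 = fx$study$ground_truth$omega0,
                                G = 0.01, lam = 0.4, m = 0, beta = 0.02,
                                n_nodes = 12)
  s_classic <- per_subject_scores(fx$study$connectome, p_classic, fx$cfg,
                                  fx$study$signals,
                                  partition = fx$study$partition)
  res <- aic_compare(s_adapt, 4, s_classic, 2)
  expect_true(is.finite(res$delta))
})
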