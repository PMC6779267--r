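# Small oscillatory system reused by the suite tests.
lesion_fixture <- function(seed = 3, n = 6) {
  c6 <- random_connectome(n, seed = 11, density = 0.7)
  p <- model_parameters(a = 0.04, omega0 = seq(0.2, 0.4, length.out = n),
                        G = 0.02, lam = 0.4, m = 0.14, beta = 0.02,
                        n_nodes = n)
  list(c = c6, p = p, cfg = tiny_cfg(seed = seed, n_samples = 150))
}

# Hand-built ensemble with prescribed FC matrices and phase summaries, for
# the vulnerability/hazard arithmetic checks.
fake_ensemble <- function(fcs, synchrony, metastability,
                          dfc = replicate(length(fcs),
                                          c(0.2, 0.5, 0.8),
                                          simplify = FALSE),
                          partition = NULL) {
  n <- nrow(fcs[[1]])
  if (is.null(partition)) partition <- rep(c("A", "B"), length.out = n)
  sets <- lapply(seq_along(fcs), function(k)
    list(fc = fc_from_matrix(fcs[[k]]),
         dfc = structure(list(samples = dfc[[k]]),
                         class = "similarity_distribution"),
         synchrony = synchrony[k], metastability = metastability[k],
         mean_amplitude = rep(0.1, n)))
  structure(list(baseline = sets[[1]], lesions = sets[-1],
                 targets = seq_len(length(fcs) - 1L), a_lesion = -2,
                 seed = 1L, partition = partition,
                 labels = sprintf("R%03d", seq_len(n))),
            class = "perturbation_ensemble")
}

test_that("the suite produces one baseline plus one summary set per region", {
  fx <- lesion_fixture()
  ens <- run_perturbation_suite(fx$c, fx$p, fx$cfg)
  expect_s3_class(ens, "perturbation_ensemble")
  expect_length(ens$lesions, 6)
  expect_named(ens$lesions, fx$c$labels)
  expect_s3_class(ens$baseline$fc, "static_fc")
  expect_error(run_perturbation_suite(fx$c, apply_perturbation(fx$p, 1, -1),
                                      fx$cfg), "oscillatory")
})

test_that("a no-op lesion reproduces the baseline bitwise and zeroes all maps", {
  fx <- lesion_fixture()
  ens <- run_perturbation_suite(fx$c, fx$p, fx$cfg, a_lesion = fx$p$a[1],
                                targets = c(2L, 4L))
  for (l in ens$lesions) {
    expect_identical(l$fc$values, ens$baseline$fc$values)
    expect_identical(l$synchrony, ens$baseline$synchrony)
  }
  nv <- nodal_vulnerability(ens)
  expect_equal(unname(nv$nodal_hyper), rep(0, 6))
  expect_equal(unname(nv$nodal_hypo), rep(0, 6))
  lv <- link_vulnerability(ens)
  expect_true(all(lv$link_hyper == 0 | is.na(lv$link_hyper)))
  suppressWarnings(hm <- hazard_map(ens, n_null = 3, seed = 2))
  expect_equal(unname(hm$static_distance), rep(0, 2))
  expect_equal(unname(hm$phase_distance), rep(0, 2))
  expect_equal(unname(hm$hazard), rep(0, 2))
})

test_that("lesioning shrinks the targeted region's oscillation amplitude", {
  fx <- lesion_fixture()
  wins <- 0L
  for (s in 1:5) {
    cfg <- tiny_cfg(seed = 100 + s, n_samples = 150)
    ens <- run_perturbation_suite(fx$c, fx$p, cfg, targets = 3L)
    amp_lesion <- ens$lesions[[1]]$mean_amplitude[3]
    amp_base <- ens$baseline$mean_amplitude[3]
    wins <- wins + (amp_lesion < amp_base)
  }
  expect_gte(wins, 4L)
})

test_that("nodal vulnerability averages signed relative strength changes", {
  base <- matrix(0.5, 3, 3); diag(base) <- 1       # strengths (1, 1, 1)
  l1 <- base; l1[1, 2] <- l1[2, 1] <- 0.25         # strength 1 -> 0.75
  l2 <- base; l2[1, 3] <- l2[3, 1] <- 0.75         # strength 1 -> 1.25
  l3 <- base; l3[1, 2] <- l3[2, 1] <- 1.0          # strength 1 -> 1.5
  ens <- fake_ensemble(list(base, l1, l2, l3), synchrony = rep(0.5, 4),
                       metastability = rep(0.1, 4))
  nv <- nodal_vulnerability(ens)
  expect_equal(unname(nv$nodal_hypo[1]), -0.25)
  expect_equal(unname(nv$nodal_hyper[1]), mean(c(0.25, 0.5)))
  expect_true(all(nv$nodal_hyper >= 0))
  expect_true(all(nv$nodal_hypo <= 0))
})

test_that("link vulnerability averages signed inter-system FC divergences", {
  mk <- function(between) {
    v <- matrix(0.6, 4, 4)
    v[1:2, 3:4] <- between
    v[3:4, 1:2] <- between
    diag(v) <- 1
    v
  }
  # baseline inter-system FC 0.4; scenarios 0.48 (+0.2), 0.36 (-0.1),
  # 0.56 (+0.4)
  ens <- fake_ensemble(list(mk(0.4), mk(0.48), mk(0.36), mk(0.56)),
                       synchrony = rep(0.5, 4),
                       metastability = rep(0.1, 4),
                       partition = c("A", "A", "B", "B"))
  lv <- link_vulnerability(ens)
  expect_equal(lv$link_hyper["A", "B"], mean(c(0.2, 0.4)), tolerance = 1e-12)
  expect_equal(lv$link_hypo["A", "B"], -0.1, tolerance = 1e-12)
  expect_equal(lv$link_hyper, t(lv$link_hyper))
  # a single +0.25 divergence
  ens2 <- fake_ensemble(list(mk(0.4), mk(0.5)), synchrony = rep(0.5, 2),
                        metastability = rep(0.1, 2),
                        partition = c("A", "A", "B", "B"))
  expect_equal(link_vulnerability(ens2)$link_hyper["A", "B"], 0.25,
               tolerance = 1e-12)
})

test_that("phase distance composes KS, synchrony and metastability Euclideanly", {
  # identical FC everywhere isolates the phase coordinates; synchrony and
  # metastability are unity-normalized across the sets, so baseline (0, 0),
  # lesion-1 (0.6, 0.8), lesion-2 (1, 1) with zero KS gives the 3-4-5
  # distance 1.0 for lesion 1
  base <- matrix(0.5, 4, 4); diag(base) <- 1
  ens <- fake_ensemble(list(base, base, base),
                       synchrony = c(0, 0.6, 1),
                       metastability = c(0, 0.8, 1))
  suppressWarnings(hm <- hazard_map(ens, n_null = 2, seed = 1))
  expect_equal(unname(hm$phase_distance[1]), 1.0, tolerance = 1e-12)
  expect_equal(unname(hm$phase_distance[2]), sqrt(2), tolerance = 1e-12)
  expect_equal(unname(hm$static_distance), c(0, 0))
  # two-point unity normalization of the distances over lesions
  expect_equal(unname(hm$hazard), c(0, 1))
})

test_that("hazard map distances are computed end-to-end on simulated lesions", {
  fx <- lesion_fixture(n = 8)
  ens <- run_perturbation_suite(fx$c, fx$p, fx$cfg)
  suppressWarnings(hm <- hazard_map(ens, threshold = 0.08, n_null = 3,
                                    seed = 4))
  expect_length(hm$hazard, 8)
  expect_true(all(hm$hazard >= 0 & hm$hazard <= 2))
  expect_true(all(hm$static_distance >= 0))
  expect_equal(ncol(hm$static_features), 1 + 2 * 2)  # 2 systems
  expect_equal(nrow(hm$static_features), 9)
})

test_that("hazard-centrality association reports FDR-corrected correlations", {
  fx <- lesion_fixture(n = 8)
  ct <- structural_centralities(fx$c)
  hm <- structure(list(hazard = setNames(ct$strength, ct$label)),
                  class = "hazard_map")
  res <- hazard_centrality_association(hm, ct)
  expect_equal(nrow(res), 4)
  expect_equal(res$r[res$measure == "strength"], 1, tolerance = 1e-12)
  expect_equal(res$p_fdr, stats::p.adjust(res$p, "BH"))
  hm0 <- structure(list(hazard = setNames(rep(1, 8), ct$label)),
                   class = "hazard_map")
  expect_error(hazard_centrality_association(hm0, ct), "constant")
})

test_that("robustness curves start at one and are reproducible", {
  fx <- lesion_fixture()
  cv <- robustness_curves(fx$c, fx$p, fx$cfg, "random",
                          f_grid = c(0, 0.3, 0.6), threshold = 0.2,
                          n_rep = 2, seed = 9)
  expect_equal(cv$fraction_in_giant[1], 1)
  expect_true(all(cv$fraction_in_giant >= 0 & cv$fraction_in_giant <= 1))
  cv2 <- robustness_curves(fx$c, fx$p, fx$cfg, "random",
                           f_grid = c(0, 0.3, 0.6), threshold = 0.2,
                           n_rep = 2, seed = 9)
  expect_identical(cv$fraction_in_giant, cv2$fraction_in_giant)
  ct <- robustness_curves(fx$c, fx$p, fx$cfg, "targeted",
                          f_grid = c(0, 0.5), threshold = 0.2, seed = 9)
  expect_equal(ct$fraction_in_giant[1], 1)
  expect_error(robustness_curves(fx$c, fx$p, fx$cfg, "random",
                                 f_grid = c(0, 2)), "f_grid")
})
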