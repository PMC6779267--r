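#' Run the single-node in silico perturbation suite
#'
#' Simulates the unperturbed model once and then once per region with that
#' region's bifurcation parameter set to `a_lesion` (default -2, shifting it
#' from the oscillatory domain into noise-driven fluctuations). All lesion
#' simulations reuse the baseline's noise seed by default, so every
#' difference from baseline is attributable to the lesion rather than to the
#' noise realization. For each of the N+1 runs the suite stores the static
#' FC, the dFC similarity distribution, and the synchrony / metastability of
#' the instantaneous phases, plus the mean oscillation amplitude per region.
#'
#' @param c A `structural_connectome`.
#' @param p_opt Baseline `wbm_parameters`; all `a` must be positive
#'   (oscillatory baseline).
#' @param cfg A `wbm_config`.
#' @param partition System identifiers (defaults to the connectome's).
#' @param a_lesion Lesion bifurcation parameter.
#' @param targets Regions to lesion (default: every region once).
#' @param independent_seeds If `TRUE`, each lesion run gets its own derived
#'   seed instead of reusing the baseline seed.
#' @param max_pairs,dfc_seed,trim Passed through to the observables.
#' @return An object of class `perturbation_ensemble` with elements
#'   `baseline`, `lesions` (one summary set per target), `targets`,
#'   `a_lesion`, `seed`, `partition`, `labels`.
#' @export
run_perturbation_suite <- function(c, p_opt, cfg, partition = c$partition,
                                   a_lesion = -2,
                                   targets = seq_len(nrow(c$weights)),
                                   independent_seeds = FALSE,
                                   max_pairs = 250000L, dfc_seed = 1L,
                                   trim = 0.05) {
  stopifnot(inherits(c, "structural_connectome"),
            inherits(p_opt, "wbm_parameters"), inherits(cfg, "wbm_config"))
  if (any(p_opt$a <= 0))
    stop("baseline must be oscillatory: all `a` must be > 0")
  summarize <- function(cfg_k, p_k, target) {
    sig <- tryCatch(extract_bold(simulate_model(c, p_k, cfg_k)),
                    error = function(e)
                      stop("simulation failed for lesion target ",
                           if (is.null(target)) "baseline" else target,
                           ": ", conditionMessage(e)))
    ph <- hilbert_phases(sig, trim = trim)
    coh <- order_parameter(ph)
    list(fc = static_fc(sig),
         dfc = dfc_similarity_distribution(ph, max_pairs = max_pairs,
                                           seed = dfc_seed),
         synchrony = coh$synchrony, metastability = coh$metastability,
         mean_amplitude = colMeans(abs(sig$data)))
  }
  baseline <- summarize(cfg, p_opt, NULL)
  lesions <- vector("list", length(targets))
  for (k in seq_along(targets)) {
    cfg_k <- cfg
    if (independent_seeds) cfg_k$seed <- derive_seed(cfg$seed, k)
    lesions[[k]] <- summarize(cfg_k,
                              apply_perturbation(p_opt, targets[k], a_lesion),
                              targets[k])
  }
  names(lesions) <- c$labels[targets]
  structure(list(baseline = baseline, lesions = lesions, targets = targets,
                 a_lesion = a_lesion, seed = cfg$seed,
                 partition = partition, labels = c$labels),
            class = "perturbation_ensemble")
}

#' @export
print.perturbation_ensemble <- function(x, ...) {
  cat("Perturbation ensemble: baseline + ", length(x$lesions),
      " single-node lesions (a_lesion = ", x$a_lesion, ", seed ", x$seed,
      ")\n", sep = "")
  invisible(x)
}

fc_strength <- function(fc) rowSums(fc$values) - diag(fc$values)

#' Nodal vulnerability maps
#'
#' For every lesion scenario, the relative change of each region's FC
#' strength (row sum of the static FC, diagonal excluded) from baseline:
#' `(strength_lesion - strength_base) / strength_base`. Per region, the mean
#' of the positive relative changes across scenarios is the nodal
#' hyper-connectivity risk and the mean of the negative changes the nodal
#' hypo-connectivity risk (0 when a region has no change of that sign).
#'
#' @param e A `perturbation_ensemble`.
#' @return List with `nodal_hyper` (>= 0), `nodal_hypo` (<= 0), and the
#'   `relative_changes` matrix (scenario x region).
#' @export
nodal_vulnerability <- function(e) {
  stopifnot(inherits(e, "perturbation_ensemble"))
  s0 <- fc_strength(e$baseline$fc)
  if (any(s0 == 0)) stop("zero baseline strength for region(s): ",
                         paste(e$labels[s0 == 0], collapse = ", "))
  rel <- t(vapply(e$lesions, function(l) (fc_strength(l$fc) - s0) / s0,
                  numeric(length(s0))))
  signed_mean <- function(x, pos) {
    v <- if (pos) x[x > 0] else x[x < 0]
    if (length(v) == 0L) 0 else mean(v)
  }
  list(nodal_hyper = stats::setNames(apply(rel, 2, signed_mean, pos = TRUE),
                                     e$labels),
       nodal_hypo = stats::setNames(apply(rel, 2, signed_mean, pos = FALSE),
                                    e$labels),
       relative_changes = rel)
}

inter_system_fc <- function(fc, partition) {
  systems <- sort(unique(partition))
  s <- length(systems)
  out <- matrix(NA_real_, s, s, dimnames = list(systems, systems))
  v <- fc$values
  for (i in seq_len(s)) for (j in i:s) {
    ai <- which(partition == systems[i])
    aj <- which(partition == systems[j])
    out[i, j] <- out[j, i] <- if (i == j) {
      blk <- v[ai, ai, drop = FALSE]
      mean(blk[upper.tri(blk)])
    } else mean(v[ai, aj, drop = FALSE])
  }
  out
}

#' Inter-system link vulnerability maps
#'
#' Per lesion scenario, the inter-system FC matrix (mean FC over node pairs
#' spanning each pair of functional systems; the diagonal holds the
#' within-system mean) is compared with the baseline's:
#' `(lesion - base) / base` elementwise. Link hyper-/hypo-connectivity risks
#' are the elementwise means of the positive / negative divergences across
#' scenarios. Entries with baseline inter-system FC of 0 are undefined
#' (`NA`).
#'
#' @param e A `perturbation_ensemble`.
#' @param partition System identifiers (defaults to the ensemble's); >= 2
#'   systems required.
#' @return List with symmetric S x S matrices `link_hyper`, `link_hypo`.
#' @export
link_vulnerability <- function(e, partition = e$partition) {
  stopifnot(inherits(e, "perturbation_ensemble"))
  if (length(unique(partition)) < 2L) stop("need at least 2 systems")
  base <- inter_system_fc(e$baseline$fc, partition)
  divs <- lapply(e$lesions, function(l)
    (inter_system_fc(l$fc, partition) - base) / base)
  undef <- base == 0
  signed_mean_mat <- function(pos) {
    out <- base * 0
    for (i in seq_len(nrow(base))) for (j in seq_len(ncol(base))) {
      v <- vapply(divs, function(d) d[i, j], numeric(1))
      v <- if (pos) v[v > 0 & is.finite(v)] else v[v < 0 & is.finite(v)]
      out[i, j] <- if (length(v) == 0L) 0 else mean(v)
    }
    out[undef] <- NA_real_
    out
  }
  list(link_hyper = signed_mean_mat(TRUE), link_hypo = signed_mean_mat(FALSE))
}

#' Feature-space hazardousness map
#'
#' Builds, for the baseline and every lesion set, a static feature vector --
#' null-normalized global efficiency, per-system null-normalized local
#' efficiency, and per-system segregation of the binarized static FC (13
#' features with 6 systems) -- and a phase feature pair (synchrony,
#' metastability). Each feature is unity-normalized across the N+1 sets
#' (undefined segregation values are imputed with the across-set median
#' first). Each lesion's static distance is the Euclidean distance of its
#' static vector from the baseline's; its phase distance is Euclidean over
#' (dFC, synchrony, metastability) where the dFC coordinate difference is the
#' Kolmogorov-Smirnov distance between the lesion's and the baseline's dFC
#' similarity distributions, entering directly. The two distance vectors are
#' unity-normalized across the lesions and summed into the hazard score.
#' A region with a high hazard score diverges strongly from the healthy
#' network profile when lesioned, i.e. has low fault tolerance.
#'
#' @param e A `perturbation_ensemble`.
#' @param partition System identifiers (defaults to the ensemble's).
#' @param threshold Absolute binarization threshold for the efficiency
#'   features (default 0.08, the liberal threshold).
#' @param n_null Null-model realizations per efficiency measure.
#' @param seed Seed for the degree-preserving null models.
#' @return An object of class `hazard_map`: list with per-lesion
#'   `static_distance`, `phase_distance`, `hazard` (in `[0, 2]`), plus the
#'   raw `static_features` matrix ((N+1) x 13) and `phase_features`.
#' @export
hazard_map <- function(e, partition = e$partition, threshold = 0.08,
                       n_null = 20L, seed = 1L) {
  stopifnot(inherits(e, "perturbation_ensemble"))
  sets <- c(list(e$baseline), e$lesions)
  systems <- sort(unique(partition))
  # one null-model seed per feature, shared across all sets, so identical FC
  # matrices always produce identical features (exact-zero self-comparison)
  static_features <- t(vapply(seq_along(sets), function(k) {
    fc <- sets[[k]]$fc
    bg <- threshold_binarize(fc, threshold)
    ge <- normalize_by_null(bg, "global_efficiency", n_null = n_null,
                            seed = derive_seed(seed, 1L))
    le <- vapply(seq_along(systems), function(si)
      normalize_by_null(bg, "local_efficiency", n_null = n_null,
                        seed = derive_seed(seed, 1L + si),
                        nodes = which(partition == systems[si])),
      numeric(1))
    seg <- system_segregation(fc, partition)[systems]
    c(global_efficiency = ge,
      stats::setNames(le, paste0("local_eff.", systems)),
      stats::setNames(seg, paste0("segregation.", systems)))
  }, numeric(1 + 2 * length(systems))))
  # impute undefined segregation entries with the across-set median
  for (j in seq_len(ncol(static_features))) {
    bad <- !is.finite(static_features[, j])
    if (any(bad)) {
      message("imputing ", sum(bad), " undefined value(s) of feature ",
              colnames(static_features)[j], " with the across-set median")
      static_features[bad, j] <-
        stats::median(static_features[!bad, j])
    }
  }
  static_norm <- apply(static_features, 2, unity_normalize)
  synchrony <- unity_normalize(vapply(sets, `[[`, numeric(1), "synchrony"))
  metastability <- unity_normalize(vapply(sets, `[[`, numeric(1),
                                          "metastability"))
  ks_dfc <- c(0, vapply(e$lesions, function(l)
    ks_distance(l$dfc, e$baseline$dfc), numeric(1)))

  li <- seq_along(e$lesions) + 1L
  static_distance <- sqrt(rowSums(
    (static_norm[li, , drop = FALSE] -
       matrix(static_norm[1, ], length(li), ncol(static_norm),
              byrow = TRUE))^2))
  phase_distance <- sqrt(ks_dfc[li]^2 +
                           (synchrony[li] - synchrony[1])^2 +
                           (metastability[li] - metastability[1])^2)
  hazard <- unity_normalize(static_distance) + unity_normalize(phase_distance)
  nm <- names(e$lesions)
  structure(list(static_distance = stats::setNames(static_distance, nm),
                 phase_distance = stats::setNames(phase_distance, nm),
                 hazard = stats::setNames(hazard, nm),
                 static_features = static_features,
                 phase_features = cbind(synchrony = synchrony,
                                        metastability = metastability,
                                        ks_dfc = ks_dfc)),
            class = "hazard_map")
}

#' @export
print.hazard_map <- function(x, ...) {
  top <- names(sort(x$hazard, decreasing = TRUE))[seq_len(min(3, length(x$hazard)))]
  cat("Hazard map over ", length(x$hazard), " lesion targets; most hazardous: ",
      paste(top, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Association between hazardousness and structural centrality
#'
#' Product-moment correlation of the hazard score with clustering, degree,
#' strength and local efficiency of the structural connectome, with
#' two-sided p-values and Benjamini-Hochberg FDR correction across the four
#' tests.
#'
#' @param h A `hazard_map` covering every region.
#' @param ct A centrality table from [structural_centralities()] on the same
#'   node set.
#' @return Data frame with columns `measure`, `r`, `p`, `p_fdr`.
#' @export
hazard_centrality_association <- function(h, ct) {
  stopifnot(inherits(h, "hazard_map"), is.data.frame(ct))
  if (length(h$hazard) != nrow(ct))
    stop("hazard map and centrality table cover different node sets")
  if (stats::sd(h$hazard) == 0) stop("constant hazard vector")
  measures <- c("clustering", "degree", "strength", "local_efficiency")
  res <- lapply(measures, function(mname) {
    tst <- stats::cor.test(h$hazard, ct[[mname]], method = "pearson")
    data.frame(measure = mname, r = unname(tst$estimate), p = tst$p.value)
  })
  out <- do.call(rbind, res)
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Robustness curves under random failures versus targeted attacks
#'
#' For each perturbed fraction `f`, lesions `floor(f * N)` regions
#' simultaneously (random: averaged over `n_rep` seeded draws; targeted: in
#' descending structural hub-score order), simulates the whole model,
#' binarizes the resulting static FC at an absolute `threshold`, and records
#' the giant-component size relative to the unperturbed run. Hub order is
#' computed on the structural connectome, never on FC. All simulations reuse
#' the baseline noise seed, so the value at `f = 0` is exactly 1.
#'
#' @param c A `structural_connectome`.
#' @param p_opt Baseline `wbm_parameters`.
#' @param cfg A `wbm_config`.
#' @param strategy `"random"` or `"targeted"`.
#' @param f_grid Fractions in `[0, 1]`.
#' @param threshold Absolute binarization threshold (the reference analysis
#'   used 0.08 as liberal and 0.27 as restrictive).
#' @param n_rep Repetitions for the random strategy (the reference analysis
#'   used 2000; desk-scale default 100).
#' @param seed Master seed for the random node draws.
#' @param a_lesion Lesion bifurcation parameter.
#' @return An object of class `robustness_curve`: list with `f_grid`,
#'   `fraction_in_giant`, `strategy`, `threshold`, `n_rep`.
#' @export
robustness_curves <- function(c, p_opt, cfg,
                              strategy = c("random", "targeted"),
                              f_grid = seq(0, 1, by = 0.1), threshold = 0.08,
                              n_rep = 100L, seed = 1L, a_lesion = -2) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(c, "structural_connectome"),
            inherits(p_opt, "wbm_parameters"), inherits(cfg, "wbm_config"))
  if (any(f_grid < 0 | f_grid > 1)) stop("`f_grid` must lie in [0, 1]")
  if (strategy == "random" && n_rep < 1L) stop("`n_rep` must be >= 1")
  n <- nrow(c$weights)
  giant_abs <- function(targets) {
    p_k <- apply_perturbation(p_opt, targets, a_lesion)
    fc <- static_fc(extract_bold(simulate_model(c, p_k, cfg)))
    comp <- igraph::components(bg_igraph(threshold_binarize(fc, threshold)))
    max(comp$csize)
  }
  g0 <- giant_abs(integer(0))
  hub_order <- order(structural_centralities(c)$hub_score, decreasing = TRUE)
  vals <- vapply(f_grid, function(f) {
    k <- floor(f * n)
    if (k == 0L) return(1)
    if (strategy == "targeted") {
      giant_abs(hub_order[seq_len(k)]) / g0
    } else {
      reps <- vapply(seq_len(n_rep), function(r) {
        seed_rng(derive_seed(seed, r * 1000L + round(f * 100)))
        giant_abs(sample.int(n, k))
      }, numeric(1))
      mean(reps) / g0
    }
  }, numeric(1))
  vals <- pmin(vals, 1)
  structure(list(f_grid = f_grid, fraction_in_giant = vals,
                 strategy = strategy, threshold = threshold,
                 n_rep = if (strategy == "random") n_rep else 1L,
                 seed = seed),
            class = "robustness_curve")
}

#' @export
print.robustness_curve <- function(x, ...) {
  cat("Robustness curve (", x$strategy, " strategy, threshold ", x$threshold,
      ")\n", sep = "")
  print(stats::setNames(round(x$fraction_in_giant, 3), x$f_grid))
  invisible(x)
}

#' @export
plot.robustness_curve <- function(x, ...) {
  graphics::plot(x$f_grid, x$fraction_in_giant, type = "b", ylim = c(0, 1),
                 xlab = "perturbed fraction f",
                 ylab = "relative giant-component size",
                 main = paste0(x$strategy, " (threshold ", x$threshold, ")"),
                 ...)
  invisible(x)
}
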