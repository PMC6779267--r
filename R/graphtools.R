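#' Binary graph container
#'
#' @param adjacency Square 0/1 matrix, symmetric, zero diagonal.
#' @param labels Node identifiers.
#' @return An object of class `binary_graph`.
#' @export
binary_graph <- function(adjacency, labels = NULL) {
  adjacency <- as.matrix(adjacency)
  if (!all(adjacency %in% c(0, 1))) stop("adjacency must be 0/1")
  if (max(abs(adjacency - t(adjacency))) > 0) stop("adjacency must be symmetric")
  diag(adjacency) <- 0
  if (is.null(labels)) labels <- default_labels(nrow(adjacency))
  dimnames(adjacency) <- list(labels, labels)
  structure(list(adjacency = adjacency, labels = labels),
            class = "binary_graph")
}

#' Binarize an FC matrix at an absolute threshold
#'
#' An edge is present iff the FC value is `>= threshold` (diagonal excluded).
#' A fixed absolute threshold, rather than a density-matched one, keeps the
#' classification rule identical across the unperturbed and lesioned FC
#' matrices it is applied to.
#'
#' @param fc A `static_fc` (or plain symmetric matrix).
#' @param threshold Absolute threshold in `[0, 1]`.
#' @return A `binary_graph`.
#' @export
threshold_binarize <- function(fc, threshold) {
  if (threshold < 0 || threshold > 1) stop("`threshold` must be in [0, 1]")
  v <- if (inherits(fc, "static_fc")) fc$values else as.matrix(fc)
  labels <- if (inherits(fc, "static_fc")) fc$labels else colnames(v)
  adj <- (v >= threshold) * 1
  diag(adj) <- 0
  binary_graph(adj, labels)
}

bg_igraph <- function(g)
  igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected",
                                      diag = FALSE)

#' Giant-component fraction
#'
#' Size of the largest connected component of the (undirected) binary graph,
#' divided by the number of nodes. An edgeless graph of N nodes gives 1/N.
#'
#' @param g A `binary_graph`.
#' @return Fraction in `(0, 1]`.
#' @export
giant_component_fraction <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  comp <- igraph::components(bg_igraph(g))
  max(comp$csize) / nrow(g$adjacency)
}

#' Global efficiency of a binary graph
#'
#' Mean over ordered node pairs of the inverse shortest-path length, with 0
#' for unreachable pairs.
#'
#' @param g A `binary_graph` with >= 2 nodes.
#' @return Scalar in `[0, 1]`.
#' @export
global_efficiency <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  n <- nrow(g$adjacency)
  if (n < 2L) stop("need >= 2 nodes")
  d <- igraph::distances(bg_igraph(g))
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Nodal and system-wise local efficiency
#'
#' Per node, the global efficiency of the subgraph induced by its neighbours
#' (0 for nodes with fewer than 2 neighbours). When `nodes` is given, the
#' subset mean is also returned, which yields the system-wise local
#' efficiency when `nodes` is one functional system.
#'
#' @param g A `binary_graph`.
#' @param nodes Optional subset of node indices.
#' @return List with `nodal` (per-node efficiencies) and `subset_mean`.
#' @export
local_efficiency <- function(g, nodes = NULL) {
  stopifnot(inherits(g, "binary_graph"))
  adj <- g$adjacency
  n <- nrow(adj)
  nodal <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) < 2L) return(0)
    global_efficiency(binary_graph(adj[nb, nb, drop = FALSE]))
  }, numeric(1))
  names(nodal) <- g$labels
  if (is.null(nodes)) nodes <- seq_len(n)
  if (length(nodes) == 0L) stop("`nodes` must be nonempty")
  list(nodal = nodal, subset_mean = mean(nodal[nodes]))
}

#' Normalize a graph measure by a degree-preserving null model
#'
#' Divides the observed measure by its mean over `n_null` degree-preserving
#' randomizations (double-edge-swap rewiring). If the graph is too sparse to
#' rewire, the observed value is returned with a warning (ratio 1).
#'
#' @param g A `binary_graph`.
#' @param measure `"global_efficiency"`, or `"local_efficiency"` with `nodes`
#'   giving the system whose mean local efficiency is normalized.
#' @param n_null Number of null realizations (>= 1).
#' @param seed Integer seed.
#' @param nodes Node subset for `measure = "local_efficiency"`.
#' @param swaps_per_edge Double-edge swaps attempted per edge per realization.
#' @return Normalized scalar (observed / null mean).
#' @export
normalize_by_null <- function(g, measure = c("global_efficiency",
                                             "local_efficiency"),
                              n_null = 20L, seed = 1L, nodes = NULL,
                              swaps_per_edge = 10L) {
  stopifnot(inherits(g, "binary_graph"))
  measure <- match.arg(measure)
  if (n_null < 1L) stop("`n_null` must be >= 1")
  eval_measure <- function(bg) {
    if (measure == "global_efficiency") global_efficiency(bg)
    else local_efficiency(bg, nodes)$subset_mean
  }
  obs <- eval_measure(g)
  ig <- bg_igraph(g)
  n_edges <- igraph::ecount(ig)
  if (n_edges < 2L) {
    warning("graph too sparse to rewire; returning 1")
    return(1)
  }
  seed_rng(seed)
  null_vals <- vapply(seq_len(n_null), function(k) {
    rg <- igraph::rewire(ig, igraph::keeping_degseq(
      niter = swaps_per_edge * n_edges))
    adj <- as.matrix(igraph::as_adjacency_matrix(rg, sparse = FALSE))
    eval_measure(binary_graph(adj, g$labels))
  }, numeric(1))
  nm <- mean(null_vals)
  if (nm == 0) {
    warning("null mean is zero; returning 1")
    return(1)
  }
  obs / nm
}

#' System segregation of an FC matrix
#'
#' Per functional system, the within-vs-between contrast
#' `(mean within-system off-diagonal FC - mean FC between that system and all
#' others) / mean within-system FC`. A nonpositive within-system mean makes
#' the measure undefined and is reported as `NA`.
#'
#' @param fc A `static_fc` (or plain symmetric matrix).
#' @param partition System identifier per node; each system needs >= 2 nodes.
#' @return Named numeric vector, one value (or `NA`) per system.
#' @export
system_segregation <- function(fc, partition) {
  v <- if (inherits(fc, "static_fc")) fc$values else as.matrix(fc)
  if (length(partition) != nrow(v)) stop("partition must cover every node")
  systems <- unique(partition)
  out <- stats::setNames(rep(NA_real_, length(systems)), systems)
  for (sys in systems) {
    idx <- which(partition == sys)
    if (length(idx) < 2L) stop("system ", sys, " has fewer than 2 nodes")
    within <- v[idx, idx, drop = FALSE]
    wm <- mean(within[upper.tri(within)])
    bm <- mean(v[idx, -idx, drop = FALSE])
    if (wm <= 0) next
    out[sys] <- (wm - bm) / wm
  }
  out
}

#' Select a binarization threshold against a reference FC
#'
#' Sweeps `n_thresholds` thresholds over `[0, 1]`; at each, both matrices are
#' binarized and the reference edges are treated as ground truth. Accuracy is
#' `(TP + TN) / all pairs`, precision `TP / (TP + FP)` over unordered
#' off-diagonal pairs (thresholds with no positive prediction yield undefined
#' precision and are excluded from the fit). A least-squares cubic polynomial
#' is fitted to precision versus threshold; the report contains the knee of
#' the fitted curve (maximal curvature \eqn{|y''|/(1 + y'^2)^{3/2}}) and the
#' crossing of the accuracy curve with the fitted precision curve (linear
#' interpolation between grid points; ties resolved towards the smaller
#' threshold). The knee marks a restrictive threshold, the intersection a
#' liberal one.
#'
#' @param sim Simulated `static_fc`.
#' @param ref Reference `static_fc` of the same shape.
#' @param n_thresholds Number of thresholds (>= 3, default 100).
#' @return An object of class `threshold_report`: list with `thresholds`,
#'   `accuracy`, `precision`, `cubic_fit` (coefficients, degree 0..3), `knee`,
#'   `knee_at_boundary` flag, `intersection`.
#' @export
select_binarization_threshold <- function(sim, ref, n_thresholds = 100L) {
  stopifnot(inherits(sim, "static_fc"), inherits(ref, "static_fc"))
  if (!all(dim(sim$values) == dim(ref$values))) stop("FC shape mismatch")
  if (n_thresholds < 3L) stop("need at least 3 thresholds")
  thr <- seq(0, 1, length.out = n_thresholds)
  sv <- upper_vals(sim$values)
  rv <- upper_vals(ref$values)
  acc <- prec <- numeric(n_thresholds)
  for (k in seq_along(thr)) {
    ps <- sv >= thr[k]
    pr <- rv >= thr[k]
    tp <- sum(ps & pr); tn <- sum(!ps & !pr)
    fp <- sum(ps & !pr); fn <- sum(!ps & pr)
    acc[k] <- (tp + tn) / length(sv)
    prec[k] <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  }
  ok <- !is.na(prec)
  if (sum(ok) < 4L) stop("too few thresholds with defined precision for a cubic fit")
  fit <- stats::lm(prec[ok] ~ poly(thr[ok], 3, raw = TRUE))
  cf <- unname(stats::coef(fit))
  fitted_prec <- cf[1] + cf[2] * thr + cf[3] * thr^2 + cf[4] * thr^3
  d1 <- cf[2] + 2 * cf[3] * thr + 3 * cf[4] * thr^2
  d2 <- 2 * cf[3] + 6 * cf[4] * thr
  curv <- abs(d2) / (1 + d1^2)^1.5
  dom <- thr >= min(thr[ok]) & thr <= max(thr[ok])
  kink <- which(dom)[which.max(curv[dom])]
  knee <- thr[kink]
  knee_at_boundary <- kink %in% c(which(dom)[1], rev(which(dom))[1]) ||
    max(curv[dom]) < 1e-8
  diffc <- acc - fitted_prec
  intersection <- NA_real_
  for (k in seq_len(n_thresholds - 1L)) {
    if (is.na(diffc[k]) || is.na(diffc[k + 1])) next
    if (diffc[k] == 0) { intersection <- thr[k]; break }
    if (diffc[k] * diffc[k + 1] < 0) {
      intersection <- thr[k] + (thr[k + 1] - thr[k]) *
        abs(diffc[k]) / (abs(diffc[k]) + abs(diffc[k + 1]))
      break
    }
  }
  structure(list(thresholds = thr, accuracy = acc, precision = prec,
                 cubic_fit = cf, knee = knee,
                 knee_at_boundary = knee_at_boundary,
                 intersection = intersection),
            class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, ...) {
  cat("Threshold report over ", length(x$thresholds), " thresholds\n",
      "  knee (restrictive): ", format(x$knee),
      if (x$knee_at_boundary) "  [at grid boundary / degenerate]" else "",
      "\n  accuracy/precision intersection (liberal): ",
      format(x$intersection), "\n", sep = "")
  invisible(x)
}
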