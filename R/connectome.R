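#' Structural connectome object
#'
#' Bundles a symmetric nonnegative weight matrix (e.g. streamline densities)
#' with region labels and a region-to-functional-system partition. The weight
#' matrix sets the coupling strengths of the whole-brain oscillator model and
#' the topology used for structural centrality and hub scoring.
#'
#' @param weights Square numeric matrix, symmetric, zero diagonal, all entries
#'   finite and nonnegative.
#' @param labels Character vector of unique region identifiers; defaults to
#'   `"R001"`, `"R002"`, ...
#' @param partition Character vector assigning each region to a functional
#'   system (e.g. the six systems `DM`, `LIM`, `dATT/CONT`, `SAL/vATT`, `SOM`,
#'   `VIS`); defaults to a single system `"ALL"`.
#' @return An object of class `structural_connectome` with elements `weights`,
#'   `labels`, `partition`.
#' @export
structural_connectome <- function(weights, labels = NULL, partition = NULL) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (n == 0L || ncol(weights) != n)
    stop("`weights` must be a non-empty square matrix")
  if (!all(is.finite(weights)))
    stop("`weights` must be finite everywhere")
  if (any(weights < 0))
    stop("`weights` must be nonnegative")
  asym <- max(abs(weights - t(weights)))
  if (asym > 1e-9)
    stop("`weights` must be symmetric (max asymmetry ", format(asym), ")")
  if (asym > 0) weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  if (is.null(labels)) labels <- default_labels(n)
  labels <- as.character(labels)
  if (length(labels) != n || anyDuplicated(labels))
    stop("`labels` must be ", n, " unique region identifiers")
  if (is.null(partition)) partition <- rep("ALL", n)
  partition <- as.character(partition)
  if (length(partition) != n || anyNA(partition))
    stop("`partition` must assign every region to a system")
  dimnames(weights) <- list(labels, labels)
  structure(list(weights = weights, labels = labels, partition = partition),
            class = "structural_connectome")
}

default_labels <- function(n) sprintf("R%03d", seq_len(n))

#' @export
print.structural_connectome <- function(x, ...) {
  ut <- x$weights[upper.tri(x$weights)]
  cat("Structural connectome: ", length(x$labels), " regions, ",
      sum(ut > 0), " edges (density ",
      formatC(mean(ut > 0), digits = 3, format = "f"), ")\n", sep = "")
  cat("Systems:", paste(sort(unique(x$partition)), collapse = ", "), "\n")
  invisible(x)
}

#' Generate a stack of synthetic subject-level connectomes
#'
#' Emulates tractography-derived subject connectomes: a shared group template
#' with modular topology (within-system edges more probable than
#' between-system) and log-normal positive weights, from which each subject
#' independently loses a `dropout` fraction of edges. This is the structural
#' half of the synthetic study generator; it stands in for diffusion-MRI
#' streamline-density connectomes.
#'
#' @param n_nodes Number of regions (>= 4).
#' @param n_subjects Number of subjects (>= 1).
#' @param n_systems Number of functional systems the template is partitioned
#'   into (contiguous blocks of nodes).
#' @param density Overall edge density of the group template, in (0, 1].
#' @param dropout Fraction of template edges zeroed independently per subject,
#'   in [0, 1).
#' @param seed Integer seed; fixed seed gives bitwise-identical output.
#' @param within_between_ratio Ratio of within- to between-system edge
#'   probability (> 1 gives modular topology).
#' @return A list of class `connectome_stack` with elements `subjects` (list
#'   of symmetric zero-diagonal matrices), `labels`, `partition`, and
#'   `template` (logical template adjacency).
#' @export
generate_subject_connectomes <- function(n_nodes, n_subjects, n_systems = 6L,
                                         density = 0.3, dropout = 0.2,
                                         seed = 1L,
                                         within_between_ratio = 4) {
  if (n_nodes < 4L) stop("`n_nodes` must be >= 4")
  if (n_subjects < 1L) stop("`n_subjects` must be >= 1")
  if (n_systems < 1L || n_systems > n_nodes) stop("invalid `n_systems`")
  if (density <= 0 || density > 1) stop("`density` must be in (0, 1]")
  if (dropout < 0 || dropout >= 1) stop("`dropout` must be in [0, 1)")
  if (within_between_ratio <= 0) stop("`within_between_ratio` must be > 0")

  labels <- default_labels(n_nodes)
  partition <- system_blocks(n_nodes, n_systems)

  seed_rng(seed)
  same <- outer(partition, partition, "==")
  ut <- upper.tri(same)
  n_pairs <- sum(ut)
  # solve per-class probabilities so that expected density is `density`
  # while p_within = ratio * p_between
  nw <- sum(same[ut]); nb <- n_pairs - nw
  p_between <- density * n_pairs / (within_between_ratio * nw + nb)
  p_within <- min(1, within_between_ratio * p_between)
  p_between <- min(1, p_between)
  pmat <- ifelse(same[ut], p_within, p_between)
  edge <- stats::runif(n_pairs) < pmat
  w <- numeric(n_pairs)
  w[edge] <- stats::rlnorm(sum(edge), meanlog = 0, sdlog = 1)

  template <- matrix(0, n_nodes, n_nodes)
  template[upper.tri(template)] <- w
  template <- template + t(template)

  subjects <- vector("list", n_subjects)
  edge_idx <- which(upper.tri(template) & template > 0)
  n_edges <- length(edge_idx)
  n_drop <- floor(dropout * n_edges)
  for (s in seq_len(n_subjects)) {
    m <- template
    # per-subject multiplicative weight jitter keeps edge weights subject-varying
    jit <- stats::rlnorm(n_edges, meanlog = 0, sdlog = 0.2)
    m[edge_idx] <- m[edge_idx] * jit
    if (n_drop > 0) m[edge_idx[sample.int(n_edges, n_drop)]] <- 0
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    dimnames(m) <- list(labels, labels)
    subjects[[s]] <- m
  }
  structure(list(subjects = subjects, labels = labels, partition = partition,
                 template = template > 0),
            class = "connectome_stack")
}

system_blocks <- function(n_nodes, n_systems) {
  sys_names <- c("DM", "LIM", "dATT/CONT", "SAL/vATT", "SOM", "VIS")
  if (n_systems > 6L) sys_names <- c(sys_names, sprintf("SYS%d", 7:n_systems))
  sizes <- diff(round(seq(0, n_nodes, length.out = n_systems + 1L)))
  rep(sys_names[seq_len(n_systems)], times = sizes)
}

#' Build a group-representative connectome with a consistency rule
#'
#' An edge is retained when it is nonzero in at least a `consistency` fraction
#' of subjects (default 60%); its group weight is the mean of that edge's
#' values across all subjects (zeros included, preserving the streamline
#' density scale). All other edges are set to zero.
#'
#' @param stack A `connectome_stack`.
#' @param consistency Required fraction of subjects with a nonzero edge,
#'   in (0, 1].
#' @param partition Optional system assignment for the result; defaults to the
#'   stack's partition.
#' @return A `structural_connectome`.
#' @export
build_group_connectome <- function(stack, consistency = 0.6, partition = NULL) {
  if (!inherits(stack, "connectome_stack") || length(stack$subjects) == 0L)
    stop("`stack` must be a non-empty connectome_stack")
  if (consistency <= 0 || consistency > 1)
    stop("`consistency` must be in (0, 1]")
  n_sub <- length(stack$subjects)
  arr <- simplify2array(stack$subjects)
  mean_w <- apply(arr, c(1, 2), mean)
  frac_nz <- apply(arr != 0, c(1, 2), mean)
  mean_w[frac_nz < consistency] <- 0
  if (is.null(partition)) partition <- stack$partition
  structural_connectome(mean_w, labels = stack$labels, partition = partition)
}

#' Rank-based Gaussian resampling of connectome weights
#'
#' Maps the nonzero undirected edge weights onto Gaussian quantiles: the edge
#' with rank \eqn{k} among \eqn{M} nonzero edges receives weight
#' \eqn{\Phi^{-1}(k/(M+1))\,\sigma + \mu}. Rank order is preserved, ties are
#' broken by the stable (row, column) index order, and zero edges stay zero.
#' With the defaults \eqn{\mu = 0.5}, \eqn{\sigma = 0.15} the nonzero weights
#' follow the normalization conventionally applied to group streamline-density
#' connectomes before coupling them into a dynamical model.
#'
#' @param c A `structural_connectome` with at least one nonzero edge.
#' @param mu Target mean of the resampled nonzero weights.
#' @param sigma Target standard deviation (> 0).
#' @return A `structural_connectome` with resampled weights.
#' @export
gaussian_resample_weights <- function(c, mu = 0.5, sigma = 0.15) {
  stopifnot(inherits(c, "structural_connectome"))
  if (sigma <= 0) stop("`sigma` must be > 0")
  w <- c$weights
  ut <- which(upper.tri(w))
  vals <- w[ut]
  nz <- which(vals > 0)
  m <- length(nz)
  if (m == 0L) stop("connectome has no nonzero edges")
  r <- rank(vals[nz], ties.method = "first")
  new_vals <- stats::qnorm(r / (m + 1)) * sigma + mu
  if (any(new_vals <= 0))
    warning("Gaussian resampling produced nonpositive weights in the extreme tail")
  out <- matrix(0, nrow(w), ncol(w))
  out[ut[nz]] <- new_vals
  out <- out + t(out)
  structural_connectome(out, labels = c$labels, partition = c$partition)
}

#' Structural centrality table and hub score
#'
#' Computes per-region strength, degree, betweenness, closeness, weighted
#' clustering, nodal local efficiency, and the composite hub score (mean of
#' the unity-normalized strength, betweenness and closeness). Path-based
#' measures use edge length 1/weight, the standard transform for
#' streamline-density connectomes; on disconnected graphs closeness is taken
#' over reachable nodes only and unreachable pairs do not contribute to
#' betweenness. Local efficiency is computed on the binary nonzero support.
#'
#' @param c A `structural_connectome`.
#' @return A data.frame (one row per region) with columns `label`, `strength`,
#'   `degree`, `betweenness`, `closeness`, `clustering`, `local_efficiency`,
#'   `hub_score`.
#' @export
structural_centralities <- function(c) {
  stopifnot(inherits(c, "structural_connectome"))
  w <- c$weights
  n <- nrow(w)
  if (n == 0L) stop("empty connectome")
  strength <- rowSums(w)
  degree <- rowSums(w > 0)

  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  ew <- igraph::E(g)$weight
  if (length(ew)) {
    btw <- igraph::betweenness(g, weights = 1 / ew, directed = FALSE)
    d <- igraph::distances(g, weights = 1 / ew)
  } else {
    btw <- numeric(n)
    d <- matrix(Inf, n, n); diag(d) <- 0
  }
  closeness <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    if (length(di) == 0L || mean(di) == 0) 0 else 1 / mean(di)
  }, numeric(1))
  clustering <- igraph::transitivity(g, type = "barrat", isolates = "zero")
  if (length(clustering) != n) clustering <- rep(0, n)  # edgeless graph

  bin <- binary_graph((w > 0) * 1, labels = c$labels)
  local_eff <- local_efficiency(bin)$nodal

  hub <- (unity_normalize(strength) + unity_normalize(btw) +
            unity_normalize(closeness)) / 3
  data.frame(label = c$labels, strength = strength, degree = degree,
             betweenness = btw, closeness = closeness,
             clustering = clustering, local_efficiency = local_eff,
             hub_score = hub, row.names = NULL)
}

#' Unity-based normalization
#'
#' Rescales `x` to `[0, 1]` as `(x - min)/(max - min)`; a degenerate
#' collection (max == min) maps to all zeros.
#'
#' @param x Numeric vector.
#' @return Numeric vector in `[0, 1]`.
#' @export
unity_normalize <- function(x) {
  rng <- range(x)
  if (!all(is.finite(rng)) || rng[2] == rng[1]) return(rep(0, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}
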