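# Spatio-temporal metrics of multi-layer dynamic networks.
#
# Three families: temporal variability (on weighted layers), the temporal
# correlation coefficient (temporal clustering, on binary layers), and
# time-respecting temporal path lengths (temporal efficiency, on binary
# layers).

#' Nodal temporal variability
#'
#' For each node k, collects its connectivity profile per layer (its row of
#' the correlation matrix, excluding the self entry) and computes one minus
#' the mean Pearson correlation between the profiles of all layer pairs:
#' \deqn{V_k = 1 - \frac{2}{T(T-1)} \sum_{t < t'} \mathrm{corr}(p_k(t), p_k(t'))}
#' Values lie in \[0, 2\]: 0 when the profile never changes, 2 when profiles
#' of different windows are perfectly anticorrelated. A constant profile in
#' any layer makes the correlation undefined and is reported as an error.
#'
#' @param net A `weighted_dynnet` with at least 2 layers.
#' @return Named numeric vector of per-node variabilities.
#' @export
nodal_temporal_variability <- function(net) {
  stopifnot(inherits(net, "weighted_dynnet"))
  T_ <- n_layers(net)
  if (T_ < 2L) stop("temporal variability needs at least 2 layers")
  N <- n_nodes(net)
  if (N < 3L) stop("connectivity profiles need at least 3 nodes")
  out <- numeric(N)
  ut <- upper.tri(matrix(0, T_, T_))
  for (k in seq_len(N)) {
    P <- net$layers[k, -k, , drop = TRUE]          # (N-1) x T profiles
    cm <- colMeans(P)
    msq <- colMeans(P * P)
    v <- msq - cm * cm
    if (any(v <= 1e-12 * pmax(msq, 1))) {
      bad <- which(v <= 1e-12 * pmax(msq, 1))[1L]
      stop(sprintf("node %s has a constant connectivity profile in layer %d",
                   net$node_labels[k], bad))
    }
    C <- stats::cor(P)                              # T x T
    out[k] <- 1 - mean(C[ut])
  }
  names(out) <- net$node_labels
  out
}

#' Global temporal variability
#'
#' Unweighted mean of the nodal temporal variabilities.
#'
#' @inheritParams nodal_temporal_variability
#' @param method `"nodal_mean"` (default) averages nodal values;
#'   `"whole_matrix"` instead computes 1 minus the mean correlation between
#'   the vectorized upper triangles of layer pairs.
#' @return A single value in \[0, 2\].
#' @export
global_temporal_variability <- function(net,
                                        method = c("nodal_mean", "whole_matrix")) {
  method <- match.arg(method)
  if (method == "nodal_mean") {
    return(mean(nodal_temporal_variability(net)))
  }
  T_ <- n_layers(net)
  if (T_ < 2L) stop("temporal variability needs at least 2 layers")
  N <- n_nodes(net)
  ut <- upper.tri(matrix(0, N, N))
  P <- vapply(seq_len(T_), function(t) net$layers[, , t][ut],
              numeric(sum(ut)))
  sds <- apply(P, 2L, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("layer %d has a constant upper triangle", which(sds == 0)[1L]))
  }
  C <- stats::cor(P)
  1 - mean(C[upper.tri(C)])
}

#' Nodal temporal correlation coefficient
#'
#' Measures temporal clustering: how consistently each node keeps its
#' neighbors between consecutive layers,
#' \deqn{C_i = \frac{1}{T-1} \sum_{t=1}^{T-1}
#'   \frac{\sum_j a_{ij}(t) a_{ij}(t+1)}
#'        {\sqrt{\sum_j a_{ij}(t) \sum_j a_{ij}(t+1)}}}
#' A step in which the node is isolated on either side has an undefined
#' ratio and contributes 0, which keeps the value in \[0, 1\] and the global
#' mean anchored to all N nodes.
#'
#' @param net A `binary_dynnet` with at least 2 layers.
#' @return Named numeric vector of per-node coefficients in \[0, 1\].
#' @export
nodal_temporal_correlation <- function(net) {
  stopifnot(inherits(net, "binary_dynnet"))
  T_ <- n_layers(net)
  if (T_ < 2L) stop("temporal correlation needs at least 2 layers")
  N <- n_nodes(net)
  acc <- numeric(N)
  A_t <- net$layers[, , 1L]
  deg_t <- rowSums(A_t)
  for (t in seq_len(T_ - 1L)) {
    A_n <- net$layers[, , t + 1L]
    deg_n <- rowSums(A_n)
    num <- rowSums(A_t * A_n)
    den <- sqrt(deg_t * deg_n)
    term <- num / den
    term[den == 0] <- 0            # isolated on either side contributes 0
    acc <- acc + term
    A_t <- A_n
    deg_t <- deg_n
  }
  out <- acc / (T_ - 1L)
  names(out) <- net$node_labels
  out
}

#' Global temporal correlation coefficient
#'
#' Mean of the nodal temporal correlation coefficients over all nodes
#' (nodes isolated throughout contribute 0).
#'
#' @inheritParams nodal_temporal_correlation
#' @return A single value in \[0, 1\].
#' @export
global_temporal_correlation <- function(net) {
  mean(nodal_temporal_correlation(net))
}

#' Temporal latency matrix (time-respecting distances)
#'
#' Computes, for every ordered node pair (i, j), the earliest layer by which
#' j can be reached from i along a time-respecting path: successive edges
#' must occupy strictly increasing layer indices (at most one edge traversal
#' per layer), and waiting at a node is free. A direct edge in layer 1 gives
#' distance 1; a pair never connected by layer T has distance `Inf`. The
#' matrix is generally asymmetric because reversing a path would require
#' decreasing layers.
#'
#' Implemented by layer-sequential frontier expansion: the set of nodes
#' reached from each source persists across layers, and at layer t every
#' neighbor-in-layer-t of the reached set is added with arrival time t.
#'
#' @param net A `binary_dynnet`.
#' @return An object of class `latency_matrix`: `d` is the N x N matrix of
#'   temporal distances (diagonal 0, `Inf` = unreachable), `n_layers` the
#'   number of layers.
#' @export
latency_matrix <- function(net) {
  stopifnot(inherits(net, "binary_dynnet"))
  N <- n_nodes(net)
  T_ <- n_layers(net)
  # column j of `reach` = set of nodes currently reached from source j
  reach <- diag(N) > 0
  D <- matrix(Inf, N, N)
  diag(D) <- 0
  for (t in seq_len(T_)) {
    A <- net$layers[, , t]
    arrived <- (A %*% reach) > 0
    new <- arrived & !reach
    if (any(new)) D[new] <- t
    reach <- reach | new
    if (all(reach)) break
  }
  # D[i, j] above is the arrival of node i from source j; transpose so that
  # d[i, j] reads "from i to j".
  d <- t(D)
  dimnames(d) <- list(net$node_labels, net$node_labels)
  structure(list(d = d, n_layers = T_, node_labels = net$node_labels),
            class = "latency_matrix")
}

#' @export
print.latency_matrix <- function(x, ...) {
  off <- x$d[row(x$d) != col(x$d)]
  cat(sprintf("<latency_matrix> %d nodes, %d layers, %.1f%% pairs unreachable\n",
              nrow(x$d), x$n_layers, 100 * mean(!is.finite(off))))
  invisible(x)
}

#' Nodal temporal path length
#'
#' Mean outgoing temporal distance d(i, j) from each node i to all other
#' nodes, over the pairs with finite distance. Outgoing distances quantify
#' how quickly information starting at i spreads. A node with no finite
#' outgoing distance is reported as `Inf`; the per-node count of unreachable
#' targets is attached as attribute `n_unreachable`.
#'
#' @param lat A [latency_matrix()].
#' @return Named numeric vector (values >= 1 or `Inf`), with attribute
#'   `n_unreachable`.
#' @export
nodal_temporal_path_length <- function(lat) {
  stopifnot(inherits(lat, "latency_matrix"))
  d <- lat$d
  N <- nrow(d)
  off <- row(d) != col(d)
  vals <- numeric(N)
  unre <- integer(N)
  for (i in seq_len(N)) {
    di <- d[i, off[i, ]]
    fin <- is.finite(di)
    unre[i] <- sum(!fin)
    vals[i] <- if (any(fin)) mean(di[fin]) else Inf
  }
  names(vals) <- lat$node_labels
  attr(vals, "n_unreachable") <- unre
  vals
}

#' Characteristic temporal path length
#'
#' Mean temporal distance over all ordered node pairs with finite distance,
#' together with the fraction of ordered pairs that are unreachable.
#' Unreachable pairs are excluded from the mean rather than imputed, and the
#' fraction is surfaced so downstream statistics can flag pathological
#' subjects.
#'
#' @param lat A [latency_matrix()].
#' @return List with `value` (mean finite distance, >= 1) and
#'   `unreachable_fraction`. All pairs unreachable is an error.
#' @export
characteristic_temporal_path_length <- function(lat) {
  stopifnot(inherits(lat, "latency_matrix"))
  d <- lat$d
  off <- d[row(d) != col(d)]
  fin <- is.finite(off)
  if (!any(fin)) stop("all ordered node pairs are temporally unreachable")
  list(value = mean(off[fin]), unreachable_fraction = mean(!fin))
}

#' Default sparsity grid
#'
#' 10% to 50% in 1% increments (41 levels).
#' @export
default_sparsity_grid <- function() seq(0.10, 0.50, by = 0.01)

#' All dynamic-network metrics for one subject
#'
#' Runs the full per-subject metric battery: sliding-window correlation
#' layers, temporal variability on the weighted network, then the temporal
#' correlation coefficient and temporal path length on binarized networks at
#' every sparsity of the grid. Sparsity-dependent metrics are additionally
#' averaged across the grid, the form used for correlation analyses.
#'
#' @param ts An [roi_time_series()].
#' @param scheme A [make_windows()] scheme.
#' @param sparsity_grid Numeric vector of sparsities (default
#'   [default_sparsity_grid()]).
#' @param rank_by Edge ranking rule for binarization, see
#'   [binarize_by_sparsity()].
#' @return A list of class `subject_metrics`:
#' \describe{
#'   \item{global}{`temporal_variability`, per-sparsity named vectors
#'     `temporal_correlation`, `temporal_path_length`,
#'     `unreachable_fraction`, and their grid means
#'     `temporal_correlation_avg`, `temporal_path_length_avg`,
#'     `unreachable_fraction_avg`.}
#'   \item{nodal}{`variability` (length N), matrices sparsity x N
#'     `correlation` and `path_length`, and their grid means
#'     `correlation_avg`, `path_length_avg`.}
#' }
#' @export
subject_metrics <- function(ts, scheme,
                            sparsity_grid = default_sparsity_grid(),
                            rank_by = "signed") {
  stopifnot(length(sparsity_grid) >= 1L, all(sparsity_grid > 0),
            all(sparsity_grid <= 1))
  net <- window_fc(ts, scheme)
  N <- n_nodes(net)
  nodal_var <- nodal_temporal_variability(net)
  ns <- length(sparsity_grid)
  skey <- sprintf("%.2f", sparsity_grid)
  corr_g <- path_g <- unre_g <- stats::setNames(numeric(ns), skey)
  corr_n <- path_n <- matrix(NA_real_, ns, N,
                             dimnames = list(skey, net$node_labels))
  for (s in seq_len(ns)) {
    bn <- binarize_by_sparsity(net, sparsity_grid[s], rank_by = rank_by)
    ci <- nodal_temporal_correlation(bn)
    lat <- latency_matrix(bn)
    li <- nodal_temporal_path_length(lat)
    cp <- characteristic_temporal_path_length(lat)
    corr_n[s, ] <- ci
    path_n[s, ] <- li
    corr_g[s] <- mean(ci)
    path_g[s] <- cp$value
    unre_g[s] <- cp$unreachable_fraction
  }
  structure(list(
    global = list(
      temporal_variability = mean(nodal_var),
      temporal_correlation = corr_g,
      temporal_path_length = path_g,
      unreachable_fraction = unre_g,
      temporal_correlation_avg = mean(corr_g),
      temporal_path_length_avg = mean(path_g),
      unreachable_fraction_avg = mean(unre_g)
    ),
    nodal = list(
      variability = nodal_var,
      correlation = corr_n,
      path_length = path_n,
      correlation_avg = colMeans(corr_n),
      path_length_avg = colMeans(path_n)
    ),
    sparsity_grid = sparsity_grid
  ), class = "subject_metrics")
}
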