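# Sliding-window construction of multi-layer dynamic functional networks.

#' ROI time-series container
#'
#' Bundles one subject's region-of-interest (ROI) BOLD time series with its
#' repetition time. Rows are volumes (time points), columns are regions.
#'
#' @param data Numeric matrix, volumes x regions; no missing values.
#' @param tr_s Repetition time in seconds (positive scalar).
#' @param node_labels Optional character vector of region identifiers;
#'   defaults to the column names of `data`, or `"n1"..."nR"`.
#'
#' @return An object of class `roi_ts` with elements `data`, `tr_s`,
#'   `node_labels`.
#' @export
roi_time_series <- function(data, tr_s, node_labels = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("time-series data must be numeric")
  if (nrow(data) < 2L) stop("need at least 2 volumes")
  if (ncol(data) < 2L) stop("need at least 2 regions")
  if (anyNA(data)) stop("time-series data contains missing values")
  if (!is.numeric(tr_s) || length(tr_s) != 1L || tr_s <= 0) {
    stop("tr_s must be a positive scalar (seconds)")
  }
  if (is.null(node_labels)) {
    node_labels <- colnames(data)
    if (is.null(node_labels)) node_labels <- paste0("n", seq_len(ncol(data)))
  }
  if (length(node_labels) != ncol(data)) {
    stop("node_labels length must equal the number of regions")
  }
  colnames(data) <- node_labels
  structure(list(data = data, tr_s = tr_s, node_labels = node_labels),
            class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> %d volumes x %d regions, TR = %g s\n",
              nrow(x$data), ncol(x$data), x$tr_s))
  invisible(x)
}

#' Read / write ROI time series as TSV
#'
#' Plain-text interchange format: one row per volume, one column per region,
#' header row of node labels, tab-separated.
#'
#' @param path File path.
#' @param tr_s Repetition time in seconds (not stored in the TSV itself).
#' @return `read_roi_ts()` returns an [roi_time_series()] object.
#' @export
read_roi_ts <- function(path, tr_s) {
  df <- utils::read.delim(path, check.names = FALSE)
  roi_time_series(as.matrix(df), tr_s = tr_s, node_labels = colnames(df))
}

#' @rdname read_roi_ts
#' @param ts An `roi_ts` object.
#' @export
write_roi_ts <- function(ts, path) {
  stopifnot(inherits(ts, "roi_ts"))
  utils::write.table(ts$data, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Build a sliding-window scheme
#'
#' Converts window and step lengths from seconds to volumes and lays out the
#' window start indices. Conversions must be exact multiples of the repetition
#' time: the scheme refuses to round, because a non-integer number of volumes
#' has no meaning for a rectangular window.
#'
#' @param n_volumes Number of usable volumes in the series.
#' @param tr_s Repetition time in seconds.
#' @param window_s Window length in seconds (default 100).
#' @param step_s Step length in seconds (default 6).
#'
#' @return An object of class `window_scheme`: `window_s`, `step_s`,
#'   `window_vols`, `step_vols`, `n_windows`, and 0-based `starts`.
#' @examples
#' make_windows(230, 2, 100, 6)  # 61 windows
#' @export
make_windows <- function(n_volumes, tr_s, window_s = 100, step_s = 6) {
  stopifnot(n_volumes >= 2, tr_s > 0, window_s > 0, step_s > 0)
  wv <- window_s / tr_s
  sv <- step_s / tr_s
  if (abs(wv - round(wv)) > 1e-9) {
    stop(sprintf("window length %g s is not a whole number of volumes at TR = %g s",
                 window_s, tr_s))
  }
  if (abs(sv - round(sv)) > 1e-9) {
    stop(sprintf("step length %g s is not a whole number of volumes at TR = %g s",
                 step_s, tr_s))
  }
  wv <- as.integer(round(wv))
  sv <- as.integer(round(sv))
  if (wv < 2L) stop("window must span at least 2 volumes")
  if (wv > n_volumes) {
    stop(sprintf("window of %d volumes exceeds the series length (%d volumes)",
                 wv, n_volumes))
  }
  n_windows <- (n_volumes - wv) %/% sv + 1L
  starts <- seq.int(0L, by = sv, length.out = n_windows)
  structure(list(window_s = window_s, step_s = step_s,
                 window_vols = wv, step_vols = sv,
                 n_windows = as.integer(n_windows), starts = starts),
            class = "window_scheme")
}

#' @export
print.window_scheme <- function(x, ...) {
  cat(sprintf("<window_scheme> %g s window / %g s step: %d vols / %d vols, %d windows\n",
              x$window_s, x$step_s, x$window_vols, x$step_vols, x$n_windows))
  invisible(x)
}

#' Write per-window correlation matrices as CSV (debug output)
#'
#' One file per window named `<subject>_w<index>.csv` with a 0-based window
#' index, each holding that layer's full correlation matrix with node labels
#' as header.
#'
#' @param net A `weighted_dynnet` from [window_fc()].
#' @param dir Output directory (created if needed).
#' @param subject Subject identifier used in the file names.
#' @return Invisibly, the vector of files written.
#' @export
write_window_layers <- function(net, dir, subject) {
  stopifnot(inherits(net, "weighted_dynnet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- vapply(seq_len(n_layers(net)), function(t) {
    f <- file.path(dir, sprintf("%s_w%d.csv", subject, t - 1L))
    utils::write.csv(as.data.frame(net$layers[, , t]), f, row.names = FALSE)
    f
  }, character(1))
  invisible(files)
}

#' Assemble a dynamic network from a list of layer matrices
#'
#' Constructors for multi-layer dynamic networks given explicit adjacency /
#' correlation matrices, one per time window. `weighted_dynamic_network()`
#' expects symmetric numeric matrices with zero diagonal and off-diagonal
#' entries in \[-1, 1\]; `binary_dynamic_network()` expects symmetric 0/1
#' matrices with zero diagonal.
#'
#' @param layers List of N x N matrices (equal dimensions), or an
#'   N x N x T array.
#' @param node_labels Optional node names (default `"n1"..."nN"`).
#' @param sparsity Optional sparsity annotation for binary networks.
#' @return A `weighted_dynnet` / `binary_dynnet` object.
#' @export
weighted_dynamic_network <- function(layers, node_labels = NULL) {
  arr <- layers_to_array(layers)
  N <- dim(arr)[1L]
  for (t in seq_len(dim(arr)[3L])) {
    L <- arr[, , t]
    if (!isTRUE(all.equal(L, t(L)))) stop(sprintf("layer %d is not symmetric", t))
    if (any(diag(L) != 0)) stop(sprintf("layer %d has nonzero diagonal", t))
    if (any(abs(L) > 1 + 1e-12)) stop(sprintf("layer %d has weights outside [-1, 1]", t))
  }
  if (is.null(node_labels)) node_labels <- paste0("n", seq_len(N))
  dimnames(arr) <- list(node_labels, node_labels, NULL)
  new_dynnet(arr, node_labels, weighted = TRUE)
}

#' @rdname weighted_dynamic_network
#' @export
binary_dynamic_network <- function(layers, node_labels = NULL, sparsity = NA) {
  arr <- layers_to_array(layers)
  N <- dim(arr)[1L]
  for (t in seq_len(dim(arr)[3L])) {
    L <- arr[, , t]
    if (!isTRUE(all.equal(L, t(L)))) stop(sprintf("layer %d is not symmetric", t))
    if (any(diag(L) != 0)) stop(sprintf("layer %d has nonzero diagonal", t))
    if (!all(L %in% c(0, 1))) stop(sprintf("layer %d is not 0/1", t))
  }
  if (is.null(node_labels)) node_labels <- paste0("n", seq_len(N))
  dimnames(arr) <- list(node_labels, node_labels, NULL)
  new_dynnet(arr, node_labels, weighted = FALSE, sparsity = sparsity)
}

layers_to_array <- function(layers) {
  if (is.array(layers) && length(dim(layers)) == 3L) {
    arr <- layers
  } else {
    stopifnot(is.list(layers), length(layers) >= 1L)
    N <- nrow(layers[[1L]])
    stopifnot(all(vapply(layers, function(L) all(dim(L) == c(N, N)), logical(1))))
    arr <- array(unlist(layers), dim = c(N, N, length(layers)))
  }
  if (dim(arr)[1L] != dim(arr)[2L]) stop("layers must be square")
  arr
}

new_dynnet <- function(layers, node_labels, weighted, sparsity = NULL) {
  structure(list(layers = layers, node_labels = node_labels,
                 sparsity = sparsity),
            class = c(if (weighted) "weighted_dynnet" else "binary_dynnet",
                      "dynnet"))
}

#' Number of layers / nodes of a dynamic network
#' @param net A `dynnet` object.
#' @export
n_layers <- function(net) dim(net$layers)[3L]

#' @rdname n_layers
#' @export
n_nodes <- function(net) dim(net$layers)[1L]

#' @export
print.dynnet <- function(x, ...) {
  kind <- if (inherits(x, "weighted_dynnet")) "weighted" else
    sprintf("binary (sparsity %.2f)", x$sparsity)
  cat(sprintf("<dynnet> %s, %d nodes x %d layers\n",
              kind, n_nodes(x), n_layers(x)))
  invisible(x)
}

#' Sliding-window functional connectivity
#'
#' Computes, for every window of the scheme, the matrix of pairwise Pearson
#' correlations between node time series, yielding a multi-layer weighted
#' dynamic network. Diagonals are fixed at 0 (self-connections are not edges).
#' A node whose series is constant within any window is an error, never a
#' silent `NA`: on preprocessed BOLD data a zero-variance window indicates a
#' broken extraction upstream.
#'
#' @param ts An [roi_time_series()] object.
#' @param scheme A [make_windows()] scheme compatible with `ts`.
#' @return A `weighted_dynnet`: `layers` is a regions x regions x n_windows
#'   array of correlation matrices.
#' @export
window_fc <- function(ts, scheme) {
  stopifnot(inherits(ts, "roi_ts"), inherits(scheme, "window_scheme"))
  X <- ts$data
  nv <- nrow(X)
  if (scheme$starts[scheme$n_windows] + scheme$window_vols > nv) {
    stop("window scheme extends past the end of the time series")
  }
  N <- ncol(X)
  T_ <- scheme$n_windows
  layers <- array(0, dim = c(N, N, T_))
  for (t in seq_len(T_)) {
    rows <- (scheme$starts[t] + 1L):(scheme$starts[t] + scheme$window_vols)
    W <- X[rows, , drop = FALSE]
    cm <- colMeans(W)
    msq <- colMeans(W * W)
    v <- msq - cm * cm
    tol <- 1e-12 * pmax(msq, 1)   # guards cancellation on constant columns
    if (any(v <= tol)) {
      bad <- which(v <= tol)[1L]
      stop(sprintf("node %s has zero variance within window %d",
                   ts$node_labels[bad], t))
    }
    C <- stats::cor(W)
    diag(C) <- 0
    layers[, , t] <- C
  }
  dimnames(layers) <- list(ts$node_labels, ts$node_labels, NULL)
  new_dynnet(layers, ts$node_labels, weighted = TRUE)
}

# Undirected node pairs (i < j) in ascending lexicographic (i, j) order,
# with the matching linear indices into an N x N matrix.
node_pairs <- function(N) {
  pr <- t(utils::combn(N, 2L))
  list(i = pr[, 1L], j = pr[, 2L], lin = (pr[, 2L] - 1L) * N + pr[, 1L])
}

# round-half-away-from-zero for positive x
round_half_up <- function(x) floor(x + 0.5)

#' Binarize a weighted dynamic network at a sparsity threshold
#'
#' Per layer, retains the `k = round(sparsity * E)` strongest connections
#' (`E = N(N-1)/2` undirected pairs) and sets all others to 0. By default the
#' raw signed correlations are ranked, so strong positive correlations win;
#' set `rank_by = "absolute"` to rank by magnitude. Ties at the cutoff are
#' broken by ascending `(i, j)` pair order, so the output is deterministic.
#'
#' @param net A `weighted_dynnet`.
#' @param sparsity Fraction of retained edges in (0, 1].
#' @param rank_by `"signed"` (default) or `"absolute"`.
#' @return A `binary_dynnet` whose layers each have exactly `k` edges.
#' @export
binarize_by_sparsity <- function(net, sparsity, rank_by = "signed") {
  stopifnot(inherits(net, "weighted_dynnet"))
  if (!rank_by %in% c("signed", "absolute")) {
    stop("rank_by must be 'signed' or 'absolute'")
  }
  if (!is.numeric(sparsity) || length(sparsity) != 1L ||
      sparsity <= 0 || sparsity > 1) {
    stop("sparsity must be a single value in (0, 1]")
  }
  N <- n_nodes(net)
  T_ <- n_layers(net)
  pp <- node_pairs(N)
  E <- length(pp$lin)
  k <- round_half_up(sparsity * E)
  if (k < 1) stop(sprintf("sparsity %g retains no edges (E = %d)", sparsity, E))
  k <- min(k, E)
  layers <- array(0L, dim = c(N, N, T_))
  # pair weights for all layers at once: E x T
  w_all <- matrix(net$layers[as.vector(outer(pp$lin, (seq_len(T_) - 1L) * N * N, "+"))],
                  E, T_)
  if (rank_by == "absolute") w_all <- abs(w_all)
  lin_lower <- (pp$i - 1L) * N + pp$j    # mirror of pp$lin below the diagonal
  for (t in seq_len(T_)) {
    # stable radix sort: ties at the cutoff fall back to ascending pair order
    ord <- order(w_all[, t], decreasing = TRUE, method = "radix")
    sel <- ord[seq_len(k)]
    off <- (t - 1L) * N * N
    layers[c(pp$lin[sel], lin_lower[sel]) + off] <- 1L
  }
  dimnames(layers) <- list(net$node_labels, net$node_labels, NULL)
  new_dynnet(layers, net$node_labels, weighted = FALSE, sparsity = sparsity)
}
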