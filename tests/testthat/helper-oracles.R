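# Independent oracles used across the suite. These deliberately reimplement
# the definitions in the most literal way possible (textbook formulas,
# exhaustive enumeration) and never share code with the package internals.

# Pearson correlation straight from the covariance / sigma ratio.
oracle_pearson <- function(a, b) {
  da <- a - mean(a)
  db <- b - mean(b)
  sum(da * db) / sqrt(sum(da^2) * sum(db^2))
}

# Temporal distances by exhaustive enumeration of every time-respecting path
# (strictly increasing layer indices, one edge per layer). Only feasible for
# tiny networks; that is the point.
oracle_latency <- function(layers) {
  N <- nrow(layers[[1L]])
  T_ <- length(layers)
  d <- matrix(Inf, N, N)
  diag(d) <- 0
  for (src in seq_len(N)) {
    walk <- function(u, t_min) {
      if (t_min > T_) return()
      for (t in t_min:T_) {
        for (v in which(layers[[t]][u, ] == 1)) {
          if (t < d[src, v]) d[src, v] <<- t
          walk(v, t + 1L)
        }
      }
    }
    walk(src, 1L)
  }
  d
}

# Nodal temporal correlation coefficient by literal double loop over the
# defining formula.
oracle_temporal_correlation <- function(layers) {
  N <- nrow(layers[[1L]])
  T_ <- length(layers)
  vapply(seq_len(N), function(i) {
    terms <- vapply(seq_len(T_ - 1L), function(t) {
      num <- sum(layers[[t]][i, ] * layers[[t + 1L]][i, ])
      den <- sqrt(sum(layers[[t]][i, ]) * sum(layers[[t + 1L]][i, ]))
      if (den == 0) 0 else num / den
    }, numeric(1))
    sum(terms) / (T_ - 1L)
  }, numeric(1))
}

# Nodal temporal variability by direct evaluation of the pairwise-profile
# correlation mean.
oracle_variability <- function(layers) {
  N <- nrow(layers[[1L]])
  T_ <- length(layers)
  vapply(seq_len(N), function(k) {
    acc <- 0
    npair <- 0
    for (t1 in seq_len(T_ - 1L)) {
      for (t2 in (t1 + 1L):T_) {
        acc <- acc + oracle_pearson(layers[[t1]][k, -k], layers[[t2]][k, -k])
        npair <- npair + 1
      }
    }
    1 - acc / npair
  }, numeric(1))
}

# Extra-sum-of-squares F for the group term from the normal equations,
# given explicit design matrices (no lm involved).
oracle_ancova_F <- function(y, X_red, X_full) {
  rss <- function(X) {
    beta <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% beta)^2)
  }
  rss_r <- rss(X_red)
  rss_f <- rss(X_full)
  df2 <- length(y) - ncol(X_full)
  list(F = (rss_r - rss_f) / (rss_f / df2), df2 = df2)
}

# BH step-up computed literally: sort, p * m / rank, running minimum from
# the largest rank down, cap at 1, unsort.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- ps * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Random binary dynamic network (Erdos-Renyi layers).
rand_binary_net <- function(N, T_, p = 0.3) {
  layers <- lapply(seq_len(T_), function(t) {
    A <- matrix(0L, N, N)
    up <- which(upper.tri(A))
    A[up] <- as.integer(stats::runif(length(up)) < p)
    A + t(A)
  })
  list(layers = layers, net = binary_dynamic_network(layers))
}

# Small weighted dynamic network with smooth random layers (no constant
# profiles w.p. 1).
rand_weighted_net <- function(N, T_) {
  layers <- lapply(seq_len(T_), function(t) {
    M <- matrix(stats::runif(N * N, -1, 1), N, N)
    M <- (M + t(M)) / 2
    diag(M) <- 0
    M
  })
  list(layers = layers, net = weighted_dynamic_network(layers))
}

# Phenotype table for stats tests: balanced groups over sites, covariates
# drawn once per call.
make_pheno <- function(n_per_group, n_sites = 2, groups = c("HC", "MDD")) {
  n <- 2 * n_per_group
  data.frame(
    id = sprintf("S%03d", seq_len(n)),
    group = rep(groups, each = n_per_group),
    age = round(stats::runif(n, 18, 65)),
    sex = sample(c("male", "female"), n, replace = TRUE),
    education = round(stats::runif(n, 5, 20)),
    mean_fd = stats::runif(n, 0.02, 0.15),
    site = paste0("site", rep_len(seq_len(n_sites), n)),
    stringsAsFactors = FALSE
  )
}
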