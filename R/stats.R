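# Group-level inference: ANCOVA with nuisance covariates and site dummies,
# sparsity-profile tests, partial Spearman correlations, BH-FDR, subgroup
# contrasts.

order_group_levels <- function(g, levels = NULL) {
  lv <- if (is.null(levels)) {
    u <- sort(unique(as.character(g)))
    if ("HC" %in% u) c("HC", setdiff(u, "HC")) else u
  } else levels
  if (length(lv) != 2L) stop("group must have exactly 2 levels")
  f <- factor(as.character(g), levels = lv)
  if (any(is.na(f))) stop("group contains values outside the requested levels")
  if (nlevels(droplevels(f)) != 2L) stop("both group levels must be present")
  f
}

check_site_identifiable <- function(site, group, drop_single_group_sites) {
  tab <- table(site, group)
  bad <- rownames(tab)[apply(tab > 0, 1L, sum) < 2L]
  if (length(bad) == 0L) return(rep(TRUE, length(site)))
  if (!drop_single_group_sites) {
    stop(sprintf("site(s) %s contain only one group; the group effect is not identified",
                 paste(bad, collapse = ", ")))
  }
  warning(sprintf("dropping %d subject(s) from single-group site(s): %s",
                  sum(site %in% bad), paste(bad, collapse = ", ")))
  !(site %in% bad)
}

#' ANCOVA group effect on a per-subject metric
#'
#' Fits the linear model
#' `y ~ group + age + sex + education + mean_fd + site` by least squares and
#' returns the partial F-test for the group term (the extra sum of squares of
#' adding group to the covariate-only model), together with the sign of the
#' covariate-adjusted group difference. Site enters as fixed-effect dummy
#' columns; with a single site the term is omitted. Every site must contain
#' both groups, otherwise the group effect is confounded with site.
#'
#' @param y Numeric vector, one metric value per subject (row of `pheno`).
#' @param pheno Data frame of per-subject phenotypes.
#' @param group_col Name of the two-level group column (default `"group"`).
#' @param covariates Columns entered as nuisance covariates (default
#'   `age, sex, education, mean_fd`). Use `character(0)` for none.
#' @param site_col Name of the site column, or `NULL` to omit site.
#' @param levels Optional explicit group level order `c(reference, test)`;
#'   `direction` is the sign of test minus reference. By default `"HC"` is
#'   the reference when present.
#' @param metric_name,sparsity Labels copied into the result row.
#' @param drop_single_group_sites If `TRUE`, subjects from sites lacking one
#'   of the groups are dropped with a warning instead of raising an error.
#' @return One-row data frame: `metric`, `sparsity`, `F`, `df1`, `df2`, `p`,
#'   `direction` (sign of adjusted test-minus-reference difference), `n`.
#' @export
ancova_group_effect <- function(y, pheno, group_col = "group",
                                covariates = c("age", "sex", "education", "mean_fd"),
                                site_col = "site", levels = NULL,
                                metric_name = "metric", sparsity = NA,
                                drop_single_group_sites = FALSE) {
  if (length(y) != nrow(pheno)) stop("y and pheno have different lengths")
  if (anyNA(y)) stop("y contains missing values")
  miss <- covariates[!covariates %in% names(pheno)]
  if (length(miss)) stop("missing covariate column(s): ", paste(miss, collapse = ", "))
  g <- order_group_levels(pheno[[group_col]], levels)

  keep <- rep(TRUE, length(y))
  use_site <- !is.null(site_col) && site_col %in% names(pheno) &&
    length(unique(pheno[[site_col]])) > 1L
  if (use_site) {
    keep <- check_site_identifiable(pheno[[site_col]], g, drop_single_group_sites)
  }
  d <- data.frame(.y = y[keep], .group = droplevels(g[keep]))
  for (cv in covariates) {
    v <- pheno[[cv]][keep]
    if (anyNA(v)) stop(sprintf("covariate '%s' contains missing values", cv))
    if (is.character(v) || is.logical(v) || is.factor(v)) {
      v <- droplevels(factor(v))
      if (nlevels(v) < 2L) {        # constant factor: absorbed by intercept
        covariates <- setdiff(covariates, cv)
        next
      }
    }
    d[[cv]] <- v
  }
  if (use_site) d$.site <- factor(pheno[[site_col]][keep])
  if (nlevels(d$.group) != 2L) stop("both group levels must be present")

  rhs_full <- c(".group", covariates, if (use_site) ".site")
  X <- stats::model.matrix(stats::reformulate(rhs_full), data = d)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  full <- stats::lm(stats::reformulate(rhs_full, ".y"), data = d)
  rhs_red <- c(covariates, if (use_site) ".site")
  red <- stats::lm(stats::reformulate(if (length(rhs_red)) rhs_red else "1", ".y"),
                   data = d)
  rss_full <- sum(stats::residuals(full)^2)
  rss_red <- sum(stats::residuals(red)^2)
  ss_extra <- rss_red - rss_full
  df2 <- full$df.residual
  test_lv <- base::levels(d$.group)[2L]
  beta <- stats::coef(full)[[paste0(".group", test_lv)]]
  if (ss_extra <= 1e-12 * max(rss_red, 1)) {
    Fv <- 0
    p <- 1
  } else if (rss_full <= 1e-12 * max(rss_red, 1)) {
    Fv <- Inf
    p <- 0
  } else {
    Fv <- ss_extra / (rss_full / df2)
    p <- stats::pf(Fv, 1, df2, lower.tail = FALSE)
  }
  data.frame(metric = metric_name, sparsity = sparsity,
             F = Fv, df1 = 1, df2 = df2, p = p,
             direction = sign(beta), n = nrow(d),
             stringsAsFactors = FALSE)
}

#' Group effect on a sparsity profile of metric values
#'
#' For metrics computed at every sparsity of the grid, the between-subject
#' group main effect of the repeated-measures design (sparsity as
#' within-subject factor) equals the ANCOVA on each subject's sparsity mean
#' when the within-subject design is complete, which is how it is computed
#' here. Per-sparsity ANCOVAs are returned alongside so that the consistency
#' of the effect across the grid can be reported. The group-by-sparsity
#' interaction is deliberately not computed.
#'
#' @param Y Numeric matrix, subjects x sparsities, complete (no missing
#'   cells); column names are taken as sparsity labels.
#' @inheritParams ancova_group_effect
#' @param ... Passed on to [ancova_group_effect()].
#' @return List with `averaged` (one-row data frame for the sparsity-mean
#'   test) and `per_sparsity` (one row per sparsity level).
#' @export
sparsity_profile_group_effect <- function(Y, pheno, metric_name = "metric", ...) {
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(pheno)) stop("Y and pheno have different numbers of subjects")
  if (anyNA(Y) || any(!is.finite(Y))) {
    stop("sparsity profile has missing or non-finite cells")
  }
  labs <- colnames(Y)
  if (is.null(labs)) labs <- as.character(seq_len(ncol(Y)))
  averaged <- ancova_group_effect(rowMeans(Y), pheno,
                                  metric_name = metric_name,
                                  sparsity = "averaged", ...)
  per <- do.call(rbind, lapply(seq_len(ncol(Y)), function(s) {
    ancova_group_effect(Y[, s], pheno, metric_name = metric_name,
                        sparsity = labs[s], ...)
  }))
  list(averaged = averaged, per_sparsity = per)
}

#' Partial Spearman rank correlation
#'
#' Rank-transforms `x` and `y` (average ranks for ties), residualizes both
#' rank vectors on the covariate design by least squares, and reports the
#' Pearson correlation of the residuals, with a t-approximation p-value at
#' `n - 2 - q` degrees of freedom (`q` = number of covariate columns after
#' dummy expansion). With no covariates this is the ordinary Spearman rho.
#' Rows with a missing value in `x`, `y` or any covariate are deleted
#' listwise.
#'
#' @param x,y Numeric vectors (e.g. a clinical score and a metric).
#' @param covariates Optional data frame of covariates (factors allowed).
#' @param variable,metric_name Labels copied into the result row.
#' @return One-row data frame: `metric`, `variable`, `rho`, `p`, `n_used`, `df`.
#' @export
partial_spearman <- function(x, y, covariates = NULL,
                             variable = "score", metric_name = "metric") {
  if (length(x) != length(y)) stop("x and y have different lengths")
  cc <- stats::complete.cases(x, y)
  if (!is.null(covariates)) {
    if (nrow(covariates) != length(x)) stop("covariates have wrong row count")
    cc <- cc & stats::complete.cases(covariates)
  }
  n <- sum(cc)
  if (n < 10L) stop(sprintf("only %d complete cases; need at least 10", n))
  xs <- x[cc]
  ys <- y[cc]
  if (length(unique(xs)) < 2L || length(unique(ys)) < 2L) {
    stop("x or y is constant after listwise deletion")
  }
  rx <- rank(xs)
  ry <- rank(ys)
  q <- 0L
  if (!is.null(covariates) && ncol(covariates) > 0L) {
    cv <- droplevels(covariates[cc, , drop = FALSE])
    # constant factors carry no information and would break the design
    const <- vapply(cv, function(v) is.factor(v) && nlevels(v) < 2L, logical(1))
    cv <- cv[, !const, drop = FALSE]
  }
  if (!is.null(covariates) && ncol(covariates) > 0L && ncol(cv) > 0L) {
    Z <- stats::model.matrix(~ ., data = cv)
    q <- ncol(Z) - 1L
    fit <- stats::lm.fit(Z, cbind(rx, ry))
    rx <- fit$residuals[, 1L]
    ry <- fit$residuals[, 2L]
  }
  rho <- stats::cor(rx, ry)
  df <- n - 2L - q
  if (df < 1L) stop("not enough residual degrees of freedom")
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt(df / (1 - rho^2))
    2 * stats::pt(-abs(tt), df)
  }
  data.frame(metric = metric_name, variable = variable, rho = rho, p = p,
             n_used = n, df = df, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment of a family of p-values (monotone, capped at
#' 1, returned in the original order).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Subgroup contrasts (FEDN / non-FEDN / HC)
#'
#' Runs the covariate-adjusted group test for every metric within each pair
#' of subgroups — FEDN vs non-FEDN patients, FEDN vs HC, non-FEDN vs HC —
#' and FDR-adjusts across the whole family (metrics x contrasts). A site
#' lacking one of the two levels of a contrast is dropped from that contrast
#' with a warning.
#'
#' @param metrics_df Data frame of per-subject metric values (one column per
#'   metric), rows aligned with `pheno`.
#' @param pheno Phenotype data frame with `group` and `fedn_status`
#'   (patients labelled `"FEDN"` / `"nonFEDN"`; controls identified by
#'   `group == control_level`).
#' @param metric_cols Columns of `metrics_df` to test (default: all).
#' @param control_level Label of the control group (default `"HC"`).
#' @inheritParams ancova_group_effect
#' @return Data frame with one row per metric x contrast: `metric`,
#'   `contrast`, `F`, `df1`, `df2`, `p`, `p_fdr`, `direction`
#'   (sign of first-named minus second-named adjusted difference), `n`.
#' @export
subgroup_contrasts <- function(metrics_df, pheno,
                               metric_cols = names(metrics_df),
                               control_level = "HC", group_col = "group",
                               covariates = c("age", "sex", "education", "mean_fd"),
                               site_col = "site") {
  if (!"fedn_status" %in% names(pheno)) stop("pheno lacks fedn_status")
  lab <- ifelse(pheno[[group_col]] == control_level, control_level,
                as.character(pheno$fedn_status))
  contrasts <- list(
    FEDN_vs_nonFEDN = c("nonFEDN", "FEDN"),
    FEDN_vs_HC      = c(control_level, "FEDN"),
    nonFEDN_vs_HC   = c(control_level, "nonFEDN")
  )
  rows <- list()
  for (cn in names(contrasts)) {
    pair <- contrasts[[cn]]
    idx <- which(lab %in% pair)
    if (length(unique(lab[idx])) < 2L) {
      stop(sprintf("contrast %s: one of the levels is absent", cn))
    }
    sub <- pheno[idx, , drop = FALSE]
    sub[[group_col]] <- lab[idx]
    for (m in metric_cols) {
      r <- ancova_group_effect(metrics_df[[m]][idx], sub,
                               group_col = group_col,
                               covariates = covariates, site_col = site_col,
                               levels = pair, metric_name = m,
                               drop_single_group_sites = TRUE)
      r$contrast <- cn
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- bh_fdr(out$p)
  out[, c("metric", "contrast", "F", "df1", "df2", "p", "p_fdr",
          "direction", "n")]
}
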