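# End-to-end orchestration: cohort metrics, group statistics, artifact
# output with deterministic seeding. The package's functions are the
# interface; `run_pipeline()` chains simulate/read -> metrics -> stats.

#' Pipeline run configuration
#'
#' @param window_s,step_s Sliding-window length and step in seconds
#'   (defaults 100 / 6; the sensitivity grid uses 40-100 / 4-8).
#' @param tr_s Repetition time in seconds.
#' @param sparsity_grid Sparsity levels for binarized metrics.
#' @param rank_by Edge ranking rule, see [binarize_by_sparsity()].
#' @param fdr_alpha Significance level applied after FDR adjustment.
#' @param nodal Run nodal-level group tests.
#' @param subgroups Run FEDN / non-FEDN / HC contrasts (needs
#'   `fedn_status`).
#' @param per_sparsity Run per-sparsity group tests alongside the
#'   sparsity-averaged ones.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return List of class `run_config`.
#' @export
run_config <- function(window_s = 100, step_s = 6, tr_s = 2,
                       sparsity_grid = default_sparsity_grid(),
                       rank_by = "signed", fdr_alpha = 0.05,
                       nodal = TRUE, subgroups = TRUE, per_sparsity = TRUE,
                       seed = 1) {
  stopifnot(window_s > 0, step_s > 0, tr_s > 0,
            all(sparsity_grid > 0), all(sparsity_grid <= 1),
            fdr_alpha > 0, fdr_alpha < 1)
  structure(list(window_s = window_s, step_s = step_s, tr_s = tr_s,
                 sparsity_grid = sparsity_grid, rank_by = rank_by,
                 fdr_alpha = fdr_alpha, nodal = nodal, subgroups = subgroups,
                 per_sparsity = per_sparsity, seed = as.integer(seed)),
            class = "run_config")
}

#' Dynamic-network metrics for every subject of a cohort
#'
#' Applies [subject_metrics()] to each subject and assembles cohort-level
#' tables: a data frame of global metrics (one row per subject) and, as
#' attributes, nodal matrices (subjects x regions) for each metric family.
#'
#' @param cohort A `cohort` (from [generate_cohort()] / [read_cohort()]) or
#'   a named list of [roi_time_series()].
#' @param config A [run_config()].
#' @return Data frame `global` columns: `id`, `temporal_variability`,
#'   `temporal_correlation_avg`, `temporal_path_length_avg`,
#'   `unreachable_fraction_avg`, plus per-sparsity columns `tc_<s>` and
#'   `tpl_<s>`. Attributes `nodal` (list of subjects x regions matrices:
#'   `variability`, `correlation_avg`, `path_length_avg`) and
#'   `sparsity_grid`.
#' @export
cohort_metrics <- function(cohort, config = run_config()) {
  ts_list <- if (inherits(cohort, "cohort")) cohort$ts else cohort
  stopifnot(length(ts_list) >= 1L)
  ids <- names(ts_list)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_along(ts_list))
  first <- ts_list[[1L]]
  scheme <- make_windows(nrow(first$data), first$tr_s,
                         config$window_s, config$step_s)
  grid <- config$sparsity_grid
  skey <- sprintf("%.2f", grid)
  n <- length(ts_list)
  N <- ncol(first$data)
  glob <- data.frame(id = ids,
                     temporal_variability = NA_real_,
                     temporal_correlation_avg = NA_real_,
                     temporal_path_length_avg = NA_real_,
                     unreachable_fraction_avg = NA_real_,
                     stringsAsFactors = FALSE)
  tc <- tpl <- matrix(NA_real_, n, length(grid),
                      dimnames = list(ids, skey))
  nodal <- list(variability = matrix(NA_real_, n, N, dimnames = list(ids, first$node_labels)),
                correlation_avg = matrix(NA_real_, n, N, dimnames = list(ids, first$node_labels)),
                path_length_avg = matrix(NA_real_, n, N, dimnames = list(ids, first$node_labels)))
  for (i in seq_len(n)) {
    sm <- subject_metrics(ts_list[[i]], scheme, sparsity_grid = grid,
                          rank_by = config$rank_by)
    glob$temporal_variability[i] <- sm$global$temporal_variability
    glob$temporal_correlation_avg[i] <- sm$global$temporal_correlation_avg
    glob$temporal_path_length_avg[i] <- sm$global$temporal_path_length_avg
    glob$unreachable_fraction_avg[i] <- sm$global$unreachable_fraction_avg
    tc[i, ] <- sm$global$temporal_correlation
    tpl[i, ] <- sm$global$temporal_path_length
    nodal$variability[i, ] <- sm$nodal$variability
    nodal$correlation_avg[i, ] <- sm$nodal$correlation_avg
    nodal$path_length_avg[i, ] <- sm$nodal$path_length_avg
  }
  colnames(tc) <- paste0("tc_", skey)
  colnames(tpl) <- paste0("tpl_", skey)
  out <- cbind(glob, as.data.frame(tc), as.data.frame(tpl))
  attr(out, "nodal") <- nodal
  attr(out, "sparsity_grid") <- grid
  attr(out, "scheme") <- scheme
  out
}

primary_metric_cols <- c(temporal_variability = "temporal_variability",
                         temporal_correlation = "temporal_correlation_avg",
                         temporal_path_length = "temporal_path_length_avg")

#' Run the full analysis pipeline on a cohort
#'
#' Chains metric computation and group statistics: (1) per-subject dynamic
#' network metrics; (2) the primary family — ANCOVA on temporal variability
#' and sparsity-profile tests on the temporal correlation coefficient and
#' characteristic temporal path length, FDR-adjusted across the three
#' metrics; (3) partial Spearman correlations of the (sparsity-averaged)
#' metrics with HAMD score and illness duration in patients, adjusting for
#' age, sex and site; (4) optional nodal-level tests (FDR across regions),
#' per-sparsity tests and subgroup contrasts. With `out_dir`, writes tidy
#' CSVs and a JSON run manifest; identical inputs and config give
#' byte-identical metric CSVs.
#'
#' @param cohort A `cohort` object or a directory written by
#'   [write_cohort()].
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @return List of class `pipeline_result`: `metrics`, `stats` (list:
#'   `primary`, `per_sparsity`, `correlations`, `nodal`, `subgroups`),
#'   `manifest`.
#' @export
run_pipeline <- function(cohort, config = run_config(), out_dir = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  pheno <- cohort$pheno
  metrics <- tryCatch(cohort_metrics(cohort, config),
                      error = function(e) stop("metrics stage: ",
                                               conditionMessage(e), call. = FALSE))
  if (!all(metrics$id == pheno$id)) stop("stats stage: metrics/phenotype id mismatch")
  stats_out <- tryCatch(
    pipeline_stats(metrics, pheno, config),
    error = function(e) stop("stats stage: ", conditionMessage(e), call. = FALSE))

  manifest <- list(
    config = unclass(config),
    seed = config$seed,
    n_subjects = nrow(pheno),
    n_per_group = as.list(table(pheno$group)),
    n_per_site = as.list(table(pheno$site)),
    package_version = as.character(utils::packageVersion("dynfc")),
    n_windows = attr(metrics, "scheme")$n_windows
  )
  res <- structure(list(metrics = metrics, stats = stats_out,
                        manifest = manifest), class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(res, out_dir)
  res
}

pipeline_stats <- function(metrics, pheno, config) {
  out <- list()
  two_groups <- length(unique(pheno$group)) == 2L
  if (!two_groups) {
    out$primary <- NULL
    message("single-group cohort: group contrasts skipped")
    return(out)
  }
  grid_cols_tc <- grep("^tc_", names(metrics), value = TRUE)
  grid_cols_tpl <- grep("^tpl_", names(metrics), value = TRUE)

  tv <- ancova_group_effect(metrics$temporal_variability, pheno,
                            metric_name = "temporal_variability")
  tc_prof <- sparsity_profile_group_effect(
    as.matrix(metrics[grid_cols_tc]), pheno,
    metric_name = "temporal_correlation")
  tpl_prof <- sparsity_profile_group_effect(
    as.matrix(metrics[grid_cols_tpl]), pheno,
    metric_name = "temporal_path_length")
  primary <- rbind(tv, tc_prof$averaged, tpl_prof$averaged)
  primary$p_fdr <- bh_fdr(primary$p)
  out$primary <- primary
  if (isTRUE(config$per_sparsity)) {
    out$per_sparsity <- rbind(tc_prof$per_sparsity, tpl_prof$per_sparsity)
  }

  # correlations with clinical scores, patients only
  pat <- pheno$group != "HC"
  if (sum(pat) >= 10L) {
    cov_df <- data.frame(age = pheno$age[pat], sex = factor(pheno$sex[pat]))
    if (length(unique(pheno$site[pat])) > 1L) {
      cov_df$site <- factor(pheno$site[pat])
    }
    corr_rows <- list()
    for (v in c("hamd", "duration_months")) {
      if (!v %in% names(pheno)) next
      x <- pheno[[v]][pat]
      if (sum(stats::complete.cases(x)) < 10L) next
      fam <- lapply(names(primary_metric_cols), function(m) {
        partial_spearman(x, metrics[[primary_metric_cols[[m]]]][pat],
                         covariates = cov_df, variable = v, metric_name = m)
      })
      fam <- do.call(rbind, fam)
      fam$p_fdr <- bh_fdr(fam$p)
      corr_rows[[v]] <- fam
    }
    if (length(corr_rows)) out$correlations <- do.call(rbind, corr_rows)
  }

  if (isTRUE(config$nodal)) {
    nodal <- attr(metrics, "nodal")
    nodal_map <- c(temporal_variability = "variability",
                   temporal_correlation = "correlation_avg",
                   temporal_path_length = "path_length_avg")
    rows <- list()
    for (m in names(nodal_map)) {
      M <- nodal[[nodal_map[[m]]]]
      fam <- lapply(colnames(M), function(nd) {
        y <- M[, nd]
        ok <- is.finite(y)
        r <- ancova_group_effect(y[ok], pheno[ok, , drop = FALSE],
                                 metric_name = m)
        r$node <- nd
        r
      })
      fam <- do.call(rbind, fam)
      fam$p_fdr <- bh_fdr(fam$p)   # FDR across regions, per metric
      rows[[m]] <- fam
    }
    out$nodal <- do.call(rbind, rows)
  }

  if (isTRUE(config$subgroups) && "fedn_status" %in% names(pheno) &&
      all(c("FEDN", "nonFEDN") %in% pheno$fedn_status[pat])) {
    md <- metrics[primary_metric_cols]
    names(md) <- names(primary_metric_cols)
    out$subgroups <- subgroup_contrasts(md, pheno)
  }
  out
}

write_pipeline_result <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  m <- res$metrics
  utils::write.csv(m, file.path(out_dir, "metrics_global.csv"), row.names = FALSE)
  nodal <- attr(m, "nodal")
  for (nm in names(nodal)) {
    utils::write.csv(data.frame(id = rownames(nodal[[nm]]), nodal[[nm]],
                                check.names = FALSE),
                     file.path(out_dir, sprintf("metrics_nodal_%s.csv", nm)),
                     row.names = FALSE)
  }
  for (nm in names(res$stats)) {
    utils::write.csv(res$stats[[nm]],
                     file.path(out_dir, sprintf("stats_%s.csv", nm)),
                     row.names = FALSE)
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Stratified split-half of a cohort
#'
#' Randomly splits subjects into two halves, stratified by group and site so
#' each half preserves the design. A stratum with a single subject cannot be
#' split; it is kept whole in one half with a warning.
#'
#' @param pheno Phenotype data frame with `id`, `group`, `site`.
#' @param seed Seed for the random split.
#' @return List with character vectors `half1` and `half2` of subject ids
#'   (disjoint, exhaustive).
#' @export
split_half <- function(pheno, seed = 1) {
  stopifnot(all(c("id", "group", "site") %in% names(pheno)))
  with_seed(seed, {
    half1 <- character(0)
    half2 <- character(0)
    strata <- split(pheno$id, list(pheno$group, pheno$site), drop = TRUE)
    for (ids in strata) {
      ids <- sample(ids)
      if (length(ids) == 1L) {
        warning("stratum with a single subject kept whole in one half")
        half1 <- c(half1, ids)
      } else {
        sel <- seq_along(ids) %% 2L == 1L
        half1 <- c(half1, ids[sel])
        half2 <- c(half2, ids[!sel])
      }
    }
    list(half1 = sort(half1), half2 = sort(half2))
  })
}

#' Subset a cohort by subject ids
#'
#' @param cohort A `cohort` object.
#' @param ids Subject ids to keep.
#' @return A `cohort` restricted to `ids`.
#' @export
subset_cohort <- function(cohort, ids) {
  stopifnot(inherits(cohort, "cohort"), all(ids %in% cohort$pheno$id))
  keep <- cohort$pheno$id %in% ids
  structure(list(ts = cohort$ts[cohort$pheno$id[keep]],
                 pheno = cohort$pheno[keep, , drop = FALSE],
                 truth = if (!is.null(cohort$truth)) cohort$truth[keep, , drop = FALSE],
                 config = cohort$config), class = "cohort")
}
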