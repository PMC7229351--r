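# Synthetic cohort generator: piecewise-stationary connectivity states with
# group-dependent switching rates, realistic covariates and a symptom score
# linked to the realized switching rate. Provides ground truth for
# parameter-recovery tests of the dynamic-network pipeline.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic per-subject substream: subject i of a cohort seeded with s
# always sees the same RNG stream, independent of generation order.
subject_seed <- function(seed, index) {
  (as.numeric(seed) * 10007 + index * 7919) %% 2147483647
}

# Block-structured correlation matrix: nodes assigned to blocks by
# `assignment`; within-block correlation `rho`, zero between blocks.
block_covariance <- function(assignment, rho) {
  same <- outer(assignment, assignment, "==")
  S <- ifelse(same, rho, 0)
  diag(S) <- 1
  S
}

#' Configuration of a synthetic cohort
#'
#' Defines a hidden-Markov covariance-switching model of resting-state ROI
#' time series. Each subject moves through `n_states` connectivity states as
#' a first-order Markov chain (geometric dwell times); within a state,
#' volumes are i.i.d. draws from a zero-mean multivariate normal with that
#' state's covariance plus isotropic observation noise. The group
#' manipulation targets the switching rate only — patients dwell for
#' `dwell_mean_vols["patient"]` volumes on average, controls for
#' `dwell_mean_vols["control"]` — so the injected effect is specifically
#' dynamic, not a difference in connectivity strength. A HAMD-like symptom
#' score is a linear function of each patient's realized switching rate plus
#' noise, so faster observed switching implies higher severity.
#'
#' State covariances default to a community-block recipe: each state
#' partitions the regions into `n_blocks` equal blocks (node-to-block
#' assignment permuted per state, seeded by `seed`) with within-block
#' correlation `within_rho` and zero between blocks. Explicit
#' `state_covariances` override the recipe.
#'
#' @param n_patients,n_controls Group sizes.
#' @param regions Number of ROIs.
#' @param volumes Number of volumes per scan.
#' @param tr_s Repetition time in seconds.
#' @param n_states Number of connectivity states (>= 2 for switching).
#' @param n_blocks Blocks per state in the covariance recipe.
#' @param within_rho Within-block correlation of the recipe, in (0, 1).
#' @param dwell_mean_vols Named numeric: mean dwell time in volumes for
#'   `patient` and `control`.
#' @param observation_noise_sd SD of isotropic observation noise added on
#'   top of the state draw.
#' @param fd_noise_gain Optional covariate effect on the series: subject
#'   noise SD is scaled by `1 + fd_noise_gain * mean_fd` (default 0 = no
#'   covariate effect on the data, covariates are nuisance only).
#' @param symptom_intercept,symptom_slope,symptom_sd HAMD-like score model:
#'   `round(intercept + slope * realized_switch_rate + N(0, sd))`, clipped
#'   to the scale's admissible range (8 to 52 for included patients).
#' @param p_fedn Probability that a patient is first-episode drug-naive.
#' @param n_sites Number of acquisition sites; subjects are assigned
#'   round-robin within group so every site contains both groups.
#' @param state_covariances Optional list of explicit positive-definite
#'   region x region matrices (overrides the recipe).
#' @param seed Integer seed; fully determines the cohort.
#' @return A validated list of class `cohort_config` (with resolved
#'   `state_covariances` and their Cholesky factors).
#' @export
cohort_config <- function(n_patients = 40, n_controls = 40,
                          regions = 20, volumes = 230, tr_s = 2,
                          n_states = 3, n_blocks = 4, within_rho = 0.6,
                          dwell_mean_vols = c(patient = 50, control = 200),
                          observation_noise_sd = 0.5,
                          fd_noise_gain = 0,
                          symptom_intercept = 8, symptom_slope = 500,
                          symptom_sd = 4,
                          p_fedn = 0.42, n_sites = 3,
                          state_covariances = NULL, seed = 1) {
  stopifnot(n_patients >= 0, n_controls >= 0, n_patients + n_controls >= 1,
            regions >= 2, volumes >= 2, tr_s > 0, n_states >= 1,
            n_sites >= 1, observation_noise_sd >= 0, p_fedn >= 0, p_fedn <= 1)
  if (!all(c("patient", "control") %in% names(dwell_mean_vols))) {
    stop("dwell_mean_vols must name 'patient' and 'control'")
  }
  if (any(dwell_mean_vols < 1)) stop("mean dwell time must be >= 1 volume")
  if (is.null(state_covariances)) {
    if (within_rho <= 0 || within_rho >= 1) stop("within_rho must be in (0, 1)")
    if (n_blocks < 1 || n_blocks > regions) stop("invalid n_blocks")
    blocks <- rep(seq_len(n_blocks), length.out = regions)
    state_covariances <- with_seed(seed, lapply(seq_len(n_states), function(s) {
      block_covariance(blocks[sample.int(regions)], within_rho)
    }))
  } else {
    if (length(state_covariances) != n_states) {
      stop("need one covariance matrix per state")
    }
  }
  chol_factors <- lapply(seq_along(state_covariances), function(s) {
    S <- state_covariances[[s]]
    if (!isTRUE(all.equal(S, t(S))) || nrow(S) != regions) {
      stop(sprintf("state %d covariance is not a symmetric %d x %d matrix",
                   s, regions, regions))
    }
    R <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(R)) stop(sprintf("state %d covariance is not positive definite", s))
    R
  })
  structure(list(
    n_patients = n_patients, n_controls = n_controls, regions = regions,
    volumes = volumes, tr_s = tr_s, n_states = n_states,
    n_blocks = n_blocks, within_rho = within_rho,
    dwell_mean_vols = dwell_mean_vols,
    observation_noise_sd = observation_noise_sd,
    fd_noise_gain = fd_noise_gain,
    symptom_intercept = symptom_intercept, symptom_slope = symptom_slope,
    symptom_sd = symptom_sd, p_fedn = p_fedn, n_sites = n_sites,
    state_covariances = state_covariances, chol_factors = chol_factors,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Markov state sequence with geometric dwell times
#'
#' First-order Markov chain over `n_states` states: uniform start,
#' stay-probability `1 - 1/dwell_mean_vols`, uniform jump among the other
#' states, so the expected dwell time equals `dwell_mean_vols`. With a
#' single state (or infinite dwell) the sequence is constant.
#'
#' @param volumes Sequence length.
#' @param n_states Number of states.
#' @param dwell_mean_vols Mean dwell time in volumes (>= 1, may be `Inf`).
#' @return Integer vector of state labels, length `volumes`.
#' @export
generate_state_sequence <- function(volumes, n_states, dwell_mean_vols) {
  stopifnot(volumes >= 1, n_states >= 1, dwell_mean_vols >= 1)
  s <- integer(volumes)
  s[1L] <- sample.int(n_states, 1L)
  if (n_states == 1L || volumes == 1L) return(rep(s[1L], volumes))
  stay <- 1 - 1 / dwell_mean_vols
  u <- stats::runif(volumes - 1L)
  jump_pick <- sample.int(n_states - 1L, volumes - 1L, replace = TRUE)
  for (v in 2L:volumes) {
    if (u[v - 1L] < stay) {
      s[v] <- s[v - 1L]
    } else {
      others <- seq_len(n_states)[-s[v - 1L]]
      s[v] <- others[jump_pick[v - 1L]]
    }
  }
  s
}

#' Simulate one subject
#'
#' Draws the state sequence for the subject's group, then each volume from
#' the current state's multivariate normal plus isotropic noise, along with
#' covariates (age, sex, education, mean framewise displacement) and — for
#' patients — the symptom score, illness duration and FEDN status.
#'
#' @param config A [cohort_config()].
#' @param group `"patient"` or `"control"`.
#' @param seed Substream seed for this subject.
#' @param id Subject identifier attached to the output.
#' @return List with `ts` (an [roi_time_series()]) and `truth` (one-row data
#'   frame: state counts, realized switching rate, covariates, scores).
#' @export
generate_subject <- function(config, group = c("patient", "control"),
                             seed = config$seed, id = "S001") {
  stopifnot(inherits(config, "cohort_config"))
  group <- match.arg(group)
  with_seed(seed, {
    V <- config$volumes
    N <- config$regions
    seq_st <- generate_state_sequence(V, config$n_states,
                                      config$dwell_mean_vols[[group]])
    n_trans <- sum(diff(seq_st) != 0)
    rate <- if (V > 1L) n_trans / (V - 1L) else 0

    # covariates (distributions chosen to resemble an adult clinical cohort)
    age <- round(min(65, max(18, stats::rnorm(1, 37, 13))))
    sex <- if (stats::runif(1) < 0.35) "male" else "female"
    education <- round(min(22, max(5, stats::rnorm(1, 12, 3))))
    mean_fd <- min(0.2, max(0.005, abs(stats::rnorm(1, 0.07, 0.033))))

    noise_sd <- config$observation_noise_sd * (1 + config$fd_noise_gain * mean_fd)
    X <- matrix(0, V, N)
    for (st in unique(seq_st)) {
      idx <- which(seq_st == st)
      Z <- matrix(stats::rnorm(length(idx) * N), length(idx), N)
      X[idx, ] <- Z %*% config$chol_factors[[st]]
    }
    if (noise_sd > 0) X <- X + matrix(stats::rnorm(V * N, sd = noise_sd), V, N)

    if (group == "patient") {
      hamd <- round(config$symptom_intercept + config$symptom_slope * rate +
                      stats::rnorm(1, 0, config$symptom_sd))
      hamd <- min(52, max(8, hamd))
      duration <- round(exp(stats::rnorm(1, log(36), 1)), 1)
      fedn <- if (stats::runif(1) < config$p_fedn) "FEDN" else "nonFEDN"
    } else {
      hamd <- NA_integer_
      duration <- NA_real_
      fedn <- "not_applicable"
    }

    ts <- roi_time_series(X, tr_s = config$tr_s,
                          node_labels = sprintf("roi%03d", seq_len(N)))
    truth <- data.frame(
      id = id, group = if (group == "patient") "MDD" else "HC",
      n_transitions = n_trans, realized_switch_rate = rate,
      dwell_mean_vols = config$dwell_mean_vols[[group]],
      age = age, sex = sex, education = education, mean_fd = mean_fd,
      hamd = hamd, duration_months = duration, fedn_status = fedn,
      stringsAsFactors = FALSE
    )
    list(ts = ts, truth = truth)
  })
}

#' Simulate a full cohort
#'
#' Generates `n_patients + n_controls` subjects with per-subject RNG
#' substreams derived from the config seed (reproducible independent of
#' order), assigns subjects to sites round-robin within group so that every
#' site contains both groups, and assembles the phenotype and ground-truth
#' tables the analysis stages consume.
#'
#' @param config A [cohort_config()].
#' @param out_dir Optional directory: when given, writes one TSV per subject
#'   plus `pheno.csv`, `truth.csv` and the resolved `config.yaml`.
#' @return List of class `cohort`: `ts` (named list of [roi_time_series()]),
#'   `pheno` (data frame: id, group, age, sex, education, mean_fd, site,
#'   hamd, duration_months, fedn_status), `truth`, `config`.
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients + config$n_controls
  groups <- rep(c("patient", "control"), c(config$n_patients, config$n_controls))
  site <- integer(n)
  site[groups == "patient"] <- rep_len(seq_len(config$n_sites), config$n_patients)
  site[groups == "control"] <- rep_len(seq_len(config$n_sites), config$n_controls)
  if (config$n_patients > 0 && config$n_controls > 0) {
    tab <- table(site, groups)
    if (any(tab == 0)) {
      stop("site assignment left a single-group site; use fewer sites or more subjects")
    }
  }
  ids <- sprintf("S%03d", seq_len(n))
  ts_list <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    sub <- generate_subject(config, groups[i],
                            seed = subject_seed(config$seed, i), id = ids[i])
    ts_list[[i]] <- sub$ts
    truth[[i]] <- sub$truth
  }
  names(ts_list) <- ids
  truth <- do.call(rbind, truth)
  truth$site <- paste0("site", site)
  pheno <- truth[, c("id", "group", "age", "sex", "education", "mean_fd",
                     "site", "hamd", "duration_months", "fedn_status")]
  cohort <- structure(list(ts = ts_list, pheno = pheno, truth = truth,
                           config = config), class = "cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (%d MDD / %d HC), %d regions x %d volumes, %d site(s)\n",
              length(x$ts), sum(x$pheno$group == "MDD"),
              sum(x$pheno$group == "HC"), x$config$regions, x$config$volumes,
              length(unique(x$pheno$site))))
  invisible(x)
}

#' Write / read a cohort as plain-text files
#'
#' One TSV of ROI time series per subject (`<id>.tsv`), `pheno.csv`,
#' `truth.csv`, and the resolved configuration as `config.yaml` (seed
#' included) for provenance.
#'
#' @param cohort A `cohort` object.
#' @param dir Directory (created if needed).
#' @return `read_cohort()` returns a `cohort` list (without ground truth if
#'   `truth.csv` is absent).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$ts)) {
    write_roi_ts(cohort$ts[[id]], file.path(dir, paste0(id, ".tsv")))
  }
  utils::write.csv(cohort$pheno, file.path(dir, "pheno.csv"), row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  cfg <- cohort$config
  cfg$state_covariances <- NULL
  cfg$chol_factors <- NULL
  cfg$dwell_mean_vols <- as.list(cfg$dwell_mean_vols)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  pheno <- utils::read.csv(file.path(dir, "pheno.csv"), stringsAsFactors = FALSE)
  ts_list <- lapply(pheno$id, function(id) {
    read_roi_ts(file.path(dir, paste0(id, ".tsv")), tr_s = cfg$tr_s)
  })
  names(ts_list) <- pheno$id
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path)) {
    utils::read.csv(truth_path, stringsAsFactors = FALSE)
  } else NULL
  structure(list(ts = ts_list, pheno = pheno, truth = truth, config = cfg),
            class = "cohort")
}
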