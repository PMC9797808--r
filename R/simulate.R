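#' Atlas-like default parcellation for simulation
#'
#' A 90-ROI, 14-network parcellation emulating the named functional
#' networks of a whole-cortex functional atlas. It includes the five
#' networks under study — LECN, RECN (left/right executive control), ASN
#' (anterior salience), dDMN and vDMN (dorsal/ventral default mode) — plus
#' nine further networks forming the rest of the cortex, with realistic
#' network sizes.
#'
#' @return A [parcellation()] tibble.
#' @export
shirer_like_parcellation <- function() {
  sizes <- c(LECN = 6, RECN = 6, ASN = 7, dDMN = 9, vDMN = 10,
             AUD = 3, BG = 5, HVIS = 2, LANG = 7, PSN = 12,
             PREC = 4, PVIS = 2, SMN = 6, VSP = 11)
  parcellation(tibble::tibble(
    roi = unlist(purrr::imap(sizes, function(k, nm) paste0(nm, "_", seq_len(k))),
                 use.names = FALSE),
    network = rep(names(sizes), sizes)
  ))
}

#' Compact parcellation for scaled-down replicate studies
#'
#' The five studied networks plus one pooled "other" network, 6 ROIs each
#' (36 ROIs). Used where many cohorts must be simulated quickly.
#'
#' @return A [parcellation()] tibble.
#' @export
compact_parcellation <- function() {
  nets <- c("LECN", "RECN", "ASN", "dDMN", "vDMN", "OTH")
  parcellation(tibble::tibble(
    roi = unlist(purrr::map(nets, function(nm) paste0(nm, "_", 1:6))),
    network = rep(nets, each = 6)
  ))
}

#' Configure the synthetic cohort generator
#'
#' Bundles every parameter of the generative model: the parcellation, the
#' block-correlation structure of the ROI signals, subject-level
#' heterogeneity, the behavioural linear model tying latent repetitive
#' negative thinking (RNT) to true network segregation and covariates, and
#' the questionnaire item model.
#'
#' @param seed Root seed; per-subject streams are derived from it so any
#'   subject is re-simulable in isolation.
#' @param n_subjects Cohort size (default 341, the study's sample size).
#' @param parc Parcellation (default [shirer_like_parcellation()]).
#' @param t_points Timepoints per subject (default 740: a 750-volume
#'   acquisition minus 10 discarded initial scans).
#' @param r_within Population within-network Pearson correlation; scalar or
#'   named per network (default 0.5).
#' @param r_between Population between-network correlation (default 0.1).
#' @param sd_r_within,sd_r_between SDs of the subject-level perturbations
#'   of `r_within`/`r_between` (defaults 0.08, 0.025).
#' @param behavioral List with `intercept`, coefficients `dass`,
#'   `emotional_stability`, `cognitive_complaints` (per SD of the latent
#'   trait), `age` (per year), `sex` (female = 1), named vector `sys`
#'   (per unit of true segregation, names = studied networks), and
#'   `noise_sd`. Covariates enter the linear model centered (age at the
#'   mid-range, sex at its probability, segregation at its population
#'   value), so the latent RNT mean equals `intercept`. Defaults plant the study's sign pattern: positive DASS,
#'   cognitive complaints and LECN segregation; negative emotional
#'   stability, age and ASN segregation; null sex and dDMN/vDMN/RECN
#'   segregation.
#' @param age_range,sex_prob Age drawn uniformly on `age_range` (years,
#'   default 43-68); sex is Bernoulli(`sex_prob`).
#' @param item_loading Standardized loading of each questionnaire item on
#'   its latent trait (default 0.85, giving internal consistencies in the
#'   0.9s for the longer scales).
#' @return A validated `simulation_config` list.
#' @details Construction fails if the implied base block correlation matrix
#'   is not positive definite or if `0 <= r_between < r_within < 1` is
#'   violated for any network.
#' @export
simulation_config <- function(seed = 1L,
                              n_subjects = 341L,
                              parc = shirer_like_parcellation(),
                              t_points = 740L,
                              r_within = 0.5,
                              r_between = 0.1,
                              sd_r_within = 0.08,
                              sd_r_between = 0.025,
                              behavioral = list(),
                              age_range = c(43, 68),
                              sex_prob = 0.5,
                              item_loading = 0.85) {
  stopifnot(inherits(parc, "parcellation"), t_points >= 3, n_subjects >= 1)
  nets <- network_levels(parc)
  rw <- expand_r_within(r_within, nets)
  if (any(rw >= 1) || any(rw <= r_between) || r_between < 0) {
    abort("Need 0 <= r_between < r_within < 1 for every network.",
          class = "sysseg_validation_error")
  }
  beh <- utils::modifyList(list(
    intercept = 0,
    dass = 0.8, emotional_stability = -0.45, cognitive_complaints = 0.35,
    age = -0.04, sex = 0,
    sys = c(LECN = 8, ASN = -8, dDMN = 0, vDMN = 0, RECN = 0),
    noise_sd = 0.5
  ), behavioral)
  bad <- setdiff(names(beh$sys), nets)
  if (length(bad) > 0) {
    abort(paste0("behavioral$sys names not in the parcellation: ",
                 paste(bad, collapse = ", ")),
          class = "sysseg_validation_error")
  }
  base <- build_block_correlation(parc, rw, r_between)
  ev <- eigen(base, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    abort("Base block correlation matrix is not positive definite.",
          class = "sysseg_validation_error")
  }
  cfg <- list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
              parc = parc, t_points = as.integer(t_points),
              r_within = rw, r_between = r_between,
              sd_r_within = sd_r_within, sd_r_between = sd_r_between,
              behavioral = beh, age_range = age_range, sex_prob = sex_prob,
              item_loading = item_loading,
              questionnaires = default_questionnaires(),
              # mapping instrument -> latent trait and response shift
              difficulty = c(ptq = 1.0, pswq = 0.85, rrs = 1.35, dass = 1.75,
                             promis = 0.4, ipip_es = -0.35))
  cfg$latent_rnt_sd <- latent_rnt_sd(cfg)
  structure(cfg, class = "simulation_config")
}

expand_r_within <- function(r_within, nets) {
  if (is.null(names(r_within))) {
    if (length(r_within) != 1) {
      abort("`r_within` must be scalar or named per network.",
            class = "sysseg_validation_error")
    }
    return(setNames(rep(r_within, length(nets)), nets))
  }
  if (!all(nets %in% names(r_within))) {
    abort("Named `r_within` must cover every network.",
          class = "sysseg_validation_error")
  }
  r_within[nets]
}

#' Block-structured correlation matrix
#'
#' Builds the R x R correlation matrix implied by a parcellation: 1 on the
#' diagonal, `r_within` (per network) on within-network cells and
#' `r_between` on every cross-network cell.
#'
#' @param parc A [parcellation()].
#' @param r_within Scalar or named per-network within-block correlation.
#' @param r_between Cross-block correlation.
#' @return R x R correlation matrix with ROI dimnames.
#' @export
build_block_correlation <- function(parc, r_within, r_between) {
  nets <- network_levels(parc)
  rw <- expand_r_within(r_within, nets)
  same <- outer(parc$network, parc$network, "==")
  m <- matrix(r_between, nrow(parc), nrow(parc))
  m[same] <- rw[as.character(parc$network)[row(m)[same]]]
  diag(m) <- 1
  dimnames(m) <- list(parc$roi, parc$roi)
  m
}

#' Simulate a zero-mean Gaussian ROI time series
#'
#' Draws `t_points` independent timepoints from a multivariate normal with
#' the given correlation matrix (no temporal autocorrelation; the analysis
#' pipeline only consumes zero-lag correlations).
#'
#' @param corr Symmetric positive-definite correlation matrix.
#' @param t_points Number of timepoints.
#' @param seed Optional seed (deterministic output for a given seed).
#' @return T x R matrix with ROI column names taken from `corr`.
#' @export
simulate_timeseries <- function(corr, t_points, seed = NULL) {
  if (!isSymmetric(unname(corr))) {
    abort("Correlation matrix must be symmetric.",
          class = "sysseg_validation_error")
  }
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    abort("Correlation matrix must be positive definite.",
          class = "sysseg_validation_error")
  }
  if (!is.null(seed)) set.seed(seed)
  m <- MASS::mvrnorm(n = t_points, mu = rep(0, ncol(corr)), Sigma = corr)
  colnames(m) <- colnames(corr)
  m
}

#' Population-truth network summary under the generative model
#'
#' The noiseless analogue of [network_summary()]: with population
#' correlations `r_within` and `r_between`, the Fisher-z within and between
#' averages are `W = atanh(r_within)` and `B = atanh(r_between)` (the
#' negative-value threshold is inactive since both are non-negative), and
#' `SyS = (W - B)/W`. Used as ground truth in parameter-recovery tests.
#'
#' @param config A [simulation_config()], or a named list with elements
#'   `r_within` (scalar/named) and `r_between`.
#' @return Tibble with `network`, `w`, `b`, `sys`.
#' @export
expected_network_summary <- function(config) {
  rw <- config$r_within
  rb <- config$r_between
  if (any(rw <= 0)) {
    abort("Population truth undefined for r_within <= 0.",
          class = "sysseg_undefined_error")
  }
  w <- atanh(rw)
  b <- atanh(rb)
  tibble::tibble(network = names(w), w = unname(w), b = b,
                 sys = unname((w - b) / w))
}

# subject-level RNG stream derived from the root seed
subject_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 2654435) %% 2147483647)
}

# delta-method approximation to the SD of the latent RNT variable, used
# only to put questionnaire item loadings on a standardized scale
latent_rnt_sd <- function(cfg) {
  beh <- cfg$behavioral
  var_sys <- vapply(names(beh$sys), function(nm) {
    rw <- cfg$r_within[[nm]]; rb <- cfg$r_between
    w <- atanh(rw); b <- atanh(rb)
    dw <- (b / w^2) / (1 - rw^2)
    db <- (1 / w) / (1 - rb^2)
    (dw * cfg$sd_r_within)^2 + (db * cfg$sd_r_between)^2
  }, numeric(1))
  sqrt(beh$dass^2 + beh$emotional_stability^2 + beh$cognitive_complaints^2 +
         beh$age^2 * diff(cfg$age_range)^2 / 12 +
         beh$sex^2 * cfg$sex_prob * (1 - cfg$sex_prob) +
         sum(beh$sys^2 * var_sys) + beh$noise_sd^2)
}

# draw integer Likert items monotone in a standardized latent trait
draw_items <- function(latent, spec, loading, difficulty) {
  k <- spec$item_count
  u <- loading * latent + sqrt(1 - loading^2) * rnorm(k)
  scored <- round(spec$item_min +
                    (spec$item_max - spec$item_min) * pnorm(u - difficulty))
  if (spec$reverse_scored) {
    # emit raw responses so that scoring (which reverses) recovers `scored`
    scored <- spec$item_min + spec$item_max - scored
  }
  as.integer(scored)
}

# simulate one subject: perturbed correlation structure, time series,
# estimated connectivity summaries, latent traits and questionnaire items
simulate_subject <- function(i, cfg, return_timeseries = FALSE) {
  set.seed(subject_seed(cfg$seed, i))
  parc <- cfg$parc
  nets <- network_levels(parc)

  # subject's perturbed block correlations (PD enforced, bounded retries)
  for (attempt in 1:20) {
    rw_i <- pmin(pmax(cfg$r_within + rnorm(length(nets), 0, cfg$sd_r_within),
                      0.05), 0.95)
    rb_i <- min(max(cfg$r_between + rnorm(1, 0, cfg$sd_r_between), 0),
                min(rw_i) - 0.05)
    corr <- build_block_correlation(parc, rw_i, rb_i)
    ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) > 0) break
    if (attempt == 20) {
      abort("Could not draw a positive-definite subject correlation.",
            class = "sysseg_validation_error")
    }
  }
  ts <- simulate_timeseries(corr, cfg$t_points)

  # estimated connectivity summaries (what the real pipeline would measure)
  conn <- compute_connectivity(ts, subject_id = paste0("s", i))
  nsum <- net_summary_values(align_conn(conn, parc), parc)

  # true (population) segregation for the studied networks
  studied <- names(cfg$behavioral$sys)
  w_true <- atanh(rw_i[match(studied, nets)])
  b_true <- atanh(rb_i)
  sys_true <- setNames((w_true - b_true) / w_true, studied)

  # covariates and latent traits; covariates enter the linear model
  # centered so the latent RNT mean equals the intercept
  age <- runif(1, cfg$age_range[1], cfg$age_range[2])
  sex <- rbinom(1, 1, cfg$sex_prob)
  dass_l <- rnorm(1); es_l <- rnorm(1); cc_l <- rnorm(1)
  beh <- cfg$behavioral
  sys_pop <- expected_network_summary(cfg)
  sys_ctr <- sys_true[names(beh$sys)] -
    sys_pop$sys[match(names(beh$sys), sys_pop$network)]
  rnt_l <- beh$intercept + beh$dass * dass_l +
    beh$emotional_stability * es_l + beh$cognitive_complaints * cc_l +
    beh$age * (age - mean(cfg$age_range)) +
    beh$sex * (sex - cfg$sex_prob) +
    sum(beh$sys * sys_ctr) +
    rnorm(1, 0, beh$noise_sd)
  rnt_std <- rnt_l / cfg$latent_rnt_sd

  traits <- c(ptq = rnt_std, pswq = rnt_std, rrs = rnt_std,
              dass = dass_l, promis = cc_l, ipip_es = es_l)
  qs <- cfg$questionnaires
  items <- purrr::imap(qs, function(spec, nm) {
    draw_items(traits[[nm]], spec, cfg$item_loading, cfg$difficulty[[nm]])
  })
  scored <- purrr::imap(items, function(it, nm) {
    sp <- qs[[nm]]
    if (sp$reverse_scored) sp$item_min + sp$item_max - it else it
  })

  lw <- tolower
  nums <- c(
    age = age, sex = sex,
    ptq = sum(scored$ptq), pswq = sum(scored$pswq),
    rrs = sum(scored$rrs),
    brooding = sum(scored$rrs[qs$rrs$subscales$brooding]),
    dass = sum(scored$dass),
    cognitive_complaints = sum(scored$promis),
    emotional_stability = sum(scored$ipip_es),
    setNames(nsum$sys[studied], paste0("sys_", lw(studied))),
    setNames(nsum$w[studied], paste0("within_", lw(studied)))
  )
  pairs <- list(c("LECN", "ASN"), c("LECN", "dDMN"), c("LECN", "vDMN"),
                c("ASN", "dDMN"), c("ASN", "vDMN"))
  for (pr in pairs) {
    if (all(pr %in% nets)) {
      nums[paste0("fc_", lw(pr[1]), "_", lw(pr[2]))] <- nsum$pair[pr[1], pr[2]]
    }
  }
  truth <- c(rnt_latent = rnt_l, dass_latent = dass_l, es_latent = es_l,
             cc_latent = cc_l, r_between_true = rb_i,
             setNames(sys_true[studied], paste0("true_sys_", lw(studied))))

  list(nums = nums, truth = truth,
       seg_w = nsum$w, seg_b = nsum$b, seg_sys = nsum$sys, pair = nsum$pair,
       items = items,
       timeseries = if (return_timeseries) ts else NULL)
}

#' Simulate a full synthetic cohort
#'
#' Generates, per subject: a perturbed block-correlation ROI time series,
#' its estimated connectivity summaries (network segregation, within- and
#' between-network connectivity), covariates, a latent RNT value from the
#' configured linear model on true segregation and covariates, and
#' item-level questionnaire responses whose totals are monotone in the
#' latent traits and bounded by the instruments' score ranges. The cohort
#' table arrives with z-scores and the RNT composite already appended.
#'
#' @param config A [simulation_config()].
#' @param return_timeseries Keep the per-subject T x R matrices? (Off by
#'   default; they are large.)
#' @return A list with elements
#'   * `cohort`: tibble, one row per subject (totals, composite, estimated
#'     segregation and connectivity predictors),
#'   * `items`: named list of n x k item matrices per instrument,
#'   * `truth`: tibble of per-subject latent values and true segregation,
#'   * `segregation`: tidy per-subject, per-network `w`/`b`/`sys` table,
#'   * `pairwise`: tidy per-subject network-pair mean connectivity,
#'   * `timeseries`: named list of matrices (if requested),
#'   * `config`: the configuration used.
#'   Fully reproducible from `config$seed`.
#' @export
simulate_cohort <- function(config, return_timeseries = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_subjects
  nets <- network_levels(config$parc)
  k <- length(nets)
  ids <- paste0("s", seq_len(n))
  subs <- purrr::map(seq_len(n), simulate_subject, cfg = config,
                     return_timeseries = return_timeseries)

  cohort <- tibble::as_tibble(do.call(rbind, purrr::map(subs, "nums")))
  cohort <- dplyr::mutate(cohort, subject = ids, .before = 1)
  cohort <- rnt_composite(cohort)

  items <- purrr::map(setNames(nm = names(config$questionnaires)),
                      function(nm) {
                        do.call(rbind, purrr::map(subs, function(s) s$items[[nm]]))
                      })

  truth <- tibble::as_tibble(do.call(rbind, purrr::map(subs, "truth")))
  truth <- dplyr::mutate(truth, subject = ids, .before = 1)

  segregation <- tibble::tibble(
    subject = rep(ids, each = k),
    network = rep(nets, n),
    w = unlist(purrr::map(subs, "seg_w"), use.names = FALSE),
    b = unlist(purrr::map(subs, "seg_b"), use.names = FALSE),
    sys = unlist(purrr::map(subs, "seg_sys"), use.names = FALSE)
  )
  off <- which(row(diag(k)) != col(diag(k)))
  pairwise <- tibble::tibble(
    subject = rep(ids, each = length(off)),
    net_a = rep(nets[row(diag(k))[off]], n),
    net_b = rep(nets[col(diag(k))[off]], n),
    fc = unlist(purrr::map(subs, function(s) s$pair[off]), use.names = FALSE)
  )

  out <- list(cohort = cohort, items = items, truth = truth,
              segregation = segregation, pairwise = pairwise,
              config = config)
  if (return_timeseries) {
    out$timeseries <- setNames(purrr::map(subs, "timeseries"), ids)
  }
  out
}
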