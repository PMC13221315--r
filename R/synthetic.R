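#' Configuration of a synthetic stakeholder cohort
#'
#' Describes a cohort to simulate: the hierarchy, the ground-truth domain
#' and local weights the participants' judgments scatter around, the group
#' design, and the noise levels.  Defaults emulate the reference workshop:
#' five stakeholder groups of seven participants each (35 total), ground
#' truth equal to the bundled reference model, moderate judgment noise.
#'
#' @param hierarchy a [hierarchy_spec()].
#' @param true_domain_weights named weights over the hierarchy's domains
#'   (sum 1).
#' @param true_local_weights named list: domain id -> local weights.
#' @param groups named integer vector: group label -> participant count
#'   (default the five reference categories, 7 each).
#' @param sigma_ahp standard deviation of Gaussian noise on the *log*
#'   pairwise ratios (dimensionless; 0 = perfectly consistent judges;
#'   default 0.15, a level at which essentially every judge still meets
#'   CR <= 0.1 on a 6x6 matrix).
#' @param sigma_swing standard deviation, in points, of additive noise on
#'   the 0-100 SWING scores (default 10).
#' @param snap_to_scale snap generated comparisons to the Saaty 1-9 scale,
#'   as a paper elicitation form would force (default `FALSE`: snapping
#'   biases ratios and is kept out of recovery analyses).
#' @param group_truth_overrides optional named list: group label -> domain
#'   weight vector replacing `true_domain_weights` for that group, for
#'   simulating systematic between-group differences.
#' @param seed integer seed; cohorts are reproducible given the seed.
#' @return object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(hierarchy = default_hierarchy(),
                          true_domain_weights = reference_domain_weights(),
                          true_local_weights = reference_local_weights(),
                          groups = setNames(rep(7L, 5L), default_groups()),
                          sigma_ahp = 0.15,
                          sigma_swing = 10,
                          snap_to_scale = FALSE,
                          group_truth_overrides = NULL,
                          seed = NULL) {
  weight_vector(true_domain_weights[domain_ids(hierarchy)])
  for (d in domain_ids(hierarchy)) {
    lw <- true_local_weights[[d]]
    if (is.null(lw))
      stop("true local weights missing for domain '", d, "'", call. = FALSE)
    if (!setequal(names(lw), domain_indicators(hierarchy, d)))
      stop("true local weights for '", d,
           "' do not match its indicators", call. = FALSE)
    weight_vector(lw)
  }
  if (is.null(names(groups)) || any(groups < 1L))
    stop("groups must be a named vector of counts >= 1", call. = FALSE)
  if (sigma_ahp < 0 || sigma_swing < 0)
    stop("noise sigmas must be nonnegative", call. = FALSE)
  for (g in names(group_truth_overrides)) {
    if (!g %in% names(groups))
      stop("truth override for unknown group '", g, "'", call. = FALSE)
    weight_vector(group_truth_overrides[[g]][domain_ids(hierarchy)])
  }
  structure(list(hierarchy = hierarchy,
                 true_domain_weights = true_domain_weights,
                 true_local_weights = true_local_weights,
                 groups = groups, sigma_ahp = sigma_ahp,
                 sigma_swing = sigma_swing,
                 snap_to_scale = snap_to_scale,
                 group_truth_overrides = group_truth_overrides,
                 seed = seed),
            class = "cohort_config")
}

snap_saaty <- function(x) {
  # x >= 1 goes to the nearest integer 1..9; x < 1 mirrors through the
  # reciprocal so snapped matrices stay exactly reciprocal
  if (x >= 1) {
    max(1, min(9, round(x)))
  } else {
    1 / max(1, min(9, round(1 / x)))
  }
}

#' Simulate one pairwise comparison matrix
#'
#' Multiplicative log-normal noise around the consistent matrix of a known
#' weight vector: for `i < j`, `a_ij = (w_i / w_j) * exp(eps)` with
#' `eps ~ N(0, sigma_ahp^2)`; the lower triangle is mirrored reciprocally,
#' so reciprocity holds by construction at any noise level.  At
#' `sigma_ahp = 0` the matrix is exactly consistent (CR = 0) and its
#' principal eigenvector equals `true_weights`.
#'
#' @param true_weights named weight vector (sum 1) over the elements.
#' @param sigma_ahp log-scale noise SD, >= 0.
#' @param snap_to_scale snap each upper-triangle entry to the nearest
#'   Saaty value (reciprocals mirrored).
#' @return a [comparison_matrix()].
#' @details Draws from the current RNG stream; seed control belongs to the
#'   caller (see [generate_cohort()]).
#' @export
generate_matrix <- function(true_weights, sigma_ahp = 0,
                            snap_to_scale = FALSE) {
  w <- weight_vector(true_weights)
  n <- length(w)
  ids <- names(w)
  A <- matrix(1, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      a <- (w[[i]] / w[[j]]) * exp(rnorm(1L, 0, sigma_ahp))
      if (snap_to_scale) a <- snap_saaty(a)
      A[i, j] <- a
      A[j, i] <- 1 / a
    }
  }
  comparison_matrix(A, ids, raw = snap_to_scale)
}

#' Simulate one SWING score table
#'
#' Inverts the normalization algebra: noiseless scores are
#' `100 * alpha_i / max(alpha)`, so normalizing them recovers the true
#' local weights exactly.  Additive Gaussian noise (SD `sigma_swing`
#' points) is then applied, scores are clipped to stay in (0, 100] (floor
#' at 1 point), and the table is rescaled so its maximum is exactly 100 —
#' the anchor every valid SWING table must carry.
#'
#' @param domain_id domain the table belongs to.
#' @param true_local named local weight vector for the domain.
#' @param sigma_swing score noise SD in points, >= 0.
#' @return a [swing_table()].
#' @export
generate_swing <- function(domain_id, true_local, sigma_swing = 0) {
  a <- weight_vector(true_local)
  s <- 100 * a / max(a)
  if (sigma_swing > 0) {
    s <- s + rnorm(length(s), 0, sigma_swing)
    s <- pmin(pmax(s, 1), 100)
  }
  s <- s * (100 / max(s))
  s[which.max(s)] <- 100               # anchor exact despite rounding
  swing_table(domain_id, s)
}

#' Generate a full synthetic stakeholder cohort
#'
#' One [judgment_set()] per configured participant: a pairwise comparison
#' matrix over the domains and one SWING table per domain, all scattered
#' around the configured ground truth.  Deterministic under the config's
#' seed; participant ids are `P01`, `P02`, ... in group order.
#'
#' @param config a [cohort_config()].
#' @return list of [judgment_set()]s.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 42))
#' length(cohort)   # 35
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  h <- config$hierarchy
  dids <- domain_ids(h)
  with_seed(config$seed, {
    k <- 0L
    out <- list()
    for (g in names(config$groups)) {
      truth <- config$group_truth_overrides[[g]]
      if (is.null(truth)) truth <- config$true_domain_weights
      for (i in seq_len(config$groups[[g]])) {
        k <- k + 1L
        m <- generate_matrix(truth[dids], config$sigma_ahp,
                             config$snap_to_scale)
        tabs <- lapply(dids, function(d)
          generate_swing(d, config$true_local_weights[[d]],
                         config$sigma_swing))
        out[[k]] <- judgment_set(sprintf("P%02d", k), g, m, tabs, h,
                                 groups = names(config$groups))
      }
    }
    out
  })
}

#' Weight-recovery experiment
#'
#' The validation harness for the whole pipeline: for each replicate it
#' generates a cohort, screens by CR <= 0.1, aggregates the retained
#' matrices (geometric mean) and solves for overall domain weights, then
#' measures the mean absolute error (MAE) against the configured truth and
#' the fraction of participants failing the consistency screen.
#'
#' @param config a [cohort_config()]; its `seed` anchors the replicate
#'   seeds (`seed + 1 ... seed + replicates`).
#' @param replicates number of cohorts to simulate, >= 1.
#' @return list with `per_replicate` (data.frame: `replicate`, `mae`,
#'   `rejection_rate`), `abs_error` (replicates x domains matrix), and
#'   `summary` (median MAE overall and per domain, mean rejection rate).
#' @export
recovery_experiment <- function(config, replicates = 100L) {
  stopifnot(inherits(config, "cohort_config"), replicates >= 1L)
  base_seed <- if (is.null(config$seed)) 0L else config$seed
  dids <- domain_ids(config$hierarchy)
  truth <- config$true_domain_weights[dids]
  err <- matrix(NA_real_, replicates, length(dids),
                dimnames = list(NULL, dids))
  rej <- numeric(replicates)
  for (r in seq_len(replicates)) {
    cfg <- config
    cfg$seed <- base_seed + r
    cohort <- generate_cohort(cfg)
    scr <- screen_judgments(cohort)
    rej[r] <- length(scr$rejected) / length(cohort)
    if (!length(scr$retained)) next    # degenerate replicate: all rejected
    w <- group_domain_weights(scr$retained, config$hierarchy)$overall$weights
    err[r, ] <- abs(w[dids] - truth)
  }
  mae <- rowMeans(err)
  list(per_replicate = data.frame(replicate = seq_len(replicates),
                                  mae = mae, rejection_rate = rej),
       abs_error = err,
       summary = list(median_mae = median(mae, na.rm = TRUE),
                      median_mae_per_domain =
                        apply(err, 2L, median, na.rm = TRUE),
                      mean_rejection_rate = mean(rej)))
}
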