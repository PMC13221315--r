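## Evaluate an expression under a private, seeded RNG stream, restoring the
## caller's .Random.seed afterwards so library calls never perturb user code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  expr
}

#' Bootstrap confidence intervals for overall domain weights
#'
#' Resamples participants with replacement, recomputes the overall domain
#' weights (geometric-mean aggregate, principal eigenvector) per replicate,
#' and reports percentile intervals.  Resampling is stratified by
#' stakeholder group by default, preserving the per-group counts of the
#' elicitation design; the unit of resampling is the whole participant,
#' never individual matrix entries, so within-person dependence among
#' judgments is respected.
#'
#' Participants are internally ordered by (group, participant id) before
#' resampling, so summaries are invariant to the input order of `judgments`
#' for a fixed seed.
#'
#' @param judgments list of (already screened) [judgment_set()]s, >= 2.
#' @param hierarchy the [hierarchy_spec()].
#' @param B number of bootstrap replicates (default 10000).
#' @param level confidence level in (0, 1) (default 0.95).
#' @param seed integer seed; identical seeds give identical summaries.
#' @param stratified resample within stakeholder groups (default) or from
#'   the pooled cohort.
#' @return data.frame with one row per domain: `element`, `point`,
#'   `lower`, `upper`, `B`, `level`, `seed`.
#' @export
bootstrap_domain_weights <- function(judgments, hierarchy, B = 10000L,
                                     level = 0.95, seed = NULL,
                                     stratified = TRUE) {
  if (length(judgments) < 2L)
    stop("bootstrap needs at least 2 participants", call. = FALSE)
  if (B < 1L) stop("B must be >= 1", call. = FALSE)
  if (level <= 0 || level >= 1)
    stop("level must be in (0, 1)", call. = FALSE)
  grp <- vapply(judgments, `[[`, character(1L), "group")
  pid <- vapply(judgments, `[[`, character(1L), "participant_id")
  ord <- order(grp, pid)
  judgments <- judgments[ord]
  grp <- grp[ord]
  dids <- domain_ids(hierarchy)
  n <- length(dids)
  m <- length(judgments)
  ## log-matrices once; a replicate's aggregate is exp(mean(log)) over the
  ## resampled index set
  logs <- array(unlist(lapply(judgments,
                              function(j) log(unclass(j$matrix)))),
                dim = c(n, n, m))
  solve_idx <- function(idx) {
    G <- exp(rowMeans(logs[, , idx, drop = FALSE], dims = 2L))
    dimnames(G) <- list(dids, dids)
    principal_weights(G)$weights
  }
  point <- solve_idx(seq_len(m))
  strata <- if (stratified) split(seq_len(m), grp) else list(seq_len(m))
  reps <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- unlist(lapply(strata, function(s)
        s[sample.int(length(s), length(s), replace = TRUE)]),
        use.names = FALSE)
      solve_idx(idx)
    }, numeric(n))
  })
  if (n == 1L) reps <- matrix(reps, nrow = 1L)
  alpha <- (1 - level) / 2
  qs <- apply(reps, 1L, quantile, probs = c(alpha, 1 - alpha), names = FALSE)
  data.frame(element = dids, point = unname(point),
             lower = qs[1L, ], upper = qs[2L, ],
             B = B, level = level,
             seed = if (is.null(seed)) NA_integer_ else seed,
             stringsAsFactors = FALSE)
}

#' Kruskal-Wallis rank test
#'
#' Nonparametric k-sample comparison: the H statistic from pooled ranks
#' with the standard tie correction, and a p-value from the chi-square
#' approximation on `groups - 1` degrees of freedom.  Computation is
#' delegated to [stats::kruskal.test()].
#'
#' @param samples named list: group label -> numeric vector of values; at
#'   least two groups, none empty.
#' @return list with `H`, `df`, `p_value` and `sizes` (named group sizes).
#' @export
#' @examples
#' kruskal_wallis(list(A = c(1, 2, 3), B = c(4, 5, 6)))$H  # 3.857143
kruskal_wallis <- function(samples) {
  if (length(samples) < 2L)
    stop("Kruskal-Wallis needs at least 2 groups", call. = FALSE)
  sizes <- vapply(samples, length, integer(1L))
  if (any(sizes == 0L))
    stop("empty group: ", names(samples)[sizes == 0L][1L], call. = FALSE)
  x <- unlist(samples, use.names = FALSE)
  g <- factor(rep(names(samples), sizes), levels = names(samples))
  if (length(unique(x)) == 1L) {
    # every observation tied: no rank variation, H = 0 by definition
    # (the tie-correction denominator of the usual formula degenerates)
    return(list(H = 0, df = length(samples) - 1L, p_value = 1,
                sizes = sizes))
  }
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, sizes = sizes)
}

#' Compare domain weights across stakeholder groups
#'
#' Each retained participant's own comparison matrix yields a personal
#' domain-weight vector (principal eigenvector); for every domain, those
#' participant-level weights are compared across stakeholder groups with
#' the Kruskal-Wallis test.  Individual weights — not group aggregates —
#' are the test unit, so each group contributes its full sample size.
#'
#' @param judgments list of screened [judgment_set()]s spanning >= 2
#'   groups.
#' @param hierarchy the [hierarchy_spec()].
#' @return data.frame with one row per domain: `domain_id`, `H`, `df`,
#'   `p_value`; group sizes in attribute `"sizes"`.
#' @export
compare_groups <- function(judgments, hierarchy) {
  grp <- vapply(judgments, `[[`, character(1L), "group")
  if (length(unique(grp)) < 2L)
    stop("group comparison needs participants from at least 2 groups",
         call. = FALSE)
  dids <- domain_ids(hierarchy)
  W <- vapply(judgments,
              function(j) principal_weights(j$matrix)$weights[dids],
              numeric(length(dids)))
  res <- lapply(seq_along(dids), function(i) {
    kruskal_wallis(split(W[i, ], grp))
  })
  out <- data.frame(domain_id = dids,
                    H = vapply(res, `[[`, numeric(1L), "H"),
                    df = vapply(res, `[[`, numeric(1L), "df"),
                    p_value = vapply(res, `[[`, numeric(1L), "p_value"),
                    stringsAsFactors = FALSE)
  attr(out, "sizes") <- res[[1L]]$sizes
  out
}
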