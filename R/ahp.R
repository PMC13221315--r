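#' Principal-eigenvector weights of a comparison matrix
#'
#' Solves the AHP eigenproblem `(A - lambda_max I) w = 0` for the dominant
#' eigenpair of a positive reciprocal matrix by power iteration with L1
#' renormalization.  By Perron-Frobenius the dominant eigenvalue of a
#' positive matrix is simple and its eigenvector strictly positive, so the
#' iteration converges geometrically; for an exactly consistent matrix
#' (rank one, `a_ij = w_i/w_j`) it converges in a single step.
#'
#' @param matrix a [comparison_matrix()] (any positive reciprocal square
#'   matrix with ids is accepted).
#' @param tol convergence threshold: successive iterates must differ by
#'   less than `tol` in the max norm (default `1e-12`).
#' @param max_iter iteration cap (default 10000).
#' @return list with `weights` (named, L1-normalized principal eigenvector)
#'   and `lambda_max` (the principal eigenvalue, `>= n`).
#' @details The returned pair satisfies
#'   `||A w - lambda_max w|| / ||w|| <= 1e-9`; if the iteration budget is
#'   exhausted before that residual is reached an error reports the
#'   residual achieved.
#' @export
#' @examples
#' m <- comparison_matrix(rbind(c(1, 3), c(1/3, 1)), c("a", "b"))
#' principal_weights(m)   # weights 0.75 / 0.25, lambda_max = 2
principal_weights <- function(matrix, tol = 1e-12, max_iter = 10000L) {
  A <- unclass(matrix)
  n <- nrow(A)
  if (n < 2L) stop("matrix order must be >= 2", call. = FALSE)
  if (any(A <= 0)) stop("matrix entries must be positive", call. = FALSE)
  w <- rep(1 / n, n)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    v <- as.vector(A %*% w)
    v <- v / sum(v)
    if (max(abs(v - w)) < tol) {
      w <- v
      converged <- TRUE
      break
    }
    w <- v
  }
  Aw <- as.vector(A %*% w)
  lambda <- sum(Aw)                      # w has unit L1 norm and Aw ~ lambda w
  resid <- sqrt(sum((Aw - lambda * w)^2)) / sqrt(sum(w^2))
  if (!converged && resid > 1e-9)
    stop(sprintf(
      "power iteration did not converge in %d iterations (residual %.3e)",
      max_iter, resid), call. = FALSE)
  names(w) <- rownames(A)
  list(weights = weight_vector(w), lambda_max = lambda)
}

#' Saaty consistency index
#'
#' `CI = (lambda_max - n) / (n - 1)`.  For positive reciprocal matrices
#' `lambda_max >= n`, so CI is nonnegative; tiny negative values within
#' `1e-9` (floating-point noise at exact consistency) are clamped to zero.
#'
#' @param lambda_max principal eigenvalue.
#' @param n matrix order, `>= 2`.
#' @return the consistency index.
#' @export
consistency_index <- function(lambda_max, n) {
  if (n < 2L) stop("consistency index needs n >= 2", call. = FALSE)
  if (lambda_max < n - 1e-9)
    stop("lambda_max (", lambda_max, ") below matrix order ", n,
         ": not a principal eigenvalue of a reciprocal matrix",
         call. = FALSE)
  max((lambda_max - n) / (n - 1), 0)
}

#' Saaty random indices for matrix orders 1-15
#'
#' Average consistency indices of randomly generated reciprocal matrices,
#' the denominators of the consistency ratio.  The standard published table
#' is bundled; pass an alternative via the `ri` argument of
#' [consistency_ratio()] to use a different calibration.
#' @return numeric vector of length 15, `random_index()[n]` is RI for
#'   order `n`.
#' @export
random_index <- function() {
  c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49,
    1.51, 1.48, 1.56, 1.57, 1.59)
}

#' Consistency ratio
#'
#' `CR = CI / RI(n)` for `n >= 3`; defined as 0 for `n <= 2`, where a
#' reciprocal matrix is always consistent (RI = 0, the division is
#' bypassed).  Judgments with `CR <= 0.1` are conventionally acceptable.
#'
#' @param CI consistency index, `>= 0`.
#' @param n matrix order, between 1 and the length of the RI table.
#' @param ri random-index table (default [random_index()]).
#' @return the consistency ratio.
#' @export
consistency_ratio <- function(CI, n, ri = random_index()) {
  if (n < 1L) stop("matrix order must be >= 1", call. = FALSE)
  if (n > length(ri))
    stop("matrix order ", n, " exceeds the random-index table (max ",
         length(ri), ")", call. = FALSE)
  if (CI < 0) stop("CI must be nonnegative", call. = FALSE)
  if (n <= 2L) return(0)
  CI / ri[n]
}

#' Full consistency diagnostics for one matrix
#'
#' @param matrix a [comparison_matrix()].
#' @param ri random-index table.
#' @return object of class `consistency_report`: list with `lambda_max`,
#'   `n`, `CI`, `RI`, `CR` and the logical `acceptable` (`CR <= 0.1`).
#' @export
consistency_report <- function(matrix, ri = random_index()) {
  n <- nrow(matrix)
  pw <- principal_weights(matrix)
  ci <- consistency_index(pw$lambda_max, n)
  cr <- consistency_ratio(ci, n, ri)
  structure(list(lambda_max = pw$lambda_max, n = n, CI = ci,
                 RI = if (n <= 2L) 0 else ri[n], CR = cr,
                 acceptable = cr <= 0.1 + 1e-12,
                 weights = pw$weights),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf(
    "AHP consistency: n = %d, lambda_max = %.6f, CI = %.4f, CR = %.4f (%s)\n",
    x$n, x$lambda_max, x$CI, x$CR,
    if (x$acceptable) "acceptable" else "rejected"))
  invisible(x)
}

#' Screen judgments by consistency ratio
#'
#' Splits a cohort into participants whose comparison matrix meets the
#' CR <= 0.1 threshold (retained for analysis) and those who fail it, each
#' rejection carrying its [consistency_report()].  Idempotent: screening a
#' retained set again changes nothing.
#'
#' @param judgments list of [judgment_set()]s.
#' @param threshold CR acceptance threshold (default 0.1).
#' @param ri random-index table.
#' @return list with `retained` (judgment sets), `rejected` (list of
#'   `list(judgment, report)`), and `reports` (a data.frame of per-
#'   participant diagnostics).
#' @export
screen_judgments <- function(judgments, threshold = 0.1,
                             ri = random_index()) {
  reports <- lapply(judgments, function(j) consistency_report(j$matrix, ri))
  ok <- vapply(reports, function(r) r$CR <= threshold + 1e-12, logical(1L))
  summary <- data.frame(
    participant = vapply(judgments, `[[`, character(1L), "participant_id"),
    group = vapply(judgments, `[[`, character(1L), "group"),
    lambda_max = vapply(reports, `[[`, numeric(1L), "lambda_max"),
    CI = vapply(reports, `[[`, numeric(1L), "CI"),
    CR = vapply(reports, `[[`, numeric(1L), "CR"),
    retained = ok, stringsAsFactors = FALSE)
  list(retained = judgments[ok],
       rejected = Map(function(j, r) list(judgment = j, report = r),
                      judgments[!ok], reports[!ok]),
       reports = summary)
}

#' Element-wise geometric mean of comparison matrices
#'
#' Aggregation of individual judgments (AIJ): each entry of the aggregate
#' is the geometric mean of the corresponding entries across judges.
#' Computed on the upper triangle in log space and mirrored, so the result
#' is exactly reciprocal by construction; the geometric mean is the only
#' averaging rule that preserves reciprocity.
#'
#' @param matrices nonempty list of [comparison_matrix()]s sharing order
#'   and element ids.
#' @return the aggregated [comparison_matrix()] (not scale-restricted).
#' @export
geometric_mean_matrix <- function(matrices) {
  if (!length(matrices)) stop("no matrices to aggregate", call. = FALSE)
  ids <- rownames(matrices[[1L]])
  n <- length(ids)
  for (m in matrices) {
    if (!identical(rownames(m), ids))
      stop("matrices must share order and element ids", call. = FALSE)
  }
  logsum <- Reduce(`+`, lapply(matrices, function(m) log(unclass(m))))
  G <- exp(logsum / length(matrices))
  up <- upper.tri(G)
  G[t(up)] <- t(1 / G)[t(up)]            # mirror reciprocals exactly
  diag(G) <- 1
  comparison_matrix(G, ids, raw = FALSE)
}

#' Group-wise and overall AHP domain weights
#'
#' For each stakeholder group, aggregates the retained members' matrices
#' with [geometric_mean_matrix()] and solves for the principal eigenvector;
#' the overall weights come either from pooling all retained matrices
#' directly (`pooling = "participants"`, default) or from aggregating the
#' group-level matrices (`pooling = "groups"`).  Groups left with no
#' retained participants are dropped with a warning.
#'
#' @param judgments list of screened [judgment_set()]s.
#' @param hierarchy the [hierarchy_spec()].
#' @param pooling how the overall matrix pools participants.
#' @param expected_groups optional label set; a warning names any expected
#'   group with no retained participants (it is omitted from the output).
#' @return list with `overall` (`weights`, `report`) and `groups` (named
#'   list of the same shape, one entry per group present).
#' @export
group_domain_weights <- function(judgments, hierarchy,
                                 pooling = c("participants", "groups"),
                                 expected_groups = NULL) {
  pooling <- match.arg(pooling)
  if (!length(judgments))
    stop("no judgments to aggregate", call. = FALSE)
  grp <- vapply(judgments, `[[`, character(1L), "group")
  if (!is.null(expected_groups)) {
    empty <- setdiff(expected_groups, grp)
    if (length(empty))
      warning("group(s) with no retained participants omitted: ",
              paste(empty, collapse = ", "), call. = FALSE)
  }
  mats <- lapply(judgments, `[[`, "matrix")
  by_group <- split(mats, grp)
  groups <- lapply(by_group, function(ms) {
    agg <- geometric_mean_matrix(ms)
    rep <- consistency_report(agg)
    list(weights = rep$weights, report = rep, n = length(ms))
  })
  overall_mat <- if (pooling == "participants") {
    geometric_mean_matrix(mats)
  } else {
    geometric_mean_matrix(lapply(by_group, geometric_mean_matrix))
  }
  orep <- consistency_report(overall_mat)
  list(overall = list(weights = orep$weights, report = orep,
                      n = length(mats)),
       groups = groups)
}
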