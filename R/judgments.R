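#' The Saaty 1-9 judgment scale
#'
#' Admissible values for a raw (participant-entered) pairwise comparison:
#' the integers 1..9 and their reciprocals.
#' @return sorted numeric vector of the 17 admissible values.
#' @export
saaty_scale <- function() sort(unique(c(1 / (9:1), 1:9)))

is_on_saaty_scale <- function(x, tol = 1e-6) {
  # relative tolerance so that decimal renderings of 1/3, 1/7, ... validate
  s <- saaty_scale()
  vapply(x, function(v) any(abs(v - s) <= tol * s), logical(1L))
}

#' Pairwise comparison matrix
#'
#' A positive reciprocal matrix of relative-importance judgments over a set
#' of elements (here: domains).  Entry `a[i, j] > 1` means element `i` is
#' judged more important than element `j`; reciprocity `a[j, i] = 1/a[i, j]`
#' is required within relative tolerance `1e-9`, and the diagonal must be
#' exactly 1.
#'
#' @param values square numeric matrix of positive entries.
#' @param element_ids character vector of element ids for rows/columns;
#'   defaults to the rownames of `values`.
#' @param raw if `TRUE`, the matrix is participant-entered and every
#'   off-diagonal entry must lie on the Saaty 1-9 scale (within relative
#'   tolerance `1e-6`).  Aggregated matrices use `raw = FALSE`.
#' @return the validated matrix with class `comparison_matrix` and
#'   dimnames set to `element_ids`.
#' @export
#' @examples
#' comparison_matrix(rbind(c(1, 3), c(1/3, 1)), c("a", "b"))
comparison_matrix <- function(values, element_ids = rownames(values),
                              raw = FALSE) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop("comparison matrix must be square", call. = FALSE)
  n <- nrow(values)
  if (n < 2L) stop("comparison matrix needs order >= 2", call. = FALSE)
  if (is.null(element_ids) || length(element_ids) != n)
    stop("element_ids must name all ", n, " rows/columns", call. = FALSE)
  if (anyDuplicated(element_ids))
    stop("duplicate element ids", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0))
    stop("comparison matrix entries must be positive and finite",
         call. = FALSE)
  if (any(diag(values) != 1))
    stop("comparison matrix diagonal must be exactly 1", call. = FALSE)
  prod <- values * t(values)
  if (any(abs(prod - 1) > 1e-9)) {
    bad <- which(abs(prod - 1) > 1e-9, arr.ind = TRUE)[1L, ]
    stop(sprintf("reciprocity violated at (%s, %s): %g * %g != 1",
                 element_ids[bad[1L]], element_ids[bad[2L]],
                 values[bad[1L], bad[2L]], values[bad[2L], bad[1L]]),
         call. = FALSE)
  }
  if (raw) {
    off <- values[row(values) != col(values)]
    if (!all(is_on_saaty_scale(off))) {
      bad <- which(row(values) != col(values) &
                     !matrix(is_on_saaty_scale(values), n, n), arr.ind = TRUE)
      stop(sprintf("entry (%s, %s) = %g is off the Saaty 1-9 scale",
                   element_ids[bad[1L, 1L]], element_ids[bad[1L, 2L]],
                   values[bad[1L, 1L], bad[1L, 2L]]), call. = FALSE)
    }
  }
  dimnames(values) <- list(element_ids, element_ids)
  structure(values, class = c("comparison_matrix", class(values)),
            raw = raw)
}

#' @export
print.comparison_matrix <- function(x, digits = 4, ...) {
  cat(sprintf("Pairwise comparison matrix (%d x %d%s)\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "raw"))) ", Saaty scale" else ""))
  print(round(unclass(x), digits))
  invisible(x)
}

#' SWING score table for one domain
#'
#' One participant's raw SWING scores over a domain's indicators: the most
#' valued improvement (the anchor swing) gets 100 points, all others are
#' scored relative to it in (0, 100].
#'
#' @param domain_id domain the scores belong to.
#' @param scores named numeric vector, names are indicator codes; all
#'   strictly positive, maximum exactly 100.
#' @return object of class `swing_table`: list with `domain_id`, `scores`
#'   and `k` (number of indicators scored).
#' @export
#' @examples
#' swing_table("planning", c(W1.1 = 100, W1.2 = 88.5, W1.3 = 100, W1.4 = 60))
swing_table <- function(domain_id, scores) {
  if (is.null(names(scores)) || anyDuplicated(names(scores)))
    stop("swing scores must be uniquely named by indicator code",
         call. = FALSE)
  if (any(!is.finite(scores)) || any(scores <= 0))
    stop("swing scores must be strictly positive (domain ", domain_id, ")",
         call. = FALSE)
  if (any(scores > 100 + 1e-9))
    stop("swing scores cannot exceed the 100-point anchor (domain ",
         domain_id, ")", call. = FALSE)
  if (abs(max(scores) - 100) > 1e-9)
    stop("swing anchor missing: maximum score is ", max(scores),
         ", must be 100 (domain ", domain_id, ")", call. = FALSE)
  structure(list(domain_id = domain_id, scores = scores,
                 k = length(scores)),
            class = "swing_table")
}

#' @export
print.swing_table <- function(x, ...) {
  cat(sprintf("SWING scores, domain '%s' (%d indicators):\n",
              x$domain_id, x$k))
  print(x$scores)
  invisible(x)
}

#' One participant's complete judgment set
#'
#' Bundles a participant's domain comparison matrix with one SWING table
#' per domain.
#'
#' @param participant_id unique participant identifier.
#' @param group stakeholder group label; must be one of `groups`.
#' @param matrix a [comparison_matrix()] over the hierarchy's domain ids.
#' @param swing_tables list of [swing_table()]s covering every domain of
#'   `hierarchy` exactly once.
#' @param hierarchy the [hierarchy_spec()] the judgments refer to.
#' @param groups admissible group labels (default the five reference
#'   stakeholder categories).
#' @return object of class `judgment_set`.
#' @export
judgment_set <- function(participant_id, group, matrix, swing_tables,
                         hierarchy, groups = default_groups()) {
  if (!group %in% groups)
    stop("participant ", participant_id, ": unknown group '", group, "'",
         call. = FALSE)
  dids <- domain_ids(hierarchy)
  if (!identical(sort(rownames(matrix)), sort(dids)))
    stop("participant ", participant_id,
         ": matrix elements do not match hierarchy domains", call. = FALSE)
  covered <- vapply(swing_tables, function(s) s$domain_id, character(1L))
  if (!identical(sort(covered), sort(dids)))
    stop("participant ", participant_id,
         ": swing tables must cover every domain exactly once",
         call. = FALSE)
  names(swing_tables) <- covered
  for (d in dids) {
    want <- domain_indicators(hierarchy, d)
    have <- names(swing_tables[[d]]$scores)
    if (!identical(sort(have), sort(want)))
      stop("participant ", participant_id, ": swing table for domain '", d,
           "' does not score exactly its indicators", call. = FALSE)
  }
  structure(list(participant_id = participant_id, group = group,
                 matrix = matrix, swing_tables = swing_tables[dids]),
            class = "judgment_set")
}

#' @export
print.judgment_set <- function(x, ...) {
  cat(sprintf("Judgment set: participant '%s' (%s), %d domains\n",
              x$participant_id, x$group, nrow(x$matrix)))
  invisible(x)
}

#' Validate a priority (weight) vector
#'
#' @param weights named numeric vector; must be nonnegative and sum to 1
#'   within absolute tolerance `1e-9`.
#' @return the vector, invisibly unchanged, for use in pipelines.
#' @export
weight_vector <- function(weights) {
  if (is.null(names(weights)))
    stop("weight vector must be named", call. = FALSE)
  if (any(weights < 0))
    stop("weights must be nonnegative", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-9)
    stop("weights must sum to 1 (got ", format(sum(weights), digits = 12),
         ")", call. = FALSE)
  weights
}

#' Normalize a nonnegative vector to sum one
#' @param x nonnegative numeric vector with positive sum.
#' @return `x / sum(x)`.
#' @export
normalize_weights <- function(x) {
  if (any(x < 0) || sum(x) <= 0)
    stop("cannot normalize: negative entries or zero sum", call. = FALSE)
  x / sum(x)
}
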