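#' Normalize SWING scores into local indicator weights
#'
#' The local weight of indicator i within its domain is its score divided
#' by the sum of all scores in the domain:
#' `alpha_i = S_i / sum_k S_k`.  Division by the domain total makes each
#' participant's weights invariant to a common rescaling of their scores.
#'
#' @param scores a [swing_table()] (or any list with `domain_id` and a
#'   named positive `scores` vector).
#' @return list with `domain_id` and `weights`, a named vector over the
#'   domain's indicator codes summing to 1.
#' @export
#' @examples
#' swing_normalize(swing_table("d", c(a = 100, b = 50, c = 50)))$weights
swing_normalize <- function(scores) {
  s <- scores$scores
  if (any(s <= 0))
    stop("swing scores must be strictly positive", call. = FALSE)
  list(domain_id = scores$domain_id,
       weights = weight_vector(s / sum(s)))
}

#' Average SWING scores across participants
#'
#' Arithmetic mean per indicator over a set of tables for one domain.  The
#' result is deliberately *not* re-anchored: the mean of per-participant
#' anchors need not be 100, and normalization is anchor-free anyway.
#'
#' @param tables nonempty list of [swing_table()]s for the same domain.
#' @return list with `domain_id`, mean `scores` (named) and `k`.
#' @export
average_swing <- function(tables) {
  if (!length(tables)) stop("no swing tables to average", call. = FALSE)
  dom <- unique(vapply(tables, `[[`, character(1L), "domain_id"))
  if (length(dom) != 1L)
    stop("cannot average swing tables from different domains: ",
         paste(dom, collapse = ", "), call. = FALSE)
  codes <- names(tables[[1L]]$scores)
  for (t in tables) {
    if (!setequal(names(t$scores), codes))
      stop("swing tables for domain '", dom,
           "' score different indicator sets", call. = FALSE)
  }
  m <- rowMeans(vapply(tables, function(t) t$scores[codes],
                       numeric(length(codes))))
  list(domain_id = dom, scores = setNames(m, codes), k = length(codes))
}

#' Local indicator weights for every domain
#'
#' For each domain, averages the selected participants' raw SWING scores
#' and normalizes the average (`normalize(mean(scores))`, the procedural
#' default), or — with `order = "normalize_first"` — normalizes each
#' participant first and averages the weights.  The two differ whenever
#' participants spread their scores differently.
#'
#' SWING responses are not filtered by the AHP consistency status of the
#' same participant: consistency screening applies to pairwise matrices
#' only.  Pass an already-screened cohort to couple the two.
#'
#' @param judgments list of [judgment_set()]s to use (e.g. all of them,
#'   or one group's).
#' @param hierarchy the [hierarchy_spec()].
#' @param order averaging order, see above.
#' @return named list: domain id -> list(`domain_id`, `weights`).
#' @export
local_weights_all <- function(judgments, hierarchy,
                              order = c("average_first",
                                        "normalize_first")) {
  order <- match.arg(order)
  if (!length(judgments))
    stop("no judgments supplied", call. = FALSE)
  out <- lapply(domain_ids(hierarchy), function(d) {
    tabs <- lapply(judgments, function(j) j$swing_tables[[d]])
    if (any(vapply(tabs, is.null, logical(1L))))
      stop("a participant lacks swing scores for domain '", d, "'",
           call. = FALSE)
    if (order == "average_first") {
      swing_normalize(average_swing(tabs))
    } else {
      ws <- vapply(tabs, function(t) swing_normalize(t)$weights[
        names(tabs[[1L]]$scores)], numeric(tabs[[1L]]$k))
      list(domain_id = d,
           weights = weight_vector(rowMeans(ws) / sum(rowMeans(ws))))
    }
  })
  setNames(out, domain_ids(hierarchy))
}
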