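#' Round half away from zero
#'
#' Decimal reporting in the priority model uses half-up rounding (0.0305 ->
#' 0.031), matching how elicitation results are conventionally printed;
#' base `round()` rounds half to even.  Applied only at output — all
#' composition uses unrounded values.
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Compose global indicator weights
#'
#' Multiplies each domain's AHP weight with its SWING local weights:
#' `global = domain_weight * local_weight`.  Because the domain weights sum
#' to one and each domain's local weights sum to one, the 33 global weights
#' form a probability vector over the whole hierarchy.
#'
#' @param domain_weights named numeric over all domain ids, summing to 1.
#' @param locals named list domain id -> local weights (as returned by
#'   [local_weights_all()], or plain named vectors summing to 1).
#' @param hierarchy the [hierarchy_spec()].
#' @return a `priority_table`: data.frame in hierarchy order with columns
#'   `domain_id`, `domain_label`, `domain_weight`, `code`, `indicator`,
#'   `local_weight`, `global_weight`.
#' @export
#' @examples
#' h <- default_hierarchy()
#' pt <- compose_global(reference_domain_weights(),
#'                      reference_local_weights(), h)
#' sum(pt$global_weight)   # exactly 1 up to 1e-12
compose_global <- function(domain_weights, locals, hierarchy) {
  dids <- domain_ids(hierarchy)
  miss <- setdiff(dids, names(domain_weights))
  if (length(miss))
    stop("domain weights missing for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  miss <- setdiff(dids, names(locals))
  if (length(miss))
    stop("local weights missing for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  weight_vector(domain_weights[dids])
  rows <- lapply(dids, function(d) {
    lw <- locals[[d]]
    if (is.list(lw)) lw <- lw$weights
    codes <- domain_indicators(hierarchy, d)
    if (!setequal(names(lw), codes))
      stop("local weights for domain '", d,
           "' do not cover exactly its indicators", call. = FALSE)
    weight_vector(lw)
    lw <- lw[codes]
    drow <- hierarchy$domains[hierarchy$domains$id == d, ]
    irow <- hierarchy$indicators[match(codes, hierarchy$indicators$code), ]
    data.frame(domain_id = d, domain_label = drow$label,
               domain_weight = unname(domain_weights[d]),
               code = codes, indicator = irow$label,
               local_weight = unname(lw),
               global_weight = unname(domain_weights[d] * lw),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("priority_table", class(out))
  out
}

#' Top-k and bottom-k indicators by global weight
#'
#' Sorts by *unrounded* global weight, descending; exact ties are broken by
#' hierarchy position (stable sort), so an earlier row outranks a later row
#' of equal weight.  The bottom list is reported smallest-first.
#'
#' @param table a `priority_table` (or any data.frame with `code` and
#'   `global_weight` in hierarchy order).
#' @param k how many indicators to return from each end; at most the row
#'   count.
#' @return list with data.frames `top` and `bottom` (`code`, `indicator`
#'   if present, `global_weight`, `rank`).
#' @export
rank_indicators <- function(table, k = 5L) {
  m <- nrow(table)
  if (k > m) stop("k exceeds number of indicators", call. = FALSE)
  ord <- order(-table$global_weight, seq_len(m))
  keep <- intersect(c("code", "indicator", "global_weight"), names(table))
  ranked <- as.data.frame(table)[ord, keep, drop = FALSE]
  ranked$rank <- seq_len(m)
  rownames(ranked) <- NULL
  list(top = ranked[seq_len(k), , drop = FALSE],
       bottom = ranked[rev(seq(m - k + 1L, m)), , drop = FALSE])
}

#' Weight quartile of every indicator
#'
#' Ranks indicators by ascending global weight (ties broken by hierarchy
#' position) and assigns quartile `ceiling(4 r / m)` to ascending rank `r`
#' of `m` rows: quartile 1 is the bottom (least-weighted) quarter,
#' quartile 4 the top.  Rank-based by construction, so tied weights fall in
#' deterministic, documented order rather than sharing a quartile.
#'
#' @param table a `priority_table`-like data.frame with `code` and
#'   `global_weight`.
#' @return named integer vector (1-4) over indicator codes, in table order.
#' @export
quartile_flags <- function(table) {
  m <- nrow(table)
  asc <- order(table$global_weight, seq_len(m))
  r <- integer(m)
  r[asc] <- seq_len(m)
  setNames(as.integer(ceiling(4 * r / m)), table$code)
}

#' Write a priority table as delimited text
#'
#' Columns `Domain`, `DomainWeight`, `Code`, `Indicator`, `LocalWeight`,
#' `GlobalWeight`; weights rounded half-up to `digits` decimals (display
#' precision only — keep the unrounded table for further computation).
#'
#' @param table a `priority_table`.
#' @param path output file.
#' @param format `"csv"` or `"tsv"`.
#' @param digits decimal places for the three weight columns.
#' @return the path, invisibly.
#' @export
render_table <- function(table, path, format = c("csv", "tsv"),
                         digits = 3) {
  format <- match.arg(format)
  if (!nrow(table)) stop("priority table is empty", call. = FALSE)
  out <- data.frame(
    Domain = table$domain_label,
    DomainWeight = round_half_up(table$domain_weight, digits),
    Code = table$code,
    Indicator = table$indicator,
    LocalWeight = round_half_up(table$local_weight, digits),
    GlobalWeight = round_half_up(table$global_weight, digits),
    stringsAsFactors = FALSE)
  write.table(out, path, sep = if (format == "csv") "," else "\t",
              row.names = FALSE, qmethod = "double",
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.priority_table <- function(x, digits = 3, ...) {
  cat(sprintf("Hierarchical priority model: %d domains, %d indicators\n",
              length(unique(x$domain_id)), nrow(x)))
  y <- as.data.frame(x)
  y$domain_weight <- round_half_up(y$domain_weight, digits)
  y$local_weight <- round_half_up(y$local_weight, digits)
  y$global_weight <- round_half_up(y$global_weight, digits)
  print(y[, c("domain_id", "domain_weight", "code", "indicator",
              "local_weight", "global_weight")])
  invisible(x)
}
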