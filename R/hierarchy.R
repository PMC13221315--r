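#' Two-level decision hierarchy
#'
#' A `hierarchy_spec` describes the decision problem: an ordered set of
#' top-level domains, each carrying an ordered set of coded indicators
#' (codes like `"W3.2"`).  Domains are weighted by AHP pairwise comparison;
#' indicators are weighted within their domain by SWING scoring.
#'
#' @param domains data.frame with columns `id` (short unique string) and
#'   `label` (free text), one row per domain, in display order.
#' @param indicators data.frame with columns `code` (unique string),
#'   `domain_id` (must match a domain `id`) and `label`, in display order.
#'
#' @return An object of class `hierarchy_spec`: a list with elements
#'   `domains` and `indicators` (validated data.frames).
#'
#' @details Invariants enforced: unique domain ids, unique indicator codes,
#'   no indicator may reference a missing domain, and every domain must have
#'   at least two indicators (a single-indicator domain has nothing to
#'   SWING-weight).
#'
#' @seealso [load_hierarchy()] to read a hierarchy from a YAML config,
#'   [default_hierarchy()] for the bundled school-sanitation hierarchy.
#' @export
#' @examples
#' h <- hierarchy_spec(
#'   domains = data.frame(id = "d1", label = "Only domain"),
#'   indicators = data.frame(code = c("W1.1", "W1.2"),
#'                           domain_id = "d1",
#'                           label = c("first", "second")))
#' n_indicators(h)
hierarchy_spec <- function(domains, indicators) {
  domains <- as.data.frame(domains, stringsAsFactors = FALSE)
  indicators <- as.data.frame(indicators, stringsAsFactors = FALSE)
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(sprintf("hierarchy %s table lacks column(s): %s", what,
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  need(domains, c("id", "label"), "domain")
  need(indicators, c("code", "domain_id", "label"), "indicator")
  if (nrow(domains) < 1L) stop("hierarchy has no domains", call. = FALSE)
  dup <- domains$id[duplicated(domains$id)]
  if (length(dup))
    stop("duplicate domain id: ", dup[1L], call. = FALSE)
  dup <- indicators$code[duplicated(indicators$code)]
  if (length(dup))
    stop("duplicate indicator code: ", dup[1L], call. = FALSE)
  dangling <- setdiff(indicators$domain_id, domains$id)
  if (length(dangling))
    stop("indicator references unknown domain: ", dangling[1L], call. = FALSE)
  counts <- table(factor(indicators$domain_id, levels = domains$id))
  if (any(counts < 2L))
    stop("domain with fewer than 2 indicators: ",
         names(counts)[counts < 2L][1L], call. = FALSE)
  rownames(domains) <- NULL
  rownames(indicators) <- NULL
  structure(list(domains = domains, indicators = indicators),
            class = "hierarchy_spec")
}

#' @export
print.hierarchy_spec <- function(x, ...) {
  cat(sprintf("Decision hierarchy: %d domains, %d indicators\n",
              nrow(x$domains), nrow(x$indicators)))
  for (i in seq_len(nrow(x$domains))) {
    k <- sum(x$indicators$domain_id == x$domains$id[i])
    cat(sprintf("  %-12s %s (%d indicators)\n",
                x$domains$id[i], x$domains$label[i], k))
  }
  invisible(x)
}

#' @rdname hierarchy_spec
#' @param hierarchy a `hierarchy_spec`.
#' @export
n_indicators <- function(hierarchy) nrow(hierarchy$indicators)

#' @rdname hierarchy_spec
#' @export
domain_ids <- function(hierarchy) hierarchy$domains$id

#' Indicator codes of one domain, in hierarchy order
#' @param hierarchy a `hierarchy_spec`.
#' @param domain_id a domain id present in the hierarchy.
#' @return character vector of indicator codes.
#' @export
domain_indicators <- function(hierarchy, domain_id) {
  if (!domain_id %in% hierarchy$domains$id)
    stop("unknown domain: ", domain_id, call. = FALSE)
  hierarchy$indicators$code[hierarchy$indicators$domain_id == domain_id]
}

#' Read a decision hierarchy from YAML
#'
#' The config is a YAML document with a top-level `domains` list; each entry
#' has `id`, `label` and an ordered `indicators` list of `{code, label}`
#' pairs:
#'
#' ```yaml
#' domains:
#' - id: planning
#'   label: Service planning
#'   indicators:
#'   - {code: W1.1, label: O&M plan}
#'   - {code: W1.2, label: Clear roles and responsibilities}
#' ```
#'
#' @param source path to a YAML file, or a single string containing YAML.
#' @return a validated [hierarchy_spec()].
#' @export
load_hierarchy <- function(source) {
  cfg <- if (length(source) == 1L && !grepl("\n", source) &&
             file.exists(source)) {
    yaml::read_yaml(source)
  } else {
    yaml::yaml.load(paste(source, collapse = "\n"))
  }
  if (is.null(cfg$domains))
    stop("hierarchy config has no 'domains' entry", call. = FALSE)
  dom <- do.call(rbind, lapply(cfg$domains, function(d) {
    if (is.null(d$id) || is.null(d$label))
      stop("hierarchy config: domain entry lacks id or label", call. = FALSE)
    data.frame(id = d$id, label = d$label, stringsAsFactors = FALSE)
  }))
  ind <- do.call(rbind, lapply(cfg$domains, function(d) {
    if (is.null(d$indicators) || !length(d$indicators))
      stop("hierarchy config: domain '", d$id, "' has no indicators",
           call. = FALSE)
    do.call(rbind, lapply(d$indicators, function(i) {
      if (is.null(i$code) || is.null(i$label))
        stop("hierarchy config: indicator entry in domain '", d$id,
             "' lacks code or label", call. = FALSE)
      data.frame(code = i$code, domain_id = d$id, label = i$label,
                 stringsAsFactors = FALSE)
    }))
  }))
  hierarchy_spec(dom, ind)
}
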