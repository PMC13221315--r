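#' Bundled reference priority model for school sanitation O&M
#'
#' The package ships the published stakeholder-derived priority model for
#' sustaining operation and maintenance (O&M) of school sanitation
#' facilities in Kampala: 6 domains weighted by AHP and 33 indicators
#' weighted by SWING, with global weights (domain x local) reported to three
#' decimals.  It serves three roles:
#'
#' 1. the default decision hierarchy ([default_hierarchy()]);
#' 2. the default ground truth of the synthetic-elicitation generator
#'    ([cohort_config()]);
#' 3. a worked fixture for the composition, ranking and quartile tools.
#'
#' The `global_weight` column carries the values as published (rounded to
#' 3 decimals); because the original composition used unrounded
#' intermediates, two rows (W4.8, W5.2) differ by 0.001 from the product of
#' the rounded `domain_weight` and `local_weight` columns.
#'
#' @return data.frame with one row per indicator, columns `domain_id`,
#'   `domain_label`, `domain_weight`, `code`, `indicator`, `local_weight`,
#'   `global_weight`, in hierarchy order.
#' @export
#' @examples
#' m <- reference_model()
#' sum(m$global_weight)          # ~1 up to rounding
#' rank_indicators(m, 5)$top
reference_model <- function() {
  row <- function(did, dlab, dw, code, ind, lw, gw)
    data.frame(domain_id = did, domain_label = dlab, domain_weight = dw,
               code = code, indicator = ind, local_weight = lw,
               global_weight = gw, stringsAsFactors = FALSE)
  rbind(
    row("planning", "Service planning", 0.234, "W1.1",
        "O&M plan", 0.287, 0.067),
    row("planning", "Service planning", 0.234, "W1.2",
        "Clear roles and responsibilities", 0.254, 0.059),
    row("planning", "Service planning", 0.234, "W1.3",
        "Dedicated budget line", 0.287, 0.067),
    row("planning", "Service planning", 0.234, "W1.4",
        "Preventive maintenance schedule", 0.172, 0.040),
    row("design", "Facility design standards", 0.193, "W2.1",
        "Sanitation technology", 0.151, 0.029),
    row("design", "Facility design standards", 0.193, "W2.2",
        "Safe containment of excreta", 0.159, 0.031),
    row("design", "Facility design standards", 0.193, "W2.3",
        "Facility accessibility for people with disability", 0.105, 0.020),
    row("design", "Facility design standards", 0.193, "W2.4",
        "Sex segregation", 0.132, 0.025),
    row("design", "Facility design standards", 0.193, "W2.5",
        "Privacy", 0.123, 0.024),
    row("design", "Facility design standards", 0.193, "W2.6",
        "MHM facility availability", 0.105, 0.020),
    row("design", "Facility design standards", 0.193, "W2.7",
        "Handwashing facilities", 0.119, 0.023),
    row("design", "Facility design standards", 0.193, "W2.8",
        "Pupil to stance ratio", 0.106, 0.020),
    row("resources", "Resource management", 0.199, "W3.1",
        "Trained personnel", 0.231, 0.046),
    row("resources", "Resource management", 0.199, "W3.2",
        "Reliable water supply", 0.269, 0.054),
    row("resources", "Resource management", 0.199, "W3.3",
        "Budget line implementation", 0.282, 0.056),
    row("resources", "Resource management", 0.199, "W3.4",
        "Material-use tracking system", 0.218, 0.043),
    row("delivery", "Service delivery", 0.137, "W4.1",
        "Facility availability", 0.148, 0.020),
    row("delivery", "Service delivery", 0.137, "W4.2",
        "General facility accessibility", 0.146, 0.020),
    row("delivery", "Service delivery", 0.137, "W4.3",
        "Facility functionality", 0.149, 0.020),
    row("delivery", "Service delivery", 0.137, "W4.4",
        "Toilet cleanliness", 0.130, 0.018),
    row("delivery", "Service delivery", 0.137, "W4.5",
        "Toilet consumables at point of use", 0.117, 0.016),
    row("delivery", "Service delivery", 0.137, "W4.6",
        "MHM materials availability", 0.103, 0.014),
    row("delivery", "Service delivery", 0.137, "W4.7",
        "Safe disposal of solid waste", 0.092, 0.013),
    row("delivery", "Service delivery", 0.137, "W4.8",
        "Safe excreta disposal", 0.115, 0.017),
    row("governance", "Governance", 0.166, "W5.1",
        "Hygiene promotion activities", 0.246, 0.041),
    row("governance", "Governance", 0.166, "W5.2",
        "Formal school management structures", 0.278, 0.047),
    row("governance", "Governance", 0.166, "W5.3",
        "Internal and external stakeholder engagement", 0.218, 0.036),
    row("governance", "Governance", 0.166, "W5.4",
        "Enforcement", 0.258, 0.043),
    row("monitoring", "M&E", 0.071, "W6.1",
        "Use of structured M&E tools", 0.230, 0.016),
    row("monitoring", "M&E", 0.071, "W6.2",
        "Multiple stakeholder monitoring", 0.197, 0.014),
    row("monitoring", "M&E", 0.071, "W6.3",
        "Making informed decisions from monitoring data", 0.196, 0.014),
    row("monitoring", "M&E", 0.071, "W6.4",
        "M&E training for personnel", 0.220, 0.016),
    row("monitoring", "M&E", 0.071, "W6.5",
        "Escalation process for unresolved issues", 0.157, 0.011)
  )
}

#' Default school-sanitation O&M hierarchy (6 domains, 33 indicators)
#'
#' The hierarchy of [reference_model()] without its weights.  Indicator code
#' prefixes (`W1.` ... `W6.`) follow the ordinal position of their domain.
#'
#' @return a [hierarchy_spec()].
#' @export
default_hierarchy <- function() {
  m <- reference_model()
  hierarchy_spec(
    domains = unique(m[, c("domain_id", "domain_label")]) |>
      (\(d) data.frame(id = d$domain_id, label = d$domain_label))(),
    indicators = data.frame(code = m$code, domain_id = m$domain_id,
                            label = m$indicator)
  )
}

#' Reference domain weights (AHP) of the bundled model
#' @return named numeric vector over the six domain ids, summing to 1.
#' @export
reference_domain_weights <- function() {
  m <- reference_model()
  d <- unique(m[, c("domain_id", "domain_weight")])
  setNames(d$domain_weight, d$domain_id)
}

#' Reference local indicator weights (SWING) of the bundled model
#' @return named list: domain id -> named numeric vector over that domain's
#'   indicator codes, each summing to 1.
#' @export
reference_local_weights <- function() {
  m <- reference_model()
  lapply(split(m, factor(m$domain_id, levels = unique(m$domain_id))),
         function(d) setNames(d$local_weight, d$code))
}

#' Default stakeholder group labels
#'
#' The five stakeholder categories of the reference study design, seven
#' participants each.  All group-aware functions accept any label set.
#' @return character vector of five group labels.
#' @export
default_groups <- function() {
  c("Regulators", "Researchers", "Practitioners",
    "Head Teachers", "Sanitation Teachers")
}
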