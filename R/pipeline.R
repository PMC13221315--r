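#' Validate a judgment file
#'
#' Parses and fully validates a judgment file against a hierarchy,
#' collecting rather than throwing errors.  The file is valid when every
#' participant has a complete, reciprocal comparison matrix (on the Saaty
#' scale when `scale = "saaty"`) and a properly anchored SWING table per
#' domain.
#'
#' @param judgments_path path to the judgment file.
#' @param hierarchy a [hierarchy_spec()], or a path to a hierarchy YAML.
#' @param groups admissible group labels.
#' @param scale see [read_judgments()].
#' @return list with `ok` (logical), `n_participants`, and `errors`
#'   (character vector of located validation messages, empty when valid).
#' @export
validate_judgment_file <- function(judgments_path, hierarchy,
                                   groups = default_groups(),
                                   scale = c("saaty", "free")) {
  scale <- match.arg(scale)
  if (is.character(hierarchy)) hierarchy <- load_hierarchy(hierarchy)
  res <- tryCatch(
    list(j = read_judgments(judgments_path, hierarchy, groups, scale),
         err = character()),
    error = function(e) list(j = NULL, err = conditionMessage(e)))
  list(ok = length(res$err) == 0L,
       n_participants = if (is.null(res$j)) NA_integer_ else length(res$j),
       errors = res$err)
}

#' Run the full priority-weighting pipeline
#'
#' End-to-end orchestration: consistency screening, geometric-mean
#' aggregation and principal-eigenvector domain weights (overall and per
#' stakeholder group), SWING local weights, composition into the global
#' priority table, stratified bootstrap confidence intervals for the
#' overall domain weights, and Kruskal-Wallis comparison of participant-
#' level domain weights across groups.  Progress, retained/rejected counts
#' and per-stage timings go to the message stream; data never does.
#'
#' @param judgments list of [judgment_set()]s, or a path to a judgment
#'   file.
#' @param hierarchy a [hierarchy_spec()] (default the bundled school-
#'   sanitation hierarchy), or a path to a hierarchy YAML.
#' @param groups admissible group labels.
#' @param scale judgment-file scale check, see [read_judgments()].
#' @param pooling overall-weight pooling mode, see
#'   [group_domain_weights()].
#' @param couple_swing_to_cr if `TRUE`, SWING tables of CR-rejected
#'   participants are excluded from local weights (default `FALSE`:
#'   consistency screening applies to pairwise judgments only).
#' @param B,level,stratified bootstrap settings, see
#'   [bootstrap_domain_weights()].
#' @param seed integer seed for the bootstrap; with fixed inputs and seed
#'   the run is fully deterministic.
#' @param out_dir optional directory; when given, writes
#'   `priority_table.csv`, `consistency.csv`, `bootstrap.csv`,
#'   `group_comparison.csv` and `model.yaml` (the unrounded model).
#' @return list with `priority_table`, `domain_weights` (overall + per
#'   group), `local_weights`, `consistency` (screening data.frame),
#'   `bootstrap`, `group_comparison`, `retained`, `rejected`, `seed`.
#' @export
run_priority_analysis <- function(judgments,
                                  hierarchy = default_hierarchy(),
                                  groups = default_groups(),
                                  scale = c("saaty", "free"),
                                  pooling = c("participants", "groups"),
                                  couple_swing_to_cr = FALSE,
                                  B = 10000L, level = 0.95,
                                  stratified = TRUE, seed = 1L,
                                  out_dir = NULL) {
  scale <- match.arg(scale)
  pooling <- match.arg(pooling)
  if (is.character(hierarchy)) hierarchy <- load_hierarchy(hierarchy)
  if (is.character(judgments))
    judgments <- read_judgments(judgments, hierarchy, groups, scale)
  if (!length(judgments)) stop("no judgments to analyse", call. = FALSE)
  t0 <- proc.time()[["elapsed"]]
  stage <- function(what) {
    t1 <- proc.time()[["elapsed"]]
    message(sprintf("[washpriority] %s (%.2fs)", what, t1 - t0))
    t0 <<- t1
  }
  message(sprintf("[washpriority] %d participants, seed %d",
                  length(judgments), seed))

  scr <- screen_judgments(judgments)
  if (!length(scr$retained))
    stop("all participants rejected by consistency screening; nothing to ",
         "analyse", call. = FALSE)
  message(sprintf("[washpriority] consistency screen: %d retained, %d rejected",
                  length(scr$retained), length(scr$rejected)))
  stage("screened")

  dw <- group_domain_weights(scr$retained, hierarchy, pooling,
                             expected_groups = unique(
                               vapply(judgments, `[[`, character(1L),
                                      "group")))
  stage("domain weights")

  swing_input <- if (couple_swing_to_cr) scr$retained else judgments
  locals <- local_weights_all(swing_input, hierarchy)
  stage("local weights")

  pt <- compose_global(dw$overall$weights, locals, hierarchy)
  stage("composed priority table")

  boot <- bootstrap_domain_weights(scr$retained, hierarchy, B = B,
                                   level = level, seed = seed,
                                   stratified = stratified)
  stage(sprintf("bootstrap (B = %d)", B))

  cmp <- if (length(unique(vapply(scr$retained, `[[`, character(1L),
                                  "group"))) >= 2L) {
    compare_groups(scr$retained, hierarchy)
  } else {
    warning("fewer than 2 groups retained; skipping group comparison",
            call. = FALSE)
    NULL
  }
  stage("group comparison")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    render_table(pt, file.path(out_dir, "priority_table.csv"))
    write.table(scr$reports, file.path(out_dir, "consistency.csv"),
                sep = ",", row.names = FALSE)
    write.table(boot, file.path(out_dir, "bootstrap.csv"),
                sep = ",", row.names = FALSE)
    if (!is.null(cmp))
      write.table(cmp, file.path(out_dir, "group_comparison.csv"),
                  sep = ",", row.names = FALSE)
    yaml::write_yaml(
      list(seed = seed,
           retained = length(scr$retained),
           rejected = length(scr$rejected),
           domain_weights = as.list(dw$overall$weights),
           local_weights = lapply(locals, function(l) as.list(l$weights)),
           global_weights = as.list(
             setNames(pt$global_weight, pt$code))),
      file.path(out_dir, "model.yaml"))
    stage(paste("artifacts written to", out_dir))
  }

  list(priority_table = pt, domain_weights = dw, local_weights = locals,
       consistency = scr$reports, bootstrap = boot,
       group_comparison = cmp, retained = scr$retained,
       rejected = scr$rejected, seed = seed)
}

#' Simulate a cohort and write it as a judgment file
#'
#' Convenience wrapper chaining [generate_cohort()] and
#' [write_judgments()]; the written file round-trips through
#' [validate_judgment_file()] (with `scale = "free"` unless the config
#' snaps to the Saaty scale).
#'
#' @param config a [cohort_config()], or a path to a YAML file of
#'   `cohort_config()` arguments (`sigma_ahp`, `sigma_swing`, `groups` as
#'   a label -> count map, `snap_to_scale`, `seed`; hierarchy and truth
#'   default to the bundled reference model).
#' @param path output judgment file.
#' @return the path, invisibly; the cohort as attribute `"cohort"`.
#' @export
simulate_cohort_file <- function(config, path) {
  if (is.character(config)) {
    cfg <- yaml::read_yaml(config)
    args <- cfg[intersect(names(cfg),
                          c("sigma_ahp", "sigma_swing", "snap_to_scale",
                            "seed"))]
    if (!is.null(cfg$groups))
      args$groups <- setNames(as.integer(unlist(cfg$groups)),
                              names(cfg$groups))
    config <- do.call(cohort_config, args)
  }
  cohort <- generate_cohort(config)
  write_judgments(cohort, path)
  message(sprintf("[washpriority] wrote %d participants to %s",
                  length(cohort), path))
  out <- invisible(path)
  attr(out, "cohort") <- cohort
  invisible(out)
}
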