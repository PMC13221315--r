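#' Read and write judgment files
#'
#' Judgments travel as UTF-8 delimited text in a long format with one record
#' per row and a fixed header `record,participant,group,item1,item2,value`:
#'
#' * `PAIR` records hold one upper-triangle pairwise comparison:
#'   `item1` and `item2` are domain ids (in hierarchy order, `item1` before
#'   `item2`) and `value` is the judgment `a[item1, item2]`.
#' * `SWING` records hold one score: `item1` is the domain id, `item2` the
#'   indicator code, `value` the score in (0, 100].
#'
#' The upper triangle is authoritative: missing lower-triangle entries are
#' derived as reciprocals; if a file carries both triangles they must agree
#' (product within `1e-9` of 1).  Values use `.` as decimal separator and
#' are written with 15 significant digits, so a write/read cycle is lossless
#' well beyond the 12 significant digits the format guarantees.
#'
#' @param judgments list of [judgment_set()]s.
#' @param path file path.
#' @param hierarchy the [hierarchy_spec()] the file refers to.
#' @param groups admissible stakeholder group labels.
#' @param scale `"saaty"` (default) restricts pairwise entries to the Saaty
#'   1-9 scale, as raw participant data must be; `"free"` accepts any
#'   positive reciprocal matrix (e.g. synthetic cohorts generated without
#'   scale snapping, or aggregated matrices).
#' @return `read_judgments()`: list of validated [judgment_set()]s.
#'   `write_judgments()`: the path, invisibly.
#' @name judgment_io
NULL

#' @rdname judgment_io
#' @export
write_judgments <- function(judgments, path) {
  rows <- list(data.frame(record = character(), participant = character(),
                          group = character(), item1 = character(),
                          item2 = character(), value = character(),
                          stringsAsFactors = FALSE))
  fmt <- function(v) formatC(v, digits = 15, format = "g")
  for (j in judgments) {
    ids <- rownames(j$matrix)
    n <- length(ids)
    pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    pr <- pr[order(pr[, 1L], pr[, 2L]), , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      record = "PAIR", participant = j$participant_id, group = j$group,
      item1 = ids[pr[, 1L]], item2 = ids[pr[, 2L]],
      value = fmt(j$matrix[pr]), stringsAsFactors = FALSE)
    for (s in j$swing_tables) {
      rows[[length(rows) + 1L]] <- data.frame(
        record = "SWING", participant = j$participant_id, group = j$group,
        item1 = s$domain_id, item2 = names(s$scores),
        value = fmt(s$scores), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  write.table(out, path, sep = ",", row.names = FALSE, qmethod = "double",
              quote = 1:5, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname judgment_io
#' @export
read_judgments <- function(path, hierarchy, groups = default_groups(),
                           scale = c("saaty", "free")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                 colClasses = c(record = "character",
                                participant = "character",
                                group = "character", item1 = "character",
                                item2 = "character", value = "numeric"))
  need <- c("record", "participant", "group", "item1", "item2", "value")
  if (!all(need %in% names(df)))
    stop("judgment file lacks required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L) return(list())
  bad <- setdiff(unique(df$record), c("PAIR", "SWING"))
  if (length(bad))
    stop("unknown record kind: ", bad[1L], call. = FALSE)
  dids <- domain_ids(hierarchy)
  n <- length(dids)
  lapply(unique(df$participant), function(pid) {
    rows <- df[df$participant == pid, , drop = FALSE]
    grp <- unique(rows$group)
    if (length(grp) != 1L)
      stop("participant ", pid, ": inconsistent group labels", call. = FALSE)
    ## --- comparison matrix from PAIR records
    pairs <- rows[rows$record == "PAIR", , drop = FALSE]
    unknown <- setdiff(c(pairs$item1, pairs$item2), dids)
    if (length(unknown))
      stop("participant ", pid, ": PAIR references unknown domain '",
           unknown[1L], "'", call. = FALSE)
    A <- matrix(NA_real_, n, n, dimnames = list(dids, dids))
    given <- matrix(FALSE, n, n, dimnames = list(dids, dids))
    diag(A) <- 1
    for (r in seq_len(nrow(pairs))) {
      i <- pairs$item1[r]; j <- pairs$item2[r]; v <- pairs$value[r]
      if (i == j)
        stop("participant ", pid, ": PAIR compares '", i, "' with itself",
             call. = FALSE)
      if (!is.finite(v) || v <= 0)
        stop("participant ", pid, ": non-positive judgment for (", i, ", ",
             j, ")", call. = FALSE)
      if (given[i, j] && abs(A[i, j] - v) > 1e-9 * v)
        stop("participant ", pid, ": duplicate PAIR (", i, ", ", j,
             ") with conflicting values", call. = FALSE)
      if (given[j, i] && abs(A[j, i] * v - 1) > 1e-9)
        stop("participant ", pid, ": reciprocity violated for (", i, ", ",
             j, "): ", v, " * ", A[j, i], " != 1", call. = FALSE)
      A[i, j] <- v
      given[i, j] <- TRUE
      if (!given[j, i]) A[j, i] <- 1 / v
    }
    if (anyNA(A)) {
      miss <- which(is.na(A), arr.ind = TRUE)[1L, ]
      stop("participant ", pid, ": missing comparison (",
           dids[miss[1L]], ", ", dids[miss[2L]], ")", call. = FALSE)
    }
    m <- tryCatch(comparison_matrix(A, dids, raw = identical(scale, "saaty")),
                  error = function(e) stop("participant ", pid, ": ",
                                           conditionMessage(e),
                                           call. = FALSE))
    ## --- swing tables from SWING records
    sw <- rows[rows$record == "SWING", , drop = FALSE]
    tables <- lapply(dids, function(d) {
      sd <- sw[sw$item1 == d, , drop = FALSE]
      if (nrow(sd) == 0L)
        stop("participant ", pid, ": no SWING scores for domain '", d, "'",
             call. = FALSE)
      if (anyDuplicated(sd$item2))
        stop("participant ", pid, ": duplicate SWING score for indicator ",
             sd$item2[duplicated(sd$item2)][1L], call. = FALSE)
      tryCatch(swing_table(d, setNames(sd$value, sd$item2)),
               error = function(e) stop("participant ", pid, ": ",
                                        conditionMessage(e), call. = FALSE))
    })
    judgment_set(pid, grp, m, tables, hierarchy, groups = groups)
  })
}
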