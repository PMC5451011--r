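#' Translate a protein summary into protein group codes
#'
#' Looks up every entry's accession number in the dictionary and prepends the
#' corresponding protein group code (PGC), leaving entry order and all other
#' fields unchanged. Coding keys on the accession, not the run-local group
#' identifier, so groups that the dictionary splits (possible under the
#' refined linking modes) remain representable.
#'
#' Accessions absent from the dictionary are an error by default, because a
#' dictionary built from (a superset of) the same files under mode `"all"`
#' contains every accession. Under the `"top_gene"` and `"top_identifier"`
#' modes pruned entries are legitimately absent; set `allow_missing = TRUE`
#' to code them with the sentinel value 0 instead (reported in a warning and
#' in the `n_unmapped` attribute).
#'
#' @param dict A `pgc_dictionary`.
#' @param summary A `protein_summary`.
#' @param allow_missing Code absent accessions as 0 instead of erroring.
#'
#' @return A `coded_summary`: the summary with a leading `pgc` column.
#'   The `split_groups` attribute lists any source groups whose members map
#'   to more than one PGC.
#' @examples
#' runs <- example_runs_regrouping()
#' dict <- build_dictionary(runs, mode = "all")
#' code_protein_groups(dict, runs[[1]])
#' @export
code_protein_groups <- function(dict, summary, allow_missing = FALSE) {
  assert_inherits(dict, "pgc_dictionary")
  assert_inherits(summary, "protein_summary")
  validate_pgc_dictionary(dict)
  if ("pgc" %in% names(summary)) summary$pgc <- NULL  # re-coding

  pgc <- dict$pgc[match(summary$accession, dict$accession)]
  missing <- is.na(pgc)
  if (any(missing)) {
    if (!allow_missing) {
      miss <- unique(summary$accession[missing])
      abort(sprintf(
        "Accession(s) not in the dictionary: %s%s. Use allow_missing = TRUE to code them as 0.",
        paste0("'", utils::head(miss, 5), "'", collapse = ", "),
        if (length(miss) > 5) sprintf(" (and %d more)", length(miss) - 5) else ""
      ))
    }
    warn(sprintf("%d entr%s not in the dictionary coded with sentinel 0.",
                 sum(missing), if (sum(missing) == 1) "y" else "ies"))
    pgc[missing] <- 0L
  }

  out <- bind_cols(tibble(pgc = as.integer(pgc)), summary)
  attr(out, "run_id") <- attr(summary, "run_id")
  attr(out, "dialect") <- attr(summary, "dialect")
  attr(out, "raw") <- attr(summary, "raw")
  attr(out, "n_unmapped") <- sum(missing)
  attr(out, "split_groups") <- split_coded_groups(out)
  class(out) <- c("coded_summary", "protein_summary", class(tibble()))
  out
}

#' Source groups whose members map to more than one PGC
#'
#' Under a mode `"all"` dictionary every member of a local group is
#' overlap-connected, so the whole group carries one code; under refined
#' dictionaries a reported group can straddle several global groups. This
#' consistency check lists such groups.
#'
#' @param coded A `coded_summary`.
#' @return A tibble with columns `group_id`, `n_pgcs` and `pgcs` (the sorted
#'   distinct non-sentinel codes), one row per affected group.
#' @export
split_coded_groups <- function(coded) {
  if (!all(c("pgc", "group_id") %in% names(coded))) {
    abort("`coded` must carry `pgc` and `group_id` columns.")
  }
  tbl <- tibble(group_id = coded$group_id, pgc = coded$pgc) |>
    filter(.data$pgc != 0L) |>
    distinct() |>
    group_by(.data$group_id) |>
    summarise(n_pgcs = n(),
              pgcs = paste(sort(.data$pgc), collapse = ","),
              .groups = "drop") |>
    filter(.data$n_pgcs > 1L)
  tbl
}

#' Code a set of local groups with a dictionary
#'
#' Codes the accessions retained by [create_local_groups()] rather than every
#' entry of the source file. This is the right input for cross-run presence
#' analyses under the refined linking modes: an accession pruned from a run's
#' local group must not make its code count as present in that run, even when
#' the accession entered the dictionary through another run.
#'
#' @param dict A `pgc_dictionary` built under the same mode.
#' @param local_groups A `local_group_set`.
#' @param allow_missing Code accessions absent from the dictionary as 0
#'   (silently; they cannot occur when the dictionary was built from a file
#'   set including this run under the same mode).
#' @return A `coded_summary` tibble with columns `pgc`, `group_id`,
#'   `accession` and `is_top`.
#' @export
code_local_groups <- function(dict, local_groups, allow_missing = TRUE) {
  assert_inherits(dict, "pgc_dictionary")
  assert_inherits(local_groups, "local_group_set")
  pgc <- dict$pgc[match(local_groups$accession, dict$accession)]
  if (anyNA(pgc)) {
    if (!allow_missing) {
      miss <- unique(local_groups$accession[is.na(pgc)])
      abort(sprintf("Accession(s) not in the dictionary: %s.",
                    paste0("'", utils::head(miss, 5), "'", collapse = ", ")))
    }
    pgc[is.na(pgc)] <- 0L
  }
  out <- bind_cols(tibble(pgc = as.integer(pgc)), as_tibble(local_groups))
  attr(out, "run_id") <- attr(local_groups, "run_id")
  class(out) <- c("coded_summary", class(tibble()))
  out
}

#' Code several summaries with one dictionary
#'
#' @param dict A `pgc_dictionary`.
#' @param summaries List of `protein_summary` objects.
#' @param allow_missing Passed to [code_protein_groups()].
#' @return A list of `coded_summary` objects, in input order.
#' @export
code_all <- function(dict, summaries, allow_missing = FALSE) {
  if (inherits(summaries, "protein_summary")) summaries <- list(summaries)
  lapply(summaries, function(s) {
    code_protein_groups(dict, s, allow_missing = allow_missing)
  })
}
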