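#' Create the local protein groups of one run
#'
#' Turns a per-run protein summary into its set of local groups, optionally
#' refining each group before cross-run linking:
#'
#' \describe{
#'   \item{`"all"`}{every accession of the reported group is kept (the
#'     default, linking whole groups).}
#'   \item{`"top_gene"`}{the top protein is kept together with every member
#'     that shares at least one gene symbol with it (case-insensitive) and,
#'     when the summary carries a rank column, has the same rank as the top
#'     entry. A top protein without gene annotation yields a singleton.}
#'   \item{`"top_identifier"`}{only the top protein is kept, so every local
#'     group is a singleton.}
#' }
#'
#' Groups refined under `"top_gene"` and `"top_identifier"` are always
#' subsets of the `"all"` groups, and the number of groups is the same in
#' every mode.
#'
#' @param summary A `protein_summary`.
#' @param mode Grouping mode: `"all"`, `"top_gene"` or `"top_identifier"`
#'   (hyphenated spellings are accepted).
#'
#' @return A `local_group_set` tibble with columns `group_id`, `accession`
#'   and `is_top`, ordered top-first within each group, and attributes
#'   `run_id` and `mode`.
#' @examples
#' runs <- example_runs_top_rotation()
#' create_local_groups(runs[[1]], mode = "top_gene")
#' @export
create_local_groups <- function(summary, mode = c("all", "top_gene",
                                                  "top_identifier")) {
  assert_inherits(summary, "protein_summary")
  mode <- match_mode(if (is.character(mode)) mode[1] else mode)
  if (nrow(summary) == 0L) abort("The summary has no protein groups.")

  keep <- switch(
    mode,
    all = rep(TRUE, nrow(summary)),
    top_identifier = summary$is_top,
    top_gene = top_gene_filter(summary)
  )

  out <- summary[keep, c("group_id", "accession", "is_top")]
  # duplicate accessions inside one source group would break set semantics
  dup <- duplicated(paste(out$group_id, out$accession, sep = "\r"))
  if (any(dup)) {
    warn(sprintf("Dropping %d duplicated accession(s) within groups.",
                 sum(dup)))
    out <- out[!dup, , drop = FALSE]
  }
  out <- out |> arrange(.data$group_id, dplyr::desc(.data$is_top))
  out <- as_tibble(out)
  attr(out, "run_id") <- attr(summary, "run_id")
  attr(out, "mode") <- mode
  class(out) <- c("local_group_set", class(tibble()))
  out
}

# topGene refinement: keep the top entry plus members sharing a gene symbol
# with it; when a rank is available, also require the top entry's rank.
top_gene_filter <- function(summary) {
  keep <- logical(nrow(summary))
  for (g in split(seq_len(nrow(summary)), summary$group_id)) {
    top_i <- g[summary$is_top[g]][1]
    keep[top_i] <- TRUE
    top_genes <- summary$genes[[top_i]]
    if (length(top_genes) == 0L) next  # unannotated top: singleton
    top_rank <- summary$rank[top_i]
    for (i in setdiff(g, top_i)) {
      if (!genes_overlap(summary$genes[[i]], top_genes)) next
      if (!is.na(top_rank) && !is.na(summary$rank[i]) &&
          abs(summary$rank[i] - top_rank) > 1e-9) next
      keep[i] <- TRUE
    }
  }
  keep
}

# Local groups as a plain list of accession character vectors (top first).
local_groups_list <- function(local_groups) {
  if (inherits(local_groups, "local_group_set")) {
    return(split(local_groups$accession, local_groups$group_id))
  }
  if (is.list(local_groups)) {
    return(local_groups)
  }
  abort("`local_groups` must be a local_group_set or a list of accession vectors.")
}

#' @export
print.local_group_set <- function(x, ...) {
  cat(sprintf("# Local groups: run '%s', mode '%s', %d groups / %d accessions\n",
              attr(x, "run_id"), attr(x, "mode"),
              length(unique(x$group_id)), nrow(x)))
  NextMethod()
}
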