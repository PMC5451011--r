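#' Dice set-similarity coefficient
#'
#' The Dice coefficient between two sets is `2|A n B| / (|A| + |B|)`: 0 when
#' the sets are disjoint, 1 when they contain the same elements. It compares
#' unordered sets, so it cannot see changes in which member is the top
#' protein — that is what [dice_top_proteins()] is for.
#'
#' @param a,b Character vectors, treated as sets (duplicates ignored).
#' @return A number in `[0, 1]`.
#' @examples
#' dice(c("p1", "p2", "p3"), c("p1", "p2"))  # 0.8
#' @export
dice <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  if (length(a) == 0L && length(b) == 0L) {
    abort("The Dice coefficient is undefined for two empty sets.")
  }
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

coded_list <- function(coded) {
  if (inherits(coded, "coded_summary")) coded <- list(coded)
  ok <- vapply(coded, inherits, logical(1), "coded_summary")
  if (length(coded) == 0L || !all(ok)) {
    abort("Expected a list of coded_summary objects.")
  }
  coded
}

run_ids <- function(coded) {
  ids <- map_chr(coded, function(x) attr(x, "run_id") %||% NA_character_)
  if (anyNA(ids) || anyDuplicated(ids)) {
    ids <- make.unique(ifelse(is.na(ids), "run", ids))
  }
  ids
}

# PGCs observed in one run (sentinel 0 excluded).
run_pgcs <- function(x) sort(unique(x$pgc[x$pgc != 0L]))

#' PGC-by-run presence matrix
#'
#' Indicates, for every protein group code observed in at least one run,
#' which runs it occurs in. This is the table used to retain groups that are
#' consistently detected across a study before downstream statistics.
#'
#' @param coded A list of `coded_summary` objects coded with one dictionary.
#' @return A `pgc_presence` tibble: column `pgc` plus one logical column per
#'   run, runs in input order.
#' @seealso [consistent_pgcs()]
#' @export
presence_matrix <- function(coded) {
  if (length(coded) == 0L) {
    out <- tibble(pgc = integer())
    class(out) <- c("pgc_presence", class(tibble()))
    return(out)
  }
  coded <- coded_list(coded)
  ids <- run_ids(coded)
  pgc_sets <- map(coded, run_pgcs)
  all_pgcs <- sort(unique(unlist(pgc_sets)))
  cols <- map(pgc_sets, function(p) all_pgcs %in% p)
  out <- bind_cols(tibble(pgc = all_pgcs), setNames(cols, ids))
  class(out) <- c("pgc_presence", class(tibble()))
  out
}

#' Codes present in a given fraction of runs
#'
#' @param presence A `pgc_presence` matrix.
#' @param threshold Minimum fraction of runs a code must appear in
#'   (default 1, i.e. all runs; biomarker studies often use values such as
#'   0.75 to keep nearly consistent groups).
#' @return Integer vector of protein group codes.
#' @export
consistent_pgcs <- function(presence, threshold = 1) {
  assert_inherits(presence, "pgc_presence")
  if (threshold < 0 || threshold > 1) abort("`threshold` must be in [0, 1].")
  runs <- setdiff(names(presence), "pgc")
  if (length(runs) == 0L || nrow(presence) == 0L) return(integer())
  frac <- rowMeans(as.matrix(presence[runs]))
  presence$pgc[frac >= threshold]
}

#' Common-code curve under stepwise incorporation of runs
#'
#' After incorporating the first `k` runs, counts the protein group codes
#' present in all of them. The curve is non-increasing in `k`, and linking
#' whole groups (mode `"all"`) always keeps it at or above the curves of the
#' refined modes on the same files.
#'
#' @param coded An ordered list of `coded_summary` objects (see
#'   [order_by_group_count()] for the conventional size-descending order).
#' @return A `pgc_curve` tibble with columns `k`, `run_id` and `n_common`.
#' @export
common_pgc_curve <- function(coded) {
  coded <- coded_list(coded)
  ids <- run_ids(coded)
  pgc_sets <- map(coded, run_pgcs)
  common <- pgc_sets[[1]]
  n_common <- integer(length(coded))
  for (k in seq_along(coded)) {
    common <- if (k == 1L) pgc_sets[[1]] else intersect(common, pgc_sets[[k]])
    n_common[k] <- length(common)
  }
  out <- tibble(k = seq_along(coded), run_id = ids, n_common = n_common)
  class(out) <- c("pgc_curve", class(tibble()))
  out
}

#' Order protein summaries by decreasing group count
#'
#' The conventional processing order for stepwise linkage diagnostics:
#' files with more protein groups first, ties broken by run label.
#'
#' @param summaries List of `protein_summary` (or `coded_summary`) objects.
#' @return The reordered list.
#' @export
order_by_group_count <- function(summaries) {
  if (inherits(summaries, "protein_summary")) summaries <- list(summaries)
  n_groups <- map_int(summaries, function(s) length(unique(s$group_id)))
  ids <- map_chr(summaries, function(s) attr(s, "run_id") %||% "")
  summaries[order(-n_groups, ids)]
}

#' Mapping change log of a stepwise dictionary build
#'
#' Processes the summaries one at a time and records, per step, how the
#' mapping changed: previously unseen accession numbers, newly created
#' global groups, and merge events (a merge of `g` existing groups counts
#' `g - 1`, so cumulative new groups minus cumulative mergers equals the
#' group count at every step).
#'
#' @param summaries Ordered list of `protein_summary` objects.
#' @param mode Grouping mode, as in [build_dictionary()].
#' @return A `pgc_change_log` tibble: `step`, `run_id`, `new_accessions`,
#'   `new_groups`, `mergers`.
#' @export
change_log <- function(summaries, mode = "all") {
  dictionary_history(build_dictionary(summaries, mode = mode))
}

#' Histogram of group sizes
#'
#' Counts groups in the conventional size bins 1, 2, 3–5 and more than 5.
#'
#' @param x A `pgc_dictionary`, a `local_group_set`, or a list of accession
#'   vectors.
#' @return A `pgc_size_hist` tibble with columns `size_bin` and `n`; the
#'   counts sum to the number of groups.
#' @export
group_size_histogram <- function(x) {
  sizes <- if (inherits(x, "pgc_dictionary")) {
    as.integer(table(x$pgc))
  } else if (inherits(x, "local_group_set")) {
    as.integer(table(x$group_id))
  } else if (is.list(x)) {
    lengths(x)
  } else {
    abort("`x` must be a dictionary, a local group set, or a list of sets.")
  }
  bins <- factor(c("1", "2", "3-5", ">5"), levels = c("1", "2", "3-5", ">5"))
  n <- c(sum(sizes == 1L), sum(sizes == 2L),
         sum(sizes >= 3L & sizes <= 5L), sum(sizes > 5L))
  out <- tibble(size_bin = bins, n = as.integer(n))
  class(out) <- c("pgc_size_hist", class(tibble()))
  out
}

#' Dice comparison of per-run groups against the dictionary
#'
#' For every run and every global group, compares the accessions the run
#' assigned to that code with the full global group: 1 when the run saw the
#' whole group, between 0 and 1 when it saw a subset, and 0 when the code is
#' absent from the run.
#'
#' @param coded List of `coded_summary` objects from a mode `"all"` build.
#' @param dict The `pgc_dictionary` used to code them.
#' @return A `pgc_dice` tibble with columns `run_id`, `pgc` and `dice`.
#' @export
dice_vs_dictionary <- function(coded, dict) {
  coded <- coded_list(coded)
  assert_inherits(dict, "pgc_dictionary")
  ids <- run_ids(coded)
  globals <- global_groups_list(dict)
  pgcs <- as.integer(names(globals))
  rows <- map2(coded, ids, function(x, id) {
    local <- split(x$accession[x$pgc != 0L], x$pgc[x$pgc != 0L])
    d <- vapply(seq_along(pgcs), function(i) {
      p <- as.character(pgcs[i])
      if (is.null(local[[p]])) 0 else dice(local[[p]], globals[[i]])
    }, numeric(1))
    tibble(run_id = id, pgc = pgcs, dice = d)
  })
  out <- bind_rows(rows)
  class(out) <- c("pgc_dice", class(tibble()))
  out
}

#' Dice comparison of top proteins across runs
#'
#' For each global group, the parent set is the union over runs of the top
#' proteins chosen to represent the group. Each run's top set is compared to
#' this parent: 1 when a unique top protein represents the group in every
#' run, below 1 when the representative varies, and 0 when the group was not
#' identified in the run.
#'
#' @inheritParams dice_vs_dictionary
#' @return A `pgc_dice` tibble with columns `run_id`, `pgc` and `dice`.
#' @export
dice_top_proteins <- function(coded, dict) {
  coded <- coded_list(coded)
  assert_inherits(dict, "pgc_dictionary")
  ids <- run_ids(coded)
  pgcs <- sort(unique(dict$pgc))
  tops_by_run <- map(coded, function(x) {
    keep <- x$is_top & x$pgc != 0L
    split(x$accession[keep], x$pgc[keep])
  })
  parent <- map(as.character(pgcs), function(p) {
    unique(unlist(map(tops_by_run, function(t) t[[p]]), use.names = FALSE))
  })
  rows <- map2(tops_by_run, ids, function(tops, id) {
    d <- vapply(seq_along(pgcs), function(i) {
      p <- as.character(pgcs[i])
      if (is.null(tops[[p]]) || length(parent[[i]]) == 0L) {
        0
      } else {
        dice(tops[[p]], parent[[i]])
      }
    }, numeric(1))
    tibble(run_id = id, pgc = pgcs, dice = d)
  })
  out <- bind_rows(rows)
  class(out) <- c("pgc_dice", class(tibble()))
  out
}
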