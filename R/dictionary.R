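#' Create an empty protein group code dictionary
#'
#' A dictionary maps accession numbers to protein group codes (PGCs). It is
#' represented as a tibble with one row per accession and columns `pgc` and
#' `accession`; global groups are the sets of accessions sharing a PGC.
#' Global groups are pairwise disjoint by construction.
#'
#' @return An empty `pgc_dictionary`.
#' @seealso [update_dictionary()], [build_dictionary()]
#' @export
pgc_dictionary <- function() {
  new_pgc_dictionary(
    tibble(pgc = integer(), accession = character()),
    next_pgc = 1L,
    history = empty_history()
  )
}

empty_history <- function() {
  tibble(step = integer(), run_id = character(),
         new_accessions = integer(), new_groups = integer(),
         mergers = integer())
}

new_pgc_dictionary <- function(tbl, next_pgc, history) {
  out <- as_tibble(tbl)
  attr(out, "next_pgc") <- as.integer(next_pgc)
  attr(out, "history") <- history
  class(out) <- c("pgc_dictionary", class(tibble()))
  out
}

validate_pgc_dictionary <- function(dict) {
  if (anyDuplicated(dict$accession)) {
    dup <- unique(dict$accession[duplicated(dict$accession)])
    abort(sprintf(
      "Dictionary invariant violated: accession(s) %s mapped to more than one PGC.",
      paste0("'", utils::head(dup, 3), "'", collapse = ", ")
    ))
  }
  invisible(dict)
}

# Global groups as a list of accession vectors named by PGC.
global_groups_list <- function(dict) {
  split(dict$accession, dict$pgc)
}

#' Merge a set of local groups into a dictionary
#'
#' The incremental update step of the protein group code algorithm: the
#' existing global groups and the incoming local groups are merged by
#' transitive overlap. Two groups are linked when they share an accession
#' number; the returned global groups are exactly the connected components
#' of that overlap relation, so they are pairwise disjoint and every
#' accession of the inputs appears in exactly one of them.
#'
#' Codes are kept stable across updates: a global group that is unchanged or
#' only extended keeps its PGC; when several existing groups merge, the
#' smallest (oldest) PGC survives; brand-new groups receive the next unused
#' code, and codes of merged-away groups are never reused.
#'
#' @param dict A `pgc_dictionary` (possibly empty).
#' @param local_groups A `local_group_set` from [create_local_groups()], or a
#'   plain list of accession character vectors.
#'
#' @return The updated `pgc_dictionary`. Its `history` attribute gains one
#'   row recording, for this update, the number of previously unseen
#'   accessions, of newly created groups, and of merge events (a merge of
#'   `g` existing groups counts `g - 1`).
#' @examples
#' d <- update_dictionary(pgc_dictionary(), list(c("a", "b"), "c"))
#' update_dictionary(d, list(c("a", "b", "c")))
#' @export
update_dictionary <- function(dict, local_groups) {
  assert_inherits(dict, "pgc_dictionary")
  validate_pgc_dictionary(dict)
  run_id <- attr(local_groups, "run_id") %||% NA_character_
  incoming <- local_groups_list(local_groups)
  incoming <- lapply(incoming, function(s) unique(as.character(s)))
  incoming <- incoming[lengths(incoming) > 0L]

  old_groups <- global_groups_list(dict)
  old_pgcs <- as.integer(names(old_groups))

  accs <- unique(c(dict$accession, unlist(incoming, use.names = FALSE)))
  if (length(accs) == 0L) {
    return(record_history(dict, run_id, 0L, 0L, 0L))
  }

  # a local group spanning several existing global groups forces a merger;
  # flag it, as it can indicate inconsistent upstream grouping
  if (length(old_groups) > 0L) {
    acc2pgc <- setNames(dict$pgc, dict$accession)
    spans <- vapply(incoming, function(s) {
      length(unique(acc2pgc[s][!is.na(acc2pgc[s])])) > 1L
    }, logical(1))
    if (any(spans)) {
      warn(sprintf(
        "%d local group(s) span multiple existing global groups; merging them.",
        sum(spans)
      ))
    }
  }

  idx_sets <- c(
    lapply(old_groups, function(s) match(s, accs)),
    lapply(incoming, function(s) match(s, accs))
  )
  comp <- uf_components(length(accs), idx_sets)

  # per component: surviving PGC = min of member PGCs, else a fresh code
  comp_ids <- unique(comp)
  old_comp <- comp[match(dict$accession, accs)]
  min_old_pgc <- if (length(old_comp) > 0L) {
    tapply(dict$pgc, old_comp, min)
  } else {
    integer()
  }
  n_old_per_comp <- if (length(old_comp) > 0L) {
    tapply(dict$pgc, old_comp, function(p) length(unique(p)))
  } else {
    integer()
  }

  next_pgc <- attr(dict, "next_pgc")
  pgc_of_comp <- integer(length(comp_ids))
  names(pgc_of_comp) <- comp_ids
  new_groups <- 0L
  for (ci in as.character(comp_ids)) {
    if (ci %in% names(min_old_pgc)) {
      pgc_of_comp[ci] <- as.integer(min_old_pgc[[ci]])
    } else {
      pgc_of_comp[ci] <- next_pgc
      next_pgc <- next_pgc + 1L
      new_groups <- new_groups + 1L
    }
  }

  mergers <- sum(pmax(as.integer(n_old_per_comp) - 1L, 0L))
  new_accessions <- length(setdiff(accs, dict$accession))

  tbl <- tibble(
    pgc = unname(pgc_of_comp[as.character(comp)]),
    accession = accs
  ) |> arrange(.data$pgc, .data$accession)

  out <- new_pgc_dictionary(tbl, next_pgc, attr(dict, "history"))
  validate_pgc_dictionary(out)
  record_history(out, run_id, new_accessions, new_groups, mergers)
}

record_history <- function(dict, run_id, new_accessions, new_groups,
                           mergers) {
  h <- attr(dict, "history")
  h <- bind_rows(h, tibble(
    step = nrow(h) + 1L, run_id = as.character(run_id),
    new_accessions = as.integer(new_accessions),
    new_groups = as.integer(new_groups),
    mergers = as.integer(mergers)
  ))
  attr(dict, "history") <- h
  dict
}

#' Build a dictionary from several protein summaries
#'
#' Folds [update_dictionary()] over the local groups of each summary in
#' order, starting from an empty dictionary. The composition of the
#' resulting global groups does not depend on the processing order; only the
#' code values do.
#'
#' @param summaries A list of `protein_summary` objects (or a single one).
#' @param mode Grouping mode passed to [create_local_groups()].
#'
#' @return A `pgc_dictionary` whose `history` attribute holds the per-file
#'   mapping change log.
#' @examples
#' runs <- example_runs_regrouping()
#' build_dictionary(runs, mode = "all")
#' @export
build_dictionary <- function(summaries, mode = "all") {
  if (inherits(summaries, "protein_summary")) summaries <- list(summaries)
  if (length(summaries) == 0L) abort("At least one protein summary is required.")
  mode <- match_mode(mode)
  dict <- pgc_dictionary()
  for (s in summaries) {
    dict <- update_dictionary(dict, create_local_groups(s, mode))
  }
  dict
}

#' Test whether a collection of accession sets is connected
#'
#' Two sets are linked when they share an accession; a collection is
#' connected when its overlap graph forms a single connected component,
#' possibly through connector sets that bridge sets with no direct overlap.
#' This is the defining property of a global group and is used as the test
#' oracle for the merging step.
#'
#' @param sets A list of non-empty accession character vectors.
#' @return `TRUE` if the overlap graph is a single component; `FALSE` for an
#'   empty collection (by convention).
#' @examples
#' is_connected(list(c("a", "x"), c("x", "y"), c("y", "b")))
#' is_connected(list(c("a", "b"), c("c", "d")))
#' @export
is_connected <- function(sets) {
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (length(sets) == 0L) return(FALSE)
  if (any(lengths(sets) == 0L)) abort("All sets must be non-empty.")
  if (length(sets) == 1L) return(TRUE)
  accs <- unique(unlist(sets, use.names = FALSE))
  # union set indices through shared accessions
  n <- length(sets)
  owner <- lapply(accs, function(a) which(map_lgl(sets, function(s) a %in% s)))
  comp <- uf_components(n, owner)
  length(unique(comp)) == 1L
}

#' Write a dictionary to a tab-separated file
#'
#' The file has a `PGC<TAB>Accession` header and one row per accession,
#' sorted by code then accession so successive versions diff cleanly. A
#' leading `# next_pgc=<n>` comment preserves the code counter, which can
#' run ahead of `max(PGC) + 1` after mergers.
#'
#' @param dict A `pgc_dictionary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dictionary <- function(dict, path) {
  assert_inherits(dict, "pgc_dictionary")
  validate_pgc_dictionary(dict)
  tbl <- dict |> arrange(.data$pgc, .data$accession)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# next_pgc=%d", attr(dict, "next_pgc")), con)
  writeLines("PGC\tAccession", con)
  if (nrow(tbl) > 0L) {
    writeLines(paste(tbl$pgc, tbl$accession, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a dictionary written by [write_dictionary()]
#'
#' @param path Path to a two-column `PGC<TAB>Accession` file.
#' @return A `pgc_dictionary`. Files without the `# next_pgc` comment load
#'   with the counter set to `max(PGC) + 1`.
#' @export
read_dictionary <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path)
  next_pgc <- NA_integer_
  comments <- grepl("^#", lines)
  np <- grep("^#\\s*next_pgc\\s*=", lines, value = TRUE)
  if (length(np) > 0L) {
    next_pgc <- as.integer(sub("^#\\s*next_pgc\\s*=\\s*", "", np[1]))
  }
  lines <- lines[!comments]
  if (length(lines) == 0L || !identical(strsplit(lines[1], "\t")[[1]],
                                        c("PGC", "Accession"))) {
    abort("Malformed dictionary file: expected a 'PGC\\tAccession' header.")
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    tbl <- tibble(pgc = integer(), accession = character())
  } else {
    parts <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(parts) != 2L)) {
      abort("Malformed dictionary file: every row must have two columns.")
    }
    pgc <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 1L)))
    if (anyNA(pgc)) abort("Malformed dictionary file: non-integer PGC.")
    tbl <- tibble(pgc = pgc, accession = vapply(parts, `[[`, "", 2L))
  }
  if (is.na(next_pgc)) {
    next_pgc <- if (nrow(tbl) > 0L) max(tbl$pgc) + 1L else 1L
  }
  out <- new_pgc_dictionary(tbl, next_pgc, empty_history())
  validate_pgc_dictionary(out)
  out
}

#' @export
print.pgc_dictionary <- function(x, ...) {
  cat(sprintf("# PGC dictionary: %d global groups, %d accessions\n",
              length(unique(x$pgc)), nrow(x)))
  NextMethod()
}

#' Tidy a PGC dictionary
#'
#' @param x A `pgc_dictionary`.
#' @param ... Unused.
#' @return A tibble with one row per accession: `pgc`, `accession` and the
#'   `group_size` of the accession's global group.
#' @method tidy pgc_dictionary
#' @export
tidy.pgc_dictionary <- function(x, ...) {
  as_tibble(x) |>
    group_by(.data$pgc) |>
    mutate(group_size = n()) |>
    ungroup()
}

#' One-row summary of a PGC dictionary
#'
#' @param x A `pgc_dictionary`.
#' @param ... Unused.
#' @return A one-row tibble: number of global groups, of accessions, of
#'   singleton groups, the largest group size, and the next unused code.
#' @method glance pgc_dictionary
#' @export
glance.pgc_dictionary <- function(x, ...) {
  sizes <- as.integer(table(x$pgc))
  tibble(
    n_groups = length(sizes),
    n_accessions = nrow(x),
    n_singletons = sum(sizes == 1L),
    max_group_size = if (length(sizes) > 0L) max(sizes) else 0L,
    next_pgc = attr(x, "next_pgc")
  )
}

#' Per-file mapping change log of a dictionary
#'
#' @param dict A `pgc_dictionary` built with [build_dictionary()] or by
#'   repeated [update_dictionary()] calls.
#' @return A `pgc_change_log` tibble: per processed file, the number of new
#'   accessions, newly created global groups, and merge events.
#' @export
dictionary_history <- function(dict) {
  assert_inherits(dict, "pgc_dictionary")
  h <- attr(dict, "history")
  class(h) <- c("pgc_change_log", class(tibble()))
  h
}
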