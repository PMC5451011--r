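#' Column dialects for protein-summary files
#'
#' MS/MS processing software exports protein summaries with different column
#' layouts. A dialect maps the columns of a tab-delimited export onto the
#' fields the linking algorithm needs: the within-run group identifier, the
#' accession number, and optionally the protein name, gene symbol(s), a
#' within-group rank, and an explicit master/top-protein flag.
#'
#' Two presets ship with the package:
#' \describe{
#'   \item{`"proteinpilot"`}{group column `N`, accession column `Accession`;
#'     the first row of each group (file order) is the top protein, as in
#'     ProteinPilot exports.}
#'   \item{`"discoverer"`}{group column `Group`, accession column `Accession`,
#'     and a `Master` flag column marking the master protein, as in Proteome
#'     Discoverer exports.}
#' }
#'
#' @param group_id Name of the column holding the within-run group identifier.
#' @param accession Name of the accession-number column.
#' @param protein_name Optional name of the protein-name column.
#' @param genes Optional name of the gene-symbol column. Multiple symbols may
#'   be separated by `;`, `,` or `|`.
#' @param rank Optional name of a numeric within-group rank/score column.
#' @param top Optional name of a column flagging the top (master) protein.
#'   Values `TRUE`, `"TRUE"`, `"True"`, `"Yes"`, `"1"`, `"Master"` or
#'   `"Master Protein"` (case-insensitive) mark the top entry. When `NULL`,
#'   the first row of each group in file order is the top.
#' @param name Label stored on summaries read with this dialect.
#'
#' @return A `pgc_dialect` list.
#' @examples
#' pgc_dialect(group_id = "GroupNo", accession = "Acc", genes = "GeneSymbol")
#' @export
pgc_dialect <- function(group_id, accession, protein_name = NULL,
                        genes = NULL, rank = NULL, top = NULL,
                        name = "custom") {
  structure(
    list(group_id = group_id, accession = accession,
         protein_name = protein_name, genes = genes,
         rank = rank, top = top, name = name),
    class = "pgc_dialect"
  )
}

dialect_presets <- function() {
  list(
    proteinpilot = pgc_dialect(
      group_id = "N", accession = "Accession",
      protein_name = "Name", genes = "Gene",
      name = "proteinpilot"
    ),
    discoverer = pgc_dialect(
      group_id = "Group", accession = "Accession",
      protein_name = "Description", genes = "Gene",
      rank = "Rank", top = "Master",
      name = "discoverer"
    )
  )
}

resolve_dialect <- function(dialect) {
  if (inherits(dialect, "pgc_dialect")) return(dialect)
  if (is.character(dialect) && length(dialect) == 1L) {
    presets <- dialect_presets()
    if (!dialect %in% names(presets)) {
      abort(sprintf(
        "Unknown dialect '%s'. Use one of %s or a pgc_dialect() mapping.",
        dialect, paste0("'", names(presets), "'", collapse = ", ")
      ))
    }
    return(presets[[dialect]])
  }
  if (is.character(dialect) || is.list(dialect)) {
    dialect <- as.list(dialect)
    if (is.null(dialect$group_id) || is.null(dialect$accession)) {
      abort("A custom dialect must map at least `group_id` and `accession`.")
    }
    return(do.call(pgc_dialect, dialect))
  }
  abort("`dialect` must be a preset name or a pgc_dialect() mapping.")
}

top_flag_values <- c("true", "yes", "1", "master", "master protein")

# Internal constructor: canonical columns + verbatim raw table as attribute.
new_protein_summary <- function(canonical, raw, run_id, dialect_name) {
  out <- as_tibble(canonical)
  attr(out, "run_id") <- run_id
  attr(out, "dialect") <- dialect_name
  attr(out, "raw") <- as_tibble(raw)
  class(out) <- c("protein_summary", class(tibble()))
  out
}

validate_protein_summary <- function(x) {
  if (any(!nzchar(x$accession) | is.na(x$accession))) {
    abort("All accession numbers must be non-empty.")
  }
  tops <- tapply(x$is_top, x$group_id, sum)
  if (any(tops != 1L)) {
    abort("Each protein group must have exactly one top entry.")
  }
  invisible(x)
}

#' Read a per-run protein summary
#'
#' Parses a tab-delimited protein-summary export (one header row) into a
#' `protein_summary` tibble with the canonical columns `group_id`,
#' `accession`, `protein_name`, `genes` (list column of symbols), `is_top`
#' and `rank`. All original columns are preserved verbatim in the `raw`
#' attribute so coded summaries can be written back without altering them.
#'
#' Rows sharing a group identifier form one protein group. Unless the dialect
#' names an explicit master-protein column, the first row of each group in
#' file order is flagged as the top protein. Duplicated
#' (`group_id`, `accession`) rows are dropped with a warning.
#'
#' @param path Path to a tab-separated protein summary with a header row.
#' @param dialect A preset name (`"proteinpilot"`, `"discoverer"`) or a
#'   [pgc_dialect()] column mapping.
#' @param run_id Label for the experimental run; defaults to the file name
#'   without extension.
#'
#' @return A `protein_summary` tibble.
#' @seealso [write_protein_summary()], [write_coded_summary()]
#' @export
read_protein_summary <- function(path, dialect = "proteinpilot",
                                 run_id = NULL) {
  dialect <- resolve_dialect(dialect)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
  if (nrow(raw) == 0L) {
    abort(sprintf("Protein summary '%s' has no data rows.", path))
  }
  if (is.null(run_id)) {
    run_id <- sub("\\.[A-Za-z0-9]+$", "", basename(path))
  }
  parse_protein_summary(raw, dialect, run_id)
}

parse_protein_summary <- function(raw, dialect, run_id) {
  needed <- c(group_id = dialect$group_id, accession = dialect$accession)
  missing <- needed[!needed %in% names(raw)]
  if (length(missing) > 0L) {
    abort(sprintf(
      "Protein summary is missing required column(s): %s.",
      paste0("'", missing, "'", collapse = ", ")
    ))
  }

  gid_raw <- raw[[dialect$group_id]]
  gid <- suppressWarnings(as.integer(gid_raw))
  if (anyNA(gid)) {
    # non-numeric group labels: map to integer codes in file order
    gid <- match(gid_raw, unique(gid_raw))
  }
  acc <- as.character(raw[[dialect$accession]])

  dup <- duplicated(paste(gid, acc, sep = "\r"))
  if (any(dup)) {
    warn(sprintf("Dropping %d duplicated (group, accession) row(s).",
                 sum(dup)))
    raw <- raw[!dup, , drop = FALSE]
    gid <- gid[!dup]
    acc <- acc[!dup]
  }

  opt_col <- function(nm) {
    if (!is.null(nm) && nm %in% names(raw)) raw[[nm]] else NULL
  }
  prot <- opt_col(dialect$protein_name) %||% rep(NA_character_, nrow(raw))
  genes <- split_genes(opt_col(dialect$genes) %||%
                         rep(NA_character_, nrow(raw)))
  rank_col <- opt_col(dialect$rank)
  rank <- if (is.null(rank_col)) {
    rep(NA_real_, nrow(raw))
  } else {
    suppressWarnings(as.numeric(rank_col))
  }

  top_col <- opt_col(dialect$top)
  if (is.null(top_col)) {
    is_top <- !duplicated(gid)
  } else {
    flagged <- tolower(trimws(as.character(top_col))) %in% top_flag_values
    # enforce exactly one top per group: first flagged row wins, and groups
    # with no flagged row fall back to their first row
    is_top <- flagged & !duplicated(paste(gid, flagged))
    no_top <- !gid %in% gid[is_top]
    if (any(no_top)) {
      is_top <- is_top | (no_top & !duplicated(gid))
    }
    if (sum(flagged) != sum(tapply(flagged, gid, any))) {
      warn("Groups with multiple master-protein flags: keeping the first.")
    }
  }

  canonical <- tibble(
    group_id = as.integer(gid),
    accession = acc,
    protein_name = as.character(prot),
    genes = genes,
    is_top = is_top,
    rank = rank
  )
  out <- new_protein_summary(canonical, raw, run_id, dialect$name)
  validate_protein_summary(out)
  out
}

#' Write a protein summary back to a tab-separated file
#'
#' Writes the verbatim original columns (the `raw` attribute) of a
#' `protein_summary`, so reading the file again with the same dialect
#' reproduces the summary.
#'
#' @param summary A `protein_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_summary <- function(summary, path) {
  assert_inherits(summary, "protein_summary")
  raw <- attr(summary, "raw")
  readr::write_tsv(raw, path, na = "", quote = "none", escape = "none",
                   progress = FALSE)
  invisible(path)
}

#' Write a coded protein summary
#'
#' Writes a coded summary as tab-separated text with the protein group code
#' (PGC) as the first column, followed by every original column unchanged.
#'
#' @param coded A `coded_summary`, as returned by [code_protein_groups()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coded_summary <- function(coded, path) {
  assert_inherits(coded, "coded_summary")
  if (!"pgc" %in% names(coded) || anyNA(coded$pgc)) {
    abort("Every entry must carry a PGC before writing a coded summary.")
  }
  raw <- attr(coded, "raw")
  out <- bind_cols(tibble(PGC = coded$pgc), raw)
  readr::write_tsv(out, path, na = "", quote = "none", escape = "none",
                   progress = FALSE)
  invisible(path)
}

#' Read a coded protein summary
#'
#' Reads a file written by [write_coded_summary()]: the leading `PGC` column
#' is restored as the `pgc` column and the remaining columns are parsed with
#' the given dialect.
#'
#' @inheritParams read_protein_summary
#' @return A `coded_summary` tibble.
#' @export
read_coded_summary <- function(path, dialect = "proteinpilot",
                               run_id = NULL) {
  dialect <- resolve_dialect(dialect)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
  if (names(raw)[1] != "PGC") {
    abort("A coded summary must have 'PGC' as its first column.")
  }
  if (nrow(raw) == 0L) {
    abort(sprintf("Coded summary '%s' has no data rows.", path))
  }
  if (is.null(run_id)) {
    run_id <- sub("\\.[A-Za-z0-9]+$", "", basename(path))
  }
  pgc <- as.integer(raw$PGC)
  summary <- parse_protein_summary(raw[-1], dialect, run_id)
  out <- bind_cols(tibble(pgc = pgc), summary)
  attr(out, "run_id") <- attr(summary, "run_id")
  attr(out, "dialect") <- attr(summary, "dialect")
  attr(out, "raw") <- attr(summary, "raw")
  class(out) <- c("coded_summary", "protein_summary", class(tibble()))
  out
}

#' @export
print.protein_summary <- function(x, ...) {
  cat(sprintf("# Protein summary: run '%s' (%s dialect), %d entries in %d groups\n",
              attr(x, "run_id"), attr(x, "dialect"),
              nrow(x), length(unique(x$group_id))))
  NextMethod()
}
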