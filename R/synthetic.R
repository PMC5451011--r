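#' Configuration for the multi-run summary simulator
#'
#' The simulator emulates the three ways protein groups drift between
#' experimental runs of one study: run-local group identifiers change, group
#' membership changes (whole groups or individual members drop out), and the
#' top protein chosen to represent a group changes. Defaults are set to
#' resemble a plasma spectral-counting study of about a dozen runs: roughly
#' 60% singleton groups and a mean of about 220 detected groups per run.
#'
#' @param n_runs Number of experimental runs.
#' @param n_true_groups Number of underlying protein groups in the study.
#' @param size_weights Named numeric vector of sampling weights over group
#'   sizes; names are the sizes.
#' @param dropout_prob Probability that a group is entirely absent from a
#'   run.
#' @param member_dropout_prob Probability that a non-top member is absent
#'   from a run's realization of its group.
#' @param top_swap_prob Probability that the run's top protein is a member
#'   other than the canonical one.
#' @param shared_gene_prob Probability that a member carries the same gene
#'   symbol as its group's canonical top (otherwise it gets its own gene).
#' @param seed Integer seed; a fixed seed makes [generate_runs()] output
#'   byte-identical across calls.
#'
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_runs = 12,
                              n_true_groups = 250,
                              size_weights = c("1" = 0.60, "2" = 0.17,
                                               "3" = 0.10, "4" = 0.06,
                                               "5" = 0.04, "6" = 0.02,
                                               "7" = 0.01),
                              dropout_prob = 0.10,
                              member_dropout_prob = 0.10,
                              top_swap_prob = 0.20,
                              shared_gene_prob = 0.80,
                              seed = 1L) {
  probs <- c(dropout_prob, member_dropout_prob, top_swap_prob,
             shared_gene_prob)
  if (any(probs < 0 | probs > 1)) abort("Probabilities must lie in [0, 1].")
  sizes <- as.integer(names(size_weights))
  if (anyNA(sizes) || any(sizes < 1L) || any(size_weights < 0)) {
    abort("`size_weights` must have positive-integer names and non-negative weights.")
  }
  if (n_runs < 1L || n_true_groups < 1L) {
    abort("`n_runs` and `n_true_groups` must be at least 1.")
  }
  structure(
    list(n_runs = as.integer(n_runs),
         n_true_groups = as.integer(n_true_groups),
         size_weights = size_weights,
         dropout_prob = dropout_prob,
         member_dropout_prob = member_dropout_prob,
         top_swap_prob = top_swap_prob,
         shared_gene_prob = shared_gene_prob,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Simulate per-run protein summaries with known group structure
#'
#' Draws a set of true protein groups, then realizes each run by dropping
#' whole groups, dropping non-top members, rotating the top protein, and
#' renumbering local group identifiers. Synthetic accessions carry version
#' suffixes (`PROT00001.2`) to exercise version handling; gene symbols are
#' `GENE0001`-style.
#'
#' The run's top protein is always present in its group's realization, so
#' with `member_dropout_prob = 0` every realization of a true group overlaps
#' every other and mode `"all"` linking recovers the true groups exactly
#' (restricted to observed accessions). With member dropout, realizations of
#' one true group can become disjoint, in which case the recoverable truth
#' is the overlap-connected refinement of the group.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `runs` (list of `protein_summary`, one per
#'   run), `truth` (tibble `true_group`, `accession`, `gene`,
#'   `canonical_top`), and `config`.
#' @examples
#' sim <- generate_runs(simulation_config(n_runs = 3, n_true_groups = 20))
#' length(sim$runs)
#' @export
generate_runs <- function(config) {
  assert_inherits(config, "simulation_config")
  set.seed(config$seed)

  sizes <- sample(as.integer(names(config$size_weights)),
                  config$n_true_groups, replace = TRUE,
                  prob = config$size_weights)
  total <- sum(sizes)
  acc_idx <- seq_len(total)
  versions <- sample(1:3, total, replace = TRUE)
  accessions <- sprintf("PROT%05d.%d", acc_idx, versions)
  group_of <- rep(seq_len(config$n_true_groups), sizes)

  shared <- stats::runif(total) < config$shared_gene_prob
  own_gene_id <- config$n_true_groups + cumsum(!shared)
  gene <- ifelse(shared,
                 sprintf("GENE%04d", group_of),
                 sprintf("GENE%04d", own_gene_id))
  members <- split(seq_len(total), group_of)
  canonical_top <- map_int(members, 1L)
  # the canonical top always shares its group's base gene
  gene[canonical_top] <- sprintf("GENE%04d", seq_len(config$n_true_groups))

  truth <- tibble(
    true_group = group_of,
    accession = accessions,
    gene = gene,
    canonical_top = acc_idx %in% canonical_top
  )

  runs <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    kept <- which(stats::runif(config$n_true_groups) >= config$dropout_prob)
    # local IDs are arbitrary: shuffle group order
    kept <- kept[sample.int(length(kept))]
    rows_n <- integer()
    rows_i <- integer()
    local_n <- 0L
    for (g in kept) {
      m <- members[[g]]
      top <- m[1L]
      if (length(m) > 1L &&
          stats::runif(1) < config$top_swap_prob) {
        pool <- m[-1L]
        top <- pool[sample.int(length(pool), 1L)]
      }
      others <- setdiff(m, top)
      others <- others[stats::runif(length(others)) >=
                         config$member_dropout_prob]
      sel <- c(top, others)
      local_n <- local_n + 1L
      rows_n <- c(rows_n, rep(local_n, length(sel)))
      rows_i <- c(rows_i, sel)
    }
    raw <- tibble(
      N = as.character(rows_n),
      Accession = accessions[rows_i],
      Name = sprintf("Synthetic protein %05d", rows_i),
      Gene = gene[rows_i]
    )
    run_id <- sprintf("run%02d", r)
    runs[[r]] <- if (nrow(raw) > 0L) {
      parse_protein_summary(raw, dialect_presets()$proteinpilot, run_id)
    } else {
      new_protein_summary(
        tibble(group_id = integer(), accession = character(),
               protein_name = character(), genes = list(),
               is_top = logical(), rank = numeric()),
        raw, run_id, "proteinpilot"
      )
    }
  }

  list(runs = runs, truth = truth, config = config)
}

make_fixture_summary <- function(raw, dialect, run_id) {
  parse_protein_summary(as_tibble(raw), dialect, run_id)
}

#' Worked example: the same proteins regrouped across three runs
#'
#' Three small ProteinPilot-style summaries of one kininogen-1 protein
#' group. In the first run the three related accessions are split over two
#' local groups; the second run reports them as a single group, which links
#' the two global groups into one; the third run adds a fourth accession to
#' the group. The fourth accession is a synthetic stand-in. Stepwise linking
#' therefore yields 2, then 1, then 1 global group(s), the final group
#' holding all four accessions.
#'
#' @return A list of three `protein_summary` objects.
#' @examples
#' glance(build_dictionary(example_runs_regrouping(), mode = "all"))
#' @export
example_runs_regrouping <- function() {
  pp <- dialect_presets()$proteinpilot
  a <- "IPI00215894.1"  # kininogen-1 isoform LMW
  b <- "IPI00797833.3"  # near-identical to the LMW isoform
  c_ <- "IPI00032328.2" # kininogen-1 isoform HMW
  d <- "IPI00884105.1"  # synthetic fourth member
  kng <- "KNG1"
  nm <- "Kininogen-1"
  list(
    make_fixture_summary(
      tibble(N = c("1", "1", "2"), Accession = c(a, b, c_),
             Name = nm, Gene = kng),
      pp, "regroup1"
    ),
    make_fixture_summary(
      tibble(N = c("1", "1", "1"), Accession = c(b, a, c_),
             Name = nm, Gene = kng),
      pp, "regroup2"
    ),
    make_fixture_summary(
      tibble(N = c("1", "1", "1", "1"), Accession = c(b, a, c_, d),
             Name = nm, Gene = kng),
      pp, "regroup3"
    )
  )
}

#' Worked example: one protein group with a rotating top protein
#'
#' Three Proteome Discoverer-style summaries of a pyruvate-kinase protein
#' group in which each run picks a different master protein. In the first
#' run the master (Q504U3, gene PKM2) shares no gene with the other members
#' (gene PKM), so the top-gene refinement keeps only the master there; in
#' the other runs all members share gene PKM. The non-master PKM accessions
#' are synthetic stand-ins. Linking whole groups joins everything into one
#' global group; linking by top gene yields two groups; linking by top
#' identifier yields three.
#'
#' @return A list of three `protein_summary` objects.
#' @examples
#' glance(build_dictionary(example_runs_top_rotation(), mode = "top_gene"))
#' @export
example_runs_top_rotation <- function() {
  dd <- dialect_presets()$discoverer
  p1 <- "Q504U3"    # master of run 1, gene PKM2
  p2 <- "P14618"    # gene PKM (synthetic stand-in member)
  p3 <- "P14618-2"  # gene PKM (synthetic stand-in member)
  p4 <- "B4DNK4"    # gene PKM (synthetic stand-in member)
  nm <- "Pyruvate kinase"
  list(
    make_fixture_summary(
      tibble(Group = "1", Accession = c(p1, p2, p3), Description = nm,
             Gene = c("PKM2", "PKM", "PKM"), Rank = "1",
             Master = c("Master Protein", "", "")),
      dd, "rotation1"
    ),
    make_fixture_summary(
      tibble(Group = "1", Accession = c(p2, p3, p4), Description = nm,
             Gene = "PKM", Rank = "1",
             Master = c("Master Protein", "", "")),
      dd, "rotation2"
    ),
    make_fixture_summary(
      tibble(Group = "1", Accession = c(p3, p2, p4), Description = nm,
             Gene = "PKM", Rank = "1",
             Master = c("Master Protein", "", "")),
      dd, "rotation3"
    )
  )
}
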