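# Independent brute-force oracle: literal repeat-until-fixpoint merging of
# overlapping sets. Deliberately does not share code with the union-find
# implementation it checks.
oracle_components <- function(sets) {
  sets <- lapply(sets, function(s) unique(as.character(s)))
  sets <- sets[lengths(sets) > 0L]
  repeat {
    merged <- FALSE
    n <- length(sets)
    if (n < 2L) break
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        if (length(intersect(sets[[i]], sets[[j]])) > 0L) {
          sets[[i]] <- union(sets[[i]], sets[[j]])
          sets[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  sets
}

# Canonical representation of a collection of groups: sorted members,
# groups ordered by first member. PGC values are deliberately dropped so
# comparisons are about composition only.
canon_groups <- function(groups) {
  groups <- unname(lapply(groups, function(g) sort(unique(as.character(g)))))
  groups <- groups[lengths(groups) > 0L]
  groups[order(vapply(groups, `[`, "", 1L))]
}

dict_groups <- function(dict) {
  canon_groups(unname(split(dict$accession, dict$pgc)))
}

# Random collection of accession sets for oracle-equivalence checks.
random_sets <- function(max_accessions = 200, max_sets = 60) {
  n_acc <- sample(2:max_accessions, 1)
  universe <- sprintf("ACC%04d", seq_len(n_acc))
  n_sets <- sample(1:max_sets, 1)
  lapply(seq_len(n_sets), function(i) {
    sample(universe, sample(1:min(8, n_acc), 1))
  })
}

# Split random sets over a few pseudo-runs so they can drive
# update_dictionary sequences.
chunk_sets <- function(sets, n_chunks) {
  idx <- sort(sample.int(n_chunks, length(sets), replace = TRUE))
  unname(split(sets, idx))
}
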