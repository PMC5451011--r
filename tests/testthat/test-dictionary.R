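test_that("updates merge overlapping groups into disjoint global groups", {
  d <- update_dictionary(pgc_dictionary(), list(c("a", "b"), "c"))
  expect_identical(dict_groups(d), list(c("a", "b"), "c"))

  d2 <- suppressWarnings(update_dictionary(d, list(c("a", "b", "c"))))
  expect_identical(dict_groups(d2), list(c("a", "b", "c")))

  d3 <- update_dictionary(d2, list(c("a", "b", "c", "d")))
  expect_identical(dict_groups(d3), list(c("a", "b", "c", "d")))
})

test_that("a connector set joins groups that never overlap directly", {
  # expected components frozen from the brute-force fixpoint oracle
  sets <- list(c("a", "b"), c("b", "c"), "d")
  expect_identical(canon_groups(oracle_components(sets)),
                   list(c("a", "b", "c"), "d"))
  d <- update_dictionary(pgc_dictionary(), sets)
  expect_identical(dict_groups(d), list(c("a", "b", "c"), "d"))
})

test_that("PGC assignment is stable across incremental updates", {
  d <- update_dictionary(pgc_dictionary(), list(c("a", "b"), "c", "x"))
  pgc_ab <- d$pgc[d$accession == "a"]
  pgc_c <- d$pgc[d$accession == "c"]
  # extension keeps the code
  d2 <- update_dictionary(d, list(c("a", "b", "e")))
  expect_equal(unique(d2$pgc[d2$accession %in% c("a", "b", "e")]), pgc_ab)
  # merger keeps the smallest (oldest) code, released codes are not reused
  d3 <- suppressWarnings(update_dictionary(d2, list(c("b", "c"))))
  merged <- unique(d3$pgc[d3$accession %in% c("a", "b", "c", "e")])
  expect_equal(merged, min(pgc_ab, pgc_c))
  d4 <- update_dictionary(d3, list("zzz"))
  expect_false(d4$pgc[d4$accession == "zzz"] %in% c(pgc_ab, pgc_c))
})

test_that("updating with already-contained groups changes nothing", {
  d <- update_dictionary(pgc_dictionary(), list(c("a", "b"), "c"))
  d2 <- update_dictionary(d, list(c("a", "b"), "c"))
  expect_equal(d2$pgc, d$pgc)
  expect_equal(d2$accession, d$accession)
  expect_equal(attr(d2, "next_pgc"), attr(d, "next_pgc"))
  h <- dictionary_history(d2)
  expect_equal(unlist(h[2, c("new_accessions", "new_groups", "mergers")]),
               c(new_accessions = 0L, new_groups = 0L, mergers = 0L))
})

test_that("a local group spanning existing groups warns and merges", {
  d <- update_dictionary(pgc_dictionary(), list(c("a", "b"), c("c", "d")))
  expect_warning(d2 <- update_dictionary(d, list(c("b", "c"))),
                 "span multiple")
  expect_identical(dict_groups(d2), list(c("a", "b", "c", "d")))
})

test_that("global groups match the brute-force oracle on random instances", {
  set.seed(101)
  for (rep in 1:40) {
    sets <- random_sets(max_accessions = 80, max_sets = 25)
    chunks <- chunk_sets(sets, sample(1:4, 1))
    d <- pgc_dictionary()
    for (ch in chunks) {
      d <- suppressWarnings(update_dictionary(d, ch))
      # disjointness after every update
      expect_false(anyDuplicated(d$accession) > 0)
    }
    expect_identical(dict_groups(d), canon_groups(oracle_components(sets)))
  }
})

test_that("group composition is invariant to file order", {
  sim <- generate_runs(simulation_config(n_runs = 6, n_true_groups = 30,
                                         seed = 11))
  ref <- dict_groups(suppressWarnings(build_dictionary(sim$runs, "all")))
  set.seed(12)
  for (i in 1:10) {
    perm <- sample(sim$runs)
    expect_identical(
      dict_groups(suppressWarnings(build_dictionary(perm, "all"))), ref
    )
  }
})

test_that("split builds equal full builds", {
  sim <- generate_runs(simulation_config(n_runs = 6, n_true_groups = 30,
                                         seed = 13))
  full <- suppressWarnings(build_dictionary(sim$runs, "all"))
  for (cut in c(1, 3, 5)) {
    d <- suppressWarnings(build_dictionary(sim$runs[1:cut], "all"))
    for (s in sim$runs[-(1:cut)]) {
      d <- suppressWarnings(update_dictionary(d, create_local_groups(s, "all")))
    }
    expect_identical(dict_groups(d), dict_groups(full))
  }
})

test_that("each global group is the union of its connected local groups", {
  sim <- generate_runs(simulation_config(n_runs = 4, n_true_groups = 25,
                                         seed = 21))
  all_locals <- unlist(lapply(sim$runs, function(s) {
    lg <- create_local_groups(s, "all")
    unname(split(lg$accession, lg$group_id))
  }), recursive = FALSE)
  d <- suppressWarnings(build_dictionary(sim$runs, "all"))
  for (g in dict_groups(d)) {
    inside <- all_locals[vapply(all_locals, function(s) all(s %in% g),
                                logical(1))]
    expect_true(is_connected(inside))
    expect_setequal(unique(unlist(inside)), g)
  }
})

test_that("is_connected implements the overlap-graph definition", {
  expect_true(is_connected(list(c("a", "b"), c("b", "c"))))
  expect_false(is_connected(list(c("a", "b"), c("c", "d"))))
  # {x, y} sets act as a connector between a and b
  expect_true(is_connected(list(c("a", "x"), c("x", "y"), c("y", "b"))))
  expect_false(is_connected(list()))
  expect_true(is_connected(list("a")))
  expect_error(is_connected(list("a", character())), "non-empty")
})

test_that("dictionaries round-trip through the two-column file format", {
  d <- suppressWarnings(update_dictionary(
    pgc_dictionary(), list(c("a", "b"), c("b", "c"), "d")
  ))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dictionary(d, path)
  lines <- readLines(path)
  expect_equal(lines[2], "PGC\tAccession")
  d2 <- read_dictionary(path)
  expect_equal(d2$pgc, d$pgc)
  expect_equal(d2$accession, d$accession)
  expect_equal(attr(d2, "next_pgc"), attr(d, "next_pgc"))

  # empty dictionary round trip
  write_dictionary(pgc_dictionary(), path)
  expect_equal(nrow(read_dictionary(path)), 0L)

  # an accession under two PGCs violates disjointness
  writeLines(c("PGC\tAccession", "1\ta", "2\ta"), path)
  expect_error(read_dictionary(path), "more than one PGC")
  writeLines(c("not\ta\theader"), path)
  expect_error(read_dictionary(path), "header")
})
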