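test_that("dice matches its closed form and boundary cases", {
  expect_equal(dice(c("a", "b"), c("a", "b")), 1)
  expect_equal(dice(c("a", "b"), c("c", "d")), 0)
  expect_equal(dice(c("a", "b", "c"), c("a", "b")), 0.8)
  expect_equal(dice(c("a", "a", "b"), c("b", "a")), 1)  # sets, not lists
  expect_error(dice(character(), character()), "undefined")
})

test_that("dice agrees with an indicator-vector oracle on random sets", {
  set.seed(5)
  universe <- sprintf("P%03d", 1:40)
  for (i in 1:200) {
    a <- sample(universe, sample(0:15, 1))
    b <- sample(universe, sample(1:15, 1))
    ia <- universe %in% a
    ib <- universe %in% b
    oracle <- 2 * sum(ia & ib) / (sum(ia) + sum(ib))
    expect_equal(dice(a, b), oracle)
    expect_equal(dice(b, a), oracle)  # symmetry
    expect_gte(oracle, 0)
    expect_lte(oracle, 1)
  }
})

make_coded <- function(runs_groups, dict = NULL) {
  # runs_groups: named list run_id -> list of accession vectors
  summaries <- lapply(names(runs_groups), function(id) {
    groups <- runs_groups[[id]]
    pp_summary(N = rep(seq_along(groups), lengths(groups)),
               Accession = unlist(groups), run_id = id)
  })
  dict <- dict %||% suppressWarnings(build_dictionary(summaries, "all"))
  list(dict = dict, coded = code_all(dict, summaries))
}

test_that("presence matrix marks each code in the runs that contain it", {
  shared <- list(c("a1", "a2"), "b1")
  x <- make_coded(list(
    r1 = c(shared, list("p1")),
    r2 = c(shared, list("p2")),
    r3 = c(shared, list("p3"))
  ))
  pm <- presence_matrix(x$coded)
  expect_s3_class(pm, "pgc_presence")
  expect_equal(dim(pm), c(5L, 4L))
  counts <- rowSums(as.matrix(pm[-1]))
  expect_equal(sort(counts), c(1, 1, 1, 3, 3))
  expect_equal(consistent_pgcs(pm, 1), sort(pm$pgc[counts == 3]))
  expect_length(consistent_pgcs(pm, 0.5), 2L)

  single <- presence_matrix(x$coded[1])
  expect_true(all(single$r1))
  expect_equal(nrow(presence_matrix(list())), 0L)
})

test_that("the common-code curve is non-increasing with known endpoints", {
  shared <- list(c("a1", "a2"))
  x <- make_coded(list(r1 = c(shared, list("p1")),
                       r2 = c(shared, list("p2")),
                       r3 = shared))
  curve <- common_pgc_curve(x$coded)
  expect_equal(curve$n_common, c(2L, 1L, 1L))
  expect_true(all(diff(curve$n_common) <= 0))

  # identical runs give a constant curve
  same <- make_coded(list(r1 = shared, r2 = shared, r3 = shared))
  expect_equal(unique(common_pgc_curve(same$coded)$n_common), 1L)

  # pairwise-disjoint runs drop to zero at the second run
  disj <- make_coded(list(r1 = list("x1"), r2 = list("x2"), r3 = list("x3")))
  expect_equal(common_pgc_curve(disj$coded)$n_common, c(1L, 0L, 0L))
})

test_that("curves order all >= top_gene >= top_identifier on shared files", {
  sim <- generate_runs(simulation_config(n_runs = 6, n_true_groups = 40,
                                         seed = 31))
  runs <- order_by_group_count(sim$runs)
  curves <- lapply(c("all", "top_gene", "top_identifier"), function(m) {
    d <- suppressWarnings(build_dictionary(runs, m))
    coded <- lapply(runs, function(s) {
      code_local_groups(d, create_local_groups(s, m))
    })
    common_pgc_curve(coded)$n_common
  })
  expect_true(all(curves[[1]] >= curves[[2]]))
  expect_true(all(curves[[2]] >= curves[[3]]))
  expect_true(all(diff(curves[[1]]) <= 0))
})

test_that("the change log counts new identities, new groups, and mergers", {
  s1 <- pp_summary(N = c(1, 1, 2), Accession = c("a", "b", "c"),
                   run_id = "f1")
  s2 <- pp_summary(N = c(1, 1, 1), Accession = c("a", "b", "c"),
                   run_id = "f2")
  s3 <- pp_summary(N = 1, Accession = "zz", run_id = "f3")
  log <- suppressWarnings(change_log(list(s1, s2, s3, s2), "all"))
  expect_equal(log$new_accessions, c(3L, 0L, 1L, 0L))
  expect_equal(log$new_groups, c(2L, 0L, 1L, 0L))
  expect_equal(log$mergers, c(0L, 1L, 0L, 0L))
  # conservation: groups created minus merges equals final group count
  d <- suppressWarnings(build_dictionary(list(s1, s2, s3, s2), "all"))
  expect_equal(sum(log$new_groups) - sum(log$mergers),
               length(unique(d$pgc)))
})

test_that("conservation of group counts holds on random instances", {
  set.seed(41)
  for (i in 1:10) {
    sets <- random_sets(max_accessions = 50, max_sets = 20)
    chunks <- chunk_sets(sets, 4)
    d <- pgc_dictionary()
    for (ch in chunks) d <- suppressWarnings(update_dictionary(d, ch))
    h <- dictionary_history(d)
    expect_equal(sum(h$new_groups) - sum(h$mergers),
                 length(unique(d$pgc)))
  }
})

test_that("group sizes are binned as 1, 2, 3-5 and >5", {
  sizes <- list(a = "x1", b = "x2", c = c("y1", "y2"),
                d = sprintf("z%d", 1:4), e = sprintf("w%d", 1:7))
  hist <- group_size_histogram(sizes)
  expect_equal(hist$n, c(2L, 1L, 1L, 1L))
  expect_equal(sum(hist$n), length(sizes))
  expect_equal(group_size_histogram(list())$n, rep(0L, 4))
  expect_equal(group_size_histogram(list("a", "b"))$n, c(2L, 0L, 0L, 0L))
  d <- update_dictionary(pgc_dictionary(), sizes)
  expect_equal(group_size_histogram(d)$n, c(2L, 1L, 1L, 1L))
})

test_that("dice against the dictionary is 1 for full groups, 0 for absent", {
  x <- make_coded(list(
    r1 = list(c("a", "b", "c", "d")),   # full group
    r2 = list(c("a", "b")),             # half the group
    r3 = list("q")                      # group absent
  ))
  dd <- dice_vs_dictionary(x$coded, x$dict)
  big <- x$dict$pgc[x$dict$accession == "a"][1]
  get <- function(run, pgc) dd$dice[dd$run_id == run & dd$pgc == pgc]
  expect_equal(get("r1", big), 1)
  expect_equal(get("r2", big), 2 * 2 / (2 + 4))
  expect_equal(get("r3", big), 0)
  expect_true(all(dd$dice >= 0 & dd$dice <= 1))
})

test_that("top-protein dice reflects rotation of the representative", {
  runs <- example_runs_top_rotation()
  dict <- suppressWarnings(build_dictionary(runs, "all"))
  coded <- code_all(dict, runs)
  dt <- dice_top_proteins(coded, dict)
  # three distinct tops across three runs: each run contributes 1 of 3
  expect_equal(unique(dt$dice), 2 * 1 / (1 + 3))

  # a unique top protein in every run gives 1 everywhere
  stable <- make_coded(list(
    r1 = list(c("t", "m1")), r2 = list(c("t", "m2")), r3 = list(c("t"))
  ))
  dts <- dice_top_proteins(stable$coded, stable$dict)
  expect_true(all(dts$dice == 1))

  # absent group scores 0
  part <- make_coded(list(r1 = list(c("t", "m1")), r2 = list("other")))
  dtp <- dice_top_proteins(part$coded, part$dict)
  p_t <- part$dict$pgc[part$dict$accession == "t"]
  expect_equal(dtp$dice[dtp$run_id == "r2" & dtp$pgc == p_t], 0)
})

test_that("runs are ordered by decreasing group count with name tie-breaks", {
  a <- pp_summary(N = c(1, 2), Accession = c("x", "y"), run_id = "b_two")
  b <- pp_summary(N = 1, Accession = "z", run_id = "one")
  c_ <- pp_summary(N = c(1, 2), Accession = c("u", "v"), run_id = "a_two")
  ord <- order_by_group_count(list(a, b, c_))
  expect_equal(vapply(ord, attr, "", "run_id"), c("a_two", "b_two", "one"))
})

test_that("autoplot methods return ggplot objects", {
  sim <- generate_runs(simulation_config(n_runs = 3, n_true_groups = 15,
                                         seed = 9))
  dict <- suppressWarnings(build_dictionary(sim$runs, "all"))
  coded <- code_all(dict, sim$runs)
  expect_s3_class(autoplot(common_pgc_curve(coded)), "ggplot")
  expect_s3_class(autoplot(dictionary_history(dict)), "ggplot")
  expect_s3_class(autoplot(presence_matrix(coded)), "ggplot")
  expect_s3_class(autoplot(dice_vs_dictionary(coded, dict)), "ggplot")
  expect_s3_class(autoplot(group_size_histogram(dict)), "ggplot")
})
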