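test_that("division counts equal genealogy depth on hand-built trees", {
  fx <- make_fixture("synchronous_tree")
  nu <- divisions_per_cell(fx$genealogy, fx$leaves)
  expect_true(all(nu == 2L))
  expect_identical(unname(divisions_per_cell(fx$genealogy, 1L)), 0L)
})

test_that("division counts match an independent recursive traversal", {
  st <- sim_run(sim_config(k_b = 1, max_cells = 128, seed = 17))
  gen <- genealogy(st)
  ids <- sample(gen$id, 50)
  nu <- divisions_per_cell(gen, ids)
  for (j in seq_along(ids)) {
    expect_identical(unname(nu[j]), recursive_depth(gen, ids[j]))
    expect_identical(unname(nu[j]), gen$nu[ids[j]])
  }
  # synchronous runs have uniform depth, memoryless runs do not
  expect_gt(length(unique(divisions_per_cell(gen))), 1L)
})

test_that("genealogical distances follow the MRCA path", {
  fx <- make_fixture("synchronous_tree")
  gen <- fx$genealogy
  expect_identical(genealogical_distance(gen, 4, 4), 0)
  expect_equal(genealogical_distance(gen, 4, 5), 2)
  expect_equal(genealogical_distance(gen, 4, 6), 4)
  # time units at the t = 2 snapshot: siblings are newborn
  expect_equal(genealogical_distance(gen, 4, 5, units = "time",
                                     t_now = 2), 0)
  expect_equal(genealogical_distance(gen, 4, 6, units = "time",
                                     t_now = 2), 2)
  # leaves extend to the snapshot
  expect_equal(genealogical_distance(gen, 4, 6, units = "time",
                                     t_now = 3), 4)
})

test_that("F_ST is 0 on a star genealogy and matches hand arithmetic", {
  star <- make_fixture("star_tree")
  expect_identical(fst_pair(star$genealogy, 2:4, 5:7), 0)
  # two deep clades: within-distance 2, between-distance 10 -> 0.8
  gen <- data.frame(
    id = 1:13,
    parent_id = c(0L, 1L, 1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 8L, 9L, 9L),
    t_birth = c(0, 1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 5, 5),
    t_death = c(1, 2, 2, 3, 3, 4, 4, 5, 5, NA, NA, NA, NA),
    nu = c(0L, 1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L, 5L, 5L))
  expect_equal(fst_pair(gen, c(10L, 11L), c(12L, 13L)), 0.8)
  expect_error(fst_pair(gen, c(10L, 11L), c(11L, 12L)), "disjoint")
  expect_error(fst_pair(gen, 10L, c(12L, 13L)), "at least 2")
})

test_that("F_ST and distances match brute-force enumeration", {
  set.seed(71)
  st <- sim_run(sim_config(k_b = 1, delta0 = 0.1, max_cells = 96,
                           max_time = 100, seed = 19))
  gen <- genealogy(st)
  live <- live_ids(st)
  for (units in c("divisions", "time")) {
    for (rep in 1:8) {
      ids <- sample(live, 12)
      a <- ids[1:6]
      b <- ids[7:12]
      expect_equal(fst_pair(gen, a, b, units = units, t_now = st$t),
                   brute_fst(gen, a, b, units = units, t_now = st$t))
    }
    for (rep in 1:25) {
      ij <- sample(live, 2)
      expect_equal(
        genealogical_distance(gen, ij[1], ij[2], units, t_now = st$t),
        brute_gen_distance(gen, ij[1], ij[2], units, t_now = st$t))
    }
  }
})

test_that("F_ST is invariant to uniform branch-length scaling", {
  st <- sim_run(sim_config(k_b = 1, max_cells = 64, seed = 23))
  gen <- genealogy(st)
  live <- live_ids(st)
  set.seed(72)
  a <- sample(live, 5)
  b <- setdiff(live, a)[1:5]
  f1 <- fst_pair(gen, a, b, units = "time", t_now = st$t)
  gen2 <- gen
  gen2$t_birth <- gen2$t_birth * 7
  gen2$t_death <- gen2$t_death * 7
  f2 <- fst_pair(gen2, a, b, units = "time", t_now = st$t * 7)
  expect_equal(f1, f2)
})

test_that("founder lineage fractions sum to one and are exact when
           division is synchronous", {
  st <- sim_run(sim_config(max_cells = 512, seed = 29))
  lf <- lineage_fractions(genealogy(st), 4)
  expect_identical(sum(lf), 1)
  expect_equal(unname(lf), rep(0.25, 4))
  expect_identical(unname(lineage_fractions(genealogy(st), 1)), 1)
  # memoryless division: fractions drift away from 1/4
  st2 <- sim_run(sim_config(k_b = 1, max_cells = 512, seed = 29))
  lf2 <- lineage_fractions(genealogy(st2), 4)
  expect_identical(sum(lf2), 1)
  expect_gt(max(abs(lf2 - 0.25)), 0)
  # populations that died out or never reached the founder count error
  st3 <- sim_run(sim_config(beta0 = 0, delta0 = 1, seed = 1))
  expect_error(lineage_fractions(genealogy(st3), 4), "no live cells")
  st4 <- sim_run(sim_config(max_cells = 2, seed = 1))
  expect_error(lineage_fractions(genealogy(st4), 4), "never reached")
})

test_that("subregions are the focal cell plus its nearest neighbors", {
  st <- sim_run(sim_config(max_cells = 256, seed = 31))
  set.seed(73)
  live <- live_ids(st)
  cart <- to_cartesian(st$coord[live, ], st$spec)
  rownames(cart) <- live
  for (rep in 1:10) {
    sub <- sample_subregion(st, 20)
    expect_length(sub$ids, 20L)
    expect_true(sub$central_id %in% sub$ids)
    d <- sqrt(colSums((t(cart) - sub$center)^2))
    inside <- max(d[as.character(sub$ids)])
    outside <- min(d[!live %in% sub$ids])
    expect_lte(inside, outside)
  }
  expect_setequal(sample_subregion(st, st$n_alive)$ids, live)
  expect_length(sample_subregion(st, 1)$ids, 1L)
  expect_error(sample_subregion(st, st$n_alive + 1L), "fewer")
})

test_that("region pairs in the distance profile are disjoint and
           separated", {
  st <- sim_run(sim_config(k_b = 1, e2_model = "linear",
                           max_cells = 1024, seed = 37))
  set.seed(74)
  pr <- fst_distance_profile(st, n_pairs = 25, size = 20)
  expect_equal(nrow(pr), 25L)
  expect_true(all(pr$distance > 0))
  expect_true(all(pr$fst >= 0 & pr$fst <= 1))
  expect_true(is.finite(attr(pr, "pearson")))
})

test_that("the growth curve is stepwise and closed-form when
           division is deterministic", {
  st <- sim_run(sim_config(max_cells = 16, seed = 41))
  g <- growth_curve(st)
  expect_equal(max(g$n[g$t <= 3.5]), 8)  # N = 2^t
  st0 <- sim_run(sim_config(max_cells = 1, seed = 1))
  g0 <- growth_curve(st0)
  expect_equal(nrow(g0), 1L)
  expect_equal(unlist(g0), c(t = 0, n = 1))
})
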