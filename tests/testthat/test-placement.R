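key_of <- function(st, coord) tumorlat:::coord_key(st, coord)

test_that("fill placement chooses uniformly among empty neighbor sites", {
  cfg <- sim_config(dimension = 2, neighborhood = "moore")
  spec <- lattice_spec("regular", 2)
  nbs <- neighbors(c(0L, 0L), spec)
  # exactly one empty neighbor: deterministic fill
  st <- state_from_coords(rbind(c(0L, 0L), nbs[-4, ]), cfg)
  focal <- st$occ[key_of(st, c(0L, 0L))]
  res <- place_fill_empty(st, focal)
  expect_equal(res$coord, nbs[4, ])
  expect_length(res$moved_ids, 0L)
  # three empty neighbors: uniform choice
  set.seed(61)
  counts <- integer(3)
  open <- nbs[c(2, 5, 7), ]
  for (i in 1:3000) {
    st <- state_from_coords(rbind(c(0L, 0L), nbs[-c(2, 5, 7), ]), cfg)
    focal <- st$occ[key_of(st, c(0L, 0L))]
    res <- place_fill_empty(st, focal)
    hit <- which(apply(open, 1L, function(v) all(v == res$coord)))
    counts[hit] <- counts[hit] + 1L
  }
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
  # no empty neighbor is a contract violation
  st <- state_from_coords(rbind(c(0L, 0L), nbs), cfg)
  focal <- st$occ[key_of(st, c(0L, 0L))]
  expect_error(place_fill_empty(st, focal), "empty neighbor")
})

test_that("push method 1 shifts the whole ray one step outward", {
  cfg <- sim_config(dimension = 2, push = 1)
  set.seed(62)
  for (i in 1:40) {
    occ <- random_occupancy(lattice_spec("regular", 2), fill = 0.6)
    st <- state_from_coords(occ, cfg)
    focal <- st$occ[key_of(st, c(0L, 0L))]
    ids_before <- live_ids(st)
    coords_before <- st$coord[seq_len(st$n), , drop = FALSE]
    res <- place_push1(st, focal)
    v <- res$coord  # focal is at the origin, so this is the direction
    if (length(res$moved_ids)) {
      shift <- st$coord[res$moved_ids, , drop = FALSE] -
        coords_before[res$moved_ids, , drop = FALSE]
      # every displaced cell moved exactly one step along the ray, and
      # sat on consecutive multiples of the direction before the push
      expect_true(all(shift == rep(v, each = length(res$moved_ids))))
      expect_equal(coords_before[res$moved_ids, , drop = FALSE],
                   outer(seq_along(res$moved_ids), v),
                   ignore_attr = TRUE)
    }
    # no cell created or destroyed by the placement itself
    expect_setequal(live_ids(st), ids_before)
    # the returned site is empty, ready for the daughter
    expect_equal(st$occ[key_of(st, res$coord)], 0L)
  }
})

test_that("push method 2 weights directions by 1/l_min", {
  # von Neumann corridor: l_min = (1, 3, 5, 5) for (+x, -x, +y, -y)
  cfg <- sim_config(dimension = 2, neighborhood = "von_neumann", push = 2)
  cells <- rbind(c(0L, 0L),
                 c(1L, 0L),
                 cbind(-(1:3), 0L),
                 cbind(0L, 1:5),
                 cbind(0L, -(1:5)))
  lm_true <- c(3L, 5L, 5L, 1L)  # offsets are lex order: -x, -y, +y, +x
  st0 <- state_from_coords(cells, cfg)
  focal <- st0$occ[key_of(st0, c(0L, 0L))]
  expect_equal(vapply(1:4, function(d) l_min(st0, c(0L, 0L), d),
                      integer(1)), lm_true)
  set.seed(63)
  counts <- integer(4)
  for (i in 1:4000) {
    st <- state_from_coords(cells, cfg)
    focal <- st$occ[key_of(st, c(0L, 0L))]
    res <- place_push2(st, focal)
    d <- which(apply(st$spec$offsets, 1L, function(v) {
      all(v == res$coord)
    }))
    counts[d] <- counts[d] + 1L
    # the ray in the chosen direction moved en bloc
    expect_length(res$moved_ids, lm_true[d])
  }
  p_true <- (1 / lm_true) / sum(1 / lm_true)
  expect_gt(stats::chisq.test(counts, p = p_true)$p.value, 0.001)
})

test_that("push methods 3 and 4 agree along a unique-minimum corridor", {
  fx4 <- make_fixture("corridor")
  st4 <- fx4$state
  res4 <- place_push4(st4, fx4$focal)
  fx3 <- make_fixture("corridor")
  st3 <- fx3$state
  res3 <- place_push3(st3, fx3$focal)
  expect_equal(res3$coord, res4$coord)
  occ_set <- function(st) {
    apply(st$coord[live_ids(st), ], 1, paste, collapse = ",")
  }
  expect_setequal(occ_set(st3), occ_set(st4))
  # push 4 displaces exactly min(l_min) cells
  expect_length(res4$moved_ids, 2L)
})

test_that("under the step model push methods 2-4 are identical paths", {
  snap <- function(p) {
    st <- sim_run(sim_config(e2_model = "step", push = p,
                             max_cells = 512, seed = 77))
    population_snapshot(st)
  }
  s2 <- snap(2)
  expect_identical(s2, snap(3))
  expect_identical(s2, snap(4))
})

test_that("step/linear placements never displace pre-existing cells", {
  for (model in c("step", "linear")) {
    st <- init_population(sim_config(e2_model = model, push = 2,
                                     max_cells = 128, seed = 5))
    schedule_cell(st, 1L)
    moved <- 0L
    while (st$n_alive < 128) {
      ev <- sim_step(st)
    }
    # reaching here without a phi = 0 contract violation means every
    # division found an empty neighbor; verify no pushes by re-running
    # placements: all cells' birth order equals creation order is implied;
    # directly assert via a division on a fresh surrounded cell instead
    expect_equal(st$n_alive, 128L)
  }
  # direct check: a fully surrounded cell under step model cannot divide
  cfg <- sim_config(dimension = 2, e2_model = "step")
  block <- as.matrix(expand.grid(-1:1, -1:1))
  st <- state_from_coords(block, cfg)
  center <- st$occ[key_of(st, c(0L, 0L))]
  expect_error(execute_division(st, center), "phi = 0")
})
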