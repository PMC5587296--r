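#' Genealogy-based statistics
#'
#' The analysis layer works on the genealogy table ([genealogy()]): a
#' strictly binary division tree in which every entity (one cell
#' generation) is a node, `nu` is the node's depth (= number of division
#' events in its ancestry), internal nodes carry their division time as
#' `t_death`, and live cells are leaves with `NA` `t_death`.
#'
#' @name tumor_stats
NULL

check_genealogy <- function(gen) {
  stopifnot(is.data.frame(gen),
            all(c("id", "parent_id", "t_birth", "t_death", "nu")
                %in% names(gen)))
  if (!identical(as.integer(gen$id), seq_len(nrow(gen)))) {
    stop("genealogy ids must be 1..n in creation order", call. = FALSE)
  }
  if (any(gen$parent_id >= gen$id)) {
    stop("every parent must precede its children", call. = FALSE)
  }
  invisible(gen)
}

#' Number of division events in each cell's ancestry (nu)
#'
#' Computes, for each requested cell, the depth of its node in the
#' division tree: the number of ancestral division events from the root
#' down to (and including) the division that created the cell. The root
#' cell, before any division, has `nu = 0`.
#'
#' @param gen A genealogy data frame (see [genealogy()]).
#' @param ids Cell ids to evaluate; default all live cells (those with
#'   `NA` `t_death`).
#' @return A named integer vector of `nu` values.
#' @export
divisions_per_cell <- function(gen, ids = NULL) {
  check_genealogy(gen)
  if (is.null(ids)) ids <- gen$id[is.na(gen$t_death)]
  parent <- gen$parent_id
  out <- vapply(ids, function(i) {
    d <- 0L
    while (parent[i] != 0L) {
      d <- d + 1L
      i <- parent[i]
    }
    d
  }, integer(1))
  names(out) <- ids
  out
}

#' Founder-lineage fractions of the live population
#'
#' Identifies the founders -- the cells alive at the first instant the
#' population size reached `n_founders` -- by replaying the genealogy's
#' birth and death events in execution order, assigns every live cell to
#' the founder whose lineage contains it, and returns each founder's
#' descendant fraction. Under synchronous division with no death these
#' fractions are exactly `1/n_founders` each.
#'
#' @param gen A genealogy data frame.
#' @param n_founders How many early cells define the lineages (default 4).
#' @param live Ids of the cells to classify; default all live cells.
#' @return A named numeric vector (names = founder ids) summing to 1.
#' @export
lineage_fractions <- function(gen, n_founders = 4, live = NULL) {
  check_genealogy(gen)
  n <- nrow(gen)
  parent <- gen$parent_id
  if (is.null(live)) live <- gen$id[is.na(gen$t_death)]
  if (!length(live)) stop("no live cells to classify", call. = FALSE)
  founders <- find_founders(gen, n_founders)
  is_founder <- logical(n)
  is_founder[founders] <- TRUE
  assign_one <- function(i) {
    while (!is_founder[i]) {
      i <- parent[i]
      if (i == 0L) stop("cell has no founder ancestor (genealogy ",
                        "inconsistent with the founder set)", call. = FALSE)
    }
    i
  }
  who <- vapply(live, assign_one, integer(1))
  counts <- table(factor(who, levels = founders))
  out <- as.numeric(counts) / length(live)
  names(out) <- founders
  out
}

# Cells alive at the first instant the population size reached n_founders,
# found by replaying divisions and deaths in execution order (division
# events are ordered by the id of their first-created daughter, which the
# engine assigns in processing order, so within-instant ties replay
# exactly).
find_founders <- function(gen, n_founders) {
  n <- nrow(gen)
  parent <- gen$parent_id
  if (n_founders < 1) stop("`n_founders` must be >= 1", call. = FALSE)
  roots <- which(parent == 0L)
  alive <- logical(n)
  alive[roots] <- TRUE
  n_alive <- length(roots)
  if (n_alive >= n_founders) return(which(alive))
  ch <- which(parent > 0L)
  kids <- split(ch, parent[ch])
  div_parents <- as.integer(names(kids))
  first_kid <- vapply(kids, min, integer(1))
  has_child <- logical(n)
  has_child[div_parents] <- TRUE
  died <- which(!is.na(gen$t_death) & !has_child)
  ev_time <- c(gen$t_death[div_parents], gen$t_death[died])
  ev_key <- c(first_kid, rep(Inf, length(died)))
  ev_what <- c(div_parents, -died)  # positive: division; negative: death
  ord <- order(ev_time, ev_key)
  for (e in ev_what[ord]) {
    if (e > 0L) {
      alive[e] <- FALSE
      alive[kids[[as.character(e)]]] <- TRUE
      n_alive <- n_alive + 1L
    } else {
      alive[-e] <- FALSE
      n_alive <- n_alive - 1L
    }
    if (n_alive >= n_founders) return(which(alive))
  }
  stop("population never reached ", n_founders, " cells", call. = FALSE)
}

#' Genealogical distance between two cells
#'
#' Sum of branch lengths on the path through the most recent common
#' ancestor. In `"divisions"` units this is `nu_a + nu_b - 2 nu_mrca`;
#' in `"time"` units each branch runs from the MRCA's division time to the
#' cell's evaluation time (`t_now` for live cells, the death time
#' otherwise), so two live cells sampled at the same snapshot are both
#' extended to "now".
#'
#' @param gen A genealogy data frame.
#' @param a,b Cell ids.
#' @param units `"divisions"` or `"time"`.
#' @param t_now Snapshot time used for live cells in `"time"` units;
#'   defaults to the latest time recorded in the genealogy.
#' @return A nonnegative number; 0 for `a == b`.
#' @export
genealogical_distance <- function(gen, a, b,
                                  units = c("divisions", "time"),
                                  t_now = NULL) {
  units <- match.arg(units)
  check_genealogy(gen)
  idx <- gen_index(gen, t_now)
  pair_distance(idx, a, b, units)
}

# Precomputed lookups shared by the pairwise-distance loops.
gen_index <- function(gen, t_now = NULL) {
  if (is.null(t_now)) t_now <- max(gen$t_birth, gen$t_death, na.rm = TRUE)
  t_end <- ifelse(is.na(gen$t_death), t_now, gen$t_death)
  list(parent = gen$parent_id, nu = gen$nu, t_div = gen$t_death,
       t_end = t_end)
}

mrca_id <- function(idx, a, b) {
  nu <- idx$nu
  parent <- idx$parent
  while (nu[a] > nu[b]) a <- parent[a]
  while (nu[b] > nu[a]) b <- parent[b]
  while (a != b) {
    a <- parent[a]
    b <- parent[b]
    if (a == 0L || b == 0L) {
      stop("cells do not share a common ancestor", call. = FALSE)
    }
  }
  a
}

pair_distance <- function(idx, a, b, units) {
  if (a == b) return(0)
  m <- mrca_id(idx, a, b)
  if (units == "divisions") {
    idx$nu[a] + idx$nu[b] - 2 * idx$nu[m]
  } else {
    (idx$t_end[a] - idx$t_div[m]) + (idx$t_end[b] - idx$t_div[m])
  }
}

#' Branch-length F_ST between two cell regions
#'
#' Differentiation between two disjoint sets of cells computed from
#' genealogical branch lengths -- the infinite-marker expectation of F_ST,
#' in the Hudson/Slatkin form `1 - pi_w / pi_b`, where `pi_w` is the
#' unweighted mean of the two within-region mean pairwise distances and
#' `pi_b` the mean between-region pairwise distance. The result is clamped
#' to `[0, 1]`; a star genealogy (all pairs equidistant) gives 0, and
#' `pi_b = 0` is defined as 0.
#'
#' @param gen A genealogy data frame.
#' @param ids_a,ids_b Disjoint vectors of cell ids, each of length >= 2.
#' @inheritParams genealogical_distance
#' @return F_ST in `[0, 1]`.
#' @export
fst_pair <- function(gen, ids_a, ids_b, units = c("divisions", "time"),
                     t_now = NULL) {
  units <- match.arg(units)
  check_genealogy(gen)
  if (length(intersect(ids_a, ids_b))) {
    stop("regions must be disjoint", call. = FALSE)
  }
  if (length(ids_a) < 2L || length(ids_b) < 2L) {
    stop("each region needs at least 2 cells", call. = FALSE)
  }
  idx <- gen_index(gen, t_now)
  mean_within <- function(ids) {
    tot <- 0
    np <- 0L
    for (i in seq_len(length(ids) - 1L)) {
      for (j in (i + 1L):length(ids)) {
        tot <- tot + pair_distance(idx, ids[i], ids[j], units)
        np <- np + 1L
      }
    }
    tot / np
  }
  tot_b <- 0
  for (i in ids_a) for (j in ids_b) {
    tot_b <- tot_b + pair_distance(idx, i, j, units)
  }
  pi_b <- tot_b / (length(ids_a) * length(ids_b))
  if (pi_b == 0) return(0)
  pi_w <- (mean_within(ids_a) + mean_within(ids_b)) / 2
  min(max(1 - pi_w / pi_b, 0), 1)
}

#' Sample a compact spatial subregion of live cells
#'
#' Emulates a multiregional biopsy: a focal cell is chosen uniformly at
#' random among live cells and the subregion consists of the focal cell
#' plus its `size - 1` nearest live cells by Cartesian distance (distance
#' ties are broken uniformly at random).
#'
#' @param state A `tumor_state`.
#' @param size Number of cells in the subregion (default 20).
#' @return A list with `ids` (member cell ids), `central_id`, and
#'   `center` (the focal cell's Cartesian coordinates).
#' @export
sample_subregion <- function(state, size = 20) {
  ids <- live_ids(state)
  cart <- to_cartesian(state$coord[ids, , drop = FALSE], state$spec)
  subregion_impl(ids, cart, size)
}

subregion_impl <- function(ids, cart, size) {
  if (length(ids) < size) {
    stop("population has fewer than `size` live cells", call. = FALSE)
  }
  f <- sample.int(length(ids), 1L)
  d2 <- rowSums((cart - rep(cart[f, ], each = nrow(cart)))^2)
  ord <- order(d2, stats::runif(length(d2)))
  list(ids = ids[ord[seq_len(size)]],
       central_id = ids[f],
       center = cart[f, ])
}

#' F_ST versus physical distance between random subregion pairs
#'
#' Repeatedly samples two disjoint compact subregions
#' ([sample_subregion()]), computes their branch-length F_ST and the
#' Euclidean distance between their central cells, and reports one record
#' per pair. The Pearson correlation between distance and F_ST across
#' records -- the isolation-by-distance signal -- is attached as attribute
#' `"pearson"`.
#'
#' @param state A `tumor_state` with at least `2 * size` live cells.
#' @param n_pairs Number of region pairs to sample.
#' @param size Cells per region (default 20).
#' @inheritParams genealogical_distance
#' @return A data frame with columns `pair`, `distance`, `fst` and
#'   attribute `"pearson"`.
#' @export
fst_distance_profile <- function(state, n_pairs = 50, size = 20,
                                 units = c("divisions", "time"),
                                 t_now = NULL) {
  units <- match.arg(units)
  ids <- live_ids(state)
  cart <- to_cartesian(state$coord[ids, , drop = FALSE], state$spec)
  if (is.null(t_now)) t_now <- state$t
  fst_profile_impl(genealogy(state), ids, cart, n_pairs, size, units,
                   t_now)
}

fst_profile_impl <- function(gen, ids, cart, n_pairs, size, units,
                             t_now) {
  if (length(ids) < 2L * size) {
    stop("need at least 2 * size live cells", call. = FALSE)
  }
  dist_v <- numeric(n_pairs)
  fst_v <- numeric(n_pairs)
  for (p in seq_len(n_pairs)) {
    ra <- subregion_impl(ids, cart, size)
    repeat {
      rb <- subregion_impl(ids, cart, size)
      if (!length(intersect(ra$ids, rb$ids))) break
    }
    dist_v[p] <- sqrt(sum((ra$center - rb$center)^2))
    fst_v[p] <- fst_pair(gen, ra$ids, rb$ids, units, t_now)
  }
  out <- data.frame(pair = seq_len(n_pairs), distance = dist_v,
                    fst = fst_v)
  r <- suppressWarnings(stats::cor(dist_v, fst_v))
  attr(out, "pearson") <- r
  out
}
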