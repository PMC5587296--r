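#' @title Tumor population state
#'
#' @description A `tumor_state` is a mutable, environment-backed container
#' holding the occupancy grid, per-cell records, pending event clocks, and
#' the append-only genealogy of every cell entity ever created. A cell
#' "entity" spans one generation: when a cell divides, its entity is
#' retired (its record becomes an internal node of the genealogy) and two
#' daughter entities are created, the resident daughter keeping the
#' parent's lattice site. This makes the genealogy a strictly binary tree
#' whose edge counts equal division counts, so a cell's `nu` (number of
#' division events in its ancestry) is its depth in the tree.
#'
#' Occupancy is held in a dense integer grid covering a cube (square)
#' centered on the origin; the grid transparently doubles in extent when
#' the tumor approaches its edge, so the lattice is effectively unbounded.
#'
#' @name tumor_state
NULL

CELL_CSC <- 1L
CELL_TAC <- 2L
CELL_TDC <- 3L

cell_type_labels <- c("CSC", "TAC", "TDC")

# Byte-compiled `state$field[i] <- v` fetches the field with an elevated
# reference count and therefore copies the whole vector on every indexed
# write -- ruinous for the occupancy grid. Evaluating pre-quoted
# assignments with the AST interpreter inside the state environment
# updates the vectors in place; scalar arguments are staged as
# dot-prefixed bindings first. All mutation of long state vectors must go
# through these expressions.
.ex <- list(
  add = quote({
    parent[.id] <- .parent
    t_birth[.id] <- t
    nu[.id] <- .nu
    type[.id] <- .type
    omega[.id] <- .omega
    mb[.id] <- .mb
    md[.id] <- .md
    mr[.id] <- .mr
    ndrv_b[.id] <- .nb
    ndrv_d[.id] <- .nd
    ndrv_r[.id] <- .nr
    alive[.id] <- TRUE
    coord[.id, ] <- .coord
    keyv[.id] <- .key
    occ[.key] <- .id
  }),
  retire = quote({
    alive[.id] <- FALSE
    t_death[.id] <- t
    next_b[.id] <- Inf
    next_d[.id] <- Inf
    next_m[.id] <- Inf
  }),
  free_site = quote(occ[.k] <- .v),
  growth = quote({
    growth_t[.gi] <- t
    growth_n[.gi] <- n_alive
  }),
  set_b = quote(next_b[.id] <- .v),
  set_d = quote(next_d[.id] <- .v),
  set_m = quote(next_m[.id] <- .v),
  ray = quote({
    occ[.newkeys] <- .ids
    keyv[.ids] <- .newkeys
    coord[.ids, ] <- .newcoords
    occ[.freekey] <- 0L
  }),
  hop = quote({
    occ[.k] <- .cur
    coord[.cur, ] <- .site
    keyv[.cur] <- .k
  }),
  move = quote({
    occ[.ok] <- 0L
    occ[.tk] <- .id
    coord[.id, ] <- .tc
    keyv[.id] <- .tk
  }),
  swap = quote({
    coord[.id, ] <- .tc
    coord[.other, ] <- .oc
    keyv[.id] <- .tk
    keyv[.other] <- .ok
    occ[.tk] <- .id
    occ[.ok] <- .other
  }))

# ---- grid helpers ---------------------------------------------------------

# 1-based key of coordinate rows in the dense occupancy grid.
coord_key <- function(state, coords) {
  if (is.null(dim(coords))) coords <- matrix(as.integer(coords), nrow = 1L)
  as.vector((coords + state$H) %*% state$strides) + 1
}

init_grid <- function(state, H) {
  d <- state$spec$dimension
  state$H <- as.integer(H)
  side <- 2L * state$H
  state$strides <- side^(seq_len(d) - 1)
  state$occ <- integer(side^d)
  state$off_keys <- as.vector(state$spec$offsets %*% state$strides)
  live <- which(state$alive[seq_len(state$n)])
  if (length(live)) {
    keys <- coord_key(state, state$coord[live, , drop = FALSE])
    state$keyv[live] <- keys
    state$occ[keys] <- live
  }
  if (!is.null(state$res_coord)) {
    state$occ[coord_key(state, state$res_coord)] <- -1L
  }
  invisible(state)
}

# Track the largest coordinate magnitude ever used; double the grid before
# any coordinate gets within 2 sites of the edge (ray walks peek at most
# one site beyond the occupied hull).
note_coord <- function(state, coord) {
  m <- max(abs(coord))
  if (m > state$maxabs) state$maxabs <- m
  if (state$maxabs >= state$H - 2L) {
    H <- state$H
    while (state$maxabs >= H - 2L) H <- 2L * H
    init_grid(state, H)
  }
  invisible(state)
}

lmin_all <- function(state, key) {
  nd <- nrow(state$spec$offsets)
  out <- integer(nd)
  for (j in seq_len(nd)) out[j] <- lmin_key(state, key, j)
  out
}

# ---- entity bookkeeping ---------------------------------------------------

ensure_capacity <- function(state, n_needed) {
  if (n_needed <= state$cap) return(invisible(state))
  cap <- state$cap
  while (cap < n_needed) cap <- 2L * cap
  pad <- cap - state$cap
  state$parent <- c(state$parent, integer(pad))
  state$t_birth <- c(state$t_birth, numeric(pad))
  state$t_death <- c(state$t_death, rep(NA_real_, pad))
  state$nu <- c(state$nu, integer(pad))
  state$type <- c(state$type, integer(pad))
  state$omega <- c(state$omega, integer(pad))
  state$mb <- c(state$mb, numeric(pad))
  state$md <- c(state$md, numeric(pad))
  state$mr <- c(state$mr, numeric(pad))
  state$ndrv_b <- c(state$ndrv_b, integer(pad))
  state$ndrv_d <- c(state$ndrv_d, integer(pad))
  state$ndrv_r <- c(state$ndrv_r, integer(pad))
  state$alive <- c(state$alive, logical(pad))
  state$coord <- rbind(state$coord,
                       matrix(0L, pad, state$spec$dimension))
  state$keyv <- c(state$keyv, numeric(pad))
  state$next_b <- c(state$next_b, rep(Inf, pad))
  state$next_d <- c(state$next_d, rep(Inf, pad))
  state$next_m <- c(state$next_m, rep(Inf, pad))
  state$cap <- cap
  invisible(state)
}

add_entity <- function(state, parent, coord, type, omega,
                       mb, md, mr, nb, nd, nr) {
  id <- state$n + 1L
  ensure_capacity(state, id)
  state$n <- id
  coord <- as.integer(coord)
  note_coord(state, coord)
  state$.id <- id
  state$.parent <- parent
  state$.nu <- if (parent == 0L) 0L else state$nu[parent] + 1L
  state$.type <- type
  state$.omega <- as.integer(omega)
  state$.mb <- mb; state$.md <- md; state$.mr <- mr
  state$.nb <- nb; state$.nd <- nd; state$.nr <- nr
  state$.coord <- coord
  state$.key <- coord_key(state, coord)
  eval(.ex$add, state)
  state$n_alive <- state$n_alive + 1L
  id
}

record_growth <- function(state) {
  i <- state$growth_len + 1L
  if (i > length(state$growth_t)) {
    length(state$growth_t) <- 2L * length(state$growth_t)
    length(state$growth_n) <- length(state$growth_t)
  }
  state$.gi <- i
  eval(.ex$growth, state)
  state$growth_len <- i
  invisible(state)
}

# ---- construction ---------------------------------------------------------

new_tumor_state <- function(config) {
  # parent = baseenv(): the in-place update expressions in `.ex` need the
  # base assignment/arithmetic functions visible from the state env
  st <- new.env(parent = baseenv())
  st$cfg <- config
  st$spec <- lattice_spec(config$lattice, config$dimension,
                          if (config$lattice == "hex") "moore"
                          else config$neighborhood)
  cap <- 256L
  st$n <- 0L
  st$cap <- cap
  st$parent <- integer(cap)
  st$t_birth <- numeric(cap)
  st$t_death <- rep(NA_real_, cap)
  st$nu <- integer(cap)
  st$type <- integer(cap)
  st$omega <- integer(cap)
  st$mb <- numeric(cap); st$md <- numeric(cap); st$mr <- numeric(cap)
  st$ndrv_b <- integer(cap); st$ndrv_d <- integer(cap)
  st$ndrv_r <- integer(cap)
  st$alive <- logical(cap)
  st$coord <- matrix(0L, cap, st$spec$dimension)
  st$keyv <- numeric(cap)
  st$next_b <- rep(Inf, cap)
  st$next_d <- rep(Inf, cap)
  st$next_m <- rep(Inf, cap)
  st$t <- 0
  st$n_alive <- 0L
  st$n_births <- 0L
  st$n_deaths <- 0L
  st$n_migrations <- 0L
  st$n_env <- 0L
  st$maxabs <- 0L
  st$res_coord <- NULL
  st$e1 <- 1
  st$env_idx <- 1L
  st$growth_t <- numeric(1024L)
  st$growth_n <- numeric(1024L)
  st$growth_len <- 0L
  st$stop_reason <- NA_character_
  init_grid(st, if (st$spec$dimension == 2L) 256L else 64L)
  class(st) <- "tumor_state"
  st
}

#' Initialize a population with a single stem cell
#'
#' Places one cancer stem cell (with a full division budget) at the lattice
#' origin at time 0 and seeds the genealogy. The origin satisfies the FCC
#' parity constraint, so this works for every lattice family.
#'
#' @param config A [sim_config()].
#' @return A `tumor_state` with one live CSC.
#' @export
init_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  st <- new_tumor_state(config)
  add_entity(st, parent = 0L, coord = rep(0L, st$spec$dimension),
             type = CELL_CSC, omega = config$omega_max,
             mb = 1, md = 1, mr = 1, nb = 0L, nd = 0L, nr = 0L)
  record_growth(st)
  st
}

#' @export
print.tumor_state <- function(x, ...) {
  cat(sprintf(
    "<tumor_state> %d live cells (%d entities), t = %.4g%s\n",
    x$n_alive, x$n, x$t,
    if (is.na(x$stop_reason)) "" else paste0(", stopped: ", x$stop_reason)))
  invisible(x)
}

#' Identifiers of live cells
#'
#' @param state A `tumor_state`.
#' @return Integer vector of live entity ids.
#' @export
live_ids <- function(state) {
  which(state$alive[seq_len(state$n)])
}

# ---- events ---------------------------------------------------------------

#' Execute a cell division
#'
#' The dividing cell's entity is retired into the genealogy and two
#' daughter entities are created: the resident daughter keeps the parent's
#' lattice site, the displaced daughter is placed by the configured push
#' method (possibly shifting pre-existing cells; see [place_daughter()]).
#' Type assignment: a CSC divides symmetrically (two CSCs) with probability
#' `p_s`, otherwise the resident daughter remains a CSC and the displaced
#' daughter is a TAC with a full division budget `omega_max`; a TAC
#' division decrements the budget of both daughters, which become TDCs at
#' zero. Each daughter independently receives new driver mutations and
#' inherits the parent's accumulated effects. Event clocks for the
#' daughters are *not* scheduled here (the engine does that).
#'
#' @param state A `tumor_state`.
#' @param id A live, non-TDC cell id.
#' @return Invisibly, a list with daughter ids `d1` (resident) and `d2`
#'   (displaced), the grid keys whose occupancy flipped (`changed_keys`),
#'   and ids of pre-existing cells that were pushed (`moved_ids`).
#' @export
execute_division <- function(state, id) {
  cfg <- state$cfg
  if (id < 1L || id > state$n || !state$alive[id]) {
    stop("cell ", id, " is not alive", call. = FALSE)
  }
  ty <- state$type[id]
  if (ty == CELL_TDC) {
    stop("a TDC cannot divide (its birth rate is 0)", call. = FALSE)
  }
  if (cfg$e2_model != "constant" &&
      all(state$occ[state$keyv[id] + state$off_keys] != 0L)) {
    stop("division scheduled with phi = 0 under the ", cfg$e2_model,
         "-function model (its rate should have been 0)", call. = FALSE)
  }
  pl <- place_daughter(state, id, cfg$push)
  if (ty == CELL_CSC) {
    if (stats::runif(1L) < cfg$p_s) {
      ty1 <- CELL_CSC; ty2 <- CELL_CSC
    } else {
      # asymmetric division: the stem cell stays at its site
      ty1 <- CELL_CSC; ty2 <- CELL_TAC
    }
    o1 <- cfg$omega_max; o2 <- cfg$omega_max
  } else {
    o1 <- o2 <- state$omega[id] - 1L
    ty1 <- ty2 <- if (o1 <= 0L) CELL_TDC else CELL_TAC
  }
  ocoord <- state$coord[id, ]
  state$.id <- id
  eval(.ex$retire, state)
  state$n_alive <- state$n_alive - 1L
  mk_daughter <- function(coord, ty, om) {
    mut <- draw_new_mutations(cfg)
    add_entity(state, id, coord, ty, om,
               mb = state$mb[id] * driver_effect_product(mut$beta),
               md = state$md[id] * driver_effect_product(mut$delta),
               mr = state$mr[id] * driver_effect_product(mut$rho),
               nb = state$ndrv_b[id] + length(mut$beta),
               nd = state$ndrv_d[id] + length(mut$delta),
               nr = state$ndrv_r[id] + length(mut$rho))
  }
  d1 <- mk_daughter(ocoord, ty1, o1)
  d2 <- mk_daughter(pl$coord, ty2, o2)
  state$n_births <- state$n_births + 1L
  invisible(list(d1 = d1, d2 = d2,
                 changed_keys = pl$changed_keys,
                 moved_ids = pl$moved_ids))
}

#' Execute a cell death
#'
#' The cell is removed from the lattice (its site becomes empty) and its
#' death time is recorded in the genealogy.
#'
#' @param state A `tumor_state`.
#' @param id A live cell id.
#' @return Invisibly, a list with the freed grid key (`changed_keys`).
#' @export
execute_death <- function(state, id) {
  if (id < 1L || id > state$n || !state$alive[id]) {
    stop("cell ", id, " is not alive", call. = FALSE)
  }
  key <- state$keyv[id]
  state$.id <- id
  eval(.ex$retire, state)
  state$.k <- key
  state$.v <- 0L
  eval(.ex$free_site, state)
  state$n_alive <- state$n_alive - 1L
  state$n_deaths <- state$n_deaths + 1L
  invisible(list(changed_keys = key, moved_ids = integer(0)))
}

#' Execute a cell migration (single-step move or swap)
#'
#' A target site is chosen among the cell's neighbors: uniformly over all
#' directions by default, or uniformly over empty neighbor sites when
#' `migration_prefer_empty` is set and any exist. If the target is empty
#' the cell moves there; if it is occupied the two cells swap coordinates.
#' The population size never changes.
#'
#' @param state A `tumor_state`.
#' @param id A live cell id.
#' @return Invisibly, a list with the grid keys whose occupancy flipped
#'   (`changed_keys`, empty for a swap) and the ids whose coordinates
#'   changed (`moved_ids`).
#' @export
execute_migration <- function(state, id) {
  if (id < 1L || id > state$n || !state$alive[id]) {
    stop("cell ", id, " is not alive", call. = FALSE)
  }
  off <- state$spec$offsets
  okey <- state$keyv[id]
  if (state$cfg$migration_prefer_empty) {
    emp <- which(state$occ[okey + state$off_keys] == 0L)
    j <- if (length(emp)) emp[sample.int(length(emp), 1L)]
         else sample.int(nrow(off), 1L)
  } else {
    j <- sample.int(nrow(off), 1L)
  }
  target <- state$coord[id, ] + off[j, ]
  note_coord(state, target)
  okey <- state$keyv[id]  # may have been re-keyed by grid growth
  tkey <- coord_key(state, target)
  other <- state$occ[tkey]
  state$n_migrations <- state$n_migrations + 1L
  if (other == 0L) {
    state$.ok <- okey
    state$.tk <- tkey
    state$.id <- id
    state$.tc <- as.integer(target)
    eval(.ex$move, state)
    invisible(list(changed_keys = c(okey, tkey), moved_ids = id))
  } else {
    state$.ok <- okey
    state$.tk <- tkey
    state$.id <- id
    state$.other <- other
    state$.tc <- as.integer(target)
    state$.oc <- state$coord[id, ]
    eval(.ex$swap, state)
    # a swap leaves the occupancy pattern unchanged
    invisible(list(changed_keys = numeric(0), moved_ids = c(id, other)))
  }
}

# ---- views ----------------------------------------------------------------

#' Genealogy table of all cell entities
#'
#' One row per entity ever created. An entity with recorded children is an
#' internal node (its `t_death` is its division time); an entity with a
#' `t_death` and no children died; entities with `NA` `t_death` are alive.
#'
#' @param state A `tumor_state`.
#' @return A data frame with columns `id`, `parent_id`, `t_birth`,
#'   `t_death`, `nu`.
#' @export
genealogy <- function(state) {
  n <- state$n
  data.frame(id = seq_len(n),
             parent_id = state$parent[seq_len(n)],
             t_birth = state$t_birth[seq_len(n)],
             t_death = state$t_death[seq_len(n)],
             nu = state$nu[seq_len(n)])
}

#' Growth curve of a run
#'
#' One row per executed event (plus the initial state); the population size
#' is piecewise constant between events.
#'
#' @param state A `tumor_state`.
#' @return A data frame with columns `t` and `n`.
#' @export
growth_curve <- function(state) {
  i <- seq_len(state$growth_len)
  data.frame(t = state$growth_t[i], n = state$growth_n[i])
}

#' Snapshot table of the live population
#'
#' @param state A `tumor_state`.
#' @return A data frame, one row per live cell (ordered by id), with the
#'   lattice coordinates, Cartesian embedding (`cx`, `cy`, and `cz` in
#'   3D), cell
#'   type, remaining division budget `omega`, times, genealogy depth `nu`,
#'   the currently composed rates `beta`, `delta`, `rho`, and driver
#'   mutation counts.
#' @export
population_snapshot <- function(state) {
  ids <- live_ids(state)
  cfg <- state$cfg
  coords <- state$coord[ids, , drop = FALSE]
  cart <- to_cartesian(coords, state$spec)
  phi <- vapply(ids, function(i) {
    mean(state$occ[state$keyv[i] + state$off_keys] == 0L)
  }, numeric(1))
  c1 <- as.numeric(state$type[ids] != CELL_TDC)
  beta <- cfg$beta0 * c1 * state$mb[ids] * state$e1 *
    e2_coefficient(cfg$e2_model, phi)
  delta <- cfg$delta0 * state$md[ids]
  rho <- cfg$rho0 * state$mr[ids]
  out <- data.frame(id = ids, parent_id = state$parent[ids])
  ax <- c("x", "y", "z")[seq_len(state$spec$dimension)]
  for (j in seq_along(ax)) out[[ax[j]]] <- coords[, j]
  for (j in seq_along(ax)) out[[paste0("c", ax[j])]] <- cart[, j]
  out$type <- cell_type_labels[state$type[ids]]
  out$omega <- state$omega[ids]
  out$t_birth <- state$t_birth[ids]
  out$t_last_division <- state$t_birth[ids]
  out$nu <- state$nu[ids]
  out$beta <- beta
  out$delta <- delta
  out$rho <- rho
  out$n_drivers_beta <- state$ndrv_b[ids]
  out$n_drivers_delta <- state$ndrv_d[ids]
  out$n_drivers_rho <- state$ndrv_r[ids]
  out
}
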