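#' Event scheduling and the simulation loop
#'
#' The engine keeps, for every live cell, at most one pending absolute
#' firing time per event class (division, death, migration), plus a global
#' queue of environmental-change times. Each step pops the globally
#' minimal firing time (ties -- which arise systematically under
#' synchronous division, `k_b = Inf` -- are resolved by a uniform random
#' choice among the tied events, so a synchronous cohort is processed in
#' shuffled order), advances the clock, executes the event, and
#' re-schedules exactly the cells whose composed rates may have changed:
#' under the constant-rate model only the cells directly involved; under
#' the step/linear models additionally every cell whose empty-neighbor
#' fraction `phi` was altered by the event (their division clocks are
#' redrawn from the gamma tail conditioned on the time already spent in
#' the cell cycle). Death and migration clocks are exponential by default
#' and are never invalidated by neighborhood changes (memorylessness makes
#' reuse exact).
#'
#' @name engine
NULL

compute_birth_rate <- function(state, id) {
  cfg <- state$cfg
  if (state$type[id] == CELL_TDC) return(0)
  r <- cfg$beta0 * state$mb[id] * state$e1
  if (r <= 0) return(0)
  if (cfg$e2_model != "constant") {
    phi <- mean(state$occ[state$keyv[id] + state$off_keys] == 0L)
    if (cfg$e2_model == "step") {
      if (phi <= 0) return(0)
    } else {
      r <- r * phi
    }
  }
  r
}

schedule_birth <- function(state, id) {
  r <- compute_birth_rate(state, id)
  state$.id <- id
  if (r <= 0) {
    state$.v <- Inf
  } else {
    tau <- state$t - state$t_birth[id]
    state$.v <- state$t +
      sample_residual_waiting_time(state$cfg$k_b, r, tau,
                                   eps = state$cfg$eps_overdue)
  }
  eval(.ex$set_b, state)
  invisible(state)
}

#' Draw and register the pending event times of a cell
#'
#' For each event class with a positive composed rate a waiting time is
#' drawn and registered as `clock + w`: division via the cell-cycle
#' conditioned gamma tail (the elapsed time `tau` is the cell's age, i.e.
#' the time since the division that created it), death and migration from
#' their unconditioned gamma distributions (each entity starts a fresh
#' cycle at its creation). Classes with rate 0 get no event. In the
#' coupled death mode no independent death clock runs; the division clock
#' decides between division and death when it fires.
#'
#' @param state A `tumor_state`.
#' @param id A live cell id.
#' @return The state, invisibly.
#' @export
schedule_cell <- function(state, id) {
  cfg <- state$cfg
  schedule_birth(state, id)
  if (cfg$death_mode == "independent") {
    dr <- cfg$delta0 * state$md[id]
    if (dr > 0) {
      state$.id <- id
      state$.v <- state$t + sample_waiting_time(cfg$k_d, dr)
      eval(.ex$set_d, state)
    }
  }
  mr <- cfg$rho0 * state$mr[id]
  if (mr > 0) {
    state$.id <- id
    state$.v <- state$t + sample_waiting_time(cfg$k_m, mr)
    eval(.ex$set_m, state)
  }
  invisible(state)
}

# Re-draw division clocks of cells whose phi (or position) changed.
# No-op under the constant-rate model, where rates ignore local density.
invalidate_after <- function(state, changed_keys, moved_ids,
                             skip_ids = integer(0)) {
  if (state$cfg$e2_model == "constant") return(invisible(state))
  affected <- moved_ids
  for (k in changed_keys) {
    occ <- state$occ[k + state$off_keys]
    affected <- c(affected, occ[occ > 0L])
  }
  affected <- unique(affected)
  affected <- affected[state$alive[affected]]
  affected <- setdiff(affected, skip_ids)
  for (i in affected) schedule_birth(state, i)
  invisible(state)
}

next_env_time <- function(state) {
  sch <- state$cfg$env_schedule
  if (is.null(sch) || state$env_idx > nrow(sch)) return(Inf)
  sch$time[state$env_idx]
}

next_event_time <- function(state) {
  min(min(state$next_b), min(state$next_d), min(state$next_m),
      next_env_time(state))
}

#' Execute the next pending event
#'
#' Pops the globally minimal firing time (uniform random choice among
#' exact ties), advances the clock, executes the event, re-schedules the
#' affected cells, and appends a growth-curve record.
#'
#' @param state A `tumor_state` with at least one pending event.
#' @return Invisibly, a list describing the executed event: `kind` (one of
#'   `"division"`, `"death"`, `"migration"`, `"environment"`), `id` (the
#'   cell involved, `NA` for environment), and `t`.
#' @export
sim_step <- function(state) {
  cfg <- state$cfg
  tb <- min(state$next_b)
  td <- min(state$next_d)
  tm <- min(state$next_m)
  te <- next_env_time(state)
  tmin <- min(tb, td, tm, te)
  if (!is.finite(tmin)) {
    stop("no pending events (queue empty with live cells)", call. = FALSE)
  }
  if (te <= tmin) {
    state$t <- te
    state$e1 <- cfg$env_schedule$multiplier[state$env_idx]
    state$env_idx <- state$env_idx + 1L
    state$n_env <- state$n_env + 1L
    # the environment changed: every waiting time is re-evaluated
    for (i in live_ids(state)) {
      state$.id <- i
      state$.v <- Inf
      eval(.ex$set_d, state)
      eval(.ex$set_m, state)
      schedule_cell(state, i)
    }
    record_growth(state)
    return(invisible(list(kind = "environment", id = NA_integer_,
                          t = state$t)))
  }
  wb <- which(state$next_b == tmin)
  wd <- which(state$next_d == tmin)
  wm <- which(state$next_m == tmin)
  cand <- c(wb, wd, wm)
  kinds <- rep(c("division", "death", "migration"),
               c(length(wb), length(wd), length(wm)))
  pick <- sample.int(length(cand), 1L)
  id <- cand[pick]
  kind <- kinds[pick]
  state$t <- tmin
  if (kind == "division") {
    state$.id <- id
    state$.v <- Inf
    eval(.ex$set_b, state)
    if (cfg$death_mode == "coupled" &&
        coupled_division_death_outcome(cfg$alpha) == "death") {
      kind <- "death"
      res <- execute_death(state, id)
    } else {
      kind <- "division"
      res <- execute_division(state, id)
      schedule_cell(state, res$d1)
      schedule_cell(state, res$d2)
    }
  } else if (kind == "death") {
    res <- execute_death(state, id)
  } else {
    state$.id <- id
    state$.v <- Inf
    eval(.ex$set_m, state)
    res <- execute_migration(state, id)
    # the consumed migration clock starts a fresh cycle
    mrate <- cfg$rho0 * state$mr[id]
    if (mrate > 0) {
      state$.id <- id
      state$.v <- state$t + sample_waiting_time(cfg$k_m, mrate)
      eval(.ex$set_m, state)
    }
  }
  skip <- if (kind == "division") c(res$d1, res$d2) else integer(0)
  invalidate_after(state, res$changed_keys, res$moved_ids, skip)
  record_growth(state)
  invisible(list(kind = kind, id = id, t = state$t))
}

#' Run a simulation
#'
#' Seeds the random stream, initializes a single stem cell at the origin,
#' and executes events until a stopping rule fires: the population reaches
#' `max_cells`, the next event would exceed `max_time`, the population
#' goes extinct, or no event is pending (a stalled tumor, e.g. one fully
#' encased in terminally differentiated cells with no death or migration).
#'
#' @param config A [sim_config()].
#' @return The final `tumor_state`; `state$stop_reason` records which rule
#'   fired (`"max_cells"`, `"max_time"`, `"extinct"`, or `"stalled"`).
#'   Use [population_snapshot()], [genealogy()], and [growth_curve()] to
#'   extract results.
#' @examples
#' st <- sim_run(sim_config(max_cells = 64, seed = 1))
#' st$t  # 6: synchronous doubling reaches 2^6 cells at time 6
#' @export
sim_run <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  state <- init_population(config)
  schedule_cell(state, 1L)
  repeat {
    if (state$n_alive >= config$max_cells) {
      state$stop_reason <- "max_cells"
      break
    }
    if (state$n_alive == 0L) {
      state$stop_reason <- "extinct"
      break
    }
    tn <- next_event_time(state)
    if (!is.finite(tn)) {
      state$stop_reason <- "stalled"
      break
    }
    if (tn > config$max_time) {
      state$stop_reason <- "max_time"
      break
    }
    sim_step(state)
  }
  state
}
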