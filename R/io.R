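#' Build a synthetic population state from explicit coordinates
#'
#' Constructs a `tumor_state` whose occupancy is given directly, for
#' constructing small deterministic scenarios (corridors, rings, blocks)
#' when testing placement mechanics and neighborhood statistics. All cells
#' are created at time 0 with no ancestry (each is its own root), so the
#' genealogy of such a state is only meaningful for occupancy-level
#' operations.
#'
#' @param coords Integer matrix of occupied coordinates (one per row).
#' @param config A [sim_config()] describing lattice and model settings.
#' @param types Cell types, `"CSC"`, `"TAC"`, or `"TDC"` (recycled).
#' @param omega Remaining division budgets (recycled).
#' @return A `tumor_state` with one live cell per row of `coords`.
#' @export
state_from_coords <- function(coords, config = sim_config(dimension = 2),
                              types = "CSC", omega = config$omega_max) {
  stopifnot(inherits(config, "sim_config"))
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  st <- new_tumor_state(config)
  types <- rep_len(match(types, cell_type_labels), nrow(coords))
  omega <- rep_len(as.integer(omega), nrow(coords))
  for (i in seq_len(nrow(coords))) {
    add_entity(st, parent = 0L, coord = coords[i, ],
               type = types[i], omega = omega[i],
               mb = 1, md = 1, mr = 1, nb = 0L, nd = 0L, nr = 0L)
  }
  record_growth(st)
  st
}

#' Deterministic fixtures for placement and genealogy tests
#'
#' * `"corridor"` -- a filled rectangle on a 2D regular lattice (von
#'   Neumann neighborhood) in which the focal cell at the origin has a
#'   unique smallest-`l_min` direction (+x, two cells deep); along this
#'   corridor push methods 3 and 4 produce identical occupancy. Returns
#'   `list(state, focal)`.
#' * `"ring"` -- a hexagonal disk of radius 2 whose boundary ring is
#'   terminally differentiated (TDC) and whose 7 interior cells are stem
#'   cells; every interior cell has `phi = 0`, the encapsulation barrier
#'   that stalls growth under the step/linear models. Returns
#'   `list(state, interior, ring)`.
#' * `"synchronous_tree"` -- the genealogy of two synchronous divisions:
#'   4 live leaves, all with `nu = 2`; sibling pairs are at division
#'   distance 2, cross pairs at 4.
#' * `"star_tree"` -- one root dividing into 8 equidistant leaves; all
#'   pairwise distances are equal, so F_ST between any two subsets is 0.
#'
#' @param name One of `"corridor"`, `"ring"`, `"synchronous_tree"`,
#'   `"star_tree"`.
#' @return A list with a `tumor_state` or a genealogy data frame (see
#'   above).
#' @export
make_fixture <- function(name = c("corridor", "ring", "synchronous_tree",
                                  "star_tree")) {
  name <- match.arg(name)
  switch(name,
    corridor = {
      cfg <- sim_config(dimension = 2, neighborhood = "von_neumann",
                        e2_model = "constant")
      coords <- as.matrix(expand.grid(x = -4:2, y = -4:4))
      st <- state_from_coords(coords, cfg)
      focal <- st$occ[coord_key(st, c(0L, 0L))]
      list(state = st, focal = focal)
    },
    ring = {
      cfg <- sim_config(lattice = "hex", dimension = 2,
                        e2_model = "step")
      ax <- as.matrix(expand.grid(x = -2:2, y = -2:2))
      hexdist <- (abs(ax[, 1]) + abs(ax[, 2]) + abs(ax[, 1] + ax[, 2])) / 2
      ax <- ax[hexdist <= 2, , drop = FALSE]
      on_ring <- ((abs(ax[, 1]) + abs(ax[, 2]) + abs(ax[, 1] + ax[, 2]))
                  / 2) == 2
      st <- state_from_coords(ax, cfg,
                              types = ifelse(on_ring, "TDC", "CSC"),
                              omega = ifelse(on_ring, 0L, 5L))
      ids <- live_ids(st)
      list(state = st, interior = ids[!on_ring], ring = ids[on_ring])
    },
    synchronous_tree = {
      gen <- data.frame(
        id = 1:7,
        parent_id = c(0L, 1L, 1L, 2L, 2L, 3L, 3L),
        t_birth = c(0, 1, 1, 2, 2, 2, 2),
        t_death = c(1, 2, 2, NA, NA, NA, NA),
        nu = c(0L, 1L, 1L, 2L, 2L, 2L, 2L))
      list(genealogy = gen, leaves = 4:7)
    },
    star_tree = {
      gen <- data.frame(
        id = 1:9,
        parent_id = c(0L, rep(1L, 8L)),
        t_birth = c(0, rep(1, 8)),
        t_death = c(1, rep(NA, 8)),
        nu = c(0L, rep(1L, 8L)))
      list(genealogy = gen, leaves = 2:9)
    })
}

#' Export the genealogy of live cells as a Newick tree
#'
#' Builds the full binary division tree, prunes it to the live cells
#' (collapsing single-child chains and summing branch lengths), and
#' returns an [ape::phylo] object, optionally writing a Newick file. Tip
#' labels are cell ids. Branch lengths are in time units (live tips extend
#' to the snapshot time) or division counts.
#'
#' @param state A `tumor_state` with at least 2 live cells.
#' @param path Optional output file for [ape::write.tree()].
#' @param units `"time"` or `"divisions"`.
#' @return The pruned `phylo` object, invisibly if `path` is given.
#' @export
export_newick <- function(state, path = NULL,
                          units = c("time", "divisions")) {
  units <- match.arg(units)
  gen <- genealogy(state)
  n <- nrow(gen)
  live <- which(state$alive[seq_len(n)])
  if (length(live) < 2L) {
    stop("Newick export needs at least 2 live cells", call. = FALSE)
  }
  has_child <- logical(n)
  has_child[gen$parent_id[gen$parent_id > 0L]] <- TRUE
  tips <- which(!has_child)
  internals <- which(has_child)
  idmap <- integer(n)
  idmap[tips] <- seq_along(tips)
  idmap[internals] <- length(tips) + seq_along(internals)
  nonroot <- which(gen$parent_id > 0L)
  t_end <- ifelse(is.na(gen$t_death), state$t, gen$t_death)
  len <- if (units == "time") {
    t_end[nonroot] - gen$t_birth[nonroot]
  } else {
    rep(1, length(nonroot))
  }
  phy <- structure(
    list(edge = cbind(idmap[gen$parent_id[nonroot]], idmap[nonroot]),
         edge.length = len,
         tip.label = as.character(tips),
         Nnode = length(internals)),
    class = "phylo")
  phy <- ape::keep.tip(phy, as.character(live))
  # the root cell's lifespan before its first division is the root edge
  phy$root.edge <- if (units == "time") {
    if (is.na(gen$t_death[1])) state$t else gen$t_death[1]
  } else {
    0
  }
  if (!is.null(path)) {
    ape::write.tree(phy, file = path)
    return(invisible(phy))
  }
  phy
}

#' Compute genealogy statistics from a run's result files
#'
#' Reads `population.tsv` and `genealogy.tsv` from a run directory (see
#' [write_outputs()]) and writes `nu.tsv` (per-cell division counts),
#' `lineage_fractions.tsv` (founder descendant fractions), and
#' `fst_profile.tsv` (branch-length F_ST versus Euclidean distance for
#' random subregion pairs, with the Pearson correlation echoed as the
#' return value).
#'
#' @param dir Directory holding `population.tsv` and `genealogy.tsv`.
#' @param out Output directory (default `dir`).
#' @param n_pairs,size,units Passed to the F_ST profile (see
#'   [fst_distance_profile()]).
#' @param n_founders Number of founder lineages (default 4).
#' @return The Pearson correlation between F_ST and distance, invisibly.
#' @export
run_stats_files <- function(dir, out = dir, n_pairs = 50, size = 20,
                            units = c("divisions", "time"),
                            n_founders = 4) {
  units <- match.arg(units)
  pop <- utils::read.delim(file.path(dir, "population.tsv"))
  gen <- utils::read.delim(file.path(dir, "genealogy.tsv"))
  gen$t_death <- as.numeric(gen$t_death)
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  nu <- divisions_per_cell(gen, pop$id)
  tsv(data.frame(id = pop$id, nu = unname(nu)), "nu.tsv")
  lf <- lineage_fractions(gen, n_founders, live = pop$id)
  tsv(data.frame(founder_id = as.integer(names(lf)),
                 fraction = unname(lf)), "lineage_fractions.tsv")
  cart <- as.matrix(pop[, intersect(c("cx", "cy", "cz"), names(pop))])
  t_now <- max(gen$t_birth, gen$t_death, na.rm = TRUE)
  pr <- fst_profile_impl(gen, pop$id, cart, n_pairs, size, units, t_now)
  names(pr)[1] <- "pair_id"
  tsv(pr, "fst_profile.tsv")
  invisible(attr(pr, "pearson"))
}

#' Write the standard result files of a run
#'
#' Writes `population.tsv` (live-cell snapshot, ordered by id),
#' `genealogy.tsv` (all entities), `growth.tsv` (the growth curve),
#' `metadata.yaml` (resolved configuration, seed, event counts,
#' termination reason), and optionally `genealogy.nwk` (live-cell
#' genealogy in Newick). Reruns with the same configuration and seed
#' produce byte-identical files.
#'
#' @param state A finished `tumor_state`.
#' @param dir Output directory (created if missing).
#' @param newick Also write the Newick genealogy (needs >= 2 live cells).
#' @return `dir`, invisibly.
#' @export
write_outputs <- function(state, dir, newick = FALSE) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", dir, call. = FALSE)
  }
  tsv <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tsv(population_snapshot(state), "population.tsv")
  tsv(genealogy(state), "genealogy.tsv")
  tsv(growth_curve(state), "growth.tsv")
  cfg <- unclass(state$cfg)
  for (k in c("k_b", "k_d", "k_m")) {
    if (is.infinite(cfg[[k]])) cfg[[k]] <- "inf"
  }
  if (!is.null(cfg$env_schedule)) {
    cfg$env_schedule <- as.list(cfg$env_schedule)
  }
  meta <- list(
    package = "tumorlat",
    version = as.character(utils::packageVersion("tumorlat")),
    config = cfg,
    seed = state$cfg$seed,
    final_time = state$t,
    n_alive = state$n_alive,
    n_entities = state$n,
    events = list(divisions = state$n_births,
                  deaths = state$n_deaths,
                  migrations = state$n_migrations,
                  environment_changes = state$n_env),
    stop_reason = state$stop_reason)
  yaml::write_yaml(meta, file.path(dir, "metadata.yaml"))
  if (newick) export_newick(state, file.path(dir, "genealogy.nwk"))
  invisible(dir)
}
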