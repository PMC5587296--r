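#' Simulation configuration
#'
#' Collects and validates every run parameter. The defaults describe the
#' baseline neutral simulation: a single cancer stem cell on a regular 3D
#' lattice with the Moore neighborhood, synchronous division (`k_b = Inf`,
#' `beta0 = 1`), the constant-rate density model with push method 2, no
#' death or migration, no driver mutations, and termination at `2^14`
#' cells.
#'
#' @param lattice Lattice family, `"regular"` or `"hex"`.
#' @param dimension 2 or 3.
#' @param neighborhood `"moore"` or `"von_neumann"` (regular lattices only).
#' @param k_b,k_d,k_m Gamma shape parameters for the division, death, and
#'   migration waiting times; positive numbers or `"inf"`. Death and
#'   migration default to 1 (exponential, memoryless).
#' @param beta0,delta0,rho0 Base potential rates of division, death, and
#'   migration (per unit time). Zero disables the event class.
#' @param e2_model Local-density birth model: `"constant"`, `"step"`, or
#'   `"linear"` (see [e2_coefficient()]).
#' @param push Daughter placement method, 1--4 (see [place_daughter()]).
#' @param death_mode `"independent"` (its own clock at rate `delta0`) or
#'   `"coupled"` (division and death share one clock; the outcome is death
#'   with probability `alpha`).
#' @param alpha Death probability used when `death_mode = "coupled"`.
#' @param p_s Probability that a stem-cell division is symmetric (two CSC
#'   daughters); with probability `1 - p_s` it is asymmetric (CSC + TAC).
#' @param omega_max Division budget of a newly created TAC.
#' @param mu_beta,mu_delta,mu_rho Per-division driver mutation rates for
#'   the three mutation classes, each in `[0, 1]`.
#' @param sbar_beta,sigma_beta Mean and SD of the Gaussian effect of a
#'   birth-rate driver mutation (`sbar_delta`/`sigma_delta`,
#'   `sbar_rho`/`sigma_rho` analogous).
#' @param sbar_delta,sigma_delta,sbar_rho,sigma_rho See above.
#' @param env_schedule Optional data frame (or list) with columns `time`
#'   and `multiplier`: a piecewise-constant schedule for the global
#'   environment factor applied to the birth rate; all clocks are redrawn
#'   when it changes.
#' @param max_cells Stop once the population reaches this size.
#' @param max_time Stop before the clock exceeds this time.
#' @param n_founders Number of early cells used for founder-lineage
#'   labeling (see [lineage_fractions()]).
#' @param migration_prefer_empty If `TRUE`, a migrating cell picks its
#'   target uniformly among empty neighbor sites when any exist; default
#'   `FALSE` picks uniformly among all neighbors (swapping when occupied).
#' @param seed Integer seed for the single random stream driving the run.
#' @param eps_overdue Minimal positive residual for an overdue
#'   deterministic (`k = Inf`) division after a rate increase.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(lattice = "regular",
                       dimension = 3,
                       neighborhood = "moore",
                       k_b = Inf, k_d = 1, k_m = 1,
                       beta0 = 1, delta0 = 0, rho0 = 0,
                       e2_model = "constant",
                       push = 2,
                       death_mode = "independent",
                       alpha = 0,
                       p_s = 1,
                       omega_max = 5,
                       mu_beta = 0, mu_delta = 0, mu_rho = 0,
                       sbar_beta = 0, sigma_beta = 0,
                       sbar_delta = 0, sigma_delta = 0,
                       sbar_rho = 0, sigma_rho = 0,
                       env_schedule = NULL,
                       max_cells = 16384,
                       max_time = Inf,
                       n_founders = 4,
                       migration_prefer_empty = FALSE,
                       seed = 1,
                       eps_overdue = 1e-9) {
  cfg <- list(
    lattice = match.arg(lattice, c("regular", "hex")),
    dimension = as.integer(dimension),
    neighborhood = match.arg(neighborhood, c("moore", "von_neumann")),
    k_b = as_shape(k_b), k_d = as_shape(k_d), k_m = as_shape(k_m),
    beta0 = as.numeric(beta0), delta0 = as.numeric(delta0),
    rho0 = as.numeric(rho0),
    e2_model = match.arg(e2_model, c("constant", "step", "linear")),
    push = as.integer(push),
    death_mode = match.arg(death_mode, c("independent", "coupled")),
    alpha = as.numeric(alpha),
    p_s = as.numeric(p_s),
    omega_max = as.integer(omega_max),
    mu_beta = as.numeric(mu_beta), mu_delta = as.numeric(mu_delta),
    mu_rho = as.numeric(mu_rho),
    sbar_beta = as.numeric(sbar_beta), sigma_beta = as.numeric(sigma_beta),
    sbar_delta = as.numeric(sbar_delta),
    sigma_delta = as.numeric(sigma_delta),
    sbar_rho = as.numeric(sbar_rho), sigma_rho = as.numeric(sigma_rho),
    env_schedule = normalize_env_schedule(env_schedule),
    max_cells = as.integer(max_cells),
    max_time = as.numeric(max_time),
    n_founders = as.integer(n_founders),
    migration_prefer_empty = isTRUE(migration_prefer_empty),
    seed = as.integer(seed),
    eps_overdue = as.numeric(eps_overdue))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

normalize_env_schedule <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0L)) return(NULL)
  x <- as.data.frame(x)
  if (!all(c("time", "multiplier") %in% names(x))) {
    stop("`env_schedule` needs columns `time` and `multiplier`",
         call. = FALSE)
  }
  x <- x[order(x$time), c("time", "multiplier")]
  if (any(x$time < 0) || any(x$multiplier < 0)) {
    stop("`env_schedule` times and multipliers must be nonnegative",
         call. = FALSE)
  }
  x
}

validate_sim_config <- function(cfg) {
  bad <- character(0)
  chk <- function(ok, what) if (!ok) bad <<- c(bad, what)
  chk(cfg$dimension %in% c(2L, 3L), "dimension (must be 2 or 3)")
  chk(!(cfg$lattice == "hex" && cfg$neighborhood == "von_neumann"),
      "neighborhood (von_neumann is incompatible with a hexagonal lattice)")
  chk(cfg$beta0 >= 0 && cfg$delta0 >= 0 && cfg$rho0 >= 0,
      "beta0/delta0/rho0 (rates must be >= 0)")
  chk(cfg$push %in% 1:4, "push (must be 1, 2, 3, or 4)")
  for (p in c("alpha", "p_s", "mu_beta", "mu_delta", "mu_rho")) {
    chk(cfg[[p]] >= 0 && cfg[[p]] <= 1,
        sprintf("%s (probability must be in [0, 1])", p))
  }
  chk(cfg$sigma_beta >= 0 && cfg$sigma_delta >= 0 && cfg$sigma_rho >= 0,
      "sigma_beta/sigma_delta/sigma_rho (must be >= 0)")
  chk(cfg$omega_max >= 0, "omega_max (must be >= 0)")
  chk(cfg$max_cells >= 1, "max_cells (must be >= 1)")
  chk(cfg$max_time > 0, "max_time (must be > 0)")
  chk(cfg$n_founders >= 1, "n_founders (must be >= 1)")
  if (length(bad)) {
    stop("invalid configuration: ", paste(bad, collapse = "; "),
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %s %dD (%s), k_b=%s beta0=%g delta0=%g rho0=%g\n",
    x$lattice, x$dimension, x$neighborhood, format(x$k_b), x$beta0,
    x$delta0, x$rho0))
  cat(sprintf("  e2=%s push=%d p_s=%g omega_max=%d max_cells=%d seed=%d\n",
              x$e2_model, x$push, x$p_s, x$omega_max, x$max_cells, x$seed))
  invisible(x)
}

#' Read a simulation configuration from YAML
#'
#' Keys absent from the file take the [sim_config()] defaults; `k_b` etc.
#' may be the string `"inf"`. Extra keys are an error so that typos are
#' caught.
#'
#' @param path Path to a YAML file, or `NULL` to use defaults.
#' @param ... Named overrides applied after the file is read.
#' @return A `sim_config`.
#' @export
load_config <- function(path = NULL, ...) {
  vals <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  over <- list(...)
  vals[names(over)] <- over
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(sim_config, vals)
}

#' Write a simulation configuration to YAML
#'
#' The written file round-trips through [load_config()].
#'
#' @param config A `sim_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  vals <- unclass(config)
  for (k in c("k_b", "k_d", "k_m")) {
    if (is.infinite(vals[[k]])) vals[[k]] <- "inf"
  }
  if (is.null(vals$env_schedule)) {
    vals$env_schedule <- NULL
  } else {
    vals$env_schedule <- as.list(vals$env_schedule)
  }
  yaml::write_yaml(vals, path)
  invisible(path)
}
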