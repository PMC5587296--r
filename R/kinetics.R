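#' Waiting-time and rate machinery
#'
#' Cell division, death, and migration are scheduled by drawing waiting
#' times from gamma distributions parameterized by a shape `k` and a rate
#' (the reciprocal of the mean waiting time). `k = 1` gives the memoryless
#' exponential used by most earlier lattice simulators; large `k`
#' concentrates the distribution around the mean, modeling the cell cycle;
#' `k = Inf` is the deterministic (delta) limit in which every division
#' takes exactly `1/rate`.
#'
#' @name kinetics
NULL

# Accepts a positive number or the strings "inf"/"Inf" and returns a
# numeric shape parameter (possibly Inf). Shapes in (0, 1) are legal but
# unusual; a message is emitted once per call.
as_shape <- function(k) {
  if (is.character(k)) {
    k <- if (tolower(k) %in% c("inf", "infinity")) Inf else as.numeric(k)
  }
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k <= 0) {
    stop("shape parameter must be a positive number or \"inf\"",
         call. = FALSE)
  }
  if (k < 1) message("shape parameter k = ", k, " < 1: waiting-time ",
                     "density is unbounded at zero")
  k
}

#' Draw division/death/migration waiting times
#'
#' Draws from a gamma distribution with shape `k` and mean `1/rate`
#' (so variance `1/(k * rate^2)`). `k = Inf` returns exactly `1/rate`;
#' `k = 1` is exponential with rate `rate`.
#'
#' @param k Shape parameter (positive, possibly `Inf`, or the string
#'   `"inf"`).
#' @param rate Positive rate; the mean waiting time is `1/rate`.
#' @param n Number of draws.
#' @return Numeric vector of `n` positive waiting times.
#' @examples
#' sample_waiting_time(Inf, 2)     # exactly 0.5
#' mean(sample_waiting_time(8, 1, 1e4))  # ~ 1
#' @export
sample_waiting_time <- function(k, rate, n = 1L) {
  k <- as_shape(k)
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate <= 0) {
    stop("`rate` must be a positive number (a zero rate means the event ",
         "never fires and must be handled by omitting it)", call. = FALSE)
  }
  if (is.infinite(k)) return(rep.int(1 / rate, n))
  if (k == 1) return(stats::rexp(n, rate))
  stats::rgamma(n, shape = k, rate = k * rate)
}

#' Draw a residual waiting time conditioned on elapsed cell-cycle time
#'
#' For a cell whose last division was `tau` time units ago, the remaining
#' time to its next division is drawn from the gamma distribution of
#' [sample_waiting_time()] conditioned on the total exceeding `tau`
#' (renormalized tail), returned as total minus `tau`. For `k = 1` this is
#' the plain exponential (memorylessness); for `k = Inf` it is
#' `max(1/rate - tau, eps)`: a cell that is already overdue (possible after
#' a rate increase) fires essentially immediately.
#'
#' Sampling is exact via the inverse CDF on the upper tail,
#' `qgamma(u * S(tau), lower.tail = FALSE)` with `u ~ U(0,1)`.
#'
#' @inheritParams sample_waiting_time
#' @param tau Nonnegative elapsed time since the last division.
#' @param eps Minimal positive residual returned in the overdue
#'   deterministic case.
#' @return A single positive residual waiting time.
#' @export
sample_residual_waiting_time <- function(k, rate, tau, eps = 1e-9) {
  k <- as_shape(k)
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate <= 0) {
    stop("`rate` must be a positive number", call. = FALSE)
  }
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0) {
    stop("`tau` must be a nonnegative number", call. = FALSE)
  }
  if (is.infinite(k)) return(max(1 / rate - tau, eps))
  if (k == 1) return(stats::rexp(1L, rate))
  if (tau == 0) return(stats::rgamma(1L, shape = k, rate = k * rate))
  s_tail <- stats::pgamma(tau, shape = k, rate = k * rate,
                          lower.tail = FALSE)
  if (s_tail < .Machine$double.xmin) {
    stop("cell-cycle tail mass below machine tolerance at tau = ", tau,
         call. = FALSE)
  }
  total <- stats::qgamma(stats::runif(1L) * s_tail, shape = k,
                         rate = k * rate, lower.tail = FALSE)
  max(total - tau, .Machine$double.eps)
}

#' Compose a potential event rate from its five factors
#'
#' Every per-cell rate is the product `base * c1 * c2 * e1 * e2` of a
#' shared base rate, a cell-type factor (`c1`, 0 for the birth rate of a
#' terminally differentiated cell), the accumulated driver-mutation factor
#' (`c2`), the global environment multiplier (`e1`), and the local-density
#' coefficient (`e2`).
#'
#' @param base Nonnegative base rate shared by all cells.
#' @param c1,c2,e1,e2 Nonnegative multiplicative factors (defaults 1).
#' @return The composed nonnegative rate.
#' @export
compose_rate <- function(base, c1 = 1, c2 = 1, e1 = 1, e2 = 1) {
  stopifnot(base >= 0, c1 >= 0, c2 >= 0, e1 >= 0, e2 >= 0)
  base * c1 * c2 * e1 * e2
}

#' Multiplicative effect of accumulated driver mutations
#'
#' Driver mutation effects are additive on the rate scale: a cell carrying
#' mutations with relative effects `s_1, ..., s_M` multiplies its potential
#' rate by `prod(1 + s_j)`. Each factor is clamped below at 0 so that a
#' deleterious mutation with `s <= -1` zeroes the rate rather than making
#' it negative.
#'
#' @param s Numeric vector of relative effects (possibly empty).
#' @return Nonnegative product; 1 for an empty vector.
#' @examples
#' driver_effect_product(99)          # 100
#' driver_effect_product(c(0.2, 0.5)) # 1.8
#' @export
driver_effect_product <- function(s) {
  if (length(s) == 0L) return(1)
  prod(pmax(0, 1 + s))
}

#' Local-density coefficient of the birth rate
#'
#' Maps the proportion `phi` of empty neighbor sites to the `e2` birth-rate
#' factor: `constant` ignores density (always 1); `step` allows division
#' only when at least one neighbor site is empty (Heaviside in `phi`);
#' `linear` makes the rate proportional to `phi`.
#'
#' @param model `"constant"`, `"step"`, or `"linear"`.
#' @param phi Proportion of empty neighbor sites in `[0, 1]`.
#' @return A coefficient in `[0, 1]`.
#' @export
e2_coefficient <- function(model = c("constant", "step", "linear"), phi) {
  model <- match.arg(model)
  stopifnot(is.numeric(phi), phi >= 0, phi <= 1)
  switch(model,
         constant = rep.int(1, length(phi)),
         step = as.numeric(phi > 0),
         linear = phi)
}

#' Draw the driver mutations arising at one cell division
#'
#' Independently for each of the three mutation classes (birth, death,
#' migration), a new driver mutation occurs with probability `mu` per cell
#' division; its relative effect is Gaussian with the class mean and
#' standard deviation (`sigma = 0` gives the mean exactly). Mutations are
#' drawn independently for each daughter cell.
#'
#' @param config A [sim_config()] (or any list with elements `mu_beta`,
#'   `sbar_beta`, `sigma_beta` and the `delta`/`rho` analogues).
#' @return A list with numeric components `beta`, `delta`, `rho`, each of
#'   length 0 or 1 (the effect `s` of the new mutation, if any).
#' @export
draw_new_mutations <- function(config) {
  out <- list(beta = numeric(0), delta = numeric(0), rho = numeric(0))
  for (cls in c("beta", "delta", "rho")) {
    mu <- config[[paste0("mu_", cls)]]
    if (mu > 0 && stats::runif(1L) < mu) {
      sbar <- config[[paste0("sbar_", cls)]]
      sigma <- config[[paste0("sigma_", cls)]]
      out[[cls]] <- if (sigma > 0) stats::rnorm(1L, sbar, sigma) else sbar
    }
  }
  out
}

#' Outcome of a coupled division/death attempt
#'
#' In the coupled death mode, division and death share a single waiting
#' time; when it fires, the event is death with probability `alpha` and
#' division otherwise (no independent death clock runs).
#'
#' @param alpha Probability of death in `[0, 1]`.
#' @return `"death"` or `"division"`.
#' @export
coupled_division_death_outcome <- function(alpha) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1)
  if (stats::runif(1L) < alpha) "death" else "division"
}
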