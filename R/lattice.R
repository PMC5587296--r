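#' Lattice geometry specification
#'
#' Defines the coordinate system and neighborhood used by the simulator.
#' Regular (square/cubic) lattices support the Moore neighborhood (all
#' `3^d - 1` surrounding sites) and the von Neumann neighborhood (the `2d`
#' axis-adjacent sites). Hexagonal lattices have a single neighborhood
#' definition: 6 neighbors in 2D (axial coordinates) and 12 in 3D, where the
#' 3D close-packed lattice is represented as face-centered cubic (FCC) --
#' all integer triples with even coordinate sum, neighbor offsets the twelve
#' permutations of `(+-1, +-1, 0)`.
#'
#' Offsets are stored in fixed lexicographic order so that seeded runs are
#' reproducible. The lattice is unbounded: coordinates are arbitrary
#' integers (subject to the FCC parity constraint in hex-3D) and occupancy
#' is stored sparsely by the simulation state.
#'
#' @param family `"regular"` or `"hex"`.
#' @param dimension 2 or 3.
#' @param neighborhood `"moore"` or `"von_neumann"`; ignored (forced to the
#'   hexagonal neighborhood) when `family = "hex"`.
#' @return An object of class `lattice_spec` with elements `family`,
#'   `dimension`, `neighborhood`, and `offsets` (an integer matrix, one
#'   displacement vector per row).
#' @examples
#' spec <- lattice_spec("regular", 3, "moore")
#' nrow(spec$offsets)  # 26
#' @export
lattice_spec <- function(family = c("regular", "hex"),
                         dimension = 3,
                         neighborhood = c("moore", "von_neumann")) {
  family <- match.arg(family)
  if (!dimension %in% c(2, 3)) {
    stop("`dimension` must be 2 or 3", call. = FALSE)
  }
  if (family == "hex") {
    if (!missing(neighborhood) &&
        identical(match.arg(neighborhood), "von_neumann")) {
      stop("hexagonal lattices have a single neighborhood definition; ",
           "`neighborhood = \"von_neumann\"` is only valid with ",
           "`family = \"regular\"`", call. = FALSE)
    }
    neighborhood <- "hex"
  } else {
    neighborhood <- match.arg(neighborhood)
  }
  structure(
    list(family = family,
         dimension = as.integer(dimension),
         neighborhood = neighborhood,
         offsets = lattice_offsets(family, dimension, neighborhood)),
    class = "lattice_spec")
}

# Offset table in lexicographic row order.
lattice_offsets <- function(family, dimension, neighborhood) {
  if (family == "regular") {
    g <- as.matrix(expand.grid(rep(list(-1:1), dimension)))
    g <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
    if (neighborhood == "von_neumann") {
      g <- g[rowSums(abs(g)) == 1L, , drop = FALSE]
    }
  } else if (dimension == 2L) {
    # axial hex coordinates: unit distance to all six neighbors
    g <- rbind(c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
               c(0L, 1L), c(1L, -1L), c(1L, 0L))
  } else {
    # FCC: permutations of (+-1, +-1, 0); all have even coordinate sum
    g <- as.matrix(expand.grid(rep(list(-1:1), 3)))
    g <- g[rowSums(abs(g)) == 2L, , drop = FALSE]
  }
  g <- g[do.call(order, as.data.frame(g)), , drop = FALSE]
  dimnames(g) <- NULL
  storage.mode(g) <- "integer"
  g
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat(sprintf("<lattice_spec> %s %dD, %s neighborhood (%d directions)\n",
              x$family, x$dimension, x$neighborhood, nrow(x$offsets)))
  invisible(x)
}

# Contract check for a single coordinate.
assert_coord <- function(coord, spec) {
  if (length(coord) != spec$dimension || any(coord != round(coord))) {
    stop("coordinate must be an integer vector of length ",
         spec$dimension, call. = FALSE)
  }
  if (spec$family == "hex" && spec$dimension == 3L &&
      sum(coord) %% 2L != 0L) {
    stop("FCC coordinate must have even coordinate sum, got (",
         paste(coord, collapse = ", "), ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Adjacent sites of a lattice coordinate
#'
#' @param coord Integer coordinate vector (length = lattice dimension; for
#'   hex-3D it must satisfy the FCC even-sum constraint).
#' @param spec A [lattice_spec()].
#' @return Integer matrix with one neighbor coordinate per row, in the fixed
#'   (lexicographic-offset) order of `spec$offsets`.
#' @examples
#' nrow(neighbors(c(0L, 0L, 0L), lattice_spec("hex", 3)))  # 12
#' @export
neighbors <- function(coord, spec) {
  assert_coord(coord, spec)
  sweep(spec$offsets, 2L, as.integer(coord), `+`)
}

#' Proportion of empty adjacent sites (phi)
#'
#' The local-density statistic driving the step- and linear-function birth
#' models: the fraction of a cell's neighbor sites that are unoccupied.
#'
#' @param state A `tumor_state` (see [init_population()]).
#' @param coord Integer coordinate vector.
#' @return A proportion in `[0, 1]`.
#' @export
site_phi <- function(state, coord) {
  assert_coord(coord, state$spec)
  keys <- coord_key(state, neighbors(coord, state$spec))
  mean(state$occ[keys] == 0L)
}

#' Distance to the nearest empty site along one direction (l_min)
#'
#' Counts the consecutive occupied sites starting at `coord + v` and
#' stepping by the direction vector `v`, up to (not counting) the first
#' empty site. Returns 0 when the adjacent site itself is empty. The search
#' is capped at one more than the current population size; a finite tumor
#' always has an empty site along any ray, so exceeding the cap is an
#' internal error.
#'
#' @param state A `tumor_state`.
#' @param coord Integer coordinate vector (the focal, occupied site).
#' @param direction Index into `state$spec$offsets` (1-based).
#' @return Nonnegative integer.
#' @export
l_min <- function(state, coord, direction) {
  spec <- state$spec
  assert_coord(coord, spec)
  if (direction < 1L || direction > nrow(spec$offsets)) {
    stop("`direction` must index a row of spec$offsets", call. = FALSE)
  }
  lmin_key(state, coord_key(state, matrix(as.integer(coord), 1L)),
           direction)
}

# key-based l_min used by the hot path; `key` is the focal site's grid key.
lmin_key <- function(state, key, direction) {
  dk <- state$off_keys[direction]
  cap <- state$n_alive + 1L
  k <- key + dk
  n <- 0L
  while (state$occ[k] != 0L) {
    n <- n + 1L
    if (n > cap) stop("l_min search cap exceeded: occupancy has no empty ",
                      "site along the ray (internal error)", call. = FALSE)
    k <- k + dk
  }
  n
}

#' Cartesian embedding of lattice coordinates
#'
#' Maps integer lattice coordinates to real space with unit
#' nearest-neighbor distance in every lattice family: identity for regular
#' lattices, the axial-to-Cartesian basis `(x + y/2, y * sqrt(3)/2)` for
#' hex-2D, and division by `sqrt(2)` for FCC.
#'
#' @param coords Integer matrix (rows = coordinates) or a single coordinate
#'   vector.
#' @param spec A [lattice_spec()].
#' @return Numeric matrix of the same shape.
#' @export
to_cartesian <- function(coords, spec) {
  if (is.null(dim(coords))) coords <- matrix(coords, nrow = 1L)
  x <- coords * 1.0
  if (spec$family == "regular") return(x)
  if (spec$dimension == 2L) {
    cbind(x[, 1L] + x[, 2L] / 2, x[, 2L] * sqrt(3) / 2)
  } else {
    x / sqrt(2)
  }
}
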