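#' Daughter-cell placement (push methods)
#'
#' Places the non-resident daughter of a dividing cell. Four methods are
#' implemented:
#'
#' * **Method 1** -- a direction is chosen uniformly at random among all
#'   neighbor directions; the daughter takes the adjacent site in that
#'   direction and every pre-existing cell along the ray is shifted one
#'   step outward until an empty site absorbs the chain.
#' * **Method 2** -- if any adjacent site is empty, one of them is filled
#'   uniformly at random (no cell moves). Otherwise the push direction is
#'   drawn with probability proportional to `1/l_min` and the `l_min`
#'   cells along the ray are shifted outward en bloc.
#' * **Method 3** -- as method 2 when an empty neighbor exists; otherwise
#'   the daughter takes the adjacent site in the direction of smallest
#'   `l_min` (ties broken uniformly), and the displaced cell iteratively
#'   moves one step in its own smallest-`l_min` direction, recomputed at
#'   every hop, until an empty site ends the chain.
#' * **Method 4** -- as method 2/3 with an empty neighbor; otherwise the
#'   single direction of smallest `l_min` (ties uniform) is pushed en
#'   bloc, exactly `l_min` cells shifting one step.
#'
#' Under the step- and linear-function density models a division is only
#' ever scheduled when an empty neighbor exists, so methods 2--4 reduce to
#' the empty-site fill and behave identically; method 1 keeps its random
#' push semantics in every model. Displaced cells retain their identity,
#' state, and clocks (a push is passive mechanics, not a division).
#'
#' This function mutates `state` (shifted cells' coordinates and the
#' occupancy grid) and returns the site for the new daughter, which the
#' caller ([execute_division()]) then occupies.
#'
#' @param state A `tumor_state`.
#' @param id The dividing cell's id (still occupying its site).
#' @param method Push method, 1--4.
#' @return A list: `coord` (integer coordinate for the daughter, empty at
#'   return), `changed_keys` (grid keys whose empty/occupied status
#'   flipped, including the daughter's site-to-be), and `moved_ids`
#'   (pre-existing cells that were shifted).
#' @export
place_daughter <- function(state, id, method = state$cfg$push) {
  stopifnot(method %in% 1:4)
  if (method == 1L) return(place_push1(state, id))
  emp <- which(state$occ[state$keyv[id] + state$off_keys] == 0L)
  if (length(emp)) return(place_fill_empty(state, id, emp))
  switch(method - 1L,
         place_push2(state, id),
         place_push3(state, id),
         place_push4(state, id))
}

#' Fill a uniformly chosen empty neighbor site
#'
#' The placement rule shared by push methods 2--4 whenever the dividing
#' cell has at least one empty adjacent site: the daughter fills one of
#' them uniformly at random and no pre-existing cell moves.
#'
#' @param state A `tumor_state`.
#' @param id The dividing cell's id.
#' @param empty_dirs Optional precomputed indices of empty directions.
#' @return As [place_daughter()].
#' @export
place_fill_empty <- function(state, id, empty_dirs = NULL) {
  if (is.null(empty_dirs)) {
    empty_dirs <- which(state$occ[state$keyv[id] + state$off_keys] == 0L)
  }
  if (!length(empty_dirs)) {
    stop("place_fill_empty requires at least one empty neighbor site",
         call. = FALSE)
  }
  j <- empty_dirs[sample.int(length(empty_dirs), 1L)]
  coord <- state$coord[id, ] + state$spec$offsets[j, ]
  note_coord(state, coord)
  list(coord = as.integer(coord),
       changed_keys = coord_key(state, coord),
       moved_ids = integer(0))
}

# Shift the l_min(dir) cells along the ray from `id`'s site one step
# outward; afterwards the adjacent site in `dir` is empty.
shift_ray <- function(state, id, dir) {
  ocoord <- state$coord[id, ]
  off <- state$spec$offsets[dir, ]
  m <- lmin_key(state, state$keyv[id], dir)
  tail_coord <- ocoord + (m + 1L) * off
  note_coord(state, tail_coord)  # may re-key the whole grid
  okey <- state$keyv[id]
  dk <- state$off_keys[dir]
  moved <- integer(0)
  if (m > 0L) {
    keys <- okey + seq_len(m) * dk
    moved <- state$occ[keys]
    state$.ids <- moved
    state$.newkeys <- keys + dk
    state$.newcoords <- state$coord[moved, , drop = FALSE] +
      rep(off, each = m)
    state$.freekey <- okey + dk
    eval(.ex$ray, state)
  }
  list(coord = as.integer(ocoord + off),
       changed_keys = okey + (m + 1) * dk,
       moved_ids = moved)
}

#' @rdname place_daughter
#' @export
place_push1 <- function(state, id) {
  dir <- sample.int(nrow(state$spec$offsets), 1L)
  shift_ray(state, id, dir)
}

#' @rdname place_daughter
#' @export
place_push2 <- function(state, id) {
  lm <- lmin_all(state, state$keyv[id])
  if (any(lm == 0L)) return(place_fill_empty(state, id, which(lm == 0L)))
  dir <- sample.int(length(lm), 1L, prob = 1 / lm)
  shift_ray(state, id, dir)
}

#' @rdname place_daughter
#' @export
place_push4 <- function(state, id) {
  lm <- lmin_all(state, state$keyv[id])
  if (any(lm == 0L)) return(place_fill_empty(state, id, which(lm == 0L)))
  ties <- which(lm == min(lm))
  dir <- ties[sample.int(length(ties), 1L)]
  shift_ray(state, id, dir)
}

#' @rdname place_daughter
#' @export
place_push3 <- function(state, id) {
  lm <- lmin_all(state, state$keyv[id])
  if (any(lm == 0L)) return(place_fill_empty(state, id, which(lm == 0L)))
  off <- state$spec$offsets
  ties <- which(lm == min(lm))
  dir <- ties[sample.int(length(ties), 1L)]
  daughter_coord <- state$coord[id, ] + off[dir, ]
  note_coord(state, daughter_coord)
  tkey <- coord_key(state, daughter_coord)
  cur <- state$occ[tkey]
  # reserve the daughter's site so chain l_min queries see it occupied,
  # surviving any grid re-keying triggered mid-chain
  state$res_coord <- as.integer(daughter_coord)
  state$.k <- tkey
  state$.v <- -1L
  eval(.ex$free_site, state)
  moved <- integer(0)
  site <- daughter_coord
  hops <- 0L
  cap <- state$n_alive + 1L
  while (cur != 0L) {
    hops <- hops + 1L
    if (hops > cap) stop("push chain longer than the population ",
                         "(internal error)", call. = FALSE)
    lm2 <- lmin_all(state, coord_key(state, site))
    t2 <- which(lm2 == min(lm2))
    d2 <- t2[sample.int(length(t2), 1L)]
    new_site <- site + off[d2, ]
    note_coord(state, new_site)
    nk <- coord_key(state, new_site)
    nxt <- state$occ[nk]
    state$.k <- nk
    state$.cur <- cur
    state$.site <- as.integer(new_site)
    eval(.ex$hop, state)
    moved <- c(moved, cur)
    cur <- nxt
    site <- new_site
  }
  state$res_coord <- NULL
  final_key <- coord_key(state, site)
  list(coord = as.integer(daughter_coord),
       changed_keys = final_key,
       moved_ids = moved)
}
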