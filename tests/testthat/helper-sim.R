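# shared helpers: small configs, brute-force oracles, random fixtures

quick_cfg <- function(...) {
  sim_config(max_cells = 256, seed = 42, ...)
}

# brute-force l_min: walk the ray over a plain coordinate set
brute_lmin <- function(occupied, focal, offset) {
  occ_keys <- apply(occupied, 1L, paste, collapse = ",")
  n <- 0L
  p <- focal + offset
  while (paste(p, collapse = ",") %in% occ_keys) {
    n <- n + 1L
    p <- p + offset
  }
  n
}

# random occupancy in a 7^3 (or 7^2) box around the origin, origin always
# occupied
random_occupancy <- function(spec, fill = 0.5) {
  rng <- -3:3
  g <- as.matrix(expand.grid(rep(list(rng), spec$dimension)))
  if (spec$family == "hex" && spec$dimension == 3L) {
    g <- g[rowSums(g) %% 2L == 0L, , drop = FALSE]
  }
  keep <- stats::runif(nrow(g)) < fill
  keep[rowSums(abs(g)) == 0L] <- TRUE
  g[keep, , drop = FALSE]
}

# independent recursive depth computation for nu
recursive_depth <- function(gen, i) {
  p <- gen$parent_id[i]
  if (p == 0L) 0L else 1L + recursive_depth(gen, p)
}

# brute-force genealogical distance: path-to-root sets
brute_gen_distance <- function(gen, a, b, units = "divisions",
                               t_now = NULL) {
  if (is.null(t_now)) t_now <- max(gen$t_birth, gen$t_death, na.rm = TRUE)
  path <- function(i) {
    out <- i
    while (gen$parent_id[i] != 0L) {
      i <- gen$parent_id[i]
      out <- c(out, i)
    }
    out
  }
  if (a == b) return(0)
  pa <- path(a)
  pb <- path(b)
  common <- intersect(pa, pb)
  m <- common[which.max(gen$nu[common])]
  if (units == "divisions") {
    gen$nu[a] + gen$nu[b] - 2 * gen$nu[m]
  } else {
    t_end <- function(i) if (is.na(gen$t_death[i])) t_now else gen$t_death[i]
    (t_end(a) - gen$t_death[m]) + (t_end(b) - gen$t_death[m])
  }
}

# brute-force Hudson F_ST by explicit double loops
brute_fst <- function(gen, ids_a, ids_b, units = "divisions",
                      t_now = NULL) {
  dmat <- function(x, y) {
    outer(seq_along(x), seq_along(y),
          Vectorize(function(i, j) {
            brute_gen_distance(gen, x[i], y[j], units, t_now)
          }))
  }
  mean_offdiag <- function(ids) {
    m <- dmat(ids, ids)
    sum(m) / (length(ids) * (length(ids) - 1L))
  }
  pi_b <- mean(dmat(ids_a, ids_b))
  if (pi_b == 0) return(0)
  pi_w <- (mean_offdiag(ids_a) + mean_offdiag(ids_b)) / 2
  min(max(1 - pi_w / pi_b, 0), 1)
}
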