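# Shared fixtures: tiny model configurations and geometry helpers.

tiny_fcfg <- function(n_embed = 4L, n_rbf = 8L)
  featurizer_config(n_embed = n_embed, n_rbf = n_rbf,
                    elements = c(1L, 6L, 7L, 8L))

tiny_cfg <- function(..., fcfg = tiny_fcfg())
  psi_config(n_psi_layers = 2L, n_heads = 2L, head_width = 8L, ...,
             fcfg = fcfg)

random_structure <- function(n, seed = NULL, elements = c(1L, 6L, 7L, 8L),
                             spread = 3) {
  if (!is.null(seed)) set.seed(seed)
  structure3d(sample(elements, n, replace = TRUE),
              matrix(stats::runif(3 * n, 0, spread), n, 3L))
}

random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3L, 3L, byrow = TRUE)
}

rigid_move <- function(s, R, t = c(0, 0, 0))
  structure3d(s$atomic_numbers, s$coordinates %*% t(R) +
                matrix(t, n_atoms(s), 3L, byrow = TRUE), label = s$label)

permute_reaction <- function(r, perm) {
  ps <- function(s) structure3d(s$atomic_numbers[perm],
                                s$coordinates[perm, , drop = FALSE],
                                label = s$label)
  reaction(ps(r$reactant), ps(r$product),
           ts_ref = if (is.null(r$ts_ref)) NULL else ps(r$ts_ref),
           properties = r$properties, id = r$id)
}

# For each strict-pair position of the permuted reaction, the position of the
# corresponding pair in the original reaction: pair (a, b) of the permuted
# structure is pair (perm[a], perm[b]) of the original.
match_strict_pairs <- function(n, perm) {
  idx <- tsgeom:::strict_pairs(n)
  key <- function(i, j) pmin(i, j) + pmax(i, j) * (n + 1L)
  match(key(perm[idx$i], perm[idx$j]), key(idx$i, idx$j))
}
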