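# Synthetic reaction generator: atom-mapped R/TS/P triples whose TS is an
# exactly realizable 3-D geometry between reactant and product, with property
# labels that are smooth functions of geometry, plus a smooth pairwise toy
# energy with analytic gradient/Hessian for relaxation and normal modes.

# ---- toy pairwise (Morse-like) energy ---------------------------------------

toy_r0 <- function(zi, zj) {
  rcov <- c(0.31, 0.28, 1.28, 0.96, 0.84, 0.76, 0.71, 0.66, 0.57, 0.58,
            1.66, 1.41, 1.21, 1.11, 1.07, 1.05, 1.02, 1.06)
  rcov[zi] + rcov[zj]
}

toy_depth <- function(zi, zj) {
  eps <- c(60, 10, 40, 45, 80, 85, 90, 95, 100, 10,
           40, 45, 55, 70, 75, 80, 85, 10)
  sqrt(eps[zi] * eps[zj])   # kcal/mol
}

TOY_A <- 1.8   # Morse steepness, 1/Angstrom

# E = sum_{i<j} D [ (1 - exp(-a (r - r0)))^2 - 1 ]
#' Toy pairwise potential energy of a structure
#'
#' A smooth Morse-like sum over atom pairs with element-dependent well depths
#' and equilibrium distances. It is deterministic and differentiable, serving
#' label plumbing and normal-mode tests; it makes no claim to chemical
#' accuracy.
#'
#' @param s A `structure3d`.
#' @return Energy in kcal/mol.
#' @export
toy_energy <- function(s) {
  idx <- strict_pairs(n_atoms(s))
  if (length(idx$i) == 0L) return(0)
  z <- s$atomic_numbers
  dm <- distance_matrix(s)
  r <- dm[cbind(idx$i, idx$j)]
  D <- toy_depth(z[idx$i], z[idx$j])
  r0 <- toy_r0(z[idx$i], z[idx$j])
  e <- exp(-TOY_A * (r - r0))
  sum(D * ((1 - e)^2 - 1))
}

toy_gradient <- function(s) {
  n <- n_atoms(s)
  idx <- strict_pairs(n)
  z <- s$atomic_numbers
  X <- s$coordinates
  G <- matrix(0, n, 3L)
  if (length(idx$i) == 0L) return(G)
  dx <- X[idx$i, , drop = FALSE] - X[idx$j, , drop = FALSE]
  r <- pmax(sqrt(rowSums(dx^2)), 1e-12)
  D <- toy_depth(z[idx$i], z[idx$j])
  r0 <- toy_r0(z[idx$i], z[idx$j])
  e <- exp(-TOY_A * (r - r0))
  fp <- 2 * D * TOY_A * (1 - e) * e          # dE/dr
  u <- dx / r
  for (c in 1:3) {
    gc <- fp * u[, c]
    G[, c] <- tabulate_add(idx$i, gc, n) - tabulate_add(idx$j, gc, n)
  }
  G
}

toy_hessian_matrix <- function(s) {
  n <- n_atoms(s)
  z <- s$atomic_numbers
  X <- s$coordinates
  H <- matrix(0, 3L * n, 3L * n)
  idx <- strict_pairs(n)
  for (p in seq_along(idx$i)) {
    i <- idx$i[p]; j <- idx$j[p]
    dx <- X[i, ] - X[j, ]
    r <- max(sqrt(sum(dx^2)), 1e-12)
    u <- dx / r
    D <- toy_depth(z[i], z[j])
    r0 <- toy_r0(z[i], z[j])
    e <- exp(-TOY_A * (r - r0))
    fp <- 2 * D * TOY_A * (1 - e) * e
    fpp <- 2 * D * TOY_A^2 * e * (2 * e - 1)
    K <- fpp * (u %o% u) + (fp / r) * (diag(3) - u %o% u)
    bi <- (i - 1L) * 3L + 1:3; bj <- (j - 1L) * 3L + 1:3
    H[bi, bi] <- H[bi, bi] + K
    H[bj, bj] <- H[bj, bj] + K
    H[bi, bj] <- H[bi, bj] - K
    H[bj, bi] <- H[bj, bi] - K
  }
  H
}

#' Relax a structure under the toy potential
#'
#' @param s A `structure3d`.
#' @param maxit BFGS iteration cap.
#' @return The relaxed `structure3d`.
#' @export
relax_structure <- function(s, maxit = 500L) {
  n <- n_atoms(s)
  fn <- function(xv) toy_energy(structure3d(s$atomic_numbers,
                                            matrix(xv, n, 3L)))
  gr <- function(xv) as.vector(toy_gradient(structure3d(s$atomic_numbers,
                                                        matrix(xv, n, 3L))))
  o <- stats::optim(as.vector(s$coordinates), fn, gr, method = "BFGS",
                    control = list(maxit = maxit, reltol = 1e-14))
  structure3d(s$atomic_numbers, matrix(o$par, n, 3L), label = s$label)
}

#' Analytic normal modes of the toy potential
#'
#' Mass-weights and diagonalizes the analytic Hessian of [toy_energy()] and
#' removes the six near-zero translational/rotational modes. Imaginary modes
#' appear as negative frequencies.
#'
#' @param s A `structure3d`, normally relaxed under the toy potential.
#' @param n_remove Number of near-zero modes to drop (default 6).
#' @return A `normal_modes` object; frequencies in cm^-1 (on the toy energy
#'   scale), modes mass-weighted-orthonormal.
#' @export
toy_normal_modes <- function(s, n_remove = 6L) {
  n <- n_atoms(s)
  if (3L * n <= n_remove) stop("too few atoms for vibrational modes")
  H <- toy_hessian_matrix(s)
  if (!all(is.finite(H))) stop("non-finite Hessian")
  m <- rep(atomic_mass(s$atomic_numbers), each = 3L)
  Hmw <- H / sqrt(outer(m, m))
  eg <- eigen(Hmw, symmetric = TRUE)
  lam <- eg$values
  ord <- order(abs(lam))          # drop the n_remove smallest-|lambda| modes
  keep <- sort(setdiff(seq_along(lam), ord[seq_len(n_remove)]),
               decreasing = FALSE)
  keep <- keep[order(lam[keep])]
  freqs <- sign(lam[keep]) * FREQ_CM * sqrt(abs(lam[keep]))
  modes <- array(0, dim = c(length(keep), n, 3L))
  for (k in seq_along(keep))
    modes[k, , ] <- matrix(eg$vectors[, keep[k]], n, 3L, byrow = TRUE)
  normal_modes(freqs, modes, s)
}

#' Toy property labels of a structure
#'
#' E is the toy potential energy; the entropies are fixed smooth functionals
#' of the distance set (deterministic, for multi-label plumbing only).
#'
#' @param s A `structure3d`.
#' @return Named vector c(E, S_vib, S_rot).
#' @export
toy_properties <- function(s) {
  d <- pair_distances(s)
  c(E = toy_energy(s),
    S_vib = 0.1 * sum(log1p(d^2)),
    S_rot = 2 * log1p(sum(d^2) / length(d)))
}

# ---- reaction generation ----------------------------------------------------

sample_separated_points <- function(n, min_sep = 0.8, box = NULL,
                                    max_tries = 400L) {
  if (is.null(box)) box <- 1.6 * n^(1 / 3) + 1.2
  X <- matrix(NA_real_, n, 3L)
  X[1L, ] <- stats::runif(3, 0, box)
  for (k in seq_len(n)[-1L]) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      cand <- stats::runif(3, 0, box)
      dmin <- min(sqrt(rowSums(sweep(X[seq_len(k - 1L), , drop = FALSE], 2L,
                                     cand)^2)))
      if (dmin >= min_sep && dmin <= 3.5) { X[k, ] <- cand; placed <- TRUE; break }
    }
    if (!placed) stop("could not satisfy separation constraints")
  }
  X
}

rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  ca <- cos(angle); sa <- sin(angle)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3L, 3L,
              byrow = TRUE)
  diag(3) + sa * K + (1 - ca) * (K %*% K)
}

min_pair_distance <- function(X) {
  if (nrow(X) < 2L) return(Inf)
  min(stats::dist(X))
}

# bend applied to the midpoint: for each displaced atom, the component of its
# centroid-relative midpoint position orthogonal to its R->P displacement.
# O(3)-equivariant, so TS distances are a function of the R/P geometry alone.
bend_vectors <- function(XR, XP, bend_scale) {
  mid <- 0.5 * (XR + XP)
  u <- XP - XR
  cen <- colMeans(mid)
  B <- matrix(0, nrow(XR), 3L)
  for (k in seq_len(nrow(XR))) {
    un <- sqrt(sum(u[k, ]^2))
    if (un < 1e-8) next
    uh <- u[k, ] / un
    w <- (mid[k, ] - cen)
    w <- w - sum(w * uh) * uh
    wn <- sqrt(sum(w^2))
    if (wn < 1e-8) next
    B[k, ] <- bend_scale * 0.5 * un * (w / wn)
  }
  B
}

#' Generate synthetic atom-mapped reactions
#'
#' Each reaction samples reactant coordinates with a minimum interatomic
#' separation, builds the product by rotating and radially stretching a
#' random atom subset (optionally forcing one bond-forming or bond-breaking
#' pair across the 156.6 pm threshold), and constructs the reference TS as
#' the midpoint geometry plus a geometry-derived bend orthogonal to the
#' R->P displacement — an exactly realizable 3-D structure whose distances
#' deviate smoothly from the interpolation. Property labels come from
#' [toy_properties()].
#'
#' @param n_reactions Number of reactions.
#' @param n_atoms_range Inclusive (min, max) atom counts.
#' @param elements Candidate atomic numbers.
#' @param bend_scale Nonlinearity of the R -> TS -> P path (0 = TS equals the
#'   midpoint, ratio targets identically 1).
#' @param p_change Probability of forcing a bond formation (or breakage) pair.
#' @param noise Gaussian jitter (Angstrom) added to the reference TS; 0 keeps
#'   the targets exactly realizable.
#' @param seed Seed; fixed seeds give bitwise-identical datasets.
#' @return List of `reaction` objects with `ts_ref` and property labels.
#' @export
synthetic_reactions <- function(n_reactions, n_atoms_range = c(4L, 8L),
                                elements = c(1L, 6L, 7L, 8L),
                                bend_scale = 0.3, p_change = 0.5, noise = 0,
                                seed = 1L) {
  stopifnot(n_reactions >= 1L, n_atoms_range[1] >= 2L, bend_scale >= 0)
  set.seed(seed)
  out <- vector("list", n_reactions)
  for (q in seq_len(n_reactions)) {
    rxn <- NULL
    for (attempt in 1:50) {
      rxn <- tryCatch(
        make_one_reaction(q, n_atoms_range, elements, bend_scale, p_change,
                          noise),
        error = function(e) NULL)
      if (!is.null(rxn)) break
    }
    if (is.null(rxn)) stop("unsatisfiable constraints for reaction ", q)
    out[[q]] <- rxn
  }
  out
}

make_one_reaction <- function(q, n_atoms_range, elements, bend_scale,
                              p_change, noise) {
  sizes <- seq(n_atoms_range[1], n_atoms_range[2])
  n <- if (length(sizes) == 1L) sizes else sample(sizes, 1L)
  z <- sample(elements, n, replace = TRUE)
  XR <- sample_separated_points(n)
  # product: rotate + radially stretch a random subset about its centroid
  nmove <- sample(seq_len(max(1L, n %/% 2L)), 1L)
  movers <- sample(n, nmove)
  XP <- XR
  cen <- colMeans(XR[movers, , drop = FALSE])
  Rm <- rotation_matrix(stats::rnorm(3), stats::runif(1, pi / 6, pi / 2))
  sc <- stats::runif(1, 0.85, 1.25)
  XP[movers, ] <- sweep(sc * sweep(XP[movers, , drop = FALSE], 2L, cen) %*%
                          t(Rm), 2L, cen, "+")
  # optionally force a bond-change pair across the 1.566 A threshold
  if (stats::runif(1) < p_change && n >= 3L) {
    ab <- sample(n, 2L)
    a <- ab[1]; b <- ab[2]
    dirv <- XR[b, ] - XR[a, ]
    dirv <- dirv / max(sqrt(sum(dirv^2)), 1e-9)
    if (stats::runif(1) < 0.5) {       # breakage: bonded in R, far in P
      XR[b, ] <- XR[a, ] + dirv * stats::runif(1, 1.0, 1.4)
      XP[b, ] <- XP[a, ] + dirv * stats::runif(1, 2.3, 3.2)
    } else {                           # formation: far in R, bonded in P
      XR[b, ] <- XR[a, ] + dirv * stats::runif(1, 2.3, 3.2)
      XP[b, ] <- XP[a, ] + dirv * stats::runif(1, 1.0, 1.4)
    }
  }
  if (min_pair_distance(XR) < 0.8 || min_pair_distance(XP) < 0.7)
    stop("separation violated")
  if (min_pair_distance(0.5 * (XR + XP)) < 0.5) stop("midpoint clash")
  # TS: bent midpoint, shrinking the bend until ratio targets stay in [0.5, 2]
  B <- bend_vectors(XR, XP, bend_scale)
  idx <- strict_pairs(n)
  mid <- 0.5 * (XR + XP)
  dI <- sqrt(rowSums((mid[idx$i, , drop = FALSE] -
                      mid[idx$j, , drop = FALSE])^2))
  XT <- NULL
  for (half in 0:6) {
    cand <- mid + B * 2^(-half)
    dT <- sqrt(rowSums((cand[idx$i, , drop = FALSE] -
                        cand[idx$j, , drop = FALSE])^2))
    ratio <- dT / dI
    if (all(ratio > 0.5 & ratio < 2) && min_pair_distance(cand) > 0.45) {
      XT <- cand; break
    }
  }
  if (is.null(XT)) stop("bend produced out-of-range ratios")
  if (noise > 0) XT <- XT + matrix(stats::rnorm(3 * n, sd = noise), n, 3L)
  sR <- structure3d(z, XR, label = "reactant")
  sP <- structure3d(z, XP, label = "product")
  sT <- structure3d(z, XT, label = "ts")
  props <- list(reactant = toy_properties(sR), ts = toy_properties(sT),
                product = toy_properties(sP))
  reaction(sR, sP, ts_ref = sT, properties = props,
           id = sprintf("synth-%04d", q))
}
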