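# Rigid superposition, normal-mode sampling, clustering, exploration pipeline.

test_that("Kabsch alignment recovers an exact superposition", {
  s <- random_structure(6, seed = 70)
  R <- random_rotation(seed = 71)
  moved <- rigid_move(s, R, c(3, -2, 1))
  al <- align_structures(moved, s)
  expect_lt(al$rmsd, 1e-8)
  expect_lt(max(abs(al$structure$coordinates - s$coordinates)), 1e-7)
  # identity case
  self <- align_structures(s, s)
  expect_equal(self$rmsd, 0, tolerance = 1e-12)
  # symmetry of the optimal RMSD
  t1 <- random_structure(6, seed = 72, elements = s$atomic_numbers)
  t1 <- structure3d(s$atomic_numbers, t1$coordinates)
  expect_equal(align_structures(s, t1)$rmsd, align_structures(t1, s)$rmsd,
               tolerance = 1e-8)
  expect_error(align_structures(s, random_structure(5, seed = 73)),
               "share atom count|element order")
})

test_that("alignment never reflects", {
  s <- random_structure(5, seed = 74)
  mirror <- structure3d(s$atomic_numbers,
                        s$coordinates %*% diag(c(-1, 1, 1)))
  al <- align_structures(mirror, s)
  # a proper rotation cannot undo a reflection of a chiral point set
  expect_gt(al$rmsd, 1e-3)
})

test_that("zero-temperature sampling returns the equilibrium", {
  s <- relax_structure(random_structure(4, seed = 75))
  nm <- toy_normal_modes(s)
  samples <- nms_sample(nm, n = 3, temperature = 0, seed = 1)
  expect_length(samples, 3)
  for (sm in samples)
    expect_identical(sm$coordinates, s$coordinates)
  expect_length(nms_sample(nm, n = 7, temperature = 300, seed = 1), 7)
})

test_that("sampled harmonic energies average to kB*T/2 per mode", {
  # single synthetic mode: unit mass-weighted vector on one atom pair
  eq <- structure3d(c(1L, 1L), rbind(c(0, 0, 0), c(1, 0, 0)))
  v <- array(0, dim = c(1, 2, 3))
  v[1, 1, 1] <- 1 / sqrt(2); v[1, 2, 1] <- -1 / sqrt(2)
  freq <- 1200                                       # cm^-1
  nm <- normal_modes(freq, v, eq)
  k_force <- (freq / tsgeom:::FREQ_CM)^2
  kT <- tsgeom:::KB_KCALMOL * 300
  set.seed(76)
  samples <- nms_sample(nm, n = 10000, temperature = 300)
  masses <- atomic_mass(eq$atomic_numbers)
  energies <- vapply(samples, function(sm) {
    dx <- sm$coordinates - eq$coordinates
    q <- sum(sqrt(rep(masses, each = 3)) * as.vector(t(dx)) *
               as.vector(t(v[1, , ])))
    0.5 * k_force * q^2
  }, numeric(1))
  expect_lt(abs(mean(energies) - kT / 2) / (kT / 2), 0.1)
})

test_that("toy normal modes of a relaxed structure are real and positive", {
  s <- relax_structure(random_structure(5, seed = 77))
  nm <- toy_normal_modes(s)
  expect_length(nm$frequencies, 3 * 5 - 6)
  expect_true(all(nm$frequencies > 0))
  # translations are exact zero modes of a pairwise potential
  all_modes <- toy_normal_modes(s, n_remove = 0L)
  expect_lt(min(abs(all_modes$frequencies)), 1)
  expect_true(sum(abs(all_modes$frequencies) < 1) >= 3)
})

test_that("analytic Hessian matches finite differences", {
  s <- random_structure(4, seed = 78)
  H <- tsgeom:::toy_hessian_matrix(s)
  n <- n_atoms(s)
  h <- 1e-5
  num <- matrix(0, 3 * n, 3 * n)
  # the Hessian is blocked per atom: flatten coordinates row-per-atom
  flat <- function(X) as.vector(t(X))
  unflat <- function(v) matrix(v, n, 3, byrow = TRUE)
  g_at <- function(v) flat(tsgeom:::toy_gradient(
    structure3d(s$atomic_numbers, unflat(v))))
  x0 <- flat(s$coordinates)
  for (k in seq_len(3 * n)) {
    xp <- x0; xm <- x0
    xp[k] <- xp[k] + h; xm[k] <- xm[k] - h
    num[, k] <- (g_at(xp) - g_at(xm)) / (2 * h)
  }
  expect_lt(max(abs(H - num)) / max(abs(H)), 1e-4)
})

test_that("clustering returns exemplars that are members of the input", {
  s0 <- random_structure(4, seed = 79)
  # all identical -> one representative
  same <- replicate(5, s0, simplify = FALSE)
  reps <- cluster_representatives(same)
  expect_length(reps, 1)
  # two tight, well-separated groups -> exactly 2, one per group
  set.seed(80)
  grp <- function(center_shift) lapply(1:50, function(k)
    structure3d(s0$atomic_numbers,
                s0$coordinates * center_shift +
                  matrix(rnorm(12, sd = 0.01), 4, 3)))
  pool <- c(grp(1), grp(1.8))
  reps2 <- cluster_representatives(pool)
  expect_length(reps2, 2)
  ex <- attr(reps2, "exemplar_indices")
  expect_true(all(ex %in% seq_along(pool)))
  expect_true(any(ex <= 50) && any(ex > 50))
  # brute-force nearest-exemplar oracle: every point joins its own group
  feats <- t(sapply(pool, pair_distances))
  assign_oracle <- apply(feats, 1, function(f)
    which.min(colSums((t(feats[ex, , drop = FALSE]) - f)^2)))
  expect_true(all(assign_oracle[1:50] == assign_oracle[1]))
  expect_true(all(assign_oracle[51:100] == assign_oracle[51]))
  expect_false(assign_oracle[1] == assign_oracle[51])
  # agreement with the clustering assignment
  lab <- attr(reps2, "assignment")
  expect_true(all(lab[1:50] == lab[1]))
  expect_true(all(lab[51:100] == lab[51]))
})

test_that("normal modes round-trip through JSON", {
  s <- relax_structure(random_structure(3, seed = 81))
  nm <- toy_normal_modes(s)
  p <- withr::local_tempfile(fileext = ".json")
  write_normal_modes(nm, p)
  back <- read_normal_modes(p)
  expect_equal(back$frequencies, nm$frequencies, tolerance = 1e-12)
  expect_equal(back$modes, nm$modes, tolerance = 1e-12)
  expect_equal(back$equilibrium$coordinates, nm$equilibrium$coordinates,
               tolerance = 1e-12)
})

test_that("degenerate exploration reduces to the equilibrium prediction", {
  rxn <- synthetic_reactions(1, n_atoms_range = c(4, 4), seed = 82)[[1]]
  relR <- relax_structure(rxn$reactant)
  relP <- relax_structure(rxn$product)
  rx <- reaction(relR, relP, id = "eq")
  m <- psi_init(tiny_cfg(), seed = 83)
  set.seed(84)
  m$params$ratio_head$W2[] <- rnorm(length(m$params$ratio_head$W2), sd = 0.2)
  nmr <- toy_normal_modes(relR)
  nmp <- toy_normal_modes(relP)
  reps <- explore_ts(rx, nmr, nmp, m, n_samples = 1, temperature = 0,
                     seed = 85)
  expect_length(reps, 1)
  # reference: align product, predict, reconstruct by hand
  pq <- align_structures(relP, relR)$structure
  rq <- reaction(relR, pq, id = "ref")
  pred <- predict_ensemble(rq, psi_ensemble(list(m)))
  ref <- reconstruct_ts(pred, interpolate_structure(rq, 0.5))
  expect_equal(pair_distances(reps[[1]]), pair_distances(ref),
               tolerance = 1e-6)
  # determinism of the full pipeline
  reps2 <- explore_ts(rx, nmr, nmp, m, n_samples = 2, temperature = 200,
                      seed = 86)
  reps3 <- explore_ts(rx, nmr, nmp, m, n_samples = 2, temperature = 200,
                      seed = 86)
  expect_identical(lapply(reps2, `[[`, "coordinates"),
                   lapply(reps3, `[[`, "coordinates"))
  expect_lte(length(reps2), 2)
})
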