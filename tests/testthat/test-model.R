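# PSI layers, readouts, atom aggregation, and network invariances.

test_that("feature width doubles per PSI layer", {
  cfg <- tiny_cfg()                       # 16 -> 32 -> 64
  expect_identical(psi_widths(cfg), c(16L, 32L, 64L))
  set.seed(1)
  x <- array(rnorm(5 * 3 * 16), dim = c(5, 3, 16))
  y <- psi_layer(x, n_heads = 2, seed = 2)
  expect_identical(dim(y), c(5L, 3L, 32L))
})

test_that("PSI layer is permutation-equivariant over the pair axis", {
  set.seed(3)
  x <- array(rnorm(7 * 3 * 16), dim = c(7, 3, 16))
  y <- psi_layer(x, n_heads = 2, seed = 4)
  perm <- sample(7)
  yp <- psi_layer(x[perm, , , drop = FALSE], n_heads = 2, seed = 4)
  expect_equal(yp, y[perm, , , drop = FALSE], tolerance = 1e-5)
})

test_that("reactions are processed independently (size extensivity)", {
  m <- psi_init(tiny_cfg(), seed = 5)
  m$params$ratio_head$W2[] <- rnorm(length(m$params$ratio_head$W2), sd = 0.3)
  rx <- synthetic_reactions(2, n_atoms_range = c(3, 5), seed = 6)
  alone <- lapply(rx, predict_single, model = m)
  batched <- predict(m, rx, tta = FALSE)
  for (k in 1:2)
    expect_identical(batched[[k]]$d_mean_pm, alone[[k]]$d_mean_pm)
})

test_that("atom aggregation recovers the symmetric pair sum", {
  # N_atom = 2: pairs (1,1), (2,1), (2,2) in canonical order
  pm <- rbind(p11 = c(1, 2), p21 = c(10, 20), p22 = c(100, 200))
  out <- aggregate_atomic(pm, i = c(1L, 2L, 2L), j = c(1L, 1L, 2L))
  expect_equal(out[1, ], c(11, 22))        # p11 + p21
  expect_equal(out[2, ], c(110, 220))      # p21 + p22
  expect_equal(aggregate_atomic(pm * 0, c(1L, 2L, 2L), c(1L, 1L, 2L)),
               matrix(0, 2, 2))
  # brute-force double-sum oracle on a random system
  set.seed(7)
  n <- 5L
  fp <- tsgeom:::full_pairs(n)
  w <- 3L
  pmat <- matrix(rnorm(length(fp$i) * w), length(fp$i), w)
  agg <- aggregate_atomic(pmat, fp$i, fp$j)
  full <- matrix(0, n, w)
  for (a in 1:n) for (b in 1:n) {
    p <- which(fp$i == max(a, b) & fp$j == min(a, b))
    full[a, ] <- full[a, ] + pmat[p, ]
  }
  expect_equal(agg, full, tolerance = 1e-12)
  expect_equal(colSums(agg), colSums(full), tolerance = 1e-12)
})

test_that("zero ratio head predicts the interpolated geometry exactly", {
  m <- psi_init(tiny_cfg(), seed = 8)     # zero-initialized final head layer
  r <- synthetic_reactions(1, n_atoms_range = c(4, 4), seed = 9)[[1]]
  fw <- psi_forward(m, r)
  expect_identical(fw$ratios, rep(1, 6))
  expect_identical(length(fw$ratios), 6L)
})

test_that("ratios stay positive for any finite weights", {
  m <- psi_init(tiny_cfg(), seed = 10)
  m$params$ratio_head$W2[] <- rnorm(length(m$params$ratio_head$W2), sd = 5)
  m$params$ratio_head$b2[] <- -3
  r <- synthetic_reactions(1, n_atoms_range = c(5, 6), seed = 11)[[1]]
  expect_true(all(psi_forward(m, r)$ratios > 0))
})

test_that("end-to-end prediction is invariant under rigid motion", {
  m <- psi_init(tiny_cfg(), seed = 12)
  m$params$ratio_head$W2[] <- rnorm(length(m$params$ratio_head$W2), sd = 0.3)
  r <- synthetic_reactions(1, n_atoms_range = c(5, 5), seed = 13)[[1]]
  R <- random_rotation(seed = 14)
  rot <- reaction(rigid_move(r$reactant, R, c(-1, 4, 2)),
                  rigid_move(r$product, R, c(-1, 4, 2)), id = r$id)
  expect_equal(psi_forward(m, rot)$ratios, psi_forward(m, r)$ratios,
               tolerance = 1e-8)
})

test_that("consistent atom reordering permutes ratios, values unchanged", {
  m <- psi_init(tiny_cfg(), seed = 15)
  m$params$ratio_head$W2[] <- rnorm(length(m$params$ratio_head$W2), sd = 0.3)
  r <- synthetic_reactions(1, n_atoms_range = c(5, 5), seed = 16)[[1]]
  n <- n_atoms(r$reactant)
  set.seed(17); perm <- sample(n)
  map <- match_strict_pairs(n, perm)
  a <- psi_forward(m, r)$ratios
  b <- psi_forward(m, permute_reaction(r, perm))$ratios
  expect_equal(b, a[map], tolerance = 1e-5)
})

test_that("initialization is deterministic under a seed", {
  a <- psi_init(tiny_cfg(), seed = 20)
  b <- psi_init(tiny_cfg(), seed = 20)
  expect_identical(coef(a), coef(b))
})

test_that("network gradients match finite differences", {
  r <- synthetic_reactions(1, n_atoms_range = c(3, 4), seed = 30)[[1]]
  fcfg <- tiny_fcfg(n_embed = 3, n_rbf = 6)
  cfg <- psi_config(n_psi_layers = 2, n_heads = 3, head_width = 6,
                    property_head = TRUE, fcfg = fcfg)
  params <- tsgeom:::psi_init_params(cfg, seed = 31, zero_heads = FALSE)
  prep <- tsgeom:::prepare_reaction(r, fcfg)
  cw <- 2000; cp <- 1
  lossfun <- function(pv) {
    p <- utils::relist(pv, params)
    pf <- tsgeom:::assemble_features(prep, p$embed)
    fwd <- tsgeom:::psi_forward_cached(p, cfg, pf)
    di <- pf$d[[2]][pf$strict] * 100
    l1 <- tsgeom:::loss_l1_batch(list(fwd$ratios), list(di),
                                 list(prep$d_true_pm))
    l3 <- edm_penalty(fwd$ratios * di / 100, n = length(pf$atomic_numbers))
    l2 <- tsgeom:::loss_l2_batch(list(fwd$props), list(prep$properties))
    cw * l1$loss + cp * (l2$loss + l3)
  }
  p <- params
  pf <- tsgeom:::assemble_features(prep, p$embed)
  fwd <- tsgeom:::psi_forward_cached(p, cfg, pf)
  di <- pf$d[[2]][pf$strict] * 100
  l1 <- tsgeom:::loss_l1_batch(list(fwd$ratios), list(di),
                               list(prep$d_true_pm))
  dA <- fwd$ratios * di / 100
  pen <- edm_penalty(dA, n = length(pf$atomic_numbers), gradient = TRUE)
  l2 <- tsgeom:::loss_l2_batch(list(fwd$props), list(prep$properties))
  nat <- length(pf$atomic_numbers)
  dpa <- list(reactant = cp * matrix(l2$dsign[[1]]$reactant, nat, 3,
                                     byrow = TRUE),
              product = cp * matrix(l2$dsign[[1]]$product, nat, 3,
                                    byrow = TRUE))
  grads <- tsgeom:::psi_backward(p, cfg, fwd,
                                 cw * l1$d_raw[[1]] + cp * pen$grad * dA, dpa)
  ga <- unlist(grads, use.names = FALSE)
  pv <- unlist(params, use.names = FALSE)
  set.seed(32); sel <- sample(length(pv), 40)
  gn <- vapply(sel, function(k) {
    h <- 1e-5; a <- pv; b <- pv
    a[k] <- a[k] + h; b[k] <- b[k] - h
    (lossfun(a) - lossfun(b)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(ga[sel] - gn) / pmax(abs(gn), 1e-4)), 1e-4)
})
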