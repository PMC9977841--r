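# 3-D coordinate reconstruction from predicted interatomic distances by
# weighted nonlinear optimization: X* = argmin_X sum_k sum_{i<j} w_ij *
# |d_ij^k - ||X_i - X_j|||, with Gaussian weights w_ij = exp(-alpha d_ij^2)
# emphasizing short (bonding-range) distances.

#' Gaussian pair weights for reconstruction
#'
#' w = exp(-alpha * d^2); monotonically decreasing in d so that short,
#' chemically critical distances dominate the objective.
#'
#' @param d Distances in Angstrom.
#' @param alpha Weight exponent in 1/Angstrom^2 (default 0.2).
#' @return Weights in (0, 1].
#' @export
pair_weights <- function(d, alpha = 0.2) {
  stopifnot(alpha >= 0, all(d >= 0))
  exp(-alpha * d^2)
}

# smooth surrogate for |x| that is exactly 0 at 0: sqrt(x^2+eps^2)-eps
recon_objective <- function(xvec, n, targets, w, i, j, eps) {
  X <- matrix(xvec, n, 3L)
  dx <- X[i, , drop = FALSE] - X[j, , drop = FALSE]
  r <- sqrt(rowSums(dx^2))
  obj <- 0
  for (k in seq_len(nrow(targets))) {
    e <- targets[k, ] - r
    obj <- obj + sum(w * (sqrt(e^2 + eps^2) - eps))
  }
  obj
}

recon_gradient <- function(xvec, n, targets, w, i, j, eps) {
  X <- matrix(xvec, n, 3L)
  dx <- X[i, , drop = FALSE] - X[j, , drop = FALSE]
  r <- pmax(sqrt(rowSums(dx^2)), 1e-12)
  dr <- numeric(length(r))
  for (k in seq_len(nrow(targets))) {
    e <- targets[k, ] - r
    dr <- dr - w * e / sqrt(e^2 + eps^2)   # d obj / d r
  }
  u <- dx / r
  G <- matrix(0, n, 3L)
  for (c in 1:3) {
    gc <- dr * u[, c]
    G[, c] <- tabulate_add(i, gc, n) - tabulate_add(j, gc, n)
  }
  as.vector(G)
}

tabulate_add <- function(idx, val, n) {
  out <- numeric(n)
  for (k in seq_along(idx)) out[idx[k]] <- out[idx[k]] + val[k]
  out
}

#' Reconstruct 3-D coordinates from predicted distances
#'
#' Minimizes the weighted sum of absolute deviations between the predicted
#' distances of every ensemble member and the pairwise distances of the
#' coordinates, starting from `init` (normally the interpolated geometry).
#' The non-smooth absolute value is replaced by the surrogate
#' sqrt(x^2 + eps^2) - eps; a smooth least-squares pass precedes the final
#' quasi-Newton minimization for robustness. Chirality is not controlled:
#' mirror images have identical distances.
#'
#' @param pred A `distance_prediction` (pm), or a numeric vector/matrix of
#'   strict-pair distances in Angstrom (rows = ensemble members).
#' @param init A `structure3d` initial geometry with matching atom count.
#' @param alpha Weight exponent (1/Angstrom^2); weights use the per-pair mean
#'   predicted distance.
#' @param eps Absolute-value smoothing length (Angstrom).
#' @param max_iter Iteration cap for each optimization stage.
#' @param tol Relative convergence tolerance.
#' @return A `structure3d` labelled "ts" with attribute `diagnostics`:
#'   list(objective, iterations, converged).
#' @export
reconstruct_ts <- function(pred, init, alpha = 0.2, eps = 1e-6,
                           max_iter = 2000L, tol = 1e-14) {
  stopifnot(inherits(init, "structure3d"))
  n <- n_atoms(init)
  idx <- strict_pairs(n)
  if (inherits(pred, "distance_prediction")) {
    targets <- pred$d_pred_pm / 100
    if (!identical(as.integer(pred$i), as.integer(idx$i)))
      stop("prediction pair index does not match init atom count")
  } else {
    targets <- pred
    if (is.null(dim(targets))) targets <- matrix(targets, nrow = 1L)
  }
  if (ncol(targets) != length(idx$i))
    stop("prediction covers ", ncol(targets), " pairs but init implies ",
         length(idx$i))
  if (!all(is.finite(targets)) || any(targets <= 0))
    stop("predicted distances must be finite and positive")
  dbar <- colMeans(targets)
  w <- pair_weights(dbar, alpha)
  x0 <- as.vector(init$coordinates)

  # stage 1: smooth weighted least squares (well-conditioned warm start)
  ls_obj <- function(xv) {
    X <- matrix(xv, n, 3L)
    r <- sqrt(rowSums((X[idx$i, , drop = FALSE] -
                       X[idx$j, , drop = FALSE])^2))
    s <- 0
    for (k in seq_len(nrow(targets))) s <- s + sum(w * (targets[k, ] - r)^2)
    s
  }
  ls_grad <- function(xv) {
    X <- matrix(xv, n, 3L)
    dx <- X[idx$i, , drop = FALSE] - X[idx$j, , drop = FALSE]
    r <- pmax(sqrt(rowSums(dx^2)), 1e-12)
    dr <- numeric(length(r))
    for (k in seq_len(nrow(targets))) dr <- dr - 2 * w * (targets[k, ] - r)
    u <- dx / r
    G <- matrix(0, n, 3L)
    for (c in 1:3) {
      gc <- dr * u[, c]
      G[, c] <- tabulate_add(idx$i, gc, n) - tabulate_add(idx$j, gc, n)
    }
    as.vector(G)
  }
  o1 <- stats::optim(x0, ls_obj, ls_grad, method = "BFGS",
                     control = list(maxit = max_iter, reltol = tol))
  # stage 2: the weighted absolute-deviation objective (smoothed)
  o2 <- stats::optim(o1$par, recon_objective, recon_gradient, method = "BFGS",
                     n = n, targets = targets, w = w, i = idx$i, j = idx$j,
                     eps = eps,
                     control = list(maxit = max_iter, reltol = tol))
  o3 <- stats::optim(o2$par, recon_objective, recon_gradient, method = "BFGS",
                     n = n, targets = targets, w = w, i = idx$i, j = idx$j,
                     eps = eps,
                     control = list(maxit = max_iter, reltol = tol))
  converged <- o3$convergence == 0L
  if (!converged)
    warning("reconstruction did not fully converge; returning best geometry")
  out <- structure3d(init$atomic_numbers, matrix(o3$par, n, 3L), label = "ts")
  attr(out, "diagnostics") <- list(objective = o3$value,
                                   iterations = unname(o1$counts[1] +
                                                       o2$counts[1] +
                                                       o3$counts[1]),
                                   converged = converged)
  out
}
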