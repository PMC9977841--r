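# Multi-TS exploration: rigid superposition, thermal normal-mode sampling,
# affinity-propagation clustering on interatomic-distance features, and the
# sample -> align -> predict -> reconstruct -> cluster pipeline.

# conversion sqrt((kcal/mol)/(amu A^2)) -> cm^-1
FREQ_CM <- 108.5914
KB_KCALMOL <- 0.0019872041

#' Optimal rigid superposition (Kabsch)
#'
#' Rotates and translates `mobile` onto `target` to minimize the RMSD;
#' reflections are excluded.
#'
#' @param mobile,target `structure3d` objects with equal atoms and order.
#' @return List with `structure` (the transformed mobile) and `rmsd`
#'   (Angstrom).
#' @export
align_structures <- function(mobile, target) {
  stopifnot(inherits(mobile, "structure3d"), inherits(target, "structure3d"))
  if (!identical(mobile$atomic_numbers, target$atomic_numbers))
    stop("structures must share atom count and element order")
  A <- mobile$coordinates
  B <- target$coordinates
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2L, ca); B0 <- sweep(B, 2L, cb)
  if (max(abs(A0)) < 1e-12 && nrow(A) > 1L)
    stop("degenerate (all-coincident) point set")
  H <- crossprod(A0, B0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  At <- sweep(A0 %*% t(R), 2L, cb, "+")
  rmsd <- sqrt(mean(rowSums((At - B)^2)))
  list(structure = structure3d(mobile$atomic_numbers, At,
                               label = mobile$label),
       rmsd = rmsd)
}

#' Normal modes container
#'
#' @param frequencies Frequencies in cm^-1 (imaginary modes as negative).
#' @param modes Array (n_modes, N_atom, 3) of mass-weighted-orthonormal mode
#'   vectors.
#' @param equilibrium Equilibrium `structure3d`.
#' @return An object of class `normal_modes`.
#' @export
normal_modes <- function(frequencies, modes, equilibrium) {
  stopifnot(inherits(equilibrium, "structure3d"))
  modes <- if (length(dim(modes)) == 3L) modes else
    array(modes, dim = c(length(frequencies), n_atoms(equilibrium), 3L))
  if (dim(modes)[1] != length(frequencies))
    stop("n_modes != length(frequencies)")
  if (!all(is.finite(modes))) stop("mode vectors must be finite")
  out <- list(frequencies = as.numeric(frequencies), modes = modes,
              equilibrium = equilibrium)
  class(out) <- "normal_modes"
  out
}

#' Sample thermally displaced geometries along normal modes
#'
#' Each sample displaces the equilibrium along every real (positive
#' frequency) mode by an amplitude a = s * sqrt(2 kB T c / k) with c uniform
#' on [0,1] and random sign s, so the expected harmonic potential energy per
#' mode is kB*T/2. At T = 0 every sample equals the equilibrium structure.
#'
#' @param nm A `normal_modes` object.
#' @param n Number of samples.
#' @param temperature Temperature in Kelvin.
#' @param seed Optional seed.
#' @return List of `structure3d` samples.
#' @export
nms_sample <- function(nm, n = 2000L, temperature = 300, seed = NULL) {
  stopifnot(inherits(nm, "normal_modes"), n >= 1L, temperature >= 0)
  if (!is.null(seed)) set.seed(seed)
  keep <- which(nm$frequencies > 0)
  if (length(keep) == 0L) stop("no real (positive-frequency) modes to sample")
  k_force <- (nm$frequencies[keep] / FREQ_CM)^2     # kcal/mol/A^2/amu
  kT <- KB_KCALMOL * temperature
  s <- nm$equilibrium
  nat <- n_atoms(s)
  invsqm <- 1 / sqrt(atomic_mass(s$atomic_numbers))
  out <- vector("list", n)
  for (q in seq_len(n)) {
    x <- s$coordinates
    if (kT > 0) {
      cs <- stats::runif(length(keep))
      sg <- sample(c(-1, 1), length(keep), replace = TRUE)
      amp <- sg * sqrt(2 * kT * cs / k_force)
      for (m in seq_along(keep)) {
        Q <- nm$modes[keep[m], , , drop = TRUE]
        if (is.null(dim(Q))) Q <- matrix(Q, nat, 3L)
        x <- x + amp[m] * Q * invsqm
      }
    }
    out[[q]] <- structure3d(s$atomic_numbers, x, label = s$label)
  }
  out
}

# ---- affinity propagation ---------------------------------------------------

#' Affinity propagation clustering
#'
#' Standard responsibility/availability message passing (similarity input,
#' exemplars are data points). Preference defaults to the median similarity.
#'
#' @param S Similarity matrix (larger = more similar).
#' @param preference Diagonal self-similarity (scalar or vector).
#' @param damping Damping factor in [0.5, 1).
#' @param maxit Maximum iterations.
#' @param convits Stop after this many iterations with an unchanged exemplar
#'   set.
#' @return List with `exemplars` (indices), `labels` (exemplar index per
#'   point), and `converged`.
#' @export
affinity_propagation <- function(S, preference = NULL, damping = 0.9,
                                 maxit = 1000L, convits = 50L) {
  n <- nrow(S)
  stopifnot(ncol(S) == n, damping >= 0.5, damping < 1)
  if (n == 1L)
    return(list(exemplars = 1L, labels = 1L, converged = TRUE))
  if (is.null(preference))
    preference <- stats::median(S[upper.tri(S) | lower.tri(S)])
  diag(S) <- preference
  # tiny deterministic jitter removes degenerate ties (no RNG involved)
  jit <- matrix((seq_len(n * n) * 31L) %% 97L, n, n) / 97
  S <- S + (abs(S) + 1e-6) * 1e-11 * jit
  R <- matrix(0, n, n); A <- matrix(0, n, n)
  last <- NULL; stable <- 0L; converged <- FALSE
  for (it in seq_len(maxit)) {
    AS <- A + S
    mx1 <- apply(AS, 1L, max)
    w1 <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(seq_len(n), w1)] <- -Inf
    mx2 <- apply(AS2, 1L, max)
    Rm <- S - mx1
    Rm[cbind(seq_len(n), w1)] <- S[cbind(seq_len(n), w1)] - mx2
    R <- damping * R + (1 - damping) * Rm
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    cs <- colSums(Rp)
    Am <- matrix(cs, n, n, byrow = TRUE) - Rp
    dA <- diag(Am)
    Am <- pmin(Am, 0)
    diag(Am) <- dA
    A <- damping * A + (1 - damping) * Am
    ex <- which(diag(A) + diag(R) > 0)
    if (identical(ex, last)) stable <- stable + 1L else stable <- 0L
    last <- ex
    if (stable >= convits && length(ex) > 0L) { converged <- TRUE; break }
  }
  ex <- last
  if (length(ex) == 0L) ex <- which.max(diag(A) + diag(R))
  labels <- ex[max.col(S[, ex, drop = FALSE], ties.method = "first")]
  labels[ex] <- ex
  list(exemplars = sort(ex), labels = labels, converged = converged)
}

# medoid of each connected component of the "closer than mean distance" graph
medoid_fallback <- function(D) {
  n <- nrow(D)
  thr <- mean(D[upper.tri(D)])
  adj <- D <= thr
  comp <- integer(n); cc <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cc <- cc + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] > 0L) next
      comp[v] <- cc
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  ex <- integer(cc)
  for (k in seq_len(cc)) {
    memb <- which(comp == k)
    ex[k] <- memb[which.min(rowSums(D[memb, memb, drop = FALSE]))]
  }
  list(exemplars = sort(ex), labels = ex[comp], converged = FALSE)
}

#' Select representative structures by clustering
#'
#' Features are the flattened strict-pair interatomic distances; similarity is
#' the negative squared Euclidean distance between feature vectors. Affinity
#' propagation returns exemplar structures that are members of the input set;
#' on non-convergence a medoid-per-connected-component fallback is used (with
#' a warning).
#'
#' @param structures List of `structure3d` with equal atom counts.
#' @param damping Affinity-propagation damping.
#' @param preference Optional preference (default median similarity).
#' @param maxit,convits Affinity-propagation iteration controls.
#' @return List of representative structures, with attribute `assignment`
#'   (exemplar index per input) and `exemplar_indices`.
#' @export
cluster_representatives <- function(structures, damping = 0.9,
                                    preference = NULL, maxit = 1000L,
                                    convits = 50L) {
  stopifnot(length(structures) >= 1L)
  n <- length(structures)
  if (n == 1L) {
    out <- structures
    attr(out, "exemplar_indices") <- 1L
    attr(out, "assignment") <- 1L
    return(out)
  }
  feats <- t(vapply(structures, pair_distances,
                    numeric(n_atoms(structures[[1]]) *
                            (n_atoms(structures[[1]]) - 1) / 2)))
  if (is.null(dim(feats))) feats <- matrix(feats, nrow = n)
  D2 <- as.matrix(stats::dist(feats))^2
  if (max(D2) < 1e-16) {
    out <- structures[1L]
    attr(out, "exemplar_indices") <- 1L
    attr(out, "assignment") <- rep(1L, n)
    return(out)
  }
  ap <- affinity_propagation(-D2, preference = preference, damping = damping,
                             maxit = maxit, convits = convits)
  if (!ap$converged) {
    warning("affinity propagation did not converge; using per-component medoids")
    ap <- medoid_fallback(sqrt(D2))
  }
  out <- structures[ap$exemplars]
  attr(out, "exemplar_indices") <- ap$exemplars
  attr(out, "assignment") <- ap$labels
  out
}

#' Explore multiple transition states via normal-mode sampling
#'
#' Pipeline: sample n reactant/product conformer pairs by NMS, rigidly align
#' each sampled product onto its sampled reactant, predict TS distances with
#' the ensemble, reconstruct each 3-D TS geometry, and cluster the results to
#' representatives.
#'
#' @param r A `reaction` (equilibrium reactant/product).
#' @param modes_r,modes_p `normal_modes` of the reactant and product.
#' @param ensemble A `psi_ensemble` (or single `psi_model`).
#' @param n_samples Number of sampled conformer pairs.
#' @param temperature Sampling temperature (K).
#' @param seed Seed for sampling.
#' @param alpha Reconstruction weight exponent.
#' @param damping,preference Clustering controls.
#' @return List of representative TS `structure3d`s with attribute
#'   `provenance` (index of the sampled pair behind each representative).
#' @export
explore_ts <- function(r, modes_r, modes_p, ensemble, n_samples = 2000L,
                       temperature = 300, seed = 1L, alpha = 0.2,
                       damping = 0.9, preference = NULL) {
  stopifnot(inherits(r, "reaction"))
  if (inherits(ensemble, "psi_model"))
    ensemble <- psi_ensemble(list(ensemble))
  set.seed(seed)
  sr <- nms_sample(modes_r, n = n_samples, temperature = temperature)
  sp <- nms_sample(modes_p, n = n_samples, temperature = temperature)
  ts_list <- vector("list", n_samples)
  ok <- logical(n_samples)
  for (q in seq_len(n_samples)) {
    res <- tryCatch({
      pq <- align_structures(sp[[q]], sr[[q]])$structure
      rq <- reaction(sr[[q]], pq, id = sprintf("%s-s%04d", r$id, q))
      pred <- predict_ensemble(rq, ensemble)
      init <- interpolate_structure(rq, 0.5)
      reconstruct_ts(pred, init, alpha = alpha)
    }, error = function(e) {
      warning(sprintf("sample %d skipped: %s", q, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) { ts_list[[q]] <- res; ok[q] <- TRUE }
  }
  ts_list <- ts_list[ok]
  if (length(ts_list) == 0L) stop("all samples failed")
  reps <- cluster_representatives(ts_list, damping = damping,
                                  preference = preference)
  attr(reps, "provenance") <- which(ok)[attr(reps, "exemplar_indices")]
  reps
}

# ---- normal-mode file I/O ---------------------------------------------------

#' Write normal modes to a JSON file
#' @param nm A `normal_modes` object.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_normal_modes <- function(nm, path) {
  obj <- list(frequencies_cm = nm$frequencies,
              modes = nm$modes,
              atomic_numbers = nm$equilibrium$atomic_numbers,
              coordinates = nm$equilibrium$coordinates)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read normal modes from a JSON file
#' @param path Input path.
#' @return A `normal_modes` object.
#' @export
read_normal_modes <- function(path) {
  obj <- jsonlite::fromJSON(path)
  eq <- structure3d(obj$atomic_numbers, obj$coordinates)
  normal_modes(obj$frequencies_cm, obj$modes, eq)
}
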