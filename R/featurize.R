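# Pair featurization: entity embeddings of atomic numbers concatenated with a
# Gaussian radial-basis expansion of interatomic distances, for each of the
# reactant, interpolated, and product structures.

#' Featurizer configuration
#'
#' Pair features have width N_f = 2 * n_embed + n_rbf (default 32+32+64 = 128).
#' Gaussian centers sit on an equidistant grid over [grid_min, grid_max]; the
#' default width parameter gamma = 1/(2 * spacing^2) makes neighbouring
#' kernels overlap at ~0.88.
#'
#' @param n_embed Per-atom embedding width.
#' @param n_rbf Number of Gaussian grid points.
#' @param grid_min,grid_max Grid range in Angstrom.
#' @param gamma Gaussian width in 1/Angstrom^2 (default from grid spacing).
#' @param elements Atomic numbers covered by the embedding table.
#' @return An object of class `featurizer_config`.
#' @export
featurizer_config <- function(n_embed = 32L, n_rbf = 64L, grid_min = 0,
                              grid_max = 8, gamma = NULL,
                              elements = c(1L, 6L, 7L, 8L)) {
  stopifnot(n_embed >= 1L, n_rbf >= 2L, grid_max > grid_min)
  spacing <- (grid_max - grid_min) / (n_rbf - 1)
  if (is.null(gamma)) gamma <- 1 / (2 * spacing^2)
  out <- list(n_embed = as.integer(n_embed), n_rbf = as.integer(n_rbf),
              grid_min = grid_min, grid_max = grid_max, gamma = gamma,
              centers = seq(grid_min, grid_max, length.out = n_rbf),
              elements = sort(unique(as.integer(elements))))
  out$n_features <- 2L * out$n_embed + out$n_rbf
  class(out) <- "featurizer_config"
  out
}

#' Gaussian expansion of a distance
#'
#' Component k is exp(-gamma * (d - mu_k)^2) for the k-th grid center mu_k.
#'
#' @param d Nonnegative distance(s) in Angstrom.
#' @param cfg A `featurizer_config`.
#' @return Matrix length(d) x n_rbf with entries in (0, 1].
#' @export
expand_distance <- function(d, cfg) {
  if (any(d < 0)) stop("distances must be nonnegative")
  outer(d, cfg$centers, function(x, mu) exp(-cfg$gamma * (x - mu)^2))
}

# full pair index i >= j (diagonal included), canonical order: j ascending,
# then i from j to n. The strict pairs (i > j) appear in the same relative
# order as strict_pairs().
full_pairs <- function(n) {
  j <- rep.int(seq_len(n), n:1L)
  i <- unlist(lapply(seq_len(n), function(a) a:n), use.names = FALSE)
  list(i = i, j = j, strict = which(i != j))
}

#' Build the pair-feature tensor of a reaction
#'
#' For each structure slice (reactant, interpolated, product) and each pair
#' i >= j, the feature row is `concat(embed(Z_i), embed(Z_j), rbf(d_ij))`.
#' Diagonal pairs (i = j, d = 0) are featurized but carry no distance target.
#'
#' @param r A `reaction`.
#' @param cfg A `featurizer_config`.
#' @param embeddings Numeric matrix (one row per element, rownames = Z) of
#'   learned atom embeddings; width must equal `cfg$n_embed`.
#' @param interp Optional precomputed interpolated `structure3d`; defaults to
#'   the midpoint `interpolate_structure(r, 0.5)`.
#' @return An object of class `pair_features`: a list with `values` (list of
#'   three N_pairs x N_f matrices in order reactant, interpolated, product),
#'   `i`, `j`, `strict` (indices of off-diagonal rows), and `d` (list of
#'   per-slice pair distances, Angstrom).
#' @export
featurize_reaction <- function(r, cfg, embeddings, interp = NULL) {
  assemble_features(prepare_reaction(r, cfg, interp = interp), embeddings)
}

# embedding-independent part of featurization; reused across training steps
prepare_reaction <- function(r, cfg, interp = NULL) {
  stopifnot(inherits(r, "reaction"), inherits(cfg, "featurizer_config"))
  if (is.null(interp)) interp <- interpolate_structure(r, 0.5)
  z <- r$reactant$atomic_numbers
  n <- length(z)
  fp <- full_pairs(n)
  slices <- list(r$reactant, interp, r$product)
  d <- lapply(slices, function(s) {
    dm <- distance_matrix(s)
    dm[cbind(fp$i, fp$j)]
  })
  rbf <- lapply(d, expand_distance, cfg = cfg)
  d_true_pm <- if (!is.null(r$ts_ref))
    pair_distances(r$ts_ref, unit = "pm") else NULL
  list(i = fp$i, j = fp$j, strict = fp$strict, d = d, rbf = rbf,
       atomic_numbers = z, d_true_pm = d_true_pm,
       properties = r$properties, id = r$id, n_embed = cfg$n_embed)
}

assemble_features <- function(prep, embeddings) {
  zc <- as.character(prep$atomic_numbers)
  if (!all(zc %in% rownames(embeddings)))
    stop("embedding table lacks element(s): ",
         paste(setdiff(zc, rownames(embeddings)), collapse = ", "))
  if (ncol(embeddings) != prep$n_embed)
    stop("embedding width != cfg$n_embed")
  # order the two embedding blocks by atomic number (larger Z first) so the
  # feature row is invariant under relabeling the pair's two atoms; ties have
  # identical embeddings, so the row is always well defined
  zi <- prep$atomic_numbers[prep$i]
  zj <- prep$atomic_numbers[prep$j]
  hi <- ifelse(zi >= zj, prep$i, prep$j)
  lo <- ifelse(zi >= zj, prep$j, prep$i)
  ei <- embeddings[zc[hi], , drop = FALSE]
  ej <- embeddings[zc[lo], , drop = FALSE]
  values <- lapply(prep$rbf, function(rb) {
    m <- cbind(ei, ej, rb)
    dimnames(m) <- NULL
    m
  })
  out <- list(values = values, i = prep$i, j = prep$j, strict = prep$strict,
              hi = hi, lo = lo, d = prep$d,
              atomic_numbers = prep$atomic_numbers)
  class(out) <- "pair_features"
  out
}

#' Convert a pair-feature object to a 3-D array
#'
#' @param pf A `pair_features` object.
#' @return Array of dimension (N_pairs, 3, N_f); slice order is reactant,
#'   interpolated, product.
#' @export
pair_feature_array <- function(pf) {
  np <- nrow(pf$values[[1]])
  nf <- ncol(pf$values[[1]])
  a <- array(NA_real_, dim = c(np, 3L, nf))
  for (s in 1:3) a[, s, ] <- pf$values[[s]]
  a
}
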