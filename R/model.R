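# The pair-sequence-interaction (PSI) network: stacked layers that alternate a
# per-structure transformer-encoder update over all atom pairs with a per-pair
# bidirectional GRU over the (reactant, interpolated, product) sequence, plus
# the distance-ratio and atomic-property readout heads.

#' Model configuration
#'
#' Feature width doubles at each PSI layer (bidirectional GRU concatenation):
#' with the defaults, 128 -> 256 -> 512. The ratio head reads the
#' interpolated-structure slice of the final features; the optional property
#' head reads atom-aggregated reactant/product features.
#'
#' @param n_psi_layers Number of stacked PSI layers.
#' @param n_heads Attention heads per encoder block.
#' @param ffn_mult Feed-forward width multiplier in the encoder.
#' @param head_width Hidden width of the two-layer readout perceptrons.
#' @param property_head Enable the atomic-property readout (E, S_vib, S_rot).
#' @param fcfg A `featurizer_config`; its `n_features` is the input width.
#' @return An object of class `psi_config`.
#' @export
psi_config <- function(n_psi_layers = 2L, n_heads = 4L, ffn_mult = 2L,
                       head_width = 256L, property_head = FALSE,
                       fcfg = featurizer_config()) {
  stopifnot(inherits(fcfg, "featurizer_config"), n_psi_layers >= 1L)
  widths <- as.integer(fcfg$n_features * 2L^(0:n_psi_layers))
  if (any(widths[-length(widths)] %% n_heads != 0L))
    stop("n_heads must divide every intermediate feature width")
  out <- list(n_psi_layers = as.integer(n_psi_layers),
              n_heads = as.integer(n_heads), ffn_mult = as.integer(ffn_mult),
              head_width = as.integer(head_width),
              property_head = isTRUE(property_head),
              fcfg = fcfg, widths = widths)
  class(out) <- "psi_config"
  out
}

#' Feature widths through the PSI stack
#'
#' @param cfg A `psi_config`.
#' @return Integer vector of widths entering/leaving each layer, e.g.
#'   c(128, 256, 512) for the defaults.
#' @export
psi_widths <- function(cfg) cfg$widths

psi_init_params <- function(cfg, seed = 1L, zero_heads = TRUE) {
  set.seed(seed)
  f <- cfg$fcfg
  embed <- rand_mat(length(f$elements), f$n_embed, scale = 0.5)
  rownames(embed) <- as.character(f$elements)
  layers <- vector("list", cfg$n_psi_layers)
  for (l in seq_len(cfg$n_psi_layers)) {
    w <- cfg$widths[l]
    layers[[l]] <- list(enc = encoder_init(w, cfg$n_heads, cfg$ffn_mult),
                        gru_f = gru_init(w, w), gru_b = gru_init(w, w))
  }
  wf <- cfg$widths[cfg$n_psi_layers + 1L]
  hw <- cfg$head_width
  mk_head <- function(nout) {
    W2 <- if (zero_heads) matrix(0, hw, nout) else rand_mat(hw, nout)
    list(W1 = rand_mat(wf, hw), b1 = rep(0, hw), W2 = W2, b2 = rep(0, nout))
  }
  params <- list(embed = embed, layers = layers, ratio_head = mk_head(1L))
  if (cfg$property_head) params$prop_head <- mk_head(3L)
  params
}

#' Initialize an untrained PSI model
#'
#' The final ratio-head layer starts at zero, so the untrained model predicts
#' ratios identically 1 (i.e. the interpolated geometry).
#'
#' @param cfg A `psi_config`.
#' @param seed Integer seed controlling weight initialization.
#' @return An object of class `psi_model`.
#' @export
psi_init <- function(cfg = psi_config(), seed = 1L) {
  out <- list(config = cfg, params = psi_init_params(cfg, seed),
              seed = as.integer(seed), trained = FALSE,
              val_mape = NA_real_, epoch = NA_integer_, history = NULL)
  class(out) <- "psi_model"
  out
}

# ---- single PSI layer -------------------------------------------------------

psi_layer_fwd <- function(xs, lp) {
  enc_caches <- vector("list", 3L)
  enc_out <- vector("list", 3L)
  for (s in 1:3) {
    enc_caches[[s]] <- encoder_fwd(xs[[s]], lp$enc)
    enc_out[[s]] <- enc_caches[[s]]$out
  }
  fw <- gru_seq_fwd(enc_out, lp$gru_f)
  bw <- gru_seq_fwd(rev(enc_out), lp$gru_b)
  out <- vector("list", 3L)
  for (t in 1:3) out[[t]] <- cbind(fw$hs[[t]], bw$hs[[4L - t]])
  list(out = out, enc_caches = enc_caches, fw = fw, bw = bw,
       w = ncol(xs[[1]]))
}

psi_layer_bwd <- function(cache, dys, lp) {
  w <- cache$w
  dh_f <- lapply(1:3, function(t) dys[[t]][, seq_len(w), drop = FALSE])
  dh_b <- lapply(1:3, function(t) dys[[4L - t]][, w + seq_len(w), drop = FALSE])
  gf <- gru_seq_bwd(cache$fw, dh_f, lp$gru_f)
  gb <- gru_seq_bwd(cache$bw, dh_b, lp$gru_b)
  dxs <- vector("list", 3L)
  grads <- list(enc = NULL, gru_f = gf$grads, gru_b = gb$grads)
  enc_grads <- NULL
  for (s in 1:3) {
    denc <- gf$dxs[[s]] + gb$dxs[[4L - s]]
    eg <- encoder_bwd(cache$enc_caches[[s]], denc, lp$enc)
    dxs[[s]] <- eg$dx
    enc_grads <- if (is.null(enc_grads)) eg$grads
                 else mapply_add(enc_grads, eg$grads)
  }
  grads$enc <- enc_grads
  list(dxs = dxs, grads = grads)
}

mapply_add <- function(a, b) {
  if (is.list(a)) return(mapply(mapply_add, a, b, SIMPLIFY = FALSE))
  a + b
}

#' Apply one PSI layer to a pair-feature array
#'
#' Step 1 updates each structure slice independently with a self-attention
#' encoder (permutation-equivariant over pairs); step 2 runs a bidirectional
#' GRU over the length-3 structure sequence for each pair independently,
#' doubling the feature width.
#'
#' @param x Array (N_pairs, 3, w) or list of three N_pairs x w matrices.
#' @param layer_params One element of `model$params$layers` (or NULL to use
#'   freshly initialized weights via `n_heads`/`ffn_mult`/`seed`).
#' @param n_heads,ffn_mult,seed Used only when `layer_params` is NULL.
#' @return Array (N_pairs, 3, 2w).
#' @export
psi_layer <- function(x, layer_params = NULL, n_heads = 4L, ffn_mult = 2L,
                      seed = 1L) {
  if (is.array(x) && length(dim(x)) == 3L) {
    xs <- lapply(1:3, function(s) x[, s, , drop = TRUE])
    xs <- lapply(xs, function(m) if (is.null(dim(m))) matrix(m, nrow = 1) else m)
  } else xs <- x
  w <- ncol(xs[[1]])
  if (is.null(layer_params)) {
    set.seed(seed)
    layer_params <- list(enc = encoder_init(w, n_heads, ffn_mult),
                         gru_f = gru_init(w, w), gru_b = gru_init(w, w))
  }
  out <- psi_layer_fwd(xs, layer_params)$out
  a <- array(NA_real_, dim = c(nrow(out[[1]]), 3L, ncol(out[[1]])))
  for (s in 1:3) a[, s, ] <- out[[s]]
  a
}

# ---- atom aggregation (pair -> atom, symmetric recovery) --------------------

#' Aggregate pair features into atomic features
#'
#' f_i = sum_j f_ij, with pairs stored only for i >= j and the missing half
#' recovered by symmetry f_ij = f_ji: each off-diagonal pair contributes to
#' both of its atoms, the diagonal pair once to its atom.
#'
#' @param pair_mat N_pairs x w matrix of pair features (canonical i >= j order).
#' @param i,j Integer pair indices (i >= j).
#' @return N_atom x w matrix of atomic features.
#' @export
aggregate_atomic <- function(pair_mat, i, j) {
  n <- max(i)
  inc <- matrix(0, n, nrow(pair_mat))
  inc[cbind(i, seq_along(i))] <- 1
  inc[cbind(j, seq_along(j))] <- inc[cbind(j, seq_along(j))] + (i != j) * 0 + 1
  # diagonal pairs got 2 from the two assignments above; fix to 1
  diag_rows <- which(i == j)
  if (length(diag_rows)) inc[cbind(i[diag_rows], diag_rows)] <- 1
  inc %*% pair_mat
}

# ---- full forward / backward ------------------------------------------------

head_fwd <- function(x, hp) {
  f1 <- linear_fwd(x, hp$W1, hp$b1)
  hrelu <- pmax(f1$out, 0)
  f2 <- linear_fwd(hrelu, hp$W2, hp$b2)
  list(out = f2$out, f1 = f1, hrelu = hrelu)
}

head_bwd <- function(cache, dy, hp) {
  g2 <- linear_bwd(list(x = cache$hrelu), dy, hp$W2)
  dhr <- g2$dx * (cache$f1$out > 0)
  g1 <- linear_bwd(cache$f1, dhr, hp$W1)
  list(dx = g1$dx, grads = list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db))
}

# forward pass over one featurized reaction; returns ratios for strict pairs
# and (optionally) per-role molecular property predictions, with cache
psi_forward_cached <- function(params, cfg, pf) {
  xs <- pf$values
  layer_caches <- vector("list", cfg$n_psi_layers)
  for (l in seq_len(cfg$n_psi_layers)) {
    layer_caches[[l]] <- psi_layer_fwd(xs, params$layers[[l]])
    xs <- layer_caches[[l]]$out
  }
  interp_strict <- xs[[2]][pf$strict, , drop = FALSE]
  rh <- head_fwd(interp_strict, params$ratio_head)
  raw <- drop(rh$out)
  ratios <- exp(raw)
  props <- NULL; prop_caches <- NULL
  if (!is.null(params$prop_head)) {
    prop_caches <- list()
    props <- list()
    for (role in c(1L, 3L)) {
      atom_f <- aggregate_atomic(xs[[role]], pf$i, pf$j)
      ph <- head_fwd(atom_f, params$prop_head)
      nm <- if (role == 1L) "reactant" else "product"
      prop_caches[[nm]] <- ph
      v <- colSums(ph$out)
      names(v) <- c("E", "S_vib", "S_rot")
      props[[nm]] <- v
    }
  }
  list(ratios = ratios, raw = raw, props = props,
       cache = list(layer_caches = layer_caches, rh = rh,
                    prop_caches = prop_caches, final = xs, pf = pf))
}

# backward: d_raw is dL/d(raw ratio-head output) for strict pairs;
# d_prop_atom is an optional list(reactant=, product=) of N_atom x 3 grads
psi_backward <- function(params, cfg, fwd, d_raw, d_prop_atom = NULL) {
  cache <- fwd$cache
  pf <- cache$pf
  np <- length(pf$i)
  wf <- cfg$widths[cfg$n_psi_layers + 1L]
  rhg <- head_bwd(cache$rh, matrix(d_raw, ncol = 1L), params$ratio_head)
  dxs <- lapply(1:3, function(s) matrix(0, np, wf))
  dxs[[2]][pf$strict, ] <- rhg$dx
  grads <- list(embed = params$embed * 0, layers = vector("list", cfg$n_psi_layers),
                ratio_head = rhg$grads)
  if (!is.null(params$prop_head)) {
    ph_grads <- NULL
    n <- length(pf$atomic_numbers)
    inc <- matrix(0, n, np)
    inc[cbind(pf$i, seq_len(np))] <- 1
    inc[cbind(pf$j, seq_len(np))] <- inc[cbind(pf$j, seq_len(np))] + 1
    dg <- which(pf$i == pf$j)
    if (length(dg)) inc[cbind(pf$i[dg], dg)] <- 1
    for (role in c(1L, 3L)) {
      nm <- if (role == 1L) "reactant" else "product"
      da <- d_prop_atom[[nm]]
      if (is.null(da)) next
      pg <- head_bwd(cache$prop_caches[[nm]], da, params$prop_head)
      dxs[[role]] <- dxs[[role]] + crossprod(inc, pg$dx)
      ph_grads <- if (is.null(ph_grads)) pg$grads else mapply_add(ph_grads, pg$grads)
    }
    grads$prop_head <- if (is.null(ph_grads))
      lapply(params$prop_head, function(m) m * 0) else ph_grads
  }
  for (l in cfg$n_psi_layers:1) {
    lb <- psi_layer_bwd(cache$layer_caches[[l]], dxs, params$layers[[l]])
    dxs <- lb$dxs
    grads$layers[[l]] <- lb$grads
  }
  # into the embedding table: feature rows are [embed(Z_hi), embed(Z_lo), rbf]
  # with the blocks ordered by atomic number at featurization
  ne <- cfg$fcfg$n_embed
  zc <- as.character(pf$atomic_numbers)
  ridx <- match(zc, rownames(params$embed))
  for (s in 1:3) {
    d <- dxs[[s]]
    di <- d[, seq_len(ne), drop = FALSE]
    dj <- d[, ne + seq_len(ne), drop = FALSE]
    for (p in seq_len(np)) {
      grads$embed[ridx[pf$hi[p]], ] <- grads$embed[ridx[pf$hi[p]], ] + di[p, ]
      grads$embed[ridx[pf$lo[p]], ] <- grads$embed[ridx[pf$lo[p]], ] + dj[p, ]
    }
  }
  grads
}

#' Run the PSI network on one reaction
#'
#' @param model A `psi_model`.
#' @param r A `reaction`.
#' @param interp Optional precomputed interpolated structure.
#' @return List with `ratios` (predicted d_TS/d_I for strict pairs i > j,
#'   canonical order), `d_interp_pm`, `i`, `j`, and `props` (per-role
#'   molecular property predictions when the property head is enabled).
#' @export
psi_forward <- function(model, r, interp = NULL) {
  stopifnot(inherits(model, "psi_model"), inherits(r, "reaction"))
  pf <- featurize_reaction(r, model$config$fcfg, model$params$embed,
                           interp = interp)
  fwd <- psi_forward_cached(model$params, model$config, pf)
  list(ratios = fwd$ratios, d_interp_pm = pf$d[[2]][pf$strict] * 100,
       i = pf$i[pf$strict], j = pf$j[pf$strict], props = fwd$props)
}
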