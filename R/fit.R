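# Model fitting: Adam optimization of L = c*L1 + c'*(L2 + L3), seeded
# 80-10-10 splitting, top-5 checkpoint selection by validation molecular MAPE,
# and the S3 surface of the fitted model.

#' Split reactions into train/validation/test subsets
#'
#' @param reactions List of `reaction` objects.
#' @param ratio Length-3 nonnegative weights, default 80-10-10.
#' @param seed Optional seed for the random permutation.
#' @return List with integer index vectors `train`, `validation`, `test`.
#' @export
split_reactions <- function(reactions, ratio = c(0.8, 0.1, 0.1), seed = NULL) {
  stopifnot(length(ratio) == 3L, all(ratio >= 0), sum(ratio) > 0)
  n <- length(reactions)
  if (!is.null(seed)) set.seed(seed)
  perm <- sample.int(n)
  ratio <- ratio / sum(ratio)
  n_train <- round(ratio[1] * n)
  n_val <- round(ratio[2] * n)
  if (n_train < 1L || (ratio[2] > 0 && n_val < 1L))
    stop("split leaves an empty subset")
  list(train = perm[seq_len(n_train)],
       validation = perm[n_train + seq_len(n_val)],
       test = perm[setdiff(seq_len(n), seq_len(n_train + n_val))])
}

# Adam with cosine learning-rate decay over a flattened parameter vector
adam_state <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(par, grad, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0, decay_mask = NULL) {
  st$t <- st$t + 1L
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mhat <- st$m / (1 - beta1^st$t)
  vhat <- st$v / (1 - beta2^st$t)
  upd <- lr * mhat / (sqrt(vhat) + eps)
  if (weight_decay > 0)                     # decoupled decay on weights only
    upd <- upd + lr * weight_decay * par * decay_mask
  list(par = par - upd, state = st)
}

# 1 for entries of weight matrices, 0 for biases/gains/scalars
weight_decay_mask <- function(params) {
  unlist(rapply(params, function(x)
    rep(if (is.matrix(x)) 1 else 0, length(x)), how = "unlist"))
}

flatten_params <- function(params) unlist(params, use.names = FALSE)

relist_params <- function(v, skeleton) {
  utils::relist(v, skeleton)
}

# validation molecular MAPE of d_pred = ratio * d_interp vs reference TS
validation_mape <- function(params, cfg, preps) {
  pred <- vector("list", length(preps))
  true <- vector("list", length(preps))
  for (k in seq_along(preps)) {
    pf <- assemble_features(preps[[k]], params$embed)
    fwd <- psi_forward_cached(params, cfg, pf)
    di <- pf$d[[2]][pf$strict] * 100
    pred[[k]] <- fwd$ratios * di
    true[[k]] <- preps[[k]]$d_true_pm
  }
  molecular_mape(pred, true)
}

#' Fit a PSI model to a set of reactions
#'
#' Minimizes the weighted loss L = c * L1 + c' * (L2 + L3), where L1 is the
#' molecular MAE of predicted TS distances (pm), L2 the property MAE over
#' reactant and product labels, and L3 the Euclidean distance-matrix
#' eigenvalue penalty, using Adam with cosine learning-rate decay. The epochs
#' with the five best validation molecular MAPE values are kept as
#' checkpoints; the returned model carries the best one.
#'
#' @param reactions List of `reaction` objects with reference TS structures.
#' @param config A `psi_config`.
#' @param c_weight Weight c of the distance loss L1 (default 2000).
#' @param c_prime Weight c' of the auxiliary losses L2 + L3 (default 0).
#' @param epochs Training epochs.
#' @param lr Base Adam learning rate (cosine-decayed to 0 over `epochs`).
#' @param weight_decay Decoupled weight decay applied to weight matrices.
#' @param warmup Linear learning-rate warmup epochs before the cosine decay.
#' @param batch_size Reactions per gradient step.
#' @param split 3-vector of train/validation/test weights, or a list of index
#'   vectors `train`/`validation` (and optionally `test`).
#' @param seed Seed controlling initialization, splitting, and shuffling.
#' @param n_checkpoints How many top epochs to retain.
#' @param verbose Print a line per epoch.
#' @return A fitted `psi_model` with fields `history` (per-epoch data frame),
#'   `checkpoints` (list, best first), `split`, and the best parameters.
#' @export
psi_fit <- function(reactions, config = psi_config(), c_weight = 2000,
                    c_prime = 0, epochs = 300L, lr = 1e-4, batch_size = 16L,
                    split = c(0.8, 0.1, 0.1), seed = 1L, n_checkpoints = 5L,
                    weight_decay = 0, warmup = 0L, verbose = FALSE) {
  stopifnot(inherits(config, "psi_config"), c_weight >= 0, c_prime >= 0)
  if (c_prime > 0 && !config$property_head) {
    has_props <- any(vapply(reactions, function(r) !is.null(r$properties),
                            logical(1)))
    if (has_props)
      config <- psi_config(config$n_psi_layers, config$n_heads,
                           config$ffn_mult, config$head_width,
                           property_head = TRUE, fcfg = config$fcfg)
  }
  if (is.list(split) && !is.null(split$train)) {
    set.seed(seed)
    idx <- split
    if (is.null(idx$test)) idx$test <- integer(0)
  } else idx <- split_reactions(reactions, split, seed = seed)
  # init draws from a derived stream so the split does not depend on the
  # architecture's parameter count
  params <- psi_init_params(config, seed + 1L)
  if (length(idx$train) == 0L || length(idx$validation) == 0L)
    stop("empty train or validation split")
  miss_ts <- vapply(reactions[c(idx$train, idx$validation)],
                    function(r) is.null(r$ts_ref), logical(1))
  if (any(miss_ts)) stop("training/validation reactions need ts_ref")

  fcfg <- config$fcfg
  preps <- lapply(reactions, prepare_reaction, cfg = fcfg)
  skeleton <- params
  par_vec <- flatten_params(params)
  ad <- adam_state(length(par_vec))
  dmask <- if (weight_decay > 0) weight_decay_mask(params) else NULL
  hist <- data.frame(epoch = integer(0), loss = numeric(0), l1 = numeric(0),
                     l2 = numeric(0), l3 = numeric(0), val_mape = numeric(0),
                     lr = numeric(0))
  checkpoints <- list()
  n_train <- length(idx$train)

  for (ep in seq_len(epochs)) {
    lr_ep <- lr * 0.5 * (1 + cos(pi * (ep - 1) / epochs))
    if (warmup > 0L && ep <= warmup) lr_ep <- lr * ep / (warmup + 1)
    ord <- idx$train[sample.int(n_train)]
    ep_l1 <- ep_l2 <- ep_l3 <- 0; n_batches <- 0L
    for (b0 in seq(1L, n_train, by = batch_size)) {
      batch <- ord[b0:min(b0 + batch_size - 1L, n_train)]
      m <- length(batch)
      fwds <- vector("list", m); pfs <- vector("list", m)
      ratios <- vector("list", m); d_interp <- vector("list", m)
      d_true <- vector("list", m)
      for (q in seq_len(m)) {
        pfs[[q]] <- assemble_features(preps[[batch[q]]], params$embed)
        fwds[[q]] <- psi_forward_cached(params, config, pfs[[q]])
        ratios[[q]] <- fwds[[q]]$ratios
        d_interp[[q]] <- pfs[[q]]$d[[2]][pfs[[q]]$strict] * 100
        d_true[[q]] <- preps[[batch[q]]]$d_true_pm
      }
      l1 <- loss_l1_batch(ratios, d_interp, d_true)
      l2 <- list(loss = 0, dsign = NULL)
      l3_val <- 0
      d_raw <- lapply(l1$d_raw, function(g) c_weight * g)
      if (c_prime > 0) {
        for (q in seq_len(m)) {
          dA <- ratios[[q]] * d_interp[[q]] / 100   # Angstrom
          n_at <- length(pfs[[q]]$atomic_numbers)
          pen <- edm_penalty(dA, n = n_at, gradient = TRUE)
          l3_val <- l3_val + pen$value / m
          d_raw[[q]] <- d_raw[[q]] + c_prime * (pen$grad * dA) / m
        }
        if (config$property_head) {
          pred_props <- lapply(fwds, `[[`, "props")
          labels <- lapply(batch, function(t) preps[[t]]$properties)
          l2 <- loss_l2_batch(pred_props, labels)
        }
      }
      grads <- NULL
      for (q in seq_len(m)) {
        dpa <- NULL
        if (c_prime > 0 && config$property_head && !is.null(l2$dsign)) {
          n_at <- length(pfs[[q]]$atomic_numbers)
          dpa <- list(
            reactant = c_prime *
              matrix(l2$dsign[[q]]$reactant, n_at, 3L, byrow = TRUE),
            product = c_prime *
              matrix(l2$dsign[[q]]$product, n_at, 3L, byrow = TRUE))
        }
        g <- psi_backward(params, config, fwds[[q]], d_raw[[q]], dpa)
        grads <- if (is.null(grads)) g else mapply_add(grads, g)
      }
      loss_val <- c_weight * l1$loss + c_prime * (l2$loss + l3_val)
      if (!is.finite(loss_val))
        stop(sprintf("non-finite loss at epoch %d (L1=%g L2=%g L3=%g)",
                     ep, l1$loss, l2$loss, l3_val))
      upd <- adam_step(par_vec, flatten_params(grads), ad, lr_ep,
                       weight_decay = weight_decay, decay_mask = dmask)
      par_vec <- upd$par; ad <- upd$state
      params <- relist_params(par_vec, skeleton)
      ep_l1 <- ep_l1 + l1$loss; ep_l2 <- ep_l2 + l2$loss
      ep_l3 <- ep_l3 + l3_val; n_batches <- n_batches + 1L
    }
    ep_l1 <- ep_l1 / n_batches; ep_l2 <- ep_l2 / n_batches
    ep_l3 <- ep_l3 / n_batches
    vm <- validation_mape(params, config, preps[idx$validation])
    hist[nrow(hist) + 1L, ] <- list(ep, c_weight * ep_l1 + c_prime *
                                      (ep_l2 + ep_l3), ep_l1, ep_l2, ep_l3,
                                    vm, lr_ep)
    checkpoints[[length(checkpoints) + 1L]] <-
      list(params = params, epoch = ep, val_mape = vm)
    o <- order(vapply(checkpoints, `[[`, numeric(1), "val_mape"))
    checkpoints <- checkpoints[o[seq_len(min(n_checkpoints,
                                             length(checkpoints)))]]
    if (verbose)
      message(sprintf("epoch %3d  L=%10.4f  L1=%8.4f  val MAPE=%7.4f%%",
                      ep, hist$loss[nrow(hist)], ep_l1, vm))
  }

  best <- checkpoints[[1L]]
  out <- list(config = config, params = best$params, seed = as.integer(seed),
              trained = TRUE, val_mape = best$val_mape, epoch = best$epoch,
              history = hist, checkpoints = checkpoints, split = idx,
              c_weight = c_weight, c_prime = c_prime,
              call = match.call())
  class(out) <- "psi_model"
  out
}

#' Extract retained checkpoints as standalone models
#'
#' @param model A fitted `psi_model`.
#' @return List of `psi_model` objects (best validation MAPE first).
#' @export
psi_checkpoints <- function(model) {
  stopifnot(inherits(model, "psi_model"))
  if (is.null(model$checkpoints)) return(list(model))
  lapply(model$checkpoints, function(ck) {
    m <- model
    m$params <- ck$params
    m$val_mape <- ck$val_mape
    m$epoch <- ck$epoch
    m$checkpoints <- NULL
    m
  })
}

#' @export
print.psi_model <- function(x, ...) {
  w <- paste(psi_widths(x$config), collapse = " -> ")
  cat(sprintf("PSI transition-state distance model (%s)\n",
              if (isTRUE(x$trained)) "fitted" else "untrained"))
  cat(sprintf("  %d PSI layer(s), feature widths %s, %d parameters\n",
              x$config$n_psi_layers, w, length(flatten_params(x$params))))
  cat(sprintf("  elements: %s; property head: %s\n",
              paste(ELEMENT_SYMBOLS[x$config$fcfg$elements], collapse = " "),
              x$config$property_head))
  if (isTRUE(x$trained))
    cat(sprintf("  best validation molecular MAPE %.4f%% (epoch %d)\n",
                x$val_mape, x$epoch))
  invisible(x)
}

#' @export
summary.psi_model <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    h <- object$history
    cat(sprintf("  trained %d epochs; final L=%.4f, val MAPE %.4f%%\n",
                nrow(h), h$loss[nrow(h)], h$val_mape[nrow(h)]))
    cat(sprintf("  checkpoints kept: %d (val MAPE %s)\n",
                length(object$checkpoints),
                paste(sprintf("%.3f", vapply(object$checkpoints, `[[`,
                                             numeric(1), "val_mape")),
                      collapse = ", ")))
  }
  invisible(object)
}

#' @export
coef.psi_model <- function(object, ...) unlist(object$params)

#' @export
plot.psi_model <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  h <- x$history
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                 ylab = "training loss", main = "loss", ...)
  graphics::plot(h$epoch, h$val_mape, type = "l", xlab = "epoch",
                 ylab = "validation molecular MAPE (%)", main = "validation",
                 ...)
  invisible(x)
}

#' Predict TS distances for new reactions
#'
#' @param object A `psi_model`.
#' @param newdata A `reaction` or list of reactions.
#' @param tta Use test-time augmentation by reaction reversal (default TRUE).
#' @param ... Unused.
#' @return A `distance_prediction` (single reaction) or list thereof.
#' @export
predict.psi_model <- function(object, newdata, tta = TRUE, ...) {
  single <- inherits(newdata, "reaction")
  rl <- if (single) list(newdata) else newdata
  out <- lapply(rl, function(r)
    if (tta) predict_tta(r, object) else predict_single(r, object))
  if (single) out[[1]] else out
}

#' Residual TS distance errors on labelled reactions
#'
#' @param object A fitted `psi_model`.
#' @param reactions Reactions with reference TS structures.
#' @param tta Use test-time augmentation.
#' @param ... Unused.
#' @return List of per-reaction residual vectors d_pred - d_true in pm.
#' @export
residuals.psi_model <- function(object, reactions,
                                tta = TRUE, ...) {
  if (inherits(reactions, "reaction")) reactions <- list(reactions)
  lapply(reactions, function(r) {
    if (is.null(r$ts_ref)) stop("residuals need ts_ref: ", r$id)
    p <- if (tta) predict_tta(r, object) else predict_single(r, object)
    p$d_mean_pm - pair_distances(r$ts_ref, unit = "pm")
  })
}
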