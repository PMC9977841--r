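# Metrics and training losses: molecule-first MAE/MAPE, the distance loss L1,
# the auxiliary property loss L2, and the Euclidean distance-matrix eigenvalue
# penalty L3, with analytic gradients.

as_reaction_list <- function(x) {
  if (is.list(x) && !is.null(names(x)) && all(c("i", "j") %in% names(x)))
    stop("expected per-reaction distance vectors, got a single prediction")
  if (!is.list(x)) list(x) else x
}

#' Molecular mean absolute error
#'
#' Mean over reactions of the per-reaction mean absolute distance error over
#' the N(N-1)/2 strict atom pairs; every reaction weighs equally regardless
#' of size.
#'
#' @param pred,true Numeric vectors of strict-pair distances (one reaction) or
#'   lists of such vectors (one element per reaction). Units pm by convention.
#' @return Scalar molecular MAE (same unit as the inputs).
#' @export
molecular_mae <- function(pred, true) {
  pred <- as_reaction_list(pred); true <- as_reaction_list(true)
  stopifnot(length(pred) == length(true))
  per <- mapply(function(p, t) {
    if (length(p) != length(t)) stop("mismatched pair counts within a reaction")
    mean(abs(t - p))
  }, pred, true)
  mean(per)
}

#' Molecular mean absolute percentage error
#'
#' Mean over reactions of the per-reaction mean of |d_true - d_pred| / d_true,
#' times 100.
#'
#' @inheritParams molecular_mae
#' @return Scalar molecular MAPE in percent.
#' @export
molecular_mape <- function(pred, true) {
  pred <- as_reaction_list(pred); true <- as_reaction_list(true)
  stopifnot(length(pred) == length(true))
  per <- mapply(function(p, t) {
    if (length(p) != length(t)) stop("mismatched pair counts within a reaction")
    if (any(t <= 0)) stop("true distances must be positive for MAPE")
    mean(abs(t - p) / t)
  }, pred, true)
  100 * mean(per)
}

# L1 for a batch: molecular MAE of ratio * d_interp vs reference TS distances,
# plus its gradient w.r.t. the raw (log-ratio) head outputs.
loss_l1_batch <- function(ratio_list, d_interp_list, d_true_list) {
  m <- length(ratio_list)
  loss <- 0
  d_raw <- vector("list", m)
  for (t in seq_len(m)) {
    r <- ratio_list[[t]]; di <- d_interp_list[[t]]; dt <- d_true_list[[t]]
    e <- r * di - dt
    npair <- length(e)
    loss <- loss + mean(abs(e)) / m
    # d/draw |r*di - dt| = sign(e) * di * r   (r = exp(raw))
    d_raw[[t]] <- sign(e) * di * r / (npair * m)
  }
  list(loss = loss, d_raw = d_raw)
}

#' Euclidean distance-matrix eigenvalue penalty
#'
#' For the matrix of squared interatomic distances with eigenvalues e_1..e_N
#' sorted by descending magnitude, the penalty is
#' sum of the first min(5, N) eigenvalues plus the sum of |e_i| of the rest.
#' A distance set realizable as 3-D points gives exactly zero (rank <= 5 and
#' zero trace); non-embeddable sets are penalized.
#'
#' @param d Either a full symmetric hollow matrix of distances, or a vector of
#'   strict-pair distances (canonical order) with `n` supplied.
#' @param n Number of atoms (needed when `d` is a vector).
#' @param gradient If TRUE, also return the gradient w.r.t. the strict-pair
#'   distances.
#' @return The penalty value, or a list(value, grad) when `gradient = TRUE`.
#' @export
edm_penalty <- function(d, n = NULL, gradient = FALSE) {
  if (is.matrix(d)) {
    n <- nrow(d)
    dm <- d
  } else {
    if (is.null(n)) stop("n is required when d is a pair vector")
    dm <- pair_vector_to_matrix(d, n)
  }
  if (!all(is.finite(dm))) stop("non-finite distances")
  D2 <- dm^2
  if (n == 1L) {
    if (!gradient) return(0)
    return(list(value = 0, grad = numeric(0)))
  }
  eg <- eigen(D2, symmetric = TRUE)
  ord <- order(abs(eg$values), decreasing = TRUE)
  ev <- eg$values[ord]
  vec <- eg$vectors[, ord, drop = FALSE]
  m <- min(5L, n)
  value <- sum(ev[seq_len(m)])
  if (n > m) value <- value + sum(abs(ev[(m + 1L):n]))
  if (!gradient) return(value)
  s <- c(rep(1, m), if (n > m) sign(ev[(m + 1L):n]))
  # dL/dD2 = sum_i s_i v_i v_i^T ; then dD2_ij/dd_ij = 2 d_ij (both triangles)
  G <- vec %*% (s * t(vec))
  idx <- strict_pairs(n)
  grad <- 2 * (G[cbind(idx$i, idx$j)] + G[cbind(idx$j, idx$i)]) *
    dm[cbind(idx$i, idx$j)]
  list(value = value, grad = grad)
}

# L2: sum over roles {reactant, product} and available targets {E,S_vib,S_rot}
# of the batch MAE between predicted and labelled molecular properties.
# pred_list / label_list: per-reaction lists of list(reactant=c(E=,...), ...)
loss_l2_batch <- function(pred_list, label_list) {
  m <- length(pred_list)
  targets <- c("E", "S_vib", "S_rot")
  roles <- c("reactant", "product")
  total <- 0
  dsign <- vector("list", m)  # per reaction, per role: length-3 signed weights
  for (t in seq_len(m)) dsign[[t]] <-
    list(reactant = numeric(3), product = numeric(3))
  for (role in roles) for (k in seq_along(targets)) {
    tgt <- targets[k]
    have <- vapply(seq_len(m), function(t)
      !is.null(label_list[[t]][[role]]) &&
        tgt %in% names(label_list[[t]][[role]]) &&
        is.finite(label_list[[t]][[role]][[tgt]]), logical(1))
    if (!any(have)) next
    idx <- which(have)
    errs <- vapply(idx, function(t)
      pred_list[[t]][[role]][[tgt]] - label_list[[t]][[role]][[tgt]], numeric(1))
    total <- total + mean(abs(errs))
    for (q in seq_along(idx))
      dsign[[idx[q]]][[role]][k] <- sign(errs[q]) / length(idx)
  }
  list(loss = total, dsign = dsign)
}

#' Stratified error report by bond-change category
#'
#' Pools absolute percentage errors over all pairs of all reactions within
#' each bond-change category, and reports the overall molecule-first metrics.
#'
#' @param pred,true Lists of per-reaction strict-pair distance vectors (pm).
#' @param categories List of per-reaction category factors (from
#'   [classify_pairs()]), aligned with the distance vectors.
#' @return An object of class `metric_report`: list with `molecular_mae_pm`,
#'   `molecular_mape_pct`, `per_category` (mean APE % per category present),
#'   `category_counts`, and `n_reactions`.
#' @export
stratified_errors <- function(pred, true, categories) {
  pred <- as_reaction_list(pred); true <- as_reaction_list(true)
  stopifnot(length(pred) == length(true), length(pred) == length(categories))
  cats <- lapply(categories, function(x) if (is.data.frame(x)) x$category else x)
  all_ape <- 100 * unlist(mapply(function(p, t) abs(t - p) / t, pred, true,
                                 SIMPLIFY = FALSE))
  all_cat <- unlist(lapply(cats, as.character))
  present <- intersect(c("none_none", "formation", "breakage", "bond_bond"),
                       unique(all_cat))
  per_category <- vapply(present, function(cc) mean(all_ape[all_cat == cc]),
                         numeric(1))
  counts <- vapply(present, function(cc) sum(all_cat == cc), numeric(1))
  out <- list(molecular_mae_pm = molecular_mae(pred, true),
              molecular_mape_pct = molecular_mape(pred, true),
              per_category = per_category, category_counts = counts,
              pooled_ape_pct = mean(all_ape),
              n_reactions = length(pred))
  class(out) <- "metric_report"
  out
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("Metric report over %d reactions\n", x$n_reactions))
  cat(sprintf("  molecular MAE : %.4f pm\n", x$molecular_mae_pm))
  cat(sprintf("  molecular MAPE: %.4f %%\n", x$molecular_mape_pct))
  cat("  mean APE by bond-change category:\n")
  for (nm in names(x$per_category))
    cat(sprintf("    %-10s %8.4f %%  (%d pairs)\n", nm, x$per_category[[nm]],
                x$category_counts[[nm]]))
  invisible(x)
}
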