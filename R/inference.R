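# Inference: single-model prediction, test-time augmentation by reaction
# reversal, and multi-checkpoint ensembling.

new_distance_prediction <- function(d_pred, d_interp_pm, i, j, provenance) {
  if (is.null(dim(d_pred))) d_pred <- matrix(d_pred, nrow = 1L)
  out <- list(d_pred_pm = d_pred, d_mean_pm = colMeans(d_pred),
              d_interp_pm = d_interp_pm, i = i, j = j,
              provenance = provenance)
  class(out) <- "distance_prediction"
  out
}

#' @export
print.distance_prediction <- function(x, ...) {
  cat(sprintf("<distance_prediction: %d pairs, %d member(s), tta=%s>\n",
              length(x$d_mean_pm), nrow(x$d_pred_pm),
              isTRUE(x$provenance$tta)))
  invisible(x)
}

#' Predict TS distances with a single model
#'
#' d_pred = ratio * d_interp for every strict pair i > j; deterministic given
#' the model parameters.
#'
#' @param r A `reaction` (ts_ref not required).
#' @param model A `psi_model`.
#' @return A `distance_prediction` (distances in pm).
#' @export
predict_single <- function(r, model) {
  fw <- psi_forward(model, r)
  new_distance_prediction(fw$ratios * fw$d_interp_pm, fw$d_interp_pm,
                          fw$i, fw$j,
                          provenance = list(ids = model$id %||% "model",
                                            tta = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict TS distances with test-time augmentation
#'
#' Averages the predicted distances of the forward and the reversed reaction,
#' which removes the direction dependence of the prediction exactly.
#'
#' @inheritParams predict_single
#' @return A `distance_prediction`.
#' @export
predict_tta <- function(r, model) {
  fw <- psi_forward(model, r)
  bw <- psi_forward(model, reverse_reaction(r))
  d <- 0.5 * (fw$ratios * fw$d_interp_pm + bw$ratios * bw$d_interp_pm)
  new_distance_prediction(d, fw$d_interp_pm, fw$i, fw$j,
                          provenance = list(ids = model$id %||% "model",
                                            tta = TRUE))
}

#' Define a model ensemble
#'
#' @param models List of `psi_model` objects (or a single fitted model whose
#'   retained checkpoints should form the ensemble).
#' @param tta Apply test-time augmentation per member (default TRUE).
#' @return An object of class `psi_ensemble`.
#' @export
psi_ensemble <- function(models, tta = TRUE) {
  if (inherits(models, "psi_model")) models <- psi_checkpoints(models)
  stopifnot(length(models) >= 1L,
            all(vapply(models, inherits, logical(1), "psi_model")))
  els <- lapply(models, function(m) m$config$fcfg$elements)
  if (!all(vapply(els, identical, logical(1), els[[1]])))
    stop("ensemble members must share a featurizer element set")
  out <- list(models = models, tta = isTRUE(tta))
  class(out) <- "psi_ensemble"
  out
}

#' @export
print.psi_ensemble <- function(x, ...) {
  cat(sprintf("<psi_ensemble: %d member(s), tta=%s>\n", length(x$models),
              x$tta))
  invisible(x)
}

#' Predict TS distances with a model ensemble
#'
#' Each member's (optionally TTA-averaged) distance set is retained for joint
#' reconstruction; the per-pair mean is exposed for metric evaluation.
#' Members are evaluated independently, so the result does not depend on
#' their order of evaluation.
#'
#' @param r A `reaction`.
#' @param ensemble A `psi_ensemble`.
#' @return A `distance_prediction` with one row of `d_pred_pm` per member.
#' @export
predict_ensemble <- function(r, ensemble) {
  stopifnot(inherits(ensemble, "psi_ensemble"))
  rows <- lapply(seq_along(ensemble$models), function(k) {
    p <- tryCatch(
      if (ensemble$tta) predict_tta(r, ensemble$models[[k]])
      else predict_single(r, ensemble$models[[k]]),
      error = function(e) stop(sprintf("ensemble member %d failed: %s", k,
                                       conditionMessage(e)), call. = FALSE))
    p
  })
  d <- do.call(rbind, lapply(rows, function(p) p$d_pred_pm))
  new_distance_prediction(d, rows[[1]]$d_interp_pm, rows[[1]]$i, rows[[1]]$j,
                          provenance = list(ids = seq_along(ensemble$models),
                                            tta = ensemble$tta))
}

#' @export
predict.psi_ensemble <- function(object, newdata, ...) {
  single <- inherits(newdata, "reaction")
  rl <- if (single) list(newdata) else newdata
  out <- lapply(rl, predict_ensemble, ensemble = object)
  if (single) out[[1]] else out
}

#' Export predictions as a data frame / CSV
#'
#' @param predictions A `distance_prediction` or list thereof.
#' @param ids Optional reaction ids (recycled from names otherwise).
#' @param path Optional CSV output path.
#' @return Data frame with reaction_id, i, j, d_interp_pm, d_mean_pm and one
#'   d_pred_pm column per member.
#' @export
prediction_table <- function(predictions, ids = NULL, path = NULL) {
  if (inherits(predictions, "distance_prediction"))
    predictions <- list(predictions)
  if (is.null(ids)) ids <- names(predictions) %||%
      sprintf("rxn-%03d", seq_along(predictions))
  tabs <- lapply(seq_along(predictions), function(k) {
    p <- predictions[[k]]
    base <- data.frame(reaction_id = ids[k], i = p$i, j = p$j,
                       d_interp_pm = p$d_interp_pm, d_mean_pm = p$d_mean_pm)
    mem <- t(p$d_pred_pm)
    colnames(mem) <- sprintf("d_pred_pm_m%02d", seq_len(nrow(p$d_pred_pm)))
    cbind(base, mem)
  })
  out <- do.call(rbind, tabs)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
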