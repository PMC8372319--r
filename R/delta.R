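# Delta-learning corrector between levels of theory: a multistate model is
# trained on the difference between high-level reference eigenvalues and
# the (frozen) base model's predictions; corrected predictions are the
# element-wise sum of base prediction and predicted delta.

#' Build delta targets from a high-level record and a base prediction
#'
#' delta_i = eps_ref_high,i - eps_base,i on the valid slots of the
#' high-level record (slots matched index-wise, both sides ascending).
#' Masked slots carry 0 and are never read.
#'
#' @param high_ref the high-level \code{eigen_record}.
#' @param base_pred numeric n_max-vector from the frozen base model (or
#'   base-level reference values when using the reference baseline).
#' @param base_mask optional mask of the base side; when supplied it must
#'   match the high-level mask.
#' @return list of class \code{"delta_record"} with \code{values},
#'   \code{mask}, \code{base_tag}, \code{high_tag}.
#' @export
delta_targets <- function(high_ref, base_pred, base_mask = NULL) {
  if (length(base_pred) != length(high_ref$values))
    stop("base prediction and high-level record have different slot counts")
  if (!is.null(base_mask) && !identical(as.logical(base_mask), high_ref$mask))
    stop("mask mismatch between base and high-level records")
  d <- (high_ref$values - base_pred) * high_ref$mask
  structure(list(values = d, mask = high_ref$mask,
                 n_occupied = high_ref$n_occupied,
                 base_tag = "base", high_tag = high_ref$level_tag,
                 id = high_ref$id),
            class = "delta_record")
}

#' Combine base predictions with a predicted delta correction
#'
#' Pure element-wise addition (exact algebra):
#' eps_corrected = eps_base + delta.
#'
#' @param base_pred numeric vector or matrix of base-level predictions (eV).
#' @param delta_pred numeric vector or matrix of predicted deltas, same
#'   shape.
#' @return corrected predictions, same shape.
#' @export
combine <- function(base_pred, delta_pred) {
  if (length(base_pred) != length(delta_pred))
    stop("base and delta predictions have different lengths")
  base_pred + delta_pred
}

#' Fit a delta-learning corrector on top of a frozen base model
#'
#' Trains a multistate-head model on the per-slot differences between
#' high-level reference energies and the base model's predictions
#' (\code{baseline = "ml"}, the default) or the base-level reference
#' energies (\code{baseline = "reference"}). The base model is never
#' updated; stacking happens only at prediction time. The corrector sees
#' only the structure as input, like any multistate model.
#'
#' @param base a fitted \code{pseudoham} base-level model.
#' @param data a \code{ph_dataset} whose structures carry base-level
#'   records.
#' @param records_high list of high-level \code{eigen_record} aligned with
#'   \code{data}.
#' @param subset integer indices of the (small) high-level training subset;
#'   default: all of \code{data}.
#' @param baseline \code{"ml"} or \code{"reference"}.
#' @param encoder,n_hidden,control,split,seed as in \code{\link{pseudoham}}
#'   (the split is over \code{subset}).
#' @return object of class \code{"pseudoham_delta"}.
#' @export
delta_fit <- function(base, data, records_high, subset = NULL,
                      baseline = c("ml", "reference"),
                      encoder = base$model$encoder, n_hidden = NULL,
                      control = train_control(), split = NULL, seed = 1L) {
  baseline <- match.arg(baseline)
  if (is.null(subset)) subset <- seq_along(data$structures)
  structures <- data$structures[subset]
  high <- records_high[subset]
  n_max <- length(high[[1]]$values)
  base_pred <- if (baseline == "ml") {
    predict(base, structures)
  } else {
    t(vapply(data$records[subset], `[[`, numeric(n_max), "values"))
  }
  deltas <- lapply(seq_along(high), function(k)
    delta_targets(high[[k]], base_pred[k, ]))
  tm <- list(ref = t(vapply(deltas, `[[`, numeric(n_max), "values")),
             mask = t(vapply(deltas, function(d) as.numeric(d$mask),
                             numeric(n_max))))
  if (is.null(split))
    split <- split_dataset(length(structures), c(0.8, 0.1, 0.1), seed = seed)
  hc <- head_config("multistate", n_max = n_max, n_hidden = n_hidden)
  mu <- mean_spectrum(tm$ref, tm$mask, split$train)
  model <- init_model(encoder, hc, seed = seed, bias_init = mu)
  graphs <- lapply(structures, mol_graph, encoder = encoder)
  fit <- fit_network(model, graphs, tm, split$train, split$validation, control)
  structure(list(base = base, model = fit$model, baseline = baseline,
                 history = fit$history, best_epoch = fit$best_epoch,
                 best_val = fit$best_val, split = split, subset = subset,
                 n_max = n_max, seed = as.integer(seed)),
            class = "pseudoham_delta")
}

#' @export
print.pseudoham_delta <- function(x, ...) {
  cat(sprintf("Delta-learning corrector (multistate head, %s baseline)\n",
              x$baseline))
  cat(sprintf("  trained on %d molecules; best validation loss %.5g eV^2\n",
              length(x$subset), x$best_val))
  invisible(x)
}

#' Predict corrected (high-level) eigenvalues
#'
#' Runs the frozen base model and the delta corrector on the same
#' structures and adds the two predictions. With the
#' \code{"reference"} baseline, base-level reference values must be
#' supplied via \code{base_values}.
#'
#' @param object a \code{pseudoham_delta}.
#' @param newdata a \code{ph_dataset}, list of structures, or one
#'   structure.
#' @param base_values optional n x n_max matrix of base-level reference
#'   energies (reference baseline only).
#' @param ... unused.
#' @return n x n_max matrix of corrected eigenvalues (eV).
#' @export
predict.pseudoham_delta <- function(object, newdata, base_values = NULL, ...) {
  structures <- if (inherits(newdata, "ph_dataset")) newdata$structures
  else if (inherits(newdata, "atomic_structure")) list(newdata)
  else newdata
  bp <- if (object$baseline == "ml") {
    predict(object$base, structures)
  } else {
    if (is.null(base_values))
      stop("reference baseline requires base_values")
    base_values
  }
  # the corrector's raw (unsorted) output preserves slot identity
  dp_raw <- net_forward(object$model$params, object$model$encoder,
                        object$model$head,
                        assemble_batch(lapply(structures, mol_graph,
                                              encoder = object$model$encoder)))$out
  combine(bp, dp_raw)
}
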