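#' Train the penalty-weight model family
#'
#' Implements the two-pass training procedure behind the model-selection
#' grid. A *primary* model is first trained with plain (halo-weighted)
#' cross-entropy. Its false positives on the training scenes define the
#' penalty regions. Every requested penalty weight is then retrained from the
#' primary model with those regions folded into the weight masks — weight 0
#' nullifies the penalty term, so the weight-0 entry is simply the primary
#' model trained for the same total number of epochs, which keeps the grid
#' comparison free of a training-length confound.
#'
#' @param scenes list of training samples (`image` + `annotation`), e.g.
#'   from [generate_dataset()].
#' @param weights penalty weights to produce models for (default
#'   `c(0, 50, 75)`).
#' @param spec a [fcn_spec()] for the freshly built primary model.
#' @param base_schedule [training_schedule()] for the primary pass.
#' @param retrain_schedule [training_schedule()] for the penalty retraining
#'   pass (typically shorter, with a smaller rate since it starts from a
#'   trained model).
#' @param halo_radius zero-weight ring width (default mark radius).
#' @param exclusion_radius,prob_threshold passed to
#'   [derive_penalty_regions()].
#' @param verbose print per-epoch training lines.
#' @return List with `primary` (the first-pass model), `models` (named list
#'   keyed by penalty weight), `penalties` (per-scene penalty masks) and
#'   `logs` (per-model loss logs).
#' @export
train_penalty_grid <- function(scenes, weights = c(0, 50, 75),
                               spec = fcn_spec(),
                               base_schedule = training_schedule(),
                               retrain_schedule = base_schedule,
                               halo_radius = NULL,
                               exclusion_radius = NULL,
                               prob_threshold = 0.5,
                               verbose = FALSE) {
  if (length(scenes) == 0) stopf("`scenes` is empty")
  base_set <- make_training_set(scenes, halo_radius = halo_radius)
  fit0 <- fcn_train(fcn_build(spec, seed = base_schedule$seed), base_set,
                    base_schedule, verbose = verbose)
  excl <- exclusion_radius %||% scenes[[1]]$annotation$mark_diameter
  penalties <- lapply(scenes, function(s)
    derive_penalty_regions(fcn_predict(fit0$model, s$image), s$annotation,
                           exclusion_radius = excl,
                           prob_threshold = prob_threshold))
  models <- list()
  logs <- list(primary = fit0$log)
  for (wt in weights) {
    tset <- make_training_set(scenes, penalty_masks = penalties,
                              penalty_weight = wt, halo_radius = halo_radius)
    fit <- fcn_train(fit0$model, tset, retrain_schedule, verbose = verbose)
    models[[as.character(wt)]] <- fit$model
    logs[[as.character(wt)]] <- fit$log
  }
  list(primary = fit0$model, models = models, penalties = penalties,
       logs = logs)
}
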