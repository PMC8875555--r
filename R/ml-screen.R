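# Dataset assembly, repeated stratified cross-validation, MCC-based model
# selection, final-model training, library screening with nearest-active
# annotation, and the external-set validation workflow (similarity
# exclusion of training actives plus their linked decoys, then retrain and
# call).

#' Assemble a labelled fingerprint dataset
#'
#' @param actives,inactives `"molecule_library"`-style data.frames with
#'   `molecule_id` and `smiles`; ids must be disjoint between classes.
#' @param fingerprint_kind fingerprint used as the feature matrix.
#' @param seed seed for the row shuffle.
#' @return list of class `"ds_dataset"`: `x` (bit matrix), `y` (1 = active),
#'   `ids`, `fingerprint_kind`.
#' @export
assemble_dataset <- function(actives, inactives, fingerprint_kind = "ECFP4",
                             seed = 1L) {
  if (nrow(actives) == 0L || nrow(inactives) == 0L) {
    stop("both classes must be non-empty")
  }
  if (length(intersect(actives$molecule_id, inactives$molecule_id)) > 0L) {
    stop("molecule ids must be disjoint between classes")
  }
  smiles <- c(stats::setNames(actives$smiles, actives$molecule_id),
              stats::setNames(inactives$smiles, inactives$molecule_id))
  y <- c(rep(1L, nrow(actives)), rep(0L, nrow(inactives)))
  fp <- fingerprint_matrix(smiles, fingerprint_kind)
  set.seed(seed)
  ord <- sample.int(length(y))
  structure(list(x = unclass(fp)[ord, , drop = FALSE], y = y[ord],
                 ids = names(smiles)[ord],
                 fingerprint_kind = fingerprint_kind),
            class = "ds_dataset")
}

# Stratified fold assignment: within each class, a shuffled 1..k cycle.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    ix <- which(y == cls)
    if (length(ix) < k) stop("class too small for ", k, "-fold stratification")
    fold[ix] <- sample(rep_len(seq_len(k), length(ix)))
  }
  fold
}

#' Repeated stratified k-fold cross-validation
#'
#' `runs` independent repartitions of stratified `k`-fold cross-validation;
#' each fold is scored on the held-out part with [compute_metrics()] at the
#' p >= 0.5 decision rule, and per-metric means and standard deviations are
#' taken over all `k x runs` fold evaluations.
#'
#' @param dataset a `"ds_dataset"`.
#' @param spec a [model_spec()].
#' @param k folds (default 5).
#' @param runs independent repartitions (default 5).
#' @return object of class `"cv_report"`: `folds` (one row per fold
#'   evaluation), `summary` (mean and SD per metric), `spec`.
#' @export
cross_validate <- function(dataset, spec, k = 5L, runs = 5L) {
  x <- dataset$x; y <- dataset$y
  rows <- list()
  for (run in seq_len(runs)) {
    set.seed(spec$seed + 7919L * run)
    fold <- stratified_folds(y, k)
    for (f in seq_len(k)) {
      test <- fold == f
      fit_spec <- spec
      fit_spec$seed <- spec$seed + 7919L * run + f
      fit <- fit_classifier(x[!test, , drop = FALSE], y[!test], fit_spec)
      p <- predict_classifier(fit, x[test, , drop = FALSE])
      ms <- compute_metrics(y[test], as.integer(p >= 0.5), p)
      rows[[length(rows) + 1L]] <- data.frame(
        run = run, fold = f, tp = ms$tp, tn = ms$tn, fp = ms$fp, fn = ms$fn,
        acc = ms$acc, auc = ms$auc, mcc = ms$mcc)
    }
  }
  folds <- do.call(rbind, rows)
  summ <- data.frame(
    metric = c("acc", "auc", "mcc"),
    mean = c(mean(folds$acc), mean(folds$auc), mean(folds$mcc)),
    sd = c(stats::sd(folds$acc), stats::sd(folds$auc), stats::sd(folds$mcc))
  )
  structure(list(folds = folds, summary = summ, spec = spec,
                 k = k, runs = runs),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<cv_report %s/%s: ACC %.3f+-%.3f AUC %.3f+-%.3f MCC %.3f+-%.3f (%dx%d folds)>\n",
              x$spec$algorithm, x$spec$fingerprint_kind,
              s$mean[1], s$sd[1], s$mean[2], s$sd[2], s$mean[3], s$sd[3],
              x$k, x$runs))
  invisible(x)
}

cv_mean_mcc <- function(report) {
  report$summary$mean[report$summary$metric == "mcc"]
}

#' Select the best model by mean cross-validated MCC
#'
#' Exact ties are broken toward the simpler algorithm (fixed order
#' NB < Logit < KNN < DT < RF < XGBoost < MLP).
#'
#' @param reports list of `"cv_report"` objects.
#' @return the winning report's [model_spec()].
#' @export
select_model <- function(reports) {
  if (length(reports) == 0L) stop("no reports supplied")
  mccs <- vapply(reports, cv_mean_mcc, numeric(1))
  simp <- match(vapply(reports, function(r) r$spec$algorithm, character(1)),
                SIMPLICITY_ORDER)
  reports[[order(-mccs, simp)[1L]]]$spec
}

#' Train the final screening model on the full dataset
#'
#' @param dataset a `"ds_dataset"`.
#' @param spec a [model_spec()].
#' @return object of class `"screen_model"`: the fitted handle, the spec, a
#'   manifest (spec, data hash, package version), and the training actives'
#'   ids/fingerprints for nearest-active annotation.
#' @export
train_final <- function(dataset, spec) {
  fit <- fit_classifier(dataset$x, dataset$y, spec)
  active_rows <- which(dataset$y == 1L)
  afp <- dataset$x[active_rows, , drop = FALSE]
  rownames(afp) <- dataset$ids[active_rows]
  attr(afp, "kind") <- dataset$fingerprint_kind
  class(afp) <- c("fp_matrix", class(afp))
  manifest <- list(
    algorithm = spec$algorithm, fingerprint_kind = spec$fingerprint_kind,
    hyperparameters = spec$hyperparameters, seed = spec$seed,
    n_actives = sum(dataset$y == 1L), n_inactives = sum(dataset$y == 0L),
    data_hash = digest::digest(list(dataset$x, dataset$y, dataset$ids)),
    package_version = as.character(utils::packageVersion("dualscreen"))
  )
  structure(list(fit = fit, spec = spec, manifest = manifest,
                 active_fps = afp),
            class = "screen_model")
}

#' @export
print.screen_model <- function(x, ...) {
  cat(sprintf("<screen_model %s/%s trained on %d actives + %d inactives>\n",
              x$spec$algorithm, x$spec$fingerprint_kind,
              x$manifest$n_actives, x$manifest$n_inactives))
  invisible(x)
}

#' Screen a library with a trained model
#'
#' Every molecule is scored with the model's positive-class probability;
#' molecules at `p >= p_threshold` are returned sorted by decreasing
#' probability (ties by id), each annotated with its nearest training
#' active and the corresponding maximum TC.
#'
#' @param model a `"screen_model"` from [train_final()].
#' @param library data.frame with `molecule_id` and `smiles`.
#' @param p_threshold probability threshold (default 0.5, inclusive).
#' @return data.frame with `molecule_id`, `probability`,
#'   `nearest_active_id`, `nearest_active_tc`.
#' @export
screen_library <- function(model, library, p_threshold = 0.5) {
  if (nrow(library) == 0L) stop("empty library")
  fp <- fingerprint_matrix(stats::setNames(library$smiles,
                                           library$molecule_id),
                           model$spec$fingerprint_kind)
  p <- predict_classifier(model$fit, unclass(fp))
  keep <- which(p >= p_threshold)
  if (length(keep) == 0L) {
    return(data.frame(molecule_id = character(0), probability = numeric(0),
                      nearest_active_id = character(0),
                      nearest_active_tc = numeric(0)))
  }
  tc <- tanimoto_matrix(fp[keep, , drop = FALSE], model$active_fps)
  act_ids <- rownames(model$active_fps)
  nn <- vapply(seq_len(nrow(tc)), function(i) {
    order(-tc[i, ], act_ids)[1L]
  }, integer(1))
  out <- data.frame(
    molecule_id = library$molecule_id[keep],
    probability = p[keep],
    nearest_active_id = act_ids[nn],
    nearest_active_tc = tc[cbind(seq_along(nn), nn)],
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$probability, out$molecule_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' External-set validation with similarity exclusion
#'
#' Training actives with maximum TC at or above `tc_exclusion` to any
#' external molecule are removed, together with exactly their linked
#' decoys; the model is retrained on the remaining data and the external
#' set is called at `p >= p_threshold`, tabulating true and false
#' positives against the supplied annotations.
#'
#' @param actives training actives (`molecule_id`, `smiles`).
#' @param decoy_set the `"decoy_set"` linking decoys to actives.
#' @param external data.frame of external molecules (`molecule_id`,
#'   `smiles`).
#' @param annotations logical vector along `external` (or character vector
#'   of its true-binder ids) marking true binders.
#' @param spec a [model_spec()] for the retrained model.
#' @param tc_exclusion exclusion threshold (default 0.6, inclusive).
#' @param p_threshold call threshold (default 0.5, inclusive).
#' @param seed seed for dataset assembly.
#' @return list of class `"external_validation"`: `excluded_actives`,
#'   `n_decoys_removed`, `calls` (per-molecule table), `tp`, `fp`,
#'   `n_called`.
#' @export
external_validation <- function(actives, decoy_set, external, annotations,
                                spec = model_spec("Logit"),
                                tc_exclusion = 0.6, p_threshold = 0.5,
                                seed = 1L) {
  if (is.character(annotations)) {
    annotations <- external$molecule_id %in% annotations
  }
  stopifnot(length(annotations) == nrow(external))
  kind <- spec$fingerprint_kind
  fa <- fingerprint_matrix(stats::setNames(actives$smiles,
                                           actives$molecule_id), kind)
  fe <- fingerprint_matrix(stats::setNames(external$smiles,
                                           external$molecule_id), kind)
  tc_ae <- tanimoto_matrix(fa, fe)
  excluded <- actives$molecule_id[apply(tc_ae, 1L, max) >= tc_exclusion]
  kept_actives <- actives[!actives$molecule_id %in% excluded, , drop = FALSE]
  if (nrow(kept_actives) == 0L) {
    stop("similarity exclusion removed every training active")
  }
  inactives <- decoy_records(decoy_set)
  n_before <- nrow(inactives)
  inactives <- inactives[!inactives$active_id %in% excluded, , drop = FALSE]
  n_removed <- n_before - nrow(inactives)

  dataset <- assemble_dataset(kept_actives, inactives, kind, seed = seed)
  model <- train_final(dataset, spec)
  hits <- screen_library(model, external, p_threshold = 0)
  p <- hits$probability[match(external$molecule_id, hits$molecule_id)]
  called <- p >= p_threshold
  calls <- data.frame(
    molecule_id = external$molecule_id, probability = p,
    called = called, true_binder = annotations, stringsAsFactors = FALSE
  )
  structure(list(
    excluded_actives = excluded, n_decoys_removed = n_removed,
    calls = calls,
    tp = sum(called & annotations), fp = sum(called & !annotations),
    n_called = sum(called)
  ), class = "external_validation")
}

#' @export
print.external_validation <- function(x, ...) {
  cat(sprintf("<external_validation: %d actives excluded (+%d decoys), %d called: %d TP / %d FP>\n",
              length(x$excluded_actives), x$n_decoys_removed, x$n_called,
              x$tp, x$fp))
  invisible(x)
}
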