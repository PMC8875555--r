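# Dataset assembly, cross-validation, model selection, screening and the
# external-validation bookkeeping.

# small separable benchmark shared across the blocks in this file
local_benchmark <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      bm <- generate_screening_benchmark(
        benchmark_spec(n_actives = 20, n_background = 80, n_planted = 8,
                       seed = 404))
      pool <- generate_decoy_pool(250, seed = 405)
      ds <- generate_decoys(bm$actives, pool, n_per_active = 8)
      cache <<- list(bm = bm, pool = pool, ds = ds,
                     inactives = decoy_records(ds))
    }
    cache
  }
})

test_that("assemble_dataset shapes, labels and guards", {
  fx <- local_benchmark()
  d <- assemble_dataset(fx$bm$actives, fx$inactives, "ECFP4", seed = 1)
  expect_equal(nrow(d$x), nrow(fx$bm$actives) + nrow(fx$inactives))
  expect_equal(ncol(d$x), 1024L)
  expect_equal(sum(d$y), nrow(fx$bm$actives))
  expect_setequal(d$ids, c(fx$bm$actives$molecule_id,
                           fx$inactives$molecule_id))
  dup <- fx$inactives
  dup$molecule_id[1] <- fx$bm$actives$molecule_id[1]
  expect_error(assemble_dataset(fx$bm$actives, dup), "disjoint")
  expect_error(assemble_dataset(fx$bm$actives[0, ], fx$inactives),
               "non-empty")
})

test_that("cross-validation separates planted structure and is deterministic", {
  fx <- local_benchmark()
  d <- assemble_dataset(fx$bm$actives, fx$inactives, "ECFP4", seed = 2)
  r1 <- cross_validate(d, model_spec("Logit", seed = 7), k = 5, runs = 2)
  expect_equal(nrow(r1$folds), 10L)
  expect_gte(r1$summary$mean[r1$summary$metric == "mcc"], 0.95)
  r2 <- cross_validate(d, model_spec("Logit", seed = 7), k = 5, runs = 2)
  expect_identical(r1$folds, r2$folds)

  # fold means reconcile with the pooled confusion counts
  pooled_acc <- with(r1$folds, sum(tp + tn) / sum(tp + tn + fp + fn))
  expect_equal(mean(r1$folds$acc), pooled_acc, tolerance = 0.02)
})

test_that("label permutation drives MCC to its null", {
  fx <- local_benchmark()
  d <- assemble_dataset(fx$bm$actives, fx$inactives, "ECFP4", seed = 3)
  set.seed(99)
  d$y <- sample(d$y)
  r <- cross_validate(d, model_spec("NB", seed = 11), k = 5, runs = 2)
  mcc <- r$summary$mean[r$summary$metric == "mcc"]
  mcc_sd <- r$summary$sd[r$summary$metric == "mcc"]
  expect_lt(abs(mcc), max(3 * mcc_sd / sqrt(nrow(r$folds)), 0.15))
})

test_that("model selection maximizes MCC with the simplicity tie-break", {
  mk_report <- function(alg, mcc) {
    structure(list(
      folds = NULL,
      summary = data.frame(metric = c("acc", "auc", "mcc"),
                           mean = c(0.9, 0.9, mcc), sd = 0),
      spec = model_spec(alg), k = 5, runs = 5), class = "cv_report")
  }
  # the CV-metric pattern of the study: MLP edges out Logit on raw MCC
  got <- select_model(list(mk_report("Logit", 0.863), mk_report("MLP", 0.883)))
  expect_equal(got$algorithm, "MLP")
  # exact tie falls to the simpler model
  got2 <- select_model(list(mk_report("MLP", 0.85), mk_report("Logit", 0.85)))
  expect_equal(got2$algorithm, "Logit")
  got3 <- select_model(list(mk_report("RF", 0.5)))
  expect_equal(got3$algorithm, "RF")
  expect_error(select_model(list()), "no reports")
})

test_that("every classifier backend fits, predicts probabilities and reruns identically", {
  fx <- local_benchmark()
  d <- assemble_dataset(fx$bm$actives, fx$inactives, "ECFP4", seed = 4)
  for (alg in c("KNN", "NB", "Logit", "DT", "RF", "MLP", "XGBoost")) {
    spec <- model_spec(alg, seed = 21)
    fit <- fit_classifier(d$x, d$y, spec)
    p <- predict_classifier(fit, d$x)
    expect_true(all(p >= 0 & p <= 1), info = alg)
    expect_gt(mean(p[d$y == 1]), 0.5, label = paste(alg, "mean active p"))
    fit2 <- fit_classifier(d$x, d$y, spec)
    expect_equal(predict_classifier(fit2, d$x), p, tolerance = 1e-12,
                 info = alg)
  }
})

test_that("train_final writes an honest manifest", {
  fx <- local_benchmark()
  d <- assemble_dataset(fx$bm$actives, fx$inactives, "ECFP4", seed = 5)
  m <- train_final(d, model_spec("NB", seed = 1))
  expect_equal(m$manifest$n_actives, nrow(fx$bm$actives))
  d2 <- d
  d2$x[1, 1] <- 1L - d2$x[1, 1]
  m2 <- train_final(d2, model_spec("NB", seed = 1))
  expect_false(identical(m$manifest$data_hash, m2$manifest$data_hash))
})

test_that("screening sorts, thresholds inclusively and annotates neighbours", {
  fx <- local_benchmark()
  d <- assemble_dataset(fx$bm$actives, fx$inactives, "ECFP4", seed = 6)
  model <- train_final(d, model_spec("Logit", seed = 2))
  all_out <- screen_library(model, fx$bm$library, p_threshold = 0)
  expect_equal(nrow(all_out), nrow(fx$bm$library))   # threshold 0 keeps all
  expect_true(!is.unsorted(rev(all_out$probability)))
  hits <- screen_library(model, fx$bm$library, p_threshold = 0.5)
  expect_true(all(hits$probability >= 0.5))
  # monotone in the threshold
  stricter <- screen_library(model, fx$bm$library, p_threshold = 0.6)
  expect_lte(nrow(stricter), nrow(hits))
  # nearest-active annotation against training actives only
  expect_true(all(hits$nearest_active_id %in% fx$bm$actives$molecule_id))
  expect_true(all(hits$nearest_active_tc >= 0 & hits$nearest_active_tc <= 1))
  # a molecule at threshold exactly is kept (comparison is >=)
  thr <- all_out$probability[3]
  at_thr <- screen_library(model, fx$bm$library, p_threshold = thr)
  expect_true(all_out$molecule_id[3] %in% at_thr$molecule_id)
  expect_error(screen_library(model, fx$bm$library[0, ]), "empty")
})

test_that("external validation excludes similar actives and their decoys", {
  fx <- local_benchmark()
  actives <- fx$bm$actives
  # external set: one near-duplicate of the first active (TC >= 0.6) plus
  # chemically disjoint drugs
  target <- actives$molecule_id[1]
  near <- actives$smiles[1]
  external <- data.frame(
    molecule_id = c("DRUG1", "DRUG2", "DRUG3"),
    smiles = c(near, "CC(=O)Nc1ccc(O)cc1", "CN1CCC(O)CC1"),
    stringsAsFactors = FALSE
  )
  ev <- external_validation(actives, fx$ds, external,
                            annotations = c(TRUE, FALSE, FALSE),
                            spec = model_spec("Logit", seed = 3))
  expect_true(target %in% ev$excluded_actives)
  n_linked <- sum(dualscreen::decoy_records(fx$ds)$active_id %in%
                    ev$excluded_actives)
  expect_equal(ev$n_decoys_removed, n_linked)
  expect_equal(nrow(ev$calls), 3L)
  # the planted near-duplicate external binder is recovered at p >= 0.5
  expect_true(ev$calls$called[ev$calls$molecule_id == "DRUG1"])
  expect_gte(ev$tp, 1)

  # chemically disjoint external set leaves the training data untouched
  far <- external[2:3, ]
  ev2 <- external_validation(actives, fx$ds, far,
                             annotations = c(FALSE, FALSE),
                             spec = model_spec("NB", seed = 3))
  expect_length(ev2$excluded_actives, 0)
  expect_equal(ev2$n_decoys_removed, 0)
  expect_equal(ev2$tp, 0)   # all-negative annotations cannot yield TPs
})
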