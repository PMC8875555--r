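# Stage orchestration: a serializable configuration whose defaults are the
# study's printed operating points, per-stage drivers reading and writing
# the documented file formats, and a JSON run manifest for provenance.

PIPELINE_STAGES <- c("simulate", "curate", "decoys", "train", "screen",
                     "validate-external", "sea", "fit-inhibition", "fit-dsf")

#' Pipeline configuration
#'
#' Nested list of stage parameters. The defaults are the analysis'
#' operating points: 500 Da / 500 nM curation with clustering at TC 0.6,
#' 40 decoys per active under the 0.6/0.8 decoy similarity ceilings,
#' 5-fold x 5-run cross-validation, screening at p >= 0.5, external
#' exclusion at TC >= 0.6, 100 Monte-Carlo cycles at a 5% noise floor, and
#' the 40-68 deg C melt-fit window.
#'
#' @param ... named overrides, e.g. `screening = list(p_threshold = 0.6)`.
#' @param seed global seed, expanded deterministically into per-stage seeds.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(..., seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    curation = list(mw_max = 500, potency_max_nM = 500,
                    cluster_tc_cutoff = 0.6),
    decoys = list(n_per_active = 40L, tc_active_max = 0.6,
                  tc_decoy_max = 0.8),
    training = list(k = 5L, runs = 5L, fingerprint_kind = "ECFP4",
                    algorithms = c("NB", "Logit", "KNN")),
    screening = list(p_threshold = 0.5),
    external = list(tc_exclusion = 0.6),
    inhibition = list(n_cycles = 100L, rel_noise = 0.05,
                      substrate_conc = 1e-3, km = 1e-3),
    dsf = list(window = c(40, 68)),
    benchmark = list(n_actives = 60L, n_background = 500L, n_planted = 20L,
                     pool_size = 1500L)
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    bad <- !nm %in% names(cfg)
    if (bad) stop("unknown config section: ", nm)
    if (is.list(cfg[[nm]])) {
      unknown <- setdiff(names(overrides[[nm]]), names(cfg[[nm]]))
      if (length(unknown)) {
        stop("unknown config field: ", nm, "$", unknown[1])
      }
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], overrides[[nm]])
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  # normalize count-valued fields so configs compare identically after a
  # JSON round-trip
  for (f in list(c("decoys", "n_per_active"), c("training", "k"),
                 c("training", "runs"), c("inhibition", "n_cycles"),
                 c("benchmark", "n_actives"), c("benchmark", "n_background"),
                 c("benchmark", "n_planted"), c("benchmark", "pool_size"))) {
    cfg[[f[1]]][[f[2]]] <- as.integer(cfg[[f[1]]][[f[2]]])
  }
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$curation$mw_max > 0, cfg$curation$potency_max_nM > 0,
    cfg$curation$cluster_tc_cutoff >= 0, cfg$curation$cluster_tc_cutoff <= 1,
    cfg$decoys$n_per_active > 0,
    cfg$decoys$tc_active_max >= 0, cfg$decoys$tc_active_max <= 1,
    cfg$decoys$tc_decoy_max >= 0, cfg$decoys$tc_decoy_max <= 1,
    cfg$training$k >= 2, cfg$training$runs >= 1,
    cfg$screening$p_threshold >= 0, cfg$screening$p_threshold <= 1,
    cfg$external$tc_exclusion >= 0, cfg$external$tc_exclusion <= 1,
    cfg$inhibition$n_cycles > 0, cfg$inhibition$rel_noise >= 0,
    cfg$dsf$window[1] < cfg$dsf$window[2]
  )
  invisible(cfg)
}

#' Serialize / restore a pipeline configuration
#'
#' @param cfg a `"pipeline_config"`.
#' @param path JSON file path.
#' @return `read_config()` returns the restored configuration.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, c(raw[setdiff(names(raw), "seed")],
                             list(seed = raw$seed)))
}

# deterministic per-stage seed from the global seed (kept below 2^31)
stage_seed <- function(cfg, stage) {
  i <- match(stage, PIPELINE_STAGES)
  as.integer((as.numeric(cfg$seed) * 1009 + i * 104729) %% 2147483647)
}

write_manifest <- function(out_dir, stage, cfg, inputs = character(0),
                           counts = list()) {
  manifest <- list(
    stage = stage,
    config_hash = digest::digest(unclass(cfg)),
    seed = cfg$seed, stage_seed = stage_seed(cfg, stage),
    inputs = lapply(stats::setNames(nm = inputs), function(f) {
      if (file.exists(f)) digest::digest(file = f) else NA_character_
    }),
    counts = counts,
    package_version = as.character(utils::packageVersion("dualscreen")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Run one pipeline stage
#'
#' Reads the documented artifacts of earlier stages from `dir`, executes
#' the stage with the configured parameters and the stage's derived seed,
#' writes the stage outputs plus a JSON manifest (config hash, seeds,
#' input-file hashes, record counts) back into `dir`, and returns the
#' stage's main result invisibly.
#'
#' @param cfg a [pipeline_config()].
#' @param stage one of `simulate`, `curate`, `decoys`, `train`, `screen`,
#'   `validate-external`, `sea`, `fit-inhibition`, `fit-dsf`.
#' @param dir run directory.
#' @return the stage result, invisibly.
#' @export
run_stage <- function(cfg, stage = PIPELINE_STAGES, dir = ".") {
  stage <- match.arg(stage)
  validate_config(cfg)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(dir, f)
  need <- function(f) {
    if (!file.exists(pth(f))) {
      stop("missing upstream artifact for stage '", stage, "': ", f)
    }
    pth(f)
  }
  sseed <- stage_seed(cfg, stage)
  result <- switch(stage,
    simulate = {
      bm <- generate_screening_benchmark(benchmark_spec(
        n_actives = cfg$benchmark$n_actives,
        n_background = cfg$benchmark$n_background,
        n_planted = cfg$benchmark$n_planted, seed = sseed))
      pool <- generate_decoy_pool(cfg$benchmark$pool_size, seed = sseed)
      write_library(bm$actives, pth("raw_actives.tsv"))
      utils::write.table(bm$library, pth("library.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      utils::write.table(bm$truth, pth("truth.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      utils::write.table(pool, pth("pool.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      write_manifest(dir, stage, cfg,
                     counts = list(actives = nrow(bm$actives),
                                   library = nrow(bm$library),
                                   pool = nrow(pool)))
      bm
    },
    curate = {
      lib <- read_library(need("raw_actives.tsv"), "smiles-table")
      ccfg <- curation_config(cfg$curation$mw_max, cfg$curation$potency_max_nM,
                              cfg$curation$cluster_tc_cutoff)
      filt <- filter_library(lib, ccfg)
      reps <- select_representative_actives(filt, ccfg,
                                            cfg$training$fingerprint_kind)
      write_library(reps, pth("actives.tsv"))
      write_manifest(dir, stage, cfg, inputs = pth("raw_actives.tsv"),
                     counts = list(read = nrow(lib),
                                   skipped = attr(lib, "n_skipped"),
                                   after_filter = nrow(filt),
                                   representatives = nrow(reps)))
      reps
    },
    decoys = {
      actives <- read_library(need("actives.tsv"), "smiles-table",
                              role = "active")
      pool <- read_tsv_(need("pool.tsv"))
      ds <- generate_decoys(actives, pool,
                            n_per_active = cfg$decoys$n_per_active,
                            tc_active_max = cfg$decoys$tc_active_max,
                            tc_decoy_max = cfg$decoys$tc_decoy_max,
                            fingerprint_kind = cfg$training$fingerprint_kind)
      write_decoy_set(ds, pth("decoys.tsv"), pth("decoy_audit.tsv"))
      write_manifest(dir, stage, cfg,
                     inputs = c(pth("actives.tsv"), pth("pool.tsv")),
                     counts = list(actives = nrow(actives),
                                   decoys = nrow(decoy_records(ds)),
                                   under_filled = length(ds$shortfalls)))
      ds
    },
    train = {
      actives <- read_library(need("actives.tsv"), "smiles-table",
                              role = "active")
      inactives <- read_tsv_(need("decoys.tsv"))
      dataset <- assemble_dataset(actives, inactives,
                                  cfg$training$fingerprint_kind,
                                  seed = sseed)
      reports <- lapply(cfg$training$algorithms, function(alg) {
        cross_validate(dataset,
                       model_spec(alg, cfg$training$fingerprint_kind,
                                  seed = sseed),
                       k = cfg$training$k, runs = cfg$training$runs)
      })
      best <- select_model(reports)
      model <- train_final(dataset, best)
      saveRDS(model, pth("model.rds"))
      cv_tab <- do.call(rbind, lapply(reports, function(r) {
        data.frame(algorithm = r$spec$algorithm,
                   fingerprint = r$spec$fingerprint_kind,
                   acc = r$summary$mean[1], acc_sd = r$summary$sd[1],
                   auc = r$summary$mean[2], auc_sd = r$summary$sd[2],
                   mcc = r$summary$mean[3], mcc_sd = r$summary$sd[3])
      }))
      utils::write.table(cv_tab, pth("cv_metrics.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      jsonlite::write_json(model$manifest, pth("model_manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      write_manifest(dir, stage, cfg,
                     inputs = c(pth("actives.tsv"), pth("decoys.tsv")),
                     counts = list(selected = best$algorithm))
      list(reports = reports, model = model)
    },
    screen = {
      model <- readRDS(need("model.rds"))
      lib <- read_tsv_(need("library.tsv"))
      hits <- screen_library(model, lib,
                             p_threshold = cfg$screening$p_threshold)
      utils::write.table(hits, pth("screen_hits.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      write_manifest(dir, stage, cfg,
                     inputs = c(pth("model.rds"), pth("library.tsv")),
                     counts = list(library = nrow(lib), hits = nrow(hits)))
      hits
    },
    sea = {
      actives <- read_library(need("actives.tsv"), "smiles-table")
      hits <- read_tsv_(need("screen_hits.tsv"))
      lib <- read_tsv_(need("library.tsv"))
      kind <- cfg$training$fingerprint_kind
      fa <- fingerprint_matrix(stats::setNames(actives$smiles,
                                               actives$molecule_id), kind)
      within <- tc_distribution(fa, label = "within actives")
      export_tc_distribution(within, pth("sea_within_actives.tsv"))
      result <- list(within = within)
      if (nrow(hits) > 0) {
        hs <- lib$smiles[match(hits$molecule_id, lib$molecule_id)]
        fh <- fingerprint_matrix(stats::setNames(hs, hits$molecule_id), kind)
        cross <- tc_distribution(fh, fa, label = "hits vs actives")
        export_tc_distribution(cross, pth("sea_hits_vs_actives.tsv"))
        result$cross <- cross
      }
      write_manifest(dir, stage, cfg,
                     inputs = c(pth("actives.tsv"), pth("screen_hits.tsv")))
      result
    },
    `validate-external` = {
      stop("the external-validation stage needs an external set and ",
           "annotations; call external_validation() directly")
    },
    `fit-inhibition` = {
      dr <- read_tsv_(need("dose_response.tsv"))
      cond <- assay_conditions(substrate_conc = cfg$inhibition$substrate_conc,
                               km = cfg$inhibition$km)
      mc <- monte_carlo_ki(dr$concentration_M, dr$response, cond,
                           n_cycles = cfg$inhibition$n_cycles,
                           rel_noise = cfg$inhibition$rel_noise,
                           seed = sseed)
      jsonlite::write_json(unclass(mc), pth("inhibition_fit.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      write_manifest(dir, stage, cfg, inputs = pth("dose_response.tsv"))
      mc
    },
    `fit-dsf` = {
      mc <- read_tsv_(need("melt_curve.tsv"))
      fit <- fit_boltzmann_tm(mc$temperature_C, mc$fluorescence,
                              window = cfg$dsf$window)
      jsonlite::write_json(unclass(fit), pth("tm_fit.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      write_manifest(dir, stage, cfg, inputs = pth("melt_curve.tsv"))
      fit
    }
  )
  invisible(result)
}

# strict TSV reader: no comment or quote interpretation, so SMILES
# containing '#' or quotes survive
read_tsv_ <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "", stringsAsFactors = FALSE)
}
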