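# Synthetic benchmark generation. Actives are built combinatorially from a
# shared scaffold (default: a benzenesulfonamide, the zinc-binding
# pharmacophore of carbonic anhydrase inhibitors) plus sampled substituent
# chains, which guarantees elevated within-class Tanimoto similarity; the
# background library and decoy candidate pool are drawn from distinct
# scaffold families. Dose-response and melt curves are simulated from the
# same models the fitting code assumes. Every generator is a pure function
# of its spec and seed.

# substituent chain units: `internal` units continue a chain, `terminal`
# units close it; concatenation of any internal prefix with one terminal
# unit is a valid SMILES continuation
SUBSTITUENT_INTERNAL <- c("C", "CC", "CO", "CN", "C(C)", "CCO", "C(=O)N")
SUBSTITUENT_TERMINAL <- c("C", "N", "O", "Cl", "F", "C(F)(F)F", "OC",
                          "N(C)C", "c2ccccc2", "C2CCCCC2", "C(=O)NC", "C#N")

# background scaffold families (sprintf templates with one substituent slot)
BACKGROUND_TEMPLATES <- c(
  "c1cc(%s)ccc1",            # benzene
  "c1cc(%s)ccn1",            # pyridine
  "C1CCC(%s)CC1",            # cyclohexane
  "c1ccc3cc(%s)ccc3c1",      # naphthalene (ring index 3: substituents use 2)
  "c1cc(%s)co1",             # furan
  "c1cc(%s)cs1",             # thiophene
  "C1CCN(%s)CC1",            # piperidine (N-substituted)
  "c1nc(%s)ccn1"             # pyrimidine
)

# all substituent chains of the given internal depths, as a deterministic
# enumeration the samplers draw from without replacement
enumerate_substituents <- function(internal = SUBSTITUENT_INTERNAL,
                                   terminal = SUBSTITUENT_TERMINAL,
                                   max_internal = 2L) {
  prefixes <- ""
  acc <- character(0)
  for (d in 0:max_internal) {
    acc <- c(acc, as.vector(outer(prefixes, terminal, paste0)))
    prefixes <- as.vector(outer(prefixes, internal, paste0))
  }
  unique(acc)
}

#' Benchmark specification for the synthetic screening problem
#'
#' @param n_actives number of scaffold-derived actives (default 60).
#' @param n_background number of background library molecules (default 500).
#' @param n_planted scaffold-derived actives planted in the screening
#'   library, disjoint from the training actives (default 20).
#' @param scaffold_smiles sprintf template (one `%s` slot) for the active
#'   scaffold; default is a para-substituted benzenesulfonamide.
#' @param substituents substituent vocabulary, see
#'   `enumerate_substituents()`.
#' @param potency_bounds_nM log-uniform potency sampling bounds for the
#'   actives (default 1-500 nM).
#' @param seed integer seed.
#' @return list of class `"benchmark_spec"`.
#' @export
benchmark_spec <- function(n_actives = 60L, n_background = 500L,
                           n_planted = 20L,
                           scaffold_smiles = "NS(=O)(=O)c1ccc(%s)cc1",
                           substituents = enumerate_substituents(),
                           potency_bounds_nM = c(1, 500), seed = 1L) {
  stopifnot(n_actives > 0, n_background > 0, n_planted >= 0,
            all(potency_bounds_nM > 0),
            potency_bounds_nM[1] < potency_bounds_nM[2])
  structure(list(n_actives = as.integer(n_actives),
                 n_background = as.integer(n_background),
                 n_planted = as.integer(n_planted),
                 scaffold_smiles = scaffold_smiles,
                 substituents = substituents,
                 potency_bounds_nM = potency_bounds_nM,
                 seed = as.integer(seed)),
            class = "benchmark_spec")
}

sample_log_uniform <- function(n, bounds) {
  exp(stats::runif(n, log(bounds[1]), log(bounds[2])))
}

make_background_smiles <- function(n, rng_templates = BACKGROUND_TEMPLATES,
                                   substituents = enumerate_substituents()) {
  combos <- expand.grid(tpl = rng_templates, sub = substituents,
                        stringsAsFactors = FALSE)
  if (nrow(combos) < n) stop("background vocabulary too small for ", n)
  pick <- sample.int(nrow(combos), n)
  sprintf(combos$tpl[pick], combos$sub[pick])
}

#' Generate a synthetic screening benchmark
#'
#' Actives share the scaffold (high pairwise TC, one common substructure);
#' the library mixes background molecules from unrelated scaffold families
#' with `n_planted` held-out scaffold molecules as ground truth. All SMILES
#' are valid by construction and verified by the parser.
#'
#' @param spec a [benchmark_spec()].
#' @return list with `actives` (a `"molecule_library"` with potencies),
#'   `library` (screening library), and `truth` (data.frame `molecule_id`,
#'   `is_active` for the library).
#' @export
generate_screening_benchmark <- function(spec) {
  set.seed(spec$seed)
  n_scaffold <- spec$n_actives + spec$n_planted
  if (length(spec$substituents) < n_scaffold) {
    stop("substituent vocabulary too small: ", length(spec$substituents),
         " < ", n_scaffold)
  }
  subs <- sample(spec$substituents, n_scaffold)
  smi <- sprintf(spec$scaffold_smiles, subs)
  pot <- sample_log_uniform(n_scaffold, spec$potency_bounds_nM)
  ids <- sprintf("ACT%04d", seq_len(n_scaffold))
  can <- canonical_smiles(smi)
  if (anyNA(can)) stop("scaffold/substituent combination produced invalid SMILES")

  act_idx <- seq_len(spec$n_actives)
  actives <- data.frame(
    molecule_id = ids[act_idx], smiles = can[act_idx], target_id = "SYN1",
    potency_type = sample(c("Ki", "IC50"), spec$n_actives, replace = TRUE),
    potency_nM = pot[act_idx], stringsAsFactors = FALSE
  )
  actives$mw <- molecular_weight(actives$smiles)
  actives$role <- "active"
  class(actives) <- c("molecule_library", class(actives))

  bg_smi <- make_background_smiles(spec$n_background,
                                   substituents = spec$substituents)
  bg_can <- canonical_smiles(bg_smi)
  if (anyNA(bg_can)) stop("background template produced invalid SMILES")
  planted_idx <- setdiff(seq_len(n_scaffold), act_idx)
  lib <- data.frame(
    molecule_id = c(sprintf("LIB%05d", seq_len(spec$n_background)),
                    sprintf("PLANT%03d", seq_along(planted_idx))),
    smiles = c(bg_can, can[planted_idx]),
    role = "query", stringsAsFactors = FALSE
  )
  ord <- sample.int(nrow(lib))
  lib <- lib[ord, , drop = FALSE]
  rownames(lib) <- NULL
  truth <- data.frame(molecule_id = lib$molecule_id,
                      is_active = startsWith(lib$molecule_id, "PLANT"))
  list(actives = actives, library = lib, truth = truth)
}

#' Generate a decoy candidate pool
#'
#' Structurally diverse molecules from the background scaffold families,
#' optionally constrained to requested property ranges (batch-generated and
#' filtered until `n` qualify).
#'
#' @param n pool size.
#' @param property_ranges optional named list of `c(lo, hi)` ranges over
#'   [property_vector()] columns.
#' @param seed integer seed.
#' @param max_batches resampling budget before the ranges are declared
#'   infeasible.
#' @return data.frame with `molecule_id`, `smiles`, `role = "candidate"`,
#'   plus the six property columns (so downstream steps can reuse them).
#' @export
generate_decoy_pool <- function(n, property_ranges = NULL, seed = 1L,
                                max_batches = 20L) {
  stopifnot(n > 0)
  set.seed(seed)
  subs <- enumerate_substituents(max_internal = 3L)
  kept <- NULL
  for (batch in seq_len(max_batches)) {
    m <- max(n, 256L)
    combos_tpl <- sample(BACKGROUND_TEMPLATES, m, replace = TRUE)
    combos_sub <- sample(subs, m, replace = TRUE)
    smi <- unique(sprintf(combos_tpl, combos_sub))
    can <- canonical_smiles(smi)
    smi <- unique(can[!is.na(can)])
    if (!is.null(kept)) smi <- setdiff(smi, kept$smiles)
    if (length(smi) == 0L) next
    props <- property_vector(smi)
    ok <- rep(TRUE, length(smi))
    for (p in names(property_ranges)) {
      rng <- property_ranges[[p]]
      ok <- ok & props[[p]] >= rng[1] & props[[p]] <= rng[2]
    }
    batch_keep <- cbind(data.frame(smiles = smi[ok],
                                   stringsAsFactors = FALSE),
                        props[ok, , drop = FALSE])
    kept <- rbind(kept, batch_keep)
    if (nrow(kept) >= n) break
  }
  if (is.null(kept) || nrow(kept) < n) {
    stop("property ranges infeasible: only ", if (is.null(kept)) 0 else nrow(kept),
         " of ", n, " candidates found")
  }
  kept <- kept[seq_len(n), , drop = FALSE]
  out <- data.frame(molecule_id = sprintf("POOL%05d", seq_len(n)),
                    smiles = kept$smiles, role = "candidate",
                    stringsAsFactors = FALSE)
  out <- cbind(out, kept[, setdiff(names(kept), "smiles"), drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Simulate a dose-response dataset
#'
#' `response = 1 / (1 + ([I]/IC50)^hill) * (1 + N(0, rel_noise))`.
#'
#' @param true_ic50 IC50 in M.
#' @param hill Hill coefficient (default 1).
#' @param concentrations inhibitor concentrations in M (default 8 points
#'   over 3 decades around the IC50).
#' @param rel_noise relative noise SD (default 0.05).
#' @param seed integer seed.
#' @return data.frame `concentration_M`, `response`.
#' @export
simulate_dose_response <- function(true_ic50, hill = 1,
                                   concentrations = NULL, rel_noise = 0.05,
                                   seed = 1L) {
  stopifnot(true_ic50 > 0)
  if (is.null(concentrations)) {
    concentrations <- true_ic50 * 10^seq(-1.5, 1.5, length.out = 8L)
  }
  set.seed(seed)
  mu <- logistic_response(concentrations, true_ic50, hill)
  resp <- mu * (1 + stats::rnorm(length(mu), 0, rel_noise))
  data.frame(concentration_M = concentrations, response = resp)
}

#' Simulate a DSF melt curve
#'
#' Boltzmann sigmoid plus Gaussian noise scaled to the plateau amplitude,
#' on a 30-90 deg C ramp.
#'
#' @param true_tm melt midpoint, deg C.
#' @param slope transition slope, deg C (default 2).
#' @param plateaus `c(low, high)` fluorescence plateaus (default 0, 1).
#' @param temperatures temperature grid (default every 0.5 deg C over
#'   30-90).
#' @param rel_noise noise SD as a fraction of the amplitude (default 0.01).
#' @param seed integer seed.
#' @return data.frame `temperature_C`, `fluorescence`.
#' @export
simulate_melt_curve <- function(true_tm, slope = 2, plateaus = c(0, 1),
                                temperatures = seq(30, 90, by = 0.5),
                                rel_noise = 0.01, seed = 1L) {
  set.seed(seed)
  amp <- plateaus[2] - plateaus[1]
  mu <- plateaus[1] + amp / (1 + exp((true_tm - temperatures) / slope))
  fl <- mu + stats::rnorm(length(mu), 0, rel_noise * abs(amp))
  data.frame(temperature_C = temperatures, fluorescence = fl)
}
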