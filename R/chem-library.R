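# Library curation: reading potency-annotated molecule tables or SDF files,
# standardization (canonical SMILES, salt stripping, unit conversion to nM),
# potency/size filtering, and representative-active selection by clustering.

POTENCY_UNIT_NM <- c(nM = 1, uM = 1e3, M = 1e9)

#' Curation configuration
#'
#' Thresholds for active-set curation: molecules must be smaller than
#' `mw_max` Da and more potent than `potency_max_nM` (both strict), and
#' actives are deduplicated by clustering at `cluster_tc_cutoff` Tanimoto.
#'
#' @param mw_max molecular-weight ceiling in Da (default 500).
#' @param potency_max_nM potency ceiling in nM (default 500).
#' @param cluster_tc_cutoff Tanimoto cutoff for clustering in `[0, 1]`
#'   (default 0.6).
#' @return list of class `"curation_config"`.
#' @export
curation_config <- function(mw_max = 500, potency_max_nM = 500,
                            cluster_tc_cutoff = 0.6) {
  stopifnot(mw_max > 0, potency_max_nM > 0,
            cluster_tc_cutoff >= 0, cluster_tc_cutoff <= 1)
  structure(list(mw_max = mw_max, potency_max_nM = potency_max_nM,
                 cluster_tc_cutoff = cluster_tc_cutoff),
            class = "curation_config")
}

#' Convert potency values to nM
#'
#' @param value numeric potency values.
#' @param unit character vector of units (`nM`, `uM`, `M`), recycled.
#' @return values in nM.
#' @export
potency_to_nM <- function(value, unit) {
  f <- POTENCY_UNIT_NM[unit]
  if (anyNA(f[!is.na(unit)])) {
    stop("unknown potency unit: ",
         paste(unique(unit[is.na(f) & !is.na(unit)]), collapse = ", "))
  }
  unname(value * f)
}

default_library_columns <- function() {
  list(molecule_id = "molecule_id", smiles = "smiles", target_id = "target_id",
       potency_type = "potency_type", potency_value = "potency_value",
       potency_unit = "potency_unit")
}

sniff_sep <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) "\t" else ","
}

#' Read and standardize a molecule library
#'
#' Reads a delimited SMILES table or an SDF file and standardizes every
#' record: SMILES canonicalized via the chemistry backend, the largest
#' covalent fragment retained (salt stripping), potencies converted to nM,
#' and duplicate molecule ids merged keeping the most potent (minimum nM)
#' measurement. Unparseable rows are skipped and counted.
#'
#' @param path input file.
#' @param format `"smiles-table"` (delimited text with a header; tab or
#'   comma) or `"sdf"`.
#' @param columns named list mapping the canonical column roles
#'   (`molecule_id`, `smiles`, `target_id`, `potency_type`, `potency_value`,
#'   `potency_unit`) to the file's column names; defaults to the canonical
#'   names. Only `molecule_id` and `smiles` are required in the file.
#' @param role role label assigned to the records (default `"candidate"`).
#' @return data.frame of class `"molecule_library"` with columns
#'   `molecule_id`, `smiles` (canonical, desalted), `target_id`,
#'   `potency_type` (`Ki`/`IC50`/`none`), `potency_nM`, `mw`, `role`;
#'   attribute `n_skipped` counts rows dropped as unparseable.
#' @export
read_library <- function(path, format = c("smiles-table", "sdf"),
                         columns = default_library_columns(),
                         role = "candidate") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  cols <- utils::modifyList(default_library_columns(), as.list(columns))
  if (format == "smiles-table") {
    tab <- utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                             stringsAsFactors = FALSE, quote = "\"",
                             comment.char = "")
    for (req in c("molecule_id", "smiles")) {
      if (!cols[[req]] %in% names(tab)) {
        stop("missing required column: ", cols[[req]])
      }
    }
    get_col <- function(role_, default) {
      nm <- cols[[role_]]
      if (nm %in% names(tab)) tab[[nm]] else rep(default, nrow(tab))
    }
    raw <- data.frame(
      molecule_id = as.character(tab[[cols$molecule_id]]),
      smiles = as.character(tab[[cols$smiles]]),
      target_id = as.character(get_col("target_id", "")),
      potency_type = as.character(get_col("potency_type", "none")),
      potency_value = suppressWarnings(as.numeric(get_col("potency_value", NA))),
      potency_unit = as.character(get_col("potency_unit", "nM")),
      stringsAsFactors = FALSE
    )
  } else {
    sdf <- ChemmineR::read.SDFset(path)
    valid <- ChemmineR::validSDF(sdf)
    sdf <- sdf[valid]
    ids <- vapply(seq_along(sdf), function(i) {
      h <- ChemmineR::header(sdf[[i]])[1]
      if (nzchar(h)) h else paste0("sdf", i)
    }, character(1))
    smi <- as.character(ChemmineR::sdf2smiles(sdf))
    db <- ChemmineR::datablock(sdf)
    field <- function(i, key, default) {
      d <- db[[i]]
      if (length(d) && key %in% names(d)) d[[key]] else default
    }
    raw <- data.frame(
      molecule_id = ids, smiles = smi,
      target_id = vapply(seq_along(sdf), field, character(1),
                         key = "target_id", default = ""),
      potency_type = vapply(seq_along(sdf), field, character(1),
                            key = "potency_type", default = "none"),
      potency_value = suppressWarnings(as.numeric(vapply(
        seq_along(sdf), field, character(1),
        key = "potency_value", default = NA_character_))),
      potency_unit = vapply(seq_along(sdf), field, character(1),
                            key = "potency_unit", default = "nM"),
      stringsAsFactors = FALSE
    )
  }
  if (nrow(raw) == 0L) stop("zero records in ", path)

  # standardize: strip salts, canonicalize; drop unparseable rows
  desalted <- strip_salts(raw$smiles)
  can <- canonical_smiles(desalted)
  ok <- !is.na(can) & nzchar(can)
  n_skipped <- sum(!ok)
  raw <- raw[ok, , drop = FALSE]
  can <- can[ok]
  if (nrow(raw) == 0L) stop("zero parseable records in ", path)

  pot_nM <- rep(NA_real_, nrow(raw))
  has_pot <- !is.na(raw$potency_value)
  pot_nM[has_pot] <- potency_to_nM(raw$potency_value[has_pot],
                                   raw$potency_unit[has_pot])
  if (any(pot_nM[!is.na(pot_nM)] <= 0)) stop("potency values must be > 0")
  ptype <- ifelse(has_pot & raw$potency_type %in% c("Ki", "IC50"),
                  raw$potency_type, "none")

  lib <- data.frame(
    molecule_id = raw$molecule_id, smiles = trimws(can),
    target_id = raw$target_id, potency_type = ptype, potency_nM = pot_nM,
    stringsAsFactors = FALSE
  )
  # duplicate ids: keep the most potent (minimum nM) measurement, whichever
  # of Ki/IC50 it came from; potency-free duplicates collapse to the first
  if (anyDuplicated(lib$molecule_id)) {
    keep <- unlist(lapply(split(seq_len(nrow(lib)), lib$molecule_id),
                          function(ix) {
      p <- lib$potency_nM[ix]
      if (all(is.na(p))) ix[1L] else ix[which.min(p)]
    }), use.names = FALSE)
    lib <- lib[sort(keep), , drop = FALSE]
  }
  lib$mw <- molecular_weight(lib$smiles)
  lib$role <- role
  rownames(lib) <- NULL
  attr(lib, "n_skipped") <- n_skipped
  class(lib) <- c("molecule_library", class(lib))
  lib
}

# Molecular weight (average atomic mass, Da) via the chemistry backend.
molecular_weight <- function(smiles) {
  ps <- parse_smiles_set(stats::setNames(smiles, paste0("m", seq_along(smiles))))
  if (!all(ps$ok)) stop("unparseable SMILES in molecular_weight()")
  props <- ChemmineR::propOB(ps$sdf)
  as.numeric(props$MW)
}

#' Filter a library on molecular weight and potency
#'
#' Retains records strictly smaller than `mw_max` Da and strictly more
#' potent than `potency_max_nM`; order preserved. Records without a potency
#' annotation are dropped (they cannot satisfy the potency criterion).
#'
#' @param records a `"molecule_library"` data.frame.
#' @param config a [curation_config()].
#' @return filtered library (possibly empty).
#' @export
filter_library <- function(records, config = curation_config()) {
  keep <- !is.na(records$mw) & records$mw < config$mw_max &
    !is.na(records$potency_nM) & records$potency_nM < config$potency_max_nM
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select one representative active per similarity cluster
#'
#' Clusters the records by sphere exclusion at the configured Tanimoto
#' cutoff and keeps the most potent (minimum `potency_nM`) member of each
#' cluster; potency ties break to the lexicographically smallest
#' `molecule_id`. Returned records are labelled `role = "active"`.
#'
#' @param records a `"molecule_library"` data.frame with potencies.
#' @param config a [curation_config()].
#' @param fingerprint_kind fingerprint used for clustering.
#' @return library of representatives (one row per cluster, input order).
#' @export
select_representative_actives <- function(records,
                                          config = curation_config(),
                                          fingerprint_kind = "ECFP4") {
  if (nrow(records) == 0L) stop("empty input")
  if (anyNA(records$potency_nM)) stop("all records must carry potency_nM")
  fps <- fingerprint_matrix(stats::setNames(records$smiles,
                                            records$molecule_id),
                            fingerprint_kind)
  cl <- butina_cluster(fps, config$cluster_tc_cutoff)
  pick <- vapply(split(seq_len(nrow(records)), cl), function(ix) {
    ix[order(records$potency_nM[ix], records$molecule_id[ix])[1L]]
  }, integer(1))
  out <- records[sort(pick), , drop = FALSE]
  out$role <- "active"
  rownames(out) <- NULL
  out
}

#' Write a library as a smiles-table
#'
#' @param records a `"molecule_library"` data.frame.
#' @param path output path (tab-delimited, canonical column names).
#' @return `path`, invisibly.
#' @export
write_library <- function(records, path) {
  tab <- data.frame(
    molecule_id = records$molecule_id, smiles = records$smiles,
    target_id = records$target_id, potency_type = records$potency_type,
    potency_value = records$potency_nM,
    potency_unit = ifelse(is.na(records$potency_nM), "", "nM"),
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
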