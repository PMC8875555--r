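# Property-matched, topologically dissimilar decoy generation (DUD-E
# style). For each active, candidates from a pool are ranked by
# physicochemical closeness and selected greedily under two hard topology
# constraints: max TC to every active below `tc_active_max` and pairwise TC
# among all selected decoys below `tc_decoy_max`. Property windows relax on
# a documented schedule when an active is under-filled; the similarity
# constraints never relax.

#' Default decoy property-matching windows
#'
#' Half-widths of the acceptance window per matched property; `net_charge`
#' is matched exactly (window 0, which the multiplicative relaxation leaves
#' at 0).
#'
#' @return named numeric vector.
#' @export
default_decoy_windows <- function() {
  c(mw = 25, clogp = 1.0, rotatable_bonds = 2, hba = 1, hbd = 1,
    net_charge = 0)
}

#' Generate property-matched decoys for a set of actives
#'
#' @param actives `"molecule_library"` data.frame of actives.
#' @param pool candidate records (`molecule_id`, `smiles`), disjoint from
#'   the actives by id.
#' @param n_per_active decoys requested per active (default 40).
#' @param tc_active_max hard ceiling on a decoy's TC to any active
#'   (default 0.6, strict `<`).
#' @param tc_decoy_max hard ceiling on pairwise TC among selected decoys
#'   (default 0.8, strict `<`).
#' @param windows property windows, see [default_decoy_windows()].
#' @param relax_factor,max_relax under-filled windows are widened by
#'   `relax_factor` per round, at most `max_relax` rounds (default 1.5, 3).
#' @param fingerprint_kind fingerprint used for the topology constraints.
#' @param active_props,pool_props optional precomputed [property_vector()]
#'   tables (rownames = molecule ids) to avoid recomputation.
#' @return object of class `"decoy_set"`: `assignments` (named list
#'   active_id -> data.frame of decoy records), `audit` (one row per decoy:
#'   ids, max TC to actives, max TC to the other selected decoys, property
#'   deltas, relaxation round used), `shortfalls` (actives with fewer than
#'   `n_per_active` decoys), and the generation parameters.
#' @export
generate_decoys <- function(actives, pool, n_per_active = 40,
                            tc_active_max = 0.6, tc_decoy_max = 0.8,
                            windows = default_decoy_windows(),
                            relax_factor = 1.5, max_relax = 3,
                            fingerprint_kind = "ECFP4",
                            active_props = NULL, pool_props = NULL) {
  if (nrow(actives) == 0L) stop("actives must be non-empty")
  if (nrow(pool) == 0L) stop("empty candidate pool")
  if (length(intersect(actives$molecule_id, pool$molecule_id)) > 0L) {
    stop("pool must be disjoint from actives by molecule_id")
  }
  prop_names <- names(default_decoy_windows())
  windows <- windows[prop_names]
  if (anyNA(windows)) stop("windows must cover all six matched properties")

  if (is.null(active_props)) {
    active_props <- property_vector(stats::setNames(actives$smiles,
                                                    actives$molecule_id))
  }
  if (is.null(pool_props)) {
    if (all(prop_names %in% names(pool))) {
      pool_props <- pool[, prop_names, drop = FALSE]   # e.g. generator output
      rownames(pool_props) <- pool$molecule_id
    } else {
      pool_props <- property_vector(stats::setNames(pool$smiles,
                                                    pool$molecule_id))
    }
  }
  if (!all(actives$molecule_id %in% rownames(active_props))) {
    stopifnot(nrow(active_props) == nrow(actives))
    rownames(active_props) <- actives$molecule_id
  }
  if (!all(pool$molecule_id %in% rownames(pool_props))) {
    stopifnot(nrow(pool_props) == nrow(pool))
    rownames(pool_props) <- pool$molecule_id
  }
  active_props <- active_props[actives$molecule_id, prop_names, drop = FALSE]
  pool_props <- pool_props[pool$molecule_id, prop_names, drop = FALSE]

  fa <- fingerprint_matrix(stats::setNames(actives$smiles,
                                           actives$molecule_id),
                           fingerprint_kind)
  fp <- fingerprint_matrix(stats::setNames(pool$smiles, pool$molecule_id),
                           fingerprint_kind)
  tc_pa <- tanimoto_matrix(fp, fa)          # pool x actives
  max_tc_active <- apply(tc_pa, 1L, max)
  # candidates too similar to ANY active are ineligible outright
  eligible_topo <- max_tc_active < tc_active_max

  # normalized property distance: |delta| scaled by the base window width
  scale <- windows
  scale[scale == 0] <- 1
  pm <- as.matrix(pool_props)
  am <- as.matrix(active_props)

  selected <- logical(nrow(pool))
  sel_fp_idx <- integer(0)                  # pool rows selected so far
  assignments <- stats::setNames(vector("list", nrow(actives)),
                                 actives$molecule_id)
  audit_rows <- list()
  shortfalls <- character(0)

  pool_ids <- pool$molecule_id
  fp_plain <- unclass(fp)
  pop_pool <- rowSums(fp_plain)

  for (ai in seq_len(nrow(actives))) {
    aid <- actives$molecule_id[ai]
    deltas <- sweep(pm, 2L, am[ai, ], "-")
    need <- n_per_active
    taken_here <- integer(0)
    for (round in 0:max_relax) {
      win <- windows * relax_factor^round
      in_win <- rowSums(abs(deltas) > rep(win, each = nrow(pm))) == 0L
      cand <- which(in_win & eligible_topo & !selected)
      if (length(cand) == 0L && round < max_relax) next
      dist <- rowSums(abs(deltas[cand, , drop = FALSE]) /
                        rep(scale, each = length(cand)))
      ord <- cand[order(dist, pool_ids[cand])]
      for (ci in ord) {
        if (length(taken_here) >= n_per_active) break
        # pairwise constraint against every decoy selected so far anywhere
        if (length(sel_fp_idx)) {
          inter <- as.numeric(fp_plain[sel_fp_idx, , drop = FALSE] %*%
                                fp_plain[ci, ])
          uni <- pop_pool[sel_fp_idx] + pop_pool[ci] - inter
          tcs <- ifelse(uni == 0, 0, inter / uni)
          if (any(tcs >= tc_decoy_max)) next
        }
        selected[ci] <- TRUE
        sel_fp_idx <- c(sel_fp_idx, ci)
        taken_here <- c(taken_here, ci)
        audit_rows[[length(audit_rows) + 1L]] <- data.frame(
          decoy_id = pool_ids[ci], active_id = aid,
          max_tc_active = max_tc_active[ci], max_tc_decoy = NA_real_,
          d_mw = deltas[ci, "mw"], d_clogp = deltas[ci, "clogp"],
          d_rotatable_bonds = deltas[ci, "rotatable_bonds"],
          d_hba = deltas[ci, "hba"], d_hbd = deltas[ci, "hbd"],
          d_net_charge = deltas[ci, "net_charge"],
          relax_round = round, stringsAsFactors = FALSE
        )
      }
      if (length(taken_here) >= n_per_active) break
    }
    if (length(taken_here) < n_per_active) shortfalls <- c(shortfalls, aid)
    assignments[[aid]] <- data.frame(
      molecule_id = pool_ids[taken_here],
      smiles = pool$smiles[taken_here],
      role = rep("inactive", length(taken_here)), stringsAsFactors = FALSE
    )
  }

  audit <- do.call(rbind, audit_rows)
  if (is.null(audit)) {
    audit <- data.frame(decoy_id = character(0), active_id = character(0))
  } else if (length(sel_fp_idx) > 1L) {
    # max TC to the other selected decoys, filled post hoc over the full set
    tc_dd <- tanimoto_matrix(fp[sel_fp_idx, , drop = FALSE])
    diag(tc_dd) <- -Inf
    mx <- apply(tc_dd, 1L, max)
    audit$max_tc_decoy <- mx[match(audit$decoy_id, pool_ids[sel_fp_idx])]
  } else {
    audit$max_tc_decoy <- 0
  }

  structure(list(
    assignments = assignments, audit = audit, shortfalls = shortfalls,
    params = list(n_per_active = n_per_active, tc_active_max = tc_active_max,
                  tc_decoy_max = tc_decoy_max, windows = windows,
                  relax_factor = relax_factor, max_relax = max_relax,
                  fingerprint_kind = fingerprint_kind)
  ), class = "decoy_set")
}

#' @export
print.decoy_set <- function(x, ...) {
  n <- sum(vapply(x$assignments, nrow, integer(1)))
  cat(sprintf("<decoy_set: %d decoys for %d actives (%d under-filled)>\n",
              n, length(x$assignments), length(x$shortfalls)))
  invisible(x)
}

#' Flatten a decoy set into an inactive library
#'
#' @param ds a `"decoy_set"`.
#' @return data.frame with `molecule_id`, `smiles`, `active_id`, `role`.
#' @export
decoy_records <- function(ds) {
  out <- do.call(rbind, lapply(names(ds$assignments), function(aid) {
    a <- ds$assignments[[aid]]
    if (nrow(a) == 0L) return(NULL)
    data.frame(molecule_id = a$molecule_id, smiles = a$smiles,
               active_id = aid, role = "inactive", stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(molecule_id = character(0), smiles = character(0),
                      active_id = character(0), role = character(0))
  }
  rownames(out) <- NULL
  out
}

#' Independently re-verify a decoy set against its constraints
#'
#' Recomputes fingerprints and properties from the SMILES and re-checks
#' every constraint the generator promises: TC to every active strictly
#' below `tc_active_max`, pairwise TC among all selected decoys strictly
#' below `tc_decoy_max`, property deltas inside the relaxation-adjusted
#' windows recorded in the audit, and per-active counts at most
#' `n_per_active`.
#'
#' @param ds a `"decoy_set"`.
#' @param actives the actives the set was generated for.
#' @return list with `ok` (all checks pass), `per_decoy` (logical per
#'   decoy), and `counts_ok`.
#' @export
verify_decoy_set <- function(ds, actives) {
  recs <- decoy_records(ds)
  if (nrow(recs) == 0L) {
    return(list(ok = TRUE, per_decoy = logical(0), counts_ok = TRUE))
  }
  kind <- ds$params$fingerprint_kind
  fa <- fingerprint_matrix(stats::setNames(actives$smiles,
                                           actives$molecule_id), kind)
  fd <- fingerprint_matrix(stats::setNames(recs$smiles, recs$molecule_id),
                           kind)
  tc_da <- tanimoto_matrix(fd, fa)
  ok_active <- apply(tc_da, 1L, max) < ds$params$tc_active_max
  tc_dd <- tanimoto_matrix(fd)
  diag(tc_dd) <- 0
  ok_decoy <- apply(tc_dd, 1L, max) < ds$params$tc_decoy_max

  props_d <- property_vector(stats::setNames(recs$smiles, recs$molecule_id))
  props_a <- property_vector(stats::setNames(actives$smiles,
                                             actives$molecule_id))
  prop_names <- names(default_decoy_windows())
  rounds <- ds$audit$relax_round[match(recs$molecule_id, ds$audit$decoy_id)]
  ok_window <- vapply(seq_len(nrow(recs)), function(i) {
    win <- ds$params$windows * ds$params$relax_factor^rounds[i]
    d <- abs(as.numeric(props_d[recs$molecule_id[i], prop_names]) -
               as.numeric(props_a[recs$active_id[i], prop_names]))
    all(d <= win + 1e-9)
  }, logical(1))

  per_decoy <- ok_active & ok_decoy & ok_window
  counts <- vapply(ds$assignments, nrow, integer(1))
  counts_ok <- all(counts <= ds$params$n_per_active)
  list(ok = all(per_decoy) && counts_ok, per_decoy = per_decoy,
       counts_ok = counts_ok)
}

#' Write decoys and audit to delimited files
#'
#' @param ds a `"decoy_set"`.
#' @param decoy_path,audit_path output paths (tab-delimited).
#' @return invisibly, a list of the two paths.
#' @export
write_decoy_set <- function(ds, decoy_path, audit_path) {
  utils::write.table(decoy_records(ds), decoy_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(ds$audit, audit_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(list(decoys = decoy_path, audit = audit_path))
}
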