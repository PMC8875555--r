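# Molecular fingerprints: an internal deterministic Morgan-style circular
# fingerprint (ECFP4/ECFP6 analogue, folded to 1024 bits) computed on the
# molecule graph, and the 166 MACCS structural keys from the OpenBabel
# pattern set. The circular fingerprint is self-contained so downstream
# results do not shift with toolkit hash revisions.

FP_LENGTH <- c(ECFP4 = 1024L, ECFP6 = 1024L, MACCS = 166L)
FP_RADIUS <- c(ECFP4 = 2L, ECFP6 = 3L)

HASH_PRIME <- 2147483647   # 2^31 - 1; keeps products exact in doubles
HASH_MULT <- 1000003

# Order-sensitive hash of a small non-negative integer vector.
hash_ints <- function(xs) {
  h <- 17
  for (x in xs) h <- (h * HASH_MULT + x) %% HASH_PRIME
  h
}

# Circular (Morgan-style) atom environments: the initial invariant encodes
# element, heavy degree, total bond order, formal charge, implicit H count
# and ring membership; each iteration folds in the sorted
# (bond order, neighbour invariant) pairs. All invariants from radius 0 up
# to the requested radius set bits after folding modulo the bit length.
ecfp_bits <- function(graph, radius, nbits) {
  n <- length(graph$element)
  anum <- ATOMIC_NUMBER[graph$element]
  anum[is.na(anum)] <- 0L
  inv <- numeric(n)
  for (a in seq_len(n)) {
    inv[a] <- hash_ints(c(anum[a], graph$degree[a], graph$bond_sum[a],
                          graph$charge[a] + 8L, graph$n_h[a],
                          as.integer(graph$in_ring[a])))
  }
  feats <- inv
  from <- graph$bonds$from; to <- graph$bonds$to; ord <- graph$bonds$order
  nbr <- vector("list", n)
  for (e in seq_along(from)) {
    nbr[[from[e]]] <- rbind(nbr[[from[e]]], c(to[e], ord[e]))
    nbr[[to[e]]] <- rbind(nbr[[to[e]]], c(from[e], ord[e]))
  }
  for (r in seq_len(radius)) {
    new_inv <- numeric(n)
    for (a in seq_len(n)) {
      nb <- nbr[[a]]
      if (is.null(nb)) {
        new_inv[a] <- hash_ints(c(r, inv[a]))
      } else {
        pairs <- cbind(nb[, 2], inv[nb[, 1]])
        o <- order(pairs[, 1], pairs[, 2])
        new_inv[a] <- hash_ints(c(r, inv[a], t(pairs[o, , drop = FALSE])))
      }
    }
    inv <- new_inv
    feats <- c(feats, inv)
  }
  unique(as.integer(feats %% nbits) + 1L)
}

#' Compute a fingerprint matrix for a set of molecules
#'
#' @param smiles character vector of SMILES (named by molecule id, or names
#'   taken from positions).
#' @param kind one of `"ECFP4"`, `"ECFP6"` (1024-bit circular fingerprints of
#'   bond radius 2 and 3) or `"MACCS"` (166 structural keys).
#' @return a 0/1 integer matrix, one row per molecule (rownames = ids), with
#'   attribute `kind`; class `"fp_matrix"`. Unparseable SMILES raise an
#'   error.
#' @export
fingerprint_matrix <- function(smiles, kind = c("ECFP4", "ECFP6", "MACCS")) {
  kind <- match.arg(kind)
  ps <- parse_smiles_set(smiles)
  if (!all(ps$ok)) {
    bad <- names(smiles)[!ps$ok]
    if (is.null(bad)) bad <- which(!ps$ok)
    stop("unparseable SMILES: ", paste(utils::head(bad, 5), collapse = ", "))
  }
  nbits <- FP_LENGTH[[kind]]
  if (kind == "MACCS") {
    # OpenBabel stores the 166 keys in a 256-bit container; bits 167..256
    # are always zero (slot access: the FPset as.matrix method is S4-only)
    fpset <- ChemmineR::fingerprintOB(ps$sdf, "MACCS")
    m <- methods::slot(fpset, "fpma")[, 1:166, drop = FALSE]
    m <- matrix(as.integer(m), nrow = nrow(m), dimnames = list(ChemmineR::cid(ps$sdf), NULL))
  } else {
    graphs <- mol_graphs(ps$sdf)
    m <- matrix(0L, nrow = length(graphs), ncol = nbits,
                dimnames = list(names(graphs), NULL))
    radius <- FP_RADIUS[[kind]]
    for (i in seq_along(graphs)) {
      m[i, ecfp_bits(graphs[[i]], radius, nbits)] <- 1L
    }
  }
  attr(m, "kind") <- kind
  class(m) <- c("fp_matrix", class(m))
  m
}

#' Fingerprint a single molecule
#'
#' @inheritParams fingerprint_matrix
#' @return a list with `kind` and `bits` (0/1 integer vector of the kind's
#'   fixed length); class `"fingerprint"`.
#' @export
fingerprint <- function(smiles, kind = c("ECFP4", "ECFP6", "MACCS")) {
  kind <- match.arg(kind)
  stopifnot(length(smiles) == 1L)
  m <- fingerprint_matrix(stats::setNames(smiles, "q"), kind)
  structure(list(kind = kind, bits = as.integer(m[1L, ])), class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<%s fingerprint: %d/%d bits set>\n", x$kind, sum(x$bits),
              length(x$bits)))
  invisible(x)
}

# Coerce fingerprint inputs (fingerprint object, 0/1 vector, single-row
# fp_matrix) to a plain bit vector plus kind.
as_fp_bits <- function(x) {
  if (inherits(x, "fingerprint")) return(list(bits = x$bits, kind = x$kind))
  if (inherits(x, "fp_matrix")) {
    stopifnot(nrow(x) == 1L)
    return(list(bits = as.integer(x[1L, ]), kind = attr(x, "kind")))
  }
  list(bits = as.integer(x), kind = attr(x, "kind"))
}
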