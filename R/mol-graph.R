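# Molecule parsing and graph extraction on top of the OpenBabel backend
# (ChemmineR/ChemmineOB). All downstream chemistry (fingerprints, salt
# stripping, heavy-atom counts) works off the graphs produced here.

DEFAULT_VALENCE <- c(
  C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1, I = 1,
  B = 3, Si = 4, Se = 2
)

ATOMIC_NUMBER <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15, S = 16,
  Cl = 17, Se = 34, Br = 35, I = 53, Na = 11, K = 19, Ca = 20, Mg = 12,
  Zn = 30, Fe = 26, Li = 3
)

#' Parse SMILES into an OpenBabel SDF set, skipping unparseable entries
#'
#' The OpenBabel batch converter aborts at the first unparseable SMILES, so
#' conversion is resumed after each failure; failed inputs are reported
#' rather than raised.
#'
#' @param smiles character vector of SMILES, optionally named. Unnamed input
#'   gets positional names.
#' @return list with `sdf` (an `SDFset` of the parseable molecules, cids set
#'   to the input names) and `ok` (logical vector along `smiles`).
#' @keywords internal
parse_smiles_set <- function(smiles) {
  n <- length(smiles)
  if (n == 0L) stop("no SMILES supplied")
  nms <- names(smiles)
  if (is.null(nms)) nms <- paste0("mol", seq_len(n))
  names(smiles) <- nms
  ok <- rep(FALSE, n)
  chunks <- list()
  start <- 1L
  while (start <= n) {
    idx <- start:n
    res <- suppressWarnings(tryCatch(
      ChemmineR::smiles2sdf(smiles[idx]),
      error = function(e) NULL
    ))
    got <- if (is.null(res)) 0L else length(res)
    if (got > 0L) {
      ok[idx[seq_len(got)]] <- TRUE
      chunks[[length(chunks) + 1L]] <- res
    }
    # the element after the last converted one failed to parse; skip it
    start <- start + got + 1L
  }
  sdf <- if (length(chunks) == 1L) {
    chunks[[1L]]
  } else if (length(chunks) > 1L) {
    merged <- methods::as(unlist(lapply(chunks, methods::as, "SDF")), "SDFset")
    ChemmineR::cid(merged) <- unlist(lapply(chunks, ChemmineR::cid))
    merged
  } else {
    NULL
  }
  list(sdf = sdf, ok = ok)
}

#' Canonical SMILES via the OpenBabel canonicalizer
#'
#' Uses the backend's canonical output format (`CAN`), so the same molecule
#' written with different atom orders maps to one string. The converter
#' aborts a batch at the first unparseable entry, so conversion resumes
#' after each failure; failed entries come back as `NA`.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of canonical SMILES, `NA` where unparseable.
#' @export
canonical_smiles <- function(smiles) {
  out <- rep(NA_character_, length(smiles))
  todo <- seq_along(smiles)
  while (length(todo) > 0L) {
    src <- paste0(paste(smiles[todo], seq_along(todo)), "\n", collapse = "")
    res <- suppressWarnings(tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", src),
      error = function(e) ""
    ))
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(trimws(lines))]
    k <- length(lines)
    if (k > 0L) {
      out[todo[seq_len(k)]] <- trimws(vapply(
        strsplit(lines, "[\t ]"), `[[`, character(1), 1L))
    }
    # entry k+1 failed to parse (or everything converted)
    if (k + 1L > length(todo)) break
    todo <- todo[-seq_len(k + 1L)]
  }
  out
}

# Split a SMILES into covalent components (dot-disconnected fragments).
smiles_components <- function(smiles) strsplit(smiles, ".", fixed = TRUE)

#' Keep the largest covalent fragment of each SMILES (salt stripping)
#'
#' Largest is by heavy-atom count; ties broken by fragment string order for
#' determinism. Molecules without a dot are returned unchanged.
#'
#' @param smiles character vector.
#' @return character vector of the retained fragments (not canonicalized).
#' @export
strip_salts <- function(smiles) {
  comps <- smiles_components(smiles)
  multi <- lengths(comps) > 1L
  if (!any(multi)) return(smiles)
  out <- smiles
  for (i in which(multi)) {
    frags <- comps[[i]]
    counts <- vapply(frags, count_heavy_atoms, integer(1))
    best <- order(-counts, frags)[1L]
    out[i] <- frags[best]
  }
  out
}

# Heavy atoms from a SMILES fragment without a full parse: counts element
# tokens (two-letter organic/bracket symbols handled, H excluded).
count_heavy_atoms <- function(frag) {
  toks <- gregexpr("Cl|Br|Si|Se|Na|Li|Mg|Ca|Zn|Fe|\\[[^]]+\\]|[BCNOPSFI]|[bcnops]",
                   frag, perl = TRUE)[[1]]
  if (toks[1] == -1L) return(0L)
  m <- regmatches(frag, gregexpr(
    "Cl|Br|Si|Se|Na|Li|Mg|Ca|Zn|Fe|\\[[^]]+\\]|[BCNOPSFI]|[bcnops]",
    frag, perl = TRUE))[[1]]
  sum(!grepl("^\\[H", m))
}

#' Build lightweight molecule graphs from parsed molecules
#'
#' @param sdf an `SDFset`.
#' @return named list of graphs; each has `element`, `charge`, `degree`,
#'   `bond_sum`, `n_h` (implicit hydrogens), `in_ring` per atom and a bond
#'   table (`from`, `to`, `order`, `in_ring`).
#' @keywords internal
mol_graphs <- function(sdf) {
  abs_ <- ChemmineR::atomblock(sdf)
  bbs <- ChemmineR::bondblock(sdf)
  out <- vector("list", length(abs_))
  names(out) <- ChemmineR::cid(sdf)
  for (i in seq_along(abs_)) {
    ab <- abs_[[i]]
    bb <- bbs[[i]]
    elem <- sub("_.*$", "", rownames(ab))
    n <- length(elem)
    chg_code <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, n)
    charge <- ifelse(chg_code == 0, 0L, 4L - as.integer(chg_code))
    # zero-bond molecules come back as a 1x2 placeholder block
    if (is.null(dim(bb)) || nrow(bb) == 0L || ncol(bb) < 3L) {
      from <- integer(0); to <- integer(0); ord <- integer(0)
    } else {
      from <- as.integer(bb[, 1]); to <- as.integer(bb[, 2])
      ord <- as.integer(bb[, 3])
    }
    degree <- tabulate(c(from, to), nbins = n)
    bond_sum <- integer(n)
    if (length(from)) {
      bs <- tapply(c(ord, ord), c(from, to), sum)
      bond_sum[as.integer(names(bs))] <- as.integer(bs)
    }
    ring_bond <- ring_bonds(n, from, to)
    in_ring <- rep(FALSE, n)
    if (any(ring_bond)) in_ring[unique(c(from[ring_bond], to[ring_bond]))] <- TRUE
    defval <- DEFAULT_VALENCE[elem]
    defval[is.na(defval)] <- 0
    n_h <- pmax(0L, as.integer(defval) + charge - bond_sum)
    n_h[is.na(n_h)] <- 0L
    out[[i]] <- list(
      element = elem, charge = charge, degree = degree, bond_sum = bond_sum,
      n_h = n_h, in_ring = in_ring,
      bonds = list(from = from, to = to, order = ord, in_ring = ring_bond)
    )
  }
  out
}

# Ring bonds = edges that are not bridges (removal keeps endpoints
# connected). Iterative DFS bridge finding; molecule graphs are tiny.
ring_bonds <- function(n_atoms, from, to) {
  m <- length(from)
  if (m == 0L) return(logical(0))
  adj <- vector("list", n_atoms)
  for (e in seq_len(m)) {
    adj[[from[e]]] <- c(adj[[from[e]]], e)
    adj[[to[e]]] <- c(adj[[to[e]]], e)
  }
  disc <- low <- integer(n_atoms)
  visited <- logical(n_atoms)
  is_bridge <- logical(m)
  timer <- 0L
  for (root in seq_len(n_atoms)) {
    if (visited[root]) next
    # stack frames: node, parent edge, pointer into adjacency list
    stack_node <- root; stack_pedge <- 0L; stack_ptr <- 1L
    timer <- timer + 1L
    visited[root] <- TRUE; disc[root] <- low[root] <- timer
    depth <- 1L
    while (depth > 0L) {
      v <- stack_node[depth]
      es <- adj[[v]]
      if (stack_ptr[depth] <= length(es)) {
        e <- es[stack_ptr[depth]]
        stack_ptr[depth] <- stack_ptr[depth] + 1L
        if (e == stack_pedge[depth]) next
        w <- if (from[e] == v) to[e] else from[e]
        if (visited[w]) {
          low[v] <- min(low[v], disc[w])
        } else {
          timer <- timer + 1L
          visited[w] <- TRUE; disc[w] <- low[w] <- timer
          depth <- depth + 1L
          stack_node[depth] <- w; stack_pedge[depth] <- e; stack_ptr[depth] <- 1L
        }
      } else {
        pe <- stack_pedge[depth]
        depth <- depth - 1L
        if (depth > 0L) {
          p <- stack_node[depth]
          low[p] <- min(low[p], low[v])
          if (low[v] > disc[p]) is_bridge[pe] <- TRUE
        }
      }
    }
  }
  !is_bridge
}
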