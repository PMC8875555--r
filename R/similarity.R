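# Tanimoto similarity, sphere-exclusion (Butina) clustering,
# nearest-neighbour lookup and similarity-ensemble (TC distribution)
# comparison between ligand sets.

#' Tanimoto coefficient between two fingerprints
#'
#' `|a AND b| / |a OR b|`, defined as 0 when both vectors are empty.
#'
#' @param a,b fingerprints of the same kind (`fingerprint` objects, 0/1
#'   vectors, or single-row `fp_matrix`).
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  fa <- as_fp_bits(a); fb <- as_fp_bits(b)
  if (!is.null(fa$kind) && !is.null(fb$kind) && fa$kind != fb$kind) {
    stop("fingerprint kind mismatch: ", fa$kind, " vs ", fb$kind)
  }
  if (length(fa$bits) != length(fb$bits)) stop("fingerprint length mismatch")
  inter <- sum(fa$bits & fb$bits)
  uni <- sum(fa$bits | fb$bits)
  if (uni == 0L) return(0)
  inter / uni
}

#' Pairwise Tanimoto matrix between fingerprint sets
#'
#' @param a an `fp_matrix` (rows = molecules).
#' @param b an `fp_matrix` of the same kind, or `NULL` for `a` vs itself.
#' @return numeric matrix of TCs, `nrow(a)` x `nrow(b)`, dimnames from row
#'   names.
#' @export
tanimoto_matrix <- function(a, b = NULL) {
  symmetric <- is.null(b)
  if (symmetric) b <- a
  ka <- attr(a, "kind"); kb <- attr(b, "kind")
  if (!is.null(ka) && !is.null(kb) && ka != kb) stop("fingerprint kind mismatch")
  am <- unclass(a); bm <- unclass(b)
  inter <- am %*% t(bm)
  pa <- rowSums(am); pb <- rowSums(bm)
  uni <- outer(pa, pb, "+") - inter
  tc <- ifelse(uni == 0, 0, inter / uni)
  dimnames(tc) <- list(rownames(a), rownames(b))
  tc
}

#' Sphere-exclusion (Butina) clustering
#'
#' Neighbour counts at `TC >= cutoff` are computed once; molecules are
#' visited in order of descending neighbour count (ties by ascending index).
#' An unassigned molecule becomes the next cluster centroid and sweeps up
#' every still-unassigned molecule within the cutoff; molecules with no
#' centroid within the cutoff end as singletons.
#'
#' @param x an `fp_matrix`, or a square symmetric similarity matrix.
#' @param cutoff TC threshold in `[0, 1]`; neighbourhood is `TC >= cutoff`.
#' @return integer vector of cluster ids (1-based, in centroid order), one
#'   per molecule; attribute `centroids` gives the centroid index of each
#'   cluster.
#' @export
butina_cluster <- function(x, cutoff) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  sim <- if (inherits(x, "fp_matrix")) tanimoto_matrix(x) else as.matrix(x)
  n <- nrow(sim)
  if (n == 0L) stop("empty input")
  if (n != ncol(sim)) stop("similarity matrix must be square")
  nb <- sim >= cutoff
  diag(nb) <- FALSE
  counts <- rowSums(nb)
  ord <- order(-counts, seq_len(n))
  cluster <- integer(n)
  centroids <- integer(0)
  next_id <- 0L
  for (i in ord) {
    if (cluster[i] != 0L) next
    next_id <- next_id + 1L
    centroids[next_id] <- i
    members <- which(cluster == 0L & (nb[i, ] | seq_len(n) == i))
    cluster[members] <- next_id
  }
  structure(cluster, centroids = centroids)
}

#' Nearest neighbour in a labelled reference set
#'
#' @param query a single fingerprint.
#' @param refs an `fp_matrix` of reference fingerprints (rownames = labels).
#' @return list with `label` and `tc` of the maximum-TC reference; ties
#'   broken by the lexicographically smallest label.
#' @export
nearest_neighbor <- function(query, refs) {
  if (is.null(dim(refs)) || nrow(refs) == 0L) stop("empty reference set")
  q <- as_fp_bits(query)
  rk <- attr(refs, "kind")
  if (!is.null(q$kind) && !is.null(rk) && q$kind != rk) {
    stop("fingerprint kind mismatch")
  }
  rm_ <- unclass(refs)
  inter <- as.numeric(rm_ %*% q$bits)
  uni <- rowSums(rm_) + sum(q$bits) - inter
  tc <- ifelse(uni == 0, 0, inter / uni)
  labels <- rownames(refs)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(refs)))
  best <- order(-tc, labels)[1L]
  list(label = labels[best], tc = unname(tc[best]))
}

#' Tanimoto distribution between (or within) ligand sets
#'
#' The similarity-ensemble view of two ligand sets: within one set, all
#' unordered pairs (no self pairs); across two sets, all cross pairs.
#'
#' @param set_a an `fp_matrix`.
#' @param set_b optional second `fp_matrix` of the same kind.
#' @param breaks histogram bin edges over `[0, 1]` (default 20 bins).
#' @param label text label for the distribution.
#' @return object of class `"tc_distribution"`: `pair_tcs`, `bin_edges`,
#'   `counts`, `label`.
#' @export
tc_distribution <- function(set_a, set_b = NULL,
                            breaks = seq(0, 1, length.out = 21L),
                            label = "") {
  if (is.null(set_b)) {
    if (nrow(set_a) < 2L) stop("within-set mode needs at least 2 molecules")
    tc <- tanimoto_matrix(set_a)
    pair_tcs <- tc[upper.tri(tc)]
  } else {
    tc <- tanimoto_matrix(set_a, set_b)
    pair_tcs <- as.numeric(tc)
  }
  h <- graphics::hist(pair_tcs, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = TRUE)
  structure(list(pair_tcs = pair_tcs, bin_edges = h$breaks,
                 counts = h$counts, label = label),
            class = "tc_distribution")
}

#' @export
print.tc_distribution <- function(x, ...) {
  cat(sprintf("<TC distribution%s: %d pairs, median %.3f, max %.3f>\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$pair_tcs), stats::median(x$pair_tcs), max(x$pair_tcs)))
  invisible(x)
}

#' Write a TC distribution as a delimited table
#'
#' Columns `bin_low`, `bin_high`, `count`.
#'
#' @param dist a `"tc_distribution"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_tc_distribution <- function(dist, path) {
  k <- length(dist$counts)
  tab <- data.frame(bin_low = dist$bin_edges[seq_len(k)],
                    bin_high = dist$bin_edges[seq_len(k) + 1L],
                    count = dist$counts)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
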