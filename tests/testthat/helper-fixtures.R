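# Shared fixtures, built in code at test time.

# closely related benzenesulfonamides (high pairwise TC) plus unrelated
# molecules; used to exercise clustering and curation
sulfonamide_pair <- function() {
  c(SA1 = "NS(=O)(=O)c1ccc(CC)cc1",
    SA2 = "NS(=O)(=O)c1ccc(CCC)cc1")
}

unrelated_molecules <- function() {
  c(NAP = "c1ccc2ccccc2c1",
    PIP = "C1CCNCC1",
    EST = "CCOC(=O)c1ccncc1")
}

write_smiles_table <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

# exhaustive sphere-exclusion reference, written with explicit set
# operations independent of the package implementation: visit molecules by
# descending neighbour count (smallest-index tie-break); each unassigned
# visitee becomes a centroid and absorbs its unassigned neighbours
butina_oracle <- function(sim, cutoff) {
  n <- nrow(sim)
  counts <- sapply(seq_len(n), function(i) {
    sum(sim[i, -i] >= cutoff)
  })
  visit <- order(-counts, seq_len(n))
  assigned <- rep(NA_integer_, n)
  cl <- 0L
  for (v in visit) {
    if (!is.na(assigned[v])) next
    cl <- cl + 1L
    members <- setdiff(which(is.na(assigned) & sim[v, ] >= cutoff), v)
    assigned[c(v, members)] <- cl
  }
  assigned
}

# small random similarity matrix with exact ties made likely
random_sim_matrix <- function(n) {
  vals <- sample(seq(0, 1, by = 0.1), n * (n - 1) / 2, replace = TRUE)
  s <- matrix(0, n, n)
  s[upper.tri(s)] <- vals
  s <- s + t(s)
  diag(s) <- 1
  s
}
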