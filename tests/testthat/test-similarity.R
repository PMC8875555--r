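# Fingerprints, Tanimoto similarity, clustering, nearest neighbour and TC
# distributions.

test_that("fingerprints are deterministic with the documented lengths", {
  for (kind in c("ECFP4", "ECFP6", "MACCS")) {
    a <- fingerprint("NS(=O)(=O)c1ccc(N)cc1", kind)
    b <- fingerprint("NS(=O)(=O)c1ccc(N)cc1", kind)
    expect_identical(a$bits, b$bits)
    expect_length(a$bits, c(ECFP4 = 1024L, ECFP6 = 1024L, MACCS = 166L)[[kind]])
  }
  expect_gte(sum(fingerprint("C", "ECFP4")$bits), 1)  # methane non-empty
  # distinct topologies map to distinct bit vectors
  bz <- fingerprint("c1ccccc1", "ECFP4")
  ch <- fingerprint("C1CCCCC1", "ECFP4")
  expect_false(identical(bz$bits, ch$bits))
  expect_error(fingerprint("((((", "ECFP4"), "unparseable")
})

test_that("tanimoto matches set arithmetic and its edge conventions", {
  mk <- function(idx) { v <- integer(16); v[idx + 1L] <- 1L; v }
  expect_equal(tanimoto(mk(c(0, 1, 2)), mk(c(1, 2, 3))), 0.5)  # 2/4
  expect_equal(tanimoto(mk(c(0, 1)), mk(c(0, 1))), 1.0)
  expect_equal(tanimoto(mk(0), mk(5)), 0.0)
  expect_equal(tanimoto(integer(16), integer(16)), 0)   # all-zero convention
  a <- fingerprint("CCO", "ECFP4"); b <- fingerprint("CCO", "MACCS")
  expect_error(tanimoto(a, b), "kind mismatch")
})

test_that("tanimoto is symmetric with unit self-similarity", {
  set.seed(42)
  n <- 200L
  A <- matrix(rbinom(n * 64, 1, 0.2), n, 64)
  B <- matrix(rbinom(n * 64, 1, 0.4), n, 64)
  for (i in seq_len(n)) {
    expect_identical(tanimoto(A[i, ], B[i, ]), tanimoto(B[i, ], A[i, ]))
  }
  nonzero <- rowSums(A) > 0
  for (i in which(nonzero)) expect_identical(tanimoto(A[i, ], A[i, ]), 1)
})

test_that("butina_cluster handles the degenerate regimes", {
  d <- diag(4)                    # all off-diagonal TC 0
  expect_equal(as.integer(butina_cluster(d, 0.5)), 1:4)
  s <- matrix(1, 4, 4)            # all TC 1
  expect_true(all(butina_cluster(s, 0.5) == 1L))
  expect_error(butina_cluster(matrix(numeric(0), 0, 0), 0.5), "empty")
})

test_that("butina_cluster agrees with the exhaustive reference", {
  set.seed(7)
  for (trial in 1:60) {
    n <- sample(2:8, 1)
    s <- random_sim_matrix(n)
    cutoff <- sample(c(0.3, 0.5, 0.7), 1)
    got <- as.integer(butina_cluster(s, cutoff))
    want <- butina_oracle(s, cutoff)
    expect_identical(got, want)
    # partition: disjoint and complete
    expect_false(anyNA(got))
    expect_equal(sort(unique(got)), seq_len(max(got)))
  }
})

test_that("nearest_neighbor returns the argmax with lexicographic ties", {
  refs <- fingerprint_matrix(c(B_far = "c1ccc2ccccc2c1",
                               A_self = "NS(=O)(=O)c1ccc(CC)cc1",
                               C_near = "NS(=O)(=O)c1ccc(CCC)cc1"), "ECFP4")
  q <- fingerprint("NS(=O)(=O)c1ccc(CC)cc1", "ECFP4")
  nn <- nearest_neighbor(q, refs)
  expect_equal(nn$label, "A_self")
  expect_equal(nn$tc, 1.0)
  # exact tie: duplicate rows under two labels -> smaller label wins
  refs2 <- refs[c("A_self", "A_self", "B_far"), ]
  rownames(refs2) <- c("zz", "aa", "bb")
  attr(refs2, "kind") <- "ECFP4"
  class(refs2) <- c("fp_matrix", class(refs2))
  expect_equal(nearest_neighbor(q, refs2)$label, "aa")
  expect_error(nearest_neighbor(q, refs[0, ]), "empty")
})

test_that("tc_distribution counts pairs exactly", {
  smis <- c(sulfonamide_pair(), unrelated_molecules())
  fps <- fingerprint_matrix(smis, "ECFP4")
  within <- tc_distribution(fps[1:4, ])
  expect_length(within$pair_tcs, 6L)           # C(4,2)
  expect_equal(sum(within$counts), 6L)
  cross <- tc_distribution(fps[1:3, ], fps[4:5, ])
  expect_length(cross$pair_tcs, 6L)            # 3 x 2
  expect_true(all(cross$pair_tcs >= 0 & cross$pair_tcs <= 1))
  # duplicated set contains exact-1 pairs
  dup <- fps[c(1, 1, 2, 2), ]
  attr(dup, "kind") <- "ECFP4"
  class(dup) <- c("fp_matrix", class(dup))
  rownames(dup) <- paste0("r", 1:4)
  expect_true(any(tc_distribution(dup)$pair_tcs == 1))
  expect_error(tc_distribution(fps[1, , drop = FALSE]), "at least 2")
})

test_that("tc_distribution export writes conserved bin counts", {
  fps <- fingerprint_matrix(c(sulfonamide_pair(), unrelated_molecules()),
                            "ECFP4")
  d <- tc_distribution(fps, label = "demo")
  path <- tempfile(fileext = ".tsv")
  export_tc_distribution(d, path)
  tab <- read.delim(path)
  expect_equal(sum(tab$count), length(d$pair_tcs))
  expect_equal(nrow(tab), length(d$counts))
})
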