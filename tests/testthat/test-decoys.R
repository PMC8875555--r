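# Property vectors and property-matched decoy generation.

test_that("property_vector follows the documented conventions", {
  pv <- property_vector(c(etoh = "CCO", acetate = "CC(=O)[O-]",
                          benzene = "c1ccccc1", glycine = "NCC(=O)O",
                          aniline = "Nc1ccccc1", amine = "NCCC"))
  expect_equal(pv["etoh", "hbd"], 1L)
  expect_equal(pv["etoh", "rotatable_bonds"], 0L)  # terminal heavy atoms
  expect_equal(pv["etoh", "net_charge"], 0L)
  expect_equal(pv["acetate", "net_charge"], -1L)   # formal charge kept
  expect_equal(pv["benzene", "hbd"], 0L)
  expect_equal(pv["benzene", "hba"], 0L)
  # rule-based protonation: -COOH deprotonates, aliphatic amine protonates
  expect_equal(pv["glycine", "net_charge"], 0L)    # zwitterion nets to 0
  expect_equal(pv["amine", "net_charge"], 1L)
  expect_equal(pv["aniline", "net_charge"], 0L)    # anilines stay neutral
  expect_true(all(pv$mw > 0))
  expect_error(property_vector("((bad"), "unparseable")
})

test_that("decoy generation respects both similarity constraints", {
  actives <- data.frame(
    molecule_id = c("A1", "A2"),
    smiles = c("NS(=O)(=O)c1ccc(CC)cc1", "NS(=O)(=O)c1ccc(OC)cc1"),
    stringsAsFactors = FALSE
  )
  # pool contains a close analog of A1 (TC > 0.6) that must never be picked
  analog <- "NS(=O)(=O)c1ccc(CCC)cc1"
  fa <- fingerprint_matrix(setNames(actives$smiles, actives$molecule_id),
                           "ECFP4")
  expect_gt(max(tanimoto_matrix(
    fingerprint_matrix(c(x = analog), "ECFP4"), fa)), 0.6)
  pool <- rbind(
    data.frame(molecule_id = "TRAP", smiles = analog),
    generate_decoy_pool(120, seed = 5)[, c("molecule_id", "smiles")]
  )
  ds <- generate_decoys(actives, pool, n_per_active = 6)
  recs <- decoy_records(ds)
  expect_false("TRAP" %in% recs$molecule_id)
  v <- verify_decoy_set(ds, actives)
  expect_true(v$ok)
  expect_true(all(v$per_decoy))
  expect_lte(nrow(recs), 6 * nrow(actives))
  # audit covers every decoy with both similarity ceilings honoured
  expect_equal(sort(ds$audit$decoy_id), sort(recs$molecule_id))
  expect_true(all(ds$audit$max_tc_active < 0.6))
  expect_true(all(ds$audit$max_tc_decoy < 0.8))
})

test_that("an unconstrained pool fills every active exactly", {
  # decoy pool molecules are dissimilar from the sulfonamide actives and
  # each other by construction at this small scale
  actives <- data.frame(molecule_id = "A1",
                        smiles = "NS(=O)(=O)c1ccc(CC)cc1")
  pool <- generate_decoy_pool(150, seed = 9)
  ds <- generate_decoys(actives, pool, n_per_active = 8)
  expect_equal(nrow(ds$assignments[["A1"]]), 8L)
  expect_equal(length(ds$shortfalls), 0L)
})

test_that("selection equals a brute-force greedy reference at small scale", {
  actives <- data.frame(
    molecule_id = c("A1", "A2"),
    smiles = c("NS(=O)(=O)c1ccc(CC)cc1", "NS(=O)(=O)c1ccc(CO)cc1"))
  pool <- generate_decoy_pool(80, seed = 21)
  n_per <- 4L
  ds <- generate_decoys(actives, pool, n_per_active = n_per)

  # independent oracle: recompute everything from scratch with plain loops
  win0 <- default_decoy_windows()
  pa <- property_vector(setNames(actives$smiles, actives$molecule_id))
  pp <- property_vector(setNames(pool$smiles, pool$molecule_id))
  fa <- fingerprint_matrix(setNames(actives$smiles, actives$molecule_id),
                           "ECFP4")
  fp <- fingerprint_matrix(setNames(pool$smiles, pool$molecule_id), "ECFP4")
  sc <- win0; sc[sc == 0] <- 1
  taken <- character(0)
  expected <- list()
  for (ai in 1:2) {
    picked <- character(0)
    for (round in 0:3) {
      win <- win0 * 1.5^round
      cand <- setdiff(pool$molecule_id, taken)
      keep <- character(0)
      for (cid in cand) {
        d <- abs(as.numeric(pp[cid, ]) - as.numeric(pa[ai, ]))
        if (any(d > win)) next
        tcs_a <- sapply(1:2, function(j) tanimoto(fp[cid, ], fa[j, ]))
        if (any(tcs_a >= 0.6)) next
        keep <- c(keep, cid)
      }
      dist <- vapply(keep, function(cid) {
        sum(abs(as.numeric(pp[cid, ]) - as.numeric(pa[ai, ])) / sc)
      }, numeric(1))
      for (cid in keep[order(dist, keep)]) {
        if (length(picked) >= n_per) break
        tcs_d <- if (length(taken)) {
          sapply(taken, function(t2) tanimoto(fp[cid, ], fp[t2, ]))
        } else 0
        if (any(tcs_d >= 0.8)) next
        picked <- c(picked, cid)
        taken <- c(taken, cid)
      }
      if (length(picked) >= n_per) break
    }
    expected[[actives$molecule_id[ai]]] <- picked
  }
  expect_equal(ds$assignments[["A1"]]$molecule_id, expected[["A1"]])
  expect_equal(ds$assignments[["A2"]]$molecule_id, expected[["A2"]])
})

test_that("decoy generation is deterministic and validates inputs", {
  actives <- data.frame(molecule_id = "A1",
                        smiles = "NS(=O)(=O)c1ccc(CC)cc1")
  pool <- generate_decoy_pool(60, seed = 2)
  d1 <- generate_decoys(actives, pool, n_per_active = 5)
  d2 <- generate_decoys(actives, pool, n_per_active = 5)
  expect_identical(decoy_records(d1), decoy_records(d2))
  expect_error(generate_decoys(actives, pool[0, ], 5), "empty")
  clash <- pool
  clash$molecule_id[1] <- "A1"
  expect_error(generate_decoys(actives, clash, 5), "disjoint")
})
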