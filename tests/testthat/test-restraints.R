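# small literal model: two lysines with NZ atoms at controllable spacing,
# plus one side-chain-less lysine pair for fallback behavior
two_lysine_model <- function(d_nz, d_ca = NULL) {
  rows <- data.frame(
    chain = "A", resno = c(1L, 1L, 5L, 5L), insert = "",
    resid = "LYS", elety = c("CA", "NZ", "CA", "NZ"), elem = c("C", "N"),
    x = c(0, 0, 1, d_nz), y = 0, z = 0, o = 1, b = 0)
  if (!is.null(d_ca)) {
    rows <- rbind(rows, data.frame(
      chain = "A", resno = c(10L, 14L), insert = "", resid = "LYS",
      elety = "CA", elem = "C", x = c(0, d_ca), y = 5, z = 0, o = 1, b = 0))
    rows <- rows[order(rows$resno), ]
  }
  structure_model(rows)
}

pair_df <- function(pa, a, pb, b) {
  data.frame(protein_a = pa, pos_a = a, protein_b = pb, pos_b = b,
             kind = ifelse(pa == pb, "intra", "inter"),
             psm_count = 1L, charges_seen = "3")
}

test_that("restraint bounds follow the DSSO policy per link kind", {
  pol <- restraint_policy()
  res <- build_restraints(rbind(pair_df("R7BP", 86, "R7BP", 93),
                                pair_df("R7BP", 10, "RGS7", 40)),
                          pol, c(R7BP = "A", RGS7 = "B"))
  expect_equal(res$lower, c(0, 10))
  expect_equal(res$upper, c(10, 20))
  expect_equal(res$policy_tag, c("intra", "inter"))
  expect_equal(res$chain_b, c("A", "B"))
  # empty in, empty out; unknown protein is named
  expect_equal(nrow(build_restraints(pair_df("X", 1, "X", 2)[0, ], pol,
                                     c(X = "A"))), 0)
  expect_error(build_restraints(pair_df("X", 1, "Y", 2), pol, c(X = "A")),
               "Y")
})

test_that("evaluation measures distances, violations and fallbacks", {
  pol <- restraint_policy()
  res <- build_restraints(pair_df("P", 1, "P", 5), pol, c(P = "A"))
  # 8 A within the 10 A bound
  rep8 <- evaluate_restraints(two_lysine_model(8), res, pol)
  expect_true(rep8$satisfied)
  expect_equal(rep8$violation, 0)
  expect_equal(rep8$atom_used, "primary")
  expect_equal(rep8$distance, 8)
  # 12 A violates by 2
  rep12 <- evaluate_restraints(two_lysine_model(12), res, pol)
  expect_false(rep12$satisfied)
  expect_equal(rep12$violation, 2)
  expect_equal(rep12$violation_side, "upper_bound")
  # side-chain-less lysines: C-alpha fallback, bounds widened to 0-23
  resf <- build_restraints(pair_df("P", 10, "P", 14), pol, c(P = "A"))
  repf <- evaluate_restraints(two_lysine_model(8, d_ca = 21), resf, pol)
  expect_equal(repf$atom_used, "fallback")
  expect_equal(repf$upper_eff, 23)
  expect_equal(repf$distance, 21)
  expect_true(repf$satisfied)
  # absent residue: missing, not an error
  resm <- build_restraints(pair_df("P", 1, "P", 99), pol, c(P = "A"))
  repm <- evaluate_restraints(two_lysine_model(8), resm, pol)
  expect_equal(repm$atom_used, "missing")
  expect_true(is.na(repm$distance))
})

test_that("inter-chain links below the lower bound are flagged separately", {
  pol <- restraint_policy()
  m <- structure_model(data.frame(
    chain = c("A", "B"), resno = 1L, insert = "", resid = "LYS",
    elety = "NZ", elem = "N", x = c(0, 4), y = 0, z = 0, o = 1, b = 0))
  res <- build_restraints(pair_df("PA", 1, "PB", 1), pol,
                          c(PA = "A", PB = "B"))
  rep <- evaluate_restraints(m, res, pol)
  expect_equal(rep$violation, 6)
  expect_equal(rep$violation_side, "lower_bound")
})

test_that("summaries count and aggregate as defined", {
  pol <- restraint_policy()
  m <- make_bundle_fixture()
  pairs <- dedupe_to_residue_pairs(make_crosslink_table(m, n_pairs = 6,
                                                        seed = 2))
  res <- build_restraints(pairs, pol, c(PROT_A = "A"))
  s <- summarize_restraints(evaluate_restraints(m, res, pol))
  expect_equal(s$n_total, 6)
  expect_equal(s$n_evaluated, 6)
  expect_equal(s$fraction_satisfied, 1)
  expect_equal(s$sum_violations, 0)
  # 3 of 4 satisfied with a single 2.5 A violation
  rep <- data.frame(distance = c(5, 6, 12.5, 7),
                    satisfied = c(TRUE, TRUE, FALSE, TRUE),
                    violation = c(0, 0, 2.5, 0))
  s2 <- summarize_restraints(rep)
  expect_equal(s2$fraction_satisfied, 0.75)
  expect_equal(s2$max_violation, 2.5)
  # degenerate: nothing evaluated
  s0 <- summarize_restraints(rep[0, ])
  expect_equal(s0$n_evaluated, 0)
  expect_true(is.na(s0$fraction_satisfied))
})

test_that("raising upper bounds never decreases satisfaction", {
  for (seed in 1:10) {
    m <- random_helix_fixture(seed)
    lys <- unique(m$atoms$resno[m$atoms$resid == "LYS"])
    combs <- utils::combn(lys, 2)
    pairs <- do.call(rbind, lapply(seq_len(ncol(combs)), function(k) {
      pair_df("PROT_A", combs[1, k], "PROT_A", combs[2, k])
    }))
    prev <- -1
    for (up in c(6, 10, 14, 20, 30)) {
      pol <- restraint_policy(intra_max = up)
      res <- build_restraints(pairs, pol, c(PROT_A = "A"))
      s <- summarize_restraints(evaluate_restraints(m, res, pol))
      expect_gte(s$n_satisfied, prev)
      prev <- s$n_satisfied
    }
  }
})

test_that("reports are order-independent", {
  m <- make_bundle_fixture()
  pol <- restraint_policy()
  pairs <- dedupe_to_residue_pairs(make_crosslink_table(m, n_pairs = 10,
                                                        seed = 3))
  res <- build_restraints(pairs, pol, c(PROT_A = "A"))
  set.seed(1)
  perm <- sample(nrow(res))
  rep1 <- evaluate_restraints(m, res, pol)
  rep2 <- evaluate_restraints(m, res[perm, ], pol)
  rownames(rep1) <- rownames(rep2) <- NULL
  expect_equal(rep2, rep1[perm, ], ignore_attr = TRUE)
})

test_that("evaluation agrees with the brute-force distance oracle", {
  pol <- restraint_policy()
  for (seed in 1:10) {
    m <- random_helix_fixture(seed)
    lys <- unique(m$atoms$resno[m$atoms$resid == "LYS"])
    combs <- utils::combn(lys, 2)
    pairs <- do.call(rbind, lapply(seq_len(ncol(combs)), function(k) {
      pair_df("PROT_A", combs[1, k], "PROT_A", combs[2, k])
    }))
    res <- build_restraints(pairs, pol, c(PROT_A = "A"))
    rep <- evaluate_restraints(m, res, pol)
    oracle <- brute_restraint_eval(m, res, pol)
    expect_equal(rep$distance, oracle$distance, tolerance = 1e-12)
    expect_equal(rep$violation, oracle$violation, tolerance = 1e-12)
    expect_equal(rep$atom_used, oracle$atom_used)
  }
})
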