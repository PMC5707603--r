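test_that("expected flux is the group mean, with degenerate groupings", {
  rec <- toy_records()
  # full grouping: CNT1 rows split by rep into groups {10,14} and {20,24}
  ef <- expected_flux(rec)
  expect_equal(ef[1:4], c(12, 12, 22, 22))
  # singleton groups return the case's own flux
  one <- rec[c(1, 3), ]
  expect_equal(as.numeric(expected_flux(one)), one$flux)
  # empty grouping: global mean
  expect_equal(as.numeric(expected_flux(rec, grouping = character(0))),
               rep(mean(rec$flux), nrow(rec)))
  expect_error(expected_flux(rec[0, ]), "empty")
  expect_error(expected_flux(rec, grouping = "Buffer"), "unknown condition")
})

test_that("MA operators center invariants per condition level", {
  rec <- toy_records()
  inv <- toy_invariants()
  ma <- ma_operators(inv, rec, "Solvent")
  # CNT1 solvent H2O only, CNT2 DMSO only: deviations from own-level mean = 0
  expect_true(all(abs(ma$dTr2_Solvent) < 1e-10))
  # two CNTs share the rep levels: Tr2 is 6 for both 3-symbol sequences,
  # Tre2 differs ("abn" embeds 5 edges, "npq" 5 too) — engineer a difference
  inv2 <- inv
  inv2$Tre2[2] <- inv2$Tre2[1] + 6
  ma <- ma_operators(inv2, rec, "rep")
  for (lev in unique(rec$rep)) {
    expect_lt(abs(mean(ma$dTre2_rep[rec$rep == lev])), 1e-10)
  }
  expect_equal(ma$dTre2_rep, rep(c(-3, 3), each = 4))
  expect_error(ma_operators(inv, rec, "Temperature"), "unknown condition")
})

test_that("MA operators are shift-invariant and handle controls", {
  rec <- toy_records()
  inv <- toy_invariants()
  shifted <- inv
  num <- vapply(shifted, is.numeric, logical(1))
  shifted[num] <- shifted[num] + 100
  for (cond in c("rep", "CNTtype", "FuncType", "Solvent")) {
    expect_equal(ma_operators(inv, rec, cond), ma_operators(shifted, rec, cond))
  }
  # control rows get zero invariants, hence defined (nonzero) deviations
  ctrl <- rec[1, ]
  ctrl$cnt_id <- "0"; ctrl$cnt_type <- "0"; ctrl$func_type <- "0"
  ma <- ma_operators(inv, rbind(rec, ctrl), "Solvent")
  expect_true(is.finite(ma$dTr2_Solvent[9]))
  expect_error(ma_operators(inv, transform(rec, cnt_id = "CNT9"), "Solvent"),
               "CNT9")
})

test_that("feature assembly has the documented shape and subsets", {
  rec <- toy_records()
  inv <- toy_invariants()
  ft <- assemble_feature_table(rec, inv)
  expect_equal(ncol(ft), 2 + 2 * 6 * 4 + 1)  # features + target
  expect_true(!anyNA(ft))
  ft8 <- assemble_feature_table(rec, inv, subset = "paper8")
  expect_equal(names(ft8), c(paper8_columns(), "flux"))
  expect_error(assemble_feature_table(rec[0, ], inv), "empty")
  expect_error(assemble_feature_table(rec, inv, subset = c("Jm_expected", "bogus")),
               "bogus")
})

test_that("feature assembly is row-order independent", {
  rec <- toy_records()
  inv <- toy_invariants()
  a <- assemble_feature_table(rec, inv)
  set.seed(9)
  b <- assemble_feature_table(rec[sample(nrow(rec)), ], inv)
  expect_equal(a, b)
})

test_that("linear PTML prediction evaluates the model equation", {
  row <- data.frame(Jm_expected = 12, t = 100, dTr2_Solvent = -3)
  expect_equal(predict_linear_ptml(ptml_coefficients(a0 = 1.5), row), 1.5)
  expect_equal(predict_linear_ptml(ptml_coefficients(a1 = 1), row), 12)
  cf <- ptml_coefficients(a0 = 1, a1 = 0.5, a2 = 0.01, beta = c(dTr2_Solvent = 2))
  expect_equal(predict_linear_ptml(cf, row), 2)
  # configurable time transform
  cf_log <- ptml_coefficients(a2 = 1, f_t = log10)
  expect_equal(predict_linear_ptml(cf_log, row), 2)
  expect_error(predict_linear_ptml(ptml_coefficients(beta = c(dTr9_X = 1)), row),
               "missing column")
})
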