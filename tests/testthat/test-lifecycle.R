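test_that("state enumeration covers every copy pair exactly once", {
  s1 <- enumerate_states(model_config(1))
  expect_equal(nrow(s1), 6L)
  expect_setequal(rownames(s1),
                  c("(0,0)", "(0,1)", "(1,0)", "(1,1)", "(0,2)", "(2,0)"))
  # ordered by (total, i1): stable documented layout
  expect_equal(unname(s1[, 1] + s1[, 2]), c(0, 1, 1, 2, 2, 2))
  expect_true(all(diff(order(s1[, 1] + s1[, 2], s1[, 1])) == 1))

  s5 <- enumerate_states(cfg5)
  expect_equal(nrow(s5), 66L)  # pairs with sum <= 10: 11 * 12 / 2
  expect_equal(anyDuplicated(rownames(s5)), 0L)
  expect_error(model_config(0), "positive")
})

test_that("replication pmf matches exhaustive Polya urn path enumeration", {
  cases <- list(c(1, 1, 2), c(1, 2, 3), c(2, 1, 3), c(1, 1, 3), c(3, 2, 4))
  for (cs in cases) {
    cfg <- model_config(cs[3])
    tab <- replication_pmf(cs[1:2], cfg)
    brute <- urn_brute_force(cs[1], cs[2], cs[3])
    for (J1 in 0:(2 * cs[3]))
      expect_equal(pmf_prob(tab, J1, 2 * cs[3] - J1), brute[J1 + 1],
                   tolerance = 1e-12,
                   label = sprintf("state (%d,%d), n_c=%d, J1=%d",
                                   cs[1], cs[2], cs[3], J1))
    expect_equal(sum(tab$prob), 1, tolerance = 1e-12)
  }
  # (1,1) at n_c=2: each of (1,3), (2,2), (3,1) with probability 1/3
  tab <- replication_pmf(c(1, 1), model_config(2))
  expect_equal(tab$prob, rep(1 / 3, 3))
})

test_that("replication degenerate cases: no template and saturation", {
  tab0 <- replication_pmf(c(0, 0), cfg5)
  expect_equal(tab0, data.frame(J1 = 0L, J2 = 0L, prob = 1))
  tab_h <- replication_pmf(c(3, 0), cfg5)     # homoplasmic urn fills up
  expect_equal(tab_h$prob[tab_h$J1 == 10], 1)
  tab_s <- replication_pmf(c(4, 6), cfg5)     # already at 2 n_c
  expect_equal(tab_s, data.frame(J1 = 4L, J2 = 6L, prob = 1))
  expect_error(replication_pmf(c(7, 6), cfg5), "exceeds")
})

test_that("monomerization removes only newly replicated copies", {
  uu <- list(presets$U, presets$U)
  # p_def = 0 keeps the whole replication outcome
  ss <- list(presets$S, presets$S)
  tab <- monomerization_pmf(c(1, 0), c(10, 0), ss, cfg5)
  expect_equal(tab$prob[tab$J1 == 10 & tab$J2 == 0], 1)
  # p_def = 1 strips every new copy, originals survive
  dead <- plasmid_variant("dead", p_def = 1)
  tab <- monomerization_pmf(c(1, 0), c(10, 0), list(dead, dead), cfg5)
  expect_equal(tab$prob[tab$J1 == 1 & tab$J2 == 0], 1)
  # p_def = 0.5, one original + two replicates: binomial over 2 trials
  half <- plasmid_variant("half", p_def = 0.5)
  tab <- monomerization_pmf(c(1, 0), c(3, 0), list(half, half),
                            model_config(2))
  expect_equal(vapply(1:3, function(j) pmf_prob(tab, j, 0), numeric(1)),
               c(0.25, 0.5, 0.25))
  expect_error(monomerization_pmf(c(2, 0), c(1, 0), uu, cfg5), "J >= i")
})

test_that("assortment pmf: fair binomial, perfect pairing, mixed case", {
  uu <- list(presets$U, presets$S)
  # no partition, two copies
  tab <- division_pmf(c(2, 0), uu)
  expect_equal(vapply(0:2, function(j) pmf_prob(tab, j, 0), numeric(1)),
               c(0.25, 0.5, 0.25))
  # perfect partitioning of four copies: both pairs split
  full <- plasmid_variant("full", p_par = 1)
  tab <- division_pmf(c(4, 0), list(full, presets$S))
  expect_equal(pmf_prob(tab, 2, 0), 1)
  # p_par = 0.5 with two copies: enumerate the split/fail branches
  tab <- division_pmf(c(2, 0), list(presets$P, presets$S))
  p <- presets$P$p_par
  expect_equal(vapply(0:2, function(j) pmf_prob(tab, j, 0), numeric(1)),
               c((1 - p) / 4, p + (1 - p) / 2, (1 - p) / 4))
})

test_that("assortment is daughter-exchangeable and conserves copies", {
  variants <- list(presets$PT, presets$U)
  for (J1 in 0:6) for (J2 in c(0, 3)) {
    tab <- division_pmf(c(J1, J2), variants)
    expect_equal(sum(tab$prob), 1, tolerance = 1e-12)
    for (r in seq_len(nrow(tab)))
      expect_equal(tab$prob[r],
                   pmf_prob(tab, J1 - tab$j1[r], J2 - tab$j2[r]),
                   tolerance = 1e-12)
    expect_equal(sum(tab$j1 * tab$prob), J1 / 2, tolerance = 1e-12)
    expect_equal(sum(tab$j2 * tab$prob), J2 / 2, tolerance = 1e-12)
  }
})

test_that("post-segregational killing survival follows loss of the TA plasmid", {
  ts <- list(presets$T, presets$S)
  expect_equal(psk_survival(c(1, 1), c(0, 2), ts), 1 - 0.883)
  expect_equal(psk_survival(c(1, 1), c(1, 0), ts), 1)
  expect_equal(psk_survival(c(0, 2), c(0, 1), ts), 1)  # parent lacked T
  st <- list(presets$S, presets$T)                     # TA in slot 2
  expect_equal(psk_survival(c(1, 1), c(2, 0), st), 1 - 0.883)
  expect_equal(psk_survival(c(1, 0), c(0, 0), ts), 1 - 0.883)
})
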