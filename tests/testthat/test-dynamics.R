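test_that("per-generation renormalization equals the normalized matrix power", {
  k <- build_kernel(presets$T, presets$S, model_config(3))
  traj <- propagate(k, c(1, 1), 20)
  P <- diag(nrow(k$matrix))
  x0 <- as.numeric(rownames(k$states) == "(1,1)")
  for (g in 1:20) {
    P <- k$matrix %*% P
    xg <- as.numeric(P %*% x0)
    expect_equal(traj$proportions[, g + 1], xg / sum(xg),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  expect_equal(unname(colSums(traj$proportions)), rep(1, 21),
               tolerance = 1e-10)
})

test_that("class proportions partition the population at every generation", {
  k <- build_kernel(presets$PT, presets$U, cfg5)
  cl <- propagate(k, c(1, 1), 50)$classes
  expect_equal(cl$homoplasmic_1 + cl$homoplasmic_2 + cl$heteroplasmic +
                 cl$plasmid_free,
               rep(1, 51), tolerance = 1e-10)
  expect_true(all(as.matrix(cl[, -1]) >= -1e-15))
  # plasmid-free proportion is monotone for TA-free pairs
  cl_free <- propagate(build_kernel(presets$U, presets$P, cfg5),
                       c(1, 1), 100)$classes$plasmid_free
  expect_true(all(diff(cl_free) >= -1e-12))
})

test_that("the plasmid-free state is absorbing", {
  k <- build_kernel(presets$U, config = cfg5)
  traj <- propagate(k, c(0, 0), 10)
  expect_equal(unname(traj$proportions["(0,0)", ]), rep(1, 11))
})

test_that("stable-variant persistence follows the closed-form decay", {
  k <- build_kernel(variant_preset("S"), config = cfg5)
  res <- persistence(k, g_max = 300)
  g <- res$host_curve$generation
  expect_equal(res$host_curve$host, (1 - 1 / 1024)^g, tolerance = 1e-12)
  expect_equal(res$seg_rate, 2^(1 - 2 * 5), tolerance = 1e-12)
  # 50% not reached in 300 generations: explicit "not reached", no error
  expect_false(res$reached)
  expect_true(is.na(res$half_life))
})

test_that("segregation rate: closed form, partition bound, TA invariance", {
  expect_equal(asymptotic_seg_rate(build_kernel(presets$S, config = cfg5)),
               1 / 512, tolerance = 1e-10)
  # cross-check the power iteration against a dense eigendecomposition
  ku <- build_kernel(presets$U, config = cfg5)
  host <- ku$states[, 1] > 0 & ku$states[, 2] == 0
  lam <- max(Re(eigen(ku$matrix[host, host])$values))
  expect_equal(asymptotic_seg_rate(ku), 2 - lam, tolerance = 1e-10)
  # with perfect monomerization, partitioning can only slow the loss
  for (p_par in c(0.25, 0.5, 1)) {
    v <- plasmid_variant("par", p_def = 0, p_par = p_par)
    expect_lte(asymptotic_seg_rate(build_kernel(v, config = cfg5)),
               2^(1 - 2 * 5) + 1e-12)
  }
  # killing leaves host-to-host transitions (hence the rate) untouched
  kt <- build_kernel(presets$T, config = cfg5)
  expect_equal(kt$matrix[host, host], ku$matrix[host, host],
               tolerance = 1e-15)
  expect_equal(asymptotic_seg_rate(kt), asymptotic_seg_rate(ku),
               tolerance = 1e-12)
})

test_that("half-life responds monotonically to the stability parameters", {
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  half_life <- function(p_def, p_par) {
    v <- plasmid_variant("g", p_def = p_def, p_par = p_par)
    res <- persistence(build_kernel(v, config = cfg5), g_max = 1500)
    if (res$reached) res$half_life_continuous else Inf
  }
  H <- outer(grid, grid, Vectorize(half_life))
  # loss-free corners (p_def = 0 with partitioning) are Inf == Inf ties
  no_greater <- function(a, b) a <= b + 1e-9 | (is.infinite(a) & is.infinite(b))
  # rows: p_def increasing -> half-life non-increasing
  for (j in seq_along(grid))
    expect_true(all(no_greater(H[-1, j], H[-length(grid), j])))
  # cols: p_par increasing -> half-life non-decreasing
  for (i in seq_along(grid))
    expect_true(all(no_greater(H[i, -length(grid)], H[i, -1])))
})

test_that("persistence half-lives order as U < P < PT < S", {
  hl <- vapply(c("U", "P", "PT", "S"), function(lab) {
    persistence(build_kernel(variant_preset(lab), config = cfg5),
                g_max = 1200)$half_life_continuous
  }, numeric(1))
  expect_true(all(diff(hl) > 0))
})

test_that("TA killing defers but does not change the asymptotic loss rate", {
  hT <- persistence(build_kernel(presets$T, config = cfg5), 520)$host_curve$host
  hU <- persistence(build_kernel(presets$U, config = cfg5), 520)$host_curve$host
  fT <- hT[402:501] / hT[401:500]
  fU <- hU[402:501] / hU[401:500]
  # the factors converge like h_T(g) itself; by g = 400 they agree to ~2e-4
  expect_lt(max(abs(fT - fU)), 1e-3)
  # and T clearly outlives U: half-life deferred by roughly 100 generations
  expect_gt(which(hT <= 0.5)[1], which(hU <= 0.5)[1] + 80)
})

test_that("competition between identical variants never crosses", {
  k <- build_kernel(presets$U, plasmid_variant("U2", p_def = 0.494), cfg5)
  res <- compete(k, g_max = 150)
  expect_true(is.na(res$crossing_generation))
  cl <- res$trajectory$classes
  expect_equal(cl$homoplasmic_1, cl$homoplasmic_2, tolerance = 1e-12)
})

test_that("founders outside the state space are rejected", {
  k <- build_kernel(presets$U, config = cfg5)
  expect_error(propagate(k, c(11, 0), 5), "exceeds")
  expect_error(propagate(k, c(-1, 0), 5), "non-negative")
  expect_error(compete(k, 10), "two-variant")
  expect_error(persistence(build_kernel(presets$T, presets$S, cfg5)),
               "single-plasmid")
})
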