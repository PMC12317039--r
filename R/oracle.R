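# Seeded agent-level Monte-Carlo simulation of the identical life cycle.
# This is a brute-force correctness oracle for the analytic kernel and a
# window into finite-population behavior; it is not performance-oriented.
#
# All randomness goes through R's global generator; functions that take a
# `seed` argument call set.seed() on entry so that identical seeds give
# bit-identical output.

#' Simulate individual cell divisions
#'
#' Draws `n` independent divisions of cells in the given birth state by
#' simulating the life cycle event by event: a sequential Polya urn for
#' replication, per-replicate Bernoulli(`p_def`) removal, pair formation
#' with Bernoulli(`p_par`) splitting, fair assortment of the remaining
#' copies, and Bernoulli(`1 - p_eff`) survival for daughters that lost a
#' TA-carrying plasmid.  No analytic shortcut from the kernel is used, so
#' the output is an independent check on [build_kernel()].
#'
#' @param state Parent cell state `(i1, i2)`.
#' @param variant1,variant2 [plasmid_variant()] objects (`variant2` may be
#'   `NULL` for a single-plasmid configuration).
#' @param config A [model_config()].
#' @param n Number of divisions to simulate.
#' @param seed Optional integer seed.
#' @return A list with `daughter1`, `daughter2` (`n x 2` integer matrices
#'   of copy numbers), `survived1`, `survived2` (logical vectors) and
#'   `mon` (the post-monomerization pools).
#' @export
simulate_divisions <- function(state, variant1, variant2 = NULL,
                               config = model_config(), n = 1e5,
                               seed = NULL) {
  vp <- .as_variant_pair(variant1, variant2)
  v1 <- vp$variant1; v2 <- vp$variant2
  state <- .check_state(state, config)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  i1 <- state[1L]; i2 <- state[2L]
  n_c <- config$n_c

  # replication: sequential urn draws, vectorized across divisions
  tot <- i1 + i2
  if (tot == 0L) {
    J1r <- integer(n); J2r <- integer(n)
  } else {
    c1 <- rep(i1, n); c2 <- rep(i2, n)
    m <- 2L * n_c - tot
    if (m > 0L) for (s in seq_len(m)) {
      pick1 <- stats::runif(n) < c1 / (c1 + c2)
      c1 <- c1 + pick1
      c2 <- c2 + !pick1
    }
    J1r <- as.integer(c1); J2r <- as.integer(c2)
  }

  # monomerization: only newly replicated copies can be removed
  J1m <- i1 + stats::rbinom(n, J1r - i1, 1 - v1$p_def)
  J2m <- i2 + stats::rbinom(n, J2r - i2, 1 - v2$p_def)

  # assortment: split pairs, then fair coin flips for the rest
  s1 <- stats::rbinom(n, J1m %/% 2L, v1$p_par)
  j1 <- s1 + stats::rbinom(n, J1m - 2L * s1, 0.5)
  s2 <- stats::rbinom(n, J2m %/% 2L, v2$p_par)
  j2 <- s2 + stats::rbinom(n, J2m - 2L * s2, 0.5)

  d1 <- cbind(j1 = j1, j2 = j2)
  d2 <- cbind(j1 = J1m - j1, j2 = J2m - j2)

  surv <- function(d) {
    ok <- rep(TRUE, n)
    if (v1$has_ta && i1 > 0L) {
      lost <- d[, 1L] == 0L
      ok[lost] <- stats::runif(sum(lost)) < 1 - v1$p_eff
    }
    if (v2$has_ta && i2 > 0L) {
      lost <- d[, 2L] == 0L
      ok[lost] <- ok[lost] & (stats::runif(sum(lost)) < 1 - v2$p_eff)
    }
    ok
  }

  list(daughter1 = d1, daughter2 = d2,
       survived1 = surv(d1), survived2 = surv(d2),
       mon = cbind(J1m = J1m, J2m = J2m))
}

#' Compare Monte-Carlo daughter frequencies with the analytic kernel
#'
#' Simulates `n` divisions from one parent state and tests the observed
#' frequencies of (surviving daughter state, killed) outcomes of the focal
#' daughter against the kernel prediction `p[i -> j] * p_surv[i -> j]`
#' with a chi-squared goodness-of-fit test.  Outcome categories with
#' expected count below `min_expected` are pooled.
#'
#' @inheritParams simulate_divisions
#' @param min_expected Minimum expected count per chi-squared category.
#' @return A list with the observed and expected counts, the chi-squared
#'   statistic and its `p_value`.
#' @export
oracle_check <- function(state, variant1, variant2 = NULL,
                         config = model_config(), n = 1e5, seed = NULL,
                         min_expected = 5) {
  kernel <- build_kernel(variant1, variant2, config)
  col <- .find_state(kernel, state)
  # P(focal daughter = j and survives) = A[j, i] / 2; remainder is death
  p_surv_state <- kernel$matrix[, col] / 2
  p_die <- max(0, 1 - sum(p_surv_state))
  expected_p <- c(p_surv_state, killed = p_die)

  sim <- simulate_divisions(state, variant1, variant2, config, n, seed)
  idx <- .state_lookup(kernel$states, config$n_c)
  d_idx <- idx[cbind(sim$daughter1[, 1L] + 1L, sim$daughter1[, 2L] + 1L)]
  cat_obs <- ifelse(sim$survived1, d_idx, length(expected_p))
  obs <- tabulate(cat_obs, nbins = length(expected_p))
  names(obs) <- names(expected_p)

  keep <- expected_p * n >= min_expected
  if (any(obs[!keep & expected_p == 0] > 0))
    stop("observed outcomes in categories with zero predicted probability",
         call. = FALSE)
  obs_pooled <- c(obs[keep], pooled = sum(obs[!keep]))
  exp_pooled <- c(expected_p[keep], pooled = sum(expected_p[!keep]))
  np <- length(exp_pooled)
  if (exp_pooled[[np]] * n < min_expected) {
    # fold an undersized pooled remainder into the smallest kept category
    # so every chi-squared bin meets the expected-count requirement
    small <- which.min(exp_pooled[-np])
    obs_pooled[small] <- obs_pooled[small] + obs_pooled[np]
    exp_pooled[small] <- exp_pooled[small] + exp_pooled[np]
    obs_pooled <- obs_pooled[-np]
    exp_pooled <- exp_pooled[-np]
  }
  test <- stats::chisq.test(obs_pooled, p = exp_pooled / sum(exp_pooled))
  list(observed = obs, expected = expected_p * n,
       statistic = unname(test$statistic), p_value = unname(test$p.value),
       n = n)
}

#' Simulate a growing population of cells
#'
#' Agent-level simulation of the whole population, one generation at a
#' time.  The population is stored as counts per cell state; every cell
#' divides each generation and surviving daughters form the next
#' generation.  Because the population doubles every generation, it is
#' subsampled without replacement back to `cap` cells whenever it exceeds
#' the cap; class frequencies are unbiased under this subsampling.
#'
#' @param variant1,variant2 [plasmid_variant()] objects (`variant2`
#'   optional).
#' @param config A [model_config()].
#' @param founder Founder state for all starting cells.
#' @param generations Number of generations to simulate.
#' @param n_founders Number of founder cells.
#' @param cap Population cap triggering subsampling.
#' @param seed Optional integer seed.
#' @return A data frame with one row per generation: the four class
#'   proportions, the host fraction `host` with its binomial standard
#'   error `se`, and the (possibly capped) population size `n`.  Note that
#'   `se` quantifies the per-generation sampling error only; once the cap
#'   is active the subsampling noise accumulates over generations, so the
#'   cumulative Monte-Carlo error of late generations grows roughly like
#'   `se * sqrt(generations)`.
#' @export
simulate_population <- function(variant1, variant2 = NULL,
                                config = model_config(),
                                founder = c(1L, 0L), generations = 50,
                                n_founders = 1e4, cap = 1e5, seed = NULL) {
  vp <- .as_variant_pair(variant1, variant2)
  if (!is.null(seed)) set.seed(seed)
  states <- enumerate_states(config)
  ns <- nrow(states)
  idx <- .state_lookup(states, config$n_c)
  free_idx <- idx[1L, 1L]
  masks <- .class_masks(states)
  counts <- integer(ns)
  counts[idx[founder[1L] + 1L, founder[2L] + 1L]] <- as.integer(n_founders)

  summarize <- function(g, counts) {
    n <- sum(counts)
    h <- if (n == 0) 0 else 1 - counts[free_idx] / n
    data.frame(
      generation = g,
      homoplasmic_1 = sum(counts[masks$homoplasmic_1]) / max(n, 1),
      homoplasmic_2 = sum(counts[masks$homoplasmic_2]) / max(n, 1),
      heteroplasmic = sum(counts[masks$heteroplasmic]) / max(n, 1),
      plasmid_free = sum(counts[masks$plasmid_free]) / max(n, 1),
      host = h, se = sqrt(h * (1 - h) / max(n, 1)), n = n)
  }

  out <- summarize(0L, counts)
  for (g in seq_len(generations)) {
    new_counts <- integer(ns)
    # plasmid-free cells divide into two plasmid-free daughters
    new_counts[free_idx] <- 2L * counts[free_idx]
    for (st in which(counts > 0L)) {
      if (st == free_idx) next
      sim <- simulate_divisions(states[st, ], vp$variant1,
                                if (vp$single) NULL else vp$variant2,
                                config, n = counts[st])
      for (side in 1:2) {
        d <- if (side == 1L) sim$daughter1 else sim$daughter2
        ok <- if (side == 1L) sim$survived1 else sim$survived2
        if (!any(ok)) next
        di <- idx[cbind(d[ok, 1L] + 1L, d[ok, 2L] + 1L)]
        tab <- tabulate(di, nbins = ns)
        new_counts <- new_counts + tab
      }
    }
    total <- sum(new_counts)
    if (total > cap) {
      new_counts <- as.integer(stats::rmultinom(1L, cap,
                                                new_counts / total))
    }
    counts <- new_counts
    out <- rbind(out, summarize(g, counts))
    if (sum(counts) == 0L) break
  }
  rownames(out) <- NULL
  out
}

#' Monte-Carlo estimate of the host fraction over generations
#'
#' Convenience wrapper around [simulate_population()] for a single-plasmid
#' configuration started from homoplasmic single-copy founders: returns
#' the per-generation host-fraction estimate with its binomial standard
#' error.
#'
#' @param variant A [plasmid_variant()].
#' @param config A [model_config()].
#' @param founders Number of founder cells.
#' @param generations Number of generations.
#' @param seed Optional integer seed.
#' @param cap Population cap (see [simulate_population()]).
#' @return Data frame with columns `generation`, `host`, `se`, `n`.
#' @export
estimate_host_fraction <- function(variant, config = model_config(),
                                   founders = 1e4, generations = 50,
                                   seed = NULL, cap = 1e5) {
  sim <- simulate_population(variant, NULL, config,
                             founder = c(1L, 0L),
                             generations = generations,
                             n_founders = founders, cap = cap, seed = seed)
  sim[, c("generation", "host", "se", "n")]
}
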