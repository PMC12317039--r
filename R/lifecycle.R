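# Exact per-generation probability distributions of the plasmid life cycle:
# Polya-urn replication, binomial monomerization depletion, (balanced)
# assortment at division, and post-segregational killing.

#' Enumerate all cell states
#'
#' A cell state is the pair of plasmid copy numbers `(i1, i2)` of the two
#' variants at cell birth.  All pairs with `i1 + i2 <= 2 * n_c` are valid;
#' `(0, 0)` is the unique plasmid-free state.  States are ordered
#' lexicographically by `(i1 + i2, i1)`, which is the stable layout used by
#' every matrix in the package.
#'
#' @param config A [model_config()].
#' @return Integer matrix with columns `i1`, `i2`; one row per state.
#' @examples
#' nrow(enumerate_states(model_config(5)))  # 66 states
#' @export
enumerate_states <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  two_nc <- 2L * config$n_c
  states <- do.call(rbind, lapply(0:two_nc, function(s) {
    cbind(i1 = 0:s, i2 = s - 0:s)
  }))
  rownames(states) <- sprintf("(%d,%d)", states[, 1L], states[, 2L])
  states
}

# Internal: dense lookup i1 x i2 -> state row index.
.state_lookup <- function(states, n_c) {
  idx <- matrix(NA_integer_, 2L * n_c + 1L, 2L * n_c + 1L)
  idx[cbind(states[, 1L] + 1L, states[, 2L] + 1L)] <- seq_len(nrow(states))
  idx
}

.check_state <- function(state, config) {
  if (!is.numeric(state) || length(state) != 2L || anyNA(state) ||
      any(state < 0) || any(state != round(state)))
    stop("a cell state must be two non-negative integers (i1, i2)",
         call. = FALSE)
  if (sum(state) > 2L * config$n_c)
    stop("invalid cell state: i1 + i2 exceeds 2 * n_c", call. = FALSE)
  as.integer(state)
}

# Rising factorial a^(k up) = a (a+1) ... (a+k-1), with a^(0 up) = 1.
.rising <- function(a, k) if (k == 0L) 1 else prod(a + seq_len(k) - 1)

#' Replication distribution (Polya urn)
#'
#' Starting from `(i1, i2)` copies at birth, plasmids are drawn one at a
#' time for replication with replacement-plus-return until the cell holds
#' `2 * n_c` copies.  The number of replications won by variant 1 then
#' follows the Polya-Eggenberger distribution.  Cells without plasmids do
#' not replicate; cells already at saturation keep their copy numbers.
#'
#' @param state Integer pair `(i1, i2)`.
#' @param config A [model_config()].
#' @return Data frame with columns `J1`, `J2` (post-replication copy
#'   numbers) and `prob`; probabilities sum to 1.
#' @examples
#' replication_pmf(c(1, 1), model_config(2))  # (1,3),(2,2),(3,1) each 1/3
#' @export
replication_pmf <- function(state, config = model_config()) {
  state <- .check_state(state, config)
  i1 <- state[1L]; i2 <- state[2L]
  n <- i1 + i2
  m <- 2L * config$n_c - n
  if (n == 0L)
    return(data.frame(J1 = 0L, J2 = 0L, prob = 1))
  if (m <= 0L)
    return(data.frame(J1 = i1, J2 = i2, prob = 1))
  k <- 0:m
  prob <- vapply(k, function(kk) {
    choose(m, kk) * .rising(i1, kk) * .rising(i2, m - kk) / .rising(n, m)
  }, numeric(1L))
  data.frame(J1 = i1 + k, J2 = i2 + m - k, prob = prob)
}

#' Monomerization distribution
#'
#' Each newly replicated copy (never the copies already present at birth)
#' is independently removed from the pool of segregating units with its
#' variant's monomerization deficiency `p_def`.  The two variants are
#' depleted independently.
#'
#' @param state Copy numbers `(i1, i2)` at birth.
#' @param rep_outcome Post-replication copy numbers `(J1, J2)`; must
#'   satisfy `J >= i` componentwise.
#' @param variants List of two [plasmid_variant()] objects (second may be
#'   omitted by passing the result of a single-variant pair).
#' @param config A [model_config()].
#' @return Data frame with columns `J1`, `J2` (post-monomerization copy
#'   numbers) and `prob`.
#' @export
monomerization_pmf <- function(state, rep_outcome, variants,
                               config = model_config()) {
  state <- .check_state(state, config)
  rep_outcome <- as.integer(rep_outcome)
  if (length(rep_outcome) != 2L || any(rep_outcome < state))
    stop("`rep_outcome` must be a copy pair with J >= i componentwise",
         call. = FALSE)
  v1 <- variants[[1L]]; v2 <- variants[[2L]]
  new1 <- rep_outcome[1L] - state[1L]
  new2 <- rep_outcome[2L] - state[2L]
  kept1 <- 0:new1
  kept2 <- 0:new2
  p1 <- stats::dbinom(kept1, new1, 1 - v1$p_def)
  p2 <- stats::dbinom(kept2, new2, 1 - v2$p_def)
  grid <- expand.grid(k1 = kept1, k2 = kept2)
  data.frame(J1 = state[1L] + grid$k1,
             J2 = state[2L] + grid$k2,
             prob = p1[grid$k1 + 1L] * p2[grid$k2 + 1L])
}

# Internal: marginal assortment pmf of one variant.  J copies form
# floor(J/2) pairs; S ~ Binomial(pairs, p_par) pairs are split one copy per
# daughter, and the remaining J - 2S copies (copies of failed pairs plus
# any unpaired copy) go to the focal daughter independently with
# probability 1/2.  With p_par = 0 this reduces to Binomial(J, 1/2).
.assort_pmf <- function(J, p_par) {
  if (J == 0L) return(1)
  q <- J %/% 2L
  p <- numeric(J + 1L)
  for (s in 0:q) {
    rest <- J - 2L * s
    p[(s + 0:rest) + 1L] <- p[(s + 0:rest) + 1L] +
      stats::dbinom(s, q, p_par) * stats::dbinom(0:rest, rest, 0.5)
  }
  p
}

#' Division (assortment) distribution
#'
#' Distribution of one daughter cell's copy numbers given the
#' post-monomerization pool.  Variants are assorted independently of each
#' other; within a variant, pairwise balanced assortment applies with that
#' variant's `p_par` and everything not successfully partitioned is
#' distributed fairly at random.  The complementary daughter receives the
#' remaining copies, so the distribution is exchangeable between daughters.
#'
#' @param mon_outcome Post-monomerization copy pair `(J1, J2)`.
#' @param variants List of two [plasmid_variant()] objects.
#' @return Data frame with columns `j1`, `j2` (one daughter's copy
#'   numbers) and `prob`.
#' @examples
#' # two copies, no partition system: 1/4, 1/2, 1/4
#' division_pmf(c(2, 0), list(variant_preset("U"), variant_preset("S")))
#' @export
division_pmf <- function(mon_outcome, variants) {
  mon_outcome <- as.integer(mon_outcome)
  if (length(mon_outcome) != 2L || anyNA(mon_outcome) || any(mon_outcome < 0))
    stop("`mon_outcome` must be two non-negative integers", call. = FALSE)
  a1 <- .assort_pmf(mon_outcome[1L], variants[[1L]]$p_par)
  a2 <- .assort_pmf(mon_outcome[2L], variants[[2L]]$p_par)
  grid <- expand.grid(j1 = 0:mon_outcome[1L], j2 = 0:mon_outcome[2L])
  data.frame(j1 = grid$j1, j2 = grid$j2,
             prob = a1[grid$j1 + 1L] * a2[grid$j2 + 1L])
}

#' Post-segregational killing survival probability
#'
#' A daughter cell that lost all copies of a TA-carrying variant present in
#' its parent survives only with probability `1 - p_eff` (killing escape).
#' All other daughters survive with probability 1.  Configurations where
#' both variants carry a TA system are not supported.
#'
#' @param parent,daughter Copy pairs `(i1, i2)` and `(j1, j2)`.
#' @param variants List of two [plasmid_variant()] objects.
#' @return Survival probability in `[0, 1]`.
#' @export
psk_survival <- function(parent, daughter, variants) {
  v1 <- variants[[1L]]; v2 <- variants[[2L]]
  if (v1$has_ta && v2$has_ta)
    stop("unsupported configuration: both variants carry a TA system",
         call. = FALSE)
  surv <- 1
  if (v1$has_ta && parent[1L] > 0 && daughter[1L] == 0)
    surv <- surv * (1 - v1$p_eff)
  if (v2$has_ta && parent[2L] > 0 && daughter[2L] == 0)
    surv <- surv * (1 - v2$p_eff)
  surv
}
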