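# Calibration of (p_def, p_par, p_eff) from serial-transfer persistence
# data: binomial maximum likelihood against the model-predicted host
# fraction, with bootstrap confidence intervals over replicates.

#' Convert serial-transfer counts to generations
#'
#' Each transfer regrows a culture from a `1:dilution_factor` inoculum, so
#' one transfer corresponds to `log2(dilution_factor)` cell doublings
#' (about 6.64 generations for the standard 1:100 dilution).
#'
#' @param t Transfer index (0 = baseline), may be a vector.
#' @param dilution_factor Dilution applied at each transfer (`> 1`).
#' @return Generations `t * log2(dilution_factor)`.
#' @examples
#' transfers_to_generations(1)   # 6.64
#' transfers_to_generations(5)   # 33.2
#' @export
transfers_to_generations <- function(t, dilution_factor = 100) {
  if (!is.numeric(dilution_factor) || length(dilution_factor) != 1L ||
      is.na(dilution_factor) || dilution_factor <= 1)
    stop("`dilution_factor` must be a single number > 1", call. = FALSE)
  if (any(t < 0)) stop("transfer indices must be >= 0", call. = FALSE)
  t * log2(dilution_factor)
}

#' Validate a serial-transfer persistence dataset
#'
#' A persistence dataset is a data frame with one row per (variant,
#' replicate, transfer) observation: `n_total` colonies screened and
#' `n_host` of them plasmid-positive.
#'
#' @param x A data frame with columns `variant`, `replicate`, `transfer`,
#'   `n_total`, `n_host`.
#' @return `x` with class `persistence_dataset`, invisibly checked.
#' @export
persistence_dataset <- function(x) {
  need <- c("variant", "replicate", "transfer", "n_total", "n_host")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("persistence data lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(x$n_host < 0 | x$n_host > x$n_total | x$n_total < 1 |
               x$transfer < 0)
  if (length(bad))
    stop("invalid persistence rows (need 0 <= n_host <= n_total, ",
         "transfer >= 0): rows ", paste(utils::head(bad, 5L), collapse = ", "),
         call. = FALSE)
  class(x) <- unique(c("persistence_dataset", class(x)))
  x
}

# Internal fast path for calibration: the single-plasmid host chain on the
# reduced state space {(i, 0) : i = 0..2 n_c}.  Agrees exactly with the
# corresponding rows/columns of build_kernel(variant, NULL, config); the
# replication step is deterministic for homoplasmic cells (the urn always
# fills up with the only variant present), so columns reduce to the
# monomerization binomial composed with the assortment pmf.
.host_chain <- function(variant, config) {
  n_c <- config$n_c
  two_nc <- 2L * n_c
  ns <- two_nc + 1L
  A <- matrix(0, ns, ns)
  A[1L, 1L] <- 2
  sv <- rep(1, ns)
  if (variant$has_ta) sv[1L] <- 1 - variant$p_eff
  for (i in seq_len(two_nc)) {
    new <- two_nc - i
    pm <- stats::dbinom(0:new, new, 1 - variant$p_def)
    dist <- numeric(ns)
    for (k in 0:new) {
      Jm <- i + k
      dist[1:(Jm + 1L)] <- dist[1:(Jm + 1L)] +
        pm[k + 1L] * .assort_pmf(Jm, variant$p_par)
    }
    A[, i + 1L] <- 2 * dist * sv
  }
  A
}

# Host fraction h(g) for g = 0..g_max from single-copy founders, via the
# reduced chain.
.host_curve <- function(variant, config, g_max) {
  A <- .host_chain(variant, config)
  x <- numeric(nrow(A)); x[2L] <- 1
  h <- numeric(g_max + 1L); h[1L] <- 1
  for (g in seq_len(g_max)) {
    x <- as.numeric(A %*% x)
    x <- x / sum(x)
    h[g + 1L] <- 1 - x[1L]
  }
  h
}

# Log-linear interpolation of a host curve at (possibly non-integer)
# generations g.
.h_at <- function(h, g) {
  g0 <- pmin(floor(g), length(h) - 2L)
  frac <- g - g0
  lh <- log(pmax(h, 1e-300))
  exp(lh[g0 + 1L] * (1 - frac) + lh[g0 + 2L] * frac)
}

# Build the candidate variant for a target parameter value theta given the
# fixed parameters.
.candidate_variant <- function(target, theta, fixed) {
  p <- list(p_def = fixed$p_def %||% 0,
            p_par = fixed$p_par %||% 0,
            p_eff = fixed$p_eff %||% 0)
  p[[target]] <- theta
  plasmid_variant(paste0("fit-", target), p$p_def, p$p_par, p$p_eff)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Calibrate one stability parameter from persistence data
#'
#' Estimates a single parameter (`p_def`, `p_par` or `p_eff`) by
#' maximizing the binomial likelihood of the observed host-positive colony
#' counts against the model-predicted host fraction `h(g)`, with the other
#' two parameters held fixed.  The calibration is sequential by design:
#' `p_def` is estimated first from the unstable (U) variant's data, then
#' `p_par` from the partition (P) variant and `p_eff` from the TA (T)
#' variant with `p_def` fixed.  Colony plating is a binomial sampling
#' process, which motivates the binomial likelihood over a least-squares
#' fit of the observed fractions.
#'
#' The 95% confidence interval is built from a nonparametric bootstrap
#' over replicates: replicates are resampled with replacement and the
#' parameter re-estimated on a fine likelihood grid with local quadratic
#' refinement.  With the default `ci_method = "t"` the interval is the
#' estimate plus/minus the bootstrap standard error scaled by the
#' t-quantile with (replicates - 1) degrees of freedom, which keeps close
#' to nominal coverage for the small replicate counts (5-8) typical of
#' these experiments; plain percentile intervals (`ci_method =
#' "percentile"`) under-cover noticeably at that scale.  Intervals are
#' clamped to `[0, 1]`.
#'
#' @param data A [persistence_dataset()] (or plain data frame with the
#'   same columns).
#' @param target One of `"p_def"`, `"p_par"`, `"p_eff"`.
#' @param fixed Named list of parameters held fixed during the fit.
#'   Estimating `p_par` or `p_eff` requires a fixed `p_def`.
#' @param config A [model_config()].
#' @param variant Variant label(s) in `data` to fit against; defaults to
#'   the canonical source of the target parameter (`"U"`, `"P"` or `"T"`).
#'   Several labels (e.g. the two resistance-marker backbones of the same
#'   variant) are pooled into one likelihood.
#' @param dilution_factor Serial-transfer dilution (see
#'   [transfers_to_generations()]).
#' @param generations_per_transfer Optional override of the
#'   transfer-to-generation conversion.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed for the bootstrap.
#' @param grid_n Size of the likelihood grid used by the bootstrap.
#' @param ci_method `"t"` (bootstrap-SE t-interval, default) or
#'   `"percentile"`.
#' @return An object of class `estimation_result` with `estimate`,
#'   `ci95` (`c(low, high)`), `fixed`, `objective` (the minimized negative
#'   log-likelihood), `boundary` flag, and the bootstrap draws.
#' @export
fit_parameter <- function(data, target = c("p_def", "p_par", "p_eff"),
                          fixed = list(), config = model_config(),
                          variant = NULL, dilution_factor = 100,
                          generations_per_transfer = NULL,
                          n_boot = 1000, seed = 1L, grid_n = 401L,
                          ci_method = c("t", "percentile")) {
  target <- match.arg(target)
  ci_method <- match.arg(ci_method)
  data <- persistence_dataset(as.data.frame(data))
  if (target != "p_def" && is.null(fixed$p_def))
    stop("estimating `", target, "` requires `fixed$p_def` ",
         "(estimate it first from the unstable variant's data)",
         call. = FALSE)
  if (is.null(variant))
    variant <- c(p_def = "U", p_par = "P", p_eff = "T")[[target]]
  rows <- data[data$variant %in% variant, , drop = FALSE]
  if (!nrow(rows))
    stop("no rows for variant(s) ", paste(variant, collapse = ", "),
         " in `data`", call. = FALSE)

  gpt <- generations_per_transfer %||% log2(dilution_factor)
  g <- rows$transfer * gpt
  g_unique <- sort(unique(g))
  g_id <- match(g, g_unique)
  g_max <- max(2L, ceiling(max(g_unique)))

  h_of <- function(theta) {
    v <- .candidate_variant(target, theta, fixed)
    h <- .h_at(.host_curve(v, config, g_max), g_unique)
    pmin(pmax(h, 1e-12), 1 - 1e-12)
  }
  nll <- function(theta) {
    p <- h_of(theta)
    -sum(stats::dbinom(rows$n_host, rows$n_total, p[g_id], log = TRUE))
  }

  opt <- stats::optimize(nll, c(0, 1), tol = 1e-6)
  estimate <- opt$minimum
  # optimize() never evaluates at the boundary; snap if the boundary is
  # better (degenerate, e.g. loss-free data)
  for (b in c(0, 1)) if (nll(b) < opt$objective) {
    estimate <- b
    opt$objective <- nll(b)
  }
  boundary <- estimate <= 1e-3 || estimate >= 1 - 1e-3

  # bootstrap over replicates on a precomputed likelihood grid
  set.seed(seed)
  theta_grid <- seq(0, 1, length.out = grid_n)
  H <- t(vapply(theta_grid, h_of, numeric(length(g_unique))))
  logH <- log(H); log1mH <- log1p(-H)
  reps <- unique(rows$replicate)
  n_rep <- length(reps)
  # per-replicate sufficient statistics per unique generation
  host_mat <- matrix(0, n_rep, length(g_unique))
  miss_mat <- matrix(0, n_rep, length(g_unique))
  for (r in seq_len(n_rep)) {
    sel <- rows$replicate == reps[r]
    host_mat[r, ] <- vapply(seq_along(g_unique), function(k)
      sum(rows$n_host[sel & g_id == k]), numeric(1L))
    miss_mat[r, ] <- vapply(seq_along(g_unique), function(k)
      sum((rows$n_total - rows$n_host)[sel & g_id == k]), numeric(1L))
  }
  boot <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    pick <- sample.int(n_rep, n_rep, replace = TRUE)
    agg_host <- colSums(host_mat[pick, , drop = FALSE])
    agg_miss <- colSums(miss_mat[pick, , drop = FALSE])
    nll_grid <- -(logH %*% agg_host + log1mH %*% agg_miss)
    k <- which.min(nll_grid)
    if (k == 1L || k == grid_n) {
      boot[b] <- theta_grid[k]
    } else {
      # quadratic refinement through the three bracketing grid points
      y0 <- nll_grid[k - 1L]; y1 <- nll_grid[k]; y2 <- nll_grid[k + 1L]
      denom <- y0 - 2 * y1 + y2
      shift <- if (denom > 0) 0.5 * (y0 - y2) / denom else 0
      boot[b] <- theta_grid[k] + shift * (theta_grid[2L] - theta_grid[1L])
    }
  }
  ci <- if (ci_method == "t") {
    # the nonparametric bootstrap SE of a statistic of n clusters is
    # biased low by sqrt((n - 1) / n); undo that before the t-interval
    se <- stats::sd(boot) * sqrt(n_rep / max(n_rep - 1L, 1L))
    half <- stats::qt(0.975, df = max(n_rep - 1L, 1L)) * se
    c(estimate - half, estimate + half)
  } else {
    unname(stats::quantile(boot, c(0.025, 0.975)))
  }
  ci <- pmin(pmax(ci, 0), 1)

  structure(
    list(parameter = target, estimate = estimate,
         ci95 = c(low = ci[1L], high = ci[2L]),
         fixed = fixed, variant = variant,
         objective = opt$objective, boundary = boundary,
         n_boot = n_boot, seed = seed, boot = boot,
         ci_method = ci_method,
         n_replicates = n_rep, config = config),
    class = "estimation_result")
}

#' @export
print.estimation_result <- function(x, ...) {
  cat(sprintf("<estimation_result> %s = %.4f  (95%% CI %.4f - %.4f)\n",
              x$parameter, x$estimate, x$ci95[["low"]], x$ci95[["high"]]))
  if (length(x$fixed))
    cat("  fixed:", paste(names(x$fixed), unlist(x$fixed), sep = " = ",
                          collapse = ", "), "\n")
  cat(sprintf("  %d replicates, %d bootstrap resamples%s\n",
              x$n_replicates, x$n_boot,
              if (x$boundary) "  [boundary estimate]" else ""))
  invisible(x)
}

#' Sequential calibration of all three stability parameters
#'
#' Runs the full sequential calibration: `p_def` from the unstable (U)
#' variant, then `p_par` from the partition (P) variant and `p_eff` from
#' the TA (T) variant with `p_def` fixed at its estimate.
#'
#' @param data A [persistence_dataset()] containing the `U`, `P` and `T`
#'   variants (or the labels given in `variants`).
#' @param config A [model_config()].
#' @param variants Named list mapping `p_def`, `p_par`, `p_eff` to the
#'   variant label(s) carrying the corresponding information.
#' @param ... Passed on to [fit_parameter()] (e.g. `n_boot`, `seed`).
#' @return Named list of three `estimation_result` objects.
#' @export
estimate_parameters <- function(data, config = model_config(),
                                variants = list(p_def = "U", p_par = "P",
                                                p_eff = "T"), ...) {
  fit_def <- fit_parameter(data, "p_def", config = config,
                           variant = variants$p_def, ...)
  fixed <- list(p_def = fit_def$estimate)
  fit_par <- fit_parameter(data, "p_par", fixed = fixed, config = config,
                           variant = variants$p_par, ...)
  fit_eff <- fit_parameter(data, "p_eff", fixed = fixed, config = config,
                           variant = variants$p_eff, ...)
  list(p_def = fit_def, p_par = fit_par, p_eff = fit_eff)
}
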