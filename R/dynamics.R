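# Deterministic propagation of cell-type proportions and derived summaries:
# persistence curves, half-lives, asymptotic segregation rates, and
# head-to-head competition trajectories.

# Class masks over a kernel's state space.
.class_masks <- function(states) {
  list(homoplasmic_1 = states[, 1L] > 0L & states[, 2L] == 0L,
       homoplasmic_2 = states[, 1L] == 0L & states[, 2L] > 0L,
       heteroplasmic = states[, 1L] > 0L & states[, 2L] > 0L,
       plasmid_free  = states[, 1L] == 0L & states[, 2L] == 0L)
}

#' Propagate cell-type proportions over generations
#'
#' Iterates the normalized matrix power `x(g) = A^g x0 / |A^g x0|`, where
#' `|.|` is the entry sum, starting from a unit mass on the founder state.
#' The proportions are renormalized after every generation, which is
#' mathematically identical to a single final normalization but avoids
#' overflow (entries of `A^g` grow like `2^g`).
#'
#' @param kernel A [build_kernel()] result.
#' @param founder Founder cell state `(i1, i2)`.
#' @param g_max Number of generations to propagate (`>= 1`).
#' @return An object of class `population_trajectory`: a list with
#'   `generations` (`0:g_max`), `proportions` (state-by-generation matrix,
#'   columns summing to 1) and `classes` (data frame of the four class
#'   proportions per generation: both homoplasmic classes, heteroplasmic
#'   and plasmid-free).
#' @export
propagate <- function(kernel, founder, g_max) {
  stopifnot(inherits(kernel, "generation_kernel"))
  if (!is.numeric(g_max) || length(g_max) != 1L || g_max < 1 ||
      g_max != round(g_max))
    stop("`g_max` must be a positive integer", call. = FALSE)
  g_max <- as.integer(g_max)
  i0 <- .find_state(kernel, founder)
  ns <- nrow(kernel$states)
  A <- kernel$matrix
  X <- matrix(0, ns, g_max + 1L,
              dimnames = list(rownames(kernel$states), NULL))
  x <- numeric(ns); x[i0] <- 1
  X[, 1L] <- x
  for (g in seq_len(g_max)) {
    x <- as.numeric(A %*% x)
    x <- x / sum(x)
    X[, g + 1L] <- x
  }
  masks <- .class_masks(kernel$states)
  classes <- data.frame(
    generation = 0:g_max,
    homoplasmic_1 = colSums(X[masks$homoplasmic_1, , drop = FALSE]),
    homoplasmic_2 = colSums(X[masks$homoplasmic_2, , drop = FALSE]),
    heteroplasmic = colSums(X[masks$heteroplasmic, , drop = FALSE]),
    plasmid_free  = colSums(X[masks$plasmid_free, , drop = FALSE]),
    row.names = NULL)
  structure(
    list(generations = 0:g_max, proportions = X, classes = classes,
         founder = as.integer(kernel$states[i0, ]),
         variants = kernel$variants, config = kernel$config),
    class = "population_trajectory")
}

#' @export
print.population_trajectory <- function(x, ...) {
  cat(sprintf(
    "<population_trajectory> founder (%d,%d), %d generations, %d states\n",
    x$founder[1L], x$founder[2L], max(x$generations), nrow(x$proportions)))
  invisible(x)
}

# Interpolated generation at which a positive non-increasing curve first
# crosses 0.5; log-linear between bracketing integer generations, rounded
# half-up.  Returns list(reached, half_life, continuous).
.half_life <- function(h) {
  gi <- which(h <= 0.5)[1L]
  if (is.na(gi))
    return(list(reached = FALSE, half_life = NA_integer_,
                continuous = NA_real_))
  if (gi == 1L)  # crossed at generation 0 (degenerate founder)
    return(list(reached = TRUE, half_life = 0L, continuous = 0))
  g1 <- gi - 1L                       # first generation with h <= 0.5
  g0 <- g1 - 1L
  h0 <- h[g0 + 1L]; h1 <- h[g1 + 1L]
  gc_ <- if (h1 == h0) as.numeric(g1) else
    g0 + (log(0.5) - log(h0)) / (log(h1) - log(h0))
  list(reached = TRUE, half_life = as.integer(floor(gc_ + 0.5)),
       continuous = gc_)
}

#' Plasmid persistence of a homoplasmic host population
#'
#' Propagates a single-plasmid kernel from the founder state `(1, 0)` and
#' summarizes the host curve `h(g)` (the proportion of plasmid-carrying
#' cells), the plasmid half-life and the asymptotic segregation rate.
#' The half-life is the generation at which `h` crosses 50%, obtained by
#' log-linear interpolation between the bracketing integer generations and
#' rounded to the nearest integer.  If the curve does not reach 50% within
#' `g_max` generations the result reports `reached = FALSE` rather than
#' raising an error.
#'
#' @param kernel A single-plasmid [build_kernel()] result.
#' @param g_max Number of generations to simulate.
#' @return An object of class `persistence_summary` with `host_curve`
#'   (data frame `generation`, `host`), `half_life`, `half_life_continuous`,
#'   `reached` and `seg_rate`.
#' @examples
#' \donttest{
#' persistence(build_kernel(variant_preset("U")), g_max = 100)
#' }
#' @export
persistence <- function(kernel, g_max = 1500) {
  stopifnot(inherits(kernel, "generation_kernel"))
  if (!kernel$single)
    stop("`persistence()` requires a single-plasmid kernel ",
         "(build_kernel(variant, NULL, ...))", call. = FALSE)
  traj <- propagate(kernel, c(1L, 0L), g_max)
  h <- 1 - traj$classes$plasmid_free
  hl <- .half_life(h)
  structure(
    list(host_curve = data.frame(generation = 0:g_max, host = h),
         half_life = hl$half_life,
         half_life_continuous = hl$continuous,
         reached = hl$reached,
         seg_rate = asymptotic_seg_rate(kernel),
         variant = kernel$variants[[1L]],
         config = kernel$config),
    class = "persistence_summary")
}

#' @export
print.persistence_summary <- function(x, ...) {
  cat(sprintf("<persistence_summary> variant %s, n_c = %d\n",
              x$variant$label, x$config$n_c))
  cat(sprintf("  segregation rate r = %.6g (1/r = %.4g)\n",
              x$seg_rate, 1 / x$seg_rate))
  if (x$reached)
    cat(sprintf("  half-life = %d generations (interpolated %.2f)\n",
                x$half_life, x$half_life_continuous))
  else
    cat(sprintf("  half-life not reached within %d generations (h = %.4f)\n",
                max(x$host_curve$generation),
                x$host_curve$host[nrow(x$host_curve)]))
  invisible(x)
}

#' Asymptotic segregation rate
#'
#' The asymptotic rate `r` at which a homoplasmic host population loses
#' its plasmid: the host proportion ultimately decays by the factor
#' `(1 - r/2)` per generation.  It is computed as `r = 2 - lambda`, where
#' `lambda` is the dominant eigenvalue of the host-to-host block of the
#' expected-offspring matrix (all states with `i1 > 0, i2 = 0`), obtained
#' by power iteration from a uniform start vector.  Because
#' post-segregational killing only affects transitions into the
#' plasmid-free state, the host block of a TA-carrying variant equals that
#' of the same variant with `p_eff = 0`, so the TA system does not alter
#' the segregation rate.
#'
#' @param kernel A single-plasmid [build_kernel()] result.
#' @param tol Relative convergence tolerance of the power iteration.
#' @param max_iter Maximum number of iterations.
#' @return The rate `r` (a probability-scale number in `(0, 2)`).
#' @examples
#' asymptotic_seg_rate(build_kernel(variant_preset("S")))  # 2^(1 - 2 n_c)
#' @export
asymptotic_seg_rate <- function(kernel, tol = 1e-12, max_iter = 1e5) {
  stopifnot(inherits(kernel, "generation_kernel"))
  if (!kernel$single)
    stop("`asymptotic_seg_rate()` requires a single-plasmid kernel",
         call. = FALSE)
  host <- kernel$states[, 1L] > 0L & kernel$states[, 2L] == 0L
  M <- kernel$matrix[host, host, drop = FALSE]
  v <- rep(1 / sum(host), sum(host))
  lambda <- NA_real_
  for (it in seq_len(max_iter)) {
    w <- as.numeric(M %*% v)
    lam_new <- sum(w * v) / sum(v * v)
    w <- w / sqrt(sum(w^2))
    if (!is.na(lambda) && abs(lam_new - lambda) <= tol * abs(lam_new)) {
      lambda <- lam_new
      return(2 - lambda)
    }
    lambda <- lam_new
    v <- w
  }
  stop("power iteration did not converge within ", max_iter, " iterations",
       call. = FALSE)
}

#' Head-to-head plasmid competition
#'
#' Propagates a two-variant kernel from the heteroplasmic founder `(1, 1)`
#' and detects the generation at which the ordering of the two homoplasmic
#' host classes inverts.  Ties at generation 0 (both classes empty) are
#' ignored; the crossing is the first integer generation at or after the
#' sign change of the difference between the homoplasmic proportions, or
#' `NA` if the ordering never inverts within `g_max` generations.
#'
#' @param kernel A two-variant [build_kernel()] result.
#' @param g_max Number of generations to simulate.
#' @return An object of class `competition_result` with `trajectory` (the
#'   [propagate()] result), `crossing_generation` and `first_dominant`
#'   (label of the variant whose homoplasmic class dominates first).
#' @examples
#' \donttest{
#' compete(build_kernel(variant_preset("T"), variant_preset("S")), 100)
#' }
#' @export
compete <- function(kernel, g_max = 500) {
  stopifnot(inherits(kernel, "generation_kernel"))
  if (kernel$single)
    stop("`compete()` requires a two-variant kernel", call. = FALSE)
  traj <- propagate(kernel, c(1L, 1L), g_max)
  cl <- traj$classes
  d <- cl$homoplasmic_1 - cl$homoplasmic_2
  valid <- cl$homoplasmic_1 > 0 & cl$homoplasmic_2 > 0 & cl$generation > 0
  crossing <- NA_integer_
  s0 <- 0
  first_dom <- NA_character_
  for (g in which(valid)) {
    if (s0 == 0 && d[g] != 0) {
      s0 <- sign(d[g])
      first_dom <- kernel$variants[[if (s0 > 0) 1L else 2L]]$label
    } else if (s0 != 0 && sign(d[g]) == -s0) {
      crossing <- cl$generation[g]
      break
    }
  }
  structure(
    list(trajectory = traj, crossing_generation = crossing,
         first_dominant = first_dom, variants = kernel$variants,
         config = kernel$config),
    class = "competition_result")
}

#' @export
print.competition_result <- function(x, ...) {
  cat(sprintf("<competition_result> %s vs %s, n_c = %d\n",
              x$variants[[1L]]$label, x$variants[[2L]]$label, x$config$n_c))
  if (is.na(x$crossing_generation))
    cat("  homoplasmic proportions do not cross within the simulated range\n")
  else
    cat(sprintf("  %s dominates first; crossing at generation %d\n",
                x$first_dominant, x$crossing_generation))
  invisible(x)
}

#' Plot a persistence curve
#'
#' Draws the host proportion over generations with the 50% (half-life)
#' level as a dashed line.  A convenience display; not part of the tested
#' numerical contract.
#'
#' @param x A [persistence()] result.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.persistence_summary <- function(x, ...) {
  graphics::plot(x$host_curve$generation, x$host_curve$host, type = "l",
                 xlab = "generation", ylab = "host proportion h(g)",
                 ylim = c(0, 1), ...)
  graphics::abline(h = 0.5, lty = 2)
  if (x$reached) graphics::abline(v = x$half_life, lty = 3)
  invisible(x)
}

#' Plot competition class trajectories
#'
#' @param x A [compete()] result.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.competition_result <- function(x, ...) {
  cl <- x$trajectory$classes
  graphics::matplot(cl$generation, cl[, -1L], type = "l", lty = 1,
                    xlab = "generation", ylab = "proportion", ...)
  graphics::legend("right", legend = colnames(cl)[-1L], lty = 1,
                   col = seq_len(4), bty = "n", cex = 0.8)
  if (!is.na(x$crossing_generation))
    graphics::abline(v = x$crossing_generation, lty = 3)
  invisible(x)
}
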