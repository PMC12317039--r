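# Assembly of the expected-offspring matrix A over all cell states.

#' Build the per-generation expected-offspring matrix
#'
#' Composes replication, monomerization and assortment into the exact
#' daughter distribution `p[i -> j]` for every parent state `i`, then sets
#' `A[j, i] = 2 * p[i -> j] * p_surv[i -> j]`: the expected number of
#' surviving `j`-type daughters produced when an `i`-type cell divides.
#' The summation over the intermediate copy-number lattice is exact; no
#' Monte-Carlo is involved.
#'
#' Passing `variant2 = NULL` builds a single-plasmid kernel: the second
#' variant is an inert placeholder that never acquires copies, and states
#' with `i2 > 0` are unreachable (they remain in the state space so that
#' the matrix layout is identical for all kernels at a given `n_c`).
#'
#' @param variant1,variant2 [plasmid_variant()] objects; `variant2` may be
#'   `NULL` for a single-plasmid configuration.  At most one variant may
#'   carry a TA system.
#' @param config A [model_config()].
#' @return An object of class `generation_kernel` with elements `states`
#'   (the ordered state enumeration), `matrix` (`A`, daughter state by
#'   parent state), `survival` (the survival factors `p_surv[i -> j]`),
#'   `variants`, `config` and `single`.
#' @examples
#' k <- build_kernel(variant_preset("S"), config = model_config(2))
#' colSums(k$matrix)  # two daughters per division, no killing
#' @export
build_kernel <- function(variant1, variant2 = NULL, config = model_config()) {
  vp <- .as_variant_pair(variant1, variant2)
  v1 <- vp$variant1; v2 <- vp$variant2
  n_c <- config$n_c
  two_nc <- 2L * n_c
  states <- enumerate_states(config)
  ns <- nrow(states)
  idx <- .state_lookup(states, n_c)

  # marginal assortment tables per variant, memoized over pool size
  as1 <- lapply(0:two_nc, .assort_pmf, p_par = v1$p_par)
  as2 <- lapply(0:two_nc, .assort_pmf, p_par = v2$p_par)

  A <- matrix(0, ns, ns, dimnames = list(rownames(states), rownames(states)))
  S <- matrix(1, ns, ns, dimnames = dimnames(A))

  for (col in seq_len(ns)) {
    i1 <- states[col, 1L]; i2 <- states[col, 2L]
    dist <- numeric(ns)
    rp <- replication_pmf(c(i1, i2), config)
    for (rr in seq_len(nrow(rp))) {
      pr <- rp$prob[rr]
      if (pr == 0) next
      n1 <- rp$J1[rr] - i1
      n2 <- rp$J2[rr] - i2
      pm1 <- stats::dbinom(0:n1, n1, 1 - v1$p_def)
      pm2 <- stats::dbinom(0:n2, n2, 1 - v2$p_def)
      for (a in 0:n1) {
        if (pm1[a + 1L] == 0) next
        J1m <- i1 + a
        for (b in 0:n2) {
          w <- pr * pm1[a + 1L] * pm2[b + 1L]
          if (w == 0) next
          J2m <- i2 + b
          block <- w * outer(as1[[J1m + 1L]], as2[[J2m + 1L]])
          target <- idx[(0:J1m) + 1L, (0:J2m) + 1L, drop = FALSE]
          dist[target] <- dist[target] + block
        }
      }
    }
    sv <- rep(1, ns)
    if (v1$has_ta && i1 > 0L)
      sv[states[, 1L] == 0L] <- 1 - v1$p_eff
    if (v2$has_ta && i2 > 0L)
      sv[states[, 2L] == 0L] <- 1 - v2$p_eff
    A[, col] <- 2 * dist * sv
    S[, col] <- sv
  }

  structure(
    list(states = states, matrix = A, survival = S,
         variants = list(v1, v2), config = config, single = vp$single),
    class = "generation_kernel")
}

#' @export
print.generation_kernel <- function(x, ...) {
  v2 <- if (x$single) "(single-plasmid)" else x$variants[[2L]]$label
  cat(sprintf(
    "<generation_kernel> %s vs %s, n_c = %d, %d states\n",
    x$variants[[1L]]$label, v2, x$config$n_c, nrow(x$states)))
  invisible(x)
}

# Internal: daughter distribution p[i -> j] for one parent state, as a
# probability vector over the kernel's state order (survival not applied).
.daughter_distribution <- function(kernel, parent) {
  col <- .find_state(kernel, parent)
  kernel$matrix[, col] / (2 * kernel$survival[, col])
}

.find_state <- function(kernel, state) {
  state <- .check_state(state, kernel$config)
  hit <- which(kernel$states[, 1L] == state[1L] &
               kernel$states[, 2L] == state[2L])
  if (!length(hit))
    stop("state (", state[1L], ",", state[2L], ") not in the kernel's ",
         "state space", call. = FALSE)
  hit
}

#' Export a kernel to delimited text
#'
#' Writes the dense expected-offspring matrix with state labels as a CSV
#' table and, optionally, a compact JSON metadata block recording `n_c`,
#' the variant parameter triplets and the state order.
#'
#' @param kernel A [build_kernel()] result.
#' @param matrix_file Path of the CSV output.
#' @param meta_file Optional path of the JSON metadata output.
#' @return `matrix_file`, invisibly.
#' @export
export_kernel <- function(kernel, matrix_file, meta_file = NULL) {
  stopifnot(inherits(kernel, "generation_kernel"))
  utils::write.csv(as.data.frame(kernel$matrix), matrix_file)
  if (!is.null(meta_file)) {
    meta <- list(
      n_c = kernel$config$n_c,
      variants = lapply(kernel$variants, function(v)
        list(label = v$label, p_def = v$p_def, p_par = v$p_par,
             p_eff = v$p_eff)),
      single = kernel$single,
      state_order = rownames(kernel$states))
    jsonlite::write_json(meta, meta_file, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(matrix_file)
}
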