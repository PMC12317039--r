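# Synthetic serial-transfer persistence datasets and competition endpoint
# tables with the sampling structure of the plasmid-stability experiments.

#' Describe a synthetic experimental design
#'
#' Captures the layout of a serial-transfer stability experiment: which
#' variants are assayed, how many replicate populations, how many 1:100
#' transfers, and how many colonies are screened per time point.  The
#' defaults mirror the study conditions: 8 replicates, 5 transfers at a
#' 1:100 dilution (about 6.64 generations each) and 100 colonies plated.
#' `overdispersion = 1` means pure binomial plating noise; larger values
#' inflate the variance between replicates by that factor via a
#' beta-binomial draw.
#'
#' @param variants A [plasmid_variant()] or list of them.
#' @param n_replicates Replicate populations per variant.
#' @param n_transfers Number of serial transfers (time points beyond the
#'   baseline).
#' @param dilution_factor Dilution at each transfer.
#' @param plating_n Colonies screened per time point.
#' @param overdispersion Variance inflation factor (`>= 1`).
#' @param seed Integer seed recorded in the design and used by the
#'   generators.
#' @return An object of class `synthetic_design`.
#' @export
synthetic_design <- function(variants = variant_preset(),
                             n_replicates = 8, n_transfers = 5,
                             dilution_factor = 100, plating_n = 100,
                             overdispersion = 1, seed = 1L) {
  if (inherits(variants, "plasmid_variant")) variants <- list(variants)
  stopifnot(all(vapply(variants, inherits, logical(1L), "plasmid_variant")))
  if (n_replicates < 1 || n_transfers < 1 || plating_n < 1)
    stop("all design counts must be positive", call. = FALSE)
  if (overdispersion < 1)
    stop("`overdispersion` must be >= 1", call. = FALSE)
  structure(
    list(variants = variants,
         n_replicates = as.integer(n_replicates),
         n_transfers = as.integer(n_transfers),
         dilution_factor = dilution_factor,
         plating_n = as.integer(plating_n),
         overdispersion = overdispersion,
         seed = as.integer(seed)),
    class = "synthetic_design")
}

# One beta-binomial (or binomial) draw vector with mean n*h and variance
# inflated by `factor` relative to binomial.
.plating_draw <- function(k, n, h, factor) {
  if (factor == 1 || h <= 0 || h >= 1)
    return(stats::rbinom(k, n, h))
  rho <- (factor - 1) / (n - 1)          # intra-plate correlation
  s <- 1 / rho - 1                       # beta concentration a + b
  p <- stats::rbeta(k, h * s, (1 - h) * s)
  stats::rbinom(k, n, p)
}

#' Generate a synthetic serial-transfer persistence dataset
#'
#' For each variant and transfer, computes the true host fraction
#' `h(g_t)` from the deterministic segregation model at
#' `g_t = t * log2(dilution_factor)` generations, then draws the number of
#' host-positive colonies among `plating_n` plated colonies binomially
#' (beta-binomially under overdispersion).  Output is fully reproducible
#' from the design's seed, which is recorded in the result's metadata.
#'
#' @param design A [synthetic_design()].
#' @param config A [model_config()].
#' @return A [persistence_dataset()] with columns `variant`, `replicate`,
#'   `transfer`, `n_total`, `n_host`; metadata (design echo, seed,
#'   generations per transfer) in `attr(, "metadata")`.
#' @examples
#' d <- synthetic_design(variant_preset("U"), seed = 42)
#' head(generate_persistence(d))
#' @export
generate_persistence <- function(design, config = model_config()) {
  stopifnot(inherits(design, "synthetic_design"))
  set.seed(design$seed)
  gpt <- log2(design$dilution_factor)
  g_t <- (0:design$n_transfers) * gpt
  g_max <- max(2L, ceiling(max(g_t)))
  out <- list()
  for (v in design$variants) {
    h <- .h_at(.host_curve(v, config, g_max), g_t)
    for (t_idx in seq_along(g_t)) {
      n_host <- .plating_draw(design$n_replicates, design$plating_n,
                              h[t_idx], design$overdispersion)
      out[[length(out) + 1L]] <- data.frame(
        variant = v$label,
        replicate = seq_len(design$n_replicates),
        transfer = t_idx - 1L,
        n_total = design$plating_n,
        n_host = n_host)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$variant, res$replicate, res$transfer), ]
  rownames(res) <- NULL
  attr(res, "metadata") <- list(
    seed = design$seed,
    n_replicates = design$n_replicates,
    n_transfers = design$n_transfers,
    dilution_factor = design$dilution_factor,
    plating_n = design$plating_n,
    overdispersion = design$overdispersion,
    generations_per_transfer = gpt,
    n_c = config$n_c)
  persistence_dataset(res)
}

#' Generate synthetic competition endpoint tables
#'
#' Computes the four cell-class proportions (homoplasmic for either
#' variant, heteroplasmic, plasmid-free) at `g_end` generations of a
#' head-to-head competition from the heteroplasmic founder `(1, 1)`, then
#' draws per-replicate colony counts of the classes from a multinomial
#' with `plating_n` trials.
#'
#' @param variant1,variant2 Competing [plasmid_variant()] objects.
#' @param design A [synthetic_design()] (supplies replicates, plating
#'   depth and seed).
#' @param g_end Endpoint of the competition, in generations (non-negative
#'   integer).
#' @param config A [model_config()].
#' @return Tidy data frame with columns `variant_pair`, `replicate`,
#'   `class`, `count`, `proportion`; counts sum to `plating_n` within each
#'   replicate.
#' @export
generate_competition_endpoints <- function(variant1, variant2, design,
                                           g_end, config = model_config()) {
  stopifnot(inherits(design, "synthetic_design"))
  if (g_end < 0 || g_end != round(g_end))
    stop("`g_end` must be a non-negative integer number of generations",
         call. = FALSE)
  set.seed(design$seed)
  classes <- c("homoplasmic_1", "homoplasmic_2", "heteroplasmic",
               "plasmid_free")
  if (g_end == 0L) {
    props <- c(0, 0, 1, 0)
  } else {
    comp <- compete(build_kernel(variant1, variant2, config), g_max = g_end)
    cl <- comp$trajectory$classes
    props <- as.numeric(cl[cl$generation == g_end, classes])
  }
  counts <- stats::rmultinom(design$n_replicates, design$plating_n, props)
  pair <- paste(variant1$label, variant2$label, sep = "_vs_")
  out <- data.frame(
    variant_pair = pair,
    replicate = rep(seq_len(design$n_replicates), each = length(classes)),
    class = rep(classes, design$n_replicates),
    count = as.integer(counts),
    proportion = as.numeric(counts) / design$plating_n)
  attr(out, "metadata") <- list(seed = design$seed, g_end = g_end,
                                expected_proportions =
                                  stats::setNames(props, classes))
  out
}
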