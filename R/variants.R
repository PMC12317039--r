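# Variant definitions and model configuration.

.check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop("`", name, "` must be a single probability in [0, 1]", call. = FALSE)
  as.numeric(x)
}

#' Define a plasmid variant by its stability parameter triplet
#'
#' A plasmid variant is characterized by three probabilities that summarize
#' its stability determinants:
#' \describe{
#'   \item{`p_def`}{monomerization deficiency: the probability that a newly
#'     replicated plasmid copy is removed from the pool of independently
#'     segregating units before cell division (e.g. because multimers are
#'     not resolved).  Copies present at cell birth are never removed.}
#'   \item{`p_par`}{active-partition efficiency: the probability that a pair
#'     of plasmid copies is pushed to opposite daughter cells at division
#'     (balanced assortment) instead of being distributed at random.}
#'   \item{`p_eff`}{post-segregational-killing efficiency of a
#'     toxin-antitoxin (TA) system: the probability that a daughter cell
#'     which lost the TA-carrying plasmid is killed.}
#' }
#' The derived flags `has_partition` and `has_ta` are `TRUE` exactly when
#' `p_par > 0` and `p_eff > 0`, respectively.
#'
#' @param label Short variant name (e.g. `"U"` or `"pCONn-U"`).
#' @param p_def,p_par,p_eff Probabilities in `[0, 1]`, see above.
#' @return An object of class `plasmid_variant`.
#' @seealso [variant_preset()] for the five canonical variants.
#' @examples
#' plasmid_variant("U", p_def = 0.494)
#' @export
plasmid_variant <- function(label, p_def = 0, p_par = 0, p_eff = 0) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop("`label` must be a non-empty string", call. = FALSE)
  p_def <- .check_prob(p_def, "p_def")
  p_par <- .check_prob(p_par, "p_par")
  p_eff <- .check_prob(p_eff, "p_eff")
  structure(
    list(label = label, p_def = p_def, p_par = p_par, p_eff = p_eff,
         has_partition = p_par > 0, has_ta = p_eff > 0),
    class = "plasmid_variant")
}

# Canonical parameter triplets (p_def, p_par, p_eff) of the five model
# plasmid variants.  S carries no stability determinant; U is the unstable
# monomerization-deficient backbone; P adds an active partition system,
# T a toxin-antitoxin system, and PT both.
.variant_presets <- list(
  S  = c(p_def = 0,     p_par = 0,     p_eff = 0),
  U  = c(p_def = 0.494, p_par = 0,     p_eff = 0),
  P  = c(p_def = 0.494, p_par = 0.456, p_eff = 0),
  T  = c(p_def = 0.494, p_par = 0,     p_eff = 0.883),
  PT = c(p_def = 0.494, p_par = 0.456, p_eff = 0.883))

#' Canonical plasmid variant presets
#'
#' Returns the calibrated parameter triplets of the five model plasmid
#' variants: stable (`S`), unstable (`U`), partition (`P`), toxin-antitoxin
#' (`T`) and partition-plus-TA (`PT`).  All unstable backbones share the
#' monomerization deficiency `p_def = 0.494`; partition variants use
#' `p_par = 0.456` and TA variants `p_eff = 0.883`.
#'
#' @param label One or more of `"S"`, `"U"`, `"P"`, `"T"`, `"PT"`.
#' @return A single `plasmid_variant` if `label` has length one, otherwise
#'   a named list of `plasmid_variant` objects.
#' @examples
#' variant_preset("PT")
#' variant_preset(c("U", "S"))
#' @export
variant_preset <- function(label = names(.variant_presets)) {
  bad <- setdiff(label, names(.variant_presets))
  if (length(bad))
    stop("unknown variant preset(s): ", paste(bad, collapse = ", "),
         " (available: ", paste(names(.variant_presets), collapse = ", "), ")",
         call. = FALSE)
  out <- lapply(label, function(l) {
    p <- .variant_presets[[l]]
    plasmid_variant(l, p[["p_def"]], p[["p_par"]], p[["p_eff"]])
  })
  names(out) <- label
  if (length(out) == 1L) out[[1L]] else out
}

#' Model configuration
#'
#' Holds the plasmid copy number at cell birth, `n_c`.  Newborn cells
#' replicate their plasmids up to `2 * n_c` copies before dividing, so the
#' cell-state space consists of all copy-number pairs summing to at most
#' `2 * n_c`.  The default `n_c = 5` corresponds to the measured mean copy
#' number (about 5.09) of the model plasmids.
#'
#' @param n_c Positive integer copy number at birth-state saturation.
#' @return An object of class `model_config`.
#' @export
model_config <- function(n_c = 5) {
  if (!is.numeric(n_c) || length(n_c) != 1L || is.na(n_c) ||
      n_c < 1 || n_c != round(n_c))
    stop("`n_c` must be a positive integer", call. = FALSE)
  structure(list(n_c = as.integer(n_c)), class = "model_config")
}

#' @export
print.plasmid_variant <- function(x, ...) {
  cat(sprintf(
    "<plasmid_variant> %s  (p_def = %.3f, p_par = %.3f, p_eff = %.3f)%s%s\n",
    x$label, x$p_def, x$p_par, x$p_eff,
    if (x$has_partition) " +par" else "",
    if (x$has_ta) " +TA" else ""))
  invisible(x)
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config> n_c = %d (replication target %d copies)\n",
              x$n_c, 2L * x$n_c))
  invisible(x)
}

# Internal: resolve a (variant1, variant2) pair.  A missing second variant
# stands for a single-plasmid configuration and is represented by an inert
# ".none" variant that never carries copies.  Pairs where both variants
# carry a TA system are rejected: post-segregational killing with two
# addictive plasmids is outside the supported model.
.absent_variant <- function() plasmid_variant(".none", 0, 0, 0)

.as_variant_pair <- function(variant1, variant2 = NULL) {
  if (!inherits(variant1, "plasmid_variant"))
    stop("`variant1` must be a plasmid_variant", call. = FALSE)
  single <- is.null(variant2)
  if (single) variant2 <- .absent_variant()
  if (!inherits(variant2, "plasmid_variant"))
    stop("`variant2` must be a plasmid_variant or NULL", call. = FALSE)
  if (variant1$has_ta && variant2$has_ta)
    stop("unsupported configuration: both variants carry a TA system ",
         "(p_eff > 0); the model only supports at most one addictive plasmid",
         call. = FALSE)
  list(variant1 = variant1, variant2 = variant2, single = single)
}
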