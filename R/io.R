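# File input/output: persistence tables, variant configuration files and
# trajectory exports.  All delimited text is comma-separated UTF-8 with a
# header row.

#' Read a serial-transfer persistence table
#'
#' Expects a CSV file with header
#' `variant,replicate,transfer,n_total,n_host`.  Rows failing the dataset
#' invariants are reported with their row numbers.
#'
#' @param file Path to the CSV file.
#' @return A [persistence_dataset()].
#' @export
read_persistence <- function(file) {
  x <- utils::read.csv(file, stringsAsFactors = FALSE)
  persistence_dataset(x)
}

#' Write a persistence table
#'
#' @param data A [persistence_dataset()] or compatible data frame.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_persistence <- function(data, file) {
  data <- persistence_dataset(as.data.frame(data))
  utils::write.csv(data, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read variant definitions and model configuration from a file
#'
#' Accepts YAML (`.yaml`/`.yml`) or JSON (`.json`).  The file holds an
#' optional top-level `n_c` and a `variants` list whose entries have keys
#' `label`, `p_def`, `p_par`, `p_eff` (missing probabilities default to
#' 0).  A file consisting of a single variant mapping is also accepted.
#'
#' @param file Path to the configuration file.
#' @return A list with `variants` (named list of [plasmid_variant()]) and
#'   `config` (a [model_config()]).
#' @export
read_variant_config <- function(file) {
  ext <- tolower(tools::file_ext(file))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(file),
    json = jsonlite::read_json(file, simplifyVector = FALSE),
    stop("unsupported config format: .", ext,
         " (use .yaml, .yml or .json)", call. = FALSE))
  entries <- raw$variants
  if (is.null(entries) && !is.null(raw$label)) entries <- list(raw)
  if (is.null(entries))
    stop("config file must contain a `variants` list (or be a single ",
         "variant mapping with a `label`)", call. = FALSE)
  variants <- lapply(entries, function(e) {
    if (is.null(e$label)) stop("variant entry without `label`", call. = FALSE)
    plasmid_variant(e$label, e$p_def %||% 0, e$p_par %||% 0, e$p_eff %||% 0)
  })
  names(variants) <- vapply(variants, `[[`, character(1L), "label")
  list(variants = variants,
       config = model_config(raw$n_c %||% 5))
}

#' Export a trajectory as tidy delimited text
#'
#' Writes one row per generation and class (long format:
#' `generation,class,proportion`); with `states = TRUE` the per-state
#' proportions are written instead, with the state label in the `class`
#' column.
#'
#' @param trajectory A [propagate()] result (also found inside
#'   [compete()] results).
#' @param file Output path.
#' @param states Write per-state proportions instead of class summaries.
#' @return `file`, invisibly.
#' @export
write_trajectory <- function(trajectory, file, states = FALSE) {
  stopifnot(inherits(trajectory, "population_trajectory"))
  if (states) {
    X <- trajectory$proportions
    out <- data.frame(
      generation = rep(trajectory$generations, each = nrow(X)),
      class = rep(rownames(X), times = ncol(X)),
      proportion = as.numeric(X))
  } else {
    cl <- trajectory$classes
    long <- utils::stack(cl[, -1L])
    out <- data.frame(generation = rep(cl$generation, 4L),
                      class = as.character(long$ind),
                      proportion = long$values)
  }
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
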