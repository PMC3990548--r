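# TSV persistence. All files are plain tab-delimited text with a header;
# expression matrices carry gene IDs in a leading `gene_id` column.

#' Write and read gene x sample expression matrices as TSV
#'
#' @param m Numeric matrix with gene IDs as rownames.
#' @param path File path.
#' @return `read_expression_matrix()` returns the matrix; the writer returns
#'   `path` invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  df <- as_tibble(m, rownames = "gene_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m
}

#' Write an expression study to a directory
#'
#' Writes `expr_reference.tsv`, `expr_test.tsv`, `samples.tsv` and (when
#' truth labels exist) `truth.tsv`.
#'
#' @param study An `expression_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_matrix(study$expr$reference,
                          file.path(dir, "expr_reference.tsv"))
  write_expression_matrix(study$expr$test, file.path(dir, "expr_test.tsv"))
  readr::write_tsv(study$samples, file.path(dir, "samples.tsv"))
  if (!is.null(study$truth)) {
    readr::write_tsv(study$truth, file.path(dir, "truth.tsv"))
  }
  invisible(dir)
}

#' Read an expression study from a directory or explicit paths
#'
#' @param reference,test Paths to the two expression TSVs.
#' @param samples Path to the sample-annotation TSV (`sample_id`,
#'   `condition`, `time_h`, `replicate`, `stage`).
#' @param truth Optional path to a truth TSV (`gene_id`, `module_id`).
#' @return An `expression_study` (without generator config).
#' @export
read_study <- function(reference, test, samples, truth = NULL) {
  ref_m <- read_expression_matrix(reference)
  test_m <- read_expression_matrix(test)
  if (!identical(rownames(ref_m), rownames(test_m))) {
    stop_coexnet("Reference and test matrices must share gene IDs and order.",
                 "coexnet_invalid_input")
  }
  samp <- readr::read_tsv(samples, show_col_types = FALSE)
  truth_tbl <- if (!is.null(truth)) readr::read_tsv(truth,
                                                    show_col_types = FALSE)
  structure(
    list(expr = list(reference = ref_m, test = test_m),
         samples = samp, truth = truth_tbl, config = NULL),
    class = "expression_study"
  )
}

#' Read a simulation configuration from YAML or JSON
#'
#' The file mirrors the arguments of [simulation_config()], with a
#' `modules` list of [module_spec()] fields.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  simulation_config_from_list(cfg)
}

simulation_config_from_list <- function(cfg) {
  if (is.null(cfg$modules) || !length(cfg$modules)) {
    stop_coexnet("Simulation config needs a non-empty `modules` list.",
                 "coexnet_invalid_config")
  }
  spec_row <- function(m) {
    # fields absent in one entry read back as NA: fall through to defaults
    m <- m[!vapply(m, function(x) length(x) == 1 && is.na(x), logical(1))]
    do.call(module_spec, m)
  }
  mods <- if (is.data.frame(cfg$modules)) {
    purrr::pmap_dfr(cfg$modules, function(...) spec_row(list(...)))
  } else {
    purrr::map_dfr(cfg$modules, spec_row)
  }
  args <- cfg[setdiff(names(cfg), "modules")]
  do.call(simulation_config, c(list(modules = mods), args))
}
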