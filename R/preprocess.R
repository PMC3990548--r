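#' Collapse probe-level rows to gene-level rows
#'
#' Averages the rows of all probes mapped to the same gene, mirroring the
#' common microarray convention of using the mean expression vector when
#' several probe sets map to one gene identifier. Probes missing from the
#' map are dropped with a warning and counted in the attributes.
#'
#' @param probe_matrix Numeric matrix, probes x samples, probe IDs as
#'   rownames.
#' @param probe_map Data frame with columns `probe_id`, `gene_id`; each
#'   probe maps to exactly one gene.
#' @return Gene x sample matrix in lexicographic gene order, with attributes
#'   `n_probes_dropped` and `n_probes_used`.
#' @export
#' @examples
#' m <- matrix(c(2, 4, 6, 4, 6, 8), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("p1", "p2"), c("s1", "s2", "s3")))
#' collapse_probes(m, data.frame(probe_id = c("p1", "p2"), gene_id = "g1"))
collapse_probes <- function(probe_matrix, probe_map) {
  check_expr_matrix(probe_matrix, "probe_matrix")
  probe_map <- as_tibble(probe_map)
  if (!all(c("probe_id", "gene_id") %in% names(probe_map))) {
    stop_coexnet("`probe_map` needs columns probe_id and gene_id.",
                 "coexnet_invalid_input")
  }
  if (anyDuplicated(probe_map$probe_id)) {
    stop_coexnet("Each probe must map to exactly one gene.",
                 "coexnet_invalid_input")
  }
  probes <- rownames(probe_matrix)
  keep <- probes %in% probe_map$probe_id
  if (!any(keep)) {
    stop_coexnet("No probe in the matrix is present in the map.",
                 "coexnet_empty_input")
  }
  if (any(!keep)) {
    rlang::warn(sprintf("%d unmapped probe(s) dropped.", sum(!keep)))
  }
  m <- probe_matrix[keep, , drop = FALSE]
  gene <- probe_map$gene_id[match(rownames(m), probe_map$probe_id)]
  genes <- sort(unique(gene))
  out <- do.call(rbind, lapply(genes, function(g) {
    colMeans(m[gene == g, , drop = FALSE])
  }))
  dimnames(out) <- list(genes, colnames(probe_matrix))
  attr(out, "n_probes_dropped") <- sum(!keep)
  attr(out, "n_probes_used") <- sum(keep)
  out
}

#' Express signals as ratios to a control profile
#'
#' Divides each gene's signal by the matching entry of a control vector
#' (e.g. the 0 h control group mean), optionally log2-transforming the
#' ratios (the default, since correlation networks on raw ratios are skewed
#' by scale).
#'
#' @param signal_matrix Gene x sample matrix of positive signals.
#' @param control_vector Named or positionally matched per-gene control
#'   values; must be strictly positive.
#' @param log2_transform Return `log2(ratio)` (default `TRUE`).
#' @return Matrix of (log-)ratios with the input dimnames.
#' @export
ratio_to_control <- function(signal_matrix, control_vector,
                             log2_transform = TRUE) {
  check_expr_matrix(signal_matrix, "signal_matrix")
  if (!is.null(names(control_vector))) {
    control_vector <- control_vector[rownames(signal_matrix)]
  }
  if (length(control_vector) != nrow(signal_matrix)) {
    stop_coexnet("`control_vector` must have one entry per gene.",
                 "coexnet_invalid_input")
  }
  bad <- which(!is.finite(control_vector) | control_vector <= 0)
  if (length(bad)) {
    stop_coexnet(
      sprintf("Non-positive control value for gene(s): %s.",
              paste(head(rownames(signal_matrix)[bad], 5), collapse = ", ")),
      "coexnet_invalid_input"
    )
  }
  out <- sweep(signal_matrix, 1, control_vector, "/")
  if (log2_transform) out <- log2(out)
  out
}

#' Filter genes by a two-sample Welch t-test between conditions
#'
#' Retains the genes whose expression differs between the two conditions at
#' the given significance level, using an unpaired two-sided Welch
#' (unequal-variance) t-test per gene across all samples of each condition.
#' No multiple-testing correction is applied: the raw per-gene threshold is
#' the filter. With `paired = TRUE` a paired t-test on column-matched
#' samples is used instead.
#'
#' @param matrix_a,matrix_b Gene x sample matrices sharing gene IDs (rows).
#' @param alpha Significance level in (0, 1].
#' @param paired Use a paired t-test on column-matched samples.
#' @return A list with `genes` (character vector of retained gene IDs) and
#'   `report`, a tibble (`gene_id`, `t`, `df`, `p_value`, `retained`) plus
#'   attributes `n_input_genes`, `n_retained`, `alpha`.
#' @export
filter_by_ttest <- function(matrix_a, matrix_b, alpha = 0.05, paired = FALSE) {
  check_expr_matrix(matrix_a, "matrix_a")
  check_expr_matrix(matrix_b, "matrix_b")
  if (!identical(rownames(matrix_a), rownames(matrix_b))) {
    stop_coexnet("Both matrices must share gene IDs in the same order.",
                 "coexnet_invalid_input")
  }
  if (!(alpha > 0 && alpha <= 1)) {
    stop_coexnet("`alpha` must be in (0, 1].", "coexnet_invalid_input")
  }
  if (paired) {
    if (ncol(matrix_a) != ncol(matrix_b)) {
      stop_coexnet("Paired test needs equal sample counts.",
                   "coexnet_invalid_input")
    }
    d <- matrix_a - matrix_b
    n <- ncol(d)
    if (n < 2) stop_coexnet("Paired test needs >= 2 sample pairs.",
                            "coexnet_invalid_input")
    m <- rowMeans(d)
    s <- apply(d, 1, sd)
    t_stat <- ifelse(s == 0, 0, m / (s / sqrt(n)))
    rep_tbl <- tibble(
      gene_id = rownames(d), t = t_stat, df = n - 1,
      p_value = 2 * pt(abs(t_stat), n - 1, lower.tail = FALSE)
    )
  } else {
    rep_tbl <- row_welch_t(matrix_a, matrix_b)
  }
  rep_tbl$retained <- rep_tbl$p_value < alpha
  report <- structure(rep_tbl,
                      n_input_genes = nrow(matrix_a),
                      n_retained = sum(rep_tbl$retained),
                      alpha = alpha)
  list(genes = rep_tbl$gene_id[rep_tbl$retained], report = report)
}

#' Select the most connected genes
#'
#' Ranks genes by whole-network soft connectivity
#' `k_i = sum_{j != i} |cor(i, j)|^power` on the supplied matrix and returns
#' the top `k_target`. Ties are broken by descending connectivity, then
#' lexicographic gene ID, so the selection is reproducible.
#'
#' @param expr_matrix Gene x sample matrix.
#' @param power Soft-threshold exponent (>= 1).
#' @param k_target How many genes to keep (`<= nrow(expr_matrix)`).
#' @return Character vector of `k_target` gene IDs, plus attribute
#'   `connectivity` (named numeric, all genes).
#' @export
select_most_connected <- function(expr_matrix, power = 6, k_target) {
  check_expr_matrix(expr_matrix, "expr_matrix")
  check_no_constant_rows(expr_matrix, "expr_matrix")
  if (k_target > nrow(expr_matrix)) {
    stop_coexnet("`k_target` exceeds the number of genes.",
                 "coexnet_invalid_input")
  }
  a <- abs(cor(t(expr_matrix)))^power
  diag(a) <- 0
  k <- rowSums(a)
  ord <- order(-k, rownames(expr_matrix))
  out <- rownames(expr_matrix)[ord][seq_len(k_target)]
  attr(out, "connectivity") <- k
  out
}
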