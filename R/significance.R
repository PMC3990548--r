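#' Gene significance between conditions
#'
#' Per-gene two-sample Welch t-test of differential expression between the
#' test and reference conditions. Gene significance (GS) is the absolute t
#' statistic; the p-value is two-sided. A moderated (pooled-variance)
#' variant is available but off by default.
#'
#' @param expr_test,expr_ref Gene x sample matrices sharing gene IDs.
#' @param moderated Use a pooled equal-variance t-statistic instead of
#'   Welch.
#' @return Tibble (`gene_id`, `gs`, `t`, `df`, `p_value`).
#' @export
gene_significance <- function(expr_test, expr_ref, moderated = FALSE) {
  check_expr_matrix(expr_test, "expr_test")
  check_expr_matrix(expr_ref, "expr_ref")
  if (!identical(rownames(expr_test), rownames(expr_ref))) {
    stop_coexnet("Both matrices must share gene IDs in the same order.",
                 "coexnet_invalid_input")
  }
  if (moderated) {
    n1 <- ncol(expr_test)
    n2 <- ncol(expr_ref)
    if (n1 < 2 || n2 < 2) {
      stop_coexnet("Each condition needs >= 2 samples.",
                   "coexnet_invalid_input")
    }
    v1 <- apply(expr_test, 1, function(r) sum((r - mean(r))^2))
    v2 <- apply(expr_ref, 1, function(r) sum((r - mean(r))^2))
    sp2 <- (v1 + v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    t_stat <- (rowMeans(expr_test) - rowMeans(expr_ref)) / se
    t_stat[se == 0] <- 0
    df <- n1 + n2 - 2
    res <- tibble(gene_id = rownames(expr_test), t = unname(t_stat), df = df,
                  p_value = 2 * pt(abs(t_stat), df, lower.tail = FALSE))
  } else {
    res <- row_welch_t(expr_test, expr_ref)
  }
  dplyr::mutate(res, gs = abs(.data$t), .after = "gene_id")
}

#' Call hub genes per module
#'
#' The hub of a module is its gene with maximal absolute kME (module
#' membership). Ties are broken by higher gene significance, then by gene
#' ID. The runner-up gene is reported alongside.
#'
#' @param partition `module_partition` or tibble (`gene_id`, `module`).
#' @param kme Gene x module kME matrix (e.g. from [module_eigengenes()]).
#' @param scores Tibble from [gene_significance()] (optional; without it
#'   ties fall through to gene ID and GS columns are `NA`).
#' @return Tibble (`module`, `hub`, `kme_own`, `gs`, `p_value`,
#'   `runner_up`).
#' @export
hub_genes <- function(partition, kme, scores = NULL) {
  labs <- if (inherits(partition, "module_partition")) partition$labels
          else as_tibble(partition)
  mods <- module_sizes_tbl(labs)
  gs_of <- function(g) {
    if (is.null(scores)) return(rep(NA_real_, length(g)))
    scores$gs[match(g, scores$gene_id)]
  }
  p_of <- function(g) {
    if (is.null(scores)) return(rep(NA_real_, length(g)))
    scores$p_value[match(g, scores$gene_id)]
  }
  purrr::map_dfr(mods$module, function(m) {
    genes <- labs$gene_id[labs$module == m]
    genes <- genes[genes %in% rownames(kme)]
    if (!length(genes) || !(m %in% colnames(kme))) {
      rlang::warn(sprintf("Module %s empty or missing from kME; skipped.", m))
      return(NULL)
    }
    k <- abs(kme[genes, m])
    g_gs <- gs_of(genes)
    ord <- order(-k, -ifelse(is.na(g_gs), -Inf, g_gs), genes)
    hub <- genes[ord[1]]
    tibble(
      module = m,
      hub = hub,
      kme_own = unname(kme[hub, m]),
      gs = gs_of(hub),
      p_value = p_of(hub),
      runner_up = if (length(genes) > 1) genes[ord[2]] else NA_character_
    )
  })
}

#' Export a thresholded edge list and node attributes
#'
#' Writes the network in the form graph tools (e.g. Cytoscape) import: one
#' row per gene pair with connection strength strictly above the threshold,
#' plus a node table carrying module labels and whole-network connectivity
#' (node size in the conventional rendering is proportional to
#' connectivity).
#'
#' @param weight_matrix Symmetric matrix of weights in \[0, 1\] (e.g.
#'   adjacency or TOM).
#' @param threshold Keep edges with weight strictly greater than this;
#'   must lie in \[0, 1).
#' @param partition Optional partition; restricts nodes to `module` when
#'   given.
#' @param module Optional single module label to restrict the export to.
#' @return List of tibbles `edges` (`gene_a`, `gene_b`, `weight`, with
#'   `gene_a < gene_b`) and `nodes` (`gene_id`, `module`, `connectivity`).
#' @export
export_edge_list <- function(weight_matrix, threshold = 0.3,
                             partition = NULL, module = NULL) {
  check_symmetric01(weight_matrix, "weight_matrix")
  if (!(threshold >= 0 && threshold < 1)) {
    stop_coexnet("`threshold` must be in [0, 1).", "coexnet_invalid_input")
  }
  genes <- rownames(weight_matrix)
  labs <- NULL
  if (!is.null(partition)) {
    labs <- if (inherits(partition, "module_partition")) partition$labels
            else as_tibble(partition)
  }
  if (!is.null(module)) {
    if (is.null(labs)) {
      stop_coexnet("Restricting to a module requires `partition`.",
                   "coexnet_invalid_input")
    }
    genes <- intersect(genes, labs$gene_id[labs$module == module])
  }
  w <- weight_matrix[genes, genes, drop = FALSE]
  idx <- which(upper.tri(w) & w > threshold, arr.ind = TRUE)
  ga <- genes[idx[, 1]]
  gb <- genes[idx[, 2]]
  swap <- ga > gb
  edges <- tibble(
    gene_a = ifelse(swap, gb, ga),
    gene_b = ifelse(swap, ga, gb),
    weight = w[idx]
  ) |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
  k_all <- rowSums(weight_matrix) - diag(weight_matrix)
  nodes <- tibble(
    gene_id = genes,
    module = if (is.null(labs)) NA_character_
             else labs$module[match(genes, labs$gene_id)],
    connectivity = unname(k_all[genes])
  )
  list(edges = edges, nodes = nodes)
}
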