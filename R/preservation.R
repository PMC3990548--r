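#' Density preservation statistic: mean intramodular adjacency
#'
#' Measures whether a module's genes remain highly connected in a network:
#' the mean off-diagonal connection strength over the module's submatrix.
#'
#' @param adjacency Adjacency matrix (genes x genes, named).
#' @param module_genes Character vector of module gene IDs (>= 3).
#' @return Scalar in \[0, 1\].
#' @export
density_statistic <- function(adjacency, module_genes) {
  if (length(module_genes) < 3) {
    stop_coexnet("A module needs >= 3 genes for the density statistic.",
                 "coexnet_invalid_input")
  }
  if (!all(module_genes %in% rownames(adjacency))) {
    stop_coexnet("All module genes must be in the network.",
                 "coexnet_invalid_input")
  }
  a <- adjacency[module_genes, module_genes]
  m <- length(module_genes)
  (sum(a) - sum(diag(a))) / (m * (m - 1))
}

#' Connectivity preservation statistic: correlation of intramodular
#' connectivity
#'
#' Measures whether the connectivity pattern among a module's genes in the
#' reference network is mirrored in the test network: the Pearson
#' correlation between the two within-module connectivity vectors (row sums
#' of the module submatrix, kIM). A zero-variance connectivity vector in
#' either network makes the statistic undefined; it is reported as 0 with a
#' warning.
#'
#' @param ref_adjacency,test_adjacency Adjacency matrices containing the
#'   module genes.
#' @param module_genes Character vector of module gene IDs (>= 4).
#' @return Scalar in \[-1, 1\].
#' @export
connectivity_statistic <- function(ref_adjacency, test_adjacency,
                                   module_genes) {
  if (length(module_genes) < 4) {
    stop_coexnet("A module needs >= 4 genes for the connectivity statistic.",
                 "coexnet_invalid_input")
  }
  k_ref <- intramodular_connectivity(ref_adjacency, module_genes)
  k_test <- intramodular_connectivity(test_adjacency, module_genes)
  if (sd(k_ref) == 0 || sd(k_test) == 0) {
    rlang::warn("Zero-variance intramodular connectivity; statistic set to 0.")
    return(0)
  }
  cor(k_ref, k_test)
}

intramodular_connectivity <- function(adjacency, module_genes) {
  if (!all(module_genes %in% rownames(adjacency))) {
    stop_coexnet("All module genes must be in the network.",
                 "coexnet_invalid_input")
  }
  a <- adjacency[module_genes, module_genes]
  rowSums(a) - diag(a)
}

#' Permutation null for a preservation statistic
#'
#' Repeatedly draws random gene sets of the module's size from the genes
#' outside the module and recomputes the chosen statistic, yielding the
#' null mean and standard deviation used to standardize the observed value
#' into a Z score. Deterministic given `seed`.
#'
#' @param test_adjacency Adjacency of the test network.
#' @param ref_adjacency Adjacency of the reference network (used by the
#'   connectivity statistic).
#' @param module_genes Genes of the module under test (excluded from the
#'   null draws).
#' @param n_perm Number of permutations (>= 50).
#' @param seed Integer seed.
#' @param statistic One of `"density"`, `"connectivity"`.
#' @return List with `mean`, `sd`, `draws` and `degenerate` (`TRUE` when the
#'   null has zero spread, in which case Z scores are `+/-Inf` sentinels).
#' @export
permutation_null <- function(test_adjacency, ref_adjacency, module_genes,
                             n_perm = 200, seed = 1,
                             statistic = c("density", "connectivity")) {
  statistic <- match.arg(statistic)
  if (n_perm < 50) {
    stop_coexnet("`n_perm` must be >= 50.", "coexnet_invalid_input")
  }
  pool <- setdiff(rownames(test_adjacency), module_genes)
  m <- length(module_genes)
  if (length(pool) < m) {
    stop_coexnet("Not enough genes outside the module for permutation draws.",
                 "coexnet_invalid_input")
  }
  draws <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      g <- sample(pool, m)
      if (statistic == "density") density_statistic(test_adjacency, g)
      else suppressWarnings(
        connectivity_statistic(ref_adjacency, test_adjacency, g))
    }, numeric(1))
  })
  s <- sd(draws)
  if (s == 0) {
    rlang::warn("Degenerate permutation null (zero spread).")
  }
  list(mean = mean(draws), sd = s, draws = draws, degenerate = s == 0)
}

z_score <- function(observed, null) {
  if (null$degenerate) {
    return(sign(observed - null$mean) * Inf)
  }
  (observed - null$mean) / null$sd
}

#' Composite preservation Z summary
#'
#' Aggregates the density- and connectivity-based Z statistics into one
#' composite: their arithmetic mean.
#'
#' @param z_density,z_connectivity Finite Z scores (infinite sentinels from
#'   degenerate nulls propagate).
#' @return Scalar Zsummary.
#' @export
z_summary <- function(z_density, z_connectivity) {
  (z_density + z_connectivity) / 2
}

#' Classify preservation evidence from Zsummary
#'
#' Zsummary above 10 is strong evidence the module is preserved, below 2 no
#' evidence, in between weak evidence. The boundary values 2 and 10
#' themselves classify as weak. Infinite sentinels map to strong or none by
#' sign.
#'
#' @param zsummary Numeric vector.
#' @return Character vector: `"strong"`, `"weak"` or `"none"`.
#' @export
#' @examples
#' classify_preservation(c(-0.65, 19, 8.6))
classify_preservation <- function(zsummary) {
  dplyr::case_when(
    zsummary > 10 ~ "strong",
    zsummary < 2 ~ "none",
    TRUE ~ "weak"
  )
}

#' Permutation preservation of modules between two networks
#'
#' For each module of the partition (detected in the reference network),
#' standardizes the observed density and connectivity statistics in the
#' test network against permutation nulls of random same-size gene sets,
#' averages the two Z scores into Zsummary and classifies the evidence.
#' Modules with no preservation evidence (Zsummary < 2) are flagged
#' `specific`: present in the network the partition came from but not in
#' the tested one.
#'
#' @param ref_network,test_network `gene_network` objects (or bare adjacency
#'   matrices) over a shared gene universe.
#' @param partition `module_partition` or tibble (`gene_id`, `module`);
#'   `"unassigned"` is ignored.
#' @param n_perm Permutations per module and statistic (default 200).
#' @param seed Integer seed.
#' @return Object of class `preservation_result`: a tibble with columns
#'   `module`, `module_size`, `density_observed`, `connectivity_observed`,
#'   `z_density`, `z_connectivity`, `z_summary`, `evidence`, `specific`,
#'   plus attributes `n_perm` and `seed`.
#' @export
module_preservation <- function(ref_network, test_network, partition,
                                n_perm = 200, seed = 1) {
  ref_a <- as_adjacency(ref_network)
  test_a <- as_adjacency(test_network)
  if (!identical(sort(rownames(ref_a)), sort(rownames(test_a)))) {
    stop_coexnet("Reference and test networks must share the gene universe.",
                 "coexnet_invalid_input")
  }
  labs <- if (inherits(partition, "module_partition")) partition$labels
          else as_tibble(partition)
  mods <- module_sizes_tbl(labs)
  rows <- purrr::map_dfr(seq_len(nrow(mods)), function(i) {
    m <- mods$module[i]
    genes <- labs$gene_id[labs$module == m]
    if (!all(genes %in% rownames(test_a))) {
      rlang::warn(sprintf("Module %s absent from the gene universe; skipped.", m))
      return(NULL)
    }
    if (length(genes) < 4) {
      rlang::warn(sprintf("Module %s has <4 genes; skipped.", m))
      return(NULL)
    }
    d_obs <- density_statistic(test_a, genes)
    c_obs <- suppressWarnings(connectivity_statistic(ref_a, test_a, genes))
    null_d <- permutation_null(test_a, ref_a, genes, n_perm,
                               seed = seed + 2L * i, statistic = "density")
    null_c <- permutation_null(test_a, ref_a, genes, n_perm,
                               seed = seed + 2L * i + 1L,
                               statistic = "connectivity")
    zd <- z_score(d_obs, null_d)
    zc <- z_score(c_obs, null_c)
    zs <- z_summary(zd, zc)
    tibble(
      module = m, module_size = length(genes),
      density_observed = d_obs, connectivity_observed = c_obs,
      z_density = zd, z_connectivity = zc, z_summary = zs,
      evidence = classify_preservation(zs),
      specific = zs < 2
    )
  })
  structure(rows, class = c("preservation_result", class(rows)),
            n_perm = n_perm, seed = seed)
}

as_adjacency <- function(x) {
  if (inherits(x, "gene_network")) return(x$adjacency)
  if (is.matrix(x)) return(x)
  stop_coexnet("Expected a gene_network or an adjacency matrix.",
               "coexnet_invalid_input")
}

#' @describeIn module_preservation Plain-tibble view.
#' @param x A `preservation_result`.
#' @param ... Unused.
#' @method tidy preservation_result
#' @export
tidy.preservation_result <- function(x, ...) {
  as_tibble(x)
}

#' @describeIn module_preservation Count of modules per evidence class.
#' @method glance preservation_result
#' @export
glance.preservation_result <- function(x, ...) {
  tibble(
    n_modules = nrow(x),
    n_strong = sum(x$evidence == "strong"),
    n_weak = sum(x$evidence == "weak"),
    n_none = sum(x$evidence == "none"),
    n_perm = attr(x, "n_perm"),
    seed = attr(x, "seed")
  )
}

#' @describeIn module_preservation Zsummary against module size with the
#'   evidence thresholds at 2 and 10.
#' @param object A `preservation_result`.
#' @method autoplot preservation_result
#' @export
autoplot.preservation_result <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$module_size, .data$z_summary,
                               label = .data$module)) +
    ggplot2::geom_hline(yintercept = 10, colour = "blue", linetype = 2) +
    ggplot2::geom_hline(yintercept = 2, colour = "darkgreen", linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(x = "module size", y = expression(Z[summary]))
}

#' Stage-wise module preservation
#'
#' Fixes the modules detected on the full test-condition network, rebuilds
#' the test-condition network from each stage's samples only, and computes
#' every module's preservation Zsummary against each stage network. Stages
#' with fewer than 4 samples are skipped with a warning.
#'
#' @param study An `expression_study` (or a list with `expr$test` matrix and
#'   a `samples` tibble holding `sample_id`, `condition`, `stage`).
#' @param partition Modules detected on the full test-condition network.
#' @param n_perm Permutations (default 200).
#' @param seed Integer seed.
#' @param power Soft-threshold power for the stage networks (default 6).
#' @param condition Which condition's samples to restage (default `"test"`).
#' @return Object of class `stage_preservation`: tibble with `module`,
#'   `stage`, `module_size`, `z_summary`, `evidence`, `n_samples`.
#' @export
stagewise_preservation <- function(study, partition, n_perm = 200, seed = 1,
                                   power = 6, condition = "test") {
  expr <- study$expr[[condition]]
  samp <- study$samples |> dplyr::filter(.data$condition == !!condition)
  if (anyNA(samp$stage) || any(samp$stage == "")) {
    bad <- samp$sample_id[is.na(samp$stage) | samp$stage == ""]
    stop_coexnet(sprintf("Missing stage annotation for sample(s): %s.",
                         paste(head(bad, 5), collapse = ", ")),
                 "coexnet_invalid_input")
  }
  full_net <- build_network(expr, power = power)
  stages <- c("priming", "proliferative", "termination")
  stages <- stages[stages %in% samp$stage]
  rows <- purrr::map_dfr(seq_along(stages), function(si) {
    st <- stages[si]
    ids <- samp$sample_id[samp$stage == st]
    if (length(ids) < 4) {
      rlang::warn(sprintf("Stage %s has <4 samples; skipped.", st))
      return(NULL)
    }
    sub <- expr[, ids, drop = FALSE]
    v <- apply(sub, 1, sd)
    keep <- v > 0
    stage_net <- build_network(sub[keep, , drop = FALSE], power = power)
    labs <- if (inherits(partition, "module_partition")) partition$labels
            else as_tibble(partition)
    labs <- labs[labs$gene_id %in% rownames(stage_net$adjacency), ]
    pres <- module_preservation(
      ref_network = full_net$adjacency[keep, keep, drop = FALSE],
      test_network = stage_net, partition = labs,
      n_perm = n_perm, seed = seed + 1000L * si
    )
    tibble(
      module = pres$module, stage = st, module_size = pres$module_size,
      z_summary = pres$z_summary, evidence = pres$evidence,
      n_samples = length(ids)
    )
  })
  structure(rows, class = c("stage_preservation", class(rows)),
            n_perm = n_perm, seed = seed)
}

#' @describeIn stagewise_preservation Wide module x stage table of Zsummary.
#' @param x A `stage_preservation`.
#' @param ... Unused.
#' @method tidy stage_preservation
#' @export
tidy.stage_preservation <- function(x, ...) {
  as_tibble(x) |>
    dplyr::select("module", "stage", "z_summary") |>
    tidyr::pivot_wider(names_from = "stage", values_from = "z_summary")
}

#' @describeIn stagewise_preservation Heatmap of Zsummary by module and
#'   stage.
#' @param object A `stage_preservation`.
#' @method autoplot stage_preservation
#' @export
autoplot.stage_preservation <- function(object, ...) {
  dat <- as_tibble(object)
  dat$stage <- factor(dat$stage,
                      levels = c("priming", "proliferative", "termination"))
  ggplot2::ggplot(dat, ggplot2::aes(.data$stage, .data$module,
                                    fill = .data$z_summary)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$z_summary)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "white", high = "firebrick",
                                  midpoint = 2) +
    ggplot2::labs(x = NULL, y = NULL, fill = expression(Z[summary]))
}
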