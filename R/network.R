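#' Pearson correlation matrix across genes
#'
#' Correlates every pair of gene expression profiles (rows) across samples.
#' Constant rows have no defined correlation and raise an error naming the
#' offending genes.
#'
#' @param expr_matrix Gene x sample matrix with >= 3 samples.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(expr_matrix) {
  check_expr_matrix(expr_matrix, "expr_matrix")
  if (ncol(expr_matrix) < 3) {
    stop_coexnet("Need at least 3 samples to correlate genes.",
                 "coexnet_invalid_input")
  }
  check_no_constant_rows(expr_matrix, "expr_matrix")
  r <- cor(t(expr_matrix))
  # guard against fp drift outside [-1, 1]
  r[r > 1] <- 1
  r[r < -1] <- -1
  r
}

#' Soft-threshold power adjacency from correlations
#'
#' Converts a correlation matrix into connection strengths of an unsigned
#' weighted network, `a_ij = |r_ij|^power`, emphasizing strong correlations
#' and punishing weak ones on an exponential scale. The diagonal is set to 0
#' so downstream sums (connectivity, topological overlap) exclude
#' self-connections.
#'
#' @param correlation Symmetric correlation matrix.
#' @param power Positive integer soft-threshold exponent.
#' @return Adjacency matrix with entries in \[0, 1\] and zero diagonal.
#' @export
adjacency_from_correlation <- function(correlation, power = 6) {
  if (!is.numeric(power) || length(power) != 1L || power < 1 ||
      power != round(power)) {
    stop_coexnet("`power` must be a positive integer >= 1.",
                 "coexnet_invalid_input")
  }
  if (!is.matrix(correlation) || nrow(correlation) != ncol(correlation)) {
    stop_coexnet("`correlation` must be square.", "coexnet_invalid_input")
  }
  a <- abs(correlation)^power
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' Computes the unsigned topological overlap
#' `t_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_{u != i,j} a_iu a_uj` and connectivity `k_i = sum_{j != i}
#' a_ij`. The overlap rewards gene pairs that are both directly connected
#' and share strongly connected neighbours; `1 - t_ij` is the clustering
#' dissimilarity used for module detection. The diagonal is reported as 1 by
#' convention.
#'
#' @param adjacency Symmetric adjacency in \[0, 1\] with zero diagonal.
#' @return Symmetric matrix with entries in \[0, 1\] and unit diagonal.
#' @export
#' @examples
#' a <- matrix(c(0, .8, .6, .8, 0, .4, .6, .4, 0), 3, 3)
#' topological_overlap(a)[1, 2]  # 1.04 / 1.4
topological_overlap <- function(adjacency) {
  check_symmetric01(adjacency, "adjacency")
  if (any(diag(adjacency) != 0)) {
    stop_coexnet("`adjacency` must have a zero diagonal.",
                 "coexnet_invalid_input")
  }
  k <- rowSums(adjacency)
  # With zero diagonal, (A %*% A)[i, j] = sum_u a_iu a_uj already excludes
  # u = i and u = j.
  l <- adjacency %*% adjacency
  denom <- outer(k, k, pmin) + 1 - adjacency
  tom <- (l + adjacency) / denom
  diag(tom) <- 1
  tom <- pmin(tom, 1)
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Scale-free topology fit for a connectivity distribution
#'
#' Bins the connectivity vector into equal-count (quantile) bins, then
#' regresses `log10(density)` on `log10(mean connectivity)` per bin, where a
#' bin's density is its count divided by total count and bin width.
#' Quantile bins are robust to the heavy tail of a scale-free distribution;
#' with them the count itself is constant, so the density carries the
#' distribution's shape. A power-law distribution appears as a straight
#' declining line; the fit index is the regression R-squared, reported as 0
#' when the slope is non-negative since scale-free structure requires
#' decay.
#'
#' @param connectivity Numeric vector of per-gene connectivities (length
#'   >= `2 * n_bins`).
#' @param n_bins Number of equal-count bins (default 10).
#' @return A one-row tibble (`r_squared`, `slope`, `n_bins`).
#' @export
scale_free_fit <- function(connectivity, n_bins = 10) {
  if (length(connectivity) < 2 * n_bins) {
    stop_coexnet(sprintf("Need >= %d genes for %d bins.", 2 * n_bins, n_bins),
                 "coexnet_invalid_input")
  }
  if (diff(range(connectivity)) == 0) {
    stop_coexnet("All connectivities equal: scale-free fit is degenerate.",
                 "coexnet_degenerate_fit")
  }
  br <- unique(quantile(connectivity, probs = seq(0, 1, length.out = n_bins + 1)))
  bins <- cut(connectivity, breaks = br, include.lowest = TRUE)
  k_mean <- tapply(connectivity, bins, mean)
  counts <- tapply(connectivity, bins, length)
  freq <- counts / (length(connectivity) * diff(br))
  ok <- is.finite(k_mean) & k_mean > 0 & is.finite(freq) & freq > 0
  if (sum(ok) < 3) {
    stop_coexnet("Too few usable bins for the scale-free regression.",
                 "coexnet_degenerate_fit")
  }
  fit <- lm(log10(freq[ok]) ~ log10(k_mean[ok]))
  slope <- unname(coef(fit)[2])
  r2 <- summary(fit)$r.squared
  if (!is.finite(slope) || slope >= 0) r2 <- 0
  tibble(r_squared = r2, slope = slope, n_bins = as.integer(n_bins))
}

#' Choose the soft-threshold power by the scale-free criterion
#'
#' Evaluates candidate powers and picks the smallest whose connectivity
#' distribution reaches the target scale-free fit. When no candidate
#' reaches the target, the best-fitting power is returned with a warning.
#'
#' @param expr_matrix Gene x sample matrix.
#' @param candidate_powers Ascending positive integers (default 1:20).
#' @param r2_target Required model fit in (0, 1] (default 0.85).
#' @param n_bins Bins for [scale_free_fit()].
#' @return A list with `power` (chosen integer) and `fits`, a tibble of
#'   (`power`, `r_squared`, `slope`).
#' @export
pick_soft_threshold <- function(expr_matrix, candidate_powers = 1:20,
                                r2_target = 0.85, n_bins = 10) {
  if (length(candidate_powers) < 1 || is.unsorted(candidate_powers)) {
    stop_coexnet("`candidate_powers` must be non-empty ascending integers.",
                 "coexnet_invalid_input")
  }
  if (!(r2_target >= 0 && r2_target <= 1)) {
    stop_coexnet("`r2_target` must be in [0, 1].", "coexnet_invalid_input")
  }
  r <- correlation_matrix(expr_matrix)
  fits <- purrr::map_dfr(candidate_powers, function(p) {
    a <- adjacency_from_correlation(r, p)
    dplyr::bind_cols(tibble(power = as.integer(p)),
                     scale_free_fit(rowSums(a), n_bins))
  })
  hit <- which(fits$r_squared >= r2_target)
  if (length(hit)) {
    power <- fits$power[hit[1]]
  } else {
    power <- fits$power[which.max(fits$r_squared)]
    rlang::warn(sprintf(
      "No candidate power reached R^2 >= %.2f; using power %d (best R^2 = %.3f).",
      r2_target, power, max(fits$r_squared)))
  }
  list(power = power, fits = fits)
}

#' Build the weighted co-expression network for one condition
#'
#' Runs correlation, power adjacency and topological overlap in one step
#' and returns them bundled with the soft power used. With `power =
#' "auto"`, the power is chosen by [pick_soft_threshold()].
#'
#' @param expr_matrix Gene x sample matrix.
#' @param power Positive integer, or `"auto"` for scale-free selection.
#' @param r2_target Scale-free target when `power = "auto"`.
#' @return An object of class `gene_network`: list with `gene_ids`,
#'   `correlation`, `adjacency`, `tom`, `connectivity`, `power` and (when
#'   auto-selected) the `fits` table.
#' @export
build_network <- function(expr_matrix, power = 6, r2_target = 0.85) {
  fits <- NULL
  if (identical(power, "auto")) {
    sel <- pick_soft_threshold(expr_matrix, r2_target = r2_target)
    power <- sel$power
    fits <- sel$fits
  }
  r <- correlation_matrix(expr_matrix)
  a <- adjacency_from_correlation(r, power)
  structure(
    list(
      gene_ids = rownames(expr_matrix),
      correlation = r,
      adjacency = a,
      tom = topological_overlap(a),
      connectivity = rowSums(a),
      power = as.integer(power),
      fits = fits
    ),
    class = "gene_network"
  )
}

#' @export
print.gene_network <- function(x, ...) {
  cat("<gene_network>\n")
  cat(sprintf("  %d genes, soft power %d\n", length(x$gene_ids), x$power))
  cat(sprintf("  mean connectivity %.3f\n", mean(x$connectivity)))
  invisible(x)
}

#' @describeIn build_network Per-gene connectivity as a tibble.
#' @param x A `gene_network`.
#' @param ... Unused.
#' @method tidy gene_network
#' @export
tidy.gene_network <- function(x, ...) {
  tibble(gene_id = x$gene_ids, connectivity = unname(x$connectivity))
}

#' @describeIn build_network One-row network summary including the
#'   scale-free fit of the realized connectivity distribution.
#' @method glance gene_network
#' @export
glance.gene_network <- function(x, ...) {
  sf <- tryCatch(scale_free_fit(x$connectivity),
                 error = function(e) tibble(r_squared = NA_real_,
                                            slope = NA_real_,
                                            n_bins = NA_integer_))
  tibble(
    n_genes = length(x$gene_ids),
    power = x$power,
    mean_connectivity = mean(x$connectivity),
    max_connectivity = max(x$connectivity),
    scale_free_r2 = sf$r_squared,
    scale_free_slope = sf$slope
  )
}

#' @describeIn build_network Scale-free fit diagnostics: R-squared by
#'   candidate power if available, else the connectivity histogram.
#' @param object A `gene_network`.
#' @method autoplot gene_network
#' @export
autoplot.gene_network <- function(object, ...) {
  if (!is.null(object$fits)) {
    ggplot2::ggplot(object$fits,
                    ggplot2::aes(.data$power, .data$r_squared)) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::geom_hline(yintercept = 0.85, linetype = 2) +
      ggplot2::labs(x = "soft-threshold power", y = expression(R^2),
                    title = "Scale-free topology fit")
  } else {
    ggplot2::ggplot(tidy(object), ggplot2::aes(.data$connectivity)) +
      ggplot2::geom_histogram(bins = 30) +
      ggplot2::labs(x = "connectivity k", y = "genes")
  }
}
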