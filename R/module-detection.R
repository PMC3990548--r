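#' Average-linkage clustering of a topological-overlap dissimilarity
#'
#' Clusters genes by UPGMA (average linkage) on a dissimilarity matrix,
#' conventionally `1 - TOM`. A single-gene input yields a degenerate
#' dendrogram with no merges rather than an error.
#'
#' @param dissimilarity Square symmetric matrix with zero diagonal and no
#'   missing values.
#' @return An `hclust` object (with zero merge rows when n = 1).
#' @export
hierarchical_cluster <- function(dissimilarity) {
  if (!is.matrix(dissimilarity) || nrow(dissimilarity) != ncol(dissimilarity)) {
    stop_coexnet("`dissimilarity` must be square.", "coexnet_invalid_input")
  }
  if (anyNA(dissimilarity) || any(!is.finite(dissimilarity))) {
    stop_coexnet("`dissimilarity` contains NA/NaN entries.",
                 "coexnet_invalid_input")
  }
  if (max(abs(dissimilarity - t(dissimilarity))) > 1e-8) {
    stop_coexnet("`dissimilarity` must be symmetric.", "coexnet_invalid_input")
  }
  if (any(diag(dissimilarity) != 0)) {
    stop_coexnet("`dissimilarity` must have a zero diagonal.",
                 "coexnet_invalid_input")
  }
  n <- nrow(dissimilarity)
  if (n == 1L) {
    return(structure(
      list(merge = matrix(integer(0), 0, 2), height = numeric(0),
           order = 1L, labels = rownames(dissimilarity),
           method = "average", call = match.call(),
           dist.method = "1 - TOM"),
      class = "hclust"
    ))
  }
  hclust(as.dist(dissimilarity), method = "average")
}

# Labels for detected modules, in decreasing size order. Conventional
# co-expression colour names, extended with numbered labels if exhausted.
module_label_sequence <- function(n) {
  colors <- c(
    "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
    "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
    "paleturquoise", "violet", "darkolivegreen", "darkmagenta"
  )
  if (n <= length(colors)) colors[seq_len(n)]
  else c(colors, sprintf("module%d", seq_len(n - length(colors)) +
                           length(colors)))
}

#' Cut a dendrogram into modules with a dynamic (adaptive) tree cut
#'
#' Splits the merge tree top-down. Merges above `cut_height` are never
#' binding (a static cut), and below it a branch is further split whenever
#' both sub-branches are at least `min_module_size` genes and the height gap
#' between the merge and its taller sub-branch exceeds a sensitivity
#' threshold controlled by `deep_split` (0 = static cut only, 4 = most
#' aggressive). Clusters smaller than `min_module_size` and leftover leaves
#' are labelled `"unassigned"`. Module labels follow decreasing size using
#' the conventional colour sequence (largest = turquoise).
#'
#' @param dendrogram An `hclust` object from [hierarchical_cluster()].
#' @param deep_split Integer 0-4 split aggressiveness (default 2).
#' @param cut_height Static cut height in (0, 1] (default 0.995).
#' @param min_module_size Minimum genes per module (default 30).
#' @return An object of class `module_partition`: list with `labels` (tibble
#'   `gene_id`, `module`), `dendrogram`, and `params`.
#' @export
dynamic_tree_cut <- function(dendrogram, deep_split = 2, cut_height = 0.995,
                             min_module_size = 30) {
  if (!inherits(dendrogram, "hclust")) {
    stop_coexnet("`dendrogram` must be an hclust object.",
                 "coexnet_invalid_input")
  }
  if (!(cut_height > 0 && cut_height <= 1)) {
    stop_coexnet("`cut_height` must be in (0, 1].", "coexnet_invalid_input")
  }
  if (min_module_size < 3) {
    stop_coexnet("`min_module_size` must be >= 3.", "coexnet_invalid_input")
  }
  if (!deep_split %in% 0:4) {
    stop_coexnet("`deep_split` must be an integer in 0..4.",
                 "coexnet_invalid_input")
  }
  labels_in <- dendrogram$labels %||% as.character(seq_along(dendrogram$order))
  n <- length(labels_in)
  merge <- dendrogram$merge
  h <- dendrogram$height
  nm <- nrow(merge)

  params <- list(deep_split = deep_split, cut_height = cut_height,
                 min_module_size = min_module_size)
  if (nm == 0L) {
    return(new_module_partition(
      tibble(gene_id = labels_in, module = "unassigned"), dendrogram, params))
  }

  # per-node child sizes and heights
  chs <- matrix(1L, nm, 2)
  chh <- matrix(0, nm, 2)
  for (i in seq_len(nm)) {
    for (j in 1:2) {
      m <- merge[i, j]
      if (m > 0) {
        chs[i, j] <- sum(chs[m, ])
        chh[i, j] <- h[m]
      }
    }
  }
  # Height-gap sensitivity by deep_split level, on the dissimilarity scale.
  gap_tol <- c(0.40, 0.25, 0.15, 0.08, 0.03)[deep_split + 1] * cut_height
  gap <- h - pmax(chh[, 1], chh[, 2])
  do_split <- (h > cut_height) |
    (chs[, 1] >= min_module_size & chs[, 2] >= min_module_size &
       gap >= gap_tol)

  # Downward pass: a node whose parent did not split inherits the parent's
  # cluster; otherwise a non-splitting node roots a new cluster.
  clus <- rep(NA_integer_, nm)
  leaf_clus <- rep(NA_integer_, n)
  next_id <- 0L
  for (i in rev(seq_len(nm))) {
    cid <- clus[i]
    if (is.na(cid) && !do_split[i]) {
      next_id <- next_id + 1L
      cid <- next_id
      clus[i] <- cid
    }
    # A node already claimed by an ancestor cluster passes that cluster on;
    # an unclaimed splitting node lets its children start fresh (NA).
    pass_on <- cid
    for (j in 1:2) {
      m <- merge[i, j]
      if (m > 0) clus[m] <- pass_on else leaf_clus[-m] <- pass_on
    }
  }

  sizes <- table(leaf_clus)
  keep <- names(sizes)[sizes >= min_module_size]
  keep <- keep[order(-sizes[keep], as.integer(keep))]
  mod_names <- module_label_sequence(length(keep))
  lab <- rep("unassigned", n)
  for (i in seq_along(keep)) {
    lab[!is.na(leaf_clus) & leaf_clus == as.integer(keep[i])] <- mod_names[i]
  }
  new_module_partition(tibble(gene_id = labels_in, module = lab),
                       dendrogram, params)
}

new_module_partition <- function(labels, dendrogram, params) {
  structure(list(labels = labels, dendrogram = dendrogram, params = params),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  sz <- module_sizes(x)
  cat("<module_partition>\n")
  cat(sprintf("  %d genes, %d module(s), %d unassigned\n",
              nrow(x$labels), nrow(sz),
              sum(x$labels$module == "unassigned")))
  if (nrow(sz)) {
    cat("  sizes: ",
        paste(sprintf("%s=%d", sz$module, sz$n), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Module sizes of a partition
#'
#' @param partition A `module_partition`.
#' @return Tibble (`module`, `n`), excluding `"unassigned"`, by decreasing
#'   size.
#' @export
module_sizes <- function(partition) {
  partition$labels |>
    dplyr::filter(.data$module != "unassigned") |>
    dplyr::count(.data$module, sort = TRUE)
}

#' @describeIn dynamic_tree_cut Gene-to-module assignments as a tibble.
#' @param x A `module_partition`.
#' @param ... Unused.
#' @method tidy module_partition
#' @export
tidy.module_partition <- function(x, ...) {
  x$labels
}

#' @describeIn dynamic_tree_cut One-row partition summary.
#' @method glance module_partition
#' @export
glance.module_partition <- function(x, ...) {
  tibble(
    n_genes = nrow(x$labels),
    n_modules = nrow(module_sizes(x)),
    n_unassigned = sum(x$labels$module == "unassigned"),
    deep_split = x$params$deep_split,
    cut_height = x$params$cut_height,
    min_module_size = x$params$min_module_size
  )
}

#' @describeIn dynamic_tree_cut Bar chart of module sizes.
#' @param object A `module_partition`.
#' @method autoplot module_partition
#' @export
autoplot.module_partition <- function(object, ...) {
  sz <- module_sizes(object)
  sz$module <- factor(sz$module, levels = sz$module)
  ggplot2::ggplot(sz, ggplot2::aes(.data$module, .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "genes") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Module eigengene of one expression block
#'
#' Standardizes each gene row to mean 0, sd 1, then takes the first right
#' singular vector of the block as the module's summary profile. The sign is
#' oriented so the eigengene correlates positively with the mean
#' standardized expression (ties broken toward the first gene). The variance
#' explained is the first squared singular value over the total.
#'
#' @param expr_submatrix Gene x sample matrix of the module's genes
#'   (>= 2 genes, >= 2 samples).
#' @return List with `me` (unit-norm sample-length profile) and
#'   `variance_explained` in \[0, 1\].
#' @export
module_eigengene <- function(expr_submatrix) {
  check_expr_matrix(expr_submatrix, "expr_submatrix")
  if (nrow(expr_submatrix) < 2 || ncol(expr_submatrix) < 2) {
    stop_coexnet("Need >= 2 genes and >= 2 samples for an eigengene.",
                 "coexnet_invalid_input")
  }
  xs <- standardize_rows(expr_submatrix)
  sv <- svd(xs)
  me <- sv$v[, 1]
  ref <- colMeans(xs)
  s <- sum(me * ref)
  if (s == 0) s <- sum(me * xs[1, ])
  if (s < 0) me <- -me
  list(
    me = setNames(me, colnames(expr_submatrix)),
    variance_explained = sv$d[1]^2 / sum(sv$d^2)
  )
}

#' Eigengenes for every module of a partition
#'
#' @param expr_matrix Gene x sample matrix covering the partition's genes.
#' @param partition A `module_partition` (or tibble `gene_id`, `module`).
#' @return Object of class `module_eigengenes`: list with `me` (sample x
#'   module matrix of unit-norm eigengenes), `variance_explained` (named
#'   vector) and `kme` (gene x module Pearson membership matrix for all
#'   genes in `expr_matrix`).
#' @export
module_eigengenes <- function(expr_matrix, partition) {
  labs <- if (inherits(partition, "module_partition")) partition$labels
          else as_tibble(partition)
  mods <- module_sizes_tbl(labs)
  if (!nrow(mods)) {
    stop_coexnet("The partition has no modules.", "coexnet_invalid_input")
  }
  me <- matrix(NA_real_, ncol(expr_matrix), nrow(mods),
               dimnames = list(colnames(expr_matrix), mods$module))
  ve <- setNames(numeric(nrow(mods)), mods$module)
  for (m in mods$module) {
    g <- labs$gene_id[labs$module == m]
    eg <- module_eigengene(expr_matrix[g, , drop = FALSE])
    me[, m] <- eg$me
    ve[m] <- eg$variance_explained
  }
  structure(
    list(me = me, variance_explained = ve,
         kme = module_membership(expr_matrix, me)),
    class = "module_eigengenes"
  )
}

module_sizes_tbl <- function(labs) {
  labs |>
    dplyr::filter(.data$module != "unassigned") |>
    dplyr::count(.data$module, sort = TRUE)
}

#' @export
print.module_eigengenes <- function(x, ...) {
  cat("<module_eigengenes>\n")
  cat(sprintf("  %d module(s) x %d samples\n", ncol(x$me), nrow(x$me)))
  cat("  variance explained: ",
      paste(sprintf("%s=%.2f", names(x$variance_explained),
                    x$variance_explained), collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn module_eigengenes Long tibble of kME module memberships.
#' @param x A `module_eigengenes`.
#' @param ... Unused.
#' @method tidy module_eigengenes
#' @export
tidy.module_eigengenes <- function(x, ...) {
  as_tibble(x$kme, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "module", values_to = "kme")
}

#' @describeIn module_eigengenes Eigengene profiles across samples.
#' @param object A `module_eigengenes`.
#' @method autoplot module_eigengenes
#' @export
autoplot.module_eigengenes <- function(object, ...) {
  dat <- as_tibble(object$me, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "module", values_to = "me") |>
    dplyr::mutate(sample_id = factor(.data$sample_id,
                                     levels = rownames(object$me)))
  ggplot2::ggplot(dat, ggplot2::aes(.data$sample_id, .data$me,
                                    colour = .data$module,
                                    group = .data$module)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "sample", y = "eigengene") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       size = 6))
}

#' Module membership (kME) of genes against eigengenes
#'
#' Pearson correlation between each gene's expression profile and each
#' module eigengene; values near +/-1 mark strong membership in an unsigned
#' network.
#'
#' @param expr_matrix Gene x sample matrix.
#' @param eigengenes Sample x module eigengene matrix (or a
#'   `module_eigengenes` object).
#' @return Gene x module matrix of correlations.
#' @export
module_membership <- function(expr_matrix, eigengenes) {
  if (inherits(eigengenes, "module_eigengenes")) eigengenes <- eigengenes$me
  if (nrow(eigengenes) != ncol(expr_matrix)) {
    stop_coexnet("Eigengenes and expression must share samples.",
                 "coexnet_invalid_input")
  }
  cor(t(expr_matrix), eigengenes)
}

#' Reassign genes to modules by maximal kME
#'
#' Iterates eigengene computation and gene reassignment: each gene moves to
#' the module whose eigengene it correlates with most strongly in absolute
#' value, and genes with `|kME| < kme_min` against every eigengene become
#' `"unassigned"`. Iteration stops at a fixed point or after `max_iter`
#' rounds. Modules reduced below 2 genes are dropped. Absolute correlation
#' is used throughout, consistent with the unsigned network, so
#' anti-correlated members (kME near -1) stay in their module.
#'
#' @param expr_matrix Gene x sample matrix (all genes eligible).
#' @param partition Initial `module_partition`.
#' @param kme_min Membership threshold (default 0.3).
#' @param max_iter Iteration cap (default 10).
#' @return A `module_partition` with extra fields `kme`
#'   (gene x module matrix), `eigengenes` (`module_eigengenes` of the final
#'   partition), `n_iterations`, and `objective` (per-iteration sum of
#'   maximal `|kME|`).
#' @export
reassign_by_kme <- function(expr_matrix, partition, kme_min = 0.3,
                            max_iter = 10) {
  labs <- partition$labels
  if (!all(labs$gene_id %in% rownames(expr_matrix))) {
    stop_coexnet("All partition genes must be rows of `expr_matrix`.",
                 "coexnet_invalid_input")
  }
  objective <- numeric(0)
  current <- labs
  eg <- NULL
  for (it in seq_len(max_iter)) {
    if (!nrow(module_sizes_tbl(current))) break
    eg <- module_eigengenes(expr_matrix[labs$gene_id, , drop = FALSE], current)
    akme <- abs(eg$kme)
    best <- max.col(akme, ties.method = "first")
    best_val <- akme[cbind(seq_len(nrow(akme)), best)]
    new_mod <- colnames(akme)[best]
    new_mod[best_val < kme_min] <- "unassigned"
    new_labs <- tibble(gene_id = rownames(akme), module = new_mod)
    # drop modules reduced below 2 genes (an eigengene needs >= 2)
    sz <- table(new_labs$module)
    dead <- names(sz)[sz < 2 & names(sz) != "unassigned"]
    new_labs$module[new_labs$module %in% dead] <- "unassigned"
    objective <- c(objective, sum(best_val[best_val >= kme_min]))
    if (identical(new_labs$module, current$module)) {
      current <- new_labs
      break
    }
    current <- new_labs
  }
  out <- new_module_partition(current, partition$dendrogram,
                              c(partition$params, list(kme_min = kme_min)))
  out$eigengenes <- eg
  out$kme <- if (!is.null(eg)) eg$kme else NULL
  out$n_iterations <- length(objective)
  out$objective <- objective
  out
}

#' Detect modules from an expression matrix and its TOM
#'
#' Convenience wrapper: average-linkage clustering of `1 - TOM`, dynamic
#' tree cut, then kME-based reassignment.
#'
#' @param expr_matrix Gene x sample matrix.
#' @param tom Topological overlap matrix for the same genes.
#' @inheritParams dynamic_tree_cut
#' @inheritParams reassign_by_kme
#' @return A `module_partition` (with kME fields, see [reassign_by_kme()]).
#' @export
detect_modules <- function(expr_matrix, tom, deep_split = 2,
                           cut_height = 0.995, min_module_size = 30,
                           kme_min = 0.3) {
  if (!identical(rownames(expr_matrix), rownames(tom))) {
    stop_coexnet("`expr_matrix` and `tom` must cover the same genes.",
                 "coexnet_invalid_input")
  }
  diss <- 1 - tom
  diag(diss) <- 0
  hc <- hierarchical_cluster(diss)
  part <- dynamic_tree_cut(hc, deep_split, cut_height, min_module_size)
  if (!nrow(module_sizes(part))) return(part)
  reassign_by_kme(expr_matrix, part, kme_min = kme_min)
}
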