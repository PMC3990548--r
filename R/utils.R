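# Internal helpers shared across modules.

# Stop with a classed condition so callers/tests can match on class.
stop_coexnet <- function(msg, class) {
  rlang::abort(msg, class = c(class, "coexnet_error"))
}

check_expr_matrix <- function(x, arg = "expr") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_coexnet(sprintf("`%s` must be a numeric matrix (genes x samples).", arg),
                 "coexnet_invalid_input")
  }
  if (is.null(rownames(x))) {
    stop_coexnet(sprintf("`%s` must have gene IDs as rownames.", arg),
                 "coexnet_invalid_input")
  }
  if (anyNA(x)) {
    stop_coexnet(sprintf("`%s` contains missing values.", arg),
                 "coexnet_invalid_input")
  }
  invisible(x)
}

# Rows with zero variance cannot enter a correlation network.
check_no_constant_rows <- function(x, arg = "expr") {
  v <- apply(x, 1, sd)
  if (any(v == 0)) {
    bad <- rownames(x)[v == 0]
    stop_coexnet(
      sprintf("Constant expression rows (zero variance) in `%s`: %s.",
              arg, paste(head(bad, 5), collapse = ", ")),
      "coexnet_invalid_input"
    )
  }
  invisible(x)
}

check_symmetric01 <- function(m, arg = "matrix", tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop_coexnet(sprintf("`%s` must be a square matrix.", arg), "coexnet_invalid_input")
  }
  if (max(abs(m - t(m))) > tol) {
    stop_coexnet(sprintf("`%s` must be symmetric.", arg), "coexnet_invalid_input")
  }
  if (min(m) < -tol || max(m) > 1 + tol) {
    stop_coexnet(sprintf("`%s` entries must lie in [0, 1].", arg), "coexnet_invalid_input")
  }
  invisible(m)
}

# Evaluate `code` with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Standardize rows of a gene x sample matrix to mean 0, sd 1.
standardize_rows <- function(x) {
  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  if (any(s == 0)) {
    stop_coexnet(
      sprintf("Constant gene row(s): %s.",
              paste(head(rownames(x)[s == 0], 5), collapse = ", ")),
      "coexnet_invalid_input"
    )
  }
  (x - mu) / s
}

# Vectorised two-sample Welch t-test over matched rows of two matrices.
# Returns a tibble with per-gene t statistics, degrees of freedom and
# two-sided p-values. Cross-checked against stats::t.test in the test suite.
row_welch_t <- function(a, b) {
  n1 <- ncol(a)
  n2 <- ncol(b)
  if (n1 < 2L || n2 < 2L) {
    stop_coexnet("Each group needs at least 2 samples for a t-test.",
                 "coexnet_invalid_input")
  }
  m1 <- rowMeans(a)
  m2 <- rowMeans(b)
  v1 <- apply(a, 1, function(r) sum((r - mean(r))^2)) / (n1 - 1)
  v2 <- apply(b, 1, function(r) sum((r - mean(r))^2)) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  # Both groups constant and equal: 0/0 -> define t = 0, p = 1.
  deg <- se2 == 0
  t_stat[deg] <- 0
  df[deg] <- n1 + n2 - 2
  p <- 2 * pt(abs(t_stat), df, lower.tail = FALSE)
  tibble(
    gene_id = rownames(a),
    t = unname(t_stat),
    df = unname(df),
    p_value = unname(p)
  )
}
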