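# Independent brute-force oracles used to check the matrix implementations.

# Triple-loop topological overlap, straight from the formula.
tom_loop_oracle <- function(a) {
  n <- nrow(a)
  k <- numeric(n)
  for (i in seq_len(n)) k[i] <- sum(a[i, -i])
  out <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      }
      out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  out
}

# Random symmetric adjacency in [0,1] with zero diagonal.
random_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  rownames(a) <- colnames(a) <- sprintf("g%02d", seq_len(n))
  a
}

random_expr <- function(n_genes, n_samples, seed, sd = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, 0, sd), n_genes)
  dimnames(m) <- list(sprintf("g%03d", seq_len(n_genes)),
                      sprintf("s%02d", seq_len(n_samples)))
  m
}

# Mean absolute off-diagonal correlation of a gene block.
mean_abs_cor <- function(block) {
  cc <- abs(cor(t(block)))
  mean(cc[upper.tri(cc)])
}

# Study configuration used by the module-recovery checks: five planted
# modules of graded size over a noisy background.
recovery_config <- function(seed, sizes = c(30, 38, 45, 52, 60),
                            n_background = 200, noise_sd = 0.4) {
  mods <- dplyr::bind_rows(lapply(seq_along(sizes), function(i) {
    module_spec(paste0("m", i), sizes[i],
                membership_low = 0.6, membership_high = 0.95)
  }))
  simulation_config(mods, n_background_genes = n_background,
                    noise_sd = noise_sd, rng_seed = seed)
}

# Hand-assembled study whose single module is expressed only during the
# proliferative stage of the test condition (noise elsewhere and in the
# reference condition) -- the condition-and-stage-specific pattern.
stage_specific_study <- function(seed, module_size = 40, n_background = 160,
                                 noise_sd = 0.4) {
  time_points <- c(2, 6, 12, 24, 30, 36, 72, 168)
  reps <- 3
  base <- simulation_config(module_spec("prolif", module_size,
                                        membership_low = 0.7,
                                        membership_high = 0.95),
                            n_background_genes = n_background,
                            time_points = time_points,
                            replicates_per_timepoint = reps,
                            noise_sd = noise_sd, rng_seed = seed)
  study <- simulate_two_condition_dataset(base)
  t_all <- rep(time_points, each = reps)
  prolif <- t_all > 6 & t_all <= 72
  e <- make_eigenprofile(time_points, reps, seed + 13L)
  e[!prolif] <- 0
  e <- (e - mean(e)) / sd(e)
  sp <- module_spec("prolif", module_size, membership_low = 0.7,
                    membership_high = 0.95)
  block <- plant_module(sp, e, noise_sd, seed + 17L)
  idx <- study$truth$module_id == "prolif"
  study$expr$test[idx, ] <- block
  withr::with_seed(seed + 19L, {
    study$expr$reference[idx, ] <- matrix(
      rnorm(sum(idx) * length(e), 0, noise_sd), sum(idx))
  })
  study
}
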