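test_that("density statistic is the mean intramodular connection strength", {
  a <- random_adjacency(12, seed = 1)
  genes <- rownames(a)[2:11]
  # loop oracle
  tot <- 0
  for (i in genes) for (j in genes) if (i != j) tot <- tot + a[i, j]
  expect_equal(density_statistic(a, genes), tot / (10 * 9), tolerance = 1e-12)

  aq <- matrix(1, 5, 5, dimnames = list(paste0("g", 1:5), paste0("g", 1:5)))
  diag(aq) <- 0
  expect_equal(density_statistic(aq, rownames(aq)), 1)
  a0 <- aq * 0
  expect_equal(density_statistic(a0, rownames(a0)), 0)
  expect_error(density_statistic(aq, rownames(aq)[1:2]),
               class = "coexnet_invalid_input")
})

test_that("connectivity statistic compares intramodular connectivity patterns", {
  a <- random_adjacency(10, seed = 2)
  genes <- rownames(a)[1:6]
  # identical networks: perfect preservation
  expect_equal(connectivity_statistic(a, a, genes), 1)

  # hand-sized 4-gene module with printed weights
  w <- matrix(c(0, .5, .2, .1,
                .5, 0, .4, .3,
                .2, .4, 0, .6,
                .1, .3, .6, 0), 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), paste0("g", 1:4)))
  w2 <- matrix(c(0, .1, .7, .2,
                 .1, 0, .2, .5,
                 .7, .2, 0, .3,
                 .2, .5, .3, 0), 4, byrow = TRUE,
               dimnames = list(paste0("g", 1:4), paste0("g", 1:4)))
  k1 <- c(.8, 1.2, 1.2, 1.0)
  k2 <- c(1.0, .8, 1.2, 1.0)
  expect_equal(connectivity_statistic(w, w2, paste0("g", 1:4)), cor(k1, k2),
               tolerance = 1e-12)

  # label shuffling destroys the pattern on average
  a2 <- random_adjacency(50, seed = 20)
  mod <- rownames(a2)[1:30]
  set.seed(3)
  stats <- replicate(100, {
    perm <- sample(mod)
    b <- a2
    b[mod, mod] <- a2[perm, perm]
    connectivity_statistic(a2, b, mod)
  })
  expect_lt(mean(abs(stats)), 0.2)

  # zero-variance connectivity: statistic 0 with a warning
  q <- matrix(0.5, 5, 5, dimnames = list(paste0("g", 1:5), paste0("g", 1:5)))
  diag(q) <- 0
  q2 <- random_adjacency(5, seed = 6)
  dimnames(q2) <- dimnames(q)
  expect_warning(out <- connectivity_statistic(q, q2, rownames(q)[1:5]),
                 "Zero-variance")
  expect_equal(out, 0)
})

test_that("permutation nulls are seeded, sane and flag degenerate spreads", {
  a <- random_adjacency(60, seed = 4)
  b <- random_adjacency(60, seed = 5)
  genes <- rownames(a)[1:10]
  n1 <- permutation_null(a, b, genes, n_perm = 200, seed = 1)
  n1b <- permutation_null(a, b, genes, n_perm = 200, seed = 1)
  expect_identical(n1$draws, n1b$draws)
  n2 <- permutation_null(a, b, genes, n_perm = 200, seed = 2)
  expect_false(identical(n1$draws, n2$draws))
  # two seeds agree within sampling error
  se <- sqrt(n1$sd^2 / 200 + n2$sd^2 / 200)
  expect_lt(abs(n1$mean - n2$mean), 3 * se)

  # constant adjacency: every draw identical
  ac <- matrix(0.4, 30, 30, dimnames = list(paste0("g", 1:30),
                                            paste0("g", 1:30)))
  diag(ac) <- 0
  expect_warning(
    nd <- permutation_null(ac, ac, rownames(ac)[1:5], n_perm = 50, seed = 1,
                           statistic = "density"),
    "Degenerate")
  expect_true(nd$degenerate)
  expect_true(all(nd$draws == 0.4))

  expect_error(permutation_null(a, b, genes, n_perm = 10),
               class = "coexnet_invalid_input")
})

test_that("Zsummary is the mean of the two Z components and classifies correctly", {
  expect_equal(z_summary(19, 19), 19)
  expect_equal(z_summary(0, 0), 0)
  expect_equal(z_summary(4, 10), 7)
  expect_identical(classify_preservation(c(-0.65, 19, 8.6)),
                   c("none", "strong", "weak"))
  # boundaries are weak
  expect_identical(classify_preservation(c(2, 10)), c("weak", "weak"))
  expect_identical(classify_preservation(c(Inf, -Inf)), c("strong", "none"))
})

test_that("preservation separates preserved, weak and condition-specific modules", {
  cfg <- simulation_config(
    dplyr::bind_rows(
      module_spec("pres", 40, membership_low = 0.7, membership_high = 0.95),
      module_spec("wk", 35, membership_low = 0.7, membership_high = 0.95,
                  preservation = "weak"),
      module_spec("spec", 30, membership_low = 0.7, membership_high = 0.95,
                  preservation = "specific_to_test")
    ),
    n_background_genes = 120, noise_sd = 0.3, rng_seed = 41
  )
  st <- simulate_two_condition_dataset(cfg)
  net_t <- build_network(st$expr$test)
  net_r <- build_network(st$expr$reference)
  truth_part <- truth_partition(st)
  pres <- module_preservation(net_t, net_r, truth_part, n_perm = 100, seed = 2)

  z <- setNames(pres$z_summary, pres$module)
  expect_gt(z[["pres"]], 10)
  expect_lt(z[["spec"]], 2)
  expect_true(pres$specific[pres$module == "spec"])
  expect_false(pres$specific[pres$module == "pres"])
  expect_gt(z[["pres"]], z[["wk"]])
  expect_gt(z[["wk"]], z[["spec"]])

  # identical networks: connectivity pattern preserved exactly
  self <- module_preservation(net_t, net_t, truth_part, n_perm = 100, seed = 3)
  expect_equal(self$connectivity_observed, rep(1, 3), tolerance = 1e-12)
  expect_true(all(self$evidence == "strong"))

  # reproducibility of the full result
  pres2 <- module_preservation(net_t, net_r, truth_part, n_perm = 100, seed = 2)
  expect_identical(tidy(pres), tidy(pres2))
})

test_that("raising planted loadings never hurts preservation", {
  z_at <- function(lo) {
    median(vapply(1:5, function(s) {
      cfg <- simulation_config(
        module_spec("m", 30, membership_low = lo,
                    membership_high = min(1, lo + 0.15)),
        n_background_genes = 80, noise_sd = 0.4, rng_seed = 600 + s
      )
      st <- simulate_two_condition_dataset(cfg)
      pres <- module_preservation(
        build_network(st$expr$test), build_network(st$expr$reference),
        truth_partition(st), n_perm = 60, seed = 1)
      pres$z_summary[pres$module == "m"]
    }, numeric(1)))
  }
  zs <- vapply(c(0.3, 0.6, 0.85), z_at, numeric(1))
  expect_true(all(diff(zs) > -1))  # monotone up to permutation noise
  expect_gt(zs[3], zs[1])
})

test_that("stage-wise preservation reproduces stage-restricted module activity", {
  st <- stage_specific_study(seed = 51)
  net <- build_network(st$expr$test)
  part <- truth_partition(st)
  expect_warning(
    sp <- stagewise_preservation(st, part, n_perm = 100, seed = 9),
    "termination"
  )
  wide <- tidy(sp)
  expect_true(all(c("priming", "proliferative") %in% names(wide)))
  row <- wide[wide$module == "prolif", ]
  expect_lt(row$priming, 2)
  expect_gt(row$proliferative, 10)

  # a module whose program varies within every stage is preserved in all
  # evaluable stages
  tp <- c(2, 6, 12, 24, 30, 36, 72, 168)
  e_all <- rep(c(1, -1), length.out = length(tp))[rank(tp)]
  e_all <- rep(e_all, each = 3)
  e_all <- (e_all - mean(e_all)) / sd(e_all)
  st2 <- st
  idx <- st2$truth$module_id == "prolif"
  st2$expr$test[idx, ] <- plant_module(
    module_spec("prolif", sum(idx), membership_low = 0.7,
                membership_high = 0.95), e_all, 0.4, seed = 99)
  sp2 <- suppressWarnings(
    stagewise_preservation(st2, part, n_perm = 100, seed = 10))
  expect_true(all(sp2$evidence[sp2$module == "prolif"] == "strong"))

  # missing stage annotation is reported by sample
  st_bad <- st
  st_bad$samples$stage[which(st_bad$samples$condition == "test")[5]] <- NA
  expect_error(stagewise_preservation(st_bad, part, n_perm = 60, seed = 1),
               class = "coexnet_invalid_input")
})
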