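test_that("gene significance is the absolute Welch t-statistic", {
  a <- random_expr(5, 8, seed = 1)
  gs <- gene_significance(a, a)
  expect_equal(gs$gs, rep(0, 5))
  expect_true(all(gs$p_value == 1))

  # hand-sized vectors against stats::t.test
  x <- matrix(c(1.2, 0.8, 1.5, 2.0, 0.4), 1,
              dimnames = list("g1", paste0("t", 1:5)))
  y <- matrix(c(0.1, -0.3, 0.5, 0.2), 1,
              dimnames = list("g1", paste0("r", 1:4)))
  gs2 <- gene_significance(x, y)
  ref <- t.test(x[1, ], y[1, ])
  expect_equal(gs2$gs, abs(unname(ref$statistic)), tolerance = 1e-12)
  expect_equal(gs2$p_value, ref$p.value, tolerance = 1e-12)

  # power grows with the shift: a 2-sd shift gives large GS
  med_gs <- median(vapply(1:50, function(s) {
    a <- random_expr(1, 12, seed = 3000 + s)
    b <- random_expr(1, 12, seed = 4000 + s) + 2
    gene_significance(b, a)$gs
  }, numeric(1)))
  expect_gt(med_gs, 4)
})

test_that("hub calls pick maximal |kME| with GS and gene-ID tie-breaks", {
  kme <- matrix(c(0.96, 0.9, 0.8, -0.5,
                  0.2, 0.3, 0.1, 0.9), ncol = 2,
                dimnames = list(c("gMCM5", "g2", "g3", "g4"),
                                c("modA", "modB")))
  part <- tibble::tibble(gene_id = rownames(kme),
                         module = c("modA", "modA", "modA", "modB"))
  # modB has < minimum genes for calls? hub_genes works per label as given
  hubs <- hub_genes(part, kme)
  expect_equal(hubs$hub[hubs$module == "modA"], "gMCM5")
  expect_equal(hubs$kme_own[hubs$module == "modA"], 0.96)
  expect_equal(hubs$runner_up[hubs$module == "modA"], "g2")

  # tie on |kME| broken by higher GS
  kme2 <- matrix(c(0.9, 0.9, 0.5), ncol = 1,
                 dimnames = list(c("gA", "gB", "gC"), "m"))
  part2 <- tibble::tibble(gene_id = rownames(kme2), module = "m")
  scores <- tibble::tibble(gene_id = c("gA", "gB", "gC"), gs = c(3, 5, 1),
                           p_value = c(0.1, 0.01, 0.5))
  hub2 <- hub_genes(part2, kme2, scores)
  expect_equal(hub2$hub, "gB")
  # remaining tie falls back to gene ID
  scores_eq <- dplyr::mutate(scores, gs = 3)
  expect_equal(hub_genes(part2, kme2, scores_eq)$hub, "gA")

  # negative kME counts by magnitude
  kme3 <- matrix(c(-0.95, 0.7), ncol = 1,
                 dimnames = list(c("gneg", "gpos"), "m"))
  part3 <- tibble::tibble(gene_id = rownames(kme3), module = "m")
  expect_equal(hub_genes(part3, kme3)$hub, "gneg")
})

test_that("the called hub carries one of the strongest planted loadings", {
  # With 24 samples the kME ranking among the very top loadings is noise
  # dominated, so the reliable guarantee is the top quartile, not the top
  # decile.
  top_quartile <- vapply(1:30, function(s) {
    cfg <- simulation_config(
      module_spec("m", 40, membership_low = 0.4, membership_high = 1),
      n_background_genes = 0, noise_sd = 0.3, rng_seed = 900 + s)
    st <- simulate_two_condition_dataset(cfg)
    part <- tibble::tibble(gene_id = st$truth$gene_id, module = "m")
    eg <- module_eigengenes(st$expr$test, part)
    hub <- hub_genes(part, eg$kme)$hub
    u <- st$loadings
    u$loading[u$gene_id == hub] >= quantile(u$loading, 0.75)
  }, logical(1))
  expect_gte(mean(top_quartile), 0.9)
})

test_that("edge-list export applies a strict threshold and round-trips", {
  w <- matrix(0, 3, 3, dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  w["g1", "g2"] <- w["g2", "g1"] <- 0.2
  w["g1", "g3"] <- w["g3", "g1"] <- 0.4
  w["g2", "g3"] <- w["g3", "g2"] <- 0.9
  out <- export_edge_list(w, threshold = 0.3)
  expect_equal(nrow(out$edges), 2)
  # weights exactly at the threshold are excluded
  w2 <- w
  w2["g1", "g3"] <- w2["g3", "g1"] <- 0.3
  expect_equal(nrow(export_edge_list(w2, threshold = 0.3)$edges), 1)
  all_low <- w * 0 + 0.3
  diag(all_low) <- 0
  expect_equal(nrow(export_edge_list(all_low, threshold = 0.3)$edges), 0)

  # random matrix: edge count equals the loop oracle, and reconstruction
  # reproduces every retained weight
  a <- random_adjacency(15, seed = 8)
  res <- export_edge_list(a, threshold = 0.5)
  cnt <- 0
  for (i in 1:14) for (j in (i + 1):15) if (a[i, j] > 0.5) cnt <- cnt + 1
  expect_equal(nrow(res$edges), cnt)
  rebuilt <- matrix(0, 15, 15, dimnames = dimnames(a))
  for (r in seq_len(nrow(res$edges))) {
    e <- res$edges[r, ]
    rebuilt[e$gene_a, e$gene_b] <- e$weight
    rebuilt[e$gene_b, e$gene_a] <- e$weight
  }
  expect_equal(rebuilt[a > 0.5 & upper.tri(a)], a[a > 0.5 & upper.tri(a)])

  expect_error(export_edge_list(a, threshold = 1),
               class = "coexnet_invalid_input")
})

test_that("expression studies and matrices survive a TSV round trip", {
  st <- simulate_two_condition_dataset(
    simulation_config(module_spec("m", 5), n_background_genes = 4,
                      time_points = c(2, 24, 72), replicates_per_timepoint = 2,
                      rng_seed = 12))
  dir <- withr::local_tempdir()
  write_study(st, dir)
  back <- read_study(file.path(dir, "expr_reference.tsv"),
                     file.path(dir, "expr_test.tsv"),
                     file.path(dir, "samples.tsv"),
                     file.path(dir, "truth.tsv"))
  expect_equal(back$expr$test, st$expr$test, tolerance = 1e-12)
  expect_equal(back$expr$reference, st$expr$reference, tolerance = 1e-12)
  expect_equal(as.data.frame(back$truth), as.data.frame(st$truth))
})

test_that("simulation configs load from YAML and JSON", {
  cfg_list <- list(
    n_background_genes = 10,
    replicates_per_timepoint = 2,
    time_points = c(2, 24),
    noise_sd = 0.5,
    rng_seed = 3,
    modules = list(
      list(module_id = "m1", size = 8),
      list(module_id = "m2", size = 6, preservation = "weak")
    )
  )
  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg_list, yml)
  cfg <- read_simulation_config(yml)
  expect_s3_class(cfg, "simulation_config")
  expect_equal(nrow(cfg$modules), 2)
  expect_equal(cfg$noise_sd, 0.5)
  jsn <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg_list, jsn, auto_unbox = TRUE)
  cfg2 <- read_simulation_config(jsn)
  expect_equal(cfg2$modules, cfg$modules)
})

test_that("the pipeline runs end to end on a planted configuration", {
  config <- list(
    simulation = list(
      n_background_genes = 80,
      noise_sd = 0.35,
      modules = list(
        list(module_id = "p1", size = 30, membership_low = 0.7,
             membership_high = 0.95),
        list(module_id = "p2", size = 30, membership_low = 0.7,
             membership_high = 0.95),
        list(module_id = "wk", size = 30, membership_low = 0.7,
             membership_high = 0.95, preservation = "weak"),
        list(module_id = "sp", size = 30, membership_low = 0.7,
             membership_high = 0.95, preservation = "specific_to_test")
      )
    ),
    modules = list(min_module_size = 20),
    preservation = list(n_perm = 60, run_stagewise = FALSE)
  )
  dir <- withr::local_tempdir()
  res <- run_pipeline(config, dir, seed = 4)
  expect_true(all(file.exists(file.path(
    dir, c("modules.tsv", "preservation.tsv", "gene_scores.tsv", "hubs.tsv",
           "edges.tsv", "nodes.tsv", "run_manifest.json", "log.txt")))))
  expect_equal(nrow(tidy(res$preservation)), 4)
  expect_true(any(res$preservation$specific))
  # the specific module's genes dominate a specific-flagged detected module
  spec_mod <- res$preservation$module[res$preservation$specific][1]
  genes <- tidy(res$partition)
  spec_genes <- genes$gene_id[genes$module == spec_mod]
  expect_gt(mean(startsWith(spec_genes, "sp_")), 0.5)

  # configuration without inputs fails up front
  expect_error(run_pipeline(list(), withr::local_tempdir(), seed = 1),
               class = "coexnet_pipeline_error")
})

test_that("hub calls are stable across reassignment iterations on clean data", {
  cfg <- simulation_config(
    dplyr::bind_rows(
      module_spec("m1", 30, membership_low = 0.8, membership_high = 1),
      module_spec("m2", 40, membership_low = 0.8, membership_high = 1)
    ),
    n_background_genes = 60, noise_sd = 0.15, rng_seed = 71)
  st <- simulate_two_condition_dataset(cfg)
  net <- build_network(st$expr$test)
  diss <- 1 - net$tom
  diag(diss) <- 0
  hc <- hierarchical_cluster(diss)
  part0 <- dynamic_tree_cut(hc)
  part1 <- reassign_by_kme(st$expr$test, part0, max_iter = 1)
  part_full <- reassign_by_kme(st$expr$test, part0, max_iter = 10)
  h1 <- hub_genes(part1, part1$kme)
  h2 <- hub_genes(part_full, part_full$kme)
  expect_equal(sort(h1$hub), sort(h2$hub))
})
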