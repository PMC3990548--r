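#' Run the full two-condition co-expression analysis
#'
#' Orchestrates the end-to-end pipeline: obtain the study (simulate from a
#' generator block or read expression TSVs), optionally reduce the gene set
#' (probe collapse, differential t-test filter, most-connected selection),
#' build one weighted network per condition, detect modules on the
#' test-condition network, quantify how those modules persist in the
#' reference-condition network and in stage-restricted networks, score
#' genes, call hubs and export a thresholded edge list. All tabular results
#' plus a machine-readable manifest are written under `out_dir`.
#'
#' The configuration is a nested list (or path to a YAML/JSON file) with
#' blocks:
#' * `simulation` — [simulation_config()] fields, *or* `expression` with
#'   paths `reference`, `test`, `samples` (and optional `truth`);
#' * `preprocess` — optional `alpha` (t-test filter; off when absent),
#'   optional `k_most_connected`;
#' * `network` — `power` (integer or `"auto"`, default 6), `r2_target`;
#' * `modules` — `deep_split`, `cut_height`, `min_module_size`, `kme_min`;
#' * `preservation` — `n_perm`, `run_stagewise` (default `TRUE`);
#' * `export` — `edge_threshold` (default 0.3), optional `module` to
#'   restrict the edge list to (defaults to all detected modules).
#'
#' @param config Nested list or path to a YAML/JSON config file.
#' @param out_dir Output directory (created).
#' @param seed Master integer seed; overrides any seed in the config.
#' @return Invisibly, a list with every intermediate object (`study`,
#'   `networks`, `partition`, `preservation`, `stage_preservation`,
#'   `scores`, `hubs`, `export`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) {
    stop_coexnet("`config` must be a list or a path to a YAML/JSON file.",
                 "coexnet_invalid_config")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.txt")
  log_line <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"), sprintf(...)),
        file = log_path, append = TRUE)
  }
  stage <- function(name, code) {
    log_line("start %s", name)
    tryCatch(force(code), error = function(e) {
      log_line("FAILED %s: %s", name, conditionMessage(e))
      rlang::abort(sprintf("Pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)),
                   class = "coexnet_pipeline_error", parent = e)
    })
  }

  seed <- as.integer(seed %||% config$simulation$rng_seed %||% 1L)

  study <- stage("input", {
    if (!is.null(config$simulation)) {
      sim_cfg <- config$simulation
      sim_cfg$rng_seed <- seed
      simulate_two_condition_dataset(simulation_config_from_list(sim_cfg))
    } else if (!is.null(config$expression)) {
      ex <- config$expression
      read_study(ex$reference, ex$test, ex$samples, ex$truth)
    } else {
      stop_coexnet("Config needs a `simulation` or `expression` block.",
                   "coexnet_invalid_config")
    }
  })

  pp <- config$preprocess %||% list()
  net_cfg <- config$network %||% list()
  power <- net_cfg$power %||% 6
  study <- stage("preprocess", {
    ref_m <- study$expr$reference
    test_m <- study$expr$test
    if (!is.null(pp$alpha)) {
      keep <- filter_by_ttest(test_m, ref_m, alpha = pp$alpha)$genes
      ref_m <- ref_m[keep, , drop = FALSE]
      test_m <- test_m[keep, , drop = FALSE]
    }
    if (!is.null(pp$k_most_connected)) {
      p_sel <- if (identical(power, "auto")) 6 else power
      keep <- select_most_connected(cbind(test_m, ref_m), power = p_sel,
                                    k_target = pp$k_most_connected)
      keep <- sort(keep)
      ref_m <- ref_m[keep, , drop = FALSE]
      test_m <- test_m[keep, , drop = FALSE]
    }
    study$expr <- list(reference = ref_m, test = test_m)
    study
  })

  networks <- stage("network", {
    list(
      reference = build_network(study$expr$reference, power = power,
                                r2_target = net_cfg$r2_target %||% 0.85),
      test = build_network(study$expr$test, power = power,
                           r2_target = net_cfg$r2_target %||% 0.85)
    )
  })

  mod_cfg <- config$modules %||% list()
  partition <- stage("module_detection", {
    detect_modules(
      study$expr$test, networks$test$tom,
      deep_split = mod_cfg$deep_split %||% 2,
      cut_height = mod_cfg$cut_height %||% 0.995,
      min_module_size = mod_cfg$min_module_size %||% 30,
      kme_min = mod_cfg$kme_min %||% 0.3
    )
  })

  pres_cfg <- config$preservation %||% list()
  n_perm <- pres_cfg$n_perm %||% 200
  preservation <- stage("preservation", {
    # Modules live in the test-condition network; preservation is measured
    # in the reference condition.
    module_preservation(networks$test, networks$reference, partition,
                        n_perm = n_perm, seed = seed)
  })

  stage_pres <- NULL
  if (isTRUE(pres_cfg$run_stagewise %||% TRUE)) {
    stage_pres <- stage("stage_preservation", {
      stagewise_preservation(study, partition, n_perm = n_perm,
                             seed = seed + 1L,
                             power = networks$test$power)
    })
  }

  scores <- stage("gene_significance", {
    gene_significance(study$expr$test, study$expr$reference)
  })
  hubs <- stage("hub_genes", {
    hub_genes(partition, partition$kme, scores)
  })
  exp_cfg <- config$export %||% list()
  edges <- stage("export", {
    export_edge_list(networks$test$adjacency,
                     threshold = exp_cfg$edge_threshold %||% 0.3,
                     partition = partition,
                     module = exp_cfg$module)
  })

  manifest <- stage("write_outputs", {
    labs <- partition$labels
    kme_own <- rep(NA_real_, nrow(labs))
    if (!is.null(partition$kme)) {
      in_mod <- labs$module != "unassigned"
      kme_own[in_mod] <- partition$kme[cbind(
        match(labs$gene_id[in_mod], rownames(partition$kme)),
        match(labs$module[in_mod], colnames(partition$kme)))]
    }
    readr::write_tsv(dplyr::mutate(labs, kme_own = kme_own),
                     file.path(out_dir, "modules.tsv"))
    if (!is.null(partition$eigengenes)) {
      readr::write_tsv(
        as_tibble(t(partition$eigengenes$me), rownames = "module"),
        file.path(out_dir, "eigengenes.tsv"))
    }
    readr::write_tsv(as_tibble(preservation),
                     file.path(out_dir, "preservation.tsv"))
    if (!is.null(stage_pres)) {
      readr::write_tsv(as_tibble(stage_pres),
                       file.path(out_dir, "stage_preservation.tsv"))
    }
    readr::write_tsv(scores, file.path(out_dir, "gene_scores.tsv"))
    readr::write_tsv(hubs, file.path(out_dir, "hubs.tsv"))
    readr::write_tsv(edges$edges, file.path(out_dir, "edges.tsv"))
    readr::write_tsv(edges$nodes, file.path(out_dir, "nodes.tsv"))
    manifest <- list(
      package_version = as.character(utils::packageVersion("coexnet")),
      seed = seed,
      n_genes = nrow(study$expr$test),
      n_samples_per_condition = ncol(study$expr$test),
      power = networks$test$power,
      module_parameters = partition$params,
      n_modules = nrow(module_sizes(partition)),
      n_perm = n_perm,
      edge_threshold = exp_cfg$edge_threshold %||% 0.3,
      outputs = c("modules.tsv", "eigengenes.tsv", "preservation.tsv",
                  if (!is.null(stage_pres)) "stage_preservation.tsv",
                  "gene_scores.tsv", "hubs.tsv", "edges.tsv", "nodes.tsv")
    )
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    manifest
  })
  log_line("done")

  invisible(list(study = study, networks = networks, partition = partition,
                 preservation = preservation,
                 stage_preservation = stage_pres, scores = scores,
                 hubs = hubs, export = edges, manifest = manifest))
}
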