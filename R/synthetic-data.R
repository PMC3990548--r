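#' Specify one planted co-expression module
#'
#' Builds a one-row tibble describing a module to be planted by
#' [simulate_two_condition_dataset()]. Planted genes follow a latent
#' single-factor model: `gene_i = u_i * eigenprofile + noise`, where the
#' loading `u_i` is drawn uniformly between `membership_low` and
#' `membership_high`. The `preservation` field controls how the module
#' appears in the reference condition:
#'
#' * `"preserved"` — same eigenprofile and loadings in both conditions;
#' * `"weak"` — loadings halved in the reference condition;
#' * `"specific_to_test"` — pure independent noise in the reference
#'   condition (the module exists only in the test condition).
#'
#' @param module_id Character label, unique within a configuration.
#' @param size Number of genes (>= 3).
#' @param membership_low,membership_high Loading range, `0 < low <= high <= 1`.
#' @param preservation One of `"preserved"`, `"weak"`, `"specific_to_test"`.
#' @param eigenprofile_seed Integer seed for this module's temporal profile;
#'   `NA` (default) derives one from the configuration seed.
#' @return A one-row tibble; rows from several calls can be combined with
#'   [dplyr::bind_rows()].
#' @seealso [simulation_config()], [simulate_two_condition_dataset()]
#' @export
#' @examples
#' module_spec("m1", size = 30, membership_low = 0.6, membership_high = 0.95)
module_spec <- function(module_id, size,
                        membership_low = 0.6, membership_high = 0.95,
                        preservation = c("preserved", "weak", "specific_to_test"),
                        eigenprofile_seed = NA_integer_) {
  preservation <- match.arg(preservation)
  if (!is.character(module_id) || length(module_id) != 1L || is.na(module_id)) {
    stop_coexnet("`module_id` must be a single string.", "coexnet_invalid_config")
  }
  if (size < 3) {
    stop_coexnet("Module `size` must be at least 3.", "coexnet_invalid_config")
  }
  if (!(membership_low > 0 && membership_low <= membership_high &&
        membership_high <= 1)) {
    stop_coexnet("Memberships must satisfy 0 < low <= high <= 1.",
                 "coexnet_invalid_config")
  }
  tibble(
    module_id = module_id,
    size = as.integer(size),
    membership_low = membership_low,
    membership_high = membership_high,
    preservation = preservation,
    eigenprofile_seed = as.integer(eigenprofile_seed)
  )
}

#' Configure a synthetic two-condition expression study
#'
#' Holds every knob of the generator: the planted modules, the number of
#' independent-noise background genes, the sampling design (time points in
#' hours and replicates per time point) and the residual noise level on the
#' log-ratio scale. Defaults emulate a two-condition liver-regeneration
#' time-course design: eight post-surgery sampling times with three
#' replicates each, expression given as log-ratios to a time-zero control.
#'
#' @param modules Tibble of module rows from [module_spec()].
#' @param n_background_genes Count of unstructured background genes (>= 0).
#' @param time_points Ordered vector of sampling times in hours.
#' @param replicates_per_timepoint Replicates per time point (>= 1).
#' @param noise_sd Residual standard deviation in log-ratio units (> 0).
#' @param rng_seed Integer master seed; the whole study is a deterministic
#'   function of the configuration including this seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(modules,
                              n_background_genes = 200L,
                              time_points = c(2, 6, 12, 24, 30, 36, 72, 168),
                              replicates_per_timepoint = 3L,
                              noise_sd = 0.4,
                              rng_seed = 1L) {
  modules <- as_tibble(modules)
  req <- c("module_id", "size", "membership_low", "membership_high",
           "preservation", "eigenprofile_seed")
  if (!all(req %in% names(modules))) {
    stop_coexnet("`modules` must be built with module_spec().",
                 "coexnet_invalid_config")
  }
  if (anyDuplicated(modules$module_id)) {
    stop_coexnet("Duplicate module_id in `modules`.", "coexnet_invalid_config")
  }
  if (n_background_genes < 0) {
    stop_coexnet("`n_background_genes` must be >= 0.", "coexnet_invalid_config")
  }
  if (replicates_per_timepoint < 1) {
    stop_coexnet("`replicates_per_timepoint` must be >= 1.", "coexnet_invalid_config")
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0) {
    stop_coexnet("`noise_sd` must be > 0.", "coexnet_invalid_config")
  }
  if (length(time_points) < 1 || is.unsorted(time_points)) {
    stop_coexnet("`time_points` must be a non-empty ordered vector of hours.",
                 "coexnet_invalid_config")
  }
  structure(
    list(
      modules = modules,
      n_background_genes = as.integer(n_background_genes),
      time_points = as.numeric(time_points),
      replicates_per_timepoint = as.integer(replicates_per_timepoint),
      noise_sd = noise_sd,
      rng_seed = as.integer(rng_seed)
    ),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat(sprintf("  %d module(s), %d background genes\n",
              nrow(x$modules), x$n_background_genes))
  cat(sprintf("  %d time points x %d replicates, noise_sd = %g, seed = %d\n",
              length(x$time_points), x$replicates_per_timepoint,
              x$noise_sd, x$rng_seed))
  invisible(x)
}

#' Assign regeneration stages to sampling times
#'
#' Maps time points (hours after surgery) to the three canonical
#' liver-regeneration stages: priming (2-6 h), proliferative (6-72 h) and
#' termination (72-168 h). A time point falling on a boundary belongs to the
#' earlier stage, so 6 h is priming and 72 h is proliferative.
#'
#' @param time_h Numeric vector of hours.
#' @param priming_max,proliferative_max Stage boundaries in hours.
#' @return Character vector of stage labels.
#' @export
#' @examples
#' assign_stage(c(2, 6, 12, 72, 168))
assign_stage <- function(time_h, priming_max = 6, proliferative_max = 72) {
  dplyr::case_when(
    time_h <= priming_max ~ "priming",
    time_h <= proliferative_max ~ "proliferative",
    TRUE ~ "termination"
  )
}

#' Generate a smooth standardized temporal eigenprofile
#'
#' Draws a random smooth function of time (quadratic trend plus a low-order
#' Fourier series over rank-spaced time points), evaluates it at every
#' sample (replicates at one time point share the value) and standardizes to
#' mean 0, sd 1 across samples. Deterministic given `seed`.
#'
#' @param time_points Vector of sampling times (hours).
#' @param replicates Replicates per time point.
#' @param seed Integer seed.
#' @return Numeric vector of length `length(time_points) * replicates`.
#' @export
make_eigenprofile <- function(time_points, replicates, seed) {
  n <- length(time_points) * replicates
  if (n < 2) {
    stop_coexnet("An eigenprofile needs at least 2 samples.",
                 "coexnet_invalid_config")
  }
  t_all <- rep(time_points, each = replicates)
  # Rank spacing: the design is dense early and sparse late; rank spacing
  # keeps the profile informative across the whole series.
  ts <- rank(t_all, ties.method = "min") - 1
  ts <- if (max(ts) > 0) ts / max(ts) else ts
  with_seed(seed, {
    a <- rnorm(2)
    b <- rnorm(3)
    cc <- rnorm(3)
    y <- a[1] * ts + a[2] * ts^2
    for (k in 1:3) {
      y <- y + b[k] * sin(2 * pi * k * ts) + cc[k] * cos(2 * pi * k * ts)
    }
    if (sd(y) == 0) y <- y + rnorm(length(y), 0, 1e-6)
    as.numeric((y - mean(y)) / sd(y))
  })
}

#' Plant one co-expression module around an eigenprofile
#'
#' Generates a gene x sample block under the latent single-factor model
#' `gene_i = u_i * eigenprofile + epsilon`, with loadings `u_i` uniform in
#' the spec's membership range and i.i.d. Gaussian noise of standard
#' deviation `noise_sd`. Genes with larger loadings correlate more strongly
#' with the eigenprofile.
#'
#' @param spec One-row tibble from [module_spec()].
#' @param eigenprofile Standardized profile from [make_eigenprofile()].
#' @param noise_sd Residual standard deviation (> 0 unless exactly 0 for the
#'   noise-free limit).
#' @param seed Integer seed.
#' @return Numeric matrix, `spec$size` rows by `length(eigenprofile)` columns.
#' @export
plant_module <- function(spec, eigenprofile, noise_sd, seed) {
  spec <- as_tibble(spec)
  if (nrow(spec) != 1L) {
    stop_coexnet("`spec` must be a single module_spec() row.",
                 "coexnet_invalid_config")
  }
  if (noise_sd < 0) {
    stop_coexnet("`noise_sd` must be >= 0.", "coexnet_invalid_config")
  }
  with_seed(seed, {
    u <- runif(spec$size, spec$membership_low, spec$membership_high)
    block <- u %o% eigenprofile +
      matrix(rnorm(spec$size * length(eigenprofile), 0, noise_sd),
             nrow = spec$size)
    attr(block, "loadings") <- u
    block
  })
}

# Orthogonalize a profile against columns of `basis` and re-standardize.
orthogonalize_profile <- function(e, basis) {
  if (!is.null(basis)) {
    for (j in seq_len(ncol(basis))) {
      bj <- basis[, j]
      e <- e - sum(e * bj) / sum(bj * bj) * bj
    }
  }
  if (sd(e) < 1e-8) {
    stop_coexnet(
      "Too many planted modules for the time grid: eigenprofiles cannot be kept distinct.",
      "coexnet_invalid_config"
    )
  }
  as.numeric((e - mean(e)) / sd(e))
}

#' Simulate a matched two-condition expression study
#'
#' Builds two gene x sample matrices over the same genes and sampling
#' design. The test-condition matrix contains every planted module; the
#' reference-condition matrix re-uses the same eigenprofiles and loadings
#' for `preserved` modules, halves the loadings for `weak` modules, and
#' replaces `specific_to_test` modules with independent noise. Background
#' genes are i.i.d. noise in both conditions. Successive module
#' eigenprofiles are orthogonalized against each other so distinct modules
#' carry distinct temporal programs.
#'
#' @param config A [simulation_config()].
#' @return An object of class `expression_study`: a list with
#'   * `expr` — named list of matrices `reference` and `test`;
#'   * `samples` — tibble (`sample_id`, `condition`, `time_h`, `replicate`,
#'     `stage`);
#'   * `truth` — tibble (`gene_id`, `module_id`), background genes labelled
#'     `"background"`;
#'   * `loadings` — tibble of planted loadings per module gene;
#'   * `config` — the input configuration.
#' @export
#' @examples
#' cfg <- simulation_config(
#'   dplyr::bind_rows(
#'     module_spec("m1", 30),
#'     module_spec("m2", 30, preservation = "specific_to_test")
#'   ),
#'   n_background_genes = 50, rng_seed = 7
#' )
#' study <- simulate_two_condition_dataset(cfg)
#' glance(study)
simulate_two_condition_dataset <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop_coexnet("`config` must be a simulation_config().", "coexnet_invalid_config")
  }
  mods <- config$modules
  n_samp <- length(config$time_points) * config$replicates_per_timepoint
  if (n_samp < 2) {
    stop_coexnet("The design needs at least 2 samples per condition.",
                 "coexnet_invalid_config")
  }

  t_all <- rep(config$time_points, each = config$replicates_per_timepoint)
  rep_all <- rep(seq_len(config$replicates_per_timepoint),
                 times = length(config$time_points))
  samples <- dplyr::bind_rows(lapply(c("reference", "test"), function(cond) {
    tibble(
      sample_id = sprintf("%s_t%03d_r%d", cond, round(t_all), rep_all),
      condition = cond,
      time_h = t_all,
      replicate = rep_all,
      stage = assign_stage(t_all)
    )
  }))

  eig_seeds <- ifelse(
    is.na(mods$eigenprofile_seed),
    (config$rng_seed %% 100000L) * 1000L + seq_len(nrow(mods)),
    mods$eigenprofile_seed
  )

  with_seed(config$rng_seed, {
    basis <- NULL
    ref_blocks <- list()
    test_blocks <- list()
    truth <- list()
    load_tbl <- list()
    for (m in seq_len(nrow(mods))) {
      sp <- mods[m, ]
      e <- make_eigenprofile(config$time_points, config$replicates_per_timepoint,
                             eig_seeds[m])
      e <- orthogonalize_profile(e, basis)
      basis <- cbind(basis, e)
      u <- runif(sp$size, sp$membership_low, sp$membership_high)
      noise_t <- matrix(rnorm(sp$size * n_samp, 0, config$noise_sd), sp$size)
      noise_r <- matrix(rnorm(sp$size * n_samp, 0, config$noise_sd), sp$size)
      test_blocks[[m]] <- u %o% e + noise_t
      ref_blocks[[m]] <- switch(
        sp$preservation,
        preserved = u %o% e + noise_r,
        weak = (u / 2) %o% e + noise_r,
        specific_to_test = noise_r
      )
      ids <- sprintf("%s_g%03d", sp$module_id, seq_len(sp$size))
      truth[[m]] <- tibble(gene_id = ids, module_id = sp$module_id)
      load_tbl[[m]] <- tibble(gene_id = ids, module_id = sp$module_id,
                              loading = u)
    }
    if (config$n_background_genes > 0) {
      nb <- config$n_background_genes
      bg_t <- matrix(rnorm(nb * n_samp, 0, config$noise_sd), nb)
      bg_r <- matrix(rnorm(nb * n_samp, 0, config$noise_sd), nb)
      test_blocks[[length(test_blocks) + 1L]] <- bg_t
      ref_blocks[[length(ref_blocks) + 1L]] <- bg_r
      truth[[length(truth) + 1L]] <- tibble(
        gene_id = sprintf("bg_g%04d", seq_len(nb)),
        module_id = "background"
      )
    }
    truth <- dplyr::bind_rows(truth)
    test_m <- do.call(rbind, test_blocks)
    ref_m <- do.call(rbind, ref_blocks)
    dimnames(test_m) <- list(truth$gene_id,
                             samples$sample_id[samples$condition == "test"])
    dimnames(ref_m) <- list(truth$gene_id,
                            samples$sample_id[samples$condition == "reference"])
    structure(
      list(
        expr = list(reference = ref_m, test = test_m),
        samples = samples,
        truth = truth,
        loadings = dplyr::bind_rows(load_tbl),
        config = config
      ),
      class = "expression_study"
    )
  })
}

#' @export
print.expression_study <- function(x, ...) {
  cat("<expression_study>\n")
  cat(sprintf("  %d genes x %d samples per condition (reference, test)\n",
              nrow(x$expr$test), ncol(x$expr$test)))
  n_mod <- sum(unique(x$truth$module_id) != "background")
  cat(sprintf("  planted modules: %d; background genes: %d\n",
              n_mod, sum(x$truth$module_id == "background")))
  invisible(x)
}

#' @describeIn simulate_two_condition_dataset Long tibble of expression
#'   values joined to sample annotations.
#' @param x An `expression_study`.
#' @param ... Unused.
#' @method tidy expression_study
#' @export
tidy.expression_study <- function(x, ...) {
  purrr::map_dfr(names(x$expr), function(cond) {
    m <- x$expr[[cond]]
    as_tibble(m, rownames = "gene_id") |>
      tidyr::pivot_longer(-"gene_id", names_to = "sample_id",
                          values_to = "value")
  }) |>
    dplyr::left_join(x$samples, by = "sample_id") |>
    dplyr::left_join(x$truth, by = "gene_id")
}

#' @describeIn simulate_two_condition_dataset One-row study summary.
#' @method glance expression_study
#' @export
glance.expression_study <- function(x, ...) {
  tibble(
    n_genes = nrow(x$expr$test),
    n_samples_per_condition = ncol(x$expr$test),
    n_modules = sum(unique(x$truth$module_id) != "background"),
    n_background = sum(x$truth$module_id == "background"),
    noise_sd = x$config$noise_sd,
    rng_seed = x$config$rng_seed
  )
}

#' @describeIn simulate_two_condition_dataset Plot planted module mean
#'   profiles over time by condition.
#' @param object An `expression_study`.
#' @method autoplot expression_study
#' @export
autoplot.expression_study <- function(object, ...) {
  dat <- tidy(object) |>
    dplyr::filter(.data$module_id != "background") |>
    dplyr::group_by(.data$module_id, .data$condition, .data$time_h) |>
    dplyr::summarise(mean_expr = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(.data$time_h, .data$mean_expr,
                                    colour = .data$module_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "time (h, log scale)", y = "mean module expression",
                  colour = "module")
}

#' Ground-truth partition of a synthetic study
#'
#' Converts the generator's truth labels into a partition usable by the
#' module-preservation and eigengene functions: planted modules keep their
#' IDs and background genes become `"unassigned"`.
#'
#' @param study An `expression_study` with truth labels.
#' @return Tibble (`gene_id`, `module`).
#' @export
truth_partition <- function(study) {
  if (is.null(study$truth)) {
    stop_coexnet("The study carries no truth labels.", "coexnet_invalid_input")
  }
  tibble(
    gene_id = study$truth$gene_id,
    module = ifelse(study$truth$module_id == "background", "unassigned",
                    study$truth$module_id)
  )
}
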