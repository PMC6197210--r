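#' Read and validate a run configuration
#'
#' The configuration is a YAML file with optional named blocks `tradeoff`,
#' `demography`, `scenarios`, `maternal`, plus top-level `seed`, `outdir`,
#' `stages` and `plots`. Unknown top-level keys or unknown keys inside a
#' block raise a configuration error naming the offending key. Missing
#' blocks fall back to package defaults.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated list of class `"run_config"`.
#' @seealso [run_pipeline()]; a default configuration ships at
#'   `system.file("extdata", "default_config.yaml", package = "immunodem")`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  known_top <- c("tradeoff", "demography", "scenarios", "maternal",
                 "seed", "outdir", "stages", "plots")
  bad <- setdiff(names(cfg), known_top)
  if (length(bad)) {
    abort(sprintf("unknown configuration key(s): %s",
                  paste(bad, collapse = ", ")))
  }
  known_block <- list(
    tradeoff = c("gamma", "eta", "rho", "mu_b", "mu_d", "i_x",
                 "se_axis_n", "mud_max", "map_i_x", "map_gamma",
                 "map_R_min", "map_R_max", "map_R_n"),
    demography = c("n_ages", "maturity", "i_x", "mu_b", "fertility"),
    scenarios = c("boost_factor", "penalty_c", "pivot", "kinds"),
    maternal = c("self_mean", "self_sd", "nonself_mean", "nonself_sd",
                 "n_ages", "maturity", "i_x", "mu_b", "fertility",
                 "mu_d", "mu_i", "mu_id", "offspring_infection",
                 "memory_discount", "transfer_efficacy",
                 "transfer_spares_muid", "offspring_immunopathology",
                 "n_bins", "n_replicates", "n_blocks", "thresholds"))
  for (blk in intersect(names(cfg), names(known_block))) {
    bad <- setdiff(names(cfg[[blk]]), known_block[[blk]])
    if (length(bad)) {
      abort(sprintf("unknown key(s) in block `%s`: %s", blk,
                    paste(bad, collapse = ", ")))
    }
  }
  stages <- cfg$stages %||% c("tradeoff", "demography", "scenarios", "maternal")
  bad <- setdiff(stages, c("tradeoff", "demography", "scenarios", "maternal"))
  if (length(bad)) {
    abort(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  }
  cfg$stages <- stages
  cfg$seed <- cfg$seed %||% 1L
  cfg$plots <- isTRUE(cfg$plots)
  structure(cfg, class = "run_config")
}

write_json_sidecar <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full experiment pipeline
#'
#' Executes the requested stages in dependency order (`tradeoff`,
#' `demography`, `scenarios`, `maternal`) and writes the canonical CSV/JSON
#' artifacts to `outdir`: the survival landscape and its peaks, the
#' discrimination-response boundary map, the demographic summary of the
#' baseline schedule, the scenario experiment table with per-age curves, and
#' the maternal threshold sweep with its optima. Every run writes a
#' `manifest.json` recording the seed, package version and stages; reruns
#' with the same configuration and seed produce byte-identical CSV output.
#' With `plots = TRUE`, PDF figures (landscape heat map, boundary map,
#' scenario panels, threshold curves) are written alongside.
#'
#' @param config A `"run_config"` from [read_run_config()], or a path to a
#'   YAML file.
#' @param outdir Output directory (created if needed); overrides the config.
#' @param seed Integer seed; overrides the config.
#' @param stages Character subset of stages to run; overrides the config. An
#'   empty character vector writes only the manifest.
#' @param plots Write PDF figures as well; overrides the config.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, outdir = NULL, seed = NULL, stages = NULL,
                         plots = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  outdir <- outdir %||% config$outdir %||% abort("no output directory given.")
  seed <- as.integer(seed %||% config$seed)
  stages <- stages %||% config$stages
  plots <- plots %||% config$plots
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  tr <- modifyList(list(gamma = 4, eta = 0.8, rho = 0.01, mu_b = 1 / 60,
                        mu_d = 1, i_x = 0.5, se_axis_n = 200, mud_max = 5,
                        map_i_x = 0.15, map_gamma = c(1, 6),
                        map_R_min = 0.02, map_R_max = 1, map_R_n = 40),
                   config$tradeoff %||% list())
  dm <- modifyList(list(n_ages = 60, maturity = 15, i_x = 0.15,
                        mu_b = 1 / 60, fertility = 1.272),
                   config$demography %||% list())
  sc <- modifyList(list(boost_factor = 2, penalty_c = 0.5, pivot = NULL,
                        kinds = c("baseline", "infection_boost",
                                  "infection_mortality_boost",
                                  "background_mortality_boost",
                                  "fertility_rising_with_age",
                                  "fertility_sensitivity_penalty",
                                  "infection_early", "infection_late")),
                   config$scenarios %||% list())
  mt_over <- config$maternal %||% list()
  thresholds <- mt_over$thresholds %||% seq(0, 2.4, by = 0.1)
  mt_over$thresholds <- NULL

  params <- immune_params(gamma = tr$gamma, eta = tr$eta, rho = tr$rho,
                          mu_b = tr$mu_b, mu_d = tr$mu_d, i_x = tr$i_x)
  base <- age_schedules(n_ages = dm$n_ages, maturity = dm$maturity,
                        i_x = dm$i_x, mu_b = dm$mu_b,
                        fertility = dm$fertility)

  if ("tradeoff" %in% stages) {
    se_axis <- seq(0.005, (1 - exp(-tr$gamma)) * 0.995,
                   length.out = tr$se_axis_n)
    mud_axis <- seq(0, tr$mud_max, length.out = tr$se_axis_n)
    ls <- survival_landscape(params, se_axis, mud_axis)
    readr::write_csv(ls$grid, file.path(outdir, "landscape.csv"))
    readr::write_csv(ls$peaks, file.path(outdir, "landscape_peaks.csv"))
    write_json_sidecar(
      list(gamma = tr$gamma, eta = tr$eta, rho = tr$rho, mu_b = tr$mu_b,
           i_x = tr$i_x, n_peaks = nrow(ls$peaks)),
      file.path(outdir, "landscape_params.json"))
    bm <- discrimination_response_map(
      tr$map_i_x,
      gamma_axis = seq(tr$map_gamma[1], tr$map_gamma[2], length.out = 11),
      R_axis = exp(seq(log(tr$map_R_min), log(tr$map_R_max),
                       length.out = tr$map_R_n)))
    readr::write_csv(bm$grid, file.path(outdir, "boundary_map.csv"))
    readr::write_csv(estimate_boundary(bm),
                     file.path(outdir, "boundary_curve.csv"))
    if (plots) {
      ggplot2::ggsave(file.path(outdir, "landscape.pdf"), autoplot(ls),
                      width = 6, height = 4)
      ggplot2::ggsave(file.path(outdir, "boundary_map.pdf"), autoplot(bm),
                      width = 6, height = 4)
    }
  }
  if ("demography" %in% stages) {
    opt <- optimize_lifespan_sensitivity(base, params)
    M <- build_leslie(base, params, opt$s_p)
    es <- eigen_summary(M)
    readr::write_csv(tidy(es), file.path(outdir, "demography_ages.csv"))
    write_json_sidecar(list(lambda = es$lambda, optimal_sp = opt$s_p,
                            optimal_se = opt$s_e),
                       file.path(outdir, "demography_summary.json"))
    if (plots) {
      ggplot2::ggsave(file.path(outdir, "demography.pdf"), autoplot(es),
                      width = 7, height = 3)
    }
  }
  if ("scenarios" %in% stages) {
    specs <- map(sc$kinds, function(k) {
      scenario_spec(k, boost_factor = sc$boost_factor,
                    penalty_c = sc$penalty_c, pivot = sc$pivot)
    })
    tab <- run_scenario_table(specs, params, base = base)
    readr::write_csv(tab[, setdiff(names(tab), "ages")],
                     file.path(outdir, "scenario_table.csv"))
    readr::write_csv(tidy(tab), file.path(outdir, "scenario_curves.csv"))
    if (plots) {
      ggplot2::ggsave(file.path(outdir, "scenarios.pdf"), autoplot(tab),
                      width = 9, height = 3.5)
    }
  }
  if ("maternal" %in% stages) {
    mt <- do.call(lineage_config, c(mt_over, list(seed = seed)))
    ot <- optimal_threshold(mt, thresholds = thresholds)
    readr::write_csv(ot$sweep, file.path(outdir, "maternal_sweep.csv"))
    write_json_sidecar(
      list(optima = ot$optima, delta = ot$delta, seed = seed,
           n_replicates = mt$n_replicates),
      file.path(outdir, "maternal_optima.json"))
    if (plots) {
      ggplot2::ggsave(file.path(outdir, "maternal.pdf"), autoplot(ot),
                      width = 6, height = 4)
    }
  }
  manifest <- list(package = "immunodem",
                   version = as.character(packageVersion("immunodem")),
                   seed = seed, stages = as.list(stages))
  write_json_sidecar(manifest, file.path(outdir, "manifest.json"))
  invisible(manifest)
}
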