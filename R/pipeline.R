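# Orchestration: the full synthetic-data -> weights -> assessment ->
# prediction -> validation chain from one config, with a JSON manifest.

#' Default pipeline configuration
#'
#' The stated desk-scale world: a 128 x 128 synthetic region, three
#' assessment years (2010 / 2015 / 2019), PCA weighting with the
#' eigenvalue-greater-than-1 retention rule, Jenks breaks frozen on the
#' baseline year, and a 10-iteration 5 x 5-filter CA-Markov prediction.
#'
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @param out output directory for artifacts.
#' @return a nested config list (YAML-serializable).
#' @export
default_pipeline_config <- function(seed = 42L, out = tempfile("heatrisk_")) {
  list(schema = 1L,
       seed = as.integer(seed),
       out = out,
       scenario = list(shape = c(128L, 128L), n_urban_cores = 3L,
                       urban_radius = 10, mountain_fraction = 0.25,
                       water_fraction = 0.08,
                       years = c(2010L, 2015L, 2019L),
                       trend_per_year = 0.02, noise_sd = 0.15,
                       smoothing_scale = 6),
       weights = list(b_formula = "abs_a_over_sqrt_x",
                      retention = "eigenvalue_gt_1", sample_cap = 50000L),
       breaks = list(mode = "jenks"),
       simulation = list(iterations = 10L, filter_size = 5L),
       write_rasters = TRUE)
}

#' The conventional five-level grading standard
#'
#' The fixed break set `0.2 / 0.4 / 0.5 / 0.58` sometimes used instead of
#' data-driven Jenks breaks (config `breaks: {mode: table}`), for
#' replication against published class maps.
#'
#' @return numeric vector of 4 thresholds.
#' @export
standard_breaks <- function() c(0.2, 0.4, 0.5, 0.58)

load_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_pipeline_config()
  known <- names(base)
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (section in c("scenario", "weights", "breaks", "simulation")) {
    if (!is.null(config[[section]])) {
      bad <- setdiff(names(config[[section]]), names(base[[section]]))
      if (length(bad))
        stop("unknown config key(s) in ", section, ": ",
             paste(bad, collapse = ", "))
      base[[section]][names(config[[section]])] <- config[[section]]
    }
  }
  flat <- setdiff(known, c("scenario", "weights", "breaks", "simulation"))
  base[intersect(names(config), flat)] <- config[intersect(names(config), flat)]
  if (!identical(as.integer(base$schema), 1L))
    stop("unsupported config schema version: ", base$schema)
  base
}

stage_log <- function(stage, t0, ...) {
  message(sprintf("[heatrisk] %-12s %6.2fs  %s", stage,
                  as.numeric(Sys.time()) - t0, paste0(..., collapse = "")))
}

#' Run the full assessment and prediction pipeline
#'
#' Executes the whole chain on the configured synthetic scenario: generate
#' the study region and the multi-year indicator stacks; derive PCA weights
#' (with KMO and Bartlett diagnostics) from the pooled normalized
#' observations; compute the hazard x vulnerability x exposure risk surface
#' per year; classify every year with the break set frozen on the baseline
#' year; account areas, transitions and dominant-factor subzones; hindcast
#' the final year from the first two (CA-Markov) and score it with Cohen's
#' kappa; and predict one period beyond the final year. Artifacts (GeoTIFF
#' rasters, CSV tables, a JSON manifest) are written under `config$out`.
#'
#' @param config a config list (see [default_pipeline_config()]) or the path
#'   to a YAML file with the same structure.
#' @return invisibly, a list with every stage's objects (`region`, `stacks`,
#'   `weights`, `adequacy`, `risk`, `classes`, `proportions`, `transitions`,
#'   `dominance`, `hindcast`, `validation`, `prediction`, `manifest`).
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  cfg <- load_pipeline_config(config)
  out_dir <- cfg$out
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- as.numeric(Sys.time())

  sc <- do.call(synthetic_scenario,
                c(cfg$scenario[setdiff(names(cfg$scenario), "shape")],
                  list(shape = unlist(cfg$scenario$shape),
                       seed = cfg$seed)))
  region <- make_study_region(sc)
  stacks <- lapply(sc$years, function(y) gen_indicator_stack(sc, region, y))
  names(stacks) <- as.character(sc$years)
  if (isTRUE(cfg$write_rasters)) {
    for (y in names(stacks)) {
      ydir <- file.path(out_dir, "data", y)
      dir.create(ydir, recursive = TRUE, showWarnings = FALSE)
      for (nm in names(stacks[[y]]$grids))
        write_raster(stacks[[y]]$grids[[nm]],
                     file.path(ydir, paste0(nm, ".tif")))
    }
    truth <- attr(stacks[[1]], "truth")
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         dataframe = "columns", digits = NA)
  }
  stage_log("simulate", t0, length(stacks), " years on ",
            paste(sc$shape, collapse = "x"))

  normed <- lapply(stacks, normalize_stack)
  obs <- stack_observations(normed, cap = cfg$weights$sample_cap)
  adequacy <- c(kmo_test(obs), bartlett_sphericity(obs)[c("chi2", "df",
                                                          "p_value")])
  w <- pca_weights(obs, canonical_indicators(),
                   retention = cfg$weights$retention,
                   b_formula = cfg$weights$b_formula)
  utils::write.csv(data.frame(indicator = names(w$weights),
                              category = unname(w$category),
                              weight = unname(w$weights)),
                   file.path(out_dir, "weights.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(kmo = adequacy$kmo, bartlett_chi2 = adequacy$chi2,
         bartlett_df = adequacy$df, bartlett_p = adequacy$p_value,
         eigenvalues = w$eigenvalues, contribution = w$contribution,
         cumulative = w$cumulative, n_retained = w$n_retained),
    file.path(out_dir, "weights_report.json"), auto_unbox = TRUE, digits = NA)
  stage_log("weights", t0, "KMO ", round(adequacy$kmo, 3), ", ",
            w$n_retained, " components")

  risk <- lapply(names(normed), function(y) {
    st <- normed[[y]]
    compute_hhr(st$grids[["lst"]],
                composite_score(st, w, "social_vulnerability"),
                composite_score(st, w, "exposure"),
                year = as.integer(y))
  })
  names(risk) <- names(normed)
  breaks <- switch(cfg$breaks$mode,
    jenks = jenks_breaks(risk[[1]]$hhr, 5L),
    table = standard_breaks(),
    file = as.numeric(utils::read.csv(cfg$breaks$file)$threshold),
    stop("unknown breaks mode: ", cfg$breaks$mode))
  classes <- lapply(risk, classify_risk, thresholds = breaks)
  proportions <- lapply(classes, area_proportions)
  transitions <- lapply(seq_len(length(classes) - 1), function(i)
    transition_accounting(classes[[i]], classes[[i + 1]]))
  dominance <- lapply(names(risk), function(y)
    dominant_factor_subzones(risk[[y]], classes[[y]]))
  names(dominance) <- names(risk)
  if (isTRUE(cfg$write_rasters)) {
    for (y in names(risk)) {
      write_raster(risk[[y]]$hhr, file.path(out_dir, paste0("hhr_", y, ".tif")))
      write_raster(classes[[y]]$classes,
                   file.path(out_dir, paste0("classes_", y, ".tif")))
    }
    utils::write.csv(data.frame(level = risk_levels,
                                sapply(proportions, identity)),
                     file.path(out_dir, "proportions.csv"), row.names = FALSE)
  }
  stage_log("assess", t0, "breaks ",
            paste(signif(breaks, 3), collapse = "/"))

  ny <- length(classes)
  sim_cfg <- simulation_config(iterations = cfg$simulation$iterations,
                               filter_size = cfg$simulation$filter_size,
                               seed = cfg$seed + 1L,
                               base_year = sc$years[ny - 1],
                               target_year = sc$years[ny])
  hindcast <- predict_risk(classes[[ny - 2]], classes[[ny - 1]], sim_cfg)
  validation <- kappa_agreement(hindcast, classes[[ny]])
  stage_log("validate", t0, "hindcast kappa ",
            round(validation$kappa, 3))

  period <- sc$years[ny] - sc$years[ny - 1]
  fut_cfg <- simulation_config(iterations = cfg$simulation$iterations,
                               filter_size = cfg$simulation$filter_size,
                               seed = cfg$seed + 2L,
                               base_year = sc$years[ny],
                               target_year = sc$years[ny] + period)
  prediction <- predict_risk(classes[[ny - 1]], classes[[ny]], fut_cfg)
  if (isTRUE(cfg$write_rasters))
    write_raster(prediction$classes,
                 file.path(out_dir, paste0("classes_",
                                           fut_cfg$target_year, ".tif")))
  stage_log("predict", t0, "target year ", fut_cfg$target_year)

  manifest <- list(
    package_version = as.character(utils::packageVersion("heatrisk")),
    r_version = R.version.string,
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "out")],
    breaks = as.numeric(breaks),
    kmo = adequacy$kmo,
    proportions = lapply(proportions, as.list),
    prediction_proportions = as.list(area_proportions(prediction)),
    hindcast_kappa = validation$kappa,
    hindcast_p = validation$p_value)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(config = cfg, scenario = sc, region = region,
                 stacks = stacks, weights = w, adequacy = adequacy,
                 risk = risk, breaks = breaks, classes = classes,
                 proportions = proportions, transitions = transitions,
                 dominance = dominance, hindcast = hindcast,
                 validation = validation, prediction = prediction,
                 manifest = manifest))
}
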