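pipeline_defaults <- function() {
  list(
    world = list(lat_min = 20, lat_max = 45, lon_min = 100, lon_max = 120,
                 resolution_arcmin = 60, noise_sd_c = 1.5,
                 precip_noise_sd = 0.2),
    scenarios = list(list(label = "warm2", delta_t_c = 2, precip_factor = 1)),
    species = list(n_occurrences = 200),
    microclimate = list(),
    ectotherm = list(nest_depth_m = 0.05),
    embryo = list(success_threshold = 0.5),
    sdm = list(learners = c("GLM", "GBM", "MAXENT", "RF", "SVM"),
               replicates = 5, train_fraction = 0.7, tss_cutoff = 0.6,
               pa_multiplier = 10, thin_arcmin = 10),
    attribution = list(class_threshold = 0.01, importance_repeats = 5),
    seed = 1
  )
}

config_domains <- function() {
  list(c("sdm", "train_fraction", 0, 1), c("sdm", "tss_cutoff", 0, 1),
       c("sdm", "replicates", 1, Inf), c("sdm", "pa_multiplier", 1, Inf),
       c("sdm", "thin_arcmin", 0, Inf),
       c("attribution", "class_threshold", 0, 1),
       c("embryo", "success_threshold", 0, 1))
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration, rejects unknown keys (naming them), checks
#' numeric settings against their documented domains, and injects defaults
#' for everything unspecified: 70% training fraction, 5 replicates, TSS
#' cutoff 0.6, 10 arc-minute thinning, contribution threshold 0.01.
#'
#' @param path YAML file path, or a list already in config shape.
#' @return validated config list of class \code{pipeline_config}.
#' @export
load_and_validate_config <- function(path) {
  user <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(user)) user <- list()
  defaults <- pipeline_defaults()
  unknown_top <- setdiff(names(user), names(defaults))
  if (length(unknown_top))
    stop("config: unknown key(s): ", paste(unknown_top, collapse = ", "))
  for (sec in intersect(names(user), names(defaults))) {
    if (sec %in% c("scenarios", "seed")) next
    bad <- setdiff(names(user[[sec]]), names(defaults[[sec]]))
    # microclimate / world sections also admit their module settings
    if (sec == "microclimate")
      bad <- setdiff(bad, names(microclimate_config()))
    if (sec == "world")
      bad <- setdiff(bad, names(synthetic_world_params()))
    if (length(bad))
      stop("config: unknown key(s) in '", sec, "': ",
           paste(bad, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, user)
  # scenarios are an unnamed list: replace wholesale, never merge
  if (!is.null(user$scenarios)) cfg$scenarios <- user$scenarios
  for (d in config_domains()) {
    v <- cfg[[d[[1]]]][[d[[2]]]]
    lo <- as.numeric(d[[3]]); hi <- as.numeric(d[[4]])
    if (!is.numeric(v) || v < lo || v > hi)
      stop(sprintf("config: %s.%s = %s outside [%s, %s]",
                   d[[1]], d[[2]], format(v), format(lo), format(hi)))
  }
  for (sc in cfg$scenarios)
    if (!is.null(sc$precip_factor) && sc$precip_factor <= 0)
      stop("config: scenario '", sc$label, "' has precip_factor <= 0")
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

default_dev_table <- function() {
  # synthetic incubation experiment consistent with a ~600 degree-day,
  # t0 = 12 degC development curve and a 24-32 degC viability plateau
  incubation_table(
    temperature_c = c(21, 24, 27, 30, 33),
    incubation_days = round(600 / (c(21, 24, 27, 30, 33) - 12), 1),
    hatching_success = c(0.3, 0.85, 0.95, 0.9, 0.4))
}

default_virtual_species <- function(traits, stack) {
  rng <- function(nm) range(stack$layers[[nm]][stack$mask])
  b1 <- rng("bio1"); wl <- rng("max_wl")
  # responses are deliberately selective so the occupied niche is a small,
  # recoverable fraction of the climate space
  virtual_species(
    traits,
    response_spec = list(
      bio1 = list(type = "gaussian", optimum = mean(b1),
                  breadth = diff(b1) / 14),
      max_wl = list(type = "logistic", midpoint = mean(wl),
                    scale = diff(wl) / 25, sign = -1)),
    combine_rule = "product")
}

#' Run the full climate-vulnerability pipeline
#'
#' Executes the stage chain synthetic world -> microclimate -> ectotherm ->
#' embryo -> hybrid SDM -> attribution for one (virtual) species and a set
#' of warming scenarios, writing every artefact as CSV with a JSON manifest
#' of file hashes, seeds and versions. Deterministic stages are bit-identical
#' across reruns of the same config and seed.
#'
#' @param config a \code{\link{load_and_validate_config}} result (or a list
#'   / YAML path accepted by it).
#' @param out_dir output directory (created if missing); NULL for no files.
#' @param traits a \code{\link{species_traits}} (defaults to the package's
#'   reference lizard).
#' @param resume if TRUE, existing artefact files in \code{out_dir} are left
#'   in place and only missing ones are rewritten.
#' @param quiet suppress per-stage messages.
#' @return list with the world grids, biophysical layer tables, stacks,
#'   ensemble, suitability maps, range-change summaries, contribution
#'   tables, importances and the manifest.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL,
                         traits = species_traits(), resume = FALSE,
                         quiet = TRUE) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    load_and_validate_config(config)
  seed <- as.integer(cfg$seed)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  artefacts <- character(0)
  emit <- function(writer, obj, name) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, name)
    if (!(resume && file.exists(path))) writer(obj, path)
    artefacts <<- c(artefacts, path)
  }
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  ## stage 1: synthetic world ------------------------------------------
  say("[world] generating grid (seed %d)", seed)
  wp <- cfg$world
  extent <- wp[c("lat_min", "lat_max", "lon_min", "lon_max")]
  params <- wp[setdiff(names(wp),
                       c("lat_min", "lat_max", "lon_min", "lon_max",
                         "resolution_arcmin"))]
  current <- generate_monthly_climate(extent, wp$resolution_arcmin, params,
                                      seed = seed)
  emit(write_climate_csv, current, "climate_current.csv")
  scen_grids <- list()
  for (sc in cfg$scenarios) {
    s <- warming_scenario(sc$delta_t_c %||% 0, sc$precip_factor %||% 1,
                          sc$label %||% "scenario")
    scen_grids[[s$label]] <- apply_warming_scenario(current, s)
    emit(write_climate_csv, scen_grids[[s$label]],
         paste0("climate_", s$label, ".csv"))
  }

  ## stage 2-4: microclimate + ectotherm + embryo -----------------------
  mc_cfg <- do.call(microclimate_config, cfg$microclimate)
  dev_model <- fit_development_model(default_dev_table(),
                                     cfg$embryo$success_threshold)
  say("[ecto] biophysical layers, %d cells x %d climates",
      n_cells(current), 1L + length(scen_grids))
  layers_for <- function(grid) compute_biophysical_layers(
    grid, traits, dev_model, mc_cfg,
    nest_depth_m = cfg$ectotherm$nest_depth_m)
  bio_current <- layers_for(current)
  emit(write_ecto_summary_csv, bio_current, "ecto_current.csv")
  bio_scen <- lapply(scen_grids, layers_for)
  for (nm in names(bio_scen))
    emit(write_ecto_summary_csv, bio_scen[[nm]],
         paste0("ecto_", nm, ".csv"))

  stack_current <- hybrid_stack(current, bio_current)
  stacks_scen <- Map(hybrid_stack, scen_grids, bio_scen)

  ## stage 5: occurrences + hybrid SDM ----------------------------------
  vsp <- default_virtual_species(traits, stack_current)
  truth <- true_suitability(vsp, stack_current$layers)
  truth[!stack_current$mask] <- 0
  occ <- sample_occurrences(vsp, current, truth,
                            n = cfg$species$n_occurrences, seed = seed + 1L)
  occ_thin <- thin_occurrences(occ, cfg$sdm$thin_arcmin, seed = seed + 2L)
  emit(write_occurrences_csv, occ_thin, "occurrences_thinned.csv")
  say("[sdm] %d -> %d records after thinning; training ensemble",
      nrow(occ$records), nrow(occ_thin$records))
  ensemble <- train_ensemble(stack_current, occ_thin, cfg$sdm,
                             seed = seed + 3L)
  emit(function(o, p) utils::write.csv(o, p, row.names = FALSE),
       ensemble$evaluation, "evaluation.csv")
  suit_current <- predict_suitability(ensemble, stack_current)
  emit(write_map_csv, suit_current, "suitability_current.csv")
  suit_scen <- lapply(stacks_scen, function(s) predict_suitability(ensemble, s))
  range_change <- list()
  for (nm in names(suit_scen)) {
    emit(write_map_csv, suit_scen[[nm]], paste0("suitability_", nm, ".csv"))
    range_change[[nm]] <- binarize_and_area_change(suit_current,
                                                   suit_scen[[nm]])
  }

  ## stage 6: attribution ------------------------------------------------
  say("[attr] response-curve contributions and importances")
  contributions <- lapply(names(stacks_scen), function(nm)
    variable_contribution(ensemble, stack_current, stacks_scen[[nm]],
                          threshold = cfg$attribution$class_threshold))
  names(contributions) <- names(stacks_scen)
  for (nm in names(contributions))
    emit(write_contribution_csv, contributions[[nm]],
         paste0("contribution_", nm, ".csv"))
  X_eval <- stack_matrix(stack_current, ensemble$design$cells)
  importance <- permutation_importance(
    ensemble, X_eval, ensemble$design$y,
    repeats = cfg$attribution$importance_repeats, seed = seed + 4L)

  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    seed = seed,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("ectoclim")),
    elapsed_s = round(proc.time()[["elapsed"]] - t0, 2),
    files = if (length(artefacts))
      as.list(tools::md5sum(artefacts)) else list())
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)

  list(config = cfg, grid_current = current, grids_scenario = scen_grids,
       bio_current = bio_current, bio_scenario = bio_scen,
       stack_current = stack_current, stacks_scenario = stacks_scen,
       truth = truth, occurrences = occ_thin, ensemble = ensemble,
       suitability_current = suit_current, suitability_scenario = suit_scen,
       range_change = range_change, contributions = contributions,
       importance = importance, manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
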