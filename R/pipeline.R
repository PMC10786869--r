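# Config-driven orchestration: synth/ingest -> bias-correct -> downscale ->
# ensemble -> evaluate -> uncertainty. Stages communicate via files so each
# is independently re-runnable; outputs carry the config hash and package
# version as provenance.

.known_keys <- c("variable", "depth_label", "scenarios", "reference", "members",
                 "observations", "training_window", "present_period",
                 "mid_period", "long_period", "n_quantiles", "mode",
                 "per_month", "h_tol", "v_tol", "out_dir", "seed", "synthetic",
                 "stages", "product_depth")

.known_variables <- c("temperature", "salinity", "ph", "oxygen", "chlorophyll")
.known_scenarios <- c("ssp126", "ssp245", "ssp585", "historical")

#' Validate and default a pipeline configuration
#'
#' Accepts a YAML file path, YAML text, or a list; checks every key against
#' the schema (unknown keys are rejected), fills defaults (assessment periods
#' 1995-2014 / 2041-2060 / 2081-2100, 100 quantiles, per-month transforms,
#' additive mode for temperature/salinity/pH and multiplicative for oxygen
#' and chlorophyll) and cross-validates periods.
#'
#' @param raw path to a YAML file, YAML text, or a named list.
#' @return a validated config list of class \code{pipeline_config}.
#' @export
validate_config <- function(raw) {
  cfg <- raw
  if (is.character(raw) && length(raw) == 1) {
    cfg <- if (file.exists(raw)) yaml::read_yaml(raw) else yaml::yaml.load(raw)
  }
  if (!is.list(cfg)) stop_validation("config must be a YAML document or list")
  bad <- setdiff(names(cfg), .known_keys)
  if (length(bad)) stop_validation("unknown config keys: ", paste(bad, collapse = ", "))
  errs <- character(0)
  cfg$variable <- cfg$variable %||% "temperature"
  if (!cfg$variable %in% .known_variables)
    errs <- c(errs, paste0("unknown variable: ", cfg$variable))
  cfg$depth_label <- cfg$depth_label %||% "surface"
  cfg$scenarios <- unlist(cfg$scenarios %||% c("ssp126", "ssp245", "ssp585"))
  if (!all(cfg$scenarios %in% .known_scenarios))
    errs <- c(errs, paste0("unknown scenario label: ",
                           paste(setdiff(cfg$scenarios, .known_scenarios), collapse = ", ")))
  cfg$present_period <- as.numeric(unlist(cfg$present_period %||% c(1995, 2014)))
  cfg$mid_period <- as.numeric(unlist(cfg$mid_period %||% c(2041, 2060)))
  cfg$long_period <- as.numeric(unlist(cfg$long_period %||% c(2081, 2100)))
  for (p in c("present_period", "mid_period", "long_period"))
    if (length(cfg[[p]]) != 2 || cfg[[p]][1] > cfg[[p]][2])
      errs <- c(errs, paste0(p, " must be c(first_year, last_year)"))
  if (cfg$present_period[2] >= cfg$mid_period[1] ||
      cfg$mid_period[2] >= cfg$long_period[1])
    errs <- c(errs, "assessment periods must not overlap and must be ordered")
  cfg$n_quantiles <- cfg$n_quantiles %||% 100
  if (cfg$n_quantiles < 2) errs <- c(errs, "n_quantiles must be >= 2")
  cfg$mode <- cfg$mode %||%
    if (cfg$variable %in% c("oxygen", "chlorophyll")) "multiplicative" else "additive"
  if (!cfg$mode %in% c("additive", "multiplicative"))
    errs <- c(errs, "mode must be additive or multiplicative")
  cfg$per_month <- isTRUE(cfg$per_month %||% TRUE)
  cfg$h_tol <- cfg$h_tol %||% 100
  cfg$v_tol <- cfg$v_tol %||% 1
  cfg$product_depth <- cfg$product_depth %||% 5
  cfg$seed <- cfg$seed %||% 1
  cfg$out_dir <- cfg$out_dir %||% "marindown_out"
  cfg$training_window <- if (!is.null(cfg$training_window))
    as.numeric(unlist(cfg$training_window)) else NULL
  if (!is.null(cfg$training_window) && cfg$training_window[1] > cfg$training_window[2])
    errs <- c(errs, "training_window must be c(first_year, last_year)")
  if (is.null(cfg$synthetic) && is.null(cfg$members))
    errs <- c(errs, "either a synthetic block or a members file list is required")
  if (length(errs)) stop_validation(paste(errs, collapse = "; "))
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(cfg)[order(names(cfg))]), tmp)
  unname(tools::md5sum(tmp))
}

.log_stage <- function(stage, msg, quiet) {
  if (!quiet) message(sprintf("[%s] %s", stage, msg))
}

# Build inputs: either generate the synthetic suite or read NetCDF files.
.pipeline_inputs <- function(cfg, quiet) {
  if (!is.null(cfg$synthetic)) {
    syn <- cfg$synthetic
    sc_args <- syn[setdiff(names(syn), c("n_models", "realizations_per_model",
                                         "n_observations", "obs_noise_sd"))]
    sc_args$variable <- cfg$variable
    sc_args$seed <- sc_args$seed %||% cfg$seed
    scfg <- do.call(synth_config, sc_args)
    trends <- scfg$scenario_trends[names(scfg$scenario_trends) %in% cfg$scenarios]
    if (!length(trends)) stop_validation("no scenario trends for requested scenarios")
    suite <- make_ensemble_suite(scfg, n_models = syn$n_models %||% 2,
                                 realizations_per_model = syn$realizations_per_model %||% 2,
                                 scenarios = names(trends))
    obs <- NULL
    if (!is.null(syn$n_observations))
      obs <- make_observations(suite$reference, syn$n_observations,
                               noise_sd = syn$obs_noise_sd %||% 0.1,
                               depth = cfg$product_depth, seed = cfg$seed + 1)
    .log_stage("prepare", sprintf("generated synthetic suite: %d members, %d scenarios",
                                  length(suite$members), length(trends)), quiet)
    return(list(reference = suite$reference, members = suite$members, obs = obs,
                truth = suite$truth))
  }
  reference <- read_field(cfg$reference)
  members <- list()
  for (m in cfg$members) {
    fld <- read_field(m$path)
    attr(fld, "model") <- m$model %||% "model"
    attr(fld, "realization") <- m$realization %||% "r1"
    attr(fld, "scenario") <- m$scenario
    members[[paste(m$model, m$realization, m$scenario, sep = "_")]] <- fld
  }
  obs <- if (!is.null(cfg$observations)) read_observations(cfg$observations) else NULL
  list(reference = reference, members = members, obs = obs, truth = NULL)
}

#' Run the downscaling pipeline
#'
#' Executes, per member: coarse-resolution DQM bias correction against the
#' coarsened reference, then statistical downscaling onto the fine reference
#' grid; then the equal-weight ensemble product per scenario; then skill
#' evaluation against the reference climatology (and point observations when
#' provided); then the mid- and long-term uncertainty assessment. All outputs
#' are written under \code{config$out_dir} with the config hash and package
#' version as provenance, and the run is deterministic given the config.
#'
#' @param config a \code{\link{validate_config}} result (or anything it
#'   accepts).
#' @param stages character subset of
#'   \code{c("downscale", "ensemble", "evaluate", "uncertainty")}; later
#'   stages read the earlier stages' files, so a subset can resume or
#'   re-evaluate precomputed products.
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with the output directory, product paths, the
#'   skill table and the change assessments.
#' @export
run_pipeline <- function(config, stages = c("downscale", "ensemble",
                                            "evaluate", "uncertainty"),
                         quiet = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("downscaled", "products", "evaluation", "uncertainty"))
    dir.create(file.path(cfg$out_dir, d), showWarnings = FALSE)
  hash <- config_hash(cfg)
  prov <- list(config_hash = hash,
               software = paste0("marindown ", as.character(utils::packageVersion("marindown"))))
  inputs <- NULL
  member_paths <- function() list.files(file.path(cfg$out_dir, "downscaled"),
                                        full.names = TRUE, pattern = "\\.nc$")
  if ("downscale" %in% stages) {
    t0 <- Sys.time()
    inputs <- .pipeline_inputs(cfg, quiet)
    ref <- inputs$reference
    m1 <- inputs$members[[1]]
    fac <- length(ref$grid$lats) / length(m1$grid$lats)
    if (fac != round(fac))
      stop_validation("reference grid is not an integer multiple of the member grid")
    ref_coarse <- coarsen(ref, as.integer(round(fac)))
    tw <- cfg$training_window %||%
      c(max(min(year_of(ref$times)), min(year_of(m1$times))),
        min(max(year_of(ref$times)), max(year_of(m1$times))))
    for (nm in names(inputs$members)) {
      mem <- inputs$members[[nm]]
      bc <- bias_correct(mem, ref_coarse, n_quantiles = cfg$n_quantiles,
                         mode = cfg$mode, per_month = cfg$per_month,
                         training_window = tw,
                         clamp_zero = cfg$variable %in% c("oxygen", "chlorophyll"))
      ds <- downscale(bc, ref, n_quantiles = cfg$n_quantiles, mode = cfg$mode,
                      per_month = cfg$per_month, training_window = tw,
                      clamp_zero = cfg$variable %in% c("oxygen", "chlorophyll"))
      write_field(ds, file.path(cfg$out_dir, "downscaled", paste0(nm, ".nc")),
                  global_attrs = c(prov, list(member = nm,
                                              scenario = attr(mem, "scenario") %||% "unknown",
                                              training_window = paste(tw, collapse = "-"))))
    }
    # reference and observations are inputs to later stages; persist them
    write_field(ref, file.path(cfg$out_dir, "reference.nc"), global_attrs = prov)
    if (!is.null(inputs$obs))
      write_observations(inputs$obs, file.path(cfg$out_dir, "observations.tsv"))
    .log_stage("downscale", sprintf("%d members downscaled in %.1f s",
                                    length(inputs$members),
                                    as.numeric(Sys.time() - t0, units = "secs")), quiet)
  }
  scen_of <- function(path) {
    got <- read_fields_nc(path)
    attr(got, "global_attrs")$scenario %||% "unknown"
  }
  product_path <- function(sc)
    file.path(cfg$out_dir, "products",
              sprintf("%s_%s_%s.nc", cfg$variable, cfg$depth_label, sc))
  if ("ensemble" %in% stages) {
    t0 <- Sys.time()
    paths <- member_paths()
    if (!length(paths)) stop_validation("no downscaled members found; run the downscale stage first")
    scen <- vapply(paths, scen_of, character(1))
    for (sc in unique(scen)) {
      flds <- lapply(paths[scen == sc], read_field)
      ids <- sub("\\.nc$", "", basename(paths[scen == sc]))
      st <- ensemble_statistics(flds, member_ids = ids)
      write_product(st, product_path(sc), provenance = prov)
    }
    .log_stage("ensemble", sprintf("%d scenario products written in %.1f s",
                                   length(unique(scen)),
                                   as.numeric(Sys.time() - t0, units = "secs")), quiet)
  }
  skill <- NULL
  if ("evaluate" %in% stages) {
    ref <- read_field(file.path(cfg$out_dir, "reference.nc"))
    paths <- list.files(file.path(cfg$out_dir, "products"), full.names = TRUE,
                        pattern = "\\.nc$")
    if (!length(paths)) stop_validation("no products found; run the ensemble stage first")
    st <- read_product(paths[1])
    tw <- cfg$training_window %||% range(year_of(ref$times))
    skill <- spatial_skill(st$mean, ref, period = tw)
    utils::write.table(as.data.frame(skill),
                       file.path(cfg$out_dir, "evaluation", "skill.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    obs_path <- file.path(cfg$out_dir, "observations.tsv")
    if (file.exists(obs_path)) {
      obs <- read_observations(obs_path)
      pairs <- match_observations(obs, st$mean, product_depth = cfg$product_depth,
                                  period = tw, h_tol = cfg$h_tol, v_tol = cfg$v_tol)
      if (nrow(pairs)) {
        ds <- distribution_summary(pairs)
        utils::write.table(
          data.frame(bin_lo = utils::head(ds$value_breaks, -1),
                     bin_hi = ds$value_breaks[-1],
                     obs_freq = ds$obs_freq, model_freq = ds$model_freq),
          file.path(cfg$out_dir, "evaluation", "distribution.tsv"),
          sep = "\t", row.names = FALSE, quote = FALSE)
        cat(sprintf("matched_pairs\t%d\noverlap\t%.6f\n", nrow(pairs), ds$overlap),
            file = file.path(cfg$out_dir, "evaluation", "matching.txt"))
      }
    }
    .log_stage("evaluate", sprintf("season-mean LSE %.3f",
                                   skill$lse[skill$season == "mean"]), quiet)
  }
  assessments <- NULL
  if ("uncertainty" %in% stages) {
    paths <- member_paths()
    if (!length(paths)) stop_validation("no downscaled members found")
    scen <- vapply(paths, scen_of, character(1))
    members_by_scenario <- lapply(split(paths, scen), function(pp)
      lapply(pp, read_field))
    if (length(members_by_scenario) == 1)
      warning("single scenario available: scenario uncertainty range will be 0")
    assessments <- list()
    for (hz in list(mid = cfg$mid_period, long = cfg$long_period)) {
      nm <- sprintf("%d-%d", hz[1], hz[2])
      ca <- uncertainty_assessment(members_by_scenario, future_period = hz,
                                   present_period = cfg$present_period)
      assessments[[nm]] <- ca
      write_fields_nc(list(change = ca$change, scenario_unc = ca$scenario_unc,
                           model_unc = ca$model_unc, internal_var = ca$internal_var,
                           ratio_scenario = ca$ratio_scenario,
                           ratio_model = ca$ratio_model,
                           ratio_internal = ca$ratio_internal),
                      file.path(cfg$out_dir, "uncertainty",
                                sprintf("change_%s.nc", nm)),
                      global_attrs = prov)
    }
    # basin-mean series over the whole domain from the first product
    paths_p <- list.files(file.path(cfg$out_dir, "products"), full.names = TRUE,
                          pattern = "\\.nc$")
    if (length(paths_p)) {
      st <- read_product(paths_p[1])
      bs <- basin_series(st, st$mean$grid$mask)
      utils::write.table(as.data.frame(bs),
                         file.path(cfg$out_dir, "uncertainty", "basin_series.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    .log_stage("uncertainty", "change maps and ratios written", quiet)
  }
  invisible(list(out_dir = cfg$out_dir, config_hash = hash, skill = skill,
                 assessments = assessments,
                 products = list.files(file.path(cfg$out_dir, "products"),
                                       full.names = TRUE)))
}
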