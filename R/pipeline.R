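#' Reference summary of published per-stratum stock changes
#'
#' The packaged table of published mean SOC stock changes per direction and
#' stratum (with bootstrap CI half-widths) for the six land-use-change
#' directions between cropland, grassland and forest in Germany, including
#' the printed "Mineral soil" and "Overall" rows.
#'
#' @return data.frame `direction, stratum, mean, ci_half`.
#' @export
reference_table <- function() {
  read.csv(system.file("extdata", "table1_stratum_means.csv",
                       package = "reciproSOC"), stringsAsFactors = FALSE)
}

#' Check the summary-table aggregation identities
#'
#' Feeds the published per-stratum means through [summarize_from_means()] and
#' compares the recomputed mineral and overall totals (and subsoil share of
#' the absolute change) against the published total rows for all six
#' directions.
#'
#' @return data.frame per direction with computed and published totals and
#'   the absolute differences.
#' @export
check_table1 <- function() {
  tab <- reference_table()
  dirs <- unique(tab$direction)
  rows <- lapply(dirs, function(dn) {
    t <- tab[tab$direction == dn, ]
    means <- setNames(as.list(t$mean), t$stratum)
    s <- summarize_from_means(means[setdiff(t$stratum, c("Overall", "Mineral soil"))],
                              direction = dn)
    data.frame(
      direction = dn,
      mineral_computed = s$mineral_total,
      mineral_published = t$mean[t$stratum == "Mineral soil"],
      overall_computed = s$overall_total,
      overall_published = t$mean[t$stratum == "Overall"],
      subsoil_share_pct = s$subsoil_share_pct,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$mineral_diff <- abs(out$mineral_computed - out$mineral_published)
  out$overall_diff <- abs(out$overall_computed - out$overall_published)
  out
}

#' Scale a subsoil stock change over a land-conversion area
#'
#' The back-of-envelope national estimate: converted area times the summed
#' mean subsoil (30-60 plus 60-90 cm) stock change per hectare, in millions
#' of tonnes of C. With the published cropland-to-grassland subsoil means
#' (7.7 + 4.5 Mg C ha-1) and the 1.4 million ha of German cropland-to-
#' grassland conversion, this gives approximately 17 million tonnes.
#'
#' @param area_ha Converted area in hectares.
#' @param subsoil_means Mean stock changes (Mg C ha-1) for the two subsoil
#'   strata; defaults to the published cropland-to-grassland values.
#' @return Millions of tonnes of C.
#' @export
upscale_subsoil <- function(area_ha = 1.4e6, subsoil_means = NULL) {
  if (is.null(subsoil_means)) {
    tab <- reference_table()
    t <- tab[tab$direction == "cropland to grassland", ]
    subsoil_means <- t$mean[t$stratum %in% c("30-60 cm", "60-90 cm")]
  }
  area_ha * sum(subsoil_means) / 1e6
}

#' Pipeline configuration
#'
#' @param seed Master seed for all randomness.
#' @param generator `NULL`, or a list of [generator_config()] arguments to
#'   run on synthetic data.
#' @param input_csv,schema Alternatively, an inventory CSV (+ column-mapping
#'   YAML) to read.
#' @param directions List of `c(current, alternate)` land-use pairs.
#' @param control A [direction_control()].
#' @param driver Run the driver analysis for each direction pair present in
#'   both orders?
#' @param ale_features Numeric driver features to produce ALE curves for.
#' @param out_dir Output directory for result files.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, generator = list(), input_csv = NULL,
                            schema = NULL,
                            directions = list(c("cropland", "grassland"),
                                              c("grassland", "cropland"),
                                              c("cropland", "forest"),
                                              c("forest", "cropland"),
                                              c("grassland", "forest"),
                                              c("forest", "grassland")),
                            control = direction_control(),
                            driver = TRUE,
                            ale_features = c("map_mm", "coarse_frac"),
                            out_dir = "results") {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Scaled-down pipeline presets
#'
#' `"smoke"`: 300 synthetic sites, 2 CV repeats, 50 trees, 3 search
#' iterations, 500 bootstrap replicates, the cropland/grassland pair with its
#' driver model — a fast end-to-end exercise of every stage.
#' `"table1_check"`: no modelling; recomputes the published-table aggregation
#' identities and the subsoil upscaling.
#'
#' @param name Preset name.
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return A `pipeline_config`.
#' @export
pipeline_preset <- function(name = c("smoke", "table1_check"), seed = 1L,
                            out_dir = "results") {
  name <- match.arg(name)
  if (name == "smoke") {
    pipeline_config(
      seed = seed,
      generator = list(n_sites = 300, seed = seed),
      directions = list(c("cropland", "grassland"), c("grassland", "cropland")),
      control = direction_control(
        repeats = 2, k = 5,
        ensemble = ensemble_control(n_iter = 3, inner_k = 3, n_perm = 2,
                                    num_trees = 50, gbt_rounds = c(30, 120)),
        n_boot = 500),
      driver = TRUE, out_dir = out_dir
    )
  } else {
    cfg <- pipeline_config(seed = seed, directions = list(), driver = FALSE,
                           out_dir = out_dir)
    cfg$table1_check <- TRUE
    cfg
  }
}

read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  ens_args <- y$ensemble %||% list()
  ctrl_args <- y$control %||% list()
  ctrl_args$ensemble <- do.call(ensemble_control, ens_args)
  cfg <- pipeline_config(
    seed = y$seed %||% 1L,
    generator = y$generator %||% list(),
    input_csv = y$input_csv, schema = y$schema,
    directions = if (!is.null(y$directions))
      lapply(y$directions, unlist) else NULL,
    control = do.call(direction_control, ctrl_args),
    driver = y$driver %||% TRUE,
    ale_features = y$ale_features %||% c("map_mm", "coarse_frac"),
    out_dir = y$out_dir %||% "results"
  )
  if (is.null(y$directions)) cfg$directions <- pipeline_config()$directions
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full reciprocal-modelling pipeline
#'
#' Generates or reads an inventory, harmonizes depths, filters sites, runs
#' every configured land-use-change direction (fit, applicability screen,
#' counterfactual prediction, bootstrap summaries), pools direction pairs for
#' the driver analysis, and writes result CSVs plus a machine-readable run
#' manifest. Outputs are byte-identical for identical config and seed.
#'
#' @param config A `pipeline_config`, or a path to a YAML file.
#' @return Invisibly, a list with the per-direction results, summaries,
#'   driver models and output paths.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(...) file.path(config$out_dir, paste0(...))
  log_lines <- character()
  say <- function(...) {
    msg <- paste0(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }
  if (isTRUE(config$table1_check)) {
    chk <- check_table1()
    write.csv(chk, outfile("table1_check.csv"), row.names = FALSE)
    say("table1_check: max aggregation difference ",
        signif(max(chk$mineral_diff, chk$overall_diff), 3))
    writeLines(log_lines, outfile("run.log"))
    return(invisible(list(table1_check = chk)))
  }
  if (!is.null(config$input_csv)) {
    say("reading inventory from ", config$input_csv)
    inv <- read_inventory(config$input_csv, schema = config$schema)
    truth <- NULL
  } else {
    gen_args <- config$generator
    gen_args$seed <- gen_args$seed %||% config$seed
    say("generating synthetic inventory (n = ",
        gen_args$n_sites %||% generator_config()$n_sites, ")")
    gen <- generate_inventory(do.call(generator_config, gen_args))
    inv <- gen$inventory
    truth <- gen$truth
  }
  say("harmonizing depth increments")
  harm <- harmonize_inventory(inv)
  frep <- filter_sites(harm)$report
  write.csv(data.frame(
    n_input = frep$n_input, n_organic_excluded = frep$n_organic_excluded,
    n_ley_excluded = frep$n_ley_excluded,
    n_nonequilibrium_excluded = frep$n_nonequilibrium_excluded,
    n_retained = frep$n_retained
  ), outfile("filter_report.csv"), row.names = FALSE)

  results <- list()
  for (i in seq_along(config$directions)) {
    dpair <- config$directions[[i]]
    dn <- paste(dpair[1], "to", dpair[2])
    say("direction ", dn)
    res <- tryCatch(
      run_direction(harm, dpair[1], dpair[2], control = config$control,
                    seed = config$seed + 10000L * i),
      error = function(e) stop("pipeline stage 'direction' failed for ", dn,
                               ": ", conditionMessage(e), call. = FALSE)
    )
    results[[dn]] <- res
    write.csv(res$deltas, outfile("deltas_", gsub(" ", "_", dn), ".csv"),
              row.names = FALSE)
  }
  summaries <- lapply(results, function(r) r$summary)
  write_results(summaries, outfile("direction_summaries.csv"))

  drivers <- list()
  if (isTRUE(config$driver)) {
    done <- character()
    for (dn in names(results)) {
      pair <- strsplit(dn, " to ")[[1]]
      rev_dn <- paste(pair[2], "to", pair[1])
      pair_key <- paste(sort(pair), collapse = "|")
      if (pair_key %in% done || !rev_dn %in% names(results)) next
      done <- c(done, pair_key)
      say("driver analysis for pair ", pair_key)
      mags <- magnitude_target(rbind(results[[dn]]$deltas,
                                     results[[rev_dn]]$deltas))
      frame <- driver_frame(mags, harm)
      dm <- fit_driver_model(frame, control = config$control,
                             seed = config$seed + 555L)
      imp <- data.frame(predictor = names(dm$importance$raw),
                        importance = dm$importance$raw,
                        normalized = dm$importance$normalized)
      write.csv(imp, outfile("driver_importance_", gsub("\\|", "_", pair_key),
                             ".csv"), row.names = FALSE)
      ales <- lapply(intersect(config$ale_features,
                               predictor_spec("driver")$numeric),
                     function(f) ale_numeric(dm, frame, f))
      drivers[[pair_key]] <- list(model = dm, importance = imp, ale = ales)
    }
  }
  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("reciproSOC")),
    n_sites = nrow(harm$sites),
    directions = names(results),
    filter = list(input = frep$n_input, retained = frep$n_retained),
    config = config[setdiff(names(config), "control")]
  )
  jsonlite::write_json(manifest, outfile("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE)
  writeLines(log_lines, outfile("run.log"))
  invisible(list(inventory = harm, truth = truth, results = results,
                 summaries = summaries, drivers = drivers,
                 filter_report = frep, out_dir = config$out_dir))
}
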