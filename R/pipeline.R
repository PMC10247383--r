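#' Assemble the ecosystem-functioning indicator panel
#'
#' Binds the directly simulated functioning indicators with the three
#' stream-derived ones: per-island oil-palm yield change (from per-palm
#' records), annualized litter input (from trap series, with the outlier
#' envelope computed over the whole landscape) and microclimate buffering
#' (negated median daily temperature amplitude, so higher = more
#' buffering). All indicators are oriented higher-is-better.
#'
#' @param dataset an `island_dataset` from [simulate_dataset()].
#' @return data.frame: `plot_id` plus the 20 functioning indicators.
#' @export
assemble_indicators <- function(dataset) {
  stopifnot(inherits(dataset, "island_dataset"))
  design <- dataset$design
  p <- dataset$params

  ycl <- yield_change_table(design, dataset$yields)

  # landscape-wide pool of per-date plot medians drives the outlier rule
  med <- stats::aggregate(mass_g ~ plot_id + date, dataset$litter,
                          stats::median)
  litter_in <- vapply(design$plot_id, function(pid) {
    litter_annualize(dataset$litter[dataset$litter$plot_id == pid, ],
                     trap_area_m2 = p$trap_area_m2,
                     dates_per_year = p$n_litter_dates,
                     reference_values = med$mass_g)
  }, numeric(1))

  buffering <- vapply(design$plot_id, function(pid) {
    -microclimate_amplitude(
      dataset$temperature[dataset$temperature$plot_id == pid, ])
  }, numeric(1))

  out <- dataset$functioning
  out$oil_palm_yield <- ycl$delta_y_island[match(out$plot_id, ycl$plot_id)]
  out$litter_input <- unname(litter_in[out$plot_id])
  out$microclimate_buffering <- unname(buffering[out$plot_id])
  ord <- intersect(functioning_effects()$indicator, names(out))
  out[, c("plot_id", ord)]
}

#' Assemble the biodiversity indicator panel
#'
#' Hill diversity per taxon at one order `q`, with the tree inventory
#' rarefied to a fixed number of individuals (trees are the only group
#' sampled at unequal area).
#'
#' @param dataset an `island_dataset`.
#' @param q diversity order (0 richness, 1 Shannon, 2 Simpson).
#' @param rarefy_spec taxon -> rarefaction target, see
#'   [plotwise_diversity()].
#' @param n_resamples,seed resampling controls for orders 1 and 2.
#' @return data.frame: `plot_id` plus one column per taxon.
#' @export
biodiversity_panel <- function(dataset, q = 0, rarefy_spec = list(trees = 24),
                               n_resamples = 200, seed = 1) {
  div <- plotwise_diversity(dataset$abundances, rarefy_spec = rarefy_spec,
                            n_resamples = n_resamples, seed = seed)
  diversity_wide(div, q = q)
}

#' Configuration for a full pipeline run
#'
#' @param seed master seed for every stochastic stage.
#' @param out_dir output directory for stage CSVs, summary and log.
#' @param params `simulation_params` for the synthesis stage.
#' @param thresholds threshold grid (integer percent).
#' @param headline_threshold threshold reported in the summary.
#' @param q_main diversity order used for the multidiversity headline.
#' @param rarefy_spec taxon rarefaction targets.
#' @param corr_cutoff pre-selection correlation cutoff.
#' @param force_drop indicators dropped a priori from redundant clusters
#'   (the published analysis dropped tree growth from the
#'   tree-growth/litter-input cluster).
#' @param stages character vector of stages to run, a subset of
#'   `c("synth", "indicators", "diversity", "multimetrics", "yield",
#'   "inference")`.
#' @param resume skip stages whose outputs already exist.
#' @return a list of class `"run_config"`.
#' @export
pipeline_config <- function(seed = 1, out_dir = tempfile("treeisland_run_"),
                            params = simulation_params(seed = seed),
                            thresholds = 1:99, headline_threshold = 50,
                            q_main = 0, rarefy_spec = list(trees = 24),
                            corr_cutoff = 0.7, force_drop = "tree_growth",
                            stages = c("synth", "indicators", "diversity",
                                       "multimetrics", "yield", "inference"),
                            resume = FALSE) {
  stopifnot(all(stages %in% c("synth", "indicators", "diversity",
                              "multimetrics", "yield", "inference")))
  cfg <- list(seed = seed, out_dir = out_dir, params = params,
              thresholds = thresholds,
              headline_threshold = headline_threshold, q_main = q_main,
              rarefy_spec = rarefy_spec, corr_cutoff = corr_cutoff,
              force_drop = force_drop, stages = stages, resume = resume)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Orchestrates synthesis, indicator assembly, diversity, multimetrics,
#' yield accounting and inference as a deterministic, logged run. Every
#' stage writes its outputs as CSV into the run directory; a JSON summary
#' collects the headline quantities (indicator counts, island-vs-control
#' multimetric medians at the headline threshold, the per-island yield
#' decomposition and SEM paths). With `resume = TRUE`, stages whose output
#' files already exist are skipped.
#'
#' @param config a `run_config` from [pipeline_config()].
#' @return (invisibly) the run directory path; the summary is also
#'   returned as attribute `"summary"`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_file <- file.path(config$out_dir, "run.log")
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    message(line)
    cat(line, "\n", file = log_file, append = TRUE)
  }
  outpath <- function(f) file.path(config$out_dir, f)
  stage_done <- function(files) {
    config$resume && all(file.exists(vapply(files, outpath, character(1))))
  }
  run_stage <- function(name, files, fun) {
    if (!(name %in% config$stages)) return(invisible(NULL))
    if (stage_done(files)) {
      logmsg("stage ", name, ": outputs present, skipped (resume)")
      return(invisible(NULL))
    }
    t0 <- Sys.time()
    fun()
    logmsg("stage ", name, ": done in ",
           format(round(as.numeric(difftime(Sys.time(), t0, units = "secs")),
                        1)), " s")
  }

  summary_out <- list(seed = config$seed)

  # -- synth ---------------------------------------------------------------
  design <- build_design(seed = config$seed)
  dataset <- simulate_dataset(design, config$params)
  run_stage("synth", "design.csv", function() {
    utils::write.csv(design, outpath("design.csv"), row.names = FALSE)
    utils::write.csv(dataset$structure, outpath("structure.csv"),
                     row.names = FALSE)
    utils::write.csv(dataset$yields, outpath("palm_yields.csv"),
                     row.names = FALSE)
  })

  # -- indicators ----------------------------------------------------------
  functioning <- assemble_indicators(dataset)
  run_stage("indicators", "functioning_indicators.csv", function() {
    utils::write.csv(functioning, outpath("functioning_indicators.csv"),
                     row.names = FALSE)
  })

  # -- diversity -----------------------------------------------------------
  biodiv <- biodiversity_panel(dataset, q = config$q_main,
                               rarefy_spec = config$rarefy_spec,
                               seed = config$seed)
  run_stage("diversity", "biodiversity_indicators.csv", function() {
    utils::write.csv(biodiv, outpath("biodiversity_indicators.csv"),
                     row.names = FALSE)
  })
  summary_out$n_biodiversity_indicators <- length(.indicator_columns(biodiv))

  # -- multimetrics --------------------------------------------------------
  sel <- preselect_indicators(functioning, corr_cutoff = config$corr_cutoff,
                              force_drop = config$force_drop)
  func_retained <- functioning[, c("plot_id", sel$retained)]
  summary_out$n_functioning_retained <- length(sel$retained)
  summary_out$dropped_indicators <- sel$dropped

  func_scaled <- unit_scale(func_retained)
  biodiv_scaled <- unit_scale(biodiv)
  mf <- multimetric_threshold(func_scaled, thresholds = config$thresholds)
  md <- multimetric_threshold(biodiv_scaled, thresholds = config$thresholds)
  run_stage("multimetrics", c("multifunctionality.csv", "multidiversity.csv"),
            function() {
    utils::write.csv(mf$counts, outpath("multifunctionality.csv"),
                     row.names = FALSE)
    utils::write.csv(md$counts, outpath("multidiversity.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(indicator = sel$dropped, status = "dropped"),
      outpath("preselection_dropped.csv"), row.names = FALSE)
  })
  is_island <- design$plot_type[match(mf$counts$plot_id, design$plot_id)] ==
    "island"
  at50 <- mf$counts$threshold == config$headline_threshold
  summary_out$multifunctionality_median_island <-
    stats::median(mf$counts$count[at50 & is_island])
  summary_out$multifunctionality_median_control <-
    stats::median(mf$counts$count[at50 & !is_island])
  at50d <- md$counts$threshold == config$headline_threshold
  summary_out$multidiversity_median_island <-
    stats::median(md$counts$count[at50d & is_island])
  summary_out$multidiversity_median_control <-
    stats::median(md$counts$count[at50d & !is_island])

  # -- yield ---------------------------------------------------------------
  ycl <- yield_change_table(design, dataset$yields)
  run_stage("yield", "yield_changes.csv", function() {
    utils::write.csv(ycl, outpath("yield_changes.csv"), row.names = FALSE)
  })
  summary_out$median_delta_y_island <-
    stats::median(ycl$delta_y_island[design$plot_type == "island"])

  # -- inference -----------------------------------------------------------
  if ("inference" %in% config$stages) {
    long_f <- make_long_response(functioning[, c("plot_id", sel$retained)],
                                 design)
    lmm_f <- fit_treatment_lmm(long_f)
    kw <- kruskal_wallis_panel(functioning, design)
    tukey <- tukey_position_test(dataset$yields)

    axes <- structure_pca(dataset$structure)
    isl <- design$plot_type == "island"
    md50 <- md$counts[at50d, ]
    sem_data <- data.frame(
      outcome = md50$count[match(design$plot_id[isl], md50$plot_id)],
      log_area = log(design$edge_m[isl]),
      log_div = log(design$diversity[isl] + 1),
      complexity = axes$scores$complexity[isl],
      dominance = axes$scores$dominance[isl]
    )
    sem <- fit_piecewise_sem(sem_data)
    run_stage("inference", c("lmm_functioning.csv", "sem_paths.csv"),
              function() {
      utils::write.csv(lmm_f, outpath("lmm_functioning.csv"),
                       row.names = FALSE)
      utils::write.csv(kw, outpath("kruskal_wallis.csv"), row.names = FALSE)
      utils::write.csv(tukey, outpath("tukey_positions.csv"),
                       row.names = FALSE)
      utils::write.csv(sem$paths, outpath("sem_paths.csv"),
                       row.names = FALSE)
      utils::write.csv(sem$claims, outpath("sem_claims.csv"),
                       row.names = FALSE)
    })
    summary_out$sem_fisher_c <- sem$fisher_c
    summary_out$sem_p_value <- sem$p_value
  }

  jsonlite::write_json(summary_out, outpath("summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logmsg("run complete: ", config$out_dir)
  out <- config$out_dir
  attr(out, "summary") <- summary_out
  invisible(out)
}
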