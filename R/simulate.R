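#' Default effect structure for the ecosystem-functioning panel
#'
#' One row per functioning indicator: measurement unit location (`mu`) and
#' scale (`unit`), direct standardized treatment effects (`beta_island`,
#' `beta_area`, `beta_div`), mediated effects through the two latent
#' vegetation-structure axes (`beta_pc1` = structural complexity, `beta_pc2`
#' = tree dominance) and residual noise (`noise_sd`, standardized units).
#' Indicators are stored pre-oriented so that higher values mean better
#' functioning (resistance to invasion is already `100 - cover`, microclimate
#' buffering is the negated daily amplitude, and so on).
#'
#' Three indicators are not drawn directly but derived from raw synthetic
#' streams downstream: `oil_palm_yield` from per-palm records,
#' `litter_input` from trap series and `microclimate_buffering` from
#' temperature series; their rows define the signal injected into those
#' streams.
#'
#' @return data.frame with one row per functioning indicator.
#' @export
functioning_effects <- function() {
  ind <- c("tree_growth", "oil_palm_yield", "agb", "native_seeds",
           "invasion_resistance", "pollinators", "pollination_rate",
           "soil_p", "inv_soil_cn", "soil_decompaction",
           "predators_vertebrates", "predators_arthropods",
           "predators_soilfauna", "herbivores_soilfauna", "decomposers",
           "litter_decomposition", "litter_input", "evapotranspiration",
           "water_infiltration", "microclimate_buffering")
  data.frame(
    indicator = ind,
    mu   = c(0.5, 0, 20, 50, 80, 30, 0.25, 0.3, 0.08, 0.8,
             300, 40, 8, 6, 10, 45, 500, 120, 5, -8),
    unit = c(0.2, 1, 8, 20, 10, 10, 0.08, 0.08, 0.02, 0.1,
             150, 12, 2.5, 2, 3, 10, 150, 25, 2.5, 1.5),
    beta_island = c(0.6, 0, 0.5, 0.4, 0.3, 0.3, 0.2, 0.2, 0.4, 0.3,
                    0.6, 0.3, 0.3, 0.3, 0.4, 0.3, 0.6, 0.2, 0.6, 0.4),
    beta_area   = c(0.3, 0, 0.2, 0.2, 0.1, 0.1, 0.1, 0.1, 0.2, 0.1,
                    0.2, 0.3, 0.2, 0.3, 0.3, 0.1, 0.3, 0.1, 0.2, 0.2),
    beta_div    = c(0.2, 0, 0.2, -0.1, 0.1, -0.1, 0, 0, 0.1, 0.1,
                    0.1, -0.2, 0, 0, 0.1, 0.1, 0.2, 0.1, 0.1, 0.1),
    beta_pc1    = c(0.3, 0, 0.3, -0.2, 0.1, -0.2, 0, 0, 0.1, 0.1,
                    0.1, -0.2, 0, 0, 0.1, 0.1, 0.3, 0.1, 0.1, 0.3),
    beta_pc2    = c(0.2, 0, 0.2, 0.1, 0.1, 0.1, 0, 0.1, 0.1, 0.1,
                    0.2, 0.2, 0.2, 0.2, 0.2, 0.1, 0.2, 0.1, 0.2, 0.2),
    noise_sd = rep(1, length(ind)),
    stringsAsFactors = FALSE
  )
}

#' Default abundance-generation parameters for the ten biodiversity taxa
#'
#' Per taxon: species-pool size, expected number of individuals per control
#' plot (`base_total`; trees use 24, the design's median individual count),
#' log-scale treatment effects on total abundance (which propagate into
#' richness through sampling) and the log-normal rank-abundance shape
#' (`sad_sigma`, larger = less even).
#'
#' @return data.frame with one row per taxon.
#' @export
taxa_params <- function() {
  taxa <- c("soil_bacteria", "soil_fungi", "soil_fauna", "herbs", "trees",
            "seeds", "pollen", "arthropods", "birds", "bats")
  data.frame(
    taxon = taxa,
    n_species = c(120, 100, 40, 50, 30, 40, 30, 60, 25, 12),
    base_total = c(800, 600, 150, 200, 24, 120, 80, 150, 40, 20),
    b_island = c(0.2, 0.2, 0.3, 0.4, 0.8, 0.3, 0.2, 0.3, 0.5, 0.4),
    b_area = c(0.05, 0.05, 0.1, 0.15, 0.4, 0.1, 0.05, 0.15, 0.2, 0.1),
    b_div = c(0, 0.05, 0.05, 0.1, 0.3, -0.1, 0.05, -0.1, 0.1, 0.1),
    sad_sigma = c(1.5, 1.5, 1.2, 1.2, 0.8, 1.2, 1, 1.2, 0.8, 0.8),
    stringsAsFactors = FALSE
  )
}

#' Simulation parameters for synthetic tree-island datasets
#'
#' Bundles every tunable of [simulate_dataset()] with defaults describing the
#' study conditions the analysis assumes: treatment effects mediated by two
#' latent structure axes, a strongly correlated tree-growth/litter-input
#' pair, yield spillover confined to the directly adjacent (position-1)
#' palms, and log-normal species-abundance distributions responding to the
#' treatments.
#'
#' @param seed master integer seed; every sub-generator derives its own
#'   stream from it.
#' @param beta_area_dominance standardized path from log island edge length
#'   to the tree-dominance latent.
#' @param beta_div_complexity standardized path from log(planted diversity
#'   + 1) to the structural-complexity latent.
#' @param latent_noise_sd residual SD of the two latents (standardized).
#' @param structure_noise_sd residual SD of the 12 structure variables
#'   around their latent loadings (standardized).
#' @param effects data.frame as [functioning_effects()].
#' @param taxa data.frame as [taxa_params()].
#' @param yield_ref_mean,yield_ref_sd per-palm annual fresh-fruit-bunch
#'   yield of reference palms, kg/palm/yr.
#' @param spillover_effect yield shift of adjacent position-1 palms,
#'   kg/palm/yr; positions 2-3 are unshifted.
#' @param inside_shift yield shift of palms remaining inside islands,
#'   kg/palm/yr.
#' @param n_reference_palms number of reference palms in the surrounding
#'   conventionally managed plantation.
#' @param corr_treegrowth_litter residual correlation between tree growth
#'   and litter input, in `[0, 1)`.
#' @param temp_base mean air temperature, deg C.
#' @param temp_amplitude_control daily 07:00-15:00 amplitude in
#'   conventionally managed plots, deg C.
#' @param temp_buffering amplitude reduction attributable to one
#'   standardized unit of buffering signal, deg C.
#' @param temp_noise_sd logger noise SD, deg C.
#' @param n_litter_dates semi-monthly litter collection dates per year.
#' @param n_traps litter traps per plot.
#' @param trap_area_m2 area of one litter trap, m^2.
#' @param litter_trap_cv coefficient of variation of trap-level litter mass.
#' @param litter_date_cv log-scale SD of date-to-date variation in litter
#'   fall (phenology and weather), shared by the traps of a plot.
#' @return a list of class `"simulation_params"`.
#' @export
simulation_params <- function(seed = 1,
                              beta_area_dominance = 0.6,
                              beta_div_complexity = 0.6,
                              latent_noise_sd = 0.5,
                              structure_noise_sd = 0.2,
                              effects = functioning_effects(),
                              taxa = taxa_params(),
                              yield_ref_mean = 150, yield_ref_sd = 20,
                              spillover_effect = 40,
                              inside_shift = 0,
                              n_reference_palms = 34,
                              corr_treegrowth_litter = 0.9,
                              temp_base = 26.7,
                              temp_amplitude_control = 8,
                              temp_buffering = 1.5,
                              temp_noise_sd = 0.2,
                              n_litter_dates = 24, n_traps = 4,
                              trap_area_m2 = 0.25, litter_trap_cv = 0.05,
                              litter_date_cv = 0.3) {
  stopifnot(latent_noise_sd >= 0, structure_noise_sd >= 0,
            yield_ref_sd >= 0, temp_noise_sd >= 0,
            abs(corr_treegrowth_litter) < 1,
            all(effects$noise_sd >= 0))
  p <- list(seed = seed,
            beta_area_dominance = beta_area_dominance,
            beta_div_complexity = beta_div_complexity,
            latent_noise_sd = latent_noise_sd,
            structure_noise_sd = structure_noise_sd,
            effects = effects, taxa = taxa,
            yield_ref_mean = yield_ref_mean, yield_ref_sd = yield_ref_sd,
            spillover_effect = spillover_effect,
            inside_shift = inside_shift,
            n_reference_palms = n_reference_palms,
            corr_treegrowth_litter = corr_treegrowth_litter,
            temp_base = temp_base,
            temp_amplitude_control = temp_amplitude_control,
            temp_buffering = temp_buffering,
            temp_noise_sd = temp_noise_sd,
            n_litter_dates = n_litter_dates, n_traps = n_traps,
            trap_area_m2 = trap_area_m2, litter_trap_cv = litter_trap_cv,
            litter_date_cv = litter_date_cv)
  class(p) <- "simulation_params"
  p
}

# centred z-transform of a covariate across plots (returns zeros when the
# covariate is constant, e.g. all-control designs)
.zc <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# loadings of the 12 structure variables on (complexity, dominance), plus
# natural-unit location/scale and [0,100] clipping flags for covers
.structure_spec <- function() {
  data.frame(
    variable = c("ssci", "mean_frac", "enl", "uci", "gap_fraction",
                 "oil_palm_cover", "tree_cover", "oil_palm_density",
                 "tree_density", "understorey_cover", "litter_cover",
                 "litter_depth"),
    l1 = c(0.8, 0.7, 0.7, 0.6, -0.8, 0, 0.1, 0, 0.1, 0.5, 0.4, 0.5),
    l2 = c(0.1, 0.05, 0.1, 0, -0.1, -0.8, 0.9, -0.7, 0.7, 0, 0.1, 0.15),
    mu = c(3, 1.5, 4, 1.6, 40, 50, 25, 100, 300, 50, 50, 2),
    sd = c(0.8, 0.2, 1, 0.25, 15, 20, 15, 30, 150, 20, 15, 0.8),
    pct = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE,
            TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Generate a seeded synthetic dataset for a tree-island design
#'
#' Draws every data stream the downstream analysis consumes, with the causal
#' skeleton the inference modules assume: planted diversity raises a latent
#' structural-complexity axis, island area raises a latent tree-dominance
#' axis, and each functioning indicator responds to direct treatment effects
#' plus effects mediated by the latents. Per-palm yields place a spillover
#' shift only on adjacent position-1 palms; tree growth and litter input are
#' generated as a correlated pair; species counts come from log-normal
#' rank-abundance distributions whose totals respond to the treatments.
#'
#' @param design an `island_design` from [build_design()].
#' @param params a `simulation_params` list.
#' @return a list of class `"island_dataset"` with elements `design`,
#'   `latents` (true latent axis values, kept for parameter-recovery
#'   checks), `structure` (plot x 12 variables), `functioning` (plot x
#'   direct-valued indicators), `abundances` (named list of plot x species
#'   count matrices), `yields` (per-palm records), `temperature` (per-plot
#'   series with 07:00 and 15:00 anchor readings) and `litter` (per-trap
#'   per-date masses).
#' @export
simulate_dataset <- function(design, params = simulation_params()) {
  stopifnot(inherits(design, "island_design"),
            inherits(params, "simulation_params"))
  seed <- params$seed
  n <- nrow(design)
  island <- as.numeric(design$plot_type == "island")
  zedge <- .zc(log(design$edge_m))
  zdiv <- .zc(log(design$diversity + 1))

  # latent structure axes
  latents <- with_substream(seed, "latents", {
    data.frame(
      plot_id = design$plot_id,
      complexity = params$beta_div_complexity * zdiv +
        stats::rnorm(n, 0, params$latent_noise_sd),
      dominance = params$beta_area_dominance * zedge +
        stats::rnorm(n, 0, params$latent_noise_sd),
      stringsAsFactors = FALSE
    )
  })

  # 12 structure variables = noisy loadings of the two latents
  sspec <- .structure_spec()
  structure <- with_substream(seed, "structure", {
    z <- sapply(seq_len(nrow(sspec)), function(j) {
      sspec$l1[j] * latents$complexity + sspec$l2[j] * latents$dominance +
        stats::rnorm(n, 0, params$structure_noise_sd)
    })
    nat <- sweep(sweep(z, 2, sspec$sd, `*`), 2, sspec$mu, `+`)
    nat[, sspec$pct] <- pmin(100, pmax(0, nat[, sspec$pct]))
    colnames(nat) <- sspec$variable
    data.frame(plot_id = design$plot_id, nat, stringsAsFactors = FALSE)
  })

  # standardized signal per functioning indicator (shared by direct values
  # and the raw streams that derived indicators are computed from)
  eff <- params$effects
  signal <- sapply(seq_len(nrow(eff)), function(j) {
    eff$beta_island[j] * (island - mean(island)) +
      eff$beta_area[j] * zedge + eff$beta_div[j] * zdiv +
      eff$beta_pc1[j] * latents$complexity +
      eff$beta_pc2[j] * latents$dominance
  })
  colnames(signal) <- eff$indicator

  # residuals: iid, except the tree-growth/litter-input pair which is drawn
  # bivariate with the configured correlation
  resid <- with_substream(seed, "functioning", {
    e <- sapply(eff$noise_sd, function(s) stats::rnorm(n, 0, s))
    rho <- params$corr_treegrowth_litter
    i_tg <- match("tree_growth", eff$indicator)
    i_li <- match("litter_input", eff$indicator)
    if (!is.na(i_tg) && !is.na(i_li)) {
      e[, i_li] <- rho * e[, i_tg] +
        sqrt(1 - rho^2) * stats::rnorm(n, 0, eff$noise_sd[i_li])
    }
    e
  })
  zval <- signal + resid
  natural <- sweep(sweep(zval, 2, eff$unit, `*`), 2, eff$mu, `+`)
  colnames(natural) <- eff$indicator

  derived <- c("oil_palm_yield", "litter_input", "microclimate_buffering")
  functioning <- data.frame(
    plot_id = design$plot_id,
    natural[, setdiff(eff$indicator, derived), drop = FALSE],
    stringsAsFactors = FALSE
  )

  # abundance tables: log-normal ranked species abundances, Poisson counts,
  # totals responding to the treatments
  abundances <- with_substream(seed, "abundances", {
    tabs <- list()
    for (t_i in seq_len(nrow(params$taxa))) {
      tp <- params$taxa[t_i, ]
      sad <- sort(stats::rlnorm(tp$n_species, 0, tp$sad_sigma),
                  decreasing = TRUE)
      prop <- sad / sum(sad)
      logmult <- tp$b_island * island + tp$b_area * zedge * island +
        tp$b_div * zdiv
      total <- tp$base_total * exp(logmult)
      het <- matrix(stats::rlnorm(n * tp$n_species, 0, 0.3),
                    nrow = n)
      lambda <- (total %o% prop) * het
      counts <- matrix(stats::rpois(length(lambda), lambda), nrow = n)
      rownames(counts) <- design$plot_id
      colnames(counts) <- sprintf("sp%03d", seq_len(tp$n_species))
      tabs[[tp$taxon]] <- counts
    }
    tabs
  })

  # per-palm yield records: spillover only at adjacent position 1
  yields <- with_substream(seed, "yields", {
    recs <- list()
    for (i in seq_len(n)) {
      pid <- design$plot_id[i]
      if (design$n_in[i] > 0) {
        shift <- if (design$plot_type[i] == "island") params$inside_shift else 0
        recs[[length(recs) + 1L]] <- data.frame(
          palm_id = sprintf("%s_in%02d", pid, seq_len(design$n_in[i])),
          plot_id = pid, position = "inside",
          annual_yield = pmax(0, stats::rnorm(
            design$n_in[i], params$yield_ref_mean + shift,
            params$yield_ref_sd)),
          stringsAsFactors = FALSE
        )
      }
      if (design$plot_type[i] == "island") {
        pos <- c("adjacent1", "adjacent2", "adjacent3")
        shift <- c(params$spillover_effect, 0, 0)
        recs[[length(recs) + 1L]] <- data.frame(
          palm_id = sprintf("%s_adj%d", pid, 1:3),
          plot_id = pid, position = pos,
          annual_yield = pmax(0, stats::rnorm(
            3, params$yield_ref_mean + shift, params$yield_ref_sd)),
          stringsAsFactors = FALSE
        )
      }
    }
    recs[[length(recs) + 1L]] <- data.frame(
      palm_id = sprintf("REF%02d", seq_len(params$n_reference_palms)),
      plot_id = NA_character_, position = "reference",
      annual_yield = pmax(0, stats::rnorm(
        params$n_reference_palms, params$yield_ref_mean,
        params$yield_ref_sd)),
      stringsAsFactors = FALSE
    )
    do.call(rbind, recs)
  })

  # temperature series: 4-h grid covering the 07:00 and 15:00 anchor hours
  buf_signal <- if ("microclimate_buffering" %in% colnames(zval)) {
    zval[, "microclimate_buffering"]
  } else rep(0, n)
  amp <- pmax(0.5, params$temp_amplitude_control -
                params$temp_buffering * buf_signal)
  temperature <- with_substream(seed, "temperature", {
    hours <- c(3, 7, 11, 15, 19, 23)
    shape <- c(-0.3, -0.5, 0.1, 0.5, 0.2, -0.2) # T(15) - T(7) = amplitude
    days <- seq_len(365)
    grid <- expand.grid(hour = hours, day = days)
    out <- lapply(seq_len(n), function(i) {
      tt <- params$temp_base + amp[i] * shape[match(grid$hour, hours)] +
        stats::rnorm(nrow(grid), 0, params$temp_noise_sd)
      data.frame(plot_id = design$plot_id[i], day = grid$day,
                 hour = grid$hour, temp_c = tt, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })

  # litter-trap series: plot-level annual rate from the litter signal,
  # split over dates and traps with small trap noise
  rate <- if ("litter_input" %in% colnames(natural)) {
    natural[, "litter_input"] # g m^-2 yr^-1 target
  } else rep(500, n)
  litter <- with_substream(seed, "litter", {
    per_date <- pmax(0.1, rate) * params$trap_area_m2 / params$n_litter_dates
    grid <- expand.grid(trap = seq_len(params$n_traps),
                        date = seq_len(params$n_litter_dates))
    # date-to-date variation (phenology, weather) shared by a plot's traps,
    # mean-one on the natural scale
    dfac <- matrix(stats::rlnorm(n * params$n_litter_dates,
                                 -params$litter_date_cv^2 / 2,
                                 params$litter_date_cv),
                   nrow = n)
    out <- lapply(seq_len(n), function(i) {
      mu <- per_date[i] * dfac[i, grid$date]
      m <- pmax(0, stats::rnorm(nrow(grid), mu, params$litter_trap_cv * mu))
      data.frame(plot_id = design$plot_id[i], date = grid$date,
                 trap = grid$trap, mass_g = m, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })

  out <- list(design = design, latents = latents, structure = structure,
              functioning = functioning, abundances = abundances,
              yields = yields, temperature = temperature, litter = litter,
              params = params)
  class(out) <- "island_dataset"
  out
}

#' @export
print.island_dataset <- function(x, ...) {
  cat("Synthetic tree-island dataset:", nrow(x$design), "plots,",
      length(x$abundances), "taxa,", nrow(x$yields), "palm records\n")
  invisible(x)
}
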