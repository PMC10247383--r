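#' The six-species planting pool
#'
#' Native multipurpose tree species used for enrichment planting in the
#' experimental design: each is planted for fruit, timber or latex and occurs
#' naturally in Sumatran lowland landscapes.
#'
#' @return character vector of six species labels.
#' @export
species_pool <- function() {
  c("Archidendron", "Parkia", "Durio", "Dyera", "Shorea", "Peronema")
}

#' Wood densities of the planting pool (g cm^-3)
#'
#' Species-level wood densities used by the tree allometry, keyed by the
#' labels of [species_pool()].
#'
#' @return named numeric vector, g cm^-3.
#' @export
wood_densities <- function() {
  c(Archidendron = 0.36, Parkia = 0.54, Durio = 0.516,
    Dyera = 0.36, Shorea = 0.44, Peronema = 0.61)
}

#' Build the random-partitions tree-island design
#'
#' Constructs the factorial experimental design: four island area classes
#' (25, 100, 400 and 1,600 m^2), each containing one unplanted (zero
#' diversity) island plus a random partition of the species pool at every
#' diversity level that divides the pool evenly. For a six-species pool the
#' levels are 1, 2, 3 and 6 species, giving 6 + 3 + 2 + 1 = 12 planted plots
#' and 13 plots per area class, hence 52 islands, plus conventionally managed
#' control plots of fixed 100 m^2 area. Within each diversity level of each
#' area class, every species appears in exactly one plot.
#'
#' Palm counts follow the plantation layout: initial palms scale with area at
#' the conventional planting density, roughly 40% of within-island palms are
#' felled at establishment (controls keep all palms), and the number of
#' directly adjacent (position-1) palms scales with the island perimeter.
#'
#' @param n_replicates_per_area plots per area class; must equal
#'   `1 + sum(length(pool) / d)` over the divisors `d` of the pool size
#'   (13 for a six-species pool).
#' @param seed integer seed controlling the random partition realization.
#' @param areas island area classes in m^2.
#' @param pool character vector of candidate species (no duplicates).
#' @param n_controls number of 100 m^2 conventionally managed control plots.
#' @param palm_density_ha conventional planting density (palms per hectare).
#' @param felled_fraction fraction of within-island palms felled at
#'   establishment.
#' @return a `data.frame` of class `"island_design"` with columns
#'   `plot_id`, `plot_type`, `area_m2`, `edge_m`, `diversity`, `composition`
#'   (semicolon-separated species), `n_palms_initial`, `n_felled`, `n_in`,
#'   `n_adj`.
#' @examples
#' d <- build_design(seed = 1)
#' table(d$plot_type)
#' sum(d$area_m2[d$plot_type == "island"]) / 1e4 # total island area, ha
#' @export
build_design <- function(n_replicates_per_area = 13, seed = 1,
                         areas = c(25, 100, 400, 1600),
                         pool = species_pool(), n_controls = 4,
                         palm_density_ha = 120, felled_fraction = 0.4) {
  p <- length(pool)
  if (p < 1 || anyDuplicated(pool)) {
    stop("species pool must be a non-empty set of unique labels")
  }
  divisors <- Filter(function(k) p %% k == 0, seq_len(p))
  expected <- 1L + sum(p %/% divisors)
  if (n_replicates_per_area != expected) {
    stop("partition arithmetic inconsistent: a pool of ", p,
         " species yields ", expected, " plots per area class, not ",
         n_replicates_per_area)
  }

  partitions <- with_substream(seed, "design", {
    lapply(areas, function(a) {
      groups <- list(character(0)) # the zero-diversity island
      for (k in divisors) {
        perm <- sample(pool)
        idx <- split(seq_len(p), rep(seq_len(p %/% k), each = k))
        groups <- c(groups, lapply(idx, function(i) sort(perm[i])))
      }
      groups
    })
  })

  rows <- list()
  i_island <- 0L
  for (a_i in seq_along(areas)) {
    area <- areas[a_i]
    for (comp in partitions[[a_i]]) {
      i_island <- i_island + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        plot_id = sprintf("I%02d", i_island),
        plot_type = "island",
        area_m2 = area,
        diversity = length(comp),
        composition = paste(comp, collapse = ";"),
        stringsAsFactors = FALSE
      )
    }
  }
  for (j in seq_len(n_controls)) {
    rows[[length(rows) + 1L]] <- data.frame(
      plot_id = sprintf("C%02d", j), plot_type = "control",
      area_m2 = 100, diversity = 0L, composition = "",
      stringsAsFactors = FALSE
    )
  }
  design <- do.call(rbind, rows)
  design$edge_m <- sqrt(design$area_m2)

  # palm counts: ceiling keeps at least one palm on the smallest islands,
  # consistent with the plantation's triangular layout
  design$n_palms_initial <- pmax(
    1L, as.integer(ceiling(design$area_m2 * palm_density_ha / 1e4))
  )
  felled <- as.integer(round(felled_fraction * design$n_palms_initial))
  felled[design$plot_type == "island" & design$area_m2 >= 100] <-
    pmax(1L, felled[design$plot_type == "island" & design$area_m2 >= 100])
  felled[design$plot_type == "control"] <- 0L
  felled <- pmin(felled, design$n_palms_initial - 1L)
  felled <- pmax(felled, 0L)
  design$n_felled <- felled
  design$n_in <- design$n_palms_initial - design$n_felled
  # adjacent position-1 palms scale with the perimeter (~9 m palm spacing)
  design$n_adj <- pmax(1L, as.integer(round(4 * design$edge_m / 9)))

  design <- design[, c("plot_id", "plot_type", "area_m2", "edge_m",
                       "diversity", "composition", "n_palms_initial",
                       "n_felled", "n_in", "n_adj")]
  attr(design, "seed") <- seed
  attr(design, "pool") <- pool
  class(design) <- c("island_design", "data.frame")
  design
}

#' @export
print.island_design <- function(x, ...) {
  n_isl <- sum(x$plot_type == "island")
  cat("Tree-island experimental design:", n_isl, "islands +",
      sum(x$plot_type == "control"), "controls =", nrow(x), "plots\n")
  cat("Total island area:",
      format(sum(x$area_m2[x$plot_type == "island"]) / 1e4, digits = 4),
      "ha\n")
  NextMethod()
  invisible(x)
}
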