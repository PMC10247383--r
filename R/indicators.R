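#' Above-ground biomass of a planted tree (kg)
#'
#' Pan-tropical allometry `0.0673 * (rho * DBH^2 * H)^0.976` with wood
#' density `rho` in g cm^-3, diameter at breast height `DBH` in cm and
#' height `H` in m. Trees below breast height have no DBH and are returned
#' as missing so plot sums can exclude them explicitly.
#'
#' @param wood_density g cm^-3.
#' @param dbh diameter at breast height, cm (NA for trees below 130 cm).
#' @param height tree height, m.
#' @return biomass in kg/tree (vectorized; NA where `dbh` is missing).
#' @examples
#' agb_tree(0.5, 10, 10) # ~28.98 kg
#' @export
agb_tree <- function(wood_density, dbh, height) {
  stopifnot(all(wood_density > 0), all(height > 0), all(dbh > 0, na.rm = TRUE))
  0.0673 * (wood_density * dbh^2 * height)^0.976
}

#' Above-ground biomass of an oil palm (kg)
#'
#' Linear allometry `71.797 * H - 7.0872` on the meristem height `H` (m).
#' Heights at or below the root `7.0872 / 71.797` m would give non-positive
#' biomass and raise an error.
#'
#' @param height_meristem height at meristem, m.
#' @return biomass in kg/palm (vectorized).
#' @examples
#' agb_palm(5) # 351.898 kg
#' @export
agb_palm <- function(height_meristem) {
  out <- 71.797 * height_meristem - 7.0872
  if (any(out <= 0)) {
    stop("palm meristem height must exceed ", format(7.0872 / 71.797),
         " m for positive biomass")
  }
  out
}

#' Total plot-level above-ground biomass (t/ha)
#'
#' Sums tree biomass over the plot area and adds the palm contribution as
#' mean palm biomass times the local stand density, so that
#' `AGB = (sum tree kg * 1e4 / A + mean palm kg * d_palm) / 1000` t/ha.
#' Necromass, litter, understorey vegetation and spontaneous trees are
#' treated as negligible.
#'
#' @param tree_kg vector of per-tree biomasses, kg (NAs excluded: trees
#'   below breast height).
#' @param palm_kg vector of per-palm biomasses of the `n_in` palms inside,
#'   kg.
#' @param area_m2 plot area, m^2.
#' @param palms_per_ha stand-density expansion factor `d_palm`, palms/ha.
#' @return total above-ground biomass, t/ha.
#' @examples
#' total_agb(tree_kg = 100, palm_kg = numeric(0), area_m2 = 100) # 10 t/ha
#' @export
total_agb <- function(tree_kg, palm_kg, area_m2, palms_per_ha = 120) {
  stopifnot(area_m2 > 0)
  tree_part <- sum(tree_kg, na.rm = TRUE) * 1e4 / area_m2 # kg/ha
  palm_part <- if (length(palm_kg) > 0) mean(palm_kg) * palms_per_ha else 0
  (tree_part + palm_part) / 1000
}

#' Plot-level basal-area increment (cm^2 m^-2 yr^-1)
#'
#' Sum of per-tree basal-area changes computed from basal diameters of two
#' consecutive yearly inventories, divided by plot area. Shrinkage beyond
#' `shrink_tol` cm is flagged with a warning (measurement error in the
#' field inventory).
#'
#' @param basal_d_start,basal_d_end matched per-tree basal diameters, cm.
#' @param area_m2 plot area, m^2.
#' @param shrink_tol tolerated apparent diameter shrinkage, cm.
#' @return increment in cm^2 m^-2 yr^-1 (equivalently m^2 ha^-1 yr^-1).
#' @examples
#' ba_increment(2, 4, 25) # 0.377
#' @export
ba_increment <- function(basal_d_start, basal_d_end, area_m2,
                         shrink_tol = 0.5) {
  stopifnot(length(basal_d_start) == length(basal_d_end), area_m2 > 0)
  if (any(basal_d_end < basal_d_start - shrink_tol, na.rm = TRUE)) {
    warning("some trees shrank by more than ", shrink_tol,
            " cm between inventories")
  }
  sum((pi / 4) * (basal_d_end^2 - basal_d_start^2), na.rm = TRUE) / area_m2
}

#' Daily temperature amplitude (microclimate metric)
#'
#' Median over days of the absolute difference between the morning and
#' afternoon readings; days missing either reading are dropped. Lower
#' amplitude means stronger microclimate buffering, so the indicator panel
#' stores the negated amplitude (see [assemble_indicators()]).
#'
#' @param series data.frame with columns `day`, `hour`, `temp_c`.
#' @param morning_hour,afternoon_hour anchor hours of the daily amplitude.
#' @return median daily amplitude, deg C per day.
#' @export
microclimate_amplitude <- function(series, morning_hour = 7,
                                   afternoon_hour = 15) {
  am <- series[series$hour == morning_hour, c("day", "temp_c")]
  pm <- series[series$hour == afternoon_hour, c("day", "temp_c")]
  both <- merge(am, pm, by = "day", suffixes = c("_am", "_pm"))
  both <- both[stats::complete.cases(both), ]
  if (nrow(both) == 0) stop("no day has both morning and afternoon readings")
  stats::median(abs(both$temp_c_pm - both$temp_c_am))
}

#' Annualized leaf-litter input (g m^-2 yr^-1)
#'
#' Aggregates trap masses to a plot-level median per sampling date, excludes
#' dates whose plot-level value falls outside 3 standard deviations around
#' the median of all supplied plot-level values, averages the remaining
#' dates, scales to a full year of collections and converts per-trap grams
#' to g m^-2 using the trap area.
#'
#' @param litter data.frame with columns `date`, `trap`, `mass_g` for one
#'   plot.
#' @param trap_area_m2 area of one trap, m^2.
#' @param dates_per_year number of collection dates in a full year
#'   (semi-monthly = 24).
#' @param reference_values optional vector of plot-level per-date values
#'   defining the outlier envelope (defaults to this plot's own values; the
#'   pipeline passes the landscape-wide pool).
#' @return annual litter input, g m^-2 yr^-1.
#' @export
litter_annualize <- function(litter, trap_area_m2 = 0.25,
                             dates_per_year = 24,
                             reference_values = NULL) {
  stopifnot(nrow(litter) > 0, trap_area_m2 > 0)
  per_date <- tapply(litter$mass_g, litter$date, stats::median, na.rm = TRUE)
  pool <- if (is.null(reference_values)) per_date else reference_values
  centre <- stats::median(pool, na.rm = TRUE)
  spread <- stats::sd(pool, na.rm = TRUE)
  keep <- if (is.finite(spread)) {
    abs(per_date - centre) <= 3 * spread
  } else rep(TRUE, length(per_date)) # a single value spans no envelope
  if (!any(keep)) stop("all litter sampling dates excluded as outliers")
  mean_per_date <- sum(per_date[keep]) / sum(keep)
  mean_per_date * dates_per_year / trap_area_m2
}

#' Infiltration correction for the manual double-ring device
#'
#' Maps manual double-ring saturated-conductivity readings onto the
#' dual-head device scale via the cross-calibration line
#' `K_corr = 1.44 + 0.55 * K_double_ring`.
#'
#' @param k_double_ring saturated hydraulic conductivity, cm/h.
#' @return corrected conductivity, cm/h.
#' @examples
#' kfs_correct(10) # 6.94
#' @export
kfs_correct <- function(k_double_ring) {
  stopifnot(all(k_double_ring >= 0))
  1.44 + 0.55 * k_double_ring
}

#' Soil-quality indicators from a soil sample
#'
#' Molar C:N uses the atomic masses 12.0107 (C) and 14.0067 (N); the
#' indicator panel uses its inverse (higher = more fertile) and the inverse
#' of bulk density ("decompaction", higher = less compacted). Available P
#' passes through unchanged.
#'
#' @param total_c,total_n total carbon and nitrogen, mg/g.
#' @param available_p plant-available phosphorus, mg/g.
#' @param bulk_density g/cm^3.
#' @return data.frame `inv_cn`, `soil_p`, `decompaction`.
#' @examples
#' soil_indicators(1.2, 0.14, 0.3, 1.25)
#' @export
soil_indicators <- function(total_c, total_n, available_p, bulk_density) {
  if (any(total_n <= 0)) stop("total nitrogen must be positive for C:N")
  if (any(bulk_density <= 0)) stop("bulk density must be positive")
  cn_molar <- (total_c / 12.0107) / (total_n / 14.0067)
  data.frame(inv_cn = 1 / cn_molar, soil_p = available_p,
             decompaction = 1 / bulk_density)
}

#' Pollination rate on phytometer plants
#'
#' Total harvested fruits divided by total observed flowers per plot; with
#' no observed flowers the rate is undefined (missing, not zero). More
#' fruits than flowers is biologically impossible under the protocol and is
#' flagged.
#'
#' @param fruits,flowers non-negative counts.
#' @return fruit-to-flower fraction (NA when `flowers == 0`).
#' @export
pollination_rate <- function(fruits, flowers) {
  stopifnot(all(fruits >= 0), all(flowers >= 0))
  if (any(fruits > flowers & flowers > 0)) {
    warning("more fruits than flowers recorded; check the input")
  }
  out <- fruits / flowers
  out[flowers == 0] <- NA_real_
  out
}
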