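#' Median reference per-palm yield
#'
#' Reference palms grow in the conventionally managed plantation away from
#' any tree island; their median annual fresh-fruit-bunch yield anchors the
#' per-island decomposition.
#'
#' @param records data.frame of palm records with columns `position` and
#'   `annual_yield` (kg/palm/yr).
#' @return median reference yield, kg/palm/yr.
#' @export
reference_yield <- function(records) {
  ref <- records$annual_yield[records$position == "reference"]
  if (length(ref) == 0) stop("no reference palm records")
  stats::median(ref)
}

#' Per-island yield-change decomposition
#'
#' Splits the annual oil-palm yield change of one island (kg/island/yr) into
#' spillover (`n_adj * (mean position-1 yield - y_ref)`), remain-change
#' (`n_in * (median inside yield - y_ref)`) and foregone yield
#' (`n_felled * y_ref`), combined as
#' `delta = spillover + remain_change - foregone`. Palms at adjacent
#' positions 2 and 3 are ignored: only the directly adjacent palm responds
#' to the treatment.
#'
#' @param plot one-row data.frame (or list) with `plot_id`, `n_felled`,
#'   `n_in`, `n_adj`.
#' @param records palm records of this plot (`position`, `annual_yield`);
#'   reference records may be present and are ignored.
#' @param y_ref reference per-palm yield from [reference_yield()].
#' @return one-row data.frame: `plot_id`, `y_spillover`, `y_remain_change`,
#'   `y_foregone`, `delta_y_island` (all kg/island/yr).
#' @examples
#' plot <- list(plot_id = "I01", n_felled = 2, n_in = 3, n_adj = 4)
#' rec <- data.frame(
#'   position = c(rep("inside", 3), "adjacent1"),
#'   annual_yield = c(90, 90, 90, 110)
#' )
#' per_island_change(plot, rec, y_ref = 100) # delta = -190
#' @export
per_island_change <- function(plot, records, y_ref) {
  stopifnot(is.finite(y_ref))
  inside <- records$annual_yield[records$position == "inside"]
  adj1 <- records$annual_yield[records$position == "adjacent1"]
  if (plot$n_in > 0 && length(inside) == 0) {
    stop("plot ", plot$plot_id, " has n_in = ", plot$n_in,
         " but no inside yield records")
  }
  y_in <- if (length(inside) > 0) stats::median(inside) else y_ref
  y_adj <- if (length(adj1) > 0) mean(adj1) else y_ref
  y_foregone <- plot$n_felled * y_ref
  y_remain <- plot$n_in * (y_in - y_ref)
  y_spill <- plot$n_adj * (y_adj - y_ref)
  data.frame(plot_id = plot$plot_id,
             y_spillover = y_spill,
             y_remain_change = y_remain,
             y_foregone = y_foregone,
             delta_y_island = y_spill + y_remain - y_foregone,
             stringsAsFactors = FALSE)
}

#' Yield-change decomposition for every plot of a design
#'
#' @param design an `island_design`.
#' @param records all palm records incl. reference palms.
#' @return data.frame with one decomposition row per plot.
#' @export
yield_change_table <- function(design, records) {
  y_ref <- reference_yield(records)
  out <- lapply(seq_len(nrow(design)), function(i) {
    plot <- design[i, ]
    per_island_change(plot, records[records$plot_id %in% plot$plot_id, ],
                      y_ref)
  })
  do.call(rbind, out)
}

#' Stand-density expansion factor (palms per hectare)
#'
#' Converts a palm count over a local neighbourhood area into a density.
#' Plots unaffected by thinning default to the conventional planting
#' density of 120 palms per hectare.
#'
#' @param neighborhood_count palms in the local neighbourhood.
#' @param neighborhood_area neighbourhood area, m^2; `NULL` (with
#'   `thinned = FALSE`) falls back to the default density.
#' @param thinned logical; was the neighbourhood affected by palm felling?
#' @param default_density_ha conventional planting density, palms/ha.
#' @return palms per hectare (scalar).
#' @examples
#' expansion_factor(3, 400) # 75 palms/ha
#' expansion_factor(thinned = FALSE) # 120 palms/ha
#' @export
expansion_factor <- function(neighborhood_count = NULL,
                             neighborhood_area = NULL,
                             thinned = TRUE, default_density_ha = 120) {
  if (!thinned && (is.null(neighborhood_count) || is.null(neighborhood_area))) {
    return(default_density_ha)
  }
  stopifnot(!is.null(neighborhood_count), !is.null(neighborhood_area))
  if (neighborhood_area <= 0) stop("neighbourhood area must be positive")
  1e4 * neighborhood_count / neighborhood_area
}

#' Per-area yield from per-palm yield
#'
#' @param y_palm per-palm annual yield, kg/palm/yr.
#' @param palms_per_ha stand-density expansion factor from
#'   [expansion_factor()].
#' @return yield in kg/ha/yr.
#' @examples
#' per_area_yield(150, 120) # 18,000 kg/ha/yr
#' @export
per_area_yield <- function(y_palm, palms_per_ha) {
  stopifnot(all(palms_per_ha > 0))
  y_palm * palms_per_ha
}
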