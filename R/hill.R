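#' Hill-number diversity of an abundance vector
#'
#' Diversity of order `q` expressed as the effective number of equally
#' abundant species: `q = 0` is species richness, `q = 1` the exponential of
#' Shannon entropy (with `0 * log(0)` taken as 0) and `q = 2` the inverse
#' Simpson concentration.
#'
#' @param counts non-negative numeric vector of per-species counts.
#' @param q diversity order, one of 0, 1, 2.
#' @return effective number of species (scalar).
#' @examples
#' hill_number(c(10, 10, 10, 10), q = 1) # 4: uniform community
#' hill_number(c(8, 1, 1), q = 2)
#' @export
hill_number <- function(counts, q = 0) {
  stopifnot(is.numeric(counts), all(counts >= 0), q %in% c(0, 1, 2))
  total <- sum(counts)
  if (total <= 0) stop("diversity undefined for an all-zero abundance vector")
  p <- counts[counts > 0] / total
  switch(as.character(q),
         "0" = length(p),
         "1" = exp(-sum(p * log(p))),
         "2" = 1 / sum(p^2))
}

#' Rarefied Hill number at a target sample size
#'
#' Standardizes diversity to `m` sampled individuals. For `q = 0` the exact
#' hypergeometric expectation is used:
#' `sum_i [1 - choose(n - n_i, m) / choose(n, m)]`. For `q = 1` and `q = 2`
#' the expectation is estimated as the mean Hill number over seeded
#' subsamples of `m` individuals drawn without replacement. Requests beyond
#' the sample size (`m > sum(counts)`) return the observed value with a
#' warning; extrapolation is out of scope.
#'
#' @inheritParams hill_number
#' @param m target number of individuals (>= 1).
#' @param n_resamples number of subsamples for `q` in {1, 2}.
#' @param seed integer seed for the resampling path.
#' @return effective number of species at sample size `m`.
#' @examples
#' rarefy_hill(c(2, 2, 2), m = 2, q = 0) # 1.8 exactly
#' @export
rarefy_hill <- function(counts, m, q = 0, n_resamples = 1000, seed = 1) {
  stopifnot(is.numeric(counts), all(counts >= 0))
  if (m < 1) stop("rarefaction target m must be >= 1")
  total <- sum(counts)
  if (total <= 0) stop("diversity undefined for an all-zero abundance vector")
  if (m > total) {
    warning("rarefaction target m = ", m, " exceeds sample size ", total,
            "; returning the observed value")
    return(hill_number(counts, q))
  }
  if (q == 0) {
    n_i <- counts[counts > 0]
    # lchoose is stable for large counts; choose(n - n_i, m) = 0 when m > n - n_i
    keep <- exp(lchoose(total - n_i, m) - lchoose(total, m))
    keep[total - n_i < m] <- 0
    return(sum(1 - keep))
  }
  pool <- rep(seq_along(counts), counts)
  with_substream(seed, "rarefy", {
    vals <- replicate(n_resamples, {
      sub <- tabulate(sample(pool, m), nbins = length(counts))
      hill_number(sub, q)
    })
    mean(vals)
  })
}

#' Plot-wise Hill diversity across taxa
#'
#' Computes Hill numbers of orders 0, 1 and 2 per plot for each taxon's
#' plot x species count table, optionally rarefying selected taxa to a fixed
#' number of individuals (the tree inventory is standardized to 24
#' individuals by default elsewhere in the pipeline because trees are the
#' only group sampled at unequal area). Plots with empty samples yield
#' missing values, never zero.
#'
#' @param tables named list of plot x species count matrices (plot ids as
#'   row names).
#' @param rarefy_spec named list or vector mapping taxon name to the
#'   rarefaction target `m`; taxa not listed are left unstandardized.
#' @param n_resamples,seed passed to [rarefy_hill()].
#' @return long data.frame with columns `plot_id`, `taxon`, `q`, `value`.
#' @export
plotwise_diversity <- function(tables, rarefy_spec = list(trees = 24),
                               n_resamples = 1000, seed = 1) {
  stopifnot(is.list(tables), length(tables) > 0)
  out <- list()
  for (taxon in names(tables)) {
    tab <- tables[[taxon]]
    m_target <- rarefy_spec[[taxon]]
    for (i in seq_len(nrow(tab))) {
      counts <- tab[i, ]
      for (q in c(0, 1, 2)) {
        val <- if (sum(counts) <= 0) {
          NA_real_
        } else if (!is.null(m_target)) {
          suppressWarnings(rarefy_hill(counts, m = m_target, q = q,
                                       n_resamples = n_resamples,
                                       seed = seed))
        } else {
          hill_number(counts, q)
        }
        out[[length(out) + 1L]] <- data.frame(
          plot_id = rownames(tab)[i], taxon = taxon, q = q, value = val,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, out)
}

#' Pivot long plot-wise diversity into a plot x indicator matrix
#'
#' @param div long data.frame from [plotwise_diversity()].
#' @param q which diversity order to extract.
#' @return data.frame with `plot_id` and one column per taxon.
#' @export
diversity_wide <- function(div, q = 0) {
  sub <- div[div$q == q, ]
  wide <- stats::reshape(sub[, c("plot_id", "taxon", "value")],
                         idvar = "plot_id", timevar = "taxon",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}
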