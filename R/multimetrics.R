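#' Standardize indicator columns to unit scale
#'
#' Min-max rescales each indicator over all plots so the observed minimum
#' maps to 0 and the maximum to 1; missing values are preserved. Applied to
#' biodiversity and ecosystem-functioning panels separately before any
#' multidiversity/multifunctionality aggregation.
#'
#' @param m data.frame with a `plot_id` column and one numeric column per
#'   indicator (or a plain numeric matrix/data.frame).
#' @return object of the same shape with each indicator on `[0, 1]`.
#' @export
unit_scale <- function(m) {
  num <- .indicator_columns(m)
  for (j in num) {
    x <- m[[j]]
    rng <- range(x, na.rm = TRUE)
    if (!all(is.finite(rng))) stop("indicator '", j, "' has no finite values")
    if (rng[1] == rng[2]) {
      stop("indicator '", j, "' is constant; unit scale is degenerate")
    }
    m[[j]] <- (x - rng[1]) / (rng[2] - rng[1])
  }
  m
}

.indicator_columns <- function(m) {
  stopifnot(is.data.frame(m))
  setdiff(names(m)[vapply(m, is.numeric, logical(1))], "plot_id")
}

#' Observed maximum of an indicator (mean of the three highest values)
#'
#' The reference maximum used by the threshold approach; averaging the top
#' three observed values damps the influence of a single extreme plot.
#'
#' @param x numeric indicator values (missing values ignored).
#' @return the mean of the three largest non-missing values.
#' @examples
#' observed_maximum(c(1, 2, 3, 10)) # 5
#' @export
observed_maximum <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3) stop("observed maximum needs at least 3 non-missing values")
  mean(sort(x, decreasing = TRUE)[1:3])
}

#' Threshold-based multidiversity / multifunctionality profile
#'
#' For each plot and each threshold percentage, counts the indicators whose
#' unit-scaled value reaches the threshold fraction of that indicator's
#' observed maximum (mean of the top three values across all plots).
#' Missing indicator values never count as passing.
#'
#' @param m unit-scaled indicator data.frame with `plot_id`.
#' @param thresholds integer percentages to evaluate (default 1 to 99).
#' @return a list of class `"threshold_profile"`: `counts` (long data.frame
#'   `plot_id`, `threshold`, `count`), `maxima` (named vector) and
#'   `n_indicators`.
#' @export
multimetric_threshold <- function(m, thresholds = 1:99) {
  stopifnot(all(thresholds >= 1), all(thresholds <= 99))
  ind <- .indicator_columns(m)
  vals <- as.matrix(m[, ind, drop = FALSE])
  maxima <- apply(vals, 2, observed_maximum)
  counts <- lapply(thresholds, function(t) {
    cut <- (t / 100) * maxima
    pass <- sweep(vals, 2, cut, `>=`)
    data.frame(plot_id = m$plot_id, threshold = t,
               count = rowSums(pass, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- list(counts = do.call(rbind, counts), maxima = maxima,
              n_indicators = length(ind))
  class(out) <- "threshold_profile"
  out
}

#' @export
print.threshold_profile <- function(x, ...) {
  cat("Threshold profile over", x$n_indicators, "indicators,",
      length(unique(x$counts$threshold)), "thresholds\n")
  invisible(x)
}

#' Averaging alternative to the threshold approach
#'
#' Per-plot mean of the unit-scaled indicators, ignoring missing values;
#' rows with no non-missing indicator are missing.
#'
#' @inheritParams multimetric_threshold
#' @return data.frame `plot_id`, `average`.
#' @export
multimetric_average <- function(m) {
  ind <- .indicator_columns(m)
  vals <- as.matrix(m[, ind, drop = FALSE])
  avg <- rowMeans(vals, na.rm = TRUE)
  avg[rowSums(!is.na(vals)) == 0] <- NA_real_
  data.frame(plot_id = m$plot_id, average = avg, stringsAsFactors = FALSE)
}

#' Correlation-cluster pre-selection of indicators
#'
#' Average-linkage hierarchical clustering on the distance
#' `1 - |Spearman rho|`; within each cluster formed below the cut height the
#' indicator with the lowest mean absolute correlation to all other
#' indicators is retained and the rest are dropped, so each cluster of
#' redundant indicators contributes once. A `force_drop` argument reproduces
#' an a-priori choice of which member to discard (e.g. dropping tree growth
#' from the tree-growth/litter-input cluster).
#'
#' @inheritParams multimetric_threshold
#' @param corr_cutoff absolute correlation above which indicators are
#'   considered redundant; the dendrogram is cut at height
#'   `1 - corr_cutoff`.
#' @param force_drop character vector of indicators to drop whenever they
#'   fall in a multi-member cluster, overriding the lowest-mean-|r| rule.
#' @return list with `retained` and `dropped` character vectors and the
#'   `clusters` assignment.
#' @export
preselect_indicators <- function(m, corr_cutoff = 0.7, force_drop = NULL) {
  ind <- .indicator_columns(m)
  if (length(ind) < 2) stop("pre-selection needs at least 2 indicators")
  vals <- as.matrix(m[, ind, drop = FALSE])
  rho <- stats::cor(vals, method = "spearman", use = "pairwise.complete.obs")
  d <- stats::as.dist(1 - abs(rho))
  cl <- stats::cutree(stats::hclust(d, method = "average"),
                      h = 1 - corr_cutoff)
  mean_abs_r <- rowMeans(abs(rho) - diag(length(ind)), na.rm = TRUE) *
    length(ind) / (length(ind) - 1)
  retained <- character(0)
  dropped <- character(0)
  for (g in unique(cl)) {
    members <- ind[cl == g]
    if (length(members) == 1) {
      retained <- c(retained, members)
      next
    }
    forced <- intersect(members, force_drop)
    keepable <- setdiff(members, forced)
    if (length(keepable) == 0) keepable <- members
    keep <- keepable[which.min(mean_abs_r[match(keepable, ind)])]
    retained <- c(retained, keep)
    dropped <- c(dropped, setdiff(members, keep))
  }
  list(retained = ind[ind %in% retained],
       dropped = ind[ind %in% dropped],
       clusters = cl)
}
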