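#' Principal-component axes of the vegetation structure
#'
#' Z-standardizes the 12 structure variables and extracts the first two
#' principal components. PC1 is oriented so that the stand structural
#' complexity index (SSCI) loads positively ("structural complexity"); PC2
#' so that tree cover loads positively ("tree dominance"). Plots with
#' missing values are mean-imputed (and flagged) so the full plot panel is
#' retained.
#'
#' @param structure data.frame with `plot_id` and the structure variables.
#' @param pc1_anchor,pc2_anchor variable names fixing the sign of each axis.
#' @return a list of class `"structure_axes"`: `scores` (data.frame
#'   `plot_id`, `complexity`, `dominance`), `loadings` (variables x 2),
#'   `variance_explained` (length-2 fractions), `imputed` (logical per
#'   plot).
#' @export
structure_pca <- function(structure, pc1_anchor = "ssci",
                          pc2_anchor = "tree_cover") {
  vars <- setdiff(names(structure)[vapply(structure, is.numeric, logical(1))],
                  "plot_id")
  if (nrow(structure) < 3) stop("PCA needs at least 3 plots")
  x <- as.matrix(structure[, vars, drop = FALSE])
  const <- apply(x, 2, function(v) stats::sd(v, na.rm = TRUE)) == 0
  if (any(const)) {
    stop("constant structure variable(s): ", paste(vars[const], collapse = ", "))
  }
  imputed <- apply(x, 1, anyNA)
  for (j in seq_len(ncol(x))) {
    x[is.na(x[, j]), j] <- mean(x[, j], na.rm = TRUE)
  }
  fit <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  scores <- fit$x[, 1:2, drop = FALSE]
  loadings <- fit$rotation[, 1:2, drop = FALSE]
  for (k in 1:2) {
    anchor <- if (k == 1) pc1_anchor else pc2_anchor
    if (anchor %in% vars && loadings[anchor, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  out <- list(
    scores = data.frame(plot_id = structure$plot_id,
                        complexity = scores[, 1], dominance = scores[, 2],
                        stringsAsFactors = FALSE),
    loadings = loadings,
    variance_explained = ve[1:2],
    imputed = imputed
  )
  class(out) <- "structure_axes"
  out
}

#' @export
print.structure_axes <- function(x, ...) {
  cat("Vegetation-structure axes: PC1 (complexity)",
      sprintf("%.1f%%", 100 * x$variance_explained[1]),
      "| PC2 (dominance)",
      sprintf("%.1f%%", 100 * x$variance_explained[2]), "\n")
  invisible(x)
}
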