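#' Build the long response table for treatment models
#'
#' Stacks a plot x indicator panel into long format, unit-scales each
#' indicator, and attaches the treatment covariates: the tree-island flag,
#' log island edge length (controls enter at the 10 m edge length of their
#' fixed 100 m^2 area) and log(planted diversity + 1).
#'
#' @param indicators data.frame with `plot_id` plus numeric indicator
#'   columns (raw scale; unit scaling is applied here).
#' @param design an `island_design`.
#' @return data.frame `plot_id`, `indicator`, `value`, `tree_island`,
#'   `log_edge`, `log_div`.
#' @export
make_long_response <- function(indicators, design) {
  scaled <- unit_scale(indicators)
  ind <- .indicator_columns(scaled)
  long <- do.call(rbind, lapply(ind, function(j) {
    data.frame(plot_id = scaled$plot_id, indicator = j,
               value = scaled[[j]], stringsAsFactors = FALSE)
  }))
  idx <- match(long$plot_id, design$plot_id)
  long$tree_island <- design$plot_type[idx] == "island"
  long$log_edge <- log(design$edge_m[idx])
  long$log_div <- log(design$diversity[idx] + 1)
  long
}

#' Linear mixed-effect treatment model over an indicator panel
#'
#' Fits the full treatment model on the long response table: tree island,
#' island area (log edge length), planted diversity (log(x+1)) and the
#' indicator as single factors, plus tree island x indicator, area x
#' indicator, diversity x indicator, area x diversity and area x diversity
#' x indicator interactions, with a plot-level random intercept. F tests
#' use Satterthwaite denominator degrees of freedom. A singular random-
#' effect fit is reported via the `singular` attribute, never silently
#' absorbed.
#'
#' @param long data.frame from [make_long_response()].
#' @return data.frame of fixed-effect tests (`term`, `F`, `df1`, `df2`,
#'   `p`), with attributes `model` (the fit) and `singular`.
#' @export
fit_treatment_lmm <- function(long) {
  stopifnot(length(unique(long$indicator)) >= 2)
  long$indicator <- factor(long$indicator)
  fit <- lmerTest::lmer(
    value ~ tree_island + log_edge + log_div + indicator +
      tree_island:indicator + log_edge:indicator + log_div:indicator +
      log_edge:log_div + log_edge:log_div:indicator + (1 | plot_id),
    data = long,
    control = lme4::lmerControl(check.conv.singular = "ignore")
  )
  an <- stats::anova(fit, type = 3)
  out <- data.frame(term = rownames(an), F = an[["F value"]],
                    df1 = an[["NumDF"]], df2 = an[["DenDF"]],
                    p = an[["Pr(>F)"]], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "model") <- fit
  attr(out, "singular") <- lme4::isSingular(fit)
  out
}

#' Kruskal-Wallis comparison of islands versus controls per indicator
#'
#' Rank-based alternative to the mixed model: one tie-corrected
#' Kruskal-Wallis test per indicator comparing tree islands against
#' conventionally managed control plots. Indicators constant across all
#' plots yield missing results.
#'
#' @param indicators data.frame with `plot_id` plus indicator columns.
#' @param design an `island_design` (provides the island/control grouping).
#' @return data.frame `indicator`, `H`, `df`, `p`.
#' @export
kruskal_wallis_panel <- function(indicators, design) {
  grp <- factor(design$plot_type[match(indicators$plot_id, design$plot_id)])
  if (length(unique(stats::na.omit(grp))) < 2) {
    stop("both island and control plots are required")
  }
  ind <- .indicator_columns(indicators)
  out <- lapply(ind, function(j) {
    x <- indicators[[j]]
    ok <- !is.na(x) & !is.na(grp)
    if (length(unique(x[ok])) < 2) {
      return(data.frame(indicator = j, H = NA_real_, df = NA_integer_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    kt <- stats::kruskal.test(x[ok], grp[ok])
    data.frame(indicator = j, H = unname(kt$statistic),
               df = unname(kt$parameter), p = kt$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Tukey-adjusted pairwise comparison of palm position classes
#'
#' Mixed model with per-palm annual yield as the response, position class
#' (inside, adjacent1-3, reference) as fixed effect and plot identity as a
#' random intercept (reference palms, which carry no plot, each form their
#' own singleton group), followed by Tukey-adjusted pairwise contrasts.
#' Position classes with fewer than 2 palms are dropped with a warning.
#'
#' @param records palm records with `palm_id`, `plot_id`, `position`,
#'   `annual_yield`.
#' @return data.frame of pairwise contrasts (`contrast`, `estimate`, `SE`,
#'   `df`, `t`, `p_adj`), with the fitted model as attribute `model`.
#' @export
tukey_position_test <- function(records) {
  counts <- table(records$position)
  small <- names(counts)[counts < 2]
  if (length(small) > 0) {
    warning("dropping position class(es) with < 2 palms: ",
            paste(small, collapse = ", "))
    records <- records[!records$position %in% small, ]
  }
  if (length(unique(records$position)) < 2) {
    stop("at least 2 position classes are required")
  }
  records$plot_id <- ifelse(is.na(records$plot_id),
                            paste0("ref_", records$palm_id),
                            records$plot_id)
  records$position <- factor(records$position)
  fit <- lmerTest::lmer(annual_yield ~ position + (1 | plot_id),
                        data = records)
  em <- emmeans::emmeans(fit, "position")
  pw <- summary(emmeans::contrast(em, method = "pairwise", adjust = "tukey"))
  out <- data.frame(contrast = as.character(pw$contrast),
                    estimate = pw$estimate, SE = pw$SE, df = pw$df,
                    t = pw$t.ratio, p_adj = pw$p.value,
                    stringsAsFactors = FALSE)
  attr(out, "model") <- fit
  out
}
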