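#' Marker-level screening statistics
#'
#' Aggregates per-well gating output into the screen's marker-level
#' quantities and classifications: percent-positive, the 5.5%
#' positivity rule, fold increase with a floored denominator, one-way
#' ANOVA across donors, the enrichment filter (fold >= 1.5 and p < 0.05),
#' stain index with robust background correction, background comparison
#' between populations, and delta-delta-Ct relative expression.
#'
#' @name screening-stats
NULL

#' Screening configuration
#'
#' @param positivity_threshold_pct percent-positive cutoff for calling a
#'   marker expressed (default 5.5, inclusive)
#' @param enrichment_fold_min minimum fold increase for enrichment
#'   (default 1.5, inclusive)
#' @param alpha significance level (default 0.05, strict)
#' @param fold_floor_pct denominator floor in percentage points
#'   (default 0.5), keeping near-zero denominators finite
#' @param variable_fold_min,variable_diff_pct module convention separating
#'   "variable" from "equally expressed" markers: variable iff fold >=
#'   `variable_fold_min` (default 1.25) or absolute difference >=
#'   `variable_diff_pct` points (default 10)
#' @param multiplicity "none" (default; raw p-values) or
#'   "benjamini-hochberg"
#' @param test "one-way-anova" (default) or "paired-t"
#' @return object of class `screen_config`
#' @export
screen_config <- function(positivity_threshold_pct = 5.5,
                          enrichment_fold_min = 1.5,
                          alpha = 0.05,
                          fold_floor_pct = 0.5,
                          variable_fold_min = 1.25,
                          variable_diff_pct = 10,
                          multiplicity = c("none", "benjamini-hochberg"),
                          test = c("one-way-anova", "paired-t")) {
  multiplicity <- match.arg(multiplicity)
  test <- match.arg(test)
  if (positivity_threshold_pct <= 0 || enrichment_fold_min <= 0 ||
      fold_floor_pct <= 0)
    stop("thresholds must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  structure(list(
    positivity_threshold_pct = positivity_threshold_pct,
    enrichment_fold_min = enrichment_fold_min, alpha = alpha,
    fold_floor_pct = fold_floor_pct,
    variable_fold_min = variable_fold_min,
    variable_diff_pct = variable_diff_pct,
    multiplicity = multiplicity, test = test
  ), class = "screen_config")
}

#' Positivity call for a marker
#'
#' A marker is positive when at least `threshold` percent of cells stain
#' in one or both populations (inclusive).
#'
#' @param pct_pop1,pct_pop2 percent-positive values on the 0-100 scale
#' @param threshold cutoff in percent (default 5.5)
#' @return logical
#' @export
classify_positive <- function(pct_pop1, pct_pop2, threshold = 5.5) {
  stopifnot(all(pct_pop1 >= 0 & pct_pop1 <= 100, na.rm = TRUE),
            all(pct_pop2 >= 0 & pct_pop2 <= 100, na.rm = TRUE))
  pmax(pct_pop1, pct_pop2) >= threshold
}

#' Fold increase in percent positive with a floored denominator
#'
#' @param pct_plt numerator percent (labelled population)
#' @param pct_fcs denominator percent (reference population)
#' @param floor denominator floor in percentage points (default 0.5)
#' @return fold, with attribute `floored` marking values where the floor
#'   was applied
#' @export
fold_increase <- function(pct_plt, pct_fcs, floor = 0.5) {
  stopifnot(floor > 0)
  floored <- pct_fcs < floor
  fold <- pct_plt / pmax(pct_fcs, floor)
  attr(fold, "floored") <- floored
  fold
}

#' Per-marker significance test across donors
#'
#' Default is a two-group one-way ANOVA F-test (equivalent to an unpaired
#' two-sided t-test for two groups); a paired t-test is available for
#' paired donor designs. Degenerate input with zero variance in both
#' groups and equal means returns p = 1 by convention.
#'
#' @param pcts_plt,pcts_fcs per-donor percent-positive values
#' @param config `screen_config`
#' @return p-value
#' @export
test_marker <- function(pcts_plt, pcts_fcs, config = screen_config()) {
  if (length(pcts_plt) < 2 || length(pcts_fcs) < 2)
    stop("test error: need >= 2 donors per group")
  if (config$test == "paired-t") {
    if (length(pcts_plt) != length(pcts_fcs))
      stop("test error: paired test requires equal group lengths")
    d <- pcts_plt - pcts_fcs
    if (stats::sd(d) == 0)
      return(if (all(d == 0)) 1 else 0)
    return(stats::t.test(pcts_plt, pcts_fcs, paired = TRUE)$p.value)
  }
  y <- c(pcts_plt, pcts_fcs)
  g <- factor(rep(c("plt", "fcs"), c(length(pcts_plt), length(pcts_fcs))))
  if (stats::var(pcts_plt) == 0 && stats::var(pcts_fcs) == 0)
    return(if (mean(pcts_plt) == mean(pcts_fcs)) 1 else 0)
  fit <- stats::aov(y ~ g)
  summary(fit)[[1]][["Pr(>F)"]][1]
}

#' Enrichment filter
#'
#' Enriched iff fold increase >= `enrichment_fold_min` (inclusive) and
#' p-value < `alpha` (strict).
#'
#' @param fold fold increase
#' @param p p-value
#' @param config `screen_config`
#' @return logical
#' @export
flag_enriched <- function(fold, p, config = screen_config()) {
  !is.na(fold) & !is.na(p) &
    fold >= config$enrichment_fold_min & p < config$alpha
}

#' Stain index with robust background correction
#'
#' `SI = (median(stained) - median(control)) / (2 * rSD(control))` with
#' `rSD = 1.4826 x MAD`, a robust spread that keeps the index stable under
#' the heavy-tailed background typical of autofluorescent cells. Undefined
#' (NA) when the control spread is zero or either input is empty.
#'
#' @param stained event matrix or reporter-intensity vector of the stained
#'   sample
#' @param control matching control sample
#' @param config `gate_config` (channel map)
#' @param robust use 1.4826*MAD (default) or the sample SD
#' @return stain index, or `NA_real_` when undefined
#' @export
stain_index <- function(stained, control, config = gate_config(),
                        robust = TRUE) {
  xs <- if (is.matrix(stained) || is.data.frame(stained))
    .chan(as.matrix(stained), config, "reporter") else as.numeric(stained)
  xc <- if (is.matrix(control) || is.data.frame(control))
    .chan(as.matrix(control), config, "reporter") else as.numeric(control)
  if (length(xs) == 0 || length(xc) == 0) return(NA_real_)
  spread <- if (robust) stats::mad(xc) else stats::sd(xc)
  if (!is.finite(spread) || spread == 0) return(NA_real_)
  (stats::median(xs) - stats::median(xc)) / (2 * spread)
}

#' Fold increase in stain index
#'
#' @param si_plt,si_fcs stain indices of the two populations
#' @return `si_plt / si_fcs`, or `NA_real_` when `si_fcs <= 0` or either
#'   input is undefined (a ratio of separations is meaningless then)
#' @export
si_fold <- function(si_plt, si_fcs) {
  ifelse(is.na(si_plt) | is.na(si_fcs) | si_fcs <= 0,
         NA_real_, si_plt / si_fcs)
}

#' Per-population background statistics from control wells
#'
#' @param control_reporter named list (by population) of reporter-intensity
#'   vectors pooled over the unstained/isotype control wells
#' @param low_n_threshold flag populations whose pooled control has fewer
#'   events than this (default 100)
#' @return data.frame: population, bg_mfi, bg_rsd, n_events, low_n; with
#'   attribute `ratio` = bg MFI of the first population over the second
#'   (with the reference/unlabelled population listed first this is the
#'   reference-over-labelled background ratio)
#' @export
background_stats <- function(control_reporter, low_n_threshold = 100L) {
  if (length(control_reporter) == 0)
    stop("no control wells identified in layout")
  df <- do.call(rbind, lapply(names(control_reporter), function(pn) {
    x <- control_reporter[[pn]]
    data.frame(population = pn,
               bg_mfi = if (length(x) > 0) stats::median(x) else NA_real_,
               bg_rsd = if (length(x) > 0) stats::mad(x) else NA_real_,
               n_events = length(x),
               low_n = length(x) < low_n_threshold,
               stringsAsFactors = FALSE)
  }))
  if (nrow(df) >= 2)
    attr(df, "ratio") <- df$bg_mfi[1] / df$bg_mfi[2]
  df
}

#' Relative expression by the delta-delta-Ct method
#'
#' `dCt = mean(Ct_target) - mean(Ct_reference)` per condition;
#' `fold = 2^-(dCt_plt - dCt_fcs)`.
#'
#' @param ct_target_plt,ct_ref_plt,ct_target_fcs,ct_ref_fcs replicate Ct
#'   values for target and reference gene in the two conditions
#' @return relative expression fold of condition PLT over FCS
#' @export
ddct_fold <- function(ct_target_plt, ct_ref_plt, ct_target_fcs, ct_ref_fcs) {
  args <- list(ct_target_plt, ct_ref_plt, ct_target_fcs, ct_ref_fcs)
  if (any(vapply(args, length, integer(1)) == 0))
    stop("replicate lists must be non-empty")
  if (!all(vapply(args, function(x) all(is.finite(x)), logical(1))))
    stop("Ct values must be finite")
  dct_plt <- mean(ct_target_plt) - mean(ct_ref_plt)
  dct_fcs <- mean(ct_target_fcs) - mean(ct_ref_fcs)
  2^-(dct_plt - dct_fcs)
}
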