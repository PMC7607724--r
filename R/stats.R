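# Shared machinery -----------------------------------------------------------

# one-sample F on contrast scores: F(1, n-1) = t^2, partial eta^2 from the
# corresponding SS partition (SS_eff = n*mean^2, SS_err = (n-1)*var).
contrast_f <- function(d, effect) {
  n <- length(d)
  if (n < 2) stop("need at least 2 participants", call. = FALSE)
  m <- mean(d)
  v <- stats::var(d)
  ss_eff <- n * m^2
  ss_err <- (n - 1) * v
  if (ss_err <= .Machine$double.eps * max(1, ss_eff)) {
    if (abs(m) <= sqrt(.Machine$double.eps)) {
      warning(sprintf("effect '%s': zero variance and zero mean; F set to 0",
                      effect), call. = FALSE)
      return(anova_row(effect, 0, 1L, n - 1L, 1, 0))
    }
    warning(sprintf("effect '%s': zero error variance; F is infinite",
                    effect), call. = FALSE)
    return(anova_row(effect, Inf, 1L, n - 1L, 0, 1))
  }
  f <- ss_eff / (ss_err / (n - 1))
  anova_row(effect, f, 1L, n - 1L,
            stats::pf(f, 1, n - 1, lower.tail = FALSE),
            ss_eff / (ss_eff + ss_err))
}

anova_row <- function(effect, f, df1, df2, p, peta) {
  data.frame(effect = effect, F = f, df_num = df1, df_den = df2,
             p = p, partial_eta_sq = peta, stringsAsFactors = FALSE)
}

table_cells <- function(table) {
  miss <- setdiff(condition_cells, names(table))
  if (length(miss))
    stop("condition table is missing cell(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(!stats::complete.cases(table[condition_cells]))
  if (length(bad))
    stop(sprintf("incomplete table: participant %s has a missing cell",
                 table$participant[bad[1]]), call. = FALSE)
  as.matrix(table[condition_cells])
}

# per-participant contrast scores for the three within effects
within_contrasts <- function(m) {
  list(
    Clarity = (m[, "LA_low"] + m[, "HA_low"]) / 2 -
      (m[, "LA_high"] + m[, "HA_high"]) / 2,
    Ambiguity = (m[, "HA_high"] + m[, "HA_low"]) / 2 -
      (m[, "LA_high"] + m[, "LA_low"]) / 2,
    `Clarity:Ambiguity` = (m[, "HA_low"] - m[, "LA_low"]) -
      (m[, "HA_high"] - m[, "LA_high"])
  )
}

# Public operations -----------------------------------------------------------

#' 2 x 2 repeated-measures ANOVA
#'
#' Within-subject ANOVA on a complete participant x 4-cell condition table
#' (factors Clarity and Ambiguity, 2 levels each).  Each effect is tested
#' via its per-participant contrast score (main effects: difference of
#' level means; interaction: double difference), giving `F(1, n-1)` equal
#' to the squared paired t statistic, with partial eta squared
#' `SS_effect / (SS_effect + SS_error)`.  With two-level factors sphericity
#' is trivially satisfied, so no correction is applied.  Degenerate
#' zero-variance contrasts yield `F = 0, p = 1` (zero mean) with a warning.
#'
#' @param table a condition table from [build_condition_table()] (columns
#'   `LA_high`, `HA_high`, `LA_low`, `HA_low`).
#' @return data.frame of 3 rows: Clarity, Ambiguity, Clarity:Ambiguity.
#' @export
rmanova_2x2 <- function(table) {
  m <- table_cells(table)
  ds <- within_contrasts(m)
  do.call(rbind, Map(contrast_f, ds, names(ds)))
}

#' Simple effect of one factor at a fixed level of the other
#'
#' One-factor repeated-measures ANOVA on the two cells at the fixed level;
#' `F(1, n-1)` equals the squared paired t on those cells (per-level paired
#' error term).
#'
#' @param table a condition table.
#' @param fixed_factor `"clarity"` or `"ambiguity"`; the other factor's
#'   effect is tested at the given level.
#' @param fixed_level level of the fixed factor (`"high_snr"`/`"low_snr"`
#'   or `"LA"`/`"HA"`).
#' @return a one-row ANOVA data.frame.
#' @export
simple_effect <- function(table, fixed_factor = c("clarity", "ambiguity"),
                          fixed_level) {
  fixed_factor <- match.arg(fixed_factor)
  m <- table_cells(table)
  if (fixed_factor == "clarity") {
    lev <- sub("_snr$", "", fixed_level)
    stopifnot(lev %in% c("high", "low"))
    d <- m[, paste0("HA_", lev)] - m[, paste0("LA_", lev)]
    eff <- sprintf("Ambiguity at %s", fixed_level)
  } else {
    stopifnot(fixed_level %in% c("LA", "HA"))
    d <- m[, paste0(fixed_level, "_low")] - m[, paste0(fixed_level, "_high")]
    eff <- sprintf("Clarity at %s", fixed_level)
  }
  contrast_f(d, eff)
}

#' Split-plot mixed ANOVA pooling two experiments
#'
#' The 2 x 2 within design crossed with Experiment as a between-subjects
#' factor.  The between effect is tested against between-subject error
#' (per-participant grand means); each within effect and its x Experiment
#' crossing are tested against the pooled within-group variance of that
#' effect's contrast scores.  All denominators have `N - 2` degrees of
#' freedom.  Group means are weighted equally (least-squares/Type III
#' convention), which coincides with the classical split-plot partition for
#' equal group sizes.
#'
#' @param tables list of exactly two condition tables (experiments 1 and 2).
#' @return data.frame of 7 rows: Experiment, the 3 within effects, and
#'   their x Experiment crossings.
#' @export
pooled_mixed_anova <- function(tables) {
  if (length(tables) != 2)
    stop("exactly two groups (experiments) are supported", call. = FALSE)
  ms <- lapply(tables, table_cells)
  n1 <- nrow(ms[[1]]); n2 <- nrow(ms[[2]])
  N <- n1 + n2
  if (n1 < 2 || n2 < 2) stop("each group needs >= 2 participants",
                             call. = FALSE)
  out <- list()

  # between-subjects effect on per-participant grand means (x4 cells for SS)
  gm <- lapply(ms, rowMeans)
  mbar <- vapply(gm, mean, numeric(1))
  pooled_ss <- sum(vapply(gm, function(g) sum((g - mean(g))^2), numeric(1)))
  grand <- sum(unlist(gm)) / N
  ss_b <- 4 * (n1 * (mbar[1] - grand)^2 + n2 * (mbar[2] - grand)^2)
  ss_e <- 4 * pooled_ss
  if (ss_e <= .Machine$double.eps * max(1, ss_b)) {
    warning("Experiment: zero between-subject error variance", call. = FALSE)
    out$Experiment <- anova_row("Experiment", if (ss_b > 0) Inf else 0,
                                1L, N - 2L, if (ss_b > 0) 0 else 1,
                                if (ss_b > 0) 1 else 0)
  } else {
    f <- ss_b / (ss_e / (N - 2))
    out$Experiment <- anova_row("Experiment", f, 1L, N - 2L,
                                stats::pf(f, 1, N - 2, lower.tail = FALSE),
                                ss_b / (ss_b + ss_e))
  }

  ds <- Map(function(m) within_contrasts(m), ms)
  for (eff in names(ds[[1]])) {
    d1 <- ds[[1]][[eff]]; d2 <- ds[[2]][[eff]]
    sp2 <- (sum((d1 - mean(d1))^2) + sum((d2 - mean(d2))^2)) / (N - 2)
    # main within effect: unweighted mean of group means
    est_main <- (mean(d1) + mean(d2)) / 2
    se2_main <- sp2 * (1 / n1 + 1 / n2) / 4
    # crossing with Experiment: group difference
    est_int <- mean(d1) - mean(d2)
    se2_int <- sp2 * (1 / n1 + 1 / n2)
    for (spec_ in list(list(est = est_main, se2 = se2_main, label = eff),
                       list(est = est_int, se2 = se2_int,
                            label = paste0(eff, ":Experiment")))) {
      if (se2_ok <- spec_$se2 > .Machine$double.eps * max(1, spec_$est^2)) {
        f <- spec_$est^2 / spec_$se2
        out[[spec_$label]] <- anova_row(spec_$label, f, 1L, N - 2L,
          stats::pf(f, 1, N - 2, lower.tail = FALSE), f / (f + N - 2))
      } else {
        warning(sprintf("effect '%s': zero error variance", spec_$label),
                call. = FALSE)
        z <- abs(spec_$est) <= sqrt(.Machine$double.eps)
        out[[spec_$label]] <- anova_row(spec_$label, if (z) 0 else Inf,
                                        1L, N - 2L, if (z) 1 else 0,
                                        if (z) 0 else 1)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Is the Clarity effect larger than the Ambiguity effect?
#'
#' Per participant, the Clarity effect `d_C` (low-SNR minus high-SNR cell
#' means) and the Ambiguity effect `d_A` (HA minus LA cell means) are
#' formed; the null `mean(d_C - d_A) = 0` is tested by a one-sample
#' `F(1, n-1)` (the squared one-sample t).  Signed differences by default;
#' `abs_effects = TRUE` compares effect magnitudes instead.
#'
#' @param tables one condition table or a list of tables (participants are
#'   concatenated, e.g. to pool experiments).
#' @param abs_effects compare `|d_C|` and `|d_A|` instead of signed scores.
#' @return a one-row ANOVA data.frame.
#' @export
effect_magnitude_contrast <- function(tables, abs_effects = FALSE) {
  if (is.data.frame(tables)) tables <- list(tables)
  ms <- lapply(tables, table_cells)
  d_c <- unlist(lapply(ms, function(m) within_contrasts(m)$Clarity))
  d_a <- unlist(lapply(ms, function(m) within_contrasts(m)$Ambiguity))
  if (abs_effects) {
    d_c <- abs(d_c); d_a <- abs(d_a)
  }
  contrast_f(d_c - d_a, "Clarity vs Ambiguity magnitude")
}

#' Partial correlation controlling for one covariate
#'
#' Residualizes `x` and `y` on `[1, covariate]` by least squares and
#' reports the Pearson correlation of the residuals, with `df = n - 3` and
#' a two-sided p value from `t = r * sqrt(df / (1 - r^2))`.
#'
#' @param x,y numeric vectors (per-participant values).
#' @param covariate numeric or two-level covariate (e.g. experiment label).
#' @return list with `r`, `p`, `df`, `n`.
#' @export
partial_correlation <- function(x, y, covariate) {
  n <- length(x)
  if (length(y) != n || length(covariate) != n)
    stop("x, y and covariate must have equal length", call. = FALSE)
  if (n < 4) stop("need at least 4 observations", call. = FALSE)
  z <- as.numeric(as.factor(covariate))
  if (stats::var(z) == 0)
    stop("covariate is constant; use a plain correlation", call. = FALSE)
  rx <- stats::lm.fit(cbind(1, z), x)$residuals
  ry <- stats::lm.fit(cbind(1, z), y)$residuals
  r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  r <- max(-1, min(1, r))  # guard against rounding past unity
  df <- n - 3
  tstat <- if (abs(r) == 1) Inf * sign(r) else r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  list(r = r, p = p, df = df, n = n)
}
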