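#' Growth-curve doubling time
#'
#' Fits log(OD600) against time by least squares over the exponential-phase
#' window and returns \eqn{\ln 2 / slope}. With exactly two points in the
#' window this reduces algebraically to the two-point formula
#' \eqn{\Delta t \cdot \log 2 / \log(OD_2 / OD_1)}. A non-positive slope
#' signals no growth (NA with a warning). The result is invariant to
#' multiplying all OD values by a constant and to the logarithm base.
#'
#' @param times numeric, hours (strictly increasing).
#' @param od600 positive OD600 readings.
#' @param window numeric c(lo, hi) fitting window, hours (default 3 to 7.5).
#' @return doubling time, hours (NA if not growing).
#' @examples
#' doubling_time(c(3, 7.5), c(0.1, 0.8))  # 3 doublings in 4.5 h -> 1.5 h
#' @export
doubling_time <- function(times, od600, window = c(3, 7.5)) {
  stopifnot(length(times) == length(od600))
  if (any(od600 <= 0)) stop("OD600 values must be strictly positive")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  sel <- times >= window[1] & times <= window[2]
  if (sum(sel) < 2) stop("need at least two samples inside the fitting window")
  fit <- stats::lm(log(od600[sel]) ~ times[sel])
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 0) {
    warning("non-positive log-OD slope: no growth in window")
    return(NA_real_)
  }
  log(2) / slope
}

#' Relative expression by the delta delta Ct method
#'
#' Per replicate, \eqn{\Delta Ct = Ct_{target} - Ct_{reference}}; the
#' strain-level relative expression is
#' \eqn{2^{-(\overline{\Delta Ct}_{strain} - \overline{\Delta Ct}_{baseline})}},
#' so the baseline strain is 1 by construction. Per-replicate values (for
#' plotting and testing) use the same baseline mean. Amplification
#' efficiency is fixed at 2 per cycle. The output is invariant to adding a
#' constant to every Ct.
#'
#' @param table data.frame with columns strain, replicate, ct_target,
#'   ct_reference (the reference is typically a stable housekeeping
#'   transcript such as TDH3).
#' @param baseline_strain strain defining expression 1 (default "WT").
#' @return list with \code{per_replicate} (data.frame: strain, replicate,
#'   delta_ct, rel_expr) and \code{per_strain} (data.frame: strain,
#'   rel_expr).
#' @export
delta_delta_ct <- function(table, baseline_strain = "WT") {
  need <- c("strain", "replicate", "ct_target", "ct_reference")
  if (!all(need %in% names(table))) {
    stop("table must have columns strain, replicate, ct_target, ct_reference")
  }
  if (any(!is.finite(table$ct_target)) || any(!is.finite(table$ct_reference))) {
    stop("missing or non-finite Ct values (reference gene absent?)")
  }
  if (!baseline_strain %in% table$strain) {
    stop(sprintf("baseline strain '%s' not present", baseline_strain))
  }
  dct <- table$ct_target - table$ct_reference
  base <- mean(dct[table$strain == baseline_strain])
  per_rep <- data.frame(strain = table$strain, replicate = table$replicate,
                        delta_ct = dct, rel_expr = 2^(-(dct - base)),
                        stringsAsFactors = FALSE)
  strain_means <- tapply(dct, table$strain, mean)
  per_strain <- data.frame(strain = names(strain_means),
                           rel_expr = as.numeric(2^(-(strain_means - base))),
                           stringsAsFactors = FALSE)
  rownames(per_strain) <- NULL
  list(per_replicate = per_rep, per_strain = per_strain)
}

#' Normalize band intensities to total protein
#'
#' @param band_intensity numeric band intensities (one per lane).
#' @param total_protein_signal matching total-protein signals (> 0).
#' @return elementwise ratio.
#' @export
normalize_to_total <- function(band_intensity, total_protein_signal) {
  stopifnot(length(band_intensity) == length(total_protein_signal))
  bad <- which(total_protein_signal == 0)
  if (length(bad)) {
    nm <- names(total_protein_signal)[bad] %||% as.character(bad)
    stop(sprintf("zero total-protein signal in lane(s): %s",
                 paste(nm, collapse = ", ")))
  }
  band_intensity / total_protein_signal
}

#' Normalize per-strain values to the wild type
#'
#' Divides every value by the mean of the wild-type strain's values, so the
#' WT mean is 1.
#'
#' @param values numeric measurements.
#' @param strains character strain of each value.
#' @param wt_strain baseline strain name (default "WT").
#' @return numeric fold vs WT, same order as \code{values}.
#' @export
normalize_to_wt <- function(values, strains, wt_strain = "WT") {
  stopifnot(length(values) == length(strains))
  wt <- values[strains == wt_strain]
  if (!length(wt)) stop(sprintf("no samples for WT strain '%s'", wt_strain))
  m <- mean(wt)
  if (m == 0) stop(sprintf("WT strain '%s' has zero mean", wt_strain))
  values / m
}

check_group <- function(x, name) {
  if (length(x) < 2) stop(sprintf("group '%s' has fewer than 2 observations", name))
  if (stats::sd(x) == 0) stop(sprintf("group '%s' has zero variance", name))
}

#' Welch's two-sample t-test
#'
#' @param x,y numeric vectors (each n >= 2 with nonzero variance).
#' @param names character length-2 group names (for error messages).
#' @return list(statistic, df, p_value, mean_x, mean_y, method).
#' @export
welch_t <- function(x, y, names = c("group1", "group2")) {
  check_group(x, names[1])
  check_group(y, names[2])
  tt <- stats::t.test(x, y)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_x = mean(x), mean_y = mean(y),
       method = "Welch two-sample t-test")
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2
#'   with nonzero variance).
#' @param alpha significance level recorded on the output (default 0.05).
#' @return list(F, df, p_value, tukey (data.frame: comparison, diff, lwr,
#'   upr, p_adj), alpha, method).
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  for (nm in names(groups)) check_group(groups[[nm]], nm)
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)), levels = names(groups))
  )
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], stringsAsFactors = FALSE)
  rownames(tukey) <- NULL
  list(F = an[["F value"]][1], df = an[["Df"]],
       p_value = an[["Pr(>F)"]][1], tukey = tukey, alpha = alpha,
       method = "one-way ANOVA + Tukey HSD")
}
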