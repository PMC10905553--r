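#' Mann-Whitney U test (exact or tie-corrected normal)
#'
#' Computes the U statistic from midrank sums and a two-sided p-value:
#' exactly, from the full permutation distribution of U, when the combined
#' sample size is at most `exact_max_n` and there are no ties; otherwise by
#' the normal approximation with tie correction and continuity correction.
#' The two-sided p doubles the smaller one-sided tail, capped at 1. The
#' exact/approximate switch is deterministic and recorded in `method`.
#'
#' @param a,b numeric samples (group 1 and group 2).
#' @param labels character pair naming the groups.
#' @param exact_max_n largest combined sample size for the exact method.
#' @return object of class `group_comparison` with fields `group_labels`,
#'   `n1`, `n2`, `means`, `sds`, `u_statistic` (U for group 1),
#'   `p_two_sided`, `method`, `fold_difference` (mean1/mean2) and the raw
#'   `values`.
#' @export
mann_whitney <- function(a, b, labels = c("group1", "group2"),
                         exact_max_n = 20L) {
  a <- as.numeric(a); b <- as.numeric(b)
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1L || n2 < 1L) stop("both groups need >= 1 value", call. = FALSE)
  pooled <- c(a, b)
  if (any(!is.finite(pooled))) stop("values must be finite", call. = FALSE)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (!ties && n1 + n2 <= exact_max_n) {
    method <- "exact"
    p_low <- pwilcox(u, n1, n2)
    p_high <- 1 - pwilcox(u - 1, n1, n2)
    p <- min(1, 2 * min(p_low, p_high))
  } else {
    method <- "normal_tie_corrected"
    n <- n1 + n2
    tab <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tab^3 - tab) / (n * (n - 1)))
    if (sigma2 <= 0)
      stop("degenerate data: all pooled values identical, U variance is zero",
           call. = FALSE)
    mu <- n1 * n2 / 2
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  sds <- c(if (n1 > 1) sd(a) else NA_real_, if (n2 > 1) sd(b) else NA_real_)
  flag <- NULL
  if (anyNA(sds)) {
    flag <- "single-value group: SD reported as 0-width"
    sds[is.na(sds)] <- 0
  }
  structure(list(group_labels = labels, n1 = n1, n2 = n2,
                 means = c(mean(a), mean(b)), sds = sds,
                 u_statistic = u, p_two_sided = p, method = method,
                 fold_difference = mean(a) / mean(b),
                 values = list(a, b), flag = flag),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> %s (n=%d): %.4g +/- %.4g vs %s (n=%d): %.4g +/- %.4g\n",
    x$group_labels[1], x$n1, x$means[1], x$sds[1],
    x$group_labels[2], x$n2, x$means[2], x$sds[2]))
  cat(sprintf("  fold difference %.3g; Mann-Whitney U = %g, two-sided p = %.4g (%s)\n",
              x$fold_difference, x$u_statistic, x$p_two_sided, x$method))
  if (!is.null(x$flag)) cat("  note:", x$flag, "\n")
  invisible(x)
}

#' Summarise per-animal values by group and compare
#'
#' Takes a long table of per-animal measurements (e.g. SEI values) and two
#' group labels; reports group means, standard deviations (n-1
#' denominator), the fold difference of the means, and the Mann-Whitney
#' comparison. Use [plot.group_comparison()] for a dot plot with group
#' mean and SD whiskers.
#'
#' @param table data.frame with columns `group` and `value` (extra columns
#'   such as `animal_id` are carried along).
#' @param groups character pair; first is the numerator of the fold
#'   difference.
#' @return a `group_comparison`.
#' @export
summarize_groups <- function(table, groups) {
  stopifnot(is.data.frame(table), all(c("group", "value") %in% names(table)))
  if (length(groups) != 2L) stop("`groups` must name two groups", call. = FALSE)
  missing <- setdiff(groups, unique(table$group))
  if (length(missing) > 0L)
    stop("unknown group label(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  a <- table$value[table$group == groups[1]]
  b <- table$value[table$group == groups[2]]
  mann_whitney(a, b, labels = groups)
}

#' Dot plot of a two-group comparison
#'
#' Per-animal values as jittered points with group mean and mean +/- SD
#' whiskers, the conventional presentation for small-group preclinical
#' summaries.
#' @param x a `group_comparison`.
#' @param ylab y-axis label.
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot.group_comparison <- function(x, ylab = "value", ...) {
  df <- data.frame(
    group = factor(rep(x$group_labels, c(x$n1, x$n2)), levels = x$group_labels),
    value = c(x$values[[1]], x$values[[2]]))
  stats_df <- data.frame(
    group = factor(x$group_labels, levels = x$group_labels),
    mean = x$means, lo = x$means - x$sds, hi = x$means + x$sds)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, size = 2, alpha = 0.8) +
    ggplot2::geom_errorbar(data = stats_df,
                           ggplot2::aes(y = .data$mean, ymin = .data$lo,
                                        ymax = .data$hi),
                           width = 0.25, linewidth = 0.4) +
    ggplot2::geom_point(data = stats_df,
                        ggplot2::aes(y = .data$mean), shape = 3, size = 3) +
    ggplot2::labs(x = NULL, y = ylab,
                  subtitle = sprintf("Mann-Whitney two-sided p = %.3g (%s)",
                                     x$p_two_sided, x$method)) +
    ggplot2::theme_classic()
}

#' Evans blue standard curve
#'
#' Linear absorbance-vs-concentration calibration for the Evans blue dye
#' extravasation assay; a valid curve has positive slope.
#'
#' @param slope absorbance per (ug/mL).
#' @param intercept absorbance at zero dye.
#' @param r_squared coefficient of determination of the fit.
#' @return object of class `standard_curve`.
#' @export
standard_curve <- function(slope, intercept, r_squared = NA_real_) {
  if (!is.finite(slope) || slope <= 0)
    stop("a valid Evans blue standard curve has slope > 0", call. = FALSE)
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared), class = "standard_curve")
}

#' @rdname standard_curve
#' @param concentrations,absorbances dilution-series table to fit.
#' @export
fit_standard_curve <- function(concentrations, absorbances) {
  fit <- fit_calibration(concentrations, absorbances)
  standard_curve(fit$slope, fit$intercept, fit$r_squared)
}

#' Evans blue tissue content from absorbance
#'
#' Converts a 630 nm absorbance reading of a formamide tissue extract to
#' dye content per tissue mass: concentration `(A - intercept)/slope`
#' (ug/mL), times extract volume (mL), divided by tissue mass (g). A
#' negative inferred concentration is clamped to 0 with attribute
#' `clamped = TRUE`.
#'
#' @param absorbance_630 absorbance at 630 nm.
#' @param curve a `standard_curve`.
#' @param extract_volume_mL formamide extract volume (> 0).
#' @param tissue_mass_g wet tissue mass (> 0).
#' @return dye content in ug per g tissue.
#' @export
evans_blue_ug_per_g <- function(absorbance_630, curve, extract_volume_mL,
                                tissue_mass_g) {
  stopifnot(inherits(curve, "standard_curve"))
  if (extract_volume_mL <= 0 || tissue_mass_g <= 0)
    stop("extract volume and tissue mass must be > 0", call. = FALSE)
  conc <- (absorbance_630 - curve$intercept) / curve$slope
  clamped <- any(conc < 0)
  conc[conc < 0] <- 0
  out <- conc * extract_volume_mL / tissue_mass_g
  if (clamped) attr(out, "clamped") <- TRUE
  out
}
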