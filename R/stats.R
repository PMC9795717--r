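# Statistical comparisons used throughout the analyses: Mann-Whitney U
# with Bonferroni adjustment for the morphometric endpoints, two-sample
# Kolmogorov-Smirnov for curvature distributions, two-way ANOVA with
# Bonferroni post hoc tests for the orientation time courses, and
# ordinary least squares for the coverage-volume relationship.

.stat_result <- function(method, statistic, p, m = 1, n = NULL, note = NULL) {
  structure(list(method = method, statistic = statistic, p = p,
                 p_adjusted = bonferroni_adjust(p, m), m_comparisons = m,
                 n = n, note = note,
                 significant = bonferroni_adjust(p, m) < SIGNIFICANCE_LEVEL),
            class = "stat_result")
}

#' Bonferroni adjustment with explicit comparison count
#'
#' @param p raw p value(s)
#' @param m number of comparisons
#' @return `min(1, m * p)`
#' @export
bonferroni_adjust <- function(p, m = 1) pmin(1, m * p)

#' Two-sided Mann-Whitney U test
#'
#' Exact null distribution when both groups have n <= 8; otherwise the
#' normal approximation with tie correction (and continuity correction).
#' With all values tied across both groups the test is degenerate and
#' p = 1 is returned.
#'
#' @param a,b numeric samples
#' @param m_comparisons Bonferroni m for the adjusted p
#' @return `stat_result` with `statistic` = U (for the first sample)
#' @export
mann_whitney <- function(a, b, m_comparisons = 1) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  if (length(unique(c(a, b))) == 1)
    return(.stat_result("Mann-Whitney U", length(a) * length(b) / 2, 1,
                        m_comparisons, c(length(a), length(b)),
                        "all values tied"))
  exact <- length(a) <= 8 && length(b) <= 8 && !any(duplicated(c(a, b)))
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  .stat_result("Mann-Whitney U", unname(wt$statistic), wt$p.value,
               m_comparisons, c(length(a), length(b)))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs; the
#' asymptotic two-sided p value is reported (appropriate for the large
#' vertex-count curvature samples this is used on).
#'
#' @param a,b numeric samples
#' @param m_comparisons Bonferroni m
#' @return `stat_result` with `statistic` = D
#' @export
ks_two_sample <- function(a, b, m_comparisons = 1) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  kt <- suppressWarnings(ks.test(a, b, exact = FALSE))
  .stat_result("two-sample KS", unname(kt$statistic), kt$p.value,
               m_comparisons, c(length(a), length(b)))
}

#' Two-way ANOVA with Bonferroni post hoc comparisons
#'
#' Fits `value ~ day * location` (both factors), reports type-II F tests
#' for the main effects and interaction, and Bonferroni-adjusted
#' pairwise comparisons of location within each day (estimated marginal
#' means). Empty cells are an error naming the cell; a response without
#' variance is flagged instead of tested.
#'
#' @param values numeric response (e.g. tilt angles)
#' @param day,location factors (coerced)
#' @return list of class `anova_result`: `anova` (data.frame: term, F,
#'   p), `posthoc` (data.frame: day, contrast, estimate, p_adjusted),
#'   `zero_variance`
#' @export
two_way_anova_bonferroni <- function(values, day, location) {
  day <- factor(day); location <- factor(location)
  if (nlevels(day) < 2 || nlevels(location) < 2)
    stop("need at least 2 levels per factor")
  tab <- table(day, location)
  if (any(tab == 0)) {
    bad <- which(tab == 0, arr.ind = TRUE)[1, ]
    stop("empty cell: day=", levels(day)[bad[1]],
         ", location=", levels(location)[bad[2]])
  }
  if (var(values) == 0) {
    return(structure(list(anova = NULL, posthoc = NULL, zero_variance = TRUE),
                     class = "anova_result"))
  }
  dat <- data.frame(value = values, day = day, location = location)
  fit <- lm(value ~ day * location, data = dat)
  an <- car::Anova(fit, type = 2)
  terms <- rownames(an)
  keep <- terms != "Residuals"
  anova_df <- data.frame(term = terms[keep], F = an[keep, "F value"],
                         p = an[keep, "Pr(>F)"])
  emm <- emmeans::emmeans(fit, ~ location | day)
  ph <- summary(emmeans::contrast(emm, method = "pairwise",
                                  adjust = "bonferroni"))
  posthoc <- data.frame(day = ph$day, contrast = as.character(ph$contrast),
                        estimate = ph$estimate, p_adjusted = ph$p.value)
  structure(list(anova = anova_df, posthoc = posthoc, zero_variance = FALSE),
            class = "anova_result")
}

#' Ordinary least-squares fit of y on x
#'
#' Used for the coverage-ratio vs sprout-volume regression. A constant
#' response yields slope 0 and r^2 = 0; a constant predictor is an
#' error.
#'
#' @param x,y numeric vectors, `length >= 2`
#' @return list: `slope`, `intercept`, `r_squared`, `n`
#' @export
linear_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (var(x) == 0) stop("x is constant; no regression possible")
  if (var(y) == 0)
    return(list(slope = 0, intercept = mean(y), r_squared = 0,
                n = length(x)))
  fit <- lm(y ~ x)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2, n = length(x))
}

#' @export
print.stat_result <- function(x, ...) {
  cat(x$method, ": statistic =", signif(x$statistic, 4),
      ", p =", signif(x$p, 4))
  if (x$m_comparisons > 1)
    cat(" (adjusted ", signif(x$p_adjusted, 4), ", m = ",
        x$m_comparisons, ")", sep = "")
  cat(if (x$significant) " *significant*" else "", "\n")
  invisible(x)
}
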