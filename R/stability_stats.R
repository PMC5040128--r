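#' Relative error of a measurement against a reference
#'
#' `RE = |D_x - D_r| / D_r`: the fractional deviation of a fractal
#' dimension from its reference value.
#'
#' @param d_x measured value(s).
#' @param d_r reference value(s), nonzero.
#' @return Non-negative relative error(s); 0 iff `d_x == d_r`.
#' @export
relative_error <- function(d_x, d_r) {
  if (any(d_r == 0)) stop("reference value must be nonzero", call. = FALSE)
  abs(d_x - d_r) / abs(d_r)
}

#' Relative standard deviation (coefficient of variation)
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.
#'
#' @param values numeric vector, length >= 2, nonzero mean.
#' @return `sd(values) / mean(values)`.
#' @export
rsd <- function(values) {
  if (length(values) < 2) stop("need >= 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("RSD undefined for zero mean", call. = FALSE)
  stats::sd(values) / m
}

#' Repeatability of a measurement across repeated acquisitions
#'
#' Per subject, the RSD of the values measured on that subject's repeated
#' acquisitions; summarized by the maximum and mean across subjects.
#'
#' @param per_subject_values named list, one numeric vector (length >= 2)
#'   per subject.
#' @return List: `per_subject` (named RSDs), `max_rsd`, `mean_rsd`.
#' @export
repeatability <- function(per_subject_values) {
  if (length(per_subject_values) == 0) stop("no subjects", call. = FALSE)
  lens <- vapply(per_subject_values, length, integer(1))
  if (any(lens < 2)) {
    stop("every subject needs >= 2 acquisitions", call. = FALSE)
  }
  per <- vapply(per_subject_values, rsd, numeric(1))
  list(per_subject = per, max_rsd = max(per), mean_rsd = mean(per))
}

#' Pairwise group comparisons after one-way ANOVA
#'
#' Fits a one-way ANOVA across groups and reports every unordered pair
#' with its mean difference, standard error, family-corrected p value
#' (Tukey's HSD) and simultaneous 95% confidence interval; the CI excludes
#' 0 iff the adjusted p is below 0.05. Degenerate input (all values
#' identical) yields p = 1 rather than NaN.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each with
#'   >= 2 values).
#' @return Data frame: `group1, group2, mean_difference, std_error,
#'   p_value, ci_lower, ci_upper`.
#' @export
pairwise_anova <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop("every group needs >= 2 values", call. = FALSE)
  }
  labs <- names(groups)
  if (is.null(labs)) labs <- paste0("G", seq_along(groups))
  df <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(labs, vapply(groups, length, integer(1))), levels = labs))
  pairs <- utils::combn(labs, 2)
  ns <- vapply(groups, length, integer(1)); names(ns) <- labs
  means <- vapply(groups, mean, numeric(1)); names(means) <- labs

  if (stats::var(df$y) == 0) {
    out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                      mean_difference = 0, std_error = 0, p_value = 1,
                      ci_lower = 0, ci_upper = 0)
    return(out)
  }
  fit <- stats::aov(y ~ g, data = df)
  tk <- stats::TukeyHSD(fit)$g
  mse <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
  out <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    key <- paste0(b, "-", a)     # TukeyHSD labels later-vs-earlier level
    row <- tk[key, ]
    data.frame(group1 = a, group2 = b,
               mean_difference = means[[a]] - means[[b]],
               std_error = sqrt(mse * (1 / ns[[a]] + 1 / ns[[b]])),
               p_value = unname(row["p adj"]),
               # CI of (a - b): negate and swap the Tukey (b - a) interval
               ci_lower = unname(-row["upr"]),
               ci_upper = unname(-row["lwr"]))
  })
  do.call(rbind, out)
}

#' Pearson correlation test
#'
#' Sample correlation with the two-sided t-test of the null hypothesis
#' that the population correlation is zero.
#'
#' @param x,y numeric vectors of equal length >= 3, each with nonzero
#'   variance.
#' @return List: `r`, `p_value`, `n`.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("need equal lengths >= 3", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
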