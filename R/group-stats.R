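#' Group summary: mean, SEM, n
#'
#' The per-group descriptive used throughout: mean over per-animal values
#' with the standard error of the mean (sample SD / sqrt(n)).
#'
#' @param values per-animal values.
#' @param label optional group label.
#' @return list of class `"group_summary"`: `label`, `values`, `mean`,
#'   `sem`, `sd`, `n`.
#' @export
group_summary <- function(values, label = NA) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("need at least one value")
  s <- if (length(values) > 1L) stats::sd(values) else NA_real_
  structure(list(label = label, values = values, mean = mean(values),
                 sem = s / sqrt(length(values)), sd = s,
                 n = length(values)),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("%s: %.4g +/- %.3g (mean +/- sem, n = %d)\n",
              if (is.na(x$label)) "group" else x$label, x$mean, x$sem, x$n))
  invisible(x)
}

#' Unpaired two-sample t-test
#'
#' Student's pooled-variance test by default (the variant that reproduces
#' the published significance calls on n = 3 groups); Welch available.
#' When both groups are constant with equal means the convention t = 0,
#' p = 1 is returned.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @param variant `"student"` (pooled) or `"welch"`.
#' @return list: `t`, `df`, `p`.
#' @export
unpaired_t <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    }
    stop("zero variance in both groups with unequal means")
  }
  ht <- stats::t.test(a, b, var.equal = (variant == "student"))
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided; exact p where the sample sizes allow, asymptotic otherwise
#' (ties force the asymptotic path silently).
#'
#' @param a,b numeric samples.
#' @return list: `D`, `p`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L) stop("each sample needs n >= 1")
  ht <- suppressWarnings(stats::ks.test(a, b))
  list(D = unname(ht$statistic), p = ht$p.value)
}

#' Simple linear fit with correlation
#'
#' OLS of y on x; `r` is the Pearson correlation, and R-squared equals r^2.
#'
#' @param x,y numeric vectors (n >= 3, x not constant).
#' @return list of class `"linear_fit"`: `slope`, `intercept`, `r`,
#'   `r_squared`, `n`, `sigma2` (residual variance), `p` (slope test).
#' @export
linear_fit <- function(x, y) {
  if (length(x) < 3L || length(x) != length(y)) {
    stop("need n >= 3 paired observations")
  }
  if (stats::var(x) == 0) stop("x is constant")
  fit <- stats::lm(y ~ x)
  # summary.lm warns on exact lines ("essentially perfect fit"); those are
  # legitimate inputs here
  s <- suppressWarnings(summary(fit))
  r <- stats::cor(x, y)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r = r, r_squared = s$r.squared, n = length(x),
                 sigma2 = s$sigma^2,
                 p = unname(s$coefficients[2L, 4L])),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("y = %.4g + %.4g x  (r = %.3f, R^2 = %.3f, n = %d)\n",
              x$intercept, x$slope, x$r, x$r_squared, x$n))
  invisible(x)
}

#' Test for equality of two regression slopes
#'
#' Pooled model `y ~ x * group`; the interaction term tests whether the two
#' slopes differ (equivalently the ANOVA comparison of the regressions).
#'
#' @param x1,y1 first dataset; @param x2,y2 second dataset.
#' @return list: `estimate` (slope difference), `F`, `t`, `df`, `p`.
#' @export
compare_slopes <- function(x1, y1, x2, y2) {
  if (stats::var(x1) == 0 || stats::var(x2) == 0) {
    stop("x is constant in one of the groups")
  }
  dat <- data.frame(x = c(x1, x2), y = c(y1, y2),
                    g = factor(rep(c("A", "B"), c(length(x1), length(x2)))))
  fit <- stats::lm(y ~ x * g, data = dat)
  s <- summary(fit)$coefficients
  row <- grep("^x:g", rownames(s))
  tval <- s[row, 3L]
  list(estimate = unname(s[row, 1L]), F = unname(tval^2),
       t = unname(tval), df = fit$df.residual,
       p = unname(s[row, 4L]))
}

#' Percent change between two group values
#'
#' `"vs_reference"` (the usual form): 100 * (reference - other) / reference,
#' positive for a decrease relative to the reference (adult) group.
#' `"vs_larger"` divides by whichever value is larger, the form occasionally
#' used for increases.
#'
#' @param reference reference-group value (e.g. adult mean).
#' @param other comparison-group value (e.g. aged mean).
#' @param convention `"vs_reference"` or `"vs_larger"`.
#' @return percent (positive = decrease vs reference under the default
#'   convention).
#' @export
percent_change <- function(reference, other,
                           convention = c("vs_reference", "vs_larger")) {
  convention <- match.arg(convention)
  den <- switch(convention,
                vs_reference = reference,
                vs_larger = pmax(abs(reference), abs(other)))
  if (any(den == 0)) stop("zero denominator in percent change")
  100 * (reference - other) / den
}
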