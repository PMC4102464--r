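#' Linearize qRT-PCR cycle-threshold differences
#'
#' `(1 + E)^dCT`: with amplification efficiency `E` each PCR cycle multiplies
#' product by `1 + E`, so a CT difference converts to a linear expression
#' ratio.
#'
#' @param delta_ct CT difference (control minus target, so higher expression
#'   gives larger values).
#' @param efficiency amplification efficiency `E` (> -1).
#' @return linear relative expression.
#' @examples
#' linearize_qpcr(3, 1)  # 8
#' @export
linearize_qpcr <- function(delta_ct, efficiency) {
  if (any(efficiency <= -1)) stop_arg("efficiency must exceed -1")
  (1 + efficiency)^delta_ct
}

#' Delta-delta-CT standardization
#'
#' Per sample, `dCT = CT_control - CT_target`; `ddCT` subtracts the
#' calibrator sample's `dCT` for the same gene; relative expression is
#' `(1 + E)^ddCT`, making the calibrator exactly 1. The orientation puts
#' higher expression at higher values so the linearized data correlate
#' positively with RPKM.
#'
#' @param qpcr data.frame with columns `sample`, `gene`, `ct_target`,
#'   `ct_control`, `efficiency`.
#' @param calibrator sample id used as the reference.
#' @return the input with added columns `delta_ct`, `ddct`,
#'   `relative_expression`.
#' @export
ddct_standardize <- function(qpcr, calibrator) {
  need <- c("sample", "gene", "ct_target", "ct_control", "efficiency")
  if (!all(need %in% names(qpcr))) stop_arg("missing qPCR columns")
  if (!calibrator %in% qpcr$sample) stop_arg("calibrator sample not present")
  if (any(is.na(qpcr$ct_control))) stop_arg("missing control CT")
  qpcr$delta_ct <- qpcr$ct_control - qpcr$ct_target
  cal <- qpcr[qpcr$sample == calibrator, ]
  m <- match(qpcr$gene, cal$gene)
  if (any(is.na(m))) stop_arg("calibrator lacks some genes")
  qpcr$ddct <- qpcr$delta_ct - cal$delta_ct[m]
  qpcr$relative_expression <- linearize_qpcr(qpcr$ddct, qpcr$efficiency)
  qpcr
}

#' Log-log ordinary least squares with named exclusions
#'
#' Both variables are log-transformed (base 10 by default) to meet
#' normality assumptions; excluded points (e.g. a named outlier gene) are
#' removed before fitting. The F statistic uses the simple-regression form
#' `F = (r2 / (1 - r2)) * (n - 2)` on 1 and n-2 degrees of freedom.
#'
#' @param x,y positive values.
#' @param base logarithm base.
#' @param exclusions indices or names (of `x`) to drop before fitting.
#' @return list: `slope`, `intercept`, `r_squared`, `f_statistic`,
#'   `p_value`, `n`, `excluded`.
#' @export
regress_loglog <- function(x, y, base = 10, exclusions = NULL) {
  keep <- rep(TRUE, length(x))
  excl_ids <- character(0)
  if (!is.null(exclusions)) {
    if (is.character(exclusions)) {
      keep[names(x) %in% exclusions] <- FALSE
      excl_ids <- intersect(exclusions, names(x))
    } else {
      keep[exclusions] <- FALSE
      excl_ids <- as.character(exclusions)
    }
  }
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop_arg("need at least 3 points after exclusions")
  if (any(x <= 0) || any(y <= 0)) stop_arg("values must be positive")
  lx <- log(x, base); ly <- log(y, base)
  fit <- lm(ly ~ lx)
  r2 <- stats::cor(lx, ly)^2
  n <- length(x)
  f <- (r2 / (1 - r2)) * (n - 2)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2, f_statistic = f,
       p_value = stats::pf(f, 1, n - 2, lower.tail = FALSE),
       n = n, excluded = excl_ids)
}

#' Convert a 2C DNA mass to a haploid genome length
#'
#' Uses 1 pg of diploid nuclear DNA = 978 million base pairs, so the haploid
#' length is `(2C / 2) * 978e6` bp.
#'
#' @param two_c_pg 2C value in picograms (> 0).
#' @return haploid genome length in bp.
#' @examples
#' pg_to_haploid_bp(2.08)  # ~1.02e9
#' @export
pg_to_haploid_bp <- function(two_c_pg) {
  if (any(two_c_pg <= 0)) stop_arg("2C mass must be positive")
  (two_c_pg / 2) * 978e6
}

#' Mean and standard error
#'
#' Arithmetic mean and `sd / sqrt(n)` with the n-1 sample standard
#' deviation.
#'
#' @param values numeric vector (length >= 2).
#' @return named vector `mean`, `se`.
#' @export
mean_se <- function(values) {
  if (length(values) < 2) stop_arg("need at least 2 values")
  c(mean = mean(values), se = sd(values) / sqrt(length(values)))
}
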