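# Verification statistics: object-matched mean IoU, outlier-screened Pearson
# agreement, Lilliefors normality testing, and broad-sense heritability from
# one-way variance components.

#' Object-matched mean intersection over union
#'
#' Objects are matched one-to-one by maximal pixel overlap (greedy, descending
#' overlap); each matched pair contributes its IoU, unmatched truth or
#' prediction objects contribute 0, and the mean is taken over
#' `max(n_truth, n_pred)` entries.
#'
#' @param pred,truth [labeled_mask()]s of identical shape.
#' @return list: `miou`, and `matches` (per-object table: truth label, matched
#'   pred label or NA, intersection, union, iou).
#' @export
mean_iou <- function(pred, truth) {
  stopifnot(inherits(pred, "labeled_mask"), inherits(truth, "labeled_mask"))
  if (!all(dim(pred$labels) == dim(truth$labels)))
    stop("masks must share the same shape")
  np <- pred$n_seeds; nt <- truth$n_seeds
  if (np == 0L && nt == 0L) {
    warning("both masks are empty; mIoU defined as 1")
    return(list(miou = 1, matches = data.frame()))
  }
  at <- tabulate(truth$labels[truth$labels > 0L], nt)
  ap <- tabulate(pred$labels[pred$labels > 0L], np)
  sel <- truth$labels > 0L & pred$labels > 0L
  ov <- if (any(sel)) {
    stats::aggregate(list(inter = rep(1L, sum(sel))),
                     by = list(t = truth$labels[sel], p = pred$labels[sel]),
                     FUN = sum)
  } else data.frame(t = integer(0), p = integer(0), inter = integer(0))
  ov <- ov[order(-ov$inter), , drop = FALSE]
  t_used <- logical(nt); p_used <- logical(np)
  match_p <- rep(NA_integer_, nt); match_i <- rep(0L, nt)
  for (r in seq_len(nrow(ov))) {
    ti <- ov$t[r]; pi <- ov$p[r]
    if (t_used[ti] || p_used[pi]) next
    t_used[ti] <- p_used[pi] <- TRUE
    match_p[ti] <- pi; match_i[ti] <- ov$inter[r]
  }
  uni <- at + ifelse(is.na(match_p), 0L, ap[ifelse(is.na(match_p), 1L, match_p)]) -
    match_i
  iou <- ifelse(uni > 0, match_i / uni, 0)
  matches <- data.frame(truth = seq_len(nt), pred = match_p,
                        intersection = match_i, union = uni, iou = iou)
  list(miou = sum(iou) / max(nt, np), matches = matches)
}

#' Pearson agreement after residual-based outlier removal
#'
#' Fits `y ~ x` by least squares, removes points whose standardized residual
#' exceeds `outlier_z` in absolute value (single pass), then recomputes the
#' Pearson correlation, its two-sided p-value, and the RMSE of `x - y` on the
#' retained points.
#'
#' @param x computational values.
#' @param y reference values (same length, >= 3).
#' @param outlier_z absolute standardized-residual cutoff.
#' @return list of class `agreement_result`: `r`, `r2`, `p_value`, `rmse`,
#'   `n_used`, `n_outliers_removed`, `outlier_rule`.
#' @export
agreement <- function(x, y, outlier_z = 3.0) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("fewer than 3 finite pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in input")
  fit <- lm(y ~ x)
  r <- resid(fit)
  s <- sqrt(sum(r^2) / fit$df.residual)
  # an (almost) exact linear relation leaves only roundoff residuals;
  # flagging those as outliers would be spurious
  keep <- if (s <= 1e-10 * max(abs(y), 1)) rep(TRUE, length(r))
  else abs(r / s) <= outlier_z
  x2 <- x[keep]; y2 <- y[keep]
  if (sd(x2) == 0 || sd(y2) == 0) stop("zero variance after outlier removal")
  ct <- cor.test(x2, y2, method = "pearson")
  structure(list(r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
                 p_value = ct$p.value,
                 rmse = sqrt(mean((x2 - y2)^2)),
                 n_used = length(x2),
                 n_outliers_removed = sum(!keep),
                 outlier_rule = sprintf("|standardized residual| > %g (single pass)",
                                        outlier_z)),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("agreement: R^2 = %.4f (r = %.4f), p = %.3g, RMSE = %.4g, n = %d (%d outlier%s removed; %s)\n",
              x$r2, x$r, x$p_value, x$rmse, x$n_used, x$n_outliers_removed,
              if (x$n_outliers_removed == 1) "" else "s", x$outlier_rule))
  invisible(x)
}

#' Kolmogorov-Smirnov normality test with estimated parameters
#'
#' One-sample KS test against a normal distribution with the sample's own
#' mean and standard deviation, using the Lilliefors correction for the
#' plugged-in parameters (via [nortest::lillie.test()]).
#'
#' @param values numeric vector, n >= 8, non-constant.
#' @return list: `statistic` (D), `p_value`.
#' @export
ks_normality <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 8L) stop("at least 8 values are required")
  if (sd(values) == 0) stop("zero variance: normality test undefined")
  t <- nortest::lillie.test(values)
  list(statistic = unname(t$statistic), p_value = t$p.value)
}

#' Broad-sense heritability from one-way variance components
#'
#' Method-of-moments estimates from the one-way random-effects ANOVA:
#' `sigma2_e = MS_within`, `sigma2_g = (MS_between - MS_within) / r`, with `r`
#' the (effective) number of replicates per genotype; negative estimates are
#' truncated to 0. `H2 = sigma2_g / (sigma2_g + sigma2_e)`.
#'
#' @param values trait values, one per genotype x replicate.
#' @param genotype genotype identifiers (same length as `values`).
#' @return list of class `variance_components`: `sigma2_g`, `sigma2_e`, `H2`,
#'   `n_genotypes`, `r_effective`.
#' @export
heritability <- function(values, genotype) {
  values <- as.numeric(values)
  genotype <- as.factor(genotype)
  if (length(values) != length(genotype)) stop("lengths differ")
  ok <- is.finite(values)
  values <- values[ok]; genotype <- droplevels(genotype[ok])
  ni <- table(genotype)
  k <- length(ni)
  if (k < 2L) stop("at least 2 genotypes are required")
  if (max(ni) < 2L)
    stop("single replicate throughout: heritability is unidentifiable")
  N <- length(values)
  fit <- aov(values ~ genotype)
  tab <- anova(fit)
  msb <- tab$`Mean Sq`[1]; msw <- tab$`Mean Sq`[2]
  r_eff <- (N - sum(ni^2) / N) / (k - 1)
  s2e <- msw
  s2g <- max((msb - msw) / r_eff, 0)
  h2 <- if (s2g + s2e > 0) s2g / (s2g + s2e) else 0
  structure(list(sigma2_g = s2g, sigma2_e = s2e, H2 = h2,
                 n_genotypes = k, r_effective = r_eff),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("variance components: sigma2_g = %.4g, sigma2_e = %.4g, H2 = %.4f (%d genotypes, r = %.2f)\n",
              x$sigma2_g, x$sigma2_e, x$H2, x$n_genotypes, x$r_effective))
  invisible(x)
}
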