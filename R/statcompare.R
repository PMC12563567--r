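#' D'Agostino & Pearson omnibus normality test
#'
#' Combines the skewness z-test (D'Agostino 1970) and the kurtosis z-test
#' (Anscombe & Glynn 1983) into the omnibus statistic
#' K2 = Z_skew^2 + Z_kurt^2, referred to a chi-squared distribution with
#' two degrees of freedom. Requires at least 8 observations (the skewness
#' approximation breaks down below that); smaller samples should fall back
#' to a nonparametric comparison.
#'
#' @param x numeric vector, n >= 8.
#' @return list with `statistic` (K2), `p.value`, `zSkew`, `zKurt`, `n`.
#' @export
dagostinoPearsonTest <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L) stop("D'Agostino & Pearson test requires n >= 8 (got ", n, ")")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero variance: normality test undefined")
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)

  # skewness z (D'Agostino 1970)
  b1 <- m3 / m2^1.5
  y <- b1 * sqrt(((n + 1) * (n + 3)) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(W2))
  alpha <- sqrt(2 / (W2 - 1))
  yA <- y / alpha
  zSkew <- delta * log(yA + sqrt(yA^2 + 1))

  # kurtosis z (Anscombe & Glynn 1983)
  b2 <- m4 / m2^2
  Eb2 <- 3 * (n - 1) / (n + 1)
  varb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(varb2)
  sqrtbeta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqrtbeta1 *
    (2 / sqrtbeta1 + sqrt(1 + 4 / sqrtbeta1^2))
  denom <- 1 + xk * sqrt(2 / (A - 4))
  term2 <- sign(denom) * ((1 - 2 / A) / abs(denom))^(1 / 3)
  zKurt <- ((1 - 2 / (9 * A)) - term2) / sqrt(2 / (9 * A))

  K2 <- zSkew^2 + zKurt^2
  list(statistic = K2,
       p.value = pchisq(K2, df = 2, lower.tail = FALSE),
       zSkew = zSkew, zKurt = zKurt, n = n)
}

#' Map a p-value to the significance-star category
#'
#' Bins: p < 0.0001 "****"; 0.0001-0.001 "***"; 0.001-0.01 "**";
#' 0.01-0.05 "*"; otherwise "ns". Values exactly on a boundary fall in the
#' weaker (less significant) category.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return character vector of categories.
#' @examples
#' starCategory(c(5e-5, 0.03, 0.5))
#' @export
starCategory <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  out <- character(length(p))
  out[p < 0.0001] <- "****"
  out[p >= 0.0001 & p < 0.001] <- "***"
  out[p >= 0.001 & p < 0.01] <- "**"
  out[p >= 0.01 & p < 0.05] <- "*"
  out[p >= 0.05] <- "ns"
  out
}

#' Dunn's multiple-comparison test after Kruskal-Wallis
#'
#' Pairwise z-statistics on pooled-rank means with tie correction,
#' comparing every treatment group against the control, with Bonferroni
#' adjustment over the reported comparisons (the adjustment variant is
#' recorded in the output).
#'
#' @param values numeric vector.
#' @param groups factor/character of the same length; the control group is
#'   `control`.
#' @param control character(1), control group label.
#' @return data.frame: group, z, p_unadjusted, p (adjusted), with the
#'   adjustment recorded in attribute `adjustment`.
#' @export
dunnTest <- function(values, groups, control) {
  groups <- as.character(groups)
  stopifnot(control %in% groups)
  N <- length(values)
  r <- rank(values)
  tie <- table(values)
  tieCorr <- sum(tie^3 - tie) / (12 * (N - 1))
  meanRank <- tapply(r, groups, mean)
  nPer <- tapply(r, groups, length)
  others <- setdiff(names(meanRank), control)
  z <- vapply(others, function(g) {
    (meanRank[[g]] - meanRank[[control]]) /
      sqrt((N * (N + 1) / 12 - tieCorr) *
             (1 / nPer[[g]] + 1 / nPer[[control]]))
  }, numeric(1))
  pUnadj <- 2 * pnorm(-abs(z))
  out <- data.frame(group = others, z = z,
                    p_unadjusted = pUnadj,
                    p = pmin(1, pUnadj * length(others)))
  attr(out, "adjustment") <- "Bonferroni over control comparisons"
  rownames(out) <- NULL
  out
}

#' Normality-gated group comparison with multiple-comparison correction
#'
#' Implements the comparison protocol used for per-cell metric tables:
#' each group is tested for normality (D'Agostino & Pearson omnibus at
#' alpha = 0.05); when all groups are normal, two groups are compared with
#' an unpaired two-tailed t-test and more than two with one-way ANOVA plus
#' Dunnett's test against the control; when any group is non-normal (or too
#' small for the normality test, n < 8), the Mann-Whitney test or the
#' Kruskal-Wallis test with Dunn's multiple comparisons is used instead.
#' P-values are mapped to significance stars with [starCategory()].
#'
#' @param values numeric vector of the per-cell metric.
#' @param groups factor/character group labels.
#' @param control character(1), control group label (default: first level).
#' @param alphaNormality numeric(1), alpha of the normality gate.
#' @return list with `test` (name of the procedure run), `parametric`,
#'   `normality` (per-group data.frame), `comparisons` (data.frame: group,
#'   p, stars), and `log` (character lines naming every delegated
#'   procedure).
#' @examples
#' set.seed(1)
#' compareGroups(c(rnorm(10), rnorm(10, 3)),
#'               rep(c("ctrl", "rnai"), each = 10), control = "ctrl")
#' @export
compareGroups <- function(values, groups, control = NULL,
                          alphaNormality = 0.05) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  lev <- unique(groups)
  if (length(lev) < 2L) stop("need at least two groups")
  if (is.null(control)) control <- lev[1]
  if (!control %in% lev) stop("control group '", control, "' not present")
  nPer <- tapply(values, groups, length)
  if (any(nPer < 3L)) stop("every group needs at least 3 values")

  normality <- do.call(rbind, lapply(lev, function(g) {
    v <- values[groups == g]
    if (length(v) < 8L || length(unique(v)) < 2L) {
      data.frame(group = g, n = length(v), p = NA_real_, normal = FALSE,
                 note = "too small for normality test; treated as non-normal")
    } else {
      t <- dagostinoPearsonTest(v)
      data.frame(group = g, n = length(v), p = t$p.value,
                 normal = t$p.value > alphaNormality, note = "")
    }
  }))
  parametric <- all(normality$normal)
  others <- setdiff(lev, control)
  log <- sprintf(
    "normality: D'Agostino & Pearson omnibus, alpha = %g -> %s branch",
    alphaNormality, if (parametric) "parametric" else "nonparametric")

  if (length(lev) == 2L) {
    if (parametric) {
      tt <- t.test(values[groups == others], values[groups == control],
                   var.equal = TRUE)
      p <- tt$p.value
      test <- "unpaired two-tailed t-test"
    } else {
      wt <- suppressWarnings(
        wilcox.test(values[groups == others], values[groups == control]))
      p <- wt$p.value
      test <- "Mann-Whitney test"
    }
    comparisons <- data.frame(group = others, p = p,
                              stars = starCategory(p))
    log <- c(log, paste0("comparison: ", test))
  } else if (parametric) {
    df <- data.frame(value = values, group = factor(groups,
                     levels = c(control, others)))
    fit <- aov(value ~ group, data = df)
    glt <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
    ps <- summary(glt)$test$pvalues
    comparisons <- data.frame(group = others, p = as.numeric(ps),
                              stars = starCategory(as.numeric(ps)))
    test <- "one-way ANOVA with Dunnett's multiple comparisons"
    log <- c(log, paste0("comparison: ", test,
                         " (multcomp::glht, single-step)"))
  } else {
    kw <- kruskal.test(values, factor(groups))
    dn <- dunnTest(values, groups, control)
    comparisons <- data.frame(group = dn$group, p = dn$p,
                              stars = starCategory(dn$p))
    test <- "Kruskal-Wallis test with Dunn's multiple comparisons"
    log <- c(log,
             sprintf("omnibus: Kruskal-Wallis p = %.4g", kw$p.value),
             paste0("comparison: Dunn z-tests, ", attr(dn, "adjustment")))
  }
  list(test = test, parametric = parametric, normality = normality,
       comparisons = comparisons, log = log)
}

#' Export group values in long form for violin plots
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @return data.frame with columns `group`, `value`, ordered by group.
#' @export
violinData <- function(values, groups) {
  df <- data.frame(group = as.character(groups), value = values)
  df[order(df$group), , drop = FALSE]
}
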