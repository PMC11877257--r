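# Statistical toolbox: chi-squared tests with Cohen's w, one-way ANOVA with
# eta-squared (from raw data or from published mean/SEM/n summaries), Tukey
# HSD, Student t-tests with Cohen's d, and simple linear regression.

#' Chi-squared test of independence with Cohen's w
#'
#' Pearson chi-squared on an r x c count table, no continuity correction;
#' effect size \eqn{w = \sqrt{\chi^2 / N}}.
#'
#' @param counts Matrix of non-negative counts with positive margins.
#' @return List: \code{chi2}, \code{df}, \code{p_value}, \code{cohens_w},
#'   \code{n}.
#' @examples
#' # firing pattern (LS/NLS) by morphology in mPFC L1 interneurons
#' chi2_independence(rbind(NGC = c(10, 1), eNGC = c(9, 3), SBC = c(4, 6)))
#' @export
chi2_independence <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin in the contingency table")
  res <- .pearson_chi2(counts)
  N <- sum(counts)
  list(chi2 = res$chi2, df = res$df, p_value = res$p_value,
       cohens_w = sqrt(res$chi2 / N), n = N)
}

#' Chi-squared goodness-of-fit test with Cohen's w
#'
#' \eqn{\sum (O - E)^2 / E} with \eqn{E_i = N p_i}; df = k - 1;
#' \eqn{w = \sqrt{\chi^2 / N}}.
#'
#' @param counts Observed category counts.
#' @param expected_proportions Hypothesised proportions summing to 1;
#'   default uniform.
#' @return List: \code{chi2}, \code{df}, \code{p_value}, \code{cohens_w},
#'   \code{n}.
#' @export
chi2_goodness_of_fit <- function(counts,
                                 expected_proportions =
                                   rep(1 / length(counts), length(counts))) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (abs(sum(expected_proportions) - 1) > 1e-8)
    stop("expected_proportions must sum to 1")
  N <- sum(counts)
  E <- N * expected_proportions
  if (any(E == 0)) stop("zero expected count")
  chi2 <- sum((counts - E)^2 / E)
  df <- length(counts) - 1L
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
       cohens_w = sqrt(chi2 / N), n = N)
}

#' One-way ANOVA with eta-squared
#'
#' Standard fixed-effects decomposition;
#' \eqn{\eta^2 = SS_{between} / SS_{total}}.
#'
#' @param groups List of numeric vectors, one per group (>= 2 groups, each
#'   n >= 2).
#' @return List: \code{F}, \code{df1}, \code{df2}, \code{p_value},
#'   \code{eta_squared}.
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2L) stop("need >= 2 groups")
  if (any(vapply(groups, length, 0L) < 2L)) stop("each group needs n >= 2")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  tab <- stats::anova(stats::lm(y ~ g))
  ssb <- tab$`Sum Sq`[1L]; ssw <- tab$`Sum Sq`[2L]
  if (ssw == 0 && ssb == 0)
    stop("F undefined: zero variance within and between groups")
  list(F = tab$`F value`[1L], df1 = tab$Df[1L], df2 = tab$Df[2L],
       p_value = tab$`Pr(>F)`[1L], eta_squared = ssb / (ssb + ssw))
}

#' One-way ANOVA reconstructed from group summaries
#'
#' Recomputes the fixed-effects ANOVA from published per-group mean, SEM and
#' n: \eqn{SD_i = SEM_i \sqrt{n_i}}, \eqn{SS_b = \sum n_i (m_i - \bar m)^2},
#' \eqn{SS_w = \sum (n_i - 1) SD_i^2}. This is the bridge that lets summary
#' tables printed in publications be checked without the raw data.
#'
#' @param means,sems,ns Per-group means, SEMs (> 0) and sizes (>= 2).
#' @return List: \code{F}, \code{df1}, \code{df2}, \code{p_value},
#'   \code{eta_squared}.
#' @examples
#' # axonal tangential extents of NGC / eNGC / SBC-like cells (um)
#' anova_from_summary(c(137.2, 328.4, 202.3), c(10.6, 19.8, 31.5),
#'                    c(16, 11, 12))
#' @export
anova_from_summary <- function(means, sems, ns) {
  if (length(means) < 2L) stop("need >= 2 group summaries")
  if (length(sems) != length(means) || length(ns) != length(means))
    stop("means, sems and ns must have equal length")
  if (any(ns < 2)) stop("each group needs n >= 2")
  if (any(sems <= 0)) stop("SEMs must be positive")
  sds <- sems * sqrt(ns)
  gm <- sum(ns * means) / sum(ns)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((ns - 1) * sds^2)
  df1 <- length(means) - 1L
  df2 <- sum(ns) - length(means)
  Fv <- (ssb / df1) / (ssw / df2)
  list(F = Fv, df1 = df1, df2 = df2,
       p_value = stats::pf(Fv, df1, df2, lower.tail = FALSE),
       eta_squared = ssb / (ssb + ssw))
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range comparisons on the pooled within-group mean square,
#' following a one-way ANOVA.
#'
#' @inheritParams anova_oneway
#' @return Data frame with one row per group pair: \code{comparison},
#'   \code{diff}, \code{p_adj}.
#' @export
tukey_hsd <- function(groups) {
  if (length(groups) < 2L) stop("need >= 2 groups")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 0L)),
              levels = names(groups))
  tk <- stats::TukeyHSD(stats::aov(y ~ g))$g
  data.frame(comparison = rownames(tk), diff = tk[, "diff"],
             p_adj = tk[, "p adj"], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Student's t-test with Cohen's d
#'
#' Two-tailed paired or unpaired t-test. Unpaired uses the pooled-variance
#' (Student) form by default, with \eqn{d = (m_a - m_b)/SD_{pooled}}; paired
#' tests the differences, with \eqn{d = \bar{d}/SD_d}. Welch's correction is
#' available by flag.
#'
#' @param a,b Numeric samples (equal length when paired).
#' @param paired Paired test?
#' @param welch Use Welch's unequal-variance form (unpaired only).
#' @return List: \code{t}, \code{df}, \code{p_value}, \code{cohens_d},
#'   \code{mean_a}, \code{mean_b}, \code{sem_a}, \code{sem_b}.
#' @export
t_tests_and_d <- function(a, b, paired = FALSE, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs n >= 2")
  if (paired && length(a) != length(b))
    stop("paired test requires equal lengths")
  if (paired && stats::sd(a - b) == 0) {
    # identical paired samples: t = 0 by convention rather than 0/0
    return(list(t = 0, df = length(a) - 1L, p_value = 1, cohens_d = 0,
                mean_a = mean(a), mean_b = mean(b),
                sem_a = stats::sd(a) / sqrt(length(a)),
                sem_b = stats::sd(b) / sqrt(length(b))))
  }
  tt <- stats::t.test(a, b, paired = paired, var.equal = !welch && !paired)
  d <- if (paired) {
    dif <- a - b
    mean(dif) / stats::sd(dif)
  } else {
    sp <- sqrt(((length(a) - 1) * stats::var(a) +
                  (length(b) - 1) * stats::var(b)) /
                 (length(a) + length(b) - 2))
    (mean(a) - mean(b)) / sp
  }
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, cohens_d = d,
       mean_a = mean(a), mean_b = mean(b),
       sem_a = stats::sd(a) / sqrt(length(a)),
       sem_b = stats::sd(b) / sqrt(length(b)))
}

#' Simple linear regression with R-squared
#'
#' @param x,y Numeric vectors (>= 3 points; x not constant).
#' @return List: \code{slope}, \code{intercept}, \code{r_squared}.
#' @export
linreg_r2 <- function(x, y) {
  if (length(x) < 3L || length(y) != length(x))
    stop("need >= 3 paired points")
  if (stats::var(x) == 0) stop("x is constant")
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = summary(fit)$r.squared)
}
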