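# Group-comparison statistics: per-group normality gate
# (Kolmogorov-Smirnov) routing to a one-tailed unpaired Student t-test
# when both groups look normal, otherwise a one-tailed Mann-Whitney U
# test. P < 0.05 is significant; summary tables carry the conventional
# star tiers (*P <= 0.05, **P <= 0.01, ***P <= 0.001).

#' Normality p-value (Kolmogorov-Smirnov)
#'
#' Tests a sample against a normal distribution with parameters estimated
#' from the sample. The default is the Lilliefors-corrected KS test
#' (appropriate when mean and SD are estimated); \code{method = "ks"}
#' gives the classical one-sample KS test against N(mean, sd), whose
#' p-values are conservative under estimated parameters. The Lilliefors
#' implementation requires n >= 5; smaller samples (3 or 4 values) fall
#' back to the classical test.
#'
#' @param sample numeric vector, n >= 3, non-constant.
#' @param method \code{"lilliefors"} (default) or \code{"ks"}.
#' @return p-value.
#' @export
ksNormality <- function(sample, method = c("lilliefors", "ks")) {
  method <- match.arg(method)
  sample <- sample[!is.na(sample)]
  if (length(sample) < 3L) stop("normality test requires n >= 3")
  if (stats::sd(sample) == 0) stop("zero-variance sample")
  if (method == "lilliefors" && length(sample) >= 5L)
    return(nortest::lillie.test(sample)$p.value)
  suppressWarnings(
    stats::ks.test(sample, "pnorm", mean = mean(sample),
                   sd = stats::sd(sample))$p.value)
}

#' Compare two groups with normality-gated test routing
#'
#' If both groups pass the normality test (p > alpha in each), an unpaired
#' one-tailed Student t-test (equal variances) is used; if either group
#' fails, the one-tailed Mann-Whitney U test. The one-tailed direction is
#' the pre-specified alternative for group A relative to group B and must
#' be given explicitly (\code{"greater"}: A > B, \code{"less"}: A < B).
#'
#' @param a,b numeric samples, each n >= 3.
#' @param direction \code{"greater"} or \code{"less"} (required).
#' @param alpha significance level (default 0.05).
#' @param metric label carried into the result.
#' @param normalityMethod passed to [ksNormality()].
#' @return a \linkS4class{GroupComparison}.
#' @examples
#' set.seed(1)
#' compareGroups(rnorm(6, 1), rnorm(6), direction = "greater",
#'               metric = "collagen_pct")
#' @export
compareGroups <- function(a, b, direction, alpha = 0.05,
                          metric = NA_character_,
                          normalityMethod = "lilliefors") {
  if (missing(direction) || !direction %in% c("greater", "less"))
    stop("one-tailed direction must be 'greater' or 'less'")
  stopifnot(length(a) >= 3L, length(b) >= 3L, alpha > 0, alpha < 1)
  pa <- ksNormality(a, normalityMethod)
  pb <- ksNormality(b, normalityMethod)
  if (pa > alpha && pb > alpha) {
    test <- "t_one_tailed"
    p <- stats::t.test(a, b, alternative = direction,
                       var.equal = TRUE)$p.value
  } else {
    test <- "mann_whitney"
    p <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = direction)$p.value)
  }
  new("GroupComparison", metric = as.character(metric),
      meanA = mean(a), sdA = stats::sd(a), nA = length(a),
      meanB = mean(b), sdB = stats::sd(b), nB = length(b),
      normalityP = c(a = pa, b = pb), test = test, direction = direction,
      pValue = p, alpha = alpha, significant = p < alpha)
}

#' Star code for a p-value
#'
#' \code{"***"} for p <= 0.001, \code{"**"} for p <= 0.01, \code{"*"} for
#' p <= 0.05, otherwise \code{""}.
#'
#' @param p p-value(s).
#' @return character vector of star codes.
#' @export
significanceStars <- function(p) {
  ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**",
                                   ifelse(p <= 0.05, "*", "")))
}

#' Summary table of group comparisons
#'
#' One row per comparison: mean +/- SD per group, n, test used, p-value
#' and star code.
#'
#' @param comparisons list of \linkS4class{GroupComparison} objects
#'   (non-empty).
#' @return data frame.
#' @export
summarizeComparisons <- function(comparisons) {
  if (is(comparisons, "GroupComparison")) comparisons <- list(comparisons)
  stopifnot(length(comparisons) > 0L,
            all(vapply(comparisons, is, logical(1), "GroupComparison")))
  do.call(rbind, lapply(comparisons, function(g) {
    data.frame(metric = g@metric,
               groupA = sprintf("%.4g +/- %.4g", g@meanA, g@sdA), nA = g@nA,
               groupB = sprintf("%.4g +/- %.4g", g@meanB, g@sdB), nB = g@nB,
               test = g@test, p = g@pValue,
               stars = significanceStars(g@pValue),
               significant = g@significant, stringsAsFactors = FALSE)
  }))
}
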