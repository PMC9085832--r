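#' Standard error of the mean
#'
#' sd/sqrt(n) with the sample (n-1) standard deviation; 0 for a single
#' value.
#'
#' @param x numeric vector
#' @export
sem <- function(x) {
  n <- length(x)
  if (n < 1) stop("empty sample")
  if (n == 1) return(0)
  sd(x) / sqrt(n)
}

#' Summarise a metric sample as mean +/- SEM
#'
#' The convention used throughout: structural metrics are averaged over
#' subunit x replica values (n = 4 x replicas = 80 for 20 replicas), a
#' choice that treats subunits within one trajectory as independent.
#' `collapse_replicas` additionally averages within replicas first
#' (n = replicas), making the pseudo-replication choice visible.
#'
#' @param values numeric vector of measurements
#' @param group optional grouping vector (e.g. replica ids) used when
#'   `collapse_replicas = TRUE`
#' @param collapse_replicas average within `group` before summarising
#' @return list(mean, sem, n)
#' @export
summarize_sample <- function(values, group = NULL,
                             collapse_replicas = FALSE) {
  if (collapse_replicas) {
    if (is.null(group)) stop("collapse_replicas needs a group vector")
    values <- as.numeric(tapply(values, group, mean))
  }
  list(mean = mean(values), sem = sem(values), n = length(values))
}

#' Two-sample t-test (Welch or pooled-variance)
#'
#' Two-tailed, unpaired. Two zero-variance samples with equal means give
#' p = 1 by convention (no evidence of a difference); with different
#' means, p = 0.
#'
#' @param a,b numeric samples, each of length >= 2
#' @param variant `"welch"` (default; unequal variances) or `"pooled"`
#'   (classical Student)
#' @param alpha significance level used for the `significant` flag
#' @return list(t_statistic, p_value, significant, alpha)
#' @export
two_sample_ttest <- function(a, b, variant = c("welch", "pooled"),
                             alpha = 0.05) {
  variant <- match.arg(variant)
  if (length(a) < 2 || length(b) < 2)
    stop("both samples need n >= 2")
  if (sd(a) == 0 && sd(b) == 0) {
    p <- if (mean(a) == mean(b)) 1 else 0
    t <- if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf
    return(list(t_statistic = t, p_value = p, significant = p < alpha,
                alpha = alpha))
  }
  tt <- t.test(a, b, var.equal = (variant == "pooled"))
  list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
       significant = tt$p.value < alpha, alpha = alpha)
}
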