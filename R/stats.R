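#' Summarize a group of per-cell measurements
#'
#' Mean, SEM (SD/sqrt(n)) and a Shapiro-Wilk normality p-value (reported
#' for n >= 3, not used to auto-switch tests).
#'
#' @param values Numeric vector (n >= 1).
#' @param label Group label.
#' @return Data.frame of class `group_summary` with columns `label`, `n`,
#'   `mean`, `sem`, `shapiro_p`.
#' @export
#' @examples
#' summarize_group(c(88, 92, 85, 90), "WT 3 uM")
summarize_group <- function(values, label = "") {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 1) stop("empty input")
  sem <- if (n > 1) stats::sd(values) / sqrt(n) else 0
  sw <- if (n >= 3 && stats::sd(values) > 0)
    stats::shapiro.test(values)$p.value else NA_real_
  out <- data.frame(label = label, n = n, mean = mean(values), sem = sem,
                    shapiro_p = sw)
  class(out) <- c("group_summary", "data.frame")
  out
}

#' Paired two-sided t test
#'
#' @param a,b Paired measurements, equal length >= 2.
#' @return List: `p` (two-sided p-value, NA if undefined), `t`, `df`,
#'   `defined` (FALSE when the differences have zero variance).
#' @export
compare_paired <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples differ in length")
  if (length(a) < 2) stop("need >= 2 pairs")
  d <- a - b
  if (stats::sd(d) == 0)
    return(list(p = NA_real_, t = NA_real_, df = length(d) - 1,
                defined = FALSE))
  tt <- stats::t.test(a, b, paired = TRUE)
  list(p = tt$p.value, t = unname(tt$statistic),
       df = unname(tt$parameter), defined = TRUE)
}

#' Two-sided Mann-Whitney U test
#'
#' Exact p-value for small samples (both groups <= `exact_max` and no
#' ties), normal approximation with tie correction otherwise (the
#' `wilcox.test` machinery).
#'
#' @param a,b Independent samples, each n >= 2.
#' @param exact_max Largest per-group n for the exact branch.
#' @return List: `p`, `U`, `exact` (logical branch indicator).
#' @export
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6))$p   # fully separated: 0.1
compare_groups <- function(a, b, exact_max = 8) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- !ties && length(a) <= exact_max && length(b) <= exact_max
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = TRUE))
  list(p = wt$p.value, U = unname(wt$statistic), exact = use_exact)
}
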