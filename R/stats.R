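#' Pooled standard deviation
#'
#' Pools replicate-series standard deviations as the square root of the sum
#' of individual variances weighted by the individual degrees of freedom:
#' `sqrt( sum((n_i - 1) * sd_i^2) / sum(n_i - 1) )`. Groups with fewer than
#' two observations carry no degrees of freedom and are excluded (with a
#' warning).
#'
#' @param sd Numeric vector of group standard deviations (>= 0).
#' @param n Integer vector of group sizes, recycled if length 1.
#' @return The pooled standard deviation, in the data's units.
#' @export
#' @examples
#' pooled_sd(c(1, 7), c(3, 3))  # 5
pooled_sd <- function(sd, n) {
  if (length(n) == 1L) n <- rep(n, length(sd))
  stopifnot(length(sd) == length(n))
  if (any(sd < 0)) stop("'sd' must be non-negative", call. = FALSE)
  keep <- n >= 2
  if (!any(keep))
    stop("no group with n >= 2: pooled SD undefined", call. = FALSE)
  if (!all(keep))
    warning("dropping ", sum(!keep), " group(s) with n < 2", call. = FALSE)
  sd <- sd[keep]; n <- n[keep]
  sqrt(sum((n - 1) * sd^2) / sum(n - 1))
}

#' Significance stars
#'
#' The conventional coding: `***` for p <= 0.001, `**` for p <= 0.01,
#' `*` for p <= 0.05, `ns` otherwise.
#'
#' @param p Probability (vectorised), each in `[0, 1]`.
#' @return Character vector of symbols.
#' @export
stars <- function(p) {
  if (any(p < 0 | p > 1 | is.na(p)))
    stop("'p' must lie in [0, 1]", call. = FALSE)
  ifelse(p <= 0.001, "***",
         ifelse(p <= 0.01, "**",
                ifelse(p <= 0.05, "*", "ns")))
}

# internal: residual sum of squares of y on a design matrix
rss_of <- function(X, y) sum(stats::lm.fit(X, y)$residuals^2)

#' Two-way fixed-effects ANOVA (donor, matrix), main effects only
#'
#' Decomposes variation in a response into donor and matrix main effects
#' with Type II sums of squares: each factor's SS is the reduction in
#' residual SS when it is added to the model already containing the other
#' factor. On balanced data this coincides with the sequential (Type I)
#' decomposition; under mild imbalance (e.g. one discarded arm) Type II
#' keeps each main effect adjusted for the other. No interaction term is
#' fitted. F statistics are each factor's mean square over the residual
#' mean square of the two-factor model; p-values come from the F
#' distribution.
#'
#' @param values Numeric response vector.
#' @param donor Factor (or coercible) of donor labels, >= 2 levels.
#' @param matrix Factor (or coercible) of matrix labels, >= 2 levels.
#' @return An object of class `two_way_anova`: a list with `table` (rows
#'   donor, matrix, residual; columns `df`, `SS`, `MS`, `F`, `p`, `stars`)
#'   and `ss_total`.
#' @export
#' @examples
#' d <- rep(c("O1", "O2", "O3", "O4"), each = 3)
#' m <- rep(c("Mno", "Mnc", "Mcov"), times = 4)
#' y <- ifelse(m == "Mno", 1, 2) + rnorm(12, sd = 0.1)
#' two_way_anova(y, d, m)
two_way_anova <- function(values, donor, matrix) {
  y <- as.numeric(values)
  donor <- factor(donor)
  matrix <- factor(matrix)
  stopifnot(length(y) == length(donor), length(y) == length(matrix))
  if (nlevels(donor) < 2 || nlevels(matrix) < 2)
    stop("each factor needs at least 2 levels", call. = FALSE)
  n <- length(y)
  df_d <- nlevels(donor) - 1L
  df_m <- nlevels(matrix) - 1L
  df_res <- n - 1L - df_d - df_m
  if (df_res < 1L)
    stop("no residual degrees of freedom", call. = FALSE)

  X_full <- stats::model.matrix(~ donor + matrix)
  X_d <- stats::model.matrix(~ donor)
  X_m <- stats::model.matrix(~ matrix)
  rss_full <- rss_of(X_full, y)
  ss_d <- rss_of(X_m, y) - rss_full    # donor | matrix
  ss_m <- rss_of(X_d, y) - rss_full    # matrix | donor
  ss_d <- max(ss_d, 0); ss_m <- max(ss_m, 0)

  ms_res <- rss_full / df_res
  Fd <- (ss_d / df_d) / ms_res
  Fm <- (ss_m / df_m) / ms_res
  pd <- stats::pf(Fd, df_d, df_res, lower.tail = FALSE)
  pm <- stats::pf(Fm, df_m, df_res, lower.tail = FALSE)

  tab <- data.frame(
    term = c("donor", "matrix", "residual"),
    df = c(df_d, df_m, df_res),
    SS = c(ss_d, ss_m, rss_full),
    MS = c(ss_d / df_d, ss_m / df_m, ms_res),
    F = c(Fd, Fm, NA),
    p = c(pd, pm, NA),
    stars = c(stars(pd), stars(pm), ""),
    stringsAsFactors = FALSE)
  structure(list(table = tab, ss_total = sum((y - mean(y))^2)),
            class = "two_way_anova")
}

#' @export
print.two_way_anova <- function(x, digits = 4, ...) {
  cat("Two-way ANOVA (donor, matrix; main effects, Type II SS)\n")
  tab <- x$table
  tab$SS <- signif(tab$SS, digits); tab$MS <- signif(tab$MS, digits)
  tab$F <- signif(tab$F, digits); tab$p <- signif(tab$p, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}
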