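#' Welch one-way ANOVA with Games-Howell post hoc comparisons
#'
#' The omnibus test is Welch's heteroscedastic one-way ANOVA (base R
#' `oneway.test` with `var.equal = FALSE`). Pairwise comparisons use the
#' Games-Howell procedure, designed for unequal variances and sample sizes:
#' for groups i, j,
#' `t = (mean_i - mean_j) / sqrt(s_i^2/n_i + s_j^2/n_j)` with
#' Welch-Satterthwaite degrees of freedom, and the p-value from the
#' studentized-range distribution with `q = t * sqrt(2)` and the number of
#' groups as the range parameter.
#'
#' @param values numeric vector of observations.
#' @param groups factor (or coercible) of group labels.
#' @param conf confidence level for the pairwise intervals.
#' @return A `welch_games_howell` list: `anova` (statistic, df, p.value),
#'   `pairwise` data.frame (group1, group2, diff, se, t, df, p, lower,
#'   upper) and `group_stats`.
#' @export
welch_anova_games_howell <- function(values, groups, conf = 0.95) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  ns <- tapply(values, groups, length)
  if (any(ns < 2L)) stop("each group needs at least 2 observations")
  vs <- tapply(values, groups, stats::var)
  if (any(vs == 0)) stop("zero variance in a group: Games-Howell undefined")
  aw <- stats::oneway.test(values ~ groups, var.equal = FALSE)
  ms <- tapply(values, groups, mean)
  k <- nlevels(groups)
  lev <- levels(groups)
  pw <- do.call(rbind, lapply(utils::combn(k, 2, simplify = FALSE),
                              function(ij) {
    i <- ij[1]; j <- ij[2]
    se2 <- vs[i] / ns[i] + vs[j] / ns[j]
    se <- sqrt(se2)
    tstat <- (ms[i] - ms[j]) / se
    df <- se2^2 / ((vs[i] / ns[i])^2 / (ns[i] - 1) +
                     (vs[j] / ns[j])^2 / (ns[j] - 1))
    p <- suppressWarnings(stats::ptukey(abs(tstat) * sqrt(2), nmeans = k,
                                        df = df, lower.tail = FALSE))
    qc <- suppressWarnings(stats::qtukey(conf, nmeans = k, df = df) / sqrt(2))
    if (!is.finite(p)) {
      # the studentized-range quantile is numerically unstable below ~2
      # degrees of freedom; fall back to the Welch t p-value there
      p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
      qc <- stats::qt(1 - (1 - conf) / 2, df)
    }
    data.frame(group1 = lev[i], group2 = lev[j],
               diff = unname(ms[i] - ms[j]), se = unname(se),
               t = unname(tstat), df = unname(df), p = unname(p),
               lower = unname(ms[i] - ms[j] - qc * se),
               upper = unname(ms[i] - ms[j] + qc * se))
  }))
  structure(list(
    anova = list(statistic = unname(aw$statistic),
                 df = unname(aw$parameter), p.value = aw$p.value),
    pairwise = pw,
    group_stats = data.frame(group = lev, n = as.vector(ns),
                             mean = as.vector(ms), var = as.vector(vs))),
    class = "welch_games_howell")
}

#' @export
print.welch_games_howell <- function(x, ...) {
  cat(sprintf("Welch ANOVA: F(%.4g, %.4g) = %.4g, p = %.4g\n",
              x$anova$df[1], x$anova$df[2], x$anova$statistic,
              x$anova$p.value))
  cat("Games-Howell pairwise comparisons:\n")
  print(x$pairwise, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Games-Howell p-value for one pair (symmetric helper)
#'
#' @param x,y numeric vectors of the two groups.
#' @param k total number of groups in the family (range parameter).
#' @return The Games-Howell p-value.
#' @export
games_howell_pair <- function(x, y, k = 2L) {
  se2 <- stats::var(x) / length(x) + stats::var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((stats::var(x) / length(x))^2 / (length(x) - 1) +
                   (stats::var(y) / length(y))^2 / (length(y) - 1))
  stats::ptukey(abs(tstat) * sqrt(2), nmeans = k, df = df,
                lower.tail = FALSE)
}
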