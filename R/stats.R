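# Nonparametric statistics used for group comparisons of mucus scores and
# ratios: Mann-Whitney U (exact by enumeration or tie-corrected normal
# approximation), Bonferroni-Dunn adjustment, Kruskal-Wallis with tie
# correction, Dunn's post-hoc z tests, Pearson correlation and simple
# linear regression.  All p values are two-sided.

mw_u_stat <- function(a, b) {
  # U for group a: pairs with a_i < b_j plus half the ties
  sum(outer(a, b, "<")) + 0.5 * sum(outer(a, b, "=="))
}

#' Mann-Whitney U test
#'
#' The reported statistic is `min(U, n_a * n_b - U)`.  The exact two-sided p
#' value is the tail probability of that statistic under full enumeration of
#' the `choose(n_a + n_b, n_a)` group-label assignments (ties handled
#' naturally); the normal approximation applies a continuity correction of
#' 0.5 and the tie-corrected variance.  `mode = "auto"` uses the exact test
#' when both groups have at most 8 observations.
#'
#' @param a,b numeric vectors (both non-empty).
#' @param mode `"exact"`, `"normal"` or `"auto"`.
#' @return list with `statistic` (U), `p_value`, `n`, `method`.
#' @export
mann_whitney_u <- function(a, b, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  na <- length(a); nb <- length(b)
  if (mode == "auto") mode <- if (na <= 8L && nb <= 8L) "exact" else "normal"
  u_a <- mw_u_stat(a, b)
  u <- min(u_a, na * nb - u_a)
  if (mode == "exact") {
    pooled <- c(a, b)
    idx <- combn(na + nb, na)
    stats <- apply(idx, 2L, function(ii) {
      ua <- mw_u_stat(pooled[ii], pooled[-ii])
      min(ua, na * nb - ua)
    })
    p <- mean(stats <= u + 1e-12)
  } else {
    N <- na + nb
    r <- rank(c(a, b))
    ties <- table(r)
    tiecor <- sum(ties^3 - ties) / (N * (N - 1))
    v <- na * nb / 12 * ((N + 1) - tiecor)
    if (v <= 0) {
      p <- 1
    } else {
      z <- (u - na * nb / 2 + 0.5) / sqrt(v)
      p <- min(1, 2 * pnorm(z))
    }
  }
  list(statistic = u, p_value = p, n = c(n_a = na, n_b = nb),
       method = paste0("mann-whitney-", mode))
}

#' Bonferroni-Dunn adjustment
#'
#' `p_adj = min(1, p * m)`, order preserved.
#'
#' @param p_values raw p values in `[0, 1]`.
#' @param m number of comparisons (>= number of p values).
#' @return adjusted p values.
#' @export
bonferroni_dunn_adjust <- function(p_values, m = length(p_values)) {
  if (!length(p_values)) return(numeric(0))
  if (any(p_values < 0 | p_values > 1)) stop("p values must be in [0, 1]")
  if (m < length(p_values)) stop("m must be >= the number of p values")
  pmin(1, p_values * m)
}

kw_h_stat <- function(groups) {
  n <- lengths(groups)
  N <- sum(n)
  r <- rank(unlist(groups))
  grp <- rep(seq_along(groups), n)
  rs <- tapply(r, grp, sum)
  h <- 12 / (N * (N + 1)) * sum(rs^2 / n) - 3 * (N + 1)
  ties <- table(r)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  list(h = h, corr = corr, N = N)
}

#' Kruskal-Wallis rank-sum test
#'
#' Mid-ranks with tie correction; p from the chi-square distribution with
#' k - 1 degrees of freedom.  All-tied input (tie correction zero) returns
#' H = 0 with p = 1 by convention.
#'
#' @param groups list of >= 2 non-empty numeric vectors, total n >= 3.
#' @return list with `statistic` (H), `p_value`, `df`, `n`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need >= 2 groups")
  if (any(lengths(groups) == 0L)) stop("all groups must be non-empty")
  s <- kw_h_stat(groups)
  if (s$N < 3L) stop("total sample size must be >= 3")
  df <- length(groups) - 1L
  if (s$corr <= 0) {
    h <- 0; p <- 1
  } else {
    h <- s$h / s$corr
    p <- pchisq(h, df, lower.tail = FALSE)
  }
  list(statistic = h, p_value = p, df = df, n = lengths(groups))
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Pairwise z statistics on mean ranks with the pooled tie-corrected
#' variance; p values adjusted by Bonferroni-Dunn over all pairs.
#'
#' @param groups list of >= 2 non-empty numeric vectors.
#' @param names optional group names.
#' @return data.table `group1, group2, z, p_value, p_adjusted`.
#' @export
dunn_posthoc <- function(groups, names = NULL) {
  if (!is.list(groups) || length(groups) < 2L) stop("need >= 2 groups")
  if (any(lengths(groups) == 0L)) stop("all groups must be non-empty")
  k <- length(groups)
  nm <- names %||% paste0("group", seq_len(k))
  n <- lengths(groups)
  N <- sum(n)
  r <- rank(unlist(groups))
  grp <- rep(seq_len(k), n)
  mr <- tapply(r, grp, mean)
  ties <- table(r)
  tiesum <- sum(ties^3 - ties)
  out <- list()
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    v <- (N * (N + 1) / 12 - tiesum / (12 * (N - 1))) * (1 / n[i] + 1 / n[j])
    z <- if (v <= 0) 0 else (mr[i] - mr[j]) / sqrt(v)
    p <- min(1, 2 * pnorm(-abs(z)))
    out[[length(out) + 1L]] <- data.table(group1 = nm[i], group2 = nm[j],
                                          z = as.numeric(z), p_value = p)
  }
  res <- rbindlist(out)
  res[, p_adjusted := bonferroni_dunn_adjust(p_value, nrow(res))]
  res[]
}

#' Pearson correlation coefficient
#'
#' @param x,y numeric vectors, length >= 3, neither constant.
#' @return the sample correlation.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  sx <- sd(x); sy <- sd(y)
  if (sx == 0 || sy == 0) stop("constant input: correlation undefined")
  sum((x - mean(x)) * (y - mean(y))) / ((length(x) - 1) * sx * sy)
}

#' Simple linear regression (ordinary least squares)
#'
#' Fits `y = slope * x + intercept`; R^2 = 1 - SS_res/SS_tot (equal to r^2),
#' two-sided p for the slope from the t distribution with n - 2 df.
#'
#' @param x,y numeric vectors, length >= 3, `x` non-constant.
#' @return list `slope, intercept, r, r_squared, p_value, n`.
#' @export
simple_linreg <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("constant x: slope undefined")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - slope * x - intercept
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  r <- if (ss_tot == 0) 0 else sign(slope) * sqrt(max(0, r2))
  se <- sqrt(ss_res / (n - 2) / sxx)
  p <- if (se == 0) 0 else min(1, 2 * pt(-abs(slope / se), n - 2))
  list(slope = slope, intercept = intercept, r = r, r_squared = r2,
       p_value = p, n = n)
}
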