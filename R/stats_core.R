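#' Kruskal-Wallis rank sum test
#'
#' Tie-corrected Kruskal-Wallis H with the chi-square approximation
#' (k - 1 df), as appropriate for the group sizes used throughout the
#' pipeline. The fully degenerate case (all values identical) returns
#' H = 0, p = 1, flagged.
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length.
#' @return List of class `test_result`: `test`, `statistic`, `df`, `p`,
#'   `groups`, `degenerate`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (length(values) < 3) stop("need total n >= 3")
  if (length(unique(values)) == 1) {
    return(structure(list(test = "kruskal_wallis", statistic = 0,
                          df = nlevels(groups) - 1L, p = 1,
                          groups = levels(groups), degenerate = TRUE),
                     class = "test_result"))
  }
  kt <- kruskal.test(values, groups)
  structure(list(test = "kruskal_wallis",
                 statistic = unname(kt$statistic),
                 df = unname(kt$parameter), p = kt$p.value,
                 groups = levels(groups), degenerate = FALSE),
            class = "test_result")
}

#' Dunn's post-hoc test of multiple comparisons
#'
#' Two-sided pairwise z tests on mean-rank differences with the pooled tie
#' correction in the standard error,
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))`
#' with `T = sum(t^3 - t)` over tie groups, Bonferroni-adjusted over all
#' pairs.
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length.
#' @param adjust Only `"bonferroni"` is supported.
#' @return Data frame `group1`, `group2`, `z`, `p`, `p_adjusted`.
#' @export
dunn_posthoc <- function(values, groups, adjust = "bonferroni") {
  stopifnot(adjust == "bonferroni")
  groups <- droplevels(as.factor(groups))
  k <- nlevels(groups)
  if (k < 2) stop("need >= 2 groups")
  if (any(table(groups) == 0)) stop("empty group")
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  ties <- table(values)
  T_ties <- sum(ties^3 - ties)
  s2 <- N * (N + 1) / 12 - T_ties / (12 * (N - 1))
  pairs <- utils::combn(levels(groups), 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    se <- sqrt(s2 * (1 / n[[g1]] + 1 / n[[g2]]))
    z <- if (se == 0) 0 else (rbar[[g1]] - rbar[[g2]]) / se
    p <- 2 * pnorm(-abs(z))
    data.frame(group1 = g1, group2 = g2, z = z, p = p,
               p_adjusted = min(1, p * m))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Ties-corrected Spearman rank correlation
#'
#' rho is the Pearson correlation of midranks (the ties-corrected form);
#' the two-sided p-value uses the t approximation on n - 2 df.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return List `rho`, `p`, `n`, `degenerate` (TRUE when either midrank
#'   vector has zero variance, in which case rho is NA).
#' @export
spearman_cor <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need n >= 3")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  }
  rho <- cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), n - 2)
  }
  list(rho = rho, p = p, n = n, degenerate = FALSE)
}

#' Chi-square test of independence
#'
#' Pearson chi-square on an r x c contingency table, without continuity
#' correction (the Yates correction is off by default even for 2 x 2;
#' set `correct = TRUE` to enable it).
#'
#' @param table Matrix or table of counts.
#' @param correct Apply the Yates continuity correction (2 x 2 only).
#' @return List of class `test_result`: `test`, `statistic`, `df`, `p`,
#'   `expected`.
#' @export
chi_square_independence <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero row or column margin")
  }
  ct <- suppressWarnings(chisq.test(table, correct = correct))
  structure(list(test = "chi_square_independence",
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value,
                 expected = ct$expected),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, df = %s, p = %.4g\n", x$test,
              x$statistic, paste(x$df, collapse = ","), x$p))
  invisible(x)
}
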