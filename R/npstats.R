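# Exact nonparametric inference: Wilcoxon rank-sum and signed-rank tests
# (permutation-exact under ties via mid-ranks), Steel-Dwass all-pairs
# comparisons, significance markers and compact letter displays.
#
# Exact tail probabilities are computed by generating-function counting
# (subset-sum dynamic programming) over doubled mid-ranks, which are always
# integers. This enumerates the full permutation null — all C(m+n, n) group
# labelings for the rank-sum test, all 2^n sign patterns for the signed-rank
# test — without materializing individual arrangements.

# Counts of j-subsets of `weights` (non-negative integers) by subset sum.
# Returns the vector of counts for subsets of size m, indexed by sum + 1.
count_subset_sums <- function(weights, m) {
  S <- sum(weights)
  f <- matrix(0, nrow = m + 1L, ncol = S + 1L)
  f[1L, 1L] <- 1
  for (r in weights) {
    top <- m
    if (r == 0L) next
    for (j in seq(top, 1L)) {
      f[j + 1L, (r + 1L):(S + 1L)] <-
        f[j + 1L, (r + 1L):(S + 1L)] + f[j, 1L:(S + 1L - r)]
    }
  }
  f[m + 1L, ]
}

# Counts of all subsets (any size) of `weights` by subset sum.
count_sign_sums <- function(weights) {
  S <- sum(weights)
  g <- numeric(S + 1L)
  g[1L] <- 1
  for (r in weights) {
    if (r == 0L) { g <- 2 * g; next }
    g[(r + 1L):(S + 1L)] <- g[(r + 1L):(S + 1L)] + g[1L:(S + 1L - r)]
  }
  g
}

two_sided_from_tails <- function(p_lower, p_upper) min(1, 2 * min(p_lower, p_upper))

tie_correction <- function(ranks) {
  t <- table(ranks)
  sum(t^3 - t)
}

np_result <- function(method, statistic, p_value, alternative, exact, n) {
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 alternative = alternative, exact = exact, n = n,
                 marker = apply_markers(p_value)),
            class = "np_test_result")
}

#' @export
print.np_test_result <- function(x, ...) {
  cat(x$method, if (x$exact) "(exact)" else "(normal approximation)", "\n")
  cat(sprintf("  %s = %g, n = %s, %s p = %.6g  %s\n",
              names(x$statistic)[1], x$statistic,
              paste(x$n, collapse = "/"), x$alternative, x$p_value,
              x$marker))
  invisible(x)
}

#' Wilcoxon rank-sum test (exact or normal approximation)
#'
#' Two-sample rank-sum test on independent groups. In exact mode the test
#' enumerates the permutation null of the rank-sum statistic over all
#' `choose(m + n, n)` assignments of the pooled mid-ranked data, so it
#' remains exact in the presence of ties; the two-sided p-value doubles the
#' smaller tail (capped at 1). The normal approximation uses the
#' tie-corrected variance, with an optional continuity correction. `"auto"`
#' switches to the approximation when the number of arrangements exceeds
#' `budget`.
#'
#' @param x,y numeric vectors (both non-empty, finite).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`,
#'   with respect to `x`.
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @param correct apply the continuity correction in approximate mode?
#' @param budget maximum number of arrangements for automatic exact mode.
#' @return An object of class `np_test_result` with the rank-sum statistic
#'   `W` (sum of `x`'s pooled mid-ranks), the p-value, and a significance
#'   marker.
#' @export
rank_sum_test <- function(x, y,
                          alternative = c("two.sided", "less", "greater"),
                          mode = c("auto", "exact", "approx"),
                          correct = TRUE, budget = 2e6) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  if (!length(x) || !length(y))
    stop("both groups must be non-empty", call. = FALSE)
  if (anyNA(x) || anyNA(y) || !all(is.finite(c(x, y))))
    stop("values must be finite and non-missing", call. = FALSE)
  m <- length(x); n <- length(y); N <- m + n
  ranks <- rank(c(x, y))
  W <- sum(ranks[seq_len(m)])
  exact <- switch(mode, exact = TRUE, approx = FALSE,
                  auto = choose(N, n) <= budget)
  if (exact) {
    r2 <- as.integer(round(2 * ranks))
    counts <- count_subset_sums(r2, m)
    total <- choose(N, m)
    w2 <- as.integer(round(2 * W))
    sums <- seq_along(counts) - 1L
    p_lower <- sum(counts[sums <= w2]) / total
    p_upper <- sum(counts[sums >= w2]) / total
    p <- switch(alternative,
                two.sided = two_sided_from_tails(p_lower, p_upper),
                less = p_lower, greater = p_upper)
  } else {
    mu <- m * (N + 1) / 2
    sigma2 <- m * n / 12 * ((N + 1) - tie_correction(ranks) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      cc <- if (correct) 0.5 else 0
      sd0 <- sqrt(sigma2)
      p <- switch(alternative,
        two.sided = {
          d <- W - mu
          z <- (abs(d) - cc) / sd0
          min(1, 2 * stats::pnorm(-max(z, 0)))
        },
        less = stats::pnorm((W - mu + cc) / sd0),
        greater = stats::pnorm(-(W - mu - cc) / sd0))
    }
  }
  np_result("Wilcoxon rank-sum test", c(W = W), p, alternative, exact,
            c(m, n))
}

#' Wilcoxon signed-rank test (exact or normal approximation)
#'
#' Paired test on per-subject differences. Zero differences are dropped
#' before ranking (Wilcoxon's convention; configurable to fail instead);
#' tied absolute differences receive mid-ranks. Exact mode enumerates all
#' `2^n` sign assignments of the ranked absolute differences; the two-sided
#' p doubles the smaller tail, capped at 1.
#'
#' @param x numeric vector: condition-A values, or the differences
#'   themselves if `y` is `NULL`.
#' @param y optional condition-B values paired with `x`.
#' @param alternative `"two.sided"`, `"less"` or `"greater"` for the
#'   location of `x - y`.
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @param zero_policy `"drop"` zero differences (default) or `"fail"`.
#' @param correct continuity correction in approximate mode.
#' @param budget maximum number of sign patterns for automatic exact mode.
#' @return An `np_test_result` with statistic `V` (sum of ranks of positive
#'   differences).
#' @export
signed_rank_test <- function(x, y = NULL,
                             alternative = c("two.sided", "less", "greater"),
                             mode = c("auto", "exact", "approx"),
                             zero_policy = c("drop", "fail"),
                             correct = TRUE, budget = 2e6) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  zero_policy <- match.arg(zero_policy)
  d <- if (is.null(y)) x else {
    if (length(x) != length(y))
      stop("paired samples must have equal length", call. = FALSE)
    x - y
  }
  if (anyNA(d) || !all(is.finite(d)))
    stop("differences must be finite and non-missing", call. = FALSE)
  if (any(d == 0)) {
    if (zero_policy == "fail")
      stop("zero differences present", call. = FALSE)
    d <- d[d != 0]
  }
  n <- length(d)
  if (n == 0L)
    stop("all differences are zero; signed-rank test is degenerate",
         call. = FALSE)
  ranks <- rank(abs(d))
  V <- sum(ranks[d > 0])
  exact <- switch(mode, exact = TRUE, approx = FALSE, auto = 2^n <= budget)
  if (exact) {
    r2 <- as.integer(round(2 * ranks))
    counts <- count_sign_sums(r2)
    total <- 2^n
    v2 <- as.integer(round(2 * V))
    sums <- seq_along(counts) - 1L
    p_lower <- sum(counts[sums <= v2]) / total
    p_upper <- sum(counts[sums >= v2]) / total
    p <- switch(alternative,
                two.sided = two_sided_from_tails(p_lower, p_upper),
                less = p_lower, greater = p_upper)
  } else {
    mu <- n * (n + 1) / 4
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - tie_correction(ranks) / 48
    if (sigma2 <= 0) {
      p <- 1
    } else {
      cc <- if (correct) 0.5 else 0
      sd0 <- sqrt(sigma2)
      p <- switch(alternative,
        two.sided = {
          z <- (abs(V - mu) - cc) / sd0
          min(1, 2 * stats::pnorm(-max(z, 0)))
        },
        less = stats::pnorm((V - mu + cc) / sd0),
        greater = stats::pnorm(-(V - mu - cc) / sd0))
    }
  }
  np_result("Wilcoxon signed-rank test", c(V = V), p, alternative, exact, n)
}

#' Steel-Dwass all-pairs nonparametric comparison
#'
#' For every unordered pair of groups, the two groups are ranked jointly
#' (mid-ranks for ties) and the rank-sum of the first group is standardized
#' by its tie-corrected null mean and variance to a z-score; the statistic
#' `q = |z| * sqrt(2)` is referred to the studentized-range distribution with
#' `k` groups and infinite degrees of freedom, which controls the
#' family-wise error rate across all `k(k-1)/2` comparisons. No continuity
#' correction is applied.
#'
#' @param groups named list of numeric vectors (k >= 2).
#' @param alpha family-wise significance level for markers.
#' @return A `data.frame` of class `pairwise_results` with one row per pair:
#'   `group_i`, `group_j`, sizes, `z`, `q`, `p_value`, `marker`. Attributes:
#'   `alpha`, `k`, per-group `medians`, and any small-group `warnings`.
#' @export
steel_dwass <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || is.null(names(groups)) || any(names(groups) == ""))
    stop("`groups` must be a named list of numeric vectors", call. = FALSE)
  k <- length(groups)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  if (anyDuplicated(names(groups)))
    stop("group names must be unique", call. = FALSE)
  sizes <- lengths(groups)
  warnings <- character(0)
  small <- names(groups)[sizes < 2L]
  if (length(small))
    warnings <- paste0("group(s) with fewer than 2 observations: ",
                       paste(small, collapse = ", "))
  labs <- names(groups)
  pairs <- utils::combn(labs, 2)
  rows <- apply(pairs, 2, function(pr) {
    xi <- groups[[pr[1]]]; xj <- groups[[pr[2]]]
    ni <- length(xi); nj <- length(xj); N <- ni + nj
    rk <- rank(c(xi, xj))
    Ri <- sum(rk[seq_len(ni)])
    mu <- ni * (N + 1) / 2
    sigma2 <- ni * nj / 12 * ((N + 1) - tie_correction(rk) / (N * (N - 1)))
    z <- if (sigma2 > 0) (Ri - mu) / sqrt(sigma2) else 0
    q <- sqrt(2) * abs(z)
    p <- stats::ptukey(q, nmeans = k, df = Inf, lower.tail = FALSE)
    data.frame(group_i = pr[1], group_j = pr[2], n_i = ni, n_j = nj,
               z = z, q = q, p_value = p, marker = apply_markers(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "k") <- k
  attr(out, "medians") <- vapply(groups, stats::median, 0)
  attr(out, "warnings") <- warnings
  class(out) <- c("pairwise_results", "data.frame")
  out
}

#' @export
print.pairwise_results <- function(x, ...) {
  cat(sprintf("Steel-Dwass all-pairs comparisons (k = %d, alpha = %g)\n",
              attr(x, "k"), attr(x, "alpha")))
  print.data.frame(x, digits = 4)
  w <- attr(x, "warnings")
  if (length(w)) cat("warning:", w, "\n")
  invisible(x)
}

#' Compact letter display from pairwise results
#'
#' Assigns letters to groups by the insert-and-absorb algorithm so that two
#' groups share at least one letter exactly when their pairwise comparison
#' is NOT significant at `alpha`. Letters are ordered by group medians: the
#' group with the highest median carries `"a"`.
#'
#' @param pw a [steel_dwass] result, or any `data.frame` with columns
#'   `group_i`, `group_j`, `p_value` covering all unordered pairs.
#' @param alpha significance level (defaults to the one stored in `pw`).
#' @param medians optional named vector of group medians used to order
#'   letters (defaults to those stored in `pw`).
#' @return An object of class `letter_assignment`: named list mapping each
#'   group to its character vector of letters, plus a `letters` string form.
#' @export
compact_letters <- function(pw, alpha = NULL, medians = NULL) {
  if (is.null(alpha)) alpha <- attr(pw, "alpha")
  if (is.null(alpha)) alpha <- 0.05
  if (is.null(medians)) medians <- attr(pw, "medians")
  groups <- unique(c(pw$group_i, pw$group_j))
  k <- length(groups)
  if (nrow(pw) != k * (k - 1) / 2)
    stop("incomplete pairwise results: need all k(k-1)/2 pairs",
         call. = FALSE)
  if (is.null(medians)) medians <- stats::setNames(rep(0, k), groups)
  # order groups by median, highest first; ties broken by name for stability
  ord <- groups[order(-medians[groups], groups)]
  sig <- pw[pw$p_value < alpha, , drop = FALSE]

  absorb <- function(cols) {
    keep <- rep(TRUE, length(cols))
    for (i in seq_along(cols)) {
      for (j in seq_along(cols)) {
        if (i != j && keep[j] && all(cols[[i]] %in% cols[[j]]) &&
            (length(cols[[i]]) < length(cols[[j]]) || i > j)) {
          keep[i] <- FALSE
          break
        }
      }
    }
    cols[keep]
  }

  cols <- list(ord)
  if (nrow(sig)) {
    for (r in seq_len(nrow(sig))) {
      a <- sig$group_i[r]; b <- sig$group_j[r]
      nxt <- list()
      for (col in cols) {
        if (a %in% col && b %in% col) {
          nxt <- c(nxt, list(setdiff(col, a), setdiff(col, b)))
        } else nxt <- c(nxt, list(col))
      }
      cols <- absorb(nxt)
    }
  }
  cols <- Filter(length, cols)
  # order columns by their best-ranked (highest-median) member
  pos <- vapply(cols, function(col) min(match(col, ord)), 0)
  cols <- cols[order(pos)]
  lett <- letters[seq_along(cols)]
  assign <- lapply(stats::setNames(ord, ord), function(g)
    lett[vapply(cols, function(col) g %in% col, TRUE)])
  structure(list(groups = ord, assignment = assign,
                 letters = vapply(assign, paste0, "", collapse = ""),
                 alpha = alpha),
            class = "letter_assignment")
}

#' @export
print.letter_assignment <- function(x, ...) {
  cat(sprintf("Compact letter display (alpha = %g)\n", x$alpha))
  for (g in x$groups)
    cat(sprintf("  %-12s %s\n", g, x$letters[[g]]))
  invisible(x)
}

#' Significance markers
#'
#' Maps p-values to the marker convention used in the figures:
#' `p < 0.01` gives `"**"`, `0.01 <= p < 0.05` gives `"*"`, anything else
#' `"N.S."` (strict inequalities).
#'
#' @param p_value numeric vector of p-values in `[0, 1]`.
#' @return character vector of markers.
#' @export
apply_markers <- function(p_value) {
  if (any(!is.finite(p_value)) || any(p_value < 0) || any(p_value > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  ifelse(p_value < 0.01, "**", ifelse(p_value < 0.05, "*", "N.S."))
}
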