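# Mann-Kendall monotone-trend test with tie correction and exact
# small-sample p-values.

#' Mann-Kendall trend test
#'
#' Tests an ordered series for monotone trend via
#' `S = sum over i < j of sign(x_j - x_i)`. The variance is tie-corrected,
#' `var_S = [n(n-1)(2n+5) - sum_t t(t-1)(2t+5)] / 18` over tie groups of
#' size t, and the two-sided p-value uses the normal approximation with
#' continuity correction ((S-1)/sqrt(var) for S > 0, (S+1)/sqrt(var) for
#' S < 0, z = 0 at S = 0). For n <= 10 an exact permutation p-value over the
#' orderings of the observed values is also reported (`p_exact`): by full
#' enumeration of distinct orderings when ties are present, or by the
#' inversion-count recursion when all values are distinct. An all-equal
#' series gives S = 0, p = 1.
#'
#' @param x Numeric series in its natural order (n >= 3).
#' @return A list of class `mk_trend`: `s`, `var_s`, `z`, `p_value`
#'   (normal approximation), `p_exact` (NA when unavailable), `n`.
#' @examples
#' mann_kendall(c(1, 2, 3, 4))
#' @export
mann_kendall <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3) stopf("mann_kendall: need n >= 3")
  s <- mk_s(x)
  ties <- table(x)
  var_s <- (n * (n - 1) * (2 * n + 5) -
            sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  if (var_s <= 0) {
    res <- list(s = s, var_s = 0, z = 0, p_value = 1, p_exact = 1, n = n)
    class(res) <- "mk_trend"
    return(res)
  }
  z <- if (s > 0) (s - 1) / sqrt(var_s) else if (s < 0) (s + 1) / sqrt(var_s) else 0
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  p_exact <- if (n <= 10) mk_exact_p(x, s) else NA_real_
  res <- list(s = s, var_s = var_s, z = z, p_value = p, p_exact = p_exact, n = n)
  class(res) <- "mk_trend"
  res
}

#' @export
print.mk_trend <- function(x, ...) {
  cat(sprintf("<mk_trend> n=%d S=%d var_S=%.3f z=%.3f p=%.4g%s\n",
              x$n, x$s, x$var_s, x$z, x$p_value,
              if (is.na(x$p_exact)) "" else sprintf(" p_exact=%.4g", x$p_exact)))
  invisible(x)
}

#' @keywords internal
#' @noRd
mk_s <- function(x) {
  n <- length(x)
  s <- 0L
  for (i in seq_len(n - 1)) {
    s <- s + sum(sign(x[(i + 1):n] - x[i]))
  }
  as.integer(s)
}

# Exact two-sided permutation p-value: P(|S_perm| >= |S_obs|) over the
# distinct orderings of the observed multiset.
#' @keywords internal
#' @noRd
mk_exact_p <- function(x, s_obs) {
  n <- length(x)
  if (!anyDuplicated(x)) {
    counts <- mk_s_distribution(n)       # counts over S = -n(n-1)/2 .. n(n-1)/2
    svals <- seq(-n * (n - 1) / 2, n * (n - 1) / 2, by = 2)
    return(sum(counts[abs(svals) >= abs(s_obs)]) / sum(counts))
  }
  n_distinct <- factorial(n) / prod(factorial(table(x)))
  if (n_distinct > 2e5) return(NA_real_)
  svals <- mk_enumerate_s(sort(x))
  mean(abs(svals) >= abs(s_obs))
}

# Distribution of S for distinct values: number of permutations of 1..n with
# k inversions, by the classical convolution; S = n(n-1)/2 - 2k.
#' @keywords internal
#' @noRd
mk_s_distribution <- function(n) {
  counts <- 1
  for (i in 2:n) {
    # convolve with 1 + q + ... + q^(i-1): sliding-window sums of width i
    padded <- c(counts, rep(0, i - 1))
    cs <- cumsum(padded)
    new <- cs
    if (length(cs) > i) {
      new[(i + 1):length(cs)] <- cs[(i + 1):length(cs)] - cs[1:(length(cs) - i)]
    }
    counts <- new
  }
  # counts[k + 1] = permutations with k inversions; S = n(n-1)/2 - 2k
  rev(as.numeric(counts))
}

# Enumerate S over all distinct permutations of a sorted multiset.
#' @keywords internal
#' @noRd
mk_enumerate_s <- function(pool) {
  results <- numeric(0)
  recurse <- function(prefix, remaining) {
    if (!length(remaining)) {
      results[[length(results) + 1]] <<- mk_s(prefix)
      return(invisible(NULL))
    }
    for (v in unique(remaining)) {
      idx <- match(v, remaining)
      recurse(c(prefix, v), remaining[-idx])
    }
  }
  recurse(numeric(0), pool)
  results
}

#' Monotone trend of a score across ordered grades
#'
#' Computes the median score within each grade (in the given grade order)
#' and applies [mann_kendall()] to the median sequence — the stage-trend
#' statistic used for progression scores.
#'
#' @param values Numeric scores, one per sample/cell.
#' @param grades Ordered grade labels aligned with `values`; order taken
#'   from factor levels (or sorted unique values). Every grade must be
#'   non-empty, and >= 3 grades are required.
#' @return A list: the `mk_trend` result plus `medians` (named by grade).
#' @export
grade_trend <- function(values, grades) {
  if (length(values) != length(grades)) stopf("grade_trend: values and grades must align")
  levs <- if (is.factor(grades)) levels(grades) else sort(unique(as.character(grades)))
  if (length(levs) < 3) stopf("grade_trend: need >= 3 ordered grades")
  med <- vapply(levs, function(g) {
    v <- values[as.character(grades) == g]
    if (!length(v)) stopf("grade_trend: grade '%s' is empty", g)
    stats::median(v)
  }, numeric(1))
  res <- mann_kendall(med)
  res$medians <- med
  res
}
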