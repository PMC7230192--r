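# Exact and classical tests used on the breeding data, implemented from first
# principles: Pearson goodness-of-fit without continuity correction,
# Fisher exact tests (2x2 and r x c) by complete enumeration of tables with
# the observed margins, the exact binomial, and the two-sample t.  Two-sided
# p-values for all exact tests follow the probability-ordering rule: the sum
# of probabilities of outcomes no more probable than the observed one.
# Probabilities are accumulated in log space so n ~ 300 tables are safe.

.P_TIE_TOL <- 1e-7  # relative tolerance when comparing outcome probabilities

new_test_result <- function(method, p_value, statistic = NA_real_,
                            df = NA_real_, ...) {
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p_value, ...),
            class = "neoxy_test")
}

#' @export
print.neoxy_test <- function(x, ...) {
  cat("<", x$method, ">\n", sep = "")
  if (!is.na(x$statistic))
    cat("  statistic =", format(x$statistic, digits = 6),
        if (!is.na(x$df)) paste0(" (df = ", x$df, ")") else "", "\n")
  cat("  p-value =", format.pval(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' Chi-square goodness-of-fit test
#'
#' Pearson goodness-of-fit statistic \eqn{\sum (O-E)^2/E} of observed counts
#' against hypothesized category probabilities, with no continuity
#' correction, and p-value from the chi-square distribution on k - 1 degrees
#' of freedom.  This is the test applied to offspring sex ratios against the
#' even-ratio null.
#'
#' @param observed non-negative integer count vector (length >= 2).
#' @param expected_probs probabilities summing to 1, same length.
#' @return A \code{"neoxy_test"} result with \code{statistic}, \code{df} and
#'   \code{p_value}.
#' @examples
#' chi2_gof(c(54, 95), c(0.5, 0.5))    # sex ratio of KII-dam progeny
#' @export
chi2_gof <- function(observed, expected_probs = NULL) {
  k <- length(observed)
  if (is.null(expected_probs)) expected_probs <- rep(1 / k, k)
  if (k < 2L || length(expected_probs) != k)
    stop("'observed' and 'expected_probs' must have equal length >= 2",
         call. = FALSE)
  if (any(observed < 0)) stop("counts must be non-negative", call. = FALSE)
  if (abs(sum(expected_probs) - 1) > 1e-8)
    stop("'expected_probs' must sum to 1", call. = FALSE)
  e <- sum(observed) * expected_probs
  if (any(e == 0)) stop("zero expected count", call. = FALSE)
  stat <- sum((observed - e)^2 / e)
  new_test_result("chi-square goodness-of-fit", statistic = stat, df = k - 1,
                  p_value = stats::pchisq(stat, df = k - 1, lower.tail = FALSE))
}

# log probability of an r x c table under the multivariate hypergeometric
# distribution conditional on its margins:
#   P = prod(row!) prod(col!) / ( n! prod(cell!) )
log_table_prob <- function(tab) {
  n <- sum(tab)
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(n + 1) - sum(lgamma(tab + 1))
}

# Enumerate all non-negative integer tables with the given margins, calling
# fn(tab) for each.  Cells are filled row-wise; the last column and last row
# are forced by the margins.  'guard' bounds the number of visited tables.
enumerate_tables <- function(row_margins, col_margins, fn, guard = 1e7) {
  r <- length(row_margins); cc <- length(col_margins)
  count <- 0L
  tab <- matrix(0L, r, cc)
  rec <- function(i, j, row_left, col_left) {
    if (i == r) {
      # last row forced
      if (any(col_left < 0)) return()
      tab[r, ] <<- col_left
      count <<- count + 1L
      if (count > guard)
        stop("Fisher enumeration guard exceeded (more than ", guard,
             " tables); use a Monte-Carlo approximation instead",
             call. = FALSE)
      fn(tab)
      return()
    }
    if (j == cc) {
      # last cell in row forced
      x <- row_left
      if (x < 0 || x > col_left[cc]) return()
      tab[i, cc] <<- x
      cl <- col_left; cl[cc] <- cl[cc] - x
      rec(i + 1L, 1L, row_margins[i + 1L], cl)
      return()
    }
    for (x in 0:min(row_left, col_left[j])) {
      tab[i, j] <<- x
      cl <- col_left; cl[j] <- cl[j] - x
      rec(i, j + 1L, row_left - x, cl)
    }
  }
  rec(1L, 1L, row_margins[1L], col_margins)
  invisible(count)
}

#' Fisher exact tests by complete enumeration
#'
#' \code{fisher_exact_2x2()} tests association in a 2x2 table conditioned on
#' its margins (hypergeometric); \code{fisher_exact_rxc()} generalizes to any
#' r x c table by complete enumeration of all tables with the observed
#' margins under the multivariate hypergeometric distribution.  The
#' two-sided p-value is the total probability of tables no more probable
#' than the observed one.  One-sided alternatives (2x2 only) are tail sums
#' over the top-left cell.  A zero margin makes the table degenerate and
#' returns p = 1.
#'
#' @param table a matrix of non-negative integer counts.
#' @param alternative \code{"two.sided"} (default), \code{"greater"} or
#'   \code{"less"}; for \code{"greater"} the odds ratio of the 2x2 table
#'   exceeds 1, i.e. the [1,1] cell is large.
#' @param guard maximum number of tables enumerated before aborting.
#' @return A \code{"neoxy_test"} result.
#' @examples
#' fisher_exact_2x2(matrix(c(54, 7, 95, 0), 2))         # KII vs KIV sex ratios
#' fisher_exact_rxc(rbind(c(9, 25, 3), c(21, 6, 0)))    # daughter karyomorphs
#' @export
fisher_exact_2x2 <- function(table, alternative = "two.sided") {
  alternative <- match.arg(alternative, c("two.sided", "greater", "less"))
  tab <- as.matrix(table)
  check_count_table(tab)
  if (!all(dim(tab) == c(2L, 2L)))
    stop("'table' must be 2 x 2", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(new_test_result("Fisher exact test (2x2)", p_value = 1))
  m <- rowSums(tab); k <- colSums(tab)
  # support of the [1,1] cell given the margins
  lo <- max(0L, k[1L] - m[2L]); hi <- min(k[1L], m[1L])
  xs <- lo:hi
  logp <- vapply(xs, function(x) {
    t2 <- matrix(c(x, k[1L] - x, m[1L] - x, m[2L] - k[1L] + x), 2L)
    log_table_prob(t2)
  }, 0)
  obs <- tab[1L, 1L]
  lp_obs <- logp[match(obs, xs)]
  p <- switch(alternative,
    two.sided = sum(exp(logp[logp <= lp_obs + .P_TIE_TOL])),
    greater   = sum(exp(logp[xs >= obs])),
    less      = sum(exp(logp[xs <= obs])))
  new_test_result("Fisher exact test (2x2)", p_value = min(1, p),
                  alternative = alternative)
}

#' @rdname fisher_exact_2x2
#' @export
fisher_exact_rxc <- function(table, guard = 1e7) {
  tab <- as.matrix(table)
  check_count_table(tab)
  rm <- rowSums(tab); cm <- colSums(tab)
  if (any(rm == 0) || any(cm == 0)) {
    tab <- tab[rm > 0, cm > 0, drop = FALSE]
    if (any(dim(tab) < 2L))
      return(new_test_result("Fisher exact test (r x c)", p_value = 1))
    rm <- rowSums(tab); cm <- colSums(tab)
  }
  lp_obs <- log_table_prob(tab)
  acc <- 0
  enumerate_tables(rm, cm, function(t2) {
    lp <- log_table_prob(t2)
    if (lp <= lp_obs + .P_TIE_TOL) acc <<- acc + exp(lp)
  }, guard = guard)
  new_test_result("Fisher exact test (r x c)", p_value = min(1, acc))
}

check_count_table <- function(tab) {
  if (anyNA(tab) || any(tab < 0) || any(tab != round(tab)))
    stop("'table' must contain non-negative integer counts", call. = FALSE)
  invisible(tab)
}

#' Exact binomial test (two-sided)
#'
#' Exact test of \code{k} successes in \code{n} trials against success
#' probability \code{p0}, two-sided by the probability-ordering rule: the sum
#' of binomial point probabilities not exceeding that of the observed count.
#'
#' @param k,n observed successes and trials, \code{0 <= k <= n}.
#' @param p0 null success probability, strictly inside (0, 1).
#' @return A \code{"neoxy_test"} result.
#' @examples
#' binomial_two_sided(7, 7, 0.5)    # all-son progeny of KIV dams
#' @export
binomial_two_sided <- function(k, n, p0 = 0.5) {
  if (!is.numeric(p0) || length(p0) != 1L || is.na(p0) || p0 <= 0 || p0 >= 1)
    stop("'p0' must lie strictly inside (0, 1)", call. = FALSE)
  if (k < 0 || k > n || k != round(k) || n != round(n))
    stop("'k' must be an integer in [0, n]", call. = FALSE)
  if (n == 0) return(new_test_result("exact binomial test", p_value = 1))
  lp <- stats::dbinom(0:n, n, p0, log = TRUE)
  p <- sum(exp(lp[lp <= lp[k + 1L] + .P_TIE_TOL]))
  new_test_result("exact binomial test", p_value = min(1, p))
}

#' Two-sample t test
#'
#' Student (pooled-variance) or Welch two-sample t statistic with a
#' two-tailed p-value, as used for comparing reproductive-success measures
#' between dam karyomorphs.
#'
#' @param x,y numeric samples of size >= 2.
#' @param welch if \code{TRUE}, use the Welch statistic with
#'   Satterthwaite degrees of freedom instead of pooling variances.
#' @return A \code{"neoxy_test"} result with \code{statistic} (t) and
#'   \code{df}.
#' @examples
#' two_sample_t(c(1, 2, 3), c(1, 2, 3, 4, 5, 6))
#' @export
two_sample_t <- function(x, y, welch = FALSE) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L)
    stop("each sample needs at least two observations", call. = FALSE)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0)
    stop("both samples have zero variance", call. = FALSE)
  if (welch) {
    se2 <- vx / nx + vy / ny
    stat <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    method <- "Welch two-sample t test"
  } else {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    stat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
    method <- "Student two-sample t test (pooled)"
  }
  new_test_result(method, statistic = stat, df = df,
                  p_value = 2 * stats::pt(-abs(stat), df = df))
}
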