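#' Upper-tail hypergeometric probability (one-sided over-representation)
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): drawing `n` genes from a
#' universe of `N` of which `K` are annotated to the term, the probability of
#' seeing at least the observed overlap `k`. This is the one-sided Fisher
#' exact test for over-representation. Computed in log space for stability.
#'
#' @param k Observed overlap (0 <= k <= min(K, n)).
#' @param K Term size (number of annotated genes in the universe).
#' @param n Query size.
#' @param N Universe size.
#' @return The tail probability in `[0, 1]`.
#' @export
hypergeom_tail <- function(k, K, n, N) {
  stopifnot(length(k) == 1L, length(K) == 1L, length(n) == 1L, length(N) == 1L)
  k <- as.integer(k); K <- as.integer(K); n <- as.integer(n); N <- as.integer(N)
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n))
    stop("inconsistent hypergeometric counts: need 0 <= k <= min(K, n) and K, n <= N")
  if (k == 0L) return(1)
  i <- k:min(K, n)
  i <- i[n - i <= N - K]                     # feasible overlaps only
  logp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  mx <- max(logp)
  min(1, exp(mx + log(sum(exp(logp - mx)))))
}

# polynomial in x with coefficients cc[1] + cc[2] x + ...
.poly <- function(cc, x) sum(cc * x^(seq_along(cc) - 1L))

#' Shapiro-Wilk normality test
#'
#' The W statistic with Royston's (1995) weight and p-value approximations
#' (algorithm AS R94), valid for sample sizes 3 to 5000. W near 1 indicates
#' agreement with a normal distribution; the p-value is the upper tail of the
#' normalized transform of W.
#'
#' @param x Numeric sample, 3 <= length(x) <= 5000, not all equal.
#' @return A list with `W`, `p` and `n`.
#' @export
shapiro_wilk <- function(x) {
  x <- sort(as.numeric(x[!is.na(x)]))
  n <- length(x)
  if (n < 3L || n > 5000L)
    stop("Shapiro-Wilk test requires 3 <= n <= 5000 (got n = ", n, ")")
  if (x[n] - x[1L] <= 0)
    stop("Shapiro-Wilk test is undefined for a constant sample")

  nn2 <- n %/% 2L
  if (n == 3L) {
    a <- sqrt(0.5)
  } else {
    m <- stats::qnorm((seq_len(nn2) - 0.375) / (n + 0.25))
    summ2 <- 2 * sum(m^2)
    ssumm2 <- sqrt(summ2)
    rsn <- 1 / sqrt(n)
    c1 <- c(0, 0.221157, -0.147981, -2.071190, 4.434685, -2.706056)
    c2 <- c(0, 0.042981, -0.293762, -1.752461, 5.682633, -3.582633)
    a1 <- .poly(c1, rsn) - m[1L] / ssumm2
    a <- numeric(nn2)
    if (n > 5L) {
      a2 <- .poly(c2, rsn) - m[2L] / ssumm2
      fac <- sqrt((summ2 - 2 * m[1L]^2 - 2 * m[2L]^2) /
                  (1 - 2 * a1^2 - 2 * a2^2))
      a[2L] <- a2
      i1 <- 3L
    } else {
      fac <- sqrt((summ2 - 2 * m[1L]^2) / (1 - 2 * a1^2))
      i1 <- 2L
    }
    a[1L] <- a1
    if (i1 <= nn2) a[i1:nn2] <- -m[i1:nn2] / fac
  }
  # full weight vector: -a reversed for the lower half, +a for the upper
  w_full <- numeric(n)
  w_full[seq_len(nn2)] <- -a[seq_len(nn2)]
  w_full[n + 1L - seq_len(nn2)] <- a[seq_len(nn2)]
  W <- sum(w_full * x)^2 / sum((x - mean(x))^2)
  if (W > 1) W <- 1

  if (n == 3L) {
    p <- (6 / pi) * (asin(sqrt(W)) - asin(sqrt(0.75)))
    p <- min(1, max(0, p))
  } else {
    y <- log(1 - W)
    if (n <= 11L) {
      gam <- .poly(c(-2.273, 0.459), n)
      if (y >= gam) {
        p <- 1e-99
      } else {
        y <- -log(gam - y)
        mu <- .poly(c(0.5440, -0.39978, 0.025054, -6.714e-4), n)
        sig <- exp(.poly(c(1.3822, -0.77857, 0.062767, -0.0020322), n))
        p <- stats::pnorm((y - mu) / sig, lower.tail = FALSE)
      }
    } else {
      ln <- log(n)
      mu <- .poly(c(-1.5861, -0.31082, -0.083751, 0.0038915), ln)
      sig <- exp(.poly(c(-0.4803, -0.082676, 0.0030302), ln))
      p <- stats::pnorm((y - mu) / sig, lower.tail = FALSE)
    }
  }
  list(W = W, p = p, n = n)
}

# U statistic of group a (midranks for ties)
.u_stat <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. `U` is the smaller of the
#' two group statistics (midranks under ties). The p-value is exact — full
#' enumeration of all `choose(n_a + n_b, n_a)` group labelings — when
#' `n_a + n_b <= 20` and there are no ties; otherwise a normal approximation
#' with tie and continuity corrections is used. Two-sided p is twice the
#' smaller one-sided tail, capped at 1.
#'
#' @param a,b Numeric samples (each non-empty).
#' @return A list with `U`, `p_two_sided`, `n_a`, `n_b`, `method`
#'   (`"exact"` or `"normal_approx"`).
#' @export
mann_whitney_u <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b))
    stop("both groups must be non-empty")
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  u_a <- .u_stat(a, b)
  u_b <- n_a * n_b - u_a
  U <- min(u_a, u_b)
  ties <- anyDuplicated(c(a, b)) > 0L
  if (n <= 20L && !ties) {
    r <- rank(c(a, b))
    idx <- utils::combn(n, n_a)
    u_all <- colSums(matrix(r[idx], nrow = n_a)) - n_a * (n_a + 1) / 2
    one_sided <- if (u_a <= n_a * n_b / 2) mean(u_all <= u_a)
                 else mean(u_all >= u_a)
    p <- min(1, 2 * one_sided)
    method <- "exact"
  } else {
    mu <- n_a * n_b / 2
    tab <- table(c(a, b))
    tie_term <- sum(tab^3 - tab) / (n * (n - 1))
    sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- u_a - mu
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
      p <- min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
    }
    method <- "normal_approx"
  }
  list(U = U, p_two_sided = p, n_a = n_a, n_b = n_b, method = method)
}
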