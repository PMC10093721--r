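#' Sample entropy
#'
#' Template-matching regularity statistic: with embedding dimension `m` and
#' tolerance `r = r_frac * sd(x)`, `B` counts ordered pairs of distinct
#' m-length templates within Chebyshev distance `r`, `A` the same for
#' (m+1)-length templates (self-matches excluded, templates taken at
#' `i = 1..N-m`), and `SampEn = -log(A / B)`. A perfectly regular signal
#' gives 0; irregular signals give larger values.
#'
#' When no (m+1)-length template pair matches (`A = 0`) the value is capped
#' at `log(B + 1)` instead of returning infinity, so feature tables stay
#' finite; the cap corresponds to the smallest resolvable conditional
#' probability `1/(B + 1)`.
#'
#' @param x numeric vector with `length(x) > m + 1`.
#' @param m embedding dimension (>= 1).
#' @param r_frac tolerance as a fraction of `sd(x)` (> 0).
#' @return non-negative scalar.
#' @export
sample_entropy <- function(x, m = 2, r_frac = 0.2) {
  check_entropy_input(x, m, r_frac)
  N <- length(x)
  sdx <- stats::sd(x)
  if (sdx == 0) return(0)          # constant: every template matches
  r <- r_frac * sdx
  nt <- N - m                       # templates of length m and m+1 start here
  Dm <- chebyshev_template_dist(x, m, nt)
  Dm1 <- pmax(Dm, chebyshev_template_dist_col(x, m + 1, nt))
  B <- sum(Dm <= r) - nt            # exclude self-matches
  A <- sum(Dm1 <= r) - nt
  if (B <= 0) return(0)
  if (A <= 0) return(log(B + 1))
  -log(A / B)
}

#' Approximate entropy
#'
#' The standard construction `ApEn = Phi^m(r) - Phi^{m+1}(r)` with
#' `Phi^m = mean_i log(C_i^m)` and `C_i^m` the fraction of m-length templates
#' (self-matches included) within Chebyshev distance `r` of template `i`.
#'
#' @inheritParams sample_entropy
#' @return scalar (approximately non-negative; small negative values can
#'   arise from the finite-sample bias of the construction).
#' @export
approximate_entropy <- function(x, m = 2, r_frac = 0.2) {
  check_entropy_input(x, m, r_frac)
  N <- length(x)
  sdx <- stats::sd(x)
  if (sdx == 0) return(0)
  r <- r_frac * sdx
  phi <- function(mm) {
    nt <- N - mm + 1L
    D <- chebyshev_template_dist(x, mm, nt)
    mean(log(rowSums(D <= r) / nt))
  }
  phi(m) - phi(m + 1L)
}

check_entropy_input <- function(x, m, r_frac) {
  if (!is.numeric(x) || !all(is.finite(x))) stop("x must be finite numeric")
  if (m < 1) stop("embedding dimension m must be >= 1")
  if (length(x) <= m + 1) stop("need length(x) > m + 1")
  if (r_frac <= 0) stop("tolerance fraction must be > 0")
}

# nt x nt Chebyshev distance matrix between m-length templates starting at
# 1..nt, built by max-folding over the m lags.
chebyshev_template_dist <- function(x, m, nt) {
  D <- abs(outer(x[seq_len(nt)], x[seq_len(nt)], "-"))
  if (m > 1) {
    for (k in seq_len(m - 1)) {
      xs <- x[(1 + k):(nt + k)]
      D <- pmax(D, abs(outer(xs, xs, "-")))
    }
  }
  D
}

# Distance contribution of only the last column of (m)-length templates
# (used to extend an (m-1)-template distance matrix over the same nt starts).
chebyshev_template_dist_col <- function(x, m, nt) {
  xs <- x[m:(nt + m - 1)]
  abs(outer(xs, xs, "-"))
}

#' Fuzzy (membership) entropy
#'
#' De Luca-Termini fuzzy-set entropy of the window's membership function:
#' memberships are the min-max normalised absolute amplitudes
#' `mu_i = (|x_i| - min|x|) / (max|x| - min|x|)`, and
#' `E = -(1/L) * sum(mu_i log mu_i + (1 - mu_i) log(1 - mu_i))`, with the
#' limit convention that terms at `mu = 0` or `mu = 1` contribute 0. A
#' constant window (degenerate normalisation) returns 0 by convention. The
#' maximum `log 2` is attained when every membership equals 0.5.
#'
#' Note this is a fuzzy-set entropy of the amplitude membership, not the
#' template-matching "FuzzyEn" statistic; the two measure different things.
#'
#' @param x numeric vector, length >= 2.
#' @param mu optional explicit membership vector in `[0, 1]`; when supplied,
#'   `x` is ignored and the entropy of `mu` is returned directly.
#' @return value in `[0, log 2]`.
#' @export
fuzzy_entropy <- function(x, mu = NULL) {
  if (is.null(mu)) {
    if (!is.numeric(x) || length(x) < 2 || !all(is.finite(x))) {
      stop("x must be finite numeric with length >= 2")
    }
    ax <- abs(x)
    rng <- range(ax)
    if (rng[1] == rng[2]) return(0)
    mu <- (ax - rng[1]) / (rng[2] - rng[1])
  }
  if (any(mu < 0 | mu > 1)) stop("memberships must lie in [0, 1]")
  term <- function(p) ifelse(p > 0, p * log(p), 0)
  mean(-(term(mu) + term(1 - mu)))
}

#' Shannon entropy of the amplitude histogram
#'
#' Equal-width histogram over `[min(x), max(x)]` with `bins` bins, natural
#' log, empty bins skipped. Samples uniformly filling `k` bins give `log k`;
#' a constant signal occupies a single bin and gives 0.
#'
#' @param x numeric vector with `length(x) >= bins`.
#' @param bins number of bins (>= 2).
#' @return non-negative scalar.
#' @export
shannon_entropy <- function(x, bins = 16) {
  if (!is.numeric(x) || !all(is.finite(x))) stop("x must be finite numeric")
  if (bins < 2) stop("bins must be >= 2")
  if (length(x) < bins) stop("need length(x) >= bins")
  rng <- range(x)
  if (rng[1] == rng[2]) return(0)
  width <- (rng[2] - rng[1]) / bins
  idx <- pmin(bins, floor((x - rng[1]) / width) + 1L)
  p <- tabulate(idx, nbins = bins) / length(x)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Permutation entropy
#'
#' Entropy (natural log, unnormalised) of the distribution of ordinal
#' patterns of `order` consecutive values taken `delay` samples apart. Ties
#' are broken by index order (earlier sample ranks lower). A strictly
#' monotone signal exhibits a single pattern and gives 0; i.i.d. noise
#' approaches `log(order!)`.
#'
#' @param x numeric vector with `length(x) >= order * delay + 1`.
#' @param order pattern length (>= 2).
#' @param delay lag between pattern elements (>= 1).
#' @return value in `[0, log(order!)]`.
#' @export
permutation_entropy <- function(x, order = 3, delay = 1) {
  if (!is.numeric(x) || !all(is.finite(x))) stop("x must be finite numeric")
  if (order < 2) stop("order must be >= 2")
  if (delay < 1) stop("delay must be >= 1")
  n_pat <- length(x) - (order - 1) * delay
  if (n_pat < 1) stop("need length(x) >= order * delay + 1")
  emb <- vapply(0:(order - 1), function(k) x[(1 + k * delay):(n_pat + k * delay)],
                numeric(n_pat))
  if (n_pat == 1) emb <- matrix(emb, nrow = 1)
  codes <- apply(emb, 1, function(v) paste(order(v), collapse = ""))
  p <- tabulate(factor(codes)) / n_pat
  -sum(p * log(p))
}

#' Higuchi fractal dimension
#'
#' Builds `k`-decimated curve lengths `L(k)` for `k = 1..kmax` (averaged over
#' the `k` phase offsets with Higuchi's end-correction factor) and returns
#' the slope of the least-squares fit of `log L(k)` against `log(1/k)`.
#' A smooth curve gives values near 1; white noise approaches 2.
#'
#' @param x numeric vector, length >= 10.
#' @param kmax largest decimation scale (>= 2).
#' @return scalar, typically in `[1, 2]`.
#' @export
higuchi_fd <- function(x, kmax = 10) {
  if (!is.numeric(x) || !all(is.finite(x))) stop("x must be finite numeric")
  N <- length(x)
  if (N < 10) stop("need length(x) >= 10")
  if (kmax < 2) stop("kmax must be >= 2")
  Lk <- vapply(seq_len(kmax), function(k) {
    lm_k <- vapply(seq_len(k), function(m) {
      n_i <- floor((N - m) / k)
      if (n_i < 1) return(NA_real_)
      idx <- m + (0:n_i) * k
      sum(abs(diff(x[idx]))) * (N - 1) / (n_i * k) / k
    }, numeric(1))
    mean(lm_k, na.rm = TRUE)
  }, numeric(1))
  ok <- is.finite(log(Lk))
  fit <- stats::lm.fit(cbind(1, log(1 / seq_len(kmax))[ok]), log(Lk)[ok])
  unname(fit$coefficients[2])
}

#' Katz fractal dimension
#'
#' With `n` steps, total path length `L = sum(|diff(x)|)` and maximum
#' amplitude excursion from the first point `d = max |x_i - x_1|`, returns
#' `FD = log10(n) / (log10(d/L) + log10(n))`. Since `d <= L`, the value is
#' always >= 1; a straight line attains exactly 1. A constant signal
#' (zero path length) returns 1 by the straight-line convention.
#'
#' @param x numeric vector, length >= 3.
#' @return scalar >= 1.
#' @export
katz_fd <- function(x) {
  if (!is.numeric(x) || !all(is.finite(x))) stop("x must be finite numeric")
  if (length(x) < 3) stop("need length(x) >= 3")
  n <- length(x) - 1
  L <- sum(abs(diff(x)))
  if (L == 0) return(1)
  d <- max(abs(x[-1] - x[1]))
  if (d == 0) return(1)
  log10(n) / (log10(d / L) + log10(n))
}
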