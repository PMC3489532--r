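#' Weighted Gaussian kernel density estimate
#'
#' The semiparametric variant replaces the parametric score components with
#' kernel density estimates. For points `x_i` with non-negative weights
#' `w_i` (total `W`) and bandwidth `h`, the density estimate is
#' `p(s) = (1 / (W h)) * sum_i w_i K((s - x_i) / h)` with `K` the standard
#' Normal density; for unit weights this reduces to the usual
#' `1/(n h) sum K((s - s_i)/h)` form with `n` the number of decoys.
#'
#' @param points Numeric vector of scores anchoring the kernels.
#' @param weights Non-negative weights, recycled scalar or same length as
#'   `points`; need not sum to 1. At least one must be positive.
#' @param bandwidth Positive kernel bandwidth `h`; the default applies
#'   [select_bandwidth()] with Silverman's rule.
#' @return A `psmix_kde` object.
#' @examples
#' k <- kde_estimate(c(-1, 1), bandwidth = 1)
#' kde_density(k, 0)  # == dnorm(1) by symmetry
#' @export
kde_estimate <- function(points, weights = 1, bandwidth = NULL) {
  stopifnot(is.numeric(points), length(points) >= 1)
  weights <- rep_len(weights, length(points))
  if (any(weights < 0) || !any(weights > 0))
    stop("weights must be non-negative with at least one positive entry",
         call. = FALSE)
  if (is.null(bandwidth))
    bandwidth <- select_bandwidth(points, weights)
  if (!is.numeric(bandwidth) || bandwidth <= 0)
    stop("`bandwidth` must be positive", call. = FALSE)
  structure(list(points = points, weights = weights, bandwidth = bandwidth),
            class = "psmix_kde")
}

#' @export
print.psmix_kde <- function(x, ...) {
  cat("<psmix kernel density: ", length(x$points), " points, h = ",
      signif(x$bandwidth, 5), ">\n", sep = "")
  invisible(x)
}

#' Evaluate a kernel density estimate
#'
#' `kde_density()` evaluates the weighted Gaussian KDE at scores `s`;
#' `kde_tail()` evaluates its exact upper tail
#' `P(S > t) = sum_i w_i (1 - Phi((t - x_i)/h)) / W` (each kernel's Normal
#' tail, so no numerical integration is needed).
#'
#' @param kde A [kde_estimate()] object.
#' @param s,t Numeric vector of evaluation points.
#' @return Numeric vector of densities / tail probabilities.
#' @export
kde_density <- function(kde, s) {
  stopifnot(inherits(kde, "psmix_kde"))
  W <- sum(kde$weights)
  h <- kde$bandwidth
  vapply(s, function(si)
    sum(kde$weights * stats::dnorm((si - kde$points) / h)) / (W * h),
    numeric(1))
}

#' @rdname kde_density
#' @export
kde_tail <- function(kde, t) {
  stopifnot(inherits(kde, "psmix_kde"))
  W <- sum(kde$weights)
  h <- kde$bandwidth
  vapply(t, function(ti)
    sum(kde$weights * stats::pnorm((ti - kde$points) / h,
                                   lower.tail = FALSE)) / W,
    numeric(1))
}

# Weighted quantile by linear interpolation on the cumulative weight scale.
weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) - w / 2
  cw <- cw / sum(w)
  stats::approx(cw, x, xout = probs, rule = 2, ties = "ordered")$y
}

#' Select a kernel bandwidth
#'
#' `"silverman"` applies the rule of thumb
#' `h = 0.9 * min(sd, IQR / 1.34) * n_eff^(-1/5)` with weighted spread
#' statistics and the effective sample size `n_eff = (sum w)^2 / sum(w^2)`,
#' a plug-in minimizer of the asymptotic mean integrated squared error.
#' `"cv"` maximizes the leave-one-out log-likelihood over a log-spaced grid
#' around the Silverman value (30 points spanning a factor of 10 each way);
#' it is O(n^2) per grid point, so reserve it for moderate sample sizes.
#'
#' @param points Numeric vector with at least 2 distinct values of positive
#'   weight.
#' @param weights Non-negative weights (recycled scalar allowed).
#' @param method `"silverman"` (default) or `"cv"`.
#' @return A positive bandwidth.
#' @export
select_bandwidth <- function(points, weights = 1,
                             method = c("silverman", "cv")) {
  method <- match.arg(method)
  weights <- rep_len(weights, length(points))
  keep <- weights > 0
  if (length(unique(points[keep])) < 2)
    stop("need at least 2 distinct points with positive weight", call. = FALSE)
  x <- points[keep]; w <- weights[keep]
  W <- sum(w)
  mw <- sum(w * x) / W
  sdw <- sqrt(sum(w * (x - mw)^2) / W)
  iqr <- diff(weighted_quantile(x, w, c(0.25, 0.75)))
  spread <- min(sdw, iqr / 1.34)
  if (spread <= 0) spread <- sdw
  n_eff <- W^2 / sum(w^2)
  h_silverman <- 0.9 * spread * n_eff^(-1 / 5)
  if (method == "silverman") return(h_silverman)

  grid <- exp(seq(log(h_silverman / 10), log(h_silverman * 10), length.out = 30))
  d <- abs(outer(x, x, "-"))
  loo <- vapply(grid, function(h) {
    K <- stats::dnorm(d / h)
    diag(K) <- 0
    # leave-one-out density at x_i under weights w
    f <- (K %*% w) / ((W - w) * h)
    if (any(f <= 0)) return(-Inf)
    sum(w * log(f))
  }, numeric(1))
  grid[which.max(loo)]
}
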