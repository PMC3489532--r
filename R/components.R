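#' Component distributions for the two-group mixture
#'
#' Constructors for the score distributions used as mixture components. The
#' positive (correct-match) component is conventionally Normal; the negative
#' (incorrect-match) component is a shifted Gamma or a Gumbel
#' (max-extreme-value) distribution, or a kernel density estimate anchored on
#' decoy scores (see [kde_estimate()]).
#'
#' The shifted Gamma uses the rate parameterization: its mean is
#' `shift + alpha / beta` and its density is zero below `shift`. The Gumbel
#' density is `(1/scale) * exp(-z - exp(-z))` with `z = (s - location)/scale`;
#' its variance is `scale^2 * pi^2 / 6`.
#'
#' @param mu,sigma Normal mean and standard deviation (`sigma > 0`).
#' @param alpha,beta,shift Gamma shape (`alpha > 0`), rate (`beta > 0`) and
#'   location shift (the minimum of the support).
#' @param location,scale Gumbel location and scale (`scale > 0`).
#' @param kde A [kde_estimate()] object.
#' @return An object of class `psmix_dist` describing one component.
#' @examples
#' component_density(dist_normal(0, 1), 0)      # 1/sqrt(2*pi)
#' component_tail(dist_gumbel(0, 1), 0)         # 1 - exp(-1)
#' @name components
NULL

new_dist <- function(kind, ...) {
  structure(list(kind = kind, ...), class = c(paste0("psmix_", kind), "psmix_dist"))
}

#' @rdname components
#' @export
dist_normal <- function(mu, sigma) {
  stopifnot(is.numeric(mu), length(mu) == 1, is.finite(mu))
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) || sigma <= 0)
    stop("`sigma` must be a positive finite number", call. = FALSE)
  new_dist("normal", mu = mu, sigma = sigma)
}

#' @rdname components
#' @export
dist_shifted_gamma <- function(alpha, beta, shift) {
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) || alpha <= 0)
    stop("`alpha` (shape) must be a positive finite number", call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1 || !is.finite(beta) || beta <= 0)
    stop("`beta` (rate) must be a positive finite number", call. = FALSE)
  stopifnot(is.numeric(shift), length(shift) == 1, is.finite(shift))
  new_dist("shifted_gamma", alpha = alpha, beta = beta, shift = shift)
}

#' @rdname components
#' @export
dist_gumbel <- function(location, scale) {
  stopifnot(is.numeric(location), length(location) == 1, is.finite(location))
  if (!is.numeric(scale) || length(scale) != 1 || !is.finite(scale) || scale <= 0)
    stop("`scale` must be a positive finite number", call. = FALSE)
  new_dist("gumbel", location = location, scale = scale)
}

#' @rdname components
#' @export
dist_kernel <- function(kde) {
  stopifnot(inherits(kde, "psmix_kde"))
  new_dist("kernel", kde = kde)
}

#' Density and upper tail of a mixture component
#'
#' `component_density(dist, s)` evaluates the probability density of a
#' component at scores `s`; `component_tail(dist, t)` evaluates the upper-tail
#' probability `P(S > t)`. Both are vectorized over the score argument and are
#' the primitives behind the E-step, p-values and model-based FDR.
#'
#' @param dist A `psmix_dist` component (see [dist_normal()] and friends).
#' @param s,t Numeric vector of scores / cutoffs.
#' @return Numeric vector: non-negative densities, or tail probabilities in
#'   `[0, 1]`.
#' @export
component_density <- function(dist, s) {
  UseMethod("component_density")
}

#' @export
component_density.psmix_normal <- function(dist, s) {
  stats::dnorm(s, dist$mu, dist$sigma)
}

#' @export
component_density.psmix_shifted_gamma <- function(dist, s) {
  d <- numeric(length(s))
  above <- s >= dist$shift
  d[above] <- stats::dgamma(s[above] - dist$shift, shape = dist$alpha, rate = dist$beta)
  d
}

#' @export
component_density.psmix_gumbel <- function(dist, s) {
  z <- (s - dist$location) / dist$scale
  exp(-z - exp(-z)) / dist$scale
}

#' @export
component_density.psmix_kernel <- function(dist, s) {
  kde_density(dist$kde, s)
}

#' @export
component_density.default <- function(dist, s) {
  stop("not a psmix component distribution", call. = FALSE)
}

#' @rdname component_density
#' @export
component_tail <- function(dist, t) {
  UseMethod("component_tail")
}

#' @export
component_tail.psmix_normal <- function(dist, t) {
  stats::pnorm(t, dist$mu, dist$sigma, lower.tail = FALSE)
}

#' @export
component_tail.psmix_shifted_gamma <- function(dist, t) {
  ifelse(t < dist$shift, 1,
         stats::pgamma(t - dist$shift, shape = dist$alpha, rate = dist$beta,
                       lower.tail = FALSE))
}

#' @export
component_tail.psmix_gumbel <- function(dist, t) {
  z <- (t - dist$location) / dist$scale
  1 - exp(-exp(-z))
}

#' @export
component_tail.psmix_kernel <- function(dist, t) {
  kde_tail(dist$kde, t)
}

#' Moments of a component distribution
#'
#' Mean and standard deviation implied by a parametric component; used for
#' reporting (e.g. turning a fitted Gumbel scale into the standard deviation
#' `scale * pi / sqrt(6)`) and for simulation sanity checks.
#'
#' @param dist A parametric `psmix_dist` component.
#' @return Named numeric vector with elements `mean` and `sd`.
#' @export
component_moments <- function(dist) {
  switch(
    dist$kind,
    normal = c(mean = dist$mu, sd = dist$sigma),
    shifted_gamma = c(mean = dist$shift + dist$alpha / dist$beta,
                      sd = sqrt(dist$alpha) / dist$beta),
    gumbel = c(mean = dist$location + 0.5772156649015329 * dist$scale,
               sd = dist$scale * pi / sqrt(6)),
    stop("moments are only defined for parametric components", call. = FALSE)
  )
}

component_sample <- function(dist, n) {
  switch(
    dist$kind,
    normal = stats::rnorm(n, dist$mu, dist$sigma),
    shifted_gamma = dist$shift + stats::rgamma(n, shape = dist$alpha, rate = dist$beta),
    gumbel = dist$location - dist$scale * log(-log(stats::runif(n))),
    stop("can only sample from parametric components", call. = FALSE)
  )
}

component_params <- function(dist) {
  switch(
    dist$kind,
    normal = c(mu = dist$mu, sigma = dist$sigma),
    shifted_gamma = c(alpha = dist$alpha, beta = dist$beta, shift = dist$shift),
    gumbel = c(location = dist$location, scale = dist$scale),
    kernel = c(bandwidth = dist$kde$bandwidth)
  )
}

#' @export
print.psmix_dist <- function(x, ...) {
  p <- component_params(x)
  cat("<", x$kind, " component: ",
      paste(names(p), signif(unname(p), 5), sep = " = ", collapse = ", "),
      ">\n", sep = "")
  invisible(x)
}
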