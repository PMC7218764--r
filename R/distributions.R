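# Uncertainty descriptors attached to model parameters.
#
# Five kinds are supported, matching the distributional assumptions of the
# analysis: point (no uncertainty), gamma parameterised by mean/variance
# (costs), triangular between 95% uncertainty-interval bounds with the point
# estimate as mode (DALY weights), beta parameterised by mean and effective
# sample size (probabilities), and uniform between bounds.

#' Uncertainty descriptors
#'
#' Constructors for the uncertainty descriptors carried by model parameters.
#' Each returns an object of class `rhd_dist` that [sample_parameter()] can
#' draw from and [dist_interval()] can bound.
#'
#' @param value Point value (also the mode of the triangular).
#' @param mean Mean of the distribution.
#' @param variance Variance (gamma); must be >= 0. Zero degenerates to the
#'   mean.
#' @param lower,upper Interval bounds; for `dist_triangular_95ui()` these are
#'   the 95% uncertainty-interval endpoints.
#' @param mode Mode of the triangular, typically the point estimate; must lie
#'   in `[lower, upper]`.
#' @param n Effective sample size of the beta (`alpha + beta = n`).
#' @return An `rhd_dist` object.
#' @examples
#' d <- dist_gamma_mean_var(mean = 4120.51, variance = 1528138)
#' sample_parameter(d)
#' dist_interval(d)
#' @name rhd_dist
NULL

new_dist <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "rhd_dist")
}

#' @rdname rhd_dist
#' @export
dist_point <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1, is.finite(value))
  new_dist("point", value = value)
}

#' @rdname rhd_dist
#' @export
dist_gamma_mean_var <- function(mean, variance) {
  if (!is.finite(mean) || mean < 0)
    stop("gamma descriptor requires a finite mean >= 0, got ", mean)
  if (!is.finite(variance) || variance < 0)
    stop("gamma descriptor requires variance >= 0, got ", variance)
  new_dist("gamma_mean_var", mean = mean, variance = variance)
}

#' @rdname rhd_dist
#' @export
dist_triangular_95ui <- function(lower, mode, upper) {
  if (!(lower <= mode && mode <= upper))
    stop(sprintf("triangular bounds must satisfy lower <= mode <= upper, got (%g, %g, %g)",
                 lower, mode, upper))
  new_dist("triangular_95ui", lower = lower, mode = mode, upper = upper)
}

#' @rdname rhd_dist
#' @export
dist_beta_mean_n <- function(mean, n) {
  if (mean < 0 || mean > 1)
    stop("beta descriptor mean must lie in [0,1], got ", mean)
  if (!is.finite(n) || n <= 0)
    stop("beta descriptor effective sample size must be > 0, got ", n)
  new_dist("beta_mean_n", mean = mean, n = n)
}

#' @rdname rhd_dist
#' @export
dist_uniform_bounds <- function(lower, upper) {
  if (lower > upper)
    stop(sprintf("uniform bounds must be ordered, got (%g, %g)", lower, upper))
  new_dist("uniform_bounds", lower = lower, upper = upper)
}

#' @export
print.rhd_dist <- function(x, ...) {
  cat(dist_to_string(x), "\n")
  invisible(x)
}

#' Point value of a descriptor
#'
#' The central (base-case) value a descriptor stands for: the point value,
#' the gamma/beta mean, the triangular mode, or the uniform midpoint.
#'
#' @param dist An `rhd_dist`.
#' @return A single numeric.
#' @export
dist_mean <- function(dist) {
  stopifnot(inherits(dist, "rhd_dist"))
  switch(dist$kind,
    point           = dist$value,
    gamma_mean_var  = dist$mean,
    triangular_95ui = dist$mode,
    beta_mean_n     = dist$mean,
    uniform_bounds  = (dist$lower + dist$upper) / 2,
    stop("unknown descriptor kind: ", dist$kind)
  )
}

# Inverse-CDF sampler for the triangular distribution; no base-R primitive.
rtriangular <- function(n, lower, mode, upper) {
  if (upper == lower) return(rep(lower, n))
  u <- stats::runif(n)
  fc <- (mode - lower) / (upper - lower)
  ifelse(u < fc,
         lower + sqrt(u * (upper - lower) * (mode - lower)),
         upper - sqrt((1 - u) * (upper - lower) * (upper - mode)))
}

#' Draw from an uncertainty descriptor
#'
#' Draws use R's global random stream; seed it with [set.seed()] for
#' reproducibility. A gamma with zero variance and a triangular with
#' coincident bounds degenerate to their point value.
#'
#' @param dist An `rhd_dist` descriptor.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_parameter <- function(dist, n = 1) {
  stopifnot(inherits(dist, "rhd_dist"))
  switch(dist$kind,
    point = rep(dist$value, n),
    gamma_mean_var = {
      if (dist$variance == 0 || dist$mean == 0) rep(dist$mean, n)
      else stats::rgamma(n,
                         shape = dist$mean^2 / dist$variance,
                         rate  = dist$mean / dist$variance)
    },
    triangular_95ui = rtriangular(n, dist$lower, dist$mode, dist$upper),
    beta_mean_n = {
      if (dist$mean %in% c(0, 1)) rep(dist$mean, n)
      else stats::rbeta(n, shape1 = dist$mean * dist$n,
                           shape2 = (1 - dist$mean) * dist$n)
    },
    uniform_bounds = stats::runif(n, dist$lower, dist$upper),
    stop("unknown descriptor kind: ", dist$kind)
  )
}

#' Central interval of a descriptor
#'
#' Bounds used by the one-way sensitivity sweep: the equal-tailed interval at
#' `level` for gamma and beta descriptors, the stated bounds for triangular
#' and uniform ones, and the degenerate point for point descriptors.
#'
#' @param dist An `rhd_dist`.
#' @param level Coverage of the central interval (gamma/beta kinds).
#' @return Numeric `c(lower, upper)`.
#' @export
dist_interval <- function(dist, level = 0.95) {
  stopifnot(inherits(dist, "rhd_dist"))
  a <- (1 - level) / 2
  switch(dist$kind,
    point = c(dist$value, dist$value),
    gamma_mean_var = {
      if (dist$variance == 0 || dist$mean == 0) c(dist$mean, dist$mean)
      else stats::qgamma(c(a, 1 - a),
                         shape = dist$mean^2 / dist$variance,
                         rate  = dist$mean / dist$variance)
    },
    triangular_95ui = c(dist$lower, dist$upper),
    beta_mean_n = {
      if (dist$mean %in% c(0, 1)) c(dist$mean, dist$mean)
      else stats::qbeta(c(a, 1 - a), shape1 = dist$mean * dist$n,
                                     shape2 = (1 - dist$mean) * dist$n)
    },
    uniform_bounds = c(dist$lower, dist$upper),
    stop("unknown descriptor kind: ", dist$kind)
  )
}

# Serialization used by the bundle CSVs: "kind(a,b,...)" with full precision.
dist_to_string <- function(dist) {
  stopifnot(inherits(dist, "rhd_dist"))
  args <- unlist(dist[setdiff(names(dist), "kind")])
  sprintf("%s(%s)", dist$kind, paste(sprintf("%.17g", args), collapse = ","))
}

dist_from_string <- function(s) {
  s <- trimws(s)
  m <- regmatches(s, regexec("^([a-z0-9_]+)\\(([^)]*)\\)$", s))[[1]]
  if (length(m) != 3)
    stop("cannot parse distribution descriptor: '", s, "'")
  kind <- m[2]
  args <- as.numeric(strsplit(m[3], ",")[[1]])
  if (anyNA(args)) stop("non-numeric argument in descriptor: '", s, "'")
  switch(kind,
    point           = dist_point(args[1]),
    gamma_mean_var  = dist_gamma_mean_var(args[1], args[2]),
    triangular_95ui = dist_triangular_95ui(args[1], args[2], args[3]),
    beta_mean_n     = dist_beta_mean_n(args[1], args[2]),
    uniform_bounds  = dist_uniform_bounds(args[1], args[2]),
    stop("unknown descriptor kind: '", kind, "'")
  )
}
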