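#' Build a sampleable distribution from a base case and uncertainty interval
#'
#' The parameter table states only a base-case value, a 95% uncertainty
#' interval and a family name, so each family is parameterised by convention:
#' * `triangular`: minimum `ui_low`, mode `base`, maximum `ui_high`;
#' * `uniform`: on `[ui_low, ui_high]`;
#' * `gamma` / `beta`: method of moments with mean `base` and standard
#'   deviation `(ui_high - ui_low) / 3.92` (the interval read as +/-1.96 sd);
#' * `fixed`: a point mass at `base`.
#'
#' @param base Base-case value (the mean for gamma/beta, the mode for
#'   triangular).
#' @param ui_low,ui_high Lower/upper bound of the 95% uncertainty interval.
#' @param family One of `"triangular"`, `"gamma"`, `"beta"`, `"uniform"`,
#'   `"fixed"`.
#' @return A `crc_dist` object for [draw_distribution()].
#' @export
#' @examples
#' d <- build_distribution(0.83, 0.80, 0.90, "beta")
#' mean(draw_distribution(d, 1e4))
build_distribution <- function(base, ui_low, ui_high, family) {
  family <- match.arg(family,
                      c("triangular", "gamma", "beta", "uniform", "fixed"))
  if (ui_low > base || base > ui_high) {
    stop("base must lie inside [ui_low, ui_high]", call. = FALSE)
  }
  sd <- (ui_high - ui_low) / 3.92
  par <- switch(
    family,
    triangular = list(min = ui_low, mode = base, max = ui_high),
    uniform = list(min = ui_low, max = ui_high),
    fixed = list(value = base),
    gamma = {
      if (base <= 0) stop("gamma requires a positive mean", call. = FALSE)
      if (sd == 0) {
        list(degenerate = base)
      } else {
        list(shape = base^2 / sd^2, rate = base / sd^2)
      }
    },
    beta = {
      if (base <= 0 || base >= 1) {
        stop("beta requires a mean strictly inside (0, 1)", call. = FALSE)
      }
      if (sd == 0) {
        list(degenerate = base)
      } else {
        v <- sd^2
        if (v >= base * (1 - base)) {
          stop("beta variance too large for mean ", base, call. = FALSE)
        }
        nu <- base * (1 - base) / v - 1
        list(shape1 = base * nu, shape2 = (1 - base) * nu)
      }
    }
  )
  structure(list(family = family, par = par), class = "crc_dist")
}

#' Draw from a `crc_dist`
#'
#' @param dist A `crc_dist` from [build_distribution()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`; every draw lies in the family's
#'   support.
#' @export
draw_distribution <- function(dist, n = 1L) {
  stopifnot(inherits(dist, "crc_dist"))
  p <- dist$par
  if (!is.null(p$degenerate)) return(rep(p$degenerate, n))
  switch(
    dist$family,
    fixed = rep(p$value, n),
    uniform = stats::runif(n, p$min, p$max),
    triangular = rtriangular(n, p$min, p$mode, p$max),
    gamma = stats::rgamma(n, shape = p$shape, rate = p$rate),
    beta = stats::rbeta(n, shape1 = p$shape1, shape2 = p$shape2)
  )
}

#' Mean of a `crc_dist`
#' @param dist A `crc_dist`.
#' @return The analytic mean of the distribution.
#' @export
dist_mean <- function(dist) {
  p <- dist$par
  if (!is.null(p$degenerate)) return(p$degenerate)
  switch(
    dist$family,
    fixed = p$value,
    uniform = (p$min + p$max) / 2,
    triangular = (p$min + p$mode + p$max) / 3,
    gamma = p$shape / p$rate,
    beta = p$shape1 / (p$shape1 + p$shape2)
  )
}

# inverse-CDF sampler; degenerate (min == max) allowed
rtriangular <- function(n, min, mode, max) {
  if (max == min) return(rep(min, n))
  u <- stats::runif(n)
  fc <- (mode - min) / (max - min)
  ifelse(
    u < fc,
    min + sqrt(u * (max - min) * (mode - min)),
    max - sqrt((1 - u) * (max - min) * (max - mode))
  )
}
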