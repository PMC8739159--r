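#' @importFrom stats rnorm runif rpois uniroot integrate
#' @importFrom rlang .data abort warn
NULL

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles into the signed degree range (-180, 180]
#'
#' @param x Numeric vector of angles in degrees.
#' @return Angles mapped modulo 360 into `(-180, 180]`.
#' @examples
#' wrap_angle_deg(c(270, -270, 180, 540))
#' @export
wrap_angle_deg <- function(x) {
  out <- x %% 360
  out[out > 180] <- out[out > 180] - 360
  out
}

#' Unit vector at a given angle
#'
#' @param angle_deg Angle in degrees, measured counter-clockwise from +x.
#' @return Length-2 numeric vector `c(x, y)` of unit length.
#' @export
unit_vec <- function(angle_deg) {
  a <- deg2rad(angle_deg)
  c(cos(a), sin(a))
}

#' Signed angle of vectors relative to an oriented frame
#'
#' Computes `alpha = atan2(v . n, v . e)` in degrees, the convention used
#' throughout: `e` is the edge/front direction, `n` the inward normal, so
#' a vector pointing exactly along the inward normal scores +90 degrees and
#' one pointing along the edge scores 0.
#'
#' @param vx,vy Vector components (vectorised).
#' @param e,n Unit edge direction and unit inward normal (length-2 each).
#' @return Signed angles in degrees in `(-180, 180]`.
#' @export
signed_angle_deg <- function(vx, vy, e, n) {
  rad2deg(atan2(vx * n[1] + vy * n[2], vx * e[1] + vy * e[2]))
}

#' Test whether angles fall in a closed angular window
#'
#' @param alpha_deg Signed angles in degrees.
#' @param window_deg Closed interval, default `c(60, 120)`.
#' @return Logical vector.
#' @export
in_window <- function(alpha_deg, window_deg = c(60, 120)) {
  alpha_deg >= window_deg[1] & alpha_deg <= window_deg[2]
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler. `kappa = 0` returns uniform angles and
#' `kappa = Inf` returns the mean direction exactly, so both degenerate
#' limits used by the generators are well defined.
#'
#' @param n Number of draws.
#' @param mu_deg Mean direction, degrees.
#' @param kappa Concentration (>= 0, may be `Inf`).
#' @return Angles in degrees in `(-180, 180]`.
#' @export
rvonmises_deg <- function(n, mu_deg = 0, kappa = 0) {
  stopifnot(is.numeric(kappa), length(kappa) == 1, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (is.infinite(kappa)) return(rep(wrap_angle_deg(mu_deg), n))
  if (kappa < 1e-12) return(wrap_angle_deg(runif(n, -180, 180)))
  mu <- deg2rad(mu_deg)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      out[i] <- mu + sign(u3 - 0.5) * acos(pmin(1, pmax(-1, f)))
      i <- i + 1L
    }
  }
  wrap_angle_deg(rad2deg(out))
}

#' Maximum-likelihood von Mises concentration
#'
#' Solves `I1(kappa)/I0(kappa) = Rbar` for the mean resultant length of the
#' sample; exponentially scaled Bessel ratios keep the solve stable at large
#' concentrations.
#'
#' @param angles_deg Sample of angles in degrees.
#' @return List with `mu_deg` (mean direction) and `kappa` (MLE).
#' @export
fit_vonmises <- function(angles_deg) {
  stopifnot(length(angles_deg) >= 2)
  a <- deg2rad(angles_deg)
  C <- mean(cos(a)); S <- mean(sin(a))
  rbar <- sqrt(C^2 + S^2)
  mu <- rad2deg(atan2(S, C))
  if (rbar < 1e-10) return(list(mu_deg = mu, kappa = 0))
  if (rbar > 1 - 1e-12) return(list(mu_deg = mu, kappa = Inf))
  A1 <- function(k) besselI(k, 1, expon.scaled = TRUE) /
    besselI(k, 0, expon.scaled = TRUE)
  upper <- 5e4
  if (rbar >= A1(upper)) {
    # large-kappa expansion: A1(k) ~ 1 - 1/(2k)
    return(list(mu_deg = mu, kappa = 1 / (2 * (1 - rbar))))
  }
  k <- uniroot(function(k) A1(k) - rbar, lower = 1e-10, upper = upper,
               tol = 1e-10)$root
  list(mu_deg = mu, kappa = k)
}

#' Probability mass of a von Mises distribution inside an angular window
#'
#' @param kappa Concentration (>= 0).
#' @param mu_deg Mean direction, degrees.
#' @param window_deg Closed window, degrees.
#' @return Probability in `[0, 1]`.
#' @export
vonmises_window_mass <- function(kappa, mu_deg = 90, window_deg = c(60, 120)) {
  stopifnot(kappa >= 0, diff(window_deg) > 0)
  if (is.infinite(kappa)) {
    return(as.numeric(in_window(wrap_angle_deg(mu_deg), window_deg)))
  }
  dens <- function(th) {
    exp(kappa * cos(deg2rad(th - mu_deg))) /
      (2 * pi * besselI(kappa, 0)) * (pi / 180)
  }
  integrate(dens, window_deg[1], window_deg[2], rel.tol = 1e-10)$value
}
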