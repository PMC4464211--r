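#' Waiting-time distributions for non-Markovian reaction events
#'
#' Constructors for the waiting-time families supported by the simulator.
#' Every constructor returns an object of class \code{"wt_dist"} (with a
#' family subclass) exposing a density, a cumulative distribution function
#' and an analytic mean through [wt_pdf()], [wt_cdf()] and [wt_mean()].
#'
#' The central family is the single-molecule Michaelis-Menten turnover-time
#' density: for one enzyme molecule cycling through binding
#' (\code{k1}), dissociation (\code{k_minus1}) and catalysis (\code{k2}) at
#' substrate concentration \code{S}, the time between two consecutive
#' product-formation events has density
#' \deqn{f(\tau) = \alpha (e^{\beta\tau} - e^{\gamma\tau}),}
#' a hypoexponential-like two-phase form with
#' \deqn{B = -(k_1 S + k_{-1} + k_2)/2, \quad A = \sqrt{B^2 - k_1 k_2 S},}
#' \eqn{\alpha = k_1 k_2 S / (2A)}, \eqn{\beta = A + B}, \eqn{\gamma = B - A}.
#' The density vanishes at \eqn{\tau = 0} (unlike the exponential) and its
#' mean satisfies the single-molecule Michaelis-Menten equation
#' \eqn{1/\langle\tau\rangle = k_2 S / (S + K_M)} with
#' \eqn{K_M = (k_{-1} + k_2)/k_1}; see [mm_mean_rate()].
#'
#' Units are the caller's responsibility: \code{k1} and \code{S} need only be
#' mutually consistent (M with M^-1 s^-1, or uM with uM^-1 s^-1). No unit
#' conversion is performed.
#'
#' @param k1 bimolecular binding rate constant (per-concentration per-time),
#'   > 0.
#' @param k2 catalytic rate constant (per-time), > 0.
#' @param k_minus1 dissociation rate constant (per-time), >= 0.
#' @param S substrate concentration, > 0, in units consistent with \code{k1}.
#' @return An object of class \code{c("wt_mm", "wt_dist")} carrying the raw
#'   parameters and the derived \code{A}, \code{B}, \code{alpha},
#'   \code{beta}, \code{gamma}.
#' @examples
#' d <- dist_mm(k1 = 1e7, k2 = 250, k_minus1 = 0, S = 5e-6)
#' d$A            # 100
#' wt_pdf(d, 0.01)
#' 1 / wt_mean(d) # equals mm_mean_rate(d)
#' @seealso [dist_exponential()], [dist_erlang()], [dist_hyperexp()],
#'   [invert_cdf()], [wt_sample()]
#' @export
dist_mm <- function(k1, k2, k_minus1, S) {
  stopifnot(length(k1) == 1L, length(k2) == 1L,
            length(k_minus1) == 1L, length(S) == 1L)
  if (!is.finite(k1) || k1 <= 0) stop("'k1' must be finite and > 0")
  if (!is.finite(k2) || k2 <= 0) stop("'k2' must be finite and > 0")
  if (!is.finite(k_minus1) || k_minus1 < 0)
    stop("'k_minus1' must be finite and >= 0")
  if (!is.finite(S) || S <= 0) stop("'S' must be finite and > 0")

  B <- -(k1 * S + k_minus1 + k2) / 2
  disc <- B^2 - k1 * k2 * S
  # disc = ((k1*S - k2 + k_minus1)^2 + 4*k_minus1*k2)/4; zero only when
  # k_minus1 = 0 and k1*S = k2 (double-root limit, rejected by design)
  if (disc <= 0 || sqrt(disc) <= abs(B) * 1e-12)
    stop("degenerate waiting-time parameters: B^2 - k1*k2*S must be > 0 ",
         "(A = 0 double-root case is not supported)", call. = FALSE)
  A <- sqrt(disc)

  out <- list(
    family = "mm_single_molecule",
    k1 = k1, k2 = k2, k_minus1 = k_minus1, S = S,
    A = A, B = B,
    alpha = k1 * k2 * S / (2 * A),
    beta = A + B,
    gamma = B - A
  )
  class(out) <- c("wt_mm", "wt_dist")
  out
}

#' Exponential waiting-time distribution
#'
#' The memoryless family: \eqn{f(\tau) = \lambda e^{-\lambda\tau}}. A
#' reaction with an exponential waiting time behaves as a Markov jump with
#' propensity \eqn{\lambda}.
#'
#' @param lam rate \eqn{\lambda} (per-time), > 0.
#' @return Object of class \code{c("wt_exponential", "wt_dist")}.
#' @export
dist_exponential <- function(lam) {
  stopifnot(length(lam) == 1L)
  if (!is.finite(lam) || lam <= 0) stop("'lam' must be finite and > 0")
  structure(list(family = "exponential", lam = lam),
            class = c("wt_exponential", "wt_dist"))
}

#' Erlang waiting-time distribution
#'
#' Sum of \code{k} i.i.d. exponential phases of rate \code{lam}:
#' \eqn{f(\tau) = \lambda^k \tau^{k-1} e^{-\lambda\tau} / (k-1)!}.
#'
#' @param k integer shape (number of phases), >= 1.
#' @param lam phase rate (per-time), > 0.
#' @return Object of class \code{c("wt_erlang", "wt_dist")}.
#' @export
dist_erlang <- function(k, lam) {
  stopifnot(length(k) == 1L, length(lam) == 1L)
  if (!is.finite(k) || k < 1 || k != round(k))
    stop("'k' must be a positive integer")
  if (!is.finite(lam) || lam <= 0) stop("'lam' must be finite and > 0")
  structure(list(family = "erlang", k = as.integer(k), lam = lam),
            class = c("wt_erlang", "wt_dist"))
}

#' Hyperexponential waiting-time distribution
#'
#' Finite mixture of exponentials:
#' \eqn{f(\tau) = \sum_i w_i \lambda_i e^{-\lambda_i \tau}} with
#' \eqn{w_i > 0}, \eqn{\sum w_i = 1}. Covers over-dispersed (CV > 1)
#' waiting times.
#'
#' @param weights mixture probabilities, all > 0, summing to 1.
#' @param rates component rates (per-time), same length as \code{weights},
#'   all > 0.
#' @return Object of class \code{c("wt_hyperexp", "wt_dist")}.
#' @export
dist_hyperexp <- function(weights, rates) {
  if (length(weights) != length(rates) || length(weights) < 1L)
    stop("'weights' and 'rates' must be non-empty and of equal length")
  if (!all(is.finite(weights)) || any(weights <= 0))
    stop("all 'weights' must be finite and > 0")
  if (abs(sum(weights) - 1) > 1e-12)
    stop("'weights' must sum to 1")
  if (!all(is.finite(rates)) || any(rates <= 0))
    stop("all 'rates' must be finite and > 0")
  structure(list(family = "hyperexponential",
                 weights = as.numeric(weights), rates = as.numeric(rates)),
            class = c("wt_hyperexp", "wt_dist"))
}

#' @export
print.wt_dist <- function(x, ...) {
  cat("Waiting-time distribution:", x$family, "\n")
  pars <- x[setdiff(names(x), "family")]
  for (nm in names(pars))
    cat("  ", nm, " = ", paste(signif(pars[[nm]], 6), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

.check_tau <- function(tau, lenient) {
  if (!all(is.finite(tau))) stop("'tau' must be finite")
  if (!lenient && any(tau < 0))
    stop("negative waiting time 'tau'; pass lenient = TRUE to map tau < 0 ",
         "to density/probability 0", call. = FALSE)
}

#' Density of a waiting-time distribution
#'
#' @param dist a \code{wt_dist} object.
#' @param tau vector of waiting times, >= 0 (per-time density returned).
#' @param lenient if TRUE, \code{tau < 0} yields 0 instead of an error.
#' @return Numeric vector of densities.
#' @export
wt_pdf <- function(dist, tau, lenient = FALSE) {
  UseMethod("wt_pdf")
}

#' @export
wt_pdf.wt_mm <- function(dist, tau, lenient = FALSE) {
  .check_tau(tau, lenient)
  out <- ifelse(tau < 0, 0,
                dist$alpha * (exp(dist$beta * tau) - exp(dist$gamma * tau)))
  pmax(out, 0)
}

#' @export
wt_pdf.wt_exponential <- function(dist, tau, lenient = FALSE) {
  .check_tau(tau, lenient)
  ifelse(tau < 0, 0, stats::dexp(pmax(tau, 0), rate = dist$lam))
}

#' @export
wt_pdf.wt_erlang <- function(dist, tau, lenient = FALSE) {
  .check_tau(tau, lenient)
  ifelse(tau < 0, 0,
         stats::dgamma(pmax(tau, 0), shape = dist$k, rate = dist$lam))
}

#' @export
wt_pdf.wt_hyperexp <- function(dist, tau, lenient = FALSE) {
  .check_tau(tau, lenient)
  out <- numeric(length(tau))
  pos <- tau >= 0
  if (any(pos)) {
    tp <- tau[pos]
    acc <- 0
    for (i in seq_along(dist$rates))
      acc <- acc + dist$weights[i] * stats::dexp(tp, rate = dist$rates[i])
    out[pos] <- acc
  }
  out
}

#' Cumulative distribution of a waiting time
#'
#' \eqn{F(\tau) = \int_0^\tau f(u)\,du}; satisfies \eqn{F(0) = 0} and
#' \eqn{F(\tau) \to 1}. For the single-molecule Michaelis-Menten family the
#' closed form
#' \eqn{F(\tau) = \alpha(e^{\beta\tau}/\beta - e^{\gamma\tau}/\gamma)
#'      - \alpha(1/\beta - 1/\gamma)}
#' is used.
#'
#' @inheritParams wt_pdf
#' @return Numeric vector of probabilities in [0, 1].
#' @export
wt_cdf <- function(dist, tau, lenient = FALSE) {
  UseMethod("wt_cdf")
}

#' @export
wt_cdf.wt_mm <- function(dist, tau, lenient = FALSE) {
  .check_tau(tau, lenient)
  b <- dist$beta; g <- dist$gamma; a <- dist$alpha
  out <- a * (exp(b * tau) / b - exp(g * tau) / g) - a * (1 / b - 1 / g)
  out[tau <= 0] <- 0
  pmin(pmax(out, 0), 1)
}

#' @export
wt_cdf.wt_exponential <- function(dist, tau, lenient = FALSE) {
  .check_tau(tau, lenient)
  ifelse(tau < 0, 0, stats::pexp(pmax(tau, 0), rate = dist$lam))
}

#' @export
wt_cdf.wt_erlang <- function(dist, tau, lenient = FALSE) {
  .check_tau(tau, lenient)
  ifelse(tau < 0, 0,
         stats::pgamma(pmax(tau, 0), shape = dist$k, rate = dist$lam))
}

#' @export
wt_cdf.wt_hyperexp <- function(dist, tau, lenient = FALSE) {
  .check_tau(tau, lenient)
  out <- numeric(length(tau))
  pos <- tau >= 0
  if (any(pos)) {
    tp <- tau[pos]
    acc <- 0
    for (i in seq_along(dist$rates))
      acc <- acc + dist$weights[i] * stats::pexp(tp, rate = dist$rates[i])
    out[pos] <- acc
  }
  out
}

#' Analytic mean waiting time
#'
#' Closed-form expectation of the waiting time: \eqn{1/\lambda}
#' (exponential), \eqn{k/\lambda} (Erlang), \eqn{\sum_i w_i/\lambda_i}
#' (hyperexponential), and the reciprocal of [mm_mean_rate()] for the
#' single-molecule Michaelis-Menten family.
#'
#' @param dist a \code{wt_dist} object.
#' @return Mean waiting time (time units).
#' @export
wt_mean <- function(dist) UseMethod("wt_mean")

#' @export
wt_mean.wt_mm <- function(dist) 1 / mm_mean_rate(dist)

#' @export
wt_mean.wt_exponential <- function(dist) 1 / dist$lam

#' @export
wt_mean.wt_erlang <- function(dist) dist$k / dist$lam

#' @export
wt_mean.wt_hyperexp <- function(dist) sum(dist$weights / dist$rates)

#' Single-molecule Michaelis-Menten rate
#'
#' The reciprocal mean turnover time of a single enzyme obeys the
#' hyperbolic Michaelis-Menten law
#' \deqn{1/\langle\tau\rangle = \frac{k_2 [S]}{[S] + K_M}, \qquad
#'       K_M = \frac{k_{-1} + k_2}{k_1},}
#' the ergodic link between single-molecule and ensemble kinetics: the same
#' constants measured in bulk experiments parameterise the waiting-time
#' density.
#'
#' @param params a \code{wt_mm} object from [dist_mm()].
#' @return Rate (per-time).
#' @export
mm_mean_rate <- function(params) {
  stopifnot(inherits(params, "wt_mm"))
  KM <- (params$k_minus1 + params$k2) / params$k1
  params$k2 * params$S / (params$S + KM)
}

#' Quantile of a waiting-time distribution
#'
#' Inverse CDF. Closed forms are used for the exponential and Erlang
#' families; the Michaelis-Menten and hyperexponential quantiles are
#' obtained by the bracketing inversion of [invert_cdf()].
#'
#' @param dist a \code{wt_dist} object.
#' @param p vector of probabilities in (0, 1).
#' @param config an [inversion_config()] for families without a closed-form
#'   inverse.
#' @return Vector of waiting times.
#' @export
wt_quantile <- function(dist, p, config = inversion_config(dist)) {
  UseMethod("wt_quantile")
}

#' @export
wt_quantile.wt_exponential <- function(dist, p,
                                       config = inversion_config(dist)) {
  stopifnot(all(p > 0), all(p < 1))
  stats::qexp(p, rate = dist$lam)
}

#' @export
wt_quantile.wt_erlang <- function(dist, p,
                                  config = inversion_config(dist)) {
  stopifnot(all(p > 0), all(p < 1))
  stats::qgamma(p, shape = dist$k, rate = dist$lam)
}

#' @export
wt_quantile.wt_dist <- function(dist, p, config = inversion_config(dist)) {
  stopifnot(all(p > 0), all(p < 1))
  .invert_cdf_vec(dist, p, config)
}
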