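#' Kinetic parameter fixture sets
#'
#' Named single-enzyme parameter sets used throughout the package's
#' validation. The A sets are single-molecule turnover parameters at fixed
#' substrate concentration (molar units: k1 in M^-1 s^-1, S in M, 0.005 mM
#' = 5e-6 M); the B sets are beta-lactamase/benzylpenicillin ensemble
#' kinetics in micromolar units (k1 in uM^-1 s^-1) with the substrate
#' concentration supplied by the caller.
#'
#' \tabular{lllll}{
#'   set \tab k1 \tab k2 (s^-1) \tab k_minus1 (s^-1) \tab S \cr
#'   A1 \tab 1e7 M^-1 s^-1 \tab 250 \tab 0 \tab 5e-6 M \cr
#'   A2 \tab 1e7 M^-1 s^-1 \tab 250 \tab 50 \tab 5e-6 M \cr
#'   A3 \tab 1e7 M^-1 s^-1 \tab 250 \tab 2000 \tab 5e-6 M \cr
#'   B1 \tab 41 uM^-1 s^-1 \tab 1920 \tab 2320 \tab caller \cr
#'   B2 \tab 22 uM^-1 s^-1 \tab 62 \tab 196 \tab caller \cr
#'   B3 \tab 123 uM^-1 s^-1 \tab 980 \tab 11800 \tab caller \cr
#' }
#'
#' @param name one of "A1", "A2", "A3", "B1", "B2", "B3".
#' @param S substrate concentration override; required for the B sets
#'   (same units as k1), optional for the A sets.
#' @return A \code{wt_mm} distribution (see [dist_mm()]) with a
#'   \code{"units"} attribute.
#' @examples
#' mm_fixture("A1")$A   # 100 s^-1
#' mm_fixture("B1", S = 50)
#' @export
mm_fixture <- function(name, S = NULL) {
  tab <- list(
    A1 = list(k1 = 1e7, k2 = 250, k_minus1 = 0, S = 5e-6,
              units = "M, M^-1 s^-1, s^-1"),
    A2 = list(k1 = 1e7, k2 = 250, k_minus1 = 50, S = 5e-6,
              units = "M, M^-1 s^-1, s^-1"),
    A3 = list(k1 = 1e7, k2 = 250, k_minus1 = 2000, S = 5e-6,
              units = "M, M^-1 s^-1, s^-1"),
    B1 = list(k1 = 41, k2 = 1920, k_minus1 = 2320, S = NULL,
              units = "uM, uM^-1 s^-1, s^-1"),
    B2 = list(k1 = 22, k2 = 62, k_minus1 = 196, S = NULL,
              units = "uM, uM^-1 s^-1, s^-1"),
    B3 = list(k1 = 123, k2 = 980, k_minus1 = 11800, S = NULL,
              units = "uM, uM^-1 s^-1, s^-1")
  )
  if (!name %in% names(tab))
    stop("unknown fixture set '", name, "'; use one of ",
         paste(names(tab), collapse = ", "))
  p <- tab[[name]]
  if (!is.null(S)) p$S <- S
  if (is.null(p$S))
    stop("fixture '", name, "' needs an explicit substrate concentration S")
  d <- dist_mm(p$k1, p$k2, p$k_minus1, p$S)
  attr(d, "units") <- p$units
  attr(d, "fixture") <- name
  d
}

#' Two-reaction demonstration network
#'
#' A 100-copy pool of species A drained by two competing channels: a
#' non-Markovian A -> B whose waiting time follows the single-molecule
#' Michaelis-Menten density (k1 = 1, k2 = 1, k_minus1 = 10, substrate = A),
#' and a Markov-jump A -> C with state-dependent exponential rate
#' 10 [A]. (The stated density 10[A] e^{-[A] tau} is not normalised; the
#' proper exponential with rate 10 [A] is used.)
#'
#' @return A list with elements \code{system} (a \code{reaction_system})
#'   and \code{init} (A = 100, B = 0, C = 0).
#' @export
example_network <- function() {
  system <- parse_reactions(c(
    "A -> B [dist=mm_single_molecule; k1=1; k2=1; k_minus1=10; substrate=A]",
    "A -> C [dist=exponential; lam_species=A; lam_scale=10]"))
  list(system = system, init = c(A = 100, B = 0, C = 0))
}

#' Pearson chi-square goodness of fit of samples against a waiting-time
#' density
#'
#' Bins the samples into equal-probability bins of the candidate
#' distribution (bin edges at CDF quantiles), computes expected counts from
#' CDF differences, merges sparse tail bins until every expected count is
#' at least 5, and reports the Pearson chi-square statistic with
#' \code{bins - 1} degrees of freedom (no parameters are fitted from the
#' samples).
#'
#' @param samples numeric vector of waiting times, length >= 100.
#' @param dist the candidate \code{wt_dist}.
#' @param bins number of equal-probability bins before merging
#'   (default 20).
#' @param alpha significance level used for the \code{pass} flag
#'   (pass = p-value > alpha, i.e. no evidence against the candidate).
#' @return A list of class \code{"gof_report"}: \code{statistic},
#'   \code{df}, \code{p_value}, \code{pass}, \code{bin_edges},
#'   \code{observed}, \code{expected}.
#' @examples
#' set.seed(1)
#' d <- dist_exponential(0.0078)
#' histogram_vs_pdf(wt_sample(d, 1000), d)$p_value
#' @export
histogram_vs_pdf <- function(samples, dist, bins = 20L, alpha = 0.01) {
  n <- length(samples)
  if (n < 100L) stop("need at least 100 samples for the chi-square test")
  stopifnot(bins >= 2L)
  probs <- seq(0, 1, length.out = bins + 1L)
  inner <- wt_quantile(dist, probs[-c(1L, bins + 1L)])
  edges <- c(0, inner, Inf)
  obs <- as.vector(table(cut(samples, breaks = edges, right = TRUE,
                             include.lowest = TRUE)))
  expd <- rep(n / bins, bins)   # equal-probability bins by construction

  # merge adjacent bins until every expected count is >= 5 (the sparsest
  # bin absorbs its right neighbour, or its left neighbour at the tail)
  while (length(expd) > 2L && min(expd) < 5) {
    i <- which.min(expd)
    j <- if (i < length(expd)) i + 1L else i - 1L
    lo <- min(i, j)
    obs[lo] <- obs[i] + obs[j]
    expd[lo] <- expd[i] + expd[j]
    obs <- obs[-(lo + 1L)]
    expd <- expd[-(lo + 1L)]
    edges <- edges[-(lo + 1L)]
  }

  stat <- sum((obs - expd)^2 / expd)
  df <- length(obs) - 1L
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p_value = p,
                 pass = p > alpha, alpha = alpha,
                 bin_edges = edges, observed = obs, expected = expd),
            class = "gof_report")
}

#' @export
print.gof_report <- function(x, ...) {
  cat(sprintf("Pearson chi-square GOF: X2 = %.3f, df = %d, p = %.4g (%s at alpha = %g)\n",
              x$statistic, x$df, x$p_value,
              if (x$pass) "no evidence against fit" else "rejected",
              x$alpha))
  invisible(x)
}

#' Simulated Michaelis-Menten saturation curve
#'
#' For each substrate concentration in \code{S_grid}, draws
#' \code{n_per_point} waiting times from the single-molecule density and
#' records the reciprocal sample mean, alongside the analytic
#' single-molecule rate \eqn{k_2 S/(S+K_M)} and the delta-method standard
#' error of the reciprocal mean
#' (\eqn{\mathrm{SE} = \sigma / (\sqrt{n}\,\mu^2)}, with \eqn{\mu},
#' \eqn{\sigma} the distribution's mean and standard deviation by
#' quadrature). Plotting \code{rate_hat} against S reproduces the
#' hyperbolic saturation profile whose plateau is \eqn{k_2}.
#'
#' @param k1,k2,k_minus1 kinetic constants (units consistent with
#'   \code{S_grid}).
#' @param S_grid positive substrate concentrations.
#' @param n_per_point number of waiting-time draws per grid point, >= 2.
#' @param seed optional integer seed.
#' @return Data frame with columns \code{S}, \code{rate_hat} (1 / mean
#'   tau), \code{rate_analytic}, \code{se}.
#' @examples
#' sc <- saturation_curve(41, 1920, 2320, S_grid = c(1, 10, 100),
#'                        n_per_point = 50, seed = 1)
#' sc
#' @export
saturation_curve <- function(k1, k2, k_minus1, S_grid,
                             n_per_point = 100L, seed = NULL) {
  stopifnot(all(S_grid > 0), n_per_point >= 2L)
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(S_grid, function(S) {
    d <- dist_mm(k1, k2, k_minus1, S)
    tau <- wt_sample(d, n_per_point)
    mu <- wt_mean(d)
    m2 <- stats::integrate(function(t) t^2 * wt_pdf(d, t), 0, Inf,
                           rel.tol = 1e-10)$value
    sigma <- sqrt(max(m2 - mu^2, 0))
    data.frame(S = S, rate_hat = 1 / mean(tau),
               rate_analytic = mm_mean_rate(d),
               se = sigma / (sqrt(n_per_point) * mu^2))
  })
  do.call(rbind, out)
}

#' Draw a random valid single-molecule parameter set
#'
#' Samples k1, k2, k_minus1 and S log-uniformly over documented ranges
#' (k1, S in [1e-1, 1e2]; k2 in [1e-1, 1e2]; k_minus1 in [1e-2, 1e2]) and
#' rejects the rare draws falling on the degenerate double-root boundary
#' (A ~ 0), so the result always constructs a valid [dist_mm()].
#'
#' @param max_tries rejection-loop bound before erroring.
#' @return A \code{wt_mm} distribution.
#' @examples
#' set.seed(1)
#' random_mm_params()
#' @export
random_mm_params <- function(max_tries = 100L) {
  runif_log <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))
  for (i in seq_len(max_tries)) {
    k1 <- runif_log(1e-1, 1e2)
    k2 <- runif_log(1e-1, 1e2)
    k_minus1 <- runif_log(1e-2, 1e2)
    S <- runif_log(1e-1, 1e2)
    d <- tryCatch(dist_mm(k1, k2, k_minus1, S), error = function(e) NULL)
    if (!is.null(d) && d$A > 1e-6 * abs(d$B)) return(d)
  }
  stop("failed to draw a valid parameter set in ", max_tries, " tries")
}
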