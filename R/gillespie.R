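#' Mass-action propensity
#'
#' Standard stochastic combinatorics: for a channel consuming \eqn{a_i}
#' copies of species \eqn{i} with stochastic rate constant \eqn{c}, the
#' propensity is \eqn{c \prod_i \binom{n_i}{a_i}}; e.g. \eqn{c\,n_A n_B}
#' for A + B and \eqn{c\,n_A(n_A-1)/2} for 2A.
#'
#' @param reactants named integer vector of stoichiometric coefficients.
#' @param c stochastic rate constant (per-time), > 0.
#' @param counts named vector of copy numbers (missing species count as 0).
#' @return Propensity (per-time), 0 when reactants are insufficient.
#' @export
mass_action_propensity <- function(reactants, c, counts) {
  stopifnot(is.numeric(c), length(c) == 1L, c > 0)
  if (length(reactants) == 0L) return(c)
  n <- counts[names(reactants)]
  n[is.na(n)] <- 0
  c * prod(choose(n, reactants))
}

# Lumped Markovian propensity v = k2 [S] / ([S] + KM) at the live state.
mm_lumped_propensity <- function(ds, counts, scale) {
  n <- unname(counts[ds$substrate])
  if (is.na(n)) n <- 0
  S <- scale * n
  KM <- (ds$k_minus1 + ds$k2) / ds$k1
  ds$k2 * S / (S + KM)
}

#' Propensity of a reaction channel in the Markovian reference model
#'
#' Dispatches on the reaction's distribution family: \code{mass_action}
#' uses the combinatorial convention of [mass_action_propensity()];
#' \code{mm_lumped} uses the Michaelis-Menten rate law
#' \eqn{v = k_2 [S]/([S]+K_M)} with \eqn{K_M = (k_{-1}+k_2)/k_1} and
#' \eqn{[S]} the scaled live substrate count; \code{exponential} channels
#' use their (possibly state-dependent) rate. Other families have no
#' Markovian propensity and are rejected.
#'
#' @param reaction an \code{nm_reaction} with a Markovian family.
#' @param counts named vector of copy numbers.
#' @param scale concentration scale (copy number to concentration).
#' @return Propensity (per-time).
#' @export
ssa_propensity <- function(reaction, counts, scale = 1) {
  ds <- reaction$dist_spec
  switch(ds$family,
    mass_action = mass_action_propensity(reaction$reactants, ds$c, counts),
    mm_lumped = mm_lumped_propensity(ds, counts, scale),
    exponential = {
      if (!is.null(ds$lam_species)) {
        n <- unname(counts[ds$lam_species])
        n[is.na(n)] <- 0
        ds$lam_scale * prod(scale * n)
      } else ds$lam
    },
    stop("reaction family '", ds$family,
         "' has no Markovian propensity; use the non-Markovian engine",
         call. = FALSE)
  )
}

#' One step of the Gillespie Direct Method
#'
#' With total propensity \eqn{a_0 = \sum_j a_j}: the waiting time is
#' \eqn{\tau \sim \mathrm{Exp}(a_0)} and channel \eqn{j} fires with
#' probability \eqn{a_j / a_0}. Channels that cannot fire (insufficient
#' reactants) contribute zero propensity.
#'
#' @inheritParams step_network
#' @param scale concentration scale for \code{mm_lumped} channels.
#' @return NULL when \eqn{a_0 = 0} (halt), otherwise a list with
#'   \code{reaction}, \code{tau}, \code{counts}, \code{time}.
#' @export
ssa_direct_step <- function(system, counts, time = 0, scale = 1) {
  a <- numeric(length(system))
  for (i in seq_along(system)) {
    r <- system[[i]]
    if (!fireable(r, counts)) next
    a[i] <- ssa_propensity(r, counts, scale)
  }
  a0 <- sum(a)
  if (a0 <= 0) return(NULL)
  tau <- stats::rexp(1, rate = a0)
  j <- sample.int(length(a), 1L, prob = a / a0)
  r <- system[[j]]
  for (sp in names(r$reactants)) counts[sp] <- counts[sp] - r$reactants[sp]
  for (sp in names(r$products)) {
    if (is.na(counts[sp])) counts[sp] <- 0
    counts[sp] <- counts[sp] + r$products[sp]
  }
  list(reaction = j, tau = tau, counts = counts, time = time + tau)
}

#' Simulate with the Gillespie Direct Method (reference model)
#'
#' Exact stochastic simulation of the Markov jump process defined by the
#' channels' propensities. Used as the benchmark "full model" when every
#' elementary reaction is listed with \code{mass_action} kinetics, and as
#' the lumped Markovian model when a single \code{mm_lumped} channel is
#' used.
#'
#' @inheritParams simulate_network
#' @param scale concentration scale for \code{mm_lumped} channels.
#' @return An \code{nm_trajectory} data frame (see [simulate_network()]);
#'   \code{attr(x, "iterations")} is the number of firings.
#' @examples
#' sys <- parse_reactions(c(
#'   "E + S -> ES [dist=mass_action; c=0.01]",
#'   "ES -> E + S [dist=mass_action; c=0.1]",
#'   "ES -> E + P [dist=mass_action; c=1]"))
#' tr <- ssa_simulate(sys, c(E = 2, S = 50),
#'                    stop_when(species = "P", count = 20), seed = 1)
#' attr(tr, "iterations")
#' @export
ssa_simulate <- function(system, init, stop = stop_when(), scale = 1,
                         seed = NULL) {
  stopifnot(inherits(system, "reaction_system"),
            inherits(stop, "stop_criterion"))
  if (!is.null(seed)) set.seed(seed)
  species <- union(attr(system, "species"), names(init))
  counts <- stats::setNames(integer(length(species)), species)
  counts[names(init)] <- as.integer(init)
  if (any(counts < 0)) stop("initial counts must be non-negative")

  cap <- 1024L
  times <- numeric(cap)
  fired <- integer(cap)
  mat <- matrix(0L, nrow = cap, ncol = length(species),
                dimnames = list(NULL, species))
  n <- 1L
  times[1L] <- 0
  fired[1L] <- NA_integer_
  mat[1L, ] <- counts
  time <- 0
  iter <- 0L

  while (!.stop_reached(stop, counts, time, iter)) {
    st <- ssa_direct_step(system, counts, time, scale)
    if (is.null(st)) break
    if (st$time > stop$max_time) break
    counts <- st$counts
    time <- st$time
    iter <- iter + 1L
    n <- n + 1L
    if (n > cap) {
      cap <- cap * 2L
      length(times) <- cap
      length(fired) <- cap
      mat <- rbind(mat, matrix(0L, nrow = cap / 2L, ncol = ncol(mat)))
    }
    times[n] <- time
    fired[n] <- st$reaction
    mat[n, ] <- counts
  }

  labels <- vapply(system, function(r) r$label, character(1))
  out <- data.frame(time = times[seq_len(n)],
                    mat[seq_len(n), , drop = FALSE],
                    reaction = labels[fired[seq_len(n)]],
                    check.names = FALSE, stringsAsFactors = FALSE)
  attr(out, "species") <- species
  attr(out, "iterations") <- iter
  class(out) <- c("nm_trajectory", "data.frame")
  out
}
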