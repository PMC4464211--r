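#' Parse a reaction-network specification
#'
#' Reads the plain-text reaction grammar, one reaction per line:
#' \preformatted{a1 X1 + a2 X2 -> b1 Y1 [dist=FAMILY; key=value; ...]}
#' Stoichiometric coefficients default to 1. Blank lines and lines starting
#' with \code{#} are ignored. The bracketed annotation selects the
#' waiting-time family for the reaction and its parameters:
#' \describe{
#'   \item{\code{mm_single_molecule}}{\code{k1}, \code{k2}, \code{k_minus1};
#'     \code{substrate=SPECIES} names the species whose live amount (times
#'     the concentration scale) enters the density as [S].}
#'   \item{\code{exponential}}{either a fixed \code{lam}, or
#'     \code{lam_species=A} (comma-separated list allowed) with optional
#'     \code{lam_scale}: the rate is \code{lam_scale} times the product of
#'     the named species' live concentrations.}
#'   \item{\code{erlang}}{\code{k}, \code{lam}.}
#'   \item{\code{hyperexponential}}{\code{weights=w1,w2,...};
#'     \code{rates=l1,l2,...}.}
#'   \item{\code{mass_action}}{stochastic rate constant \code{c}; the
#'     waiting time is exponential with the combinatorial mass-action
#'     propensity (the Markovian limit).}
#'   \item{\code{mm_lumped}}{\code{k1}, \code{k2}, \code{k_minus1},
#'     \code{substrate=SPECIES}; exponential waiting time with the
#'     Michaelis-Menten propensity \eqn{v = k_2 [S]/([S]+K_M)} (the lumped
#'     Markovian model).}
#' }
#'
#' A species may not appear twice on the same side of a reaction; write the
#' summed coefficient instead.
#'
#' @param text character vector of lines, or a single string with embedded
#'   newlines, or (when \code{file}) a path.
#' @param file if TRUE, \code{text} is a file path.
#' @return An object of class \code{"reaction_system"}: a list of reactions
#'   with a \code{species} attribute.
#' @examples
#' sys <- parse_reactions(c(
#'   "A -> B [dist=mm_single_molecule; k1=1; k2=1; k_minus1=10; substrate=A]",
#'   "A -> C [dist=exponential; lam_species=A; lam_scale=10]"))
#' sys
#' @export
parse_reactions <- function(text, file = FALSE) {
  if (file) text <- readLines(text, warn = FALSE)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  reactions <- list()
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[[ln]])
    if (raw == "" || startsWith(raw, "#")) next
    reactions[[length(reactions) + 1L]] <- .parse_reaction_line(raw, ln)
  }
  if (length(reactions) == 0L) stop("no reactions found in input")
  for (i in seq_along(reactions)) {
    reactions[[i]]$index <- i
    if (is.null(reactions[[i]]$label))
      reactions[[i]]$label <- paste0("R", i)
  }
  species <- unique(unlist(lapply(reactions, function(r)
    c(names(r$reactants), names(r$products)))))
  structure(reactions, species = species, class = "reaction_system")
}

.parse_side <- function(side, line_no, what) {
  side <- trimws(side)
  if (side == "" || side == "0") return(integer(0))
  terms <- strsplit(side, "+", fixed = TRUE)[[1]]
  out <- integer(0)
  for (term in terms) {
    m <- regmatches(term, regexec(
      "^\\s*([0-9]+)?\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*$", term))[[1]]
    if (length(m) == 0L)
      stop(sprintf("line %d: cannot parse %s term '%s'",
                   line_no, what, trimws(term)), call. = FALSE)
    coef <- if (m[2] == "") 1L else as.integer(m[2])
    if (coef <= 0L)
      stop(sprintf("line %d: coefficient must be a positive integer in '%s'",
                   line_no, trimws(term)), call. = FALSE)
    sp <- m[3]
    if (sp %in% names(out))
      stop(sprintf("line %d: species '%s' repeated on one side; write the summed coefficient instead",
                   line_no, sp), call. = FALSE)
    out[sp] <- coef
  }
  out
}

.known_families <- c("mm_single_molecule", "exponential", "erlang",
                     "hyperexponential", "mass_action", "mm_lumped")

.parse_reaction_line <- function(raw, line_no) {
  spec <- list()
  m <- regmatches(raw, regexec("^(.*?)\\s*\\[(.*)\\]\\s*$", raw))[[1]]
  if (length(m) > 0L) {
    raw <- m[2]
    for (kv in strsplit(m[3], ";", fixed = TRUE)[[1]]) {
      kv <- trimws(kv)
      if (kv == "") next
      eq <- regmatches(kv, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*)$", kv))[[1]]
      if (length(eq) == 0L)
        stop(sprintf("line %d: cannot parse annotation '%s'", line_no, kv),
             call. = FALSE)
      spec[[eq[2]]] <- trimws(eq[3])
    }
  }
  arrow <- regmatches(raw, regexec("^(.*?)->(.*)$", raw))[[1]]
  if (length(arrow) == 0L)
    stop(sprintf("line %d: no '->' found in '%s'", line_no, raw),
         call. = FALSE)
  reactants <- .parse_side(arrow[2], line_no, "reactant")
  products <- .parse_side(arrow[3], line_no, "product")
  if (length(reactants) == 0L && length(products) == 0L)
    stop(sprintf("line %d: reaction needs at least one reactant or product",
                 line_no), call. = FALSE)
  if (is.null(spec$dist))
    stop(sprintf("line %d: missing [dist=...] annotation", line_no),
         call. = FALSE)
  if (!(spec$dist %in% .known_families))
    stop(sprintf("line %d: unknown distribution family '%s'",
                 line_no, spec$dist), call. = FALSE)
  dist_spec <- .build_dist_spec(spec, line_no)
  structure(list(reactants = reactants, products = products,
                 dist_spec = dist_spec, label = spec$label, line = line_no),
            class = "nm_reaction")
}

.num <- function(spec, key, line_no, required = TRUE) {
  v <- spec[[key]]
  if (is.null(v)) {
    if (required)
      stop(sprintf("line %d: family '%s' requires parameter '%s'",
                   line_no, spec$dist, key), call. = FALSE)
    return(NULL)
  }
  out <- suppressWarnings(as.numeric(strsplit(v, ",", fixed = TRUE)[[1]]))
  if (any(is.na(out)))
    stop(sprintf("line %d: parameter '%s' is not numeric ('%s')",
                 line_no, key, v), call. = FALSE)
  out
}

.build_dist_spec <- function(spec, line_no) {
  fam <- spec$dist
  out <- list(family = fam)
  if (fam %in% c("mm_single_molecule", "mm_lumped")) {
    out$k1 <- .num(spec, "k1", line_no)
    out$k2 <- .num(spec, "k2", line_no)
    out$k_minus1 <- .num(spec, "k_minus1", line_no)
    if (is.null(spec$substrate))
      stop(sprintf("line %d: family '%s' requires 'substrate=SPECIES'",
                   line_no, fam), call. = FALSE)
    out$substrate <- spec$substrate
  } else if (fam == "exponential") {
    out$lam <- .num(spec, "lam", line_no, required = is.null(spec$lam_species))
    if (!is.null(spec$lam_species)) {
      out$lam_species <- trimws(strsplit(spec$lam_species, ",", fixed = TRUE)[[1]])
      sc <- .num(spec, "lam_scale", line_no, required = FALSE)
      out$lam_scale <- if (is.null(sc)) 1 else sc
    }
  } else if (fam == "erlang") {
    out$k <- .num(spec, "k", line_no)
    out$lam <- .num(spec, "lam", line_no)
  } else if (fam == "hyperexponential") {
    out$weights <- .num(spec, "weights", line_no)
    out$rates <- .num(spec, "rates", line_no)
  } else if (fam == "mass_action") {
    out$c <- .num(spec, "c", line_no)
  }
  out
}

#' Serialise a reaction system back to its text grammar
#'
#' Inverse of [parse_reactions()]: re-parsing the output yields an
#' equivalent system.
#'
#' @param system a \code{reaction_system}.
#' @return Character vector, one line per reaction.
#' @export
format_reactions <- function(system) {
  stopifnot(inherits(system, "reaction_system"))
  vapply(system, .format_reaction, character(1))
}

.format_side <- function(side) {
  if (length(side) == 0L) return("0")
  paste(ifelse(side == 1L, names(side), paste(side, names(side))),
        collapse = " + ")
}

.format_reaction <- function(r) {
  ds <- r$dist_spec
  kv <- vapply(setdiff(names(ds), "family"), function(k)
    paste0(k, "=", paste(ds[[k]], collapse = ",")), character(1))
  sprintf("%s -> %s [dist=%s%s]", .format_side(r$reactants),
          .format_side(r$products), ds$family,
          if (length(kv)) paste0("; ", paste(kv, collapse = "; ")) else "")
}

#' @export
print.reaction_system <- function(x, ...) {
  cat("Reaction system:", length(x), "reaction(s),",
      length(attr(x, "species")), "species\n")
  lab <- vapply(x, function(r) r$label, character(1))
  for (i in seq_along(x))
    cat(sprintf("  %s: %s\n", lab[i], .format_reaction(x[[i]])))
  invisible(x)
}

#' Can a reaction fire in a given state?
#'
#' TRUE iff every reactant species has at least its stoichiometric
#' coefficient's worth of copies. Species absent from \code{counts} are
#' treated as 0.
#'
#' @param reaction an \code{nm_reaction} (element of a
#'   \code{reaction_system}).
#' @param counts named integer vector of copy numbers.
#' @return Logical scalar.
#' @export
fireable <- function(reaction, counts) {
  req <- reaction$reactants
  if (length(req) == 0L) return(TRUE)
  have <- counts[names(req)]
  have[is.na(have)] <- 0
  all(have >= req)
}

#' Engine configuration
#'
#' @param scale concentration scale: factor converting a species copy
#'   number to the concentration fed into live distribution parameters
#'   (default 1: copy numbers are used directly as concentrations).
#' @param precision absolute inversion precision forwarded to
#'   [inversion_config()]; NULL uses the per-distribution relative default.
#' @param first_of_n optional species name: for
#'   \code{mm_single_molecule} channels, sample one waiting time per copy
#'   of this species (e.g. the free enzyme) and take the minimum, instead
#'   of the default single draw per channel.
#' @return A list of class \code{"engine_config"}.
#' @export
engine_config <- function(scale = 1, precision = NULL, first_of_n = NULL) {
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0)
  structure(list(scale = scale, precision = precision,
                 first_of_n = first_of_n),
            class = "engine_config")
}

# Instantiate the live wt_dist of a reaction at the current state.
# Returns NULL when the live parameters are invalid (e.g. substrate
# exhausted), in which case the engine treats the reaction as not
# fireable.
.live_dist <- function(reaction, counts, config) {
  ds <- reaction$dist_spec
  conc <- function(sp) {
    n <- counts[sp]
    if (is.na(n)) n <- 0
    config$scale * n
  }
  tryCatch(switch(ds$family,
    mm_single_molecule = dist_mm(ds$k1, ds$k2, ds$k_minus1,
                                 conc(ds$substrate)),
    exponential = {
      lam <- if (!is.null(ds$lam_species))
        ds$lam_scale * prod(vapply(ds$lam_species, conc, numeric(1)))
      else ds$lam
      dist_exponential(lam)
    },
    erlang = dist_erlang(ds$k, ds$lam),
    hyperexponential = dist_hyperexp(ds$weights, ds$rates),
    mass_action = dist_exponential(
      mass_action_propensity(reaction$reactants, ds$c, counts)),
    mm_lumped = dist_exponential(
      mm_lumped_propensity(ds, counts, config$scale)),
    stop("unknown family ", ds$family)
  ), error = function(e) NULL)
}

#' One iteration of the non-Markovian race engine
#'
#' Samples a waiting time for every fireable reaction from its
#' distribution evaluated at the \emph{current} state, fires the reaction
#' with the smallest waiting time (ties broken by lowest reaction index),
#' updates the copy numbers and advances the clock. Losing samples are
#' discarded: every reaction is resampled afresh at the next iteration.
#'
#' Reactions whose live distribution parameters are invalid at the current
#' state (for instance a Michaelis-Menten channel whose substrate count is
#' zero) are treated as not fireable.
#'
#' @param system a \code{reaction_system}.
#' @param counts named integer vector of copy numbers.
#' @param time current simulation clock.
#' @param config an [engine_config()].
#' @return NULL when no reaction can fire (halt), otherwise a list with
#'   \code{reaction} (index), \code{tau}, \code{counts}, \code{time}.
#' @export
step_network <- function(system, counts, time = 0,
                         config = engine_config()) {
  best_tau <- Inf
  best_i <- 0L
  for (i in seq_along(system)) {
    r <- system[[i]]
    if (!fireable(r, counts)) next
    d <- .live_dist(r, counts, config)
    if (is.null(d)) next
    cfg <- if (is.null(config$precision)) inversion_config(d)
           else inversion_config(d, precision = config$precision)
    ndraw <- 1L
    if (!is.null(config$first_of_n) &&
        r$dist_spec$family == "mm_single_molecule") {
      ndraw <- counts[config$first_of_n]
      if (is.na(ndraw) || ndraw < 1L) ndraw <- 1L
    }
    tau <- min(wt_sample(d, ndraw, config = cfg))
    if (tau < best_tau) {      # strict <: lowest index wins ties
      best_tau <- tau
      best_i <- i
    }
  }
  if (best_i == 0L) return(NULL)
  r <- system[[best_i]]
  for (sp in names(r$reactants)) counts[sp] <- counts[sp] - r$reactants[sp]
  for (sp in names(r$products)) {
    if (is.na(counts[sp])) counts[sp] <- 0
    counts[sp] <- counts[sp] + r$products[sp]
  }
  if (any(counts < 0)) stop("internal error: negative copy number")
  list(reaction = best_i, tau = best_tau, counts = counts,
       time = time + best_tau)
}

#' Stopping criterion for a simulation
#'
#' @param max_time stop once the clock would exceed this time (the state at
#'   halt is the last state reached at or before it).
#' @param max_iterations stop after this many reaction firings.
#' @param species,count stop as soon as \code{species} reaches at least
#'   \code{count} copies.
#' @return A list of class \code{"stop_criterion"}.
#' @export
stop_when <- function(max_time = Inf, max_iterations = Inf,
                      species = NULL, count = NULL) {
  if (xor(is.null(species), is.null(count)))
    stop("'species' and 'count' must be given together")
  structure(list(max_time = max_time, max_iterations = max_iterations,
                 species = species, count = count),
            class = "stop_criterion")
}

.stop_reached <- function(stop, counts, time, iter) {
  if (iter >= stop$max_iterations) return(TRUE)
  if (time >= stop$max_time) return(TRUE)
  if (!is.null(stop$species)) {
    n <- counts[stop$species]
    if (!is.na(n) && n >= stop$count) return(TRUE)
  }
  FALSE
}

#' Simulate a reaction network with non-Markovian waiting times
#'
#' Runs the race engine of [step_network()] from an initial state until the
#' stopping criterion is met or no reaction can fire. Each trajectory
#' record holds the time stamp, the species copy numbers, and the label of
#' the last reaction fired; consecutive records differ by exactly one
#' reaction's stoichiometry.
#'
#' @param system a \code{reaction_system} from [parse_reactions()].
#' @param init named vector of initial copy numbers; species missing from
#'   it start at 0.
#' @param stop a [stop_when()] criterion.
#' @param config an [engine_config()].
#' @param seed optional integer seed for reproducible trajectories.
#' @return A data frame of class \code{"nm_trajectory"} with columns
#'   \code{time}, one column per species, and \code{reaction} (label of the
#'   fired reaction; NA on the initial record). The number of iterations
#'   (= firings) is \code{nrow - 1}.
#' @examples
#' sys <- parse_reactions(c(
#'   "A -> B [dist=exponential; lam=1]",
#'   "B -> C [dist=exponential; lam=2]"))
#' tr <- simulate_network(sys, c(A = 5), stop_when(max_time = 100), seed = 1)
#' tail(tr, 3)
#' @export
simulate_network <- function(system, init,
                             stop = stop_when(),
                             config = engine_config(),
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
    st <- step_network(system, counts, time, config)
    if (is.null(st)) break
    if (st$time > stop$max_time) break   # would overshoot the horizon
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

#' @export
print.nm_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d iteration(s), final time %.6g\n",
              attr(x, "iterations"), x$time[nrow(x)]))
  print.data.frame(utils::tail(as.data.frame(x), 6L), row.names = FALSE)
  invisible(x)
}

#' @export
plot.nm_trajectory <- function(x, ..., legend_pos = "topright") {
  sp <- attr(x, "species")
  graphics::matplot(x$time, as.matrix(x[, sp, drop = FALSE]), type = "s",
                    lty = 1, xlab = "time", ylab = "copy number", ...)
  graphics::legend(legend_pos, legend = sp, lty = 1,
                   col = seq_along(sp), bty = "n")
  invisible(x)
}

#' Write a trajectory as CSV
#'
#' Emits the record the simulator defines: a time stamp, the copy numbers
#' at that time, and the last reaction fired, with header
#' \code{time,<species...>,reaction}.
#'
#' @param trajectory an \code{nm_trajectory}.
#' @param path output file path.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "nm_trajectory"))
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Read a key-value simulation config file
#'
#' Plain-text \code{key = value} lines (\code{#} comments allowed):
#' \code{init.<SPECIES>} initial copy numbers; \code{stop.time},
#' \code{stop.iterations}, \code{stop.species} + \code{stop.count} the stop
#' criterion; \code{seed}; \code{precision}; \code{scale}.
#'
#' @param path file path.
#' @return A list with elements \code{init}, \code{stop}, \code{seed},
#'   \code{config}.
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (raw in lines) {
    s <- trimws(sub("#.*$", "", raw))
    if (s == "") next
    m <- regmatches(s, regexec("^([A-Za-z_.][A-Za-z0-9_.]*)\\s*=\\s*(.*)$", s))[[1]]
    if (length(m) == 0L) stop("cannot parse config line: ", raw)
    kv[[m[2]]] <- trimws(m[3])
  }
  init_keys <- grep("^init\\.", names(kv), value = TRUE)
  init <- stats::setNames(as.numeric(unlist(kv[init_keys])),
                          sub("^init\\.", "", init_keys))
  stop_crit <- stop_when(
    max_time = if (is.null(kv$stop.time)) Inf else as.numeric(kv$stop.time),
    max_iterations = if (is.null(kv$stop.iterations)) Inf
                     else as.numeric(kv$stop.iterations),
    species = kv$stop.species,
    count = if (is.null(kv$stop.count)) NULL else as.numeric(kv$stop.count))
  list(init = init,
       stop = stop_crit,
       seed = if (is.null(kv$seed)) NULL else as.integer(kv$seed),
       config = engine_config(
         scale = if (is.null(kv$scale)) 1 else as.numeric(kv$scale),
         precision = if (is.null(kv$precision)) NULL
                     else as.numeric(kv$precision)))
}
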