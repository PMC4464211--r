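mm_scheme_text <- c(
  "E + S -> ES [dist=mass_action; c=0.01]",
  "ES -> E + S [dist=mass_action; c=0.1]",
  "ES -> E + P [dist=mass_action; c=1]")

test_that("the reaction grammar parses stoichiometry and annotations", {
  sys <- parse_reactions(
    "A -> B [dist=mm_single_molecule; k1=1.0; k2=1.0; k_minus1=10.0; substrate=A]")
  expect_length(sys, 1L)
  expect_equal(sys[[1]]$reactants, c(A = 1L))
  expect_equal(sys[[1]]$products, c(B = 1L))
  expect_equal(sys[[1]]$dist_spec$k_minus1, 10)

  full <- parse_reactions(mm_scheme_text)
  expect_length(full, 3L)
  expect_setequal(attr(full, "species"), c("E", "S", "ES", "P"))
  expect_equal(full[[1]]$reactants, c(E = 1L, S = 1L))

  two <- parse_reactions("2 A -> B [dist=exponential; lam=1]")
  expect_equal(two[[1]]$reactants, c(A = 2L))
})

test_that("reaction systems round-trip through the serializer", {
  sys <- parse_reactions(c(
    mm_scheme_text,
    "S -> P [dist=mm_lumped; k1=1e7; k2=250; k_minus1=50; substrate=S]",
    "A -> C [dist=exponential; lam_species=A; lam_scale=10]",
    "X -> Y [dist=erlang; k=2; lam=0.0078]",
    "X -> Z [dist=hyperexponential; weights=0.4,0.6; rates=0.5,4]"))
  sys2 <- parse_reactions(format_reactions(sys))
  expect_equal(format_reactions(sys2), format_reactions(sys))
  for (i in seq_along(sys)) {
    expect_equal(sys2[[i]]$reactants, sys[[i]]$reactants)
    expect_equal(sys2[[i]]$products, sys[[i]]$products)
    expect_equal(sys2[[i]]$dist_spec, sys[[i]]$dist_spec)
  }
})

test_that("malformed reaction lines fail with informative errors", {
  expect_error(parse_reactions("A -> B [dist=weibull; k=2]"),
               "unknown distribution family")
  expect_error(parse_reactions("A + A -> B [dist=exponential; lam=1]"),
               "repeated on one side")
  expect_error(parse_reactions("0 A -> B [dist=exponential; lam=1]"),
               "positive integer")
  expect_error(parse_reactions(c("A -> B [dist=exponential; lam=1]",
                                 "A = B [dist=exponential; lam=1]")),
               "line 2")
  expect_error(parse_reactions("A -> B"), "dist")
  expect_error(parse_reactions("A -> B [dist=exponential]"), "lam")
  expect_error(parse_reactions("S -> P [dist=mm_lumped; k1=1; k2=1; k_minus1=0]"),
               "substrate")
})

test_that("fireability follows reactant stoichiometry with absent = 0", {
  sys <- parse_reactions(c("A -> B [dist=exponential; lam=1]",
                           "2 A -> B [dist=exponential; lam=1]"))
  expect_false(fireable(sys[[1]], c(A = 0)))
  expect_true(fireable(sys[[1]], c(A = 1)))
  expect_false(fireable(sys[[2]], c(A = 1)))
  expect_true(fireable(sys[[2]], c(A = 2)))
  expect_false(fireable(sys[[1]], c(B = 5)))  # A absent -> count 0
})

test_that("the race engine conserves mass and advances the clock", {
  ex <- example_network()
  tr <- simulate_network(ex$system, ex$init, seed = 5)
  expect_true(all(tr$A + tr$B + tr$C == 100))
  expect_true(all(diff(tr$time) > 0))
  expect_equal(tr$A[nrow(tr)], 0)           # run to exhaustion of A
  expect_equal(tr$B[nrow(tr)] + tr$C[nrow(tr)], 100)
  expect_equal(attr(tr, "iterations"), 100)
  # consecutive records differ by exactly one reaction's stoichiometry
  lab <- vapply(ex$system, function(r) r$label, character(1))
  for (i in 2:nrow(tr)) {
    j <- match(tr$reaction[i], lab)
    r <- ex$system[[j]]
    delta <- unlist(tr[i, c("A", "B", "C")]) - unlist(tr[i - 1, c("A", "B", "C")])
    expected <- c(A = 0, B = 0, C = 0)
    expected[names(r$reactants)] <- expected[names(r$reactants)] - r$reactants
    expected[names(r$products)] <- expected[names(r$products)] + r$products
    expect_equal(delta, expected)
  }
})

test_that("a single reaction halts exactly at reactant exhaustion", {
  sys <- parse_reactions("A -> B [dist=exponential; lam=2]")
  tr <- simulate_network(sys, c(A = 3), seed = 1)
  expect_equal(attr(tr, "iterations"), 3)
  expect_equal(tr$A[nrow(tr)], 0)
  expect_equal(tr$B[nrow(tr)], 3)
  # a further step from the final state signals halt
  expect_null(step_network(sys, c(A = 0L, B = 3L)))
})

test_that("enzyme copies are conserved in the full MM scheme", {
  sys <- parse_reactions(mm_scheme_text)
  tr <- simulate_network(sys, c(E = 1, S = 30),
                         stop_when(species = "P", count = 30), seed = 2)
  expect_true(all(tr$E + tr$ES == 1))
  expect_true(all(tr$S + tr$ES + tr$P == 30))
})

test_that("stop criteria bound time, iterations and product counts", {
  ex <- example_network()
  tr0 <- simulate_network(ex$system, ex$init, stop_when(max_time = 0))
  expect_equal(nrow(tr0), 1L)                  # only the initial record
  expect_equal(attr(tr0, "iterations"), 0)

  tr5 <- simulate_network(ex$system, ex$init,
                          stop_when(max_iterations = 5), seed = 3)
  expect_equal(attr(tr5, "iterations"), 5)

  sys <- parse_reactions(
    "S -> P [dist=mm_lumped; k1=1; k2=5; k_minus1=1; substrate=S]")
  trp <- simulate_network(sys, c(S = 100),
                          stop_when(species = "P", count = 20), seed = 4)
  expect_equal(trp$P[nrow(trp)], 20)
  expect_equal(attr(trp, "iterations"), 20)    # one product per firing
})

test_that("channels with invalid live parameters are skipped, not fatal", {
  # the MM channel needs S > 0; once A is exhausted by the drain channel
  # the MM channel must simply stop competing
  sys <- parse_reactions(c(
    "A -> B [dist=mm_single_molecule; k1=1; k2=1; k_minus1=10; substrate=A]",
    "A -> C [dist=exponential; lam=50]"))
  tr <- simulate_network(sys, c(A = 5), seed = 6)
  expect_equal(tr$A[nrow(tr)], 0)
  expect_equal(tr$B[nrow(tr)] + tr$C[nrow(tr)], 5)
})

test_that("trajectories are reproducible byte-for-byte under a seed", {
  ex <- example_network()
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_trajectory(simulate_network(ex$system, ex$init, seed = 77), f1)
  write_trajectory(simulate_network(ex$system, ex$init, seed = 77), f2)
  expect_identical(readLines(f1), readLines(f2))
  header <- readLines(f1, n = 1)
  expect_equal(header, "time,A,B,C,reaction")
  unlink(c(f1, f2))
})

test_that("simulation config files round-trip initial state and criteria", {
  f <- tempfile(fileext = ".cfg")
  writeLines(c("# demo config", "init.A = 100", "init.B = 0",
               "stop.species = B", "stop.count = 10",
               "seed = 12", "scale = 0.5", "precision = 1e-8"), f)
  cfg <- read_sim_config(f)
  expect_equal(cfg$init, c(A = 100, B = 0))
  expect_equal(cfg$stop$species, "B")
  expect_equal(cfg$stop$count, 10)
  expect_equal(cfg$seed, 12L)
  expect_equal(cfg$config$scale, 0.5)
  expect_equal(cfg$config$precision, 1e-8)
  unlink(f)
})
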