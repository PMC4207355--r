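test_that("FBA on a bound-limited linear chain hits the uptake bound", {
  net <- chain_net(uptake = 10)
  sol <- fba(net)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 10, tolerance = 1e-9)
  # steady state and bounds hold at the optimum
  expect_lt(max(abs(as.numeric(net$S %*% sol$fluxes))), 1e-6)
  expect_true(all(sol$fluxes >= net$reactions$lower - 1e-9))
  expect_true(all(sol$fluxes <= net$reactions$upper + 1e-9))
})

test_that("infeasible and unbounded models are reported in status", {
  net <- chain_net()
  # force biomass above what uptake allows
  bad <- set_bounds(net, "BIOMASS", lower = 50)
  expect_equal(fba(bad)$status, "infeasible")
  # a reversible pair with infinite bounds is unbounded in the loop direction
  loop <- metabolic_network(
    metabolites = data.frame(id = c("a", "b")),
    reactions = data.frame(id = c("F", "B"),
                           lower = c(-Inf, -Inf), upper = c(Inf, Inf)),
    stoichiometry = list(F = c(a = -1, b = 1), B = c(b = -1, a = 1)))
  expect_equal(fba(loop, objective = "F")$status, "unbounded")
})

test_that("FVA equals brute-force vertex enumeration on small fixtures", {
  for (s in 1:10) {
    net <- random_toy_network(s, n_reactions = 5 + s %% 4,
                              n_metabolites = 2 + s %% 3)
    oracle <- brute_force_flux_extrema(net)
    got <- fva(net)
    expect_equal(got$min, oracle$min, tolerance = 1e-8)
    expect_equal(got$max, oracle$max, tolerance = 1e-8)
  }
})

test_that("a dead-end consumer is blocked to [0, 0]", {
  net <- metabolic_network(
    metabolites = data.frame(id = c("a", "dead")),
    reactions = data.frame(id = c("EX_a", "R_dead"),
                           lower = c(-10, 0), upper = c(0, 1000)),
    stoichiometry = list(EX_a = c(a = -1), R_dead = c(a = -1, dead = 1)))
  rng <- fva(net, "R_dead")
  expect_equal(c(rng$min, rng$max), c(0, 0), tolerance = 1e-9)
})

test_that("FVA ranges contain the FBA optimum and are nested under tightening", {
  net <- make_toy_network(2, 2, seed = 3)
  sol <- fba(net)
  rng <- fva(net, fixed = stats::setNames(
    list(c(sol$objective_value * (1 - 1e-6), sol$objective_value)),
    net$biomass))
  j <- match(names(sol$fluxes), rng$id)
  expect_true(all(sol$fluxes >= rng$min[j] - 1e-5))
  expect_true(all(sol$fluxes <= rng$max[j] + 1e-5))
  expect_true(all(rng$min <= rng$max + 1e-9))
  # tightening any bound shrinks ranges monotonically
  wide <- fva(net)
  tight <- fva(set_bounds(net, "EX_sub", lower = -5))
  expect_true(all(tight$min >= wide$min - 1e-9))
  expect_true(all(tight$max <= wide$max + 1e-9))
})

test_that("infeasible pins name the conflicting constraint", {
  net <- chain_net()
  expect_error(fva(net, fixed = list(BIOMASS = 99)),
               "infeasible pin.*BIOMASS")
})

test_that("gene deletions follow GPR semantics and are monotone", {
  net <- chain_net()   # R1: g_r1 ; R2: g_r2a or g_r2b
  # one isozyme down: reaction stays active
  d1 <- apply_gene_deletion(net, "g_r2a")
  expect_equal(fba(d1)$objective_value, 10, tolerance = 1e-9)
  # both isozymes: blocked
  d2 <- apply_gene_deletion(net, c("g_r2a", "g_r2b"))
  expect_equal(fba(d2)$objective_value, 0, tolerance = 1e-9)
  # single-gene rule: blocked at once
  d3 <- apply_gene_deletion(net, "g_r1")
  expect_equal(fba(d3)$objective_value, 0, tolerance = 1e-9)
  expect_warning(apply_gene_deletion(net, "nonexistent_gene"), "unknown gene")
  # deleting a superset never increases max biomass
  net2 <- make_toy_network(2, 2, seed = 9)
  genes <- net2$genes
  prev <- fba(net2)$objective_value
  for (k in seq_along(genes)) {
    cur <- fba(apply_gene_deletion(net2, genes[seq_len(k)]))$objective_value
    expect_lte(cur, prev + 1e-9)
    prev <- cur
  }
})

test_that("flux normalization rescales linearly and preserves steady state", {
  net <- chain_net()
  sol <- fba(set_bounds(net, "EX_sub", lower = -5))
  expect_equal(sol$fluxes[["EX_sub"]], -5, tolerance = 1e-9)
  scaled <- normalize_fluxes(sol, "EX_sub", target = 10)
  expect_equal(scaled$fluxes[["EX_sub"]], -10, tolerance = 1e-9)
  expect_equal(scaled$fluxes, sol$fluxes * 2, tolerance = 1e-12)
  expect_lt(max(abs(as.numeric(net$S %*% scaled$fluxes))), 1e-6)
  # already at target: identity
  again <- normalize_fluxes(scaled, "EX_sub", target = 10)
  expect_equal(again$fluxes, scaled$fluxes, tolerance = 1e-12)
  # zero reference flux errors
  blocked <- fba(set_bounds(net, "EX_sub", 0, 0))
  expect_error(normalize_fluxes(blocked, "EX_sub"), "zero")
})
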