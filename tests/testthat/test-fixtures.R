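test_that("toy networks are connected, feasible, and hand-computable", {
  # 1 branch, length 2: EX_sub, two conversions, biomass, product/cell
  # exchanges; max biomass = uptake bound x unit yield
  net <- make_toy_network(n_branches = 1, branch_length = 2, seed = 1)
  expect_equal(fba(net)$objective_value, 10, tolerance = 1e-9)
  expect_true(all(c("EX_sub", "R_1_1", "R_1_2", "BIOMASS") %in%
                    net$reactions$id))
  # n branches split the uptake
  net3 <- make_toy_network(n_branches = 3, branch_length = 2, seed = 1)
  expect_equal(fba(net3)$objective_value, 10 / 3, tolerance = 1e-8)
  # any spec: optimal with positive growth
  for (s in c(2, 5, 8)) {
    sol <- fba(make_toy_network(n_branches = 1 + s %% 3,
                                branch_length = 1 + s %% 3, seed = s))
    expect_equal(sol$status, "optimal")
    expect_gt(sol$objective_value, 0)
  }
})

test_that("fixture generation is seed-deterministic", {
  a <- make_toy_network(2, 3, seed = 7)
  b <- make_toy_network(2, 3, seed = 7)
  expect_identical(a$reactions, b$reactions)
  expect_identical(as.matrix(a$S), as.matrix(b$S))
  c1 <- make_bottleneck_fixture(4)
  c2 <- make_bottleneck_fixture(4)
  expect_identical(c1$control$levels, c2$control$levels)
  expect_identical(c1$target, c2$target)
  # fixtures pass balance checking (synthetic single-token formulas)
  reps <- network_balance(a)
  expect_true(all(vapply(reps, function(r) r$balanced, TRUE)))
})

test_that("planted regulation round-trips through the GPR semantics", {
  net <- make_toy_network(2, 3, seed = 15)
  gprd <- net$reactions$id[!vapply(net$gpr, is.null, TRUE)]
  # single target at 0.5, complex and isozyme targets included by seed sweep
  for (tgt in gprd[1:4]) {
    prof <- plant_regulation(net, tgt, fold = 0.5, seed = 2)
    m <- build_fold_change_map(net, prof$control, prof$stress)
    expect_equal(unname(m[tgt]), 0.5, tolerance = 1e-12)
    expect_true(all(m[setdiff(names(m), tgt)] >= 1 - 1e-12))
  }
  # AND target: only the weakest subunit is scaled
  and_rxn <- gprd[vapply(net$gpr[gprd], function(g) g$kind == "and", TRUE)]
  if (length(and_rxn)) {
    prof <- plant_regulation(net, and_rxn[1], fold = 0.25, seed = 3)
    genes <- gpr_genes(net$gpr[[and_rxn[1]]])
    changed <- sum(prof$control$levels[genes] != prof$stress$levels[genes])
    expect_equal(changed, 1L)
  }
  # OR target: all transcripts scale so the sum scales
  or_rxn <- gprd[vapply(net$gpr[gprd], function(g) g$kind == "or", TRUE)]
  if (length(or_rxn)) {
    prof <- plant_regulation(net, or_rxn[1], fold = 0.25, seed = 3)
    genes <- gpr_genes(net$gpr[[or_rxn[1]]])
    expect_equal(unname(prof$stress$levels[genes] /
                          prof$control$levels[genes]),
                 rep(0.25, length(genes)))
  }
  expect_error(plant_regulation(net, "EX_sub", fold = 0.5), "without GPR")
})

test_that("the brute-force oracle matches its own closed forms", {
  # single bounded exchange: its own bounds
  one <- metabolic_network(
    metabolites = data.frame(id = "a"),
    reactions = data.frame(id = c("EX_in", "EX_out"),
                           lower = c(-7, 0), upper = c(0, 12)),
    stoichiometry = list(EX_in = c(a = -1), EX_out = c(a = -1)))
  o <- brute_force_flux_extrema(one)
  expect_equal(o$min, c(-7, 0))
  expect_equal(o$max, c(0, 7))
  # blocked reaction: (0, 0)
  blocked <- fva(set_bounds(one, "EX_in", 0, 0))
  ob <- brute_force_flux_extrema(set_bounds(one, "EX_in", 0, 0))
  expect_equal(c(ob$min[2], ob$max[2]), c(0, 0))
  expect_equal(blocked$min, ob$min, tolerance = 1e-9)
  # refuses oversized problems rather than hanging
  expect_error(brute_force_flux_extrema(make_toy_network(4, 3, seed = 1)),
               "refused")
})

test_that("cycle motifs splice into toy networks", {
  net <- make_toy_network(1, 2, seed = 2, planted_cycles = "three_cycle")
  expect_true(all(c("RDMBO", "DMBO", "ACLM") %in% net$reactions$id))
  cands <- find_cycle_candidates(net)
  expect_setequal(cands, c("RDMBO", "DMBO", "ACLM"))
  # growth is unaffected by the spliced loop
  expect_equal(fba(net)$objective_value, 10, tolerance = 1e-8)
})
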