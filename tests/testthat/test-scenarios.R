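test_that("an empty config is a no-op: scenario ranges equal plain FVA", {
  net <- branched_net()
  plain <- fva(net, c("EX_a", "EX_b"))
  got <- run_scenario(net, scenario_config(), c("EX_a", "EX_b"))
  expect_equal(got$min, plain$min, tolerance = 1e-9)
  expect_equal(got$max, plain$max, tolerance = 1e-9)
})

test_that("blocks, nutrient bounds, and growth pins compose", {
  net <- make_toy_network(2, 2, seed = 13)
  cfg <- scenario_config(
    blocked_reactions = "EX_P_1",
    nutrient_bounds = list(EX_sub = c(-5, 0)),
    pinned_growth = "max")
  got <- run_scenario(net, cfg, c("EX_P_1", "EX_P_2", "EX_cell"))
  expect_equal(c(got$min[1], got$max[1]), c(0, 0), tolerance = 1e-9)
  # halved uptake halves the attainable biomass-linked export
  expect_lte(max(got$max), 5 + 1e-6)
  # an impossible nutrient bound names its constraint group
  bad <- scenario_config(nutrient_bounds = list(EX_sub = c(0, 0)),
                         pinned_growth = 1)
  expect_error(run_scenario(net, bad, "EX_cell"), "pinned_growth")
})

test_that("gene deletions flow through scenarios", {
  net <- chain_net()
  cfg <- scenario_config(deleted_genes = c("g_r2a", "g_r2b"))
  got <- run_scenario(net, cfg, "EX_cell")
  expect_equal(c(got$min, got$max), c(0, 0), tolerance = 1e-9)
})

test_that("redox freedom enlarges cofactor-limited ranges and nothing else", {
  net <- redox_net()
  # without interconversion, every P needs one NADH from OX, and OX's NAD
  # must come back from RED: P production is stoichiometrically locked
  base <- fva(net, c("EX_p", "EX_q"))
  free <- redox_free_variant(net, pairs = list(nad = c("nad", "nadh")))
  rng <- fva(free, c("EX_p", "EX_q"))
  # feasible-set enlargement: no range shrinks
  expect_true(all(rng$max >= base$max - 1e-9))
  expect_true(all(rng$min <= base$min + 1e-9))
  # the NADH-consuming product gains capacity
  expect_gt(rng$max[rng$id == "EX_p"], base$max[base$id == "EX_p"] + 1)
  # missing cofactors are reported by id
  expect_error(redox_free_variant(chain_net()), "nad")
  # a network without cofactor coupling is untouched in its ranges
  aug <- redox_free_variant(
    add_reactions(chain_net(),
                  data.frame(id = "NADS", lower = 0, upper = 0),
                  list(NADS = c(nad = 1, nadh = 1))),
    pairs = list(nad = c("nad", "nadh")))
  rng2 <- fva(aug, c("EX_cell"))
  expect_equal(rng2$max, 10, tolerance = 1e-9)
})

test_that("cell-recycle bounds take a fraction of maximal uptake", {
  net <- chain_net()
  nb <- cell_recycle_bounds(net, "EX_sub", fraction = 0.8)
  expect_equal(nb$EX_sub[1], -8, tolerance = 1e-6)
  cfg <- scenario_config(nutrient_bounds = nb)
  got <- run_scenario(net, cfg, "EX_cell")
  expect_equal(got$max, 8, tolerance = 1e-5)
  # tightening nutrient bounds never increases max biomass
  expect_lte(fba(apply_scenario(net, cfg))$objective_value,
             fba(net)$objective_value + 1e-9)
})

test_that("yield space reports stoichiometrically forced yields and flags", {
  # linear toy: 1 substrate -> 1 product, yield 1 everywhere feasible
  net <- chain_net()
  cfg <- scenario_config(pinned_growth = 0)
  ys <- yield_space(net, cfg, nutrient = "EX_sub", products = "EX_cell",
                    resolution = 4)
  feas <- ys[ys$feasible & !ys$degenerate, ]
  expect_gt(nrow(feas), 0)
  expect_true(all(abs(feas$yield_EX_cell - 1) < 1e-5))
  # yield * nutrient magnitude recovers the product flux
  expect_true(all(abs(feas$yield_EX_cell * abs(feas$nutrient_flux) -
                        feas$EX_cell) < 1e-5))
  # zero product at zero uptake is degenerate, not an error
  expect_true(any(ys$degenerate | !ys$feasible) || all(ys$EX_cell > 0))

  # two products: the feasible region projects the branched polytope
  net2 <- branched_net()
  ys2 <- yield_space(net2, scenario_config(), nutrient = "EX_s",
                     products = c("EX_a", "EX_b"), resolution = 3)
  feas2 <- ys2[ys2$feasible & !ys2$degenerate, ]
  # every feasible point respects EX_a + EX_b = uptake magnitude
  expect_true(all(abs(feas2$EX_a + feas2$EX_b - abs(feas2$nutrient_flux))
                  < 1e-5))
})

test_that("knockout comparisons quantify production shifts", {
  # removing the EX_a cap by gene deletion on a competing route raises
  # the max of the other product
  net <- metabolic_network(
    metabolites = data.frame(id = c("s", "a", "b")),
    reactions = data.frame(
      id = c("EX_s", "R_sa", "R_sb", "EX_a", "EX_b"),
      lower = c(-10, 0, 0, 0, 0), upper = c(0, 1000, 1000, 1000, 1000),
      gpr = c("", "g_sa", "g_sb", "", "")),
    stoichiometry = list(EX_s = c(s = -1), R_sa = c(s = -1, a = 1),
                         R_sb = c(s = -1, b = 1), EX_a = c(a = -1),
                         EX_b = c(b = -1)))
  wt <- fva(net, "EX_b")
  ko <- fva(apply_gene_deletion(net, "g_sa"), "EX_b")
  # production minimum rises when the competing drain disappears
  expect_gte(ko$min, wt$min)
  expect_equal(ko$min, 0, tolerance = 1e-9)
  expect_equal(ko$max, wt$max, tolerance = 1e-9)
})

test_that("MFA comparison flags measurements outside the predicted range", {
  rng <- structure(data.frame(id = c("HK", "PFK", "PYK"),
                              min = c(0, 2, 1), max = c(1, 6, 3)),
                   class = c("flux_ranges", "data.frame"))
  res <- compare_to_mfa(rng, c(HK = 1.02, PFK = 4, PYK = 0.5, XYZ = 1))
  rep <- res$report
  expect_equal(rep$inside, c(FALSE, TRUE, FALSE))
  expect_equal(rep$distance, c(0.02, 0, 0.5), tolerance = 1e-12)
  expect_equal(res$unmatched, "XYZ")
  # randomized agreement with a naive interval check
  set.seed(12)
  for (i in 1:20) {
    lo <- sort(stats::runif(4, -5, 5)); hi <- lo + stats::runif(4, 0, 3)
    r <- structure(data.frame(id = letters[1:4], min = lo, max = hi),
                   class = c("flux_ranges", "data.frame"))
    v <- stats::setNames(stats::runif(4, -6, 8), letters[1:4])
    got <- compare_to_mfa(r, v)$report
    expect_equal(got$inside, unname(v >= lo - 1e-6 & v <= hi + 1e-6))
  }
})

test_that("growth-rate presets carry the standard pins", {
  g <- preset_growth_rates()
  expect_equal(unname(g["wild_type_acidogenic"]), 0.52)
  expect_equal(unname(g["defined_media"]), 0.07)
  cfg <- preset_co_gassing("HYD", "EX_but")
  expect_equal(cfg$blocked_reactions, "HYD")
  expect_equal(cfg$nutrient_bounds$EX_but, c(-10, 0))
  expect_s3_class(preset_redox_free(), "scenario_config")
})
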