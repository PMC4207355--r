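test_that("bound contraction follows the c_j multiplication rule", {
  ur <- structure(data.frame(id = c("A", "B", "C"),
                             min = c(0, -8, 0), max = c(20, 20, 5)),
                  class = c("flux_ranges", "data.frame"))
  reg <- regulate_bounds(ur, c(A = 0.5, B = 0.5, C = 1.2))
  # c = 0.5 on [0, 20] -> [0, 10]
  expect_equal(c(reg$lower_reg[1], reg$upper_reg[1]), c(0, 10))
  # reversible [-8, 20] -> [-4, 10]: reverse-direction capacity also halves
  expect_equal(c(reg$lower_reg[2], reg$upper_reg[2]), c(-4, 10))
  # c >= 1 never relaxes anything
  expect_equal(c(reg$lower_reg[3], reg$upper_reg[3]), c(0, 5))
  expect_equal(reg$active, c(TRUE, TRUE, FALSE))
  # a forced-flux reaction's positive lower bound scales down too
  reg2 <- regulate_bounds(structure(data.frame(id = "D", min = 2, max = 10),
                                    class = c("flux_ranges", "data.frame")),
                          c(D = 0.5))
  expect_equal(c(reg2$lower_reg, reg2$upper_reg), c(1, 5))
  expect_error(regulate_bounds(ur, c(A = 0)), "positive")
})

test_that("biomass attenuation measures the relative drop in max growth", {
  net <- chain_net()
  ur <- fva(net)
  # all c_j = 1: identical models, zero change
  reg1 <- regulate_bounds(ur, c(R1 = 1))
  att1 <- biomass_attenuation(net, reg1)
  expect_equal(att1$rel_change, 0, tolerance = 1e-9)
  # sole biomass-feeding path at c = 0.3: linear propagation, 70% drop
  reg2 <- regulate_bounds(ur, c(R1 = 0.3))
  att2 <- biomass_attenuation(net, reg2)
  expect_equal(att2$v_ur, 10, tolerance = 1e-9)
  expect_equal(att2$v_reg, 3, tolerance = 1e-9)
  expect_equal(att2$rel_change, 0.7, tolerance = 1e-9)
  # a model that cannot grow at all is an error
  dead <- set_bounds(net, "BIOMASS", 0, 0)
  reg_dead <- regulate_bounds(fva(dead), c(R1 = 1))
  expect_error(biomass_attenuation(dead, reg_dead), "cannot grow")
})

test_that("core-set membership requires an attained regulatory bound", {
  net <- chain_net()
  ur <- fva(net)
  # no active reactions: empty core set
  reg <- regulate_bounds(ur, c(R1 = 1))
  att <- biomass_attenuation(net, reg)
  ids <- identify_core_set(net, reg, att$v_reg)
  expect_length(ids$core$reactions, 0)
  # planted bottleneck: its contracted upper bound is attained at optimum
  reg2 <- regulate_bounds(ur, c(R1 = 0.4, R2 = 0.9))
  att2 <- biomass_attenuation(net, reg2)
  ids2 <- identify_core_set(net, reg2, att2$v_reg)
  expect_equal(ids2$core$reactions, "R1")
  expect_setequal(ids2$core$genes, "g_r1")
  # the regulated FVA at pinned biomass is reported for every reaction
  expect_setequal(ids2$fva_regulated$id, net$reactions$id)
})

test_that("corereg extracts a two-level hierarchy from sequential bottlenecks", {
  net <- chain_net()
  fit <- corereg(net, c(R1 = 0.4, R2 = 0.6))
  expect_s3_class(fit, "corereg")
  cs <- core_sets(fit)
  # k=1 recovers the binding bottleneck, k=2 the weaker one
  expect_equal(cs$k1$reactions, "R1")
  expect_equal(cs$k2$reactions, "R2")
  expect_equal(fit$iterations[[1]]$v_reg, 4, tolerance = 1e-8)
  expect_equal(fit$iterations[[2]]$v_reg, 6, tolerance = 1e-8)
  # regulated optimum never exceeds unregulated, at every order
  for (it in fit$iterations) expect_lte(it$v_reg, it$v_ur + 1e-9)
  # neutralizing core k weakly increases the next regulated optimum
  expect_gte(fit$iterations[[2]]$v_reg, fit$iterations[[1]]$v_reg - 1e-9)
  expect_equal(fit$terminated_reason, "attenuation_below_threshold")
  # the terminating minimal-effect iteration is still recorded
  last <- fit$iterations[[length(fit$iterations)]]
  expect_equal(last$core$biomass_effect, "minimal")
})

test_that("all-inert fold changes terminate immediately at k = 1", {
  net <- chain_net()
  fit <- corereg(net, c(R1 = 1, R2 = 1.5))
  expect_length(fit$iterations, 1)
  expect_equal(fit$terminated_reason, "attenuation_below_threshold")
  expect_length(core_sets(fit)$k1$reactions, 0)
  expect_equal(fit$iterations[[1]]$rel_change, 0, tolerance = 1e-9)
})

test_that("core sufficiency holds for reported sets and fails for broken ones", {
  fx <- make_bottleneck_fixture(17)
  cm <- build_fold_change_map(fx$network, fx$control, fx$stress)
  fit <- corereg(fx$network, cm)
  k1 <- core_sets(fit)$k1
  expect_true(fx$target %in% k1$reactions)
  ok <- verify_core_sufficiency(fx$network, cm, k1)
  expect_true(ok$sufficient)
  # trivially true when the core is every active reaction
  active <- names(cm)[attr(cm, "active")]
  expect_true(verify_core_sufficiency(fx$network, cm, active)$sufficient)
  # deliberately dropping the bottleneck breaks sufficiency
  broken <- setdiff(active, fx$target)
  bad <- verify_core_sufficiency(fx$network, cm, broken)
  expect_false(bad$sufficient)
  expect_gt(bad$max_deviation, 0.1)
})

test_that("fit methods print, summarize, and expose coefficients", {
  net <- chain_net()
  fit <- corereg(net, c(R1 = 0.4))
  expect_output(print(fit), "core set: R1")
  s <- summary(fit)
  expect_s3_class(s, "summary.corereg")
  expect_equal(s$table$k, seq_along(fit$iterations))
  expect_output(print(s), "attenuation")
  cf <- coef(fit)
  expect_equal(unname(cf["R1"]), 1)   # neutralized after extraction
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
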