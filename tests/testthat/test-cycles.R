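test_that("a duplicated reaction pair is detected and classified as equivalent", {
  fx <- loop_planted_net(1)
  cands <- find_cycle_candidates(fx$network)
  expect_setequal(cands, fx$planted)
  cyc <- null_space_cycles(fx$network, cands)
  expect_length(cyc, 1)
  expect_setequal(cyc[[1]]$support, fx$planted)
  expect_equal(classify_cycle(cyc[[1]], fx$network), "equivalent_pair")
})

test_that("an acyclic chain with closed exchanges has no candidates", {
  expect_length(find_cycle_candidates(chain_net()), 0)
})

test_that("three-reaction motif: all three flagged, one support-3 cycle, removal fixes it", {
  figA <- figure1_fixtures()$fig1A
  cands <- find_cycle_candidates(figA)
  expect_setequal(cands, c("RDMBO", "DMBO", "ACLM"))
  cyc <- null_space_cycles(figA, cands)
  expect_length(cyc, 1)
  expect_length(cyc[[1]]$support, 3)
  expect_equal(classify_cycle(cyc[[1]], figA), "multi_reaction")
  # removing the aggregate reaction eliminates the cycle in one pass
  res <- curate_until_closed(figA, data.frame(reaction_id = "ACLM",
                                              action = "remove"))
  expect_true(res$converged)
  expect_length(res$report[[1]]$candidates, 0)
})

test_that("seven-reaction motif resolves by one removal plus one restriction", {
  figC <- figure1_fixtures()$fig1C
  cands <- find_cycle_candidates(figC)
  expect_length(cands, 7)
  cyc <- null_space_cycles(figC, cands)
  expect_length(cyc, 1)
  expect_length(cyc[[1]]$support, 7)
  acts <- data.frame(reaction_id = c("MDH", "ASPA"),
                     action = c("remove", "forward_only"))
  res <- curate_until_closed(figC, acts)
  expect_true(res$converged)
  # directionality restriction was applied
  expect_equal(res$network$reactions$lower[
    res$network$reactions$id == "ASPA"], 0)
})

test_that("null-space vectors satisfy S v = 0 and enumerate all loop reactions", {
  for (s in 1:12) {
    fx <- loop_planted_net(s)
    cands <- find_cycle_candidates(fx$network)
    cyc <- null_space_cycles(fx$network, cands)
    S <- as.matrix(fx$network$S)
    support_union <- character()
    for (v in cyc) {
      full <- stats::setNames(numeric(ncol(S)), colnames(S))
      full[names(v$coefficients)] <- v$coefficients
      expect_lt(max(abs(S %*% full)), 1e-8)           # soundness
      expect_equal(unname(max(abs(v$coefficients))), 1)  # normalization
      support_union <- union(support_union, v$support)
    }
    # completeness against the independent oracle: loop reactions are
    # exactly those with nonzero extrema when all exchanges are closed
    closed <- set_bounds(fx$network, exchange_reactions(fx$network), 0, 0)
    if (nrow(closed$reactions) <= 12) {
      oracle <- brute_force_flux_extrema(closed)
      loopy <- oracle$id[abs(oracle$min) > 1e-6 | abs(oracle$max) > 1e-6]
      expect_setequal(support_union, loopy)
    }
  }
})

test_that("a support-2 vector over non-matching columns is not an equivalent pair", {
  # same conversion but different cofactor usage: columns differ
  net <- metabolic_network(
    metabolites = data.frame(id = c("a", "b", "nad", "nadh", "nadp", "nadph")),
    reactions = data.frame(id = c("R_nad", "R_nadp"),
                           lower = -1000, upper = 1000),
    stoichiometry = list(
      R_nad = c(a = -1, nad = -1, b = 1, nadh = 1),
      R_nadp = c(a = -1, nadp = -1, b = 1, nadph = 1)))
  fake <- list(support = c("R_nad", "R_nadp"),
               coefficients = c(R_nad = 1, R_nadp = -1))
  expect_equal(classify_cycle(fake, net), "multi_reaction")
})

test_that("Gibbs directionality rule follows the 4 kcal/mol threshold", {
  net <- metabolic_network(
    metabolites = data.frame(id = c("a", "b")),
    reactions = data.frame(id = c("R1", "R2", "R3", "R4"),
                           lower = -1000, upper = 1000),
    stoichiometry = list(R1 = c(a = -1, b = 1), R2 = c(a = -1, b = 1),
                         R3 = c(a = -1, b = 1), R4 = c(a = -1, b = 2)))
  recs <- data.frame(reaction_id = c("R1", "R2", "R3"),
                     dG = c(-10, -5, 6), error = c(2, 3, 1))
  acts <- gibbs_restrict(net, recs)
  expect_equal(acts$action[acts$reaction_id == "R1"], "forward_only")
  expect_false("R2" %in% acts$reaction_id)   # range reaches within 4 of zero
  expect_equal(acts$action[acts$reaction_id == "R3"], "reverse_only")
  # idempotence: after applying, the same records propose nothing new
  cured <- apply_curation(net, acts)
  expect_equal(nrow(gibbs_restrict(cured, recs)), 0)
  # a bound already consistent with the direction is never reversed
  fwd <- set_bounds(net, "R1", lower = 0)
  acts2 <- gibbs_restrict(fwd, recs[1, ])
  expect_equal(nrow(acts2), 0)
})

test_that("curation reports unresolved cycles instead of dropping them", {
  figA <- figure1_fixtures()$fig1A
  res <- curate_until_closed(figA, NULL)     # no actions supplied
  expect_false(res$converged)
  expect_gt(length(res$report[[1]]$candidates), 0)
  expect_error(apply_curation(figA, data.frame(reaction_id = "NOPE",
                                               action = "remove")),
               "absent reaction")
})
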