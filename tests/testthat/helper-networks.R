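# Shared hand-built fixtures.  Everything is constructed in code; no data
# files.

# A -> B -> C chain with uptake 10; unit yields throughout.
chain_net <- function(uptake = 10) example_chain_network(uptake = uptake)

# Branched network: sub splits into two products via independent routes.
branched_net <- function() {
  metabolic_network(
    metabolites = data.frame(id = c("s", "a", "b"), formula = "X", charge = 0),
    reactions = data.frame(
      id = c("EX_s", "R_sa", "R_sb", "EX_a", "EX_b"),
      lower = c(-10, 0, 0, 0, 0),
      upper = c(0, 1000, 1000, 8, 1000)),
    stoichiometry = list(
      EX_s = c(s = -1), R_sa = c(s = -1, a = 1), R_sb = c(s = -1, b = 1),
      EX_a = c(a = -1), EX_b = c(b = -1)))
}

# Glucose phosphorylation with real formulas; balanced as written.
hexokinase_mets <- function() {
  data.frame(
    id = c("glc", "atp", "g6p", "adp", "h", "h2o"),
    formula = c("C6H12O6", "C10H12N5O13P3", "C6H11O9P", "C10H12N5O10P2",
                "H", "H2O"),
    charge = c(0, -4, -2, -3, 1, 0),
    stringsAsFactors = FALSE)
}
hexokinase_sto <- function() c(glc = -1, atp = -1, g6p = 1, adp = 1, h = 1)

# Network with an NADH-limited product so redox freedom matters: each P
# costs two NADH but oxidation yields only one per A, so at most half the
# carbon can reach P unless NAD/NADH interconvert freely.
redox_net <- function() {
  metabolic_network(
    metabolites = data.frame(
      id = c("s", "a", "p", "q", "nad", "nadh"),
      formula = c("X", "X", "X", "X", "N", "N"), charge = 0),
    reactions = data.frame(
      id = c("EX_s", "OX", "RED", "ALT", "EX_p", "EX_q"),
      lower = c(-10, 0, 0, 0, 0, 0),
      upper = c(0, 1000, 1000, 1000, 1000, 1000)),
    stoichiometry = list(
      EX_s = c(s = -1),
      OX = c(s = -1, nad = -1, a = 1, nadh = 1),
      RED = c(a = -1, nadh = -2, p = 1, nad = 2),
      ALT = c(a = -1, q = 1),
      EX_p = c(p = -1), EX_q = c(q = -1)))
}

# Random loop-planted fixture: a toy network plus a reversed duplicate of
# one internal reaction, forming a two-reaction infeasible cycle.
loop_planted_net <- function(seed) {
  net <- make_toy_network(n_branches = 1 + seed %% 2, branch_length = 2,
                          seed = seed)
  internal <- grep("^R_", net$reactions$id, value = TRUE)
  pick <- internal[1 + seed %% length(internal)]
  sto <- reaction_stoichiometry(net, pick)
  dup <- paste0(pick, "_dup")
  net <- add_reactions(net,
    data.frame(id = dup, lower = -1000, upper = 0),
    stats::setNames(list(sto), dup))
  list(network = net, planted = c(pick, dup))
}
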