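test_that("formula parsing handles counts, multi-letter elements, R groups", {
  expect_equal(parse_formula("C6H12O6"), c(C = 6, H = 12, O = 6))
  expect_equal(parse_formula("CoC2"), c(C = 2, Co = 1))
  expect_equal(parse_formula("R"), c(R = 1))
  expect_null(parse_formula(NA))
  expect_error(parse_formula("6CH"), "cannot parse")
})

test_that("glucose phosphorylation balances; dropping H+ shows up exactly", {
  mets <- hexokinase_mets()
  rep1 <- check_balance(hexokinase_sto(), mets)
  expect_true(rep1$balanced)
  expect_true(all(abs(rep1$element_imbalance) < 1e-12))
  expect_equal(rep1$charge_imbalance, 0)

  no_h <- hexokinase_sto()[names(hexokinase_sto()) != "h"]
  rep2 <- check_balance(no_h, mets)
  expect_false(rep2$balanced)
  expect_equal(unname(rep2$element_imbalance["H"]), -1)
  expect_equal(rep2$charge_imbalance, -1)
})

test_that("balance report equals a brute-force atom tally on random reactions", {
  set.seed(42)
  els <- c("C", "H", "O", "N", "P")
  for (rep in 1:50) {
    k <- sample(2:5, 1)
    ids <- paste0("m", seq_len(k))
    counts <- matrix(sample(0:6, k * length(els), replace = TRUE), k,
                     dimnames = list(ids, els))
    charge <- sample(-2:2, k, replace = TRUE)
    mets <- data.frame(
      id = ids,
      formula = apply(counts, 1, function(ct)
        paste0(els[ct > 0], ct[ct > 0], collapse = "")),
      charge = charge, stringsAsFactors = FALSE)
    mets <- mets[nzchar(mets$formula), , drop = FALSE]
    if (nrow(mets) < 2) next
    sto <- stats::setNames(sample(c(-3:-1, 1:3), nrow(mets), replace = TRUE),
                           mets$id)
    got <- check_balance(sto, mets)
    # independent tally: loop over atoms one by one
    want <- stats::setNames(numeric(length(els)), els)
    for (m in mets$id) {
      f <- parse_formula(mets$formula[mets$id == m])
      for (e in names(f)) want[e] <- want[e] + sto[[m]] * f[[e]]
    }
    common <- names(got$element_imbalance)
    expect_equal(got$element_imbalance[common], want[common],
                 tolerance = 1e-12)
    expect_equal(got$charge_imbalance,
                 sum(sto * mets$charge[match(names(sto), mets$id)]))
  }
})

test_that("balance is linear in the coefficients", {
  mets <- hexokinase_mets()
  sto <- hexokinase_sto()
  sto["h"] <- 0.5                         # deliberately imbalanced
  sto <- sto[sto != 0]
  r1 <- check_balance(sto, mets)
  r3 <- check_balance(3 * sto, mets)
  expect_equal(r3$element_imbalance, 3 * r1$element_imbalance)
  expect_equal(r3$charge_imbalance, 3 * r1$charge_imbalance)
})

test_that("unknown formulas and R-group mismatches are unbalanceable", {
  mets <- data.frame(id = c("x", "y"), formula = c(NA, "C2"), charge = c(0, 0))
  r <- check_balance(c(x = -1, y = 1), mets)
  expect_true(r$unbalanceable)
  expect_match(r$reason, "unknown formula")

  mets2 <- data.frame(id = c("acpR", "acpR2"),
                      formula = c("C2R", "C2R2"), charge = 0)
  r2 <- check_balance(c(acpR = -1, acpR2 = 1), mets2)
  expect_true(r2$unbalanceable)
  expect_match(r2$reason, "R-group")
  expect_s3_class(rebalance(c(acpR = -1, acpR2 = 1), mets2),
                  "rebalance_failure")
})

test_that("rebalance restores balance with H+/H2O and fails cleanly otherwise", {
  mets <- hexokinase_mets()
  # drop the product proton: fixed by +1 H+ on the product side
  sto <- hexokinase_sto()[setdiff(names(hexokinase_sto()), "h")]
  fix <- rebalance(sto, mets)
  expect_false(inherits(fix, "rebalance_failure"))
  expect_equal(unname(fix$stoichiometry["h"]), 1)
  expect_true(fix$report$balanced)

  # remove one water from a hydrolysis-style balanced reaction
  hyd <- c(atp = -1, h2o = -1, adp = 1, h = 1)  # missing phosphate: P imbalance
  bad <- rebalance(hyd, mets)
  expect_s3_class(bad, "rebalance_failure")
  expect_true(any(grepl("P", bad$elements)))

  # randomized H/O/charge perturbations of a balanced reaction recover
  set.seed(7)
  for (i in 1:20) {
    sto <- hexokinase_sto()
    dh <- sample(-2:2, 1); dw <- sample(-2:2, 1)
    if (dh != 0) {
      sto["h"] <- sto["h"] + dh
      sto <- sto[sto != 0]
    }
    if (dw != 0) sto["h2o"] <- dw
    fix <- rebalance(sto, mets)
    expect_false(inherits(fix, "rebalance_failure"))
    expect_true(check_balance(fix$stoichiometry, mets)$balanced)
  }
})

test_that("network_balance skips exchanges and biomass", {
  net <- chain_net()
  reps <- network_balance(net)
  expect_false(any(grepl("^EX_", names(reps))))
  expect_false("BIOMASS" %in% names(reps))
  expect_true(all(vapply(reps, function(r) r$balanced, TRUE)))
})
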