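# Seed-deterministic synthetic networks, planted regulation, cycle motifs,
# and a brute-force flux oracle.  Everything here is first-class, tested
# code: the rest of the package is validated against these generators
# without any external model files.

local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Minimal linear-chain network
#'
#' Substrate exchange (uptake up to 10), a two-step conversion chain, a
#' biomass reaction and a product exchange; handy for examples and desk
#' checks (max biomass = uptake bound x unit yield = 10).
#'
#' @param uptake maximum substrate uptake (positive magnitude).
#' @return a [metabolic_network()].
#' @export
example_chain_network <- function(uptake = 10) {
  metabolic_network(
    metabolites = data.frame(id = c("sub", "mid", "pre", "cell"),
                             formula = c("X", "X", "X", "X"),
                             charge = 0),
    reactions = data.frame(
      id = c("EX_sub", "R1", "R2", "BIOMASS", "EX_cell"),
      lower = c(-uptake, 0, 0, 0, 0),
      upper = c(0, 1000, 1000, 1000, 1000),
      gpr = c("", "g_r1", "g_r2a or g_r2b", "", "")),
    stoichiometry = list(
      EX_sub = c(sub = -1),
      R1 = c(sub = -1, mid = 1),
      R2 = c(mid = -1, pre = 1),
      BIOMASS = c(pre = -1, cell = 1),
      EX_cell = c(cell = -1)),
    biomass = "BIOMASS")
}

#' Generate a branched toy metabolic network
#'
#' Builds a connected, feasible network: one substrate exchange (uptake
#' bound 10 mmol gDW^-1 h^-1), `n_branches` parallel internal pathways of
#' `branch_length` unit conversions each, a product exchange per branch,
#' and a biomass reaction draining one unit of every branch-end
#' metabolite.  GPR rules mix single genes with complexes (`and`) and
#' isozymes (`or`) when requested.  Metabolite formulas are the single
#' synthetic token `X`, so every internal reaction is balanced by
#' construction.  Output is fully determined by the arguments and `seed`.
#'
#' @param n_branches number of parallel pathways (>= 1).
#' @param branch_length conversions per pathway (>= 1).
#' @param with_isozymes,with_complexes include `or` / `and` rules.
#' @param planted_cycles character subset of
#'   `c("three_cycle", "seven_cycle")`: internal loop motifs spliced into
#'   the network (see [figure1_fixtures()]).
#' @param seed integer seed controlling the randomized GPR assignment.
#' @param uptake substrate uptake bound (magnitude).
#' @return a [metabolic_network()] with positive maximum biomass
#'   `uptake / n_branches`.
#' @export
make_toy_network <- function(n_branches = 2, branch_length = 2,
                             with_isozymes = TRUE, with_complexes = TRUE,
                             planted_cycles = character(), seed = 1,
                             uptake = 10) {
  stopifnot(n_branches >= 1, branch_length >= 1)
  bad <- setdiff(planted_cycles, c("three_cycle", "seven_cycle"))
  if (length(bad)) stop("unknown cycle motif: ", paste(bad, collapse = ", "))

  mets <- c("sub")
  rxn_id <- "EX_sub"; lo <- -uptake; up <- 0; gpr <- ""
  sto <- list(EX_sub = c(sub = -1))
  ends <- character(n_branches)
  local_seed(seed, {
    for (b in seq_len(n_branches)) {
      prev <- "sub"
      for (s in seq_len(branch_length)) {
        met <- sprintf("X_%d_%d", b, s)
        mets <- c(mets, met)
        id <- sprintf("R_%d_%d", b, s)
        rxn_id <- c(rxn_id, id); lo <- c(lo, 0); up <- c(up, 1000)
        sto[[id]] <- stats::setNames(c(-1, 1), c(prev, met))
        # GPR style: seeded draw among leaf / complex / isozyme pair
        style <- sample(c("leaf",
                          if (with_complexes) "and",
                          if (with_isozymes) "or"), 1L)
        g <- switch(style,
          leaf = sprintf("g_%s", id),
          and = sprintf("g_%s_s1 and g_%s_s2", id, id),
          or = sprintf("g_%s_i1 or g_%s_i2", id, id))
        gpr <- c(gpr, g)
        prev <- met
      }
      ends[b] <- prev
      ex <- sprintf("EX_P_%d", b)
      rxn_id <- c(rxn_id, ex); lo <- c(lo, 0); up <- c(up, 1000); gpr <- c(gpr, "")
      sto[[ex]] <- stats::setNames(-1, prev)
    }
  })
  mets <- c(mets, "cell")
  rxn_id <- c(rxn_id, "BIOMASS", "EX_cell")
  lo <- c(lo, 0, 0); up <- c(up, 1000, 1000); gpr <- c(gpr, "", "")
  sto$BIOMASS <- stats::setNames(c(rep(-1, n_branches), n_branches),
                                 c(ends, "cell"))
  sto$EX_cell <- c(cell = -1)

  net <- metabolic_network(
    metabolites = data.frame(id = mets, formula = "X", charge = 0),
    reactions = data.frame(id = rxn_id, lower = lo, upper = up, gpr = gpr),
    stoichiometry = sto, biomass = "BIOMASS")

  for (motif in planted_cycles) net <- splice_cycle_motif(net, motif)
  sol <- fba(net)
  if (sol$status != "optimal" || sol$objective_value <= 0)
    stop("fixture generation produced an infeasible or zero-growth network")
  net
}

# splice a loop motif into an existing network (new metabolites/reactions)
splice_cycle_motif <- function(net, motif) {
  m <- figure1_fixtures()[[switch(motif, three_cycle = "fig1A",
                                  seven_cycle = "fig1C")]]
  keep <- !m$reactions$is_exchange
  ids <- m$reactions$id[keep]
  add_reactions(net,
    data.frame(id = ids,
               lower = m$reactions$lower[keep],
               upper = m$reactions$upper[keep],
               gpr = m$reactions$gpr[keep]),
    stoich_list(m)[ids])
}

#' Loop-motif fixtures
#'
#' Two networks embedding a thermodynamically infeasible cycle in an
#' otherwise acyclic scaffold, named after their roles in cycle curation.
#' `fig1A`: an aggregate two-step reaction (`ACLM`) coexisting with its
#' two constituent steps (`RDMBO`, `DMBO`) forms a three-reaction loop;
#' removing the aggregate reaction eliminates it.  `fig1C`: a
#' seven-reaction loop through aspartate/fumarate/malate-like pool
#' metabolites (`ASPA`, `FH`, `MDH`, `AAT`, `GDH`, `SCS`, `SDH`
#' analogues); removing `MDH` and restricting `ASPA` to the forward
#' direction breaks it.  Both are synthetic stand-ins built to exercise
#' the detection machinery, not reconstructions of any real pathway.
#'
#' @return named list of [metabolic_network()] objects `fig1A`, `fig1C`.
#' @export
figure1_fixtures <- function() {
  # fig1A: A -> B -> C stepwise, plus aggregate A -> C, all reversible
  figA <- metabolic_network(
    metabolites = data.frame(id = c("alac", "dhmb", "kiv", "a_ext"),
                             formula = "X", charge = 0),
    reactions = data.frame(
      id = c("RDMBO", "DMBO", "ACLM", "EX_a"),
      lower = c(-1000, -1000, -1000, -10),
      upper = c(1000, 1000, 1000, 1000)),
    stoichiometry = list(
      RDMBO = c(alac = -1, dhmb = 1),
      DMBO = c(dhmb = -1, kiv = 1),
      ACLM = c(alac = -1, kiv = 1),
      EX_a = c(alac = -1)))
  # fig1C: ring of seven reversible conversions M1 -> ... -> M7 -> M1
  mets <- c("asp", "fum", "mal", "oaa", "cit", "akg", "glu")
  ids <- c("ASPA", "FH", "MDH", "CS", "ICDH", "GDH", "AAT")
  sto <- list()
  for (i in seq_len(7)) {
    sto[[ids[i]]] <- stats::setNames(c(-1, 1),
                                     c(mets[i], mets[i %% 7 + 1]))
  }
  sto$EX_asp <- c(asp = -1)
  figC <- metabolic_network(
    metabolites = data.frame(id = mets, formula = "X", charge = 0),
    reactions = data.frame(
      id = c(ids, "EX_asp"),
      lower = c(rep(-1000, 7), -10),
      upper = c(rep(1000, 7), 1000)),
    stoichiometry = sto)
  list(fig1A = figA, fig1C = figC)
}

#' Plant a known regulation signal into expression profiles
#'
#' Builds a control profile (seeded random levels around 100) and a stress
#' profile whose per-reaction fold change, recomputed through the GPR
#' min/sum semantics, equals `fold` exactly on the target reactions and is
#' >= 1 elsewhere.  Complex (`and`) targets have only their
#' minimum-expression subunit scaled; isozyme (`or`) targets have every
#' transcript scaled so the sum scales.
#'
#' @param network a [metabolic_network()].
#' @param targets reaction ids to down-regulate (all with fold change
#'   `fold`), or a named numeric vector of per-reaction fold changes in
#'   (0, 1); each target must carry a GPR.
#' @param fold planted fold change in (0, 1), used when `targets` is a
#'   character vector.
#' @param decoy_folds optional named vector of fold changes >= 1 applied to
#'   other GPR-bearing reactions (inert up-regulation decoys).
#' @param seed integer seed for the control levels.
#' @return list with elements `control` and `stress`
#'   ([expression_profile()] objects).
#' @export
plant_regulation <- function(network, targets, fold = NULL, decoy_folds = NULL,
                             seed = 1) {
  stopifnot(inherits(network, "metabolic_network"))
  if (is.character(targets)) {
    stopifnot(is.numeric(fold), length(fold) == 1L, fold > 0, fold < 1)
    targets <- stats::setNames(rep(fold, length(targets)), targets)
  }
  stopifnot(is.numeric(targets), !is.null(names(targets)),
            all(targets > 0), all(targets < 1))
  no_gpr <- names(targets)[vapply(network$gpr[names(targets)], is.null, TRUE)]
  if (length(no_gpr))
    stop("target reaction without GPR: ", paste(no_gpr, collapse = ", "))
  if (!is.null(decoy_folds) && any(decoy_folds < 1))
    stop("decoy folds must be >= 1")

  genes <- network$genes
  control <- local_seed(seed,
    stats::setNames(stats::runif(length(genes), 50, 150), genes))
  stress <- control

  scale_subtree <- function(node, f) {
    # multiply the subtree's evaluated level by f in the stress profile
    if (node$kind == "gene") {
      stress[node$gene] <<- stress[node$gene] * f
    } else if (node$kind == "or") {
      for (ch in node$children) scale_subtree(ch, f)
    } else {                                    # and: scale the binding child
      lv <- vapply(node$children, function(ch) gpr_level(ch, stress), 0)
      scale_subtree(node$children[[which.min(lv)]], f)
    }
  }
  for (id in names(targets)) scale_subtree(network$gpr[[id]], targets[[id]])
  for (id in names(decoy_folds)) {
    if (is.null(network$gpr[[id]]))
      stop("decoy reaction without GPR: ", id)
    scale_subtree(network$gpr[[id]], decoy_folds[[id]])
  }
  # shared genes could distort a planted fold; verify the round trip
  for (id in names(targets)) {
    got <- reaction_fold_change(network$gpr[[id]], control, stress)
    if (abs(got - targets[[id]]) > 1e-9)
      stop("planted regulation did not round-trip for ", id,
           " (genes shared across targets?)")
  }
  list(control = expression_profile("control", control),
       stress = expression_profile("stress", stress))
}

#' Brute-force flux extrema by vertex enumeration
#'
#' Independent oracle for FBA/FVA on desk-scale networks: enumerates every
#' vertex of the flux polytope \eqn{\{v : S v = 0,\ lb \le v \le ub\}}
#' basis-by-basis (all column subsets of size rank(S), all assignments of
#' the remaining reactions to their bounds) and reads off per-reaction
#' extrema.  Exponential in the reaction count, so refused above
#' `max_reactions`; deliberately shares no code with the simplex engine.
#'
#' @param network a [metabolic_network()] with finite bounds.
#' @param reactions reaction ids (default all).
#' @param max_reactions hard ceiling on network size (12).
#' @return data.frame with columns `id`, `min`, `max`.  An empty polytope
#'   (no vertex satisfies the constraints) is an error.
#' @export
brute_force_flux_extrema <- function(network, reactions = NULL,
                                     max_reactions = 12L) {
  stopifnot(inherits(network, "metabolic_network"))
  M <- nrow(network$reactions)
  if (M > max_reactions)
    stop("vertex enumeration refused above ", max_reactions, " reactions")
  S <- as.matrix(network$S)
  lb <- network$reactions$lower
  ub <- network$reactions$upper
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("vertex enumeration needs finite bounds")
  r <- qr(S)$rank
  vertices <- list()
  basis_sets <- if (r == 0L) list(integer(0)) else
    utils::combn(M, r, simplify = FALSE)
  for (B in basis_sets) {
    NB <- setdiff(seq_len(M), B)
    if (r > 0L) {
      qrB <- qr(S[, B, drop = FALSE])
      if (qrB$rank < r) next
    }
    grid <- if (length(NB))
      as.matrix(expand.grid(rep(list(c(1, 2)), length(NB)),
                            KEEP.OUT.ATTRS = FALSE))
    else matrix(0, 1, 0)                 # full-rank basis: single candidate
    vn <- matrix(0, length(NB), nrow(grid))
    for (i in seq_along(NB))
      vn[i, ] <- ifelse(grid[, i] == 1, lb[NB[i]], ub[NB[i]])
    v <- matrix(0, M, nrow(grid))
    v[NB, ] <- vn
    if (r > 0L) {
      rhs <- -S[, NB, drop = FALSE] %*% vn
      v[B, ] <- qr.coef(qrB, rhs)
    }
    resid <- S %*% v
    ok <- colSums(abs(resid)) < 1e-8 &
      apply(v >= lb - 1e-9 & v <= ub + 1e-9, 2, all) &
      !apply(is.na(v), 2, any)
    if (any(ok)) vertices[[length(vertices) + 1L]] <- v[, ok, drop = FALSE]
  }
  if (!length(vertices))
    stop("empty flux polytope: no vertex satisfies the constraints")
  V <- do.call(cbind, vertices)
  ids <- if (is.null(reactions)) network$reactions$id else reactions
  j <- match(ids, network$reactions$id)
  if (anyNA(j)) stop("unknown reaction: ", paste(ids[is.na(j)], collapse = ", "))
  data.frame(id = ids,
             min = apply(V[j, , drop = FALSE], 1, min),
             max = apply(V[j, , drop = FALSE], 1, max),
             stringsAsFactors = FALSE)
}

#' Random small network for property tests
#'
#' A random sparse stoichiometric matrix over a handful of internal
#' metabolites with bounds straddling zero (so the zero flux vector is
#' always feasible) and varied magnitudes; used to cross-check the LP
#' engine against [brute_force_flux_extrema()].
#'
#' @param seed integer seed.
#' @param n_reactions number of reactions (3-10).
#' @param n_metabolites number of internal metabolites.
#' @return a [metabolic_network()].
#' @export
random_toy_network <- function(seed, n_reactions = 6L, n_metabolites = 3L) {
  stopifnot(n_reactions >= 2L, n_reactions <= 10L, n_metabolites >= 1L)
  local_seed(seed, {
    mets <- sprintf("m%d", seq_len(n_metabolites))
    repeat {
      sto <- list()
      for (j in seq_len(n_reactions)) {
        k <- sample(1:min(3, n_metabolites), 1L)
        who <- sample(mets, k)
        coef <- sample(c(-2, -1, 1, 2), k, replace = TRUE)
        sto[[sprintf("r%d", j)]] <- stats::setNames(coef, who)
      }
      # every metabolite must appear in some reaction
      if (setequal(unique(unlist(lapply(sto, names))), mets)) break
    }
    lo <- -round(stats::runif(n_reactions, 1, 20), 1)
    up <- round(stats::runif(n_reactions, 1, 20), 1)
    metabolic_network(
      metabolites = data.frame(id = mets, formula = "X", charge = 0),
      reactions = data.frame(id = names(sto), lower = lo, upper = up),
      stoichiometry = sto)
  })
}

#' Single-bottleneck fixture for parameter-recovery tests
#'
#' A branched toy network plus expression profiles in which exactly one
#' reaction on the mandatory biomass path is severely down-regulated (the
#' planted bottleneck) while a second reaction on the same path gets a
#' mild, non-binding down-regulation and the remaining reactions are
#' mildly up-regulated decoys.  The bottleneck's contracted upper bound is
#' the unique binding constraint at the regulated biomass optimum, so the
#' primary core set must recover exactly it; the mild reaction makes the
#' core-sufficiency check non-trivial (its regulation is present in the
#' full model but absent from the core-only model).
#'
#' The binding fold defaults to `0.8 / n_branches`: with an uptake bound
#' of 10 shared by `n` branches, the optimal per-branch flux is `10 / n`
#' while the contracted upper bound is `10 * fold`, so the planted bound
#' binds iff `fold < 1 / n` and yields a 20% biomass attenuation at the
#' default.
#'
#' @param seed integer seed driving the branch layout, target choice, and
#'   expression noise.
#' @param fold planted fold change in (0, 1), or `NULL` for the binding
#'   default `0.8 / n_branches`.
#' @param mild_fold fold change of the non-binding secondary target.
#' @return list with `network`, `control`, `stress`, `target` (the
#'   planted bottleneck id), and `mild` (the non-binding regulated id).
#' @export
make_bottleneck_fixture <- function(seed, fold = NULL, mild_fold = 0.9) {
  params <- local_seed(seed, list(
    n_branches = sample(1:3, 1L),
    branch_length = sample(2:3, 1L),
    which_step = stats::runif(1)))
  net <- make_toy_network(n_branches = params$n_branches,
                          branch_length = params$branch_length,
                          seed = seed + 1000L)
  if (is.null(fold)) fold <- 0.8 / params$n_branches
  # bottleneck: a step on branch 1 (every branch feeds biomass, so branch-1
  # flux is mandatory at optimum); the mild target is a different step on
  # the same branch, whose contracted bound can never be reached
  step <- min(1L + floor(params$which_step * params$branch_length),
              params$branch_length)
  target <- sprintf("R_1_%d", step)
  mild <- sprintf("R_1_%d", if (step == 1L) 2L else step - 1L)
  decoys <- setdiff(grep("^R_", net$reactions$id, value = TRUE),
                    c(target, mild))
  decoys <- decoys[vapply(net$gpr[decoys], Negate(is.null), TRUE)]
  df <- if (length(decoys))
    stats::setNames(rep(1.5, length(decoys)), decoys) else NULL
  prof <- plant_regulation(net,
                           stats::setNames(c(fold, mild_fold), c(target, mild)),
                           decoy_folds = df, seed = seed + 2000L)
  list(network = net, control = prof$control, stress = prof$stress,
       target = target, mild = mild)
}
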