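#' Find reactions that can participate in thermodynamically infeasible cycles
#'
#' A thermodynamically infeasible cycle is an internal loop that can carry
#' flux with no net exchange with the environment.  With every exchange
#' reaction closed (bounds `[0, 0]`), only such loops can carry flux at
#' all, and any reaction in one can be driven to its bound.  FVA is run
#' with no biomass constraint and a reaction is a candidate iff one of its
#' flux extrema reaches the default bound magnitude `B` (within `tol`).
#'
#' @param network a [metabolic_network()].
#' @param bound_magnitude the "infinity" bound `B`; defaults to the
#'   network's `default_bound` attribute (1000).
#' @param tol band below `B` still counted as hitting the bound.
#' @return character vector of candidate reaction ids (possibly empty).
#' @export
find_cycle_candidates <- function(network, bound_magnitude = NULL, tol = 1e-6) {
  stopifnot(inherits(network, "metabolic_network"))
  if (is.null(bound_magnitude))
    bound_magnitude <- attr(network, "default_bound")
  closed <- set_bounds(network, exchange_reactions(network), 0, 0)
  rng <- fva(closed)
  hit <- abs(rng$max) >= bound_magnitude - tol |
         abs(rng$min) >= bound_magnitude - tol
  rng$id[hit]
}

#' Null-space basis of candidate cycle reactions
#'
#' Restricts the stoichiometric matrix to the candidate columns and
#' computes a basis of its null space by rank-revealing Gaussian
#' elimination: every basis vector is an internal flux mode
#' (\eqn{S v = 0}) supported on the candidates, i.e. a thermodynamically
#' infeasible cycle.  Each vector is scaled so its largest-magnitude
#' coefficient is +1.
#'
#' @param network a [metabolic_network()].
#' @param candidates reaction ids from [find_cycle_candidates()].
#' @param tol numerical rank tolerance.
#' @return list of cycle vectors, each a list with `support` (reaction
#'   ids) and `coefficients` (named numeric over the support), ordered by
#'   increasing support size (small cycles are reviewed first).  Empty if
#'   the submatrix has full column rank.
#' @export
null_space_cycles <- function(network, candidates, tol = 1e-9) {
  stopifnot(inherits(network, "metabolic_network"))
  if (!length(candidates)) stop("'candidates' must be nonempty")
  j <- match(candidates, network$reactions$id)
  if (anyNA(j)) stop("unknown reaction: ",
                     paste(candidates[is.na(j)], collapse = ", "))
  A <- as.matrix(network$S[, j, drop = FALSE])
  ns <- nullspace_basis(A, tol = tol)
  if (!ncol(ns)) return(list())
  out <- lapply(seq_len(ncol(ns)), function(k) {
    v <- ns[, k]
    v <- v / v[which.max(abs(v))]          # largest-magnitude coefficient +1
    supp <- abs(v) > 1e-8
    list(support = candidates[supp],
         coefficients = stats::setNames(v[supp], candidates[supp]))
  })
  out[order(vapply(out, function(cyc) length(cyc$support), 0L))]
}

# null space of A by reduced row echelon form with partial pivoting:
# free columns generate the standard (sparse) basis vectors.
nullspace_basis <- function(A, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  R <- A
  pivot_col <- integer(0)
  row <- 1L
  scale <- max(abs(A), 1)
  for (col in seq_len(n)) {
    if (row > m) break
    p <- which.max(abs(R[row:m, col])) + row - 1L
    if (abs(R[p, col]) <= tol * scale) next
    if (p != row) R[c(p, row), ] <- R[c(row, p), ]
    R[row, ] <- R[row, ] / R[row, col]
    others <- setdiff(seq_len(m), row)
    R[others, ] <- R[others, ] - outer(R[others, col], R[row, ])
    pivot_col <- c(pivot_col, col)
    row <- row + 1L
  }
  free <- setdiff(seq_len(n), pivot_col)
  if (!length(free)) return(matrix(0, n, 0))
  basis <- matrix(0, n, length(free))
  for (k in seq_along(free)) {
    f <- free[k]
    basis[f, k] <- 1
    if (length(pivot_col))
      basis[pivot_col, k] <- -R[seq_along(pivot_col), f]
  }
  basis
}

#' Classify a cycle as an equivalent pair or a multi-reaction loop
#'
#' Two-reaction cycles arise from duplicated reactions: both convert the
#' same reactants to products (or vice versa) with the same co-factors,
#' differing only in orientation, so their stoichiometric columns are
#' equal or negated.  Everything else is a genuine multi-reaction loop.
#'
#' @param cycle a cycle vector from [null_space_cycles()].
#' @param network a [metabolic_network()].
#' @param tol tolerance on the column comparison.
#' @return `"equivalent_pair"` or `"multi_reaction"`.
#' @export
classify_cycle <- function(cycle, network, tol = 1e-8) {
  stopifnot(inherits(network, "metabolic_network"))
  if (length(cycle$support) != 2L) return("multi_reaction")
  a <- as.numeric(network$S[, cycle$support[1]])
  b <- as.numeric(network$S[, cycle$support[2]])
  if (max(abs(a - b)) < tol || max(abs(a + b)) < tol) "equivalent_pair"
  else "multi_reaction"
}

#' Directionality restrictions from reaction Gibbs free energies
#'
#' A reaction whose Gibbs free-energy range (value +/- error) lies
#' entirely more than `threshold` kcal/mol away from zero is restricted
#' to the direction the free energy specifies: strongly negative means
#' forward-only (lower bound raised to 0), strongly positive means
#' reverse-only (upper bound lowered to 0).  Bounds already consistent
#' with the free-energy direction are never touched, so the operation is
#' idempotent.
#'
#' @param network a [metabolic_network()].
#' @param records data.frame with columns `reaction_id`, `dG` (kcal/mol)
#'   and `error` (half-width, kcal/mol, non-negative).
#' @param threshold kcal/mol distance from zero required to act; 4 by the
#'   standard convention.
#' @return data.frame of curation actions with columns `reaction_id`,
#'   `action` (`"forward_only"` or `"reverse_only"`), `rationale`.
#' @export
gibbs_restrict <- function(network, records, threshold = 4) {
  stopifnot(inherits(network, "metabolic_network"))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  stopifnot(all(c("reaction_id", "dG", "error") %in% names(records)))
  if (any(records$error < 0)) stop("Gibbs error half-widths must be >= 0")
  j <- match(records$reaction_id, network$reactions$id)
  if (anyNA(j)) stop("unknown reaction: ",
                     paste(records$reaction_id[is.na(j)], collapse = ", "))
  acts <- list()
  for (k in seq_len(nrow(records))) {
    dg <- records$dG[k]; err <- records$error[k]
    id <- records$reaction_id[k]
    lo <- network$reactions$lower[j[k]]; up <- network$reactions$upper[j[k]]
    if (dg + err < -threshold && lo < 0) {
      acts[[length(acts) + 1L]] <- data.frame(
        reaction_id = id, action = "forward_only",
        rationale = sprintf("dG range [%g, %g] kcal/mol entirely below -%g",
                            dg - err, dg + err, threshold),
        stringsAsFactors = FALSE)
    } else if (dg - err > threshold && up > 0) {
      acts[[length(acts) + 1L]] <- data.frame(
        reaction_id = id, action = "reverse_only",
        rationale = sprintf("dG range [%g, %g] kcal/mol entirely above +%g",
                            dg - err, dg + err, threshold),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(acts))
    return(data.frame(reaction_id = character(), action = character(),
                      rationale = character(), stringsAsFactors = FALSE))
  do.call(rbind, acts)
}

#' Apply curation actions to a network
#'
#' @param network a [metabolic_network()].
#' @param actions data.frame with columns `reaction_id` and `action`
#'   (`"remove"`, `"forward_only"`, `"reverse_only"`), applied in order;
#'   an action naming an absent reaction is an error.
#' @return the curated network.
#' @export
apply_curation <- function(network, actions) {
  stopifnot(inherits(network, "metabolic_network"))
  if (is.null(actions) || nrow(as.data.frame(actions)) == 0L) return(network)
  actions <- as.data.frame(actions, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(actions))) {
    id <- actions$reaction_id[k]
    if (!id %in% network$reactions$id)
      stop("curation action on absent reaction: ", id)
    network <- switch(actions$action[k],
      remove = remove_reactions(network, id),
      forward_only = set_bounds(network, id,
        lower = max(0, network$reactions$lower[match(id, network$reactions$id)])),
      reverse_only = set_bounds(network, id,
        upper = min(0, network$reactions$upper[match(id, network$reactions$id)])),
      stop("unknown curation action: ", actions$action[k]))
  }
  network
}

#' Apply curation actions and verify the model is cycle-free
#'
#' Applies the ordered action list, then iterates cycle detection
#' ([find_cycle_candidates()] then [null_space_cycles()]), reporting the
#' cycles remaining after each pass.  The loop terminates when no
#' candidates remain, or when cycles persist with no pending action - the
#' survivors are reported, never silently dropped, because choosing
#' between removal and directionality restriction needs evidence the
#' package cannot supply.
#'
#' @param network a [metabolic_network()].
#' @param actions data.frame of curation actions as in [apply_curation()].
#' @return list with `network` (curated), `converged` (TRUE iff no cycle
#'   candidates remain), and `report`: a list of per-pass records, each
#'   with `candidates` and `cycles`.
#' @export
curate_until_closed <- function(network, actions = NULL) {
  net <- apply_curation(network, actions)
  passes <- list()
  repeat {
    cands <- find_cycle_candidates(net)
    if (!length(cands)) {
      passes[[length(passes) + 1L]] <- list(candidates = character(),
                                            cycles = list())
      return(list(network = net, converged = TRUE, report = passes))
    }
    cycles <- null_space_cycles(net, cands)
    passes[[length(passes) + 1L]] <- list(candidates = cands, cycles = cycles)
    # all supplied actions were applied up front; persisting cycles have no
    # pending action, so report and stop
    return(list(network = net, converged = FALSE, report = passes))
  }
}
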