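#' Flux balance analysis
#'
#' Maximizes (or minimizes) the flux of one reaction subject to
#' steady-state mass balance \eqn{\sum_j S_{ij} v_j = 0} for every
#' metabolite \eqn{i} and the flux bounds
#' \eqn{v_j^{min} \le v_j \le v_j^{max}}.  The canonical use maximizes the
#' biomass reaction, whose optimal flux is the maximum attainable growth
#' rate.
#'
#' @param network a [metabolic_network()].
#' @param objective reaction id to optimize; defaults to the network's
#'   biomass reaction.
#' @param sense `"max"` or `"min"`.
#' @return an object of class `"lp_solution"`: list with `status`
#'   (`"optimal"`, `"infeasible"`, or `"unbounded"`), `objective_value`,
#'   and `fluxes` (named vector over all reactions; `NA` unless optimal).
#'   Infeasibility and unboundedness are reported in `status`, never as
#'   errors.
#' @examples
#' net <- example_chain_network()
#' fba(net)
#' @export
fba <- function(network, objective = network$biomass, sense = c("max", "min")) {
  stopifnot(inherits(network, "metabolic_network"))
  sense <- match.arg(sense)
  if (is.null(objective)) stop("no objective: network has no biomass reaction")
  j <- match(objective, network$reactions$id)
  if (is.na(j)) stop("unknown objective reaction: ", objective)
  M <- nrow(network$reactions)
  obj <- numeric(M); obj[j] <- 1
  res <- lp_solve(network$S, rep(0, nrow(network$S)),
                  network$reactions$lower, network$reactions$upper,
                  obj, maximize = (sense == "max"))
  fluxes <- stats::setNames(res$x, network$reactions$id)
  structure(list(status = res$status,
                 objective_value = res$objective,
                 objective = objective, sense = sense, fluxes = fluxes),
            class = "lp_solution")
}

#' @export
print.lp_solution <- function(x, ...) {
  cat("LP solution (", x$sense, " ", x$objective, "): status ", x$status,
      if (x$status == "optimal") paste0(", objective ",
                                        format(x$objective_value, digits = 7)),
      "\n", sep = "")
  invisible(x)
}

#' Flux variability analysis
#'
#' For each target reaction solves two LPs, maximizing and minimizing its
#' flux subject to mass balance and bounds (optionally with additional
#' pinned constraints), giving the attainable flux interval
#' \eqn{[v_j^{min}, v_j^{max}]}.
#'
#' @param network a [metabolic_network()].
#' @param reactions reaction ids to analyze (default: all).
#' @param fixed named list of extra pins applied before the analysis: each
#'   element is either a single value (bound fixed to it) or a
#'   `c(lower, upper)` interval, named by reaction id.
#' @return a data.frame of class `"flux_ranges"` with columns `id`, `min`,
#'   `max`.  If the pinned constraint set is infeasible, an error names
#'   the first pin whose addition makes the model infeasible.
#' @examples
#' net <- example_chain_network()
#' fva(net)
#' @export
fva <- function(network, reactions = NULL, fixed = NULL) {
  stopifnot(inherits(network, "metabolic_network"))
  if (is.null(reactions)) reactions <- network$reactions$id
  j <- match(reactions, network$reactions$id)
  if (anyNA(j)) stop("unknown reaction: ",
                     paste(reactions[is.na(j)], collapse = ", "))
  net <- network
  if (!is.null(fixed) && length(fixed)) {
    if (is.null(names(fixed)) || any(!nzchar(names(fixed))))
      stop("'fixed' must be a named list of pins")
    for (id in names(fixed)) {
      v <- fixed[[id]]
      if (length(v) == 1L) v <- c(v, v)
      net_try <- set_bounds(net, id, lower = v[1], upper = v[2])
      chk <- lp_solve(net_try$S, rep(0, nrow(net_try$S)),
                      net_try$reactions$lower, net_try$reactions$upper,
                      numeric(nrow(net_try$reactions)), maximize = TRUE)
      if (chk$status == "infeasible")
        stop("infeasible pin: constraint on ", sQuote(id),
             " conflicts with the model")
      net <- net_try
    }
  }
  S <- net$S; nr <- nrow(S)
  lo <- net$reactions$lower; up <- net$reactions$upper
  M <- nrow(net$reactions)
  mins <- maxs <- numeric(length(j))
  for (k in seq_along(j)) {
    obj <- numeric(M); obj[j[k]] <- 1
    rmax <- lp_solve(S, rep(0, nr), lo, up, obj, maximize = TRUE)
    rmin <- lp_solve(S, rep(0, nr), lo, up, obj, maximize = FALSE)
    if (rmax$status == "infeasible" || rmin$status == "infeasible")
      stop("infeasible model during FVA")
    maxs[k] <- rmax$objective
    mins[k] <- rmin$objective
  }
  structure(data.frame(id = reactions, min = mins, max = maxs,
                       stringsAsFactors = FALSE),
            class = c("flux_ranges", "data.frame"))
}

#' Simulate gene deletions through GPR rules
#'
#' Evaluates every reaction's GPR with the deleted genes set to absent
#' (complex subunits are a conjunction, isozymes a disjunction); reactions
#' left without enzymatic support get bounds `[0, 0]`.  Reactions with no
#' GPR are untouched.
#'
#' @param network a [metabolic_network()].
#' @param deleted character vector of gene ids; ids not in the network
#'   raise a warning and are ignored.
#' @return the constrained network.
#' @export
apply_gene_deletion <- function(network, deleted) {
  stopifnot(inherits(network, "metabolic_network"))
  unknown <- setdiff(deleted, network$genes)
  if (length(unknown)) {
    warning("ignoring unknown gene id: ", paste(unknown, collapse = ", "))
    deleted <- intersect(deleted, network$genes)
  }
  if (!length(deleted)) return(network)
  blocked <- vapply(network$gpr, function(g)
    !is.null(g) && !gpr_eval(g, deleted), TRUE)
  if (any(blocked))
    network <- set_bounds(network, network$reactions$id[blocked], 0, 0)
  network
}

#' Rescale fluxes to a reference uptake
#'
#' Multiplies every flux (or flux range) by `target / |reference flux|`,
#' the standard normalization to, e.g., a glucose uptake of
#' 10 mmol gDW^-1 h^-1.  Steady state is preserved because scaling is
#' linear.
#'
#' @param x an `"lp_solution"` or `"flux_ranges"` object.
#' @param reference reaction id whose flux sets the scale.
#' @param target desired magnitude of the reference flux after scaling.
#' @return object of the same class with all fluxes rescaled.
#' @export
normalize_fluxes <- function(x, reference, target = 10) {
  if (inherits(x, "lp_solution")) {
    ref <- x$fluxes[[reference]]
    if (is.na(ref) || abs(ref) < 1e-12)
      stop("reference flux of ", sQuote(reference), " is zero; cannot normalize")
    f <- target / abs(ref)
    x$fluxes <- x$fluxes * f
    x$objective_value <- x$objective_value * f
    return(x)
  }
  if (inherits(x, "flux_ranges")) {
    row <- match(reference, x$id)
    if (is.na(row)) stop("unknown reference reaction: ", reference)
    ref <- max(abs(c(x$min[row], x$max[row])))
    if (ref < 1e-12)
      stop("reference flux of ", sQuote(reference), " is zero; cannot normalize")
    f <- target / ref
    x$min <- x$min * f
    x$max <- x$max * f
    return(x)
  }
  stop("x must be an 'lp_solution' or 'flux_ranges' object")
}
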