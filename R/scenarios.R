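#' Scenario configuration
#'
#' Bundles the constraint edits that define a simulation condition:
#' fermentation phase, growth pin, nutrient bounds, reaction blocks, gene
#' deletions, redox freedom, and extra reactions (e.g. a glycerol uptake
#' route added for a co-feed study).
#'
#' @param phase `"acidogenic"` (growth on the base nutrients) or
#'   `"solventogenic"` (acids supplied as additional nutrients, acid and
#'   amino-acid export capped; the caller supplies the affected exchange
#'   ids via `nutrient_bounds` / `export_blocks`).
#' @param pinned_growth `NULL` (no pin), `"max"` (pin at the FBA optimum),
#'   or a growth rate in h^-1.
#' @param nutrient_bounds named list: exchange id -> single value (both
#'   bounds) or `c(lower, upper)`.
#' @param blocked_reactions reaction ids forced to zero flux.
#' @param deleted_genes gene ids knocked out through the GPRs.
#' @param redox_free add free cofactor interconversion (see
#'   [redox_free_variant()]).
#' @param extra_reactions `NULL`, or `list(reactions = <data.frame>,
#'   stoichiometry = <named list>)` appended via [add_reactions()].
#' @param export_blocks exchange ids restricted to uptake only
#'   (upper bound 0), the solventogenic-phase export constraint.
#' @return an object of class `"scenario_config"`.
#' @export
scenario_config <- function(phase = c("acidogenic", "solventogenic"),
                            pinned_growth = NULL,
                            nutrient_bounds = list(),
                            blocked_reactions = character(),
                            deleted_genes = character(),
                            redox_free = FALSE,
                            extra_reactions = NULL,
                            export_blocks = character()) {
  phase <- match.arg(phase)
  if (!is.null(pinned_growth) && !identical(pinned_growth, "max"))
    stopifnot(is.numeric(pinned_growth), length(pinned_growth) == 1L,
              pinned_growth >= 0)
  structure(list(phase = phase, pinned_growth = pinned_growth,
                 nutrient_bounds = nutrient_bounds,
                 blocked_reactions = blocked_reactions,
                 deleted_genes = deleted_genes, redox_free = redox_free,
                 extra_reactions = extra_reactions,
                 export_blocks = export_blocks),
            class = "scenario_config")
}

# apply a scenario in stages, naming the stage that breaks feasibility
apply_scenario <- function(network, config) {
  stopifnot(inherits(network, "metabolic_network"),
            inherits(config, "scenario_config"))
  feasible <- function(net) {
    r <- lp_solve(net$S, rep(0, nrow(net$S)), net$reactions$lower,
                  net$reactions$upper, numeric(nrow(net$reactions)))
    r$status != "infeasible"
  }
  stage <- function(net, what) {
    if (!feasible(net))
      stop("infeasible scenario: constraint group ", sQuote(what),
           " makes the model infeasible")
    net
  }
  net <- network
  if (!is.null(config$extra_reactions))
    net <- stage(add_reactions(net, config$extra_reactions$reactions,
                               config$extra_reactions$stoichiometry),
                 "extra_reactions")
  if (length(config$deleted_genes))
    net <- stage(apply_gene_deletion(net, config$deleted_genes),
                 "deleted_genes")
  if (length(config$blocked_reactions))
    net <- stage(set_bounds(net, config$blocked_reactions, 0, 0),
                 "blocked_reactions")
  if (length(config$export_blocks)) {
    ids <- config$export_blocks
    j <- match(ids, net$reactions$id)
    if (anyNA(j)) stop("unknown reaction: ", paste(ids[is.na(j)], collapse = ", "))
    net <- stage(set_bounds(net, ids,
                            upper = pmin(net$reactions$upper[j], 0)),
                 "export_blocks")
  }
  for (id in names(config$nutrient_bounds)) {
    v <- config$nutrient_bounds[[id]]
    if (length(v) == 1L) v <- c(v, v)
    net <- stage(set_bounds(net, id, v[1], v[2]),
                 paste0("nutrient_bounds[", id, "]"))
  }
  if (isTRUE(config$redox_free)) net <- stage(redox_free_variant(net),
                                              "redox_free")
  if (!is.null(config$pinned_growth)) {
    if (is.null(net$biomass)) stop("cannot pin growth: no biomass reaction")
    v <- if (identical(config$pinned_growth, "max")) {
      sol <- fba(net)
      if (sol$status != "optimal")
        stop("infeasible scenario: constraint group 'pinned_growth' ",
             "(FBA for the growth maximum failed)")
      sol$objective_value
    } else config$pinned_growth
    net <- stage(set_bounds(net, net$biomass, lower = v * (1 - 1e-6),
                            upper = max(v, net$reactions$upper[
                              match(net$biomass, net$reactions$id)])),
                 "pinned_growth")
  }
  net
}

#' Run a simulation scenario
#'
#' Applies the configuration (gene deletions, blocks, nutrient bounds,
#' redox freedom, growth pin) and reports the FVA production range of each
#' product exchange, mirroring how fermentation conditions are assessed:
#' negative values indicate consumption, positive production.
#'
#' @param network a [metabolic_network()].
#' @param config a [scenario_config()].
#' @param products exchange reaction ids to report.
#' @return a `"flux_ranges"` data.frame over `products`.
#' @export
run_scenario <- function(network, config, products) {
  net <- apply_scenario(network, config)
  fva(net, reactions = products)
}

#' Add free redox-cofactor interconversion
#'
#' Appends reversible, bound-magnitude interconversion reactions
#' NAD <-> NADH and NADP <-> NADPH, removing the reducing-equivalent
#' constraint from the model.  Protons/electrons are deliberately not
#' tracked by these pseudo-reactions (a sink convention): they express
#' "reducing equivalents are free", not a chemical mechanism.
#'
#' @param network a [metabolic_network()].
#' @param pairs named list of cofactor id pairs to couple; each element is
#'   `c(oxidized_id, reduced_id)`.
#' @return the network with one reversible interconversion reaction per
#'   pair (`RF_<oxidized>`); an error lists any absent cofactor ids.
#' @export
redox_free_variant <- function(network,
                               pairs = list(nad = c("nad", "nadh"),
                                            nadp = c("nadp", "nadph"))) {
  stopifnot(inherits(network, "metabolic_network"))
  need <- unique(unlist(pairs))
  absent <- setdiff(need, network$metabolites$id)
  if (length(absent))
    stop("cofactor metabolite(s) absent from the network: ",
         paste(absent, collapse = ", "))
  B <- attr(network, "default_bound")
  ids <- paste0("RF_", vapply(pairs, `[`, "", 1L))
  sto <- lapply(pairs, function(p) stats::setNames(c(-1, 1), p))
  names(sto) <- ids
  add_reactions(network,
                data.frame(id = ids, lower = -B, upper = B,
                           stringsAsFactors = FALSE),
                sto)
}

#' Uptake bounds for nutrient-limited (cell recycle) conditions
#'
#' Cell-recycle fermentations limit ammonia and phosphate availability;
#' this helper computes, for each listed exchange, `fraction` of its
#' maximal uptake magnitude under wild-type maximum growth (the FVA
#' minimum, uptake being negative) and returns pins suitable for
#' `nutrient_bounds`.
#'
#' @param network a [metabolic_network()].
#' @param exchanges exchange reaction ids to limit.
#' @param fraction fraction of the maximal uptake magnitude retained
#'   (default 0.8).
#' @return named list of `c(lower, upper)` bounds.
#' @export
cell_recycle_bounds <- function(network, exchanges, fraction = 0.8) {
  stopifnot(inherits(network, "metabolic_network"))
  sol <- fba(network)
  if (sol$status != "optimal") stop("wild-type FBA failed")
  net <- set_bounds(network, network$biomass,
                    lower = sol$objective_value * (1 - 1e-6))
  rng <- fva(net, reactions = exchanges)
  out <- lapply(seq_len(nrow(rng)), function(k) {
    lo <- fraction * rng$min[k]           # uptake is negative
    j <- match(rng$id[k], network$reactions$id)
    c(lo, network$reactions$upper[j])
  })
  names(out) <- rng$id
  out
}

#' Yield space over a product grid
#'
#' Maps the attainable product-yield region at a fixed growth rate: FVA
#' gives each product's range; over a grid of product flux combinations,
#' each point pins the products, minimizes the nutrient uptake, and
#' reports yields as product flux divided by the minimum nutrient flux
#' magnitude.  Infeasible grid points are flagged, as are degenerate
#' points where the minimal nutrient flux is zero.
#'
#' @param network a [metabolic_network()].
#' @param config a [scenario_config()]; its `pinned_growth` should be the
#'   experimentally reported growth rate.
#' @param nutrient exchange id of the limiting nutrient (uptake negative).
#' @param products 2 or 3 product exchange ids.
#' @param resolution grid points per product axis.
#' @return data.frame with one row per grid point: pinned product fluxes,
#'   `nutrient_flux` (minimal uptake, negative), per-product `yield_*`
#'   columns (mol product per mol nutrient), `feasible`, `degenerate`.
#' @export
yield_space <- function(network, config, nutrient, products, resolution = 5) {
  stopifnot(length(products) %in% c(1:3), resolution >= 2)
  net <- apply_scenario(network, config)
  rng <- fva(net, reactions = products)
  axes <- lapply(seq_along(products), function(k)
    seq(rng$min[k], rng$max[k], length.out = resolution))
  names(axes) <- products
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  jn <- match(nutrient, net$reactions$id)
  if (is.na(jn)) stop("unknown nutrient exchange: ", nutrient)
  n <- nrow(grid)
  nut <- rep(NA_real_, n); feas <- logical(n); degen <- logical(n)
  yields <- matrix(NA_real_, n, length(products),
                   dimnames = list(NULL, paste0("yield_", products)))
  slack <- function(v) 1e-6 * max(1, abs(v))
  for (i in seq_len(n)) {
    neti <- net
    ok <- TRUE
    for (k in seq_along(products)) {
      v <- grid[i, k]
      neti <- tryCatch(set_bounds(neti, products[k],
                                  v - slack(v), v + slack(v)),
                       error = function(e) { ok <<- FALSE; neti })
    }
    if (!ok) next
    # minimal uptake magnitude: maximize the (negative) nutrient flux
    sol <- fba(neti, objective = nutrient, sense = "max")
    if (sol$status != "optimal") { feas[i] <- FALSE; next }
    feas[i] <- TRUE
    nut[i] <- sol$objective_value
    m <- abs(nut[i])
    if (m < 1e-9) { degen[i] <- TRUE; next }
    yields[i, ] <- as.numeric(grid[i, ]) / m
  }
  out <- cbind(grid, nutrient_flux = nut, as.data.frame(yields),
               feasible = feas, degenerate = degen)
  rownames(out) <- NULL
  out
}

#' Compare model flux ranges with measured fluxes
#'
#' @param fva_ranges a `"flux_ranges"` data.frame (model predictions).
#' @param mfa_values named numeric vector of measured fluxes (e.g. from
#'   13C metabolic flux analysis), normalized to the same substrate
#'   uptake as the model.
#' @param tol tolerance treated as inside the range.
#' @return list with `report` (data.frame: `id`, `measured`, `min`, `max`,
#'   `inside`, `distance` to the nearest endpoint when outside) and
#'   `unmatched` (measured ids absent from the ranges).
#' @export
compare_to_mfa <- function(fva_ranges, mfa_values, tol = 1e-6) {
  stopifnot(all(c("id", "min", "max") %in% names(fva_ranges)),
            is.numeric(mfa_values), !is.null(names(mfa_values)))
  shared <- intersect(names(mfa_values), fva_ranges$id)
  unmatched <- setdiff(names(mfa_values), shared)
  j <- match(shared, fva_ranges$id)
  lo <- fva_ranges$min[j]; up <- fva_ranges$max[j]
  v <- mfa_values[shared]
  inside <- v >= lo - tol & v <= up + tol
  dist <- ifelse(inside, 0, pmax(lo - v, v - up))
  list(report = data.frame(id = shared, measured = unname(v),
                           min = lo, max = up, inside = unname(inside),
                           distance = unname(dist), stringsAsFactors = FALSE),
       unmatched = unmatched)
}

#' Named scenario presets
#'
#' Ready-made [scenario_config()] constructors for the standard
#' fermentation analyses.  Each takes the network-specific reaction ids it
#' needs, since id conventions differ between models.
#'
#' `preset_co_gassing`: CO sparging inhibits the hydrogenase (flux forced
#' to zero) while butyrate is taken up as an additional nutrient, forcing
#' the acidogenic-to-solventogenic transition.
#'
#' `preset_cell_recycle`: ammonia/phosphate uptake restricted to a
#' fraction of the maximal FVA ranges (see [cell_recycle_bounds()]),
#' solventogenic phase.
#'
#' `preset_redox_free`: free NAD(P)/NAD(P)H interconversion, used to probe
#' which products are limited by reducing-equivalent availability.
#'
#' `preset_growth_rates` returns the named growth-rate pins (h^-1) used by
#' the standard comparisons: wild type acidogenic 0.52, hydrogenase
#' inhibited 0.47, wild type solventogenic/complex media 0.32, dPTB and
#' dHBD 0.18, dACK 0.184, dADC 0.182, cell recycle 0.17, defined media
#' 0.07.
#'
#' @param hydrogenase,butyrate_exchange,exchanges reaction ids in the
#'   target network.
#' @param network a [metabolic_network()] (where ranges must be computed).
#' @param butyrate_uptake maximal butyrate uptake magnitude.
#' @param fraction see [cell_recycle_bounds()].
#' @param growth growth pin passed through.
#' @name scenario_presets
NULL

#' @rdname scenario_presets
#' @export
preset_co_gassing <- function(hydrogenase, butyrate_exchange,
                              butyrate_uptake = 10, growth = "max") {
  scenario_config(
    phase = "acidogenic",
    pinned_growth = growth,
    blocked_reactions = hydrogenase,
    nutrient_bounds = stats::setNames(
      list(c(-abs(butyrate_uptake), 0)), butyrate_exchange))
}

#' @rdname scenario_presets
#' @export
preset_cell_recycle <- function(network, exchanges, fraction = 0.8,
                                growth = "max") {
  scenario_config(
    phase = "solventogenic",
    pinned_growth = growth,
    nutrient_bounds = cell_recycle_bounds(network, exchanges, fraction))
}

#' @rdname scenario_presets
#' @export
preset_redox_free <- function(growth = NULL) {
  scenario_config(phase = "acidogenic", pinned_growth = growth,
                  redox_free = TRUE)
}

#' @rdname scenario_presets
#' @export
preset_growth_rates <- function() {
  c(wild_type_acidogenic = 0.52, hydrogenase_inhibited = 0.47,
    wild_type_complex = 0.32, dPTB = 0.18, dACK = 0.184, dADC = 0.182,
    dHBD = 0.18, cell_recycle = 0.17, defined_media = 0.07)
}
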