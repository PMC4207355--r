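#' Contract unregulated flux bounds by expression fold changes
#'
#' For every reaction with a down-regulation signal (\eqn{c_j < 1}), both
#' unregulated FVA bounds are multiplied by \eqn{c_j}:
#' \deqn{v_j^{U,R} = v_j^{U,UR} \cdot c_j, \qquad
#'       v_j^{L,R} = v_j^{L,UR} \cdot c_j.}
#' For a reversible reaction the (negative) lower bound shrinks toward
#' zero, lowering the maximum attainable flux in the reverse direction;
#' the rule is applied unconditionally, so a strictly positive lower bound
#' also scales down.  Reactions with \eqn{c_j \ge 1} or no data keep their
#' unregulated bounds.
#'
#' @param ur a `"flux_ranges"` data.frame from [fva()] computed on the
#'   unregulated model with no biomass constraint (so the ranges are the
#'   widest attainable bounds).
#' @param c_map a [fold_change_map()] (or named positive vector).
#' @return a data.frame of class `"regulated_bounds"` with columns `id`,
#'   `lower_ur`, `upper_ur`, `lower_reg`, `upper_reg`, `active`, `c`.
#' @export
regulate_bounds <- function(ur, c_map) {
  stopifnot(inherits(ur, "flux_ranges") || all(c("id", "min", "max") %in% names(ur)))
  cv <- as.numeric(c_map)
  names(cv) <- names(c_map)
  if (anyNA(cv) || any(cv <= 0)) stop("fold changes must be positive (c_j > 0)")
  cj <- stats::setNames(rep(1, nrow(ur)), ur$id)
  shared <- intersect(names(cv), ur$id)
  cj[shared] <- cv[shared]
  active <- cj < 1
  out <- data.frame(id = ur$id,
                    lower_ur = ur$min, upper_ur = ur$max,
                    lower_reg = ifelse(active, ur$min * cj, ur$min),
                    upper_reg = ifelse(active, ur$max * cj, ur$max),
                    active = unname(active), c = unname(cj),
                    stringsAsFactors = FALSE)
  structure(out, class = c("regulated_bounds", "data.frame"))
}

# swap a network's bounds for a two-column bound table
with_bounds <- function(network, ids, lower, upper) {
  set_bounds(network, ids, lower, upper)
}

#' Biomass attenuation under regulation
#'
#' Maximizes biomass twice - under the unregulated bounds and under the
#' regulated bounds - and reports the relative change
#' \eqn{(v^{max,UR} - v^{max,R}) / v^{max,UR}}.
#'
#' @param network a [metabolic_network()] with a biomass reaction.
#' @param reg a `"regulated_bounds"` table from [regulate_bounds()].
#' @return list with `v_ur`, `v_reg`, `rel_change`.  An unregulated
#'   optimum of zero (a model that cannot grow at all) is an error.
#' @export
biomass_attenuation <- function(network, reg) {
  stopifnot(inherits(network, "metabolic_network"))
  if (is.null(network$biomass)) stop("network has no biomass reaction")
  net_ur <- with_bounds(network, reg$id, reg$lower_ur, reg$upper_ur)
  net_r <- with_bounds(network, reg$id, reg$lower_reg, reg$upper_reg)
  s_ur <- fba(net_ur)
  s_r <- fba(net_r)
  if (s_ur$status != "optimal" || s_r$status != "optimal")
    stop("model infeasible under ",
         if (s_ur$status != "optimal") "unregulated" else "regulated", " bounds")
  if (s_ur$objective_value <= 1e-12)
    stop("unregulated maximum biomass is zero; the model cannot grow")
  list(v_ur = s_ur$objective_value, v_reg = s_r$objective_value,
       rel_change = (s_ur$objective_value - s_r$objective_value) /
         s_ur$objective_value)
}

#' Identify the core set of order k
#'
#' Runs FVA on the regulated model with biomass pinned at its regulated
#' maximum; a regulated (active) reaction whose achieved flux bound
#' coincides with the imposed regulatory bound - upper with upper, or
#' lower with lower - is a binding constraint and enters the core set.
#'
#' @param network a [metabolic_network()] with a biomass reaction.
#' @param reg a `"regulated_bounds"` table.
#' @param v_reg the regulated maximum biomass from [biomass_attenuation()].
#' @param k order of the core set being extracted.
#' @param tol equality tolerance: bounds match when
#'   `|achieved - imposed| <= max(tol, tol * |imposed|)`.
#' @param pin_slack relative slack on the biomass pin (the lower bound is
#'   set to `v_reg * (1 - pin_slack)`) to avoid solver-level
#'   infeasibility of an exact equality.
#' @return list with `core` (list: `k`, `reactions`, `genes`,
#'   `biomass_effect`, filled in by the caller) and `fva_regulated` (the
#'   pinned-biomass flux ranges).
#' @export
identify_core_set <- function(network, reg, v_reg, k = 1L,
                              tol = 1e-6, pin_slack = 1e-6) {
  stopifnot(inherits(network, "metabolic_network"))
  net_r <- with_bounds(network, reg$id, reg$lower_reg, reg$upper_reg)
  pin <- v_reg * (1 - pin_slack)
  net_r <- set_bounds(net_r, network$biomass, lower = pin)
  rng <- tryCatch(fva(net_r), error = function(e)
    stop("infeasible biomass pin at v = ", format(v_reg), ": ",
         conditionMessage(e)))
  hit <- function(achieved, imposed)
    abs(achieved - imposed) <= pmax(tol, tol * abs(imposed))
  ord <- match(reg$id, rng$id)
  binding <- reg$active &
    (hit(rng$max[ord], reg$upper_reg) | hit(rng$min[ord], reg$lower_reg))
  members <- reg$id[binding]
  genes <- unique(unlist(lapply(network$gpr[members], gpr_genes),
                         use.names = FALSE))
  if (is.null(genes)) genes <- character()
  list(core = list(k = as.integer(k), reactions = members, genes = genes,
                   biomass_effect = NA_character_),
       fva_regulated = rng)
}

#' Hierarchical core regulatory set extraction (CoreReg)
#'
#' The method asks which few reactions' expression-derived bound
#' contractions are, by themselves, responsible for the regulated model's
#' behavior.  Starting from the unregulated flux ranges (FVA with no
#' biomass constraint), it repeats for k = 1, 2, ...:
#' contract bounds by the current fold changes ([regulate_bounds()]);
#' measure the biomass attenuation ([biomass_attenuation()]); pin biomass
#' at the regulated optimum and collect the regulated reactions whose
#' bounds are binding ([identify_core_set()]) - the core set of order k;
#' then neutralize those reactions' fold changes (\eqn{c_j \gets 1}) and
#' continue, so later iterations expose subordinate focal points of
#' regulation.  Iteration stops once the attenuation falls below
#' `threshold` (the final, minimal-effect core set is still recorded),
#' when a core set comes back empty, or at `max_k`.
#'
#' @param network a [metabolic_network()] with a biomass reaction.
#' @param c_map a [fold_change_map()] (or named positive vector) of
#'   per-reaction fold changes.
#' @param threshold relative biomass-attenuation threshold below which the
#'   remaining regulation is considered immaterial; 2% by convention.
#' @param max_k maximum core-set order to extract.
#' @param tol bound-equality tolerance, see [identify_core_set()].
#' @return an object of class `"corereg"`: list with `iterations` (one
#'   record per k: `k`, `v_ur`, `v_reg`, `rel_change`, `core`),
#'   `fva_regulated` (pinned-biomass ranges at k = 1), `fva_unregulated`,
#'   `terminated_reason` (`"attenuation_below_threshold"`,
#'   `"empty_core_set"`, or `"max_order_reached"`), `threshold`, and the
#'   final neutralized fold-change state.
#' @examples
#' net <- example_chain_network()
#' fit <- corereg(net, c(R1 = 0.5))
#' fit
#' @export
corereg <- function(network, c_map, threshold = 0.02, max_k = 6L, tol = 1e-6) {
  stopifnot(inherits(network, "metabolic_network"))
  if (is.null(network$biomass)) stop("network has no biomass reaction")
  if (!(is.numeric(threshold) && threshold >= 0 && threshold < 1))
    stop("'threshold' must be a fraction in [0, 1)")
  cv <- stats::setNames(as.numeric(c_map), names(c_map))
  if (anyNA(cv) || any(cv <= 0)) stop("fold changes must be positive (c_j > 0)")

  ur <- fva(network)                      # Step 1: widest attainable bounds
  iterations <- list()
  fva_reg1 <- NULL
  reason <- "max_order_reached"
  k <- 1L
  repeat {
    reg <- regulate_bounds(ur, cv)
    att <- biomass_attenuation(network, reg)
    ids <- identify_core_set(network, reg, att$v_reg, k = k, tol = tol)
    if (k == 1L) fva_reg1 <- ids$fva_regulated
    minimal <- att$rel_change < threshold
    core <- ids$core
    core$biomass_effect <- if (minimal) "minimal" else "substantial"
    iterations[[k]] <- list(k = k, v_ur = att$v_ur, v_reg = att$v_reg,
                            rel_change = att$rel_change, core = core)
    if (minimal) { reason <- "attenuation_below_threshold"; break }
    if (!length(core$reactions)) { reason <- "empty_core_set"; break }
    cv[core$reactions] <- 1               # neutralize this order's regulation
    k <- k + 1L
    if (k > max_k) { reason <- "max_order_reached"; break }
  }
  structure(list(iterations = iterations, fva_unregulated = ur,
                 fva_regulated = fva_reg1, terminated_reason = reason,
                 threshold = threshold, final_fold_changes = cv,
                 network = network, call = match.call()),
            class = "corereg")
}

#' Check that a core set alone reproduces the regulated flux ranges
#'
#' The method's defining property: applying the bound contraction only to
#' the core-set members must reproduce, at that model's own maximum
#' biomass, the flux ranges of the fully regulated model for every
#' reaction.
#'
#' @param network a [metabolic_network()] with a biomass reaction.
#' @param c_map the full [fold_change_map()] used for the fit.
#' @param core a core set (the `core` element of a `corereg` iteration, or
#'   a character vector of reaction ids).
#' @param tol per-bound tolerance, as in [identify_core_set()].
#' @param pin_slack relative slack on the biomass pins.
#' @return list with `sufficient` (logical), `max_deviation` (largest
#'   elementwise difference between the two sets of flux ranges), and
#'   `ranges` (per-reaction comparison table).
#' @export
verify_core_sufficiency <- function(network, c_map, core,
                                    tol = 1e-6, pin_slack = 1e-6) {
  stopifnot(inherits(network, "metabolic_network"))
  members <- if (is.character(core)) core else core$reactions
  cv <- stats::setNames(as.numeric(c_map), names(c_map))
  ur <- fva(network)

  ranges_at_max <- function(cvec) {
    reg <- regulate_bounds(ur, cvec)
    net <- with_bounds(network, reg$id, reg$lower_reg, reg$upper_reg)
    vmax <- fba(net)$objective_value
    net <- set_bounds(net, network$biomass, lower = vmax * (1 - pin_slack))
    fva(net)
  }
  full <- ranges_at_max(cv)
  cv_core <- cv
  cv_core[setdiff(names(cv_core), members)] <- 1
  core_only <- ranges_at_max(cv_core)

  ord <- match(full$id, core_only$id)
  dev <- pmax(abs(full$min - core_only$min[ord]),
              abs(full$max - core_only$max[ord]))
  cmp <- data.frame(id = full$id,
                    min_full = full$min, max_full = full$max,
                    min_core = core_only$min[ord], max_core = core_only$max[ord],
                    deviation = dev, stringsAsFactors = FALSE)
  list(sufficient = max(dev) <= max(tol, tol * max(abs(c(full$min, full$max)))),
       max_deviation = max(dev), ranges = cmp)
}

#' @export
print.corereg <- function(x, ...) {
  cat("CoreReg fit: ", length(x$iterations), " iteration(s), terminated: ",
      x$terminated_reason, "\n", sep = "")
  for (it in x$iterations) {
    eff <- it$core$biomass_effect
    cat(sprintf("  k=%d  v_biom(UR)=%.6g  v_biom(R)=%.6g  attenuation=%.2f%%%s\n",
                it$k, it$v_ur, it$v_reg, 100 * it$rel_change,
                if (identical(eff, "minimal")) "  [minimal effect on biomass]" else ""))
    cat("     core set: ",
        if (length(it$core$reactions))
          paste(it$core$reactions, collapse = ", ") else "(empty)", "\n",
        sep = "")
  }
  invisible(x)
}

#' @export
summary.corereg <- function(object, ...) {
  its <- object$iterations
  tab <- data.frame(
    k = vapply(its, function(i) i$k, 0L),
    v_biomass_unregulated = vapply(its, function(i) i$v_ur, 0),
    v_biomass_regulated = vapply(its, function(i) i$v_reg, 0),
    attenuation = vapply(its, function(i) i$rel_change, 0),
    n_core_reactions = vapply(its, function(i) length(i$core$reactions), 0L),
    biomass_effect = vapply(its, function(i) i$core$biomass_effect, ""),
    stringsAsFactors = FALSE)
  genes <- lapply(its, function(i) i$core$genes)
  names(genes) <- paste0("k", tab$k)
  structure(list(table = tab, genes = genes,
                 terminated_reason = object$terminated_reason,
                 threshold = object$threshold),
            class = "summary.corereg")
}

#' @export
print.summary.corereg <- function(x, ...) {
  cat("CoreReg summary (termination threshold ",
      100 * x$threshold, "% biomass attenuation)\n", sep = "")
  print(x$table, row.names = FALSE)
  cat("terminated:", x$terminated_reason, "\n")
  for (k in names(x$genes))
    if (length(x$genes[[k]]))
      cat("  ", k, " genes: ", paste(x$genes[[k]], collapse = ", "), "\n",
          sep = "")
  invisible(x)
}

#' @export
coef.corereg <- function(object, ...) object$final_fold_changes

#' Core sets of a CoreReg fit
#'
#' @param object a `"corereg"` fit.
#' @return named list of core sets (`k1`, `k2`, ...), each with elements
#'   `k`, `reactions`, `genes`, `biomass_effect`.
#' @export
core_sets <- function(object) {
  stopifnot(inherits(object, "corereg"))
  out <- lapply(object$iterations, function(i) i$core)
  names(out) <- paste0("k", vapply(out, function(cs) cs$k, 0L))
  out
}

#' @export
plot.corereg <- function(x, ...) {
  its <- x$iterations
  k <- vapply(its, function(i) i$k, 0L)
  ratio <- vapply(its, function(i) i$v_reg / i$v_ur, 0)
  graphics::barplot(stats::setNames(ratio, paste0("k=", k)),
                    ylim = c(0, 1), ylab = "regulated / unregulated max biomass",
                    xlab = "core-set order", ...)
  graphics::abline(h = 1 - x$threshold, lty = 2)
  invisible(x)
}
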