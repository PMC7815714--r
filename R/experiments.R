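# Harvested species still extant at the baseline: the calibrated set. A
# harvested species that never persisted in the unfished community has no
# biomass to fish.
harvested_alive <- function(params, baseline) {
  hv <- params$species[params$harvested]
  hv[baseline$B[hv] > baseline$threshold]
}

#' Percent biomass change between two states
#'
#' `change = (after/before - 1) * 100`. Exactly -100 for species driven to
#' zero; `NA` (undefined) where the before-state biomass is zero.
#'
#' @param before,after Non-negative biomass vectors of equal length.
#' @return Numeric vector of percentages.
#' @examples
#' biomass_change(c(2, 1, 4), c(2, 0, 6))  # 0, -100, +50
#' @export
biomass_change <- function(before, after) {
  if (length(before) != length(after)) {
    stop("before/after lengths differ", call. = FALSE)
  }
  ifelse(before > 0, (after / before - 1) * 100, NA_real_)
}

#' Calibrate fishing mortalities to a biomass-reduction target
#'
#' Finds, for every harvested species simultaneously, the per-day fishing
#' mortality `F_max` such that the post-perturbation state (integrating for
#' `T` days from the unfished baseline with all mortalities applied at once)
#' leaves each species at `(1 - target/100)` of its baseline biomass. The
#' nominal `target = 100` case is one-sided by construction: it seeks the
#' *smallest* mortality driving the residual biomass *below* 1% of baseline
#' -- a 100% nominal reduction need not mean extinction, because the biomass
#' removed each day is biomass produced a day earlier.
#'
#' Harvested species are dynamically coupled (most strongly: co-harvested
#' producers under a fully shared carrying capacity), so every evaluation is
#' one coupled simulation with the whole current mortality vector. For
#' two-sided targets the update is a damped per-species secant step on
#' log-mortality versus log-biomass, which self-corrects as the
#' co-mortalities move. For the one-sided 100% target the update is a
#' bracket search on each species' smallest over-fishing mortality, with a
#' bracket side discarded and rebuilt whenever a later evaluation
#' contradicts it.
#'
#' @param params An `atn_params` (its `F_max` is ignored; the baseline is
#'   unfished).
#' @param target_reduction Percent reduction in (0, 100].
#' @param species Character vector of species to calibrate (default: the
#'   harvested set).
#' @param B_init Initial biomasses for the baseline equilibration (default
#'   [atn_initial_biomass()] with `seed`).
#' @param seed Seed for the default initial biomasses.
#' @param T Days integrated per evaluation.
#' @param spinup Days of unfished baseline equilibration (twice the
#'   perturbation window by default, so slow competitive transients have
#'   settled before the reference state is taken).
#' @param tol Relative tolerance on the achieved biomass (two-sided
#'   targets).
#' @param max_iter Iteration cap; non-convergence is an error naming the
#'   offending species.
#' @param F_init Optional warm-start mortality vector (e.g. the result for
#'   a lower target); default 0.05 per species.
#' @param on_fail `"error"` (default) stops on non-convergence naming the
#'   offending species; `"best"` returns the best iterate seen together
#'   with `converged = FALSE` and the per-species achieved fractions, for
#'   workflows that report the achieved reduction rather than abort.
#'   Co-harvested producers under a fully shared carrying capacity admit no
#'   joint interior equilibrium, so exact simultaneous targets can be
#'   genuinely unattainable on some webs.
#' @param rtol,atol Solver tolerances used for the search evaluations.
#' @param baseline Optional precomputed unfished `atn_equilibrium`.
#' @return List: `F_max` (named vector), `achieved` (achieved fraction of
#'   baseline biomass per species), `target_fraction`, `converged`,
#'   `baseline`.
#' @export
calibrate_fmax <- function(params, target_reduction, species = NULL,
                           B_init = NULL, seed = 1L, T = 3650,
                           spinup = 2 * T, tol = 0.01, max_iter = 80,
                           F_init = NULL, on_fail = c("error", "best"),
                           rtol = 1e-8, atol = 1e-10, baseline = NULL) {
  on_fail <- match.arg(on_fail)
  if (target_reduction <= 0 || target_reduction > 100) {
    stop("target_reduction must be in (0, 100]", call. = FALSE)
  }
  p0 <- set_fmax(params, 0)
  if (is.null(baseline)) {
    if (is.null(B_init)) B_init <- atn_initial_biomass(params, seed)
    baseline <- equilibrate(p0, B_init, T = spinup)
  }
  if (is.null(species)) species <- params$species[params$harvested]
  if (length(species) == 0) stop("no species to calibrate", call. = FALSE)
  Bb <- baseline$B[species]
  if (any(Bb <= baseline$threshold)) {
    stop("species extinct at baseline: ",
         paste(species[Bb <= baseline$threshold], collapse = ", "), call. = FALSE)
  }
  n_sp <- length(species)
  target_frac <- if (target_reduction >= 100) 0.01 else 1 - target_reduction / 100
  target_B <- target_frac * Bb
  eval_F <- function(Fv) {
    eq <- equilibrate(set_fmax(p0, stats::setNames(Fv, species)),
                      baseline$B, T = T, rtol = rtol, atol = atol)
    eq$B[species]
  }
  F0 <- if (is.null(F_init)) {
    stats::setNames(rep(0.05, n_sp), species)
  } else {
    stats::setNames(pmax(as.numeric(F_init[species]), 1e-9), species)
  }

  if (target_reduction >= 100) {
    cal_one_sided(eval_F, F0, target_B, Bb, species, max_iter,
                  target_frac, baseline, on_fail)
  } else {
    cal_secant(eval_F, F0, target_B, Bb, species, max_iter, tol,
               target_frac, baseline, on_fail)
  }
}

# Damped joint secant on log F vs log B. The cap of one doubling per step
# keeps the iteration from leaping across the steep exclusion regime of
# co-harvested producers.
cal_secant <- function(eval_F, F0, target_B, Bb, species, max_iter, tol,
                       target_frac, baseline, on_fail = "error") {
  floorB <- 1e-9
  within_tol <- function(got) {
    abs(got - target_B) <= tol * pmax(target_B, baseline$threshold)
  }
  F_prev <- F0 * 1.1
  B_prev <- pmax(eval_F(F_prev), floorB)
  F_cur <- ifelse(B_prev > target_B, F0 * 2, F0 / 2)
  B_cur <- B_prev
  best <- list(err = Inf, F = F_cur, B = B_cur)
  for (it in seq_len(max_iter)) {
    B_cur <- pmax(eval_F(F_cur), floorB)
    ok <- within_tol(B_cur)
    worst <- max(abs(B_cur - target_B) / target_B)
    if (worst < best$err) best <- list(err = worst, F = F_cur, B = B_cur)
    if (all(ok)) {
      return(list(F_max = F_cur, achieved = B_cur / Bb,
                  target_fraction = target_frac, converged = TRUE,
                  baseline = baseline))
    }
    slope <- (log(B_cur) - log(B_prev)) / (log(F_cur) - log(F_prev))
    step <- (log(target_B) - log(B_cur)) / slope
    bad <- !is.finite(step) | slope >= 0
    step[bad] <- ifelse(B_cur[bad] > target_B[bad], log(1.5), -log(1.5))
    step <- pmin(pmax(step, -log(2)), log(2))
    # freeze species already on target: moving them only perturbs the rest
    step[ok] <- 0
    F_next <- pmin(pmax(F_cur * exp(step), 1e-9), 1e3)
    F_prev <- F_cur
    B_prev <- B_cur
    F_cur <- F_next
  }
  if (on_fail == "best") {
    return(list(F_max = best$F, achieved = best$B / Bb,
                target_fraction = target_frac, converged = FALSE,
                baseline = baseline))
  }
  off <- species[!within_tol(B_cur)]
  stop("F_max calibration did not converge for: ",
       paste(off, collapse = ", "), call. = FALSE)
}

# One-sided search for the smallest mortality pushing each species below its
# residual target. lo tracks the largest under-fishing mortality seen, hi
# the smallest over-fishing one; a side contradicted under the current
# co-mortalities is discarded and rebuilt.
cal_one_sided <- function(eval_F, F0, target_B, Bb, species, max_iter,
                          target_frac, baseline, on_fail = "error") {
  n_sp <- length(species)
  lo <- stats::setNames(rep(0, n_sp), species)
  hi <- stats::setNames(rep(Inf, n_sp), species)
  F_cur <- F0
  B_cur <- NULL
  for (it in seq_len(max_iter)) {
    B_cur <- eval_F(F_cur)
    over <- B_cur <= target_B
    stale_hi <- !over & F_cur >= hi
    hi[stale_hi] <- Inf
    stale_lo <- over & F_cur <= lo
    lo[stale_lo] <- 0
    lo[!over] <- pmax(lo[!over], F_cur[!over])
    hi[over] <- pmin(hi[over], F_cur[over])
    bracketed <- is.finite(hi) & lo > 0
    if (all(over) && all(bracketed) && all(hi / lo <= 1.15)) {
      return(list(F_max = F_cur, achieved = B_cur / Bb,
                  target_fraction = target_frac, converged = TRUE,
                  baseline = baseline))
    }
    F_cur <- ifelse(
      is.finite(hi),
      ifelse(lo > 0, sqrt(lo * hi), hi / 4),
      pmax(F_cur, 1e-6) * 3
    )
    # once every species is bracketed tightly, evaluate at the upper edges
    # so the returned vector jointly over-fishes everyone
    if (all(bracketed) && all(hi / lo <= 1.15)) F_cur <- hi
  }
  if (on_fail == "best") {
    return(list(F_max = ifelse(is.finite(hi), hi, F_cur),
                achieved = B_cur / Bb, target_fraction = target_frac,
                converged = FALSE, baseline = baseline))
  }
  off <- species[B_cur > target_B]
  stop("F_max calibration did not converge for: ",
       paste(off, collapse = ", "), call. = FALSE)
}

#' Run one fishing-by-subsidy scenario
#'
#' Equilibrates the unperturbed model for `T` days ("before" state), then
#' applies the perturbation as a step change -- the calibrated fishing
#' mortalities and/or the altered plankton subsidy `s (1 + subsidy/100)` --
#' and integrates a further `T` days from the before state ("after" state).
#' Per-species and per-trophic-category percent biomass changes follow
#' [biomass_change()]; category aggregates are changes in summed biomass
#' (extinct species contribute zero to the numerator), split by harvested
#' status.
#'
#' @param web A `food_web` (supplies category and harvested labels).
#' @param params An `atn_params` built from `web`.
#' @param fishing Nominal percent biomass reduction of every harvested
#'   species: 0 (no fishing), 50, 80 or 100.
#' @param subsidy Percent change of the plankton subsidy, e.g. -100, -80,
#'   -50, 0, +50, +80, +100.
#' @param f_max Named mortality vector for the harvested species (from
#'   [calibrate_fmax()]). Calibrated internally when `NULL` and
#'   `fishing > 0`.
#' @param B_init,seed,T,spinup As in [calibrate_fmax()].
#' @param baseline Optional precomputed unperturbed `atn_equilibrium`,
#'   shared across the cells of a factorial design.
#' @return A `scenario_result`: fields `species` (tibble: `species`,
#'   `category`, `harvested`, `before`, `after`, `change_pct`, `extinct`),
#'   `category` (tibble of aggregate changes), `extinct` (character),
#'   `fishing`, `subsidy`, `before`/`after` equilibria.
#' @examples
#' \donttest{
#' gen <- generate_web(synth_spec(S = 30, seed = 1))
#' res <- run_scenario(gen$web, gen$params, fishing = 0, subsidy = -100)
#' glance(res)
#' }
#' @export
run_scenario <- function(web, params, fishing = 0, subsidy = 0,
                         f_max = NULL, B_init = NULL, seed = 1L, T = 3650,
                         spinup = 2 * T, baseline = NULL) {
  stopifnot(fishing >= 0, fishing <= 100, subsidy >= -100)
  if (is.null(baseline)) {
    if (is.null(B_init)) B_init <- atn_initial_biomass(params, seed)
    baseline <- equilibrate(set_fmax(params, 0), B_init, T = spinup)
  }
  if (fishing > 0 && is.null(f_max)) {
    f_max <- calibrate_fmax(params, fishing, T = T, baseline = baseline,
                            species = harvested_alive(params, baseline))$F_max
  }
  p2 <- set_fmax(params, 0)
  if (fishing > 0) p2 <- set_fmax(p2, f_max)
  p2 <- set_subsidy(p2, params$s * (1 + subsidy / 100))
  after <- equilibrate(p2, baseline$B, T = T)

  sp <- params$species
  before_B <- baseline$B[sp]
  after_B <- after$B[sp]
  species_tbl <- tibble::tibble(
    species = sp,
    category = unname(params$category[sp]),
    harvested = unname(params$harvested[sp]),
    before = unname(before_B),
    after = unname(after_B),
    change_pct = biomass_change(unname(before_B), unname(after_B)),
    extinct = unname(before_B > 0 & after_B == 0)
  )
  cat_tbl <- dplyr::bind_rows(
    species_tbl |>
      dplyr::group_by(.data$category) |>
      dplyr::summarise(
        harvested = NA,
        before = sum(.data$before), after = sum(.data$after),
        change_pct = biomass_change(sum(.data$before), sum(.data$after)),
        .groups = "drop"
      ),
    species_tbl |>
      dplyr::group_by(.data$category, .data$harvested) |>
      dplyr::summarise(
        before = sum(.data$before), after = sum(.data$after),
        change_pct = biomass_change(sum(.data$before), sum(.data$after)),
        .groups = "drop"
      )
  )
  structure(
    list(
      species = species_tbl,
      category = cat_tbl,
      extinct = species_tbl$species[species_tbl$extinct],
      fishing = fishing, subsidy = subsidy,
      before = baseline, after = after
    ),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result> fishing=", x$fishing, "% subsidy=",
      sprintf("%+d", as.integer(x$subsidy)), "%; extinctions: ",
      length(x$extinct), "\n", sep = "")
  invisible(x)
}

#' Full factorial fishing-by-subsidy design
#'
#' Runs every (fishing, subsidy) cell from one common unperturbed baseline.
#' Fishing mortalities are calibrated once per fishing level and reused
#' across subsidy levels.
#'
#' @inheritParams run_scenario
#' @param fishing_levels,subsidy_levels Numeric vectors of levels (percent);
#'   0 means no perturbation on that axis.
#' @return A `factorial_result`: a tibble with one row per cell (`fishing`,
#'   `subsidy`, `n_extinct`, `result` list-column of `scenario_result`s)
#'   plus attributes `baseline` and `f_max` (per fishing level).
#' @export
run_factorial <- function(web, params,
                          fishing_levels = c(50, 80, 100),
                          subsidy_levels = c(-100, -80, -50, 50, 80, 100),
                          B_init = NULL, seed = 1L, T = 3650, spinup = 2 * T) {
  if (is.null(B_init)) B_init <- atn_initial_biomass(params, seed)
  baseline <- equilibrate(set_fmax(params, 0), B_init, T = spinup)
  f_levels <- sort(unique(fishing_levels))
  # calibrate ascending levels, warm-starting each from the previous one
  f_max_by_level <- list()
  warm <- NULL
  for (f in f_levels) {
    f_max_by_level[[paste0("f", f)]] <- if (f == 0) NULL else {
      warm <- calibrate_fmax(params, f, T = T, baseline = baseline,
                             species = harvested_alive(params, baseline),
                             F_init = warm)$F_max
      warm
    }
  }
  grid <- tidyr::expand_grid(fishing = f_levels, subsidy = sort(unique(subsidy_levels)))
  cells <- purrr::pmap(grid, function(fishing, subsidy) {
    run_scenario(web, params, fishing = fishing, subsidy = subsidy,
                 f_max = f_max_by_level[[paste0("f", fishing)]],
                 T = T, baseline = baseline)
  })
  out <- dplyr::mutate(grid,
                       n_extinct = vapply(cells, function(r) length(r$extinct), integer(1)),
                       result = cells)
  attr(out, "baseline") <- baseline
  attr(out, "f_max") <- f_max_by_level
  class(out) <- c("factorial_result", class(out))
  out
}

#' Dynamic deletion sequence
#'
#' Runs a deletion sequence through the bioenergetic model: after the
#' baseline equilibration, each species of `order` is removed outright
#' (state dropped from the dynamics, not merely fished), the model is
#' integrated a further `T` days to a new steady state, and the species
#' whose biomass fell below the extinction threshold are recorded as
#' secondary extinctions. Species already extinct at baseline are excluded
#' from the accounting.
#'
#' @inheritParams run_scenario
#' @param order Character vector of distinct species to remove, in order.
#' @return A `deletion_run` with `mode = "dynamic"`; its `S` is the number
#'   of species alive at baseline, the reference for the R50 index.
#' @export
run_dynamic_sequence <- function(web, params, order, B_init = NULL,
                                 seed = 1L, T = 3650, spinup = 2 * T,
                                 baseline = NULL) {
  order <- as.character(order)
  if (anyDuplicated(order)) stop("duplicated species in order", call. = FALSE)
  unknown <- setdiff(order, params$species)
  if (length(unknown) > 0) {
    stop("node(s) not in the dynamic web: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(baseline)) {
    if (is.null(B_init)) B_init <- atn_initial_biomass(params, seed)
    baseline <- equilibrate(set_fmax(params, 0), B_init, T = spinup)
  }
  alive0 <- names(baseline$B)[baseline$B > 0]
  S <- length(alive0)
  half <- ceiling(S / 2)

  B <- baseline$B
  removed <- character(0)
  sec_set <- character(0)
  steps <- length(order)
  n_sec <- integer(steps)
  new_sec <- integer(steps)
  r50 <- NA_real_
  p <- set_fmax(params, 0)
  for (k in seq_len(steps)) {
    removed <- c(removed, order[k])
    B[order[k]] <- 0
    # a removed node is dropped from the equations: zero biomass crosses the
    # extinction threshold at t = 0 and is excluded from further dynamics
    eq <- equilibrate(p, B, T = T)
    B <- eq$B
    dead <- names(B)[B == 0]
    # once a species has starved it stays counted secondary, even if its
    # turn for primary removal comes later in the order
    sec_set <- union(sec_set, setdiff(intersect(dead, alive0), removed))
    n_sec[k] <- length(sec_set)
    new_sec[k] <- n_sec[k] - if (k > 1) n_sec[k - 1] else 0L
    if (is.na(r50) && length(intersect(dead, alive0)) >= half) r50 <- k / S
  }
  new_deletion_run(
    tibble::tibble(step = seq_len(steps), removed_species = order,
                   n_primary = seq_len(steps), n_secondary = n_sec,
                   new_secondary = new_sec),
    r50 = r50, mode = "dynamic", S = S
  )
}
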