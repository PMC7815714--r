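#' Allometric biological rates
#'
#' Builds the normalised intrinsic growth, metabolic and maximum-consumption
#' rates of the bioenergetic model from body masses. Rates scale with body
#' mass as a power law with exponent -0.25 and are normalised by the growth
#' rate of the reference producer -- the producer with the smallest body
#' mass, hence the highest mass-specific growth rate, whose normalised
#' growth rate is exactly 1. Consumers get a metabolic rate
#' `x = (a_x/a_r) (M/M_ref)^-0.25` and a mass-independent maximum
#' consumption-to-metabolism ratio `y = a_y/a_x`, identical for every
#' consumer.
#'
#' @param masses Positive numeric vector of body masses (any consistent unit).
#' @param is_producer Logical vector: which species are primary producers
#'   (the plankton node counts as a producer).
#' @param a_r,a_x,a_y Positive allometric constants for production,
#'   metabolism and maximum consumption.
#' @return List with `r` (producers, `NA` for consumers), `x` (consumers,
#'   `NA` for producers), scalar `y`, and `M_ref`.
#' @examples
#' build_rates(c(1, 16, 100), c(TRUE, TRUE, FALSE))
#' @export
build_rates <- function(masses, is_producer, a_r = 1, a_x = 0.314, a_y = 2.512) {
  if (any(masses <= 0) || anyNA(masses)) stop("non-positive body mass", call. = FALSE)
  if (!any(is_producer)) stop("no producer in the web", call. = FALSE)
  stopifnot(a_r > 0, a_x > 0, a_y > 0)
  M_ref <- min(masses[is_producer])
  rel <- (masses / M_ref)^(-0.25)
  r <- ifelse(is_producer, rel, NA_real_)
  x <- ifelse(is_producer, NA_real_, (a_x / a_r) * rel)
  list(r = r, x = x, y = a_y / a_x, M_ref = M_ref)
}

#' Build bioenergetic model parameters for a food web
#'
#' Maps every species and feeding link of a food web onto the parameters of
#' the subsidised allometric trophic network model: allometric rates from
#' [build_rates()], a Hill-type functional response, logistic producer
#' growth under a single shared carrying capacity, a constant plankton
#' subsidy and per-species fishing mortality. The fisheries node, when
#' present, is structural only: it is excluded from the dynamic state and
#' harvesting enters solely through `F_max`.
#'
#' @param web A `food_web`.
#' @param a_r,a_x,a_y Allometric constants (see [build_rates()]).
#' @param q Hill exponent of the functional response; 1.2 gives a response
#'   intermediate between type II and type III.
#' @param B0 Half-saturation biomass, recycled over links (per-link values
#'   allowed via `link_overrides`).
#' @param d Consumer interference coefficient, recycled over consumers.
#' @param e_herb,e_carn Assimilation efficiency for links whose resource is
#'   a producer (herbivory) or an animal (carnivory).
#' @param f_a Fraction of ingested biomass assimilated.
#' @param f_m Fraction of consumer biomass respired for maintenance.
#' @param K Community-wide carrying capacity shared by all producers.
#' @param s Constant plankton subsidy (biomass per day added to the plankton
#'   node); ignored when the web has no plankton node.
#' @param F_max Fishing mortality (fraction of standing biomass removed per
#'   day). Either a single default applied to harvested species or a named
#'   vector; non-harvested species always default to 0.
#' @param c_competition Optional producer competition matrix `c_ij` (rows and
#'   columns in producer order). `NULL` means fully shared capacity
#'   (`c_ij = 1` for every producer pair).
#' @param link_overrides Optional data frame `consumer, resource, field,
#'   value` overriding per-link `omega`, `e` or `B0`.
#' @return An object of class `atn_params`.
#' @examples
#' fx <- fixture_chain()
#' p <- atn_params(fx, K = 1)
#' p
#' @export
atn_params <- function(web,
                       a_r = 1, a_x = 0.314, a_y = 2.512,
                       q = 1.2, B0 = 0.5, d = 0,
                       e_herb = 0.45, e_carn = 0.85,
                       f_a = 0.4, f_m = 0.1,
                       K = 10, s = 0.5,
                       F_max = 0,
                       c_competition = NULL,
                       link_overrides = NULL) {
  stopifnot(q > 0, K > 0, f_a >= 0, f_a <= 1, f_m >= 0, f_m <= 1,
            e_herb > 0, e_herb <= 1, e_carn > 0, e_carn <= 1, s >= 0)
  fish <- fisheries_node(web)
  nodes <- web$nodes[!web$nodes$is_fisheries, , drop = FALSE]
  sp <- nodes$species
  n <- length(sp)
  links <- web$links[!(web$links$consumer %in% fish) &
                       !(web$links$resource %in% fish), , drop = FALSE]
  is_producer <- nodes$category %in% c("producer", "plankton")
  rates <- build_rates(nodes$body_mass, is_producer, a_r, a_x, a_y)

  ci <- match(links$consumer, sp)
  ri <- match(links$resource, sp)
  nres <- tabulate(ci, nbins = n)
  lk <- tibble::tibble(
    consumer = links$consumer, resource = links$resource,
    ci = ci, ri = ri,
    omega = 1 / nres[ci],
    e = ifelse(is_producer[ri], e_herb, e_carn),
    B0 = rep_len(B0, length(ci))
  )
  if (!is.null(link_overrides) && nrow(link_overrides) > 0) {
    for (k in seq_len(nrow(link_overrides))) {
      ov <- link_overrides[k, ]
      hit <- lk$consumer == ov$consumer & lk$resource == ov$resource
      if (!any(hit)) {
        stop("override for unknown link ", ov$consumer, " -> ", ov$resource,
             call. = FALSE)
      }
      if (!ov$field %in% c("omega", "e", "B0")) {
        stop("unknown link field: ", ov$field, call. = FALSE)
      }
      lk[[ov$field]][hit] <- as.numeric(ov$value)
    }
    # renormalise preferences per consumer after overrides
    tot <- tapply(lk$omega, lk$ci, sum)
    lk$omega <- lk$omega / as.numeric(tot[as.character(lk$ci)])
  }

  d_vec <- rep_len(d, n)
  fm_vec <- stats::setNames(rep(0, n), sp)
  if (!is.null(names(F_max))) {
    unknown <- setdiff(names(F_max), sp)
    if (length(unknown) > 0) {
      stop("F_max for unknown species: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    fm_vec[names(F_max)] <- F_max
  } else if (length(F_max) == 1) {
    fm_vec[nodes$harvested] <- F_max
  } else {
    stop("F_max must be a scalar or a named vector", call. = FALSE)
  }
  if (any(fm_vec < 0)) stop("negative F_max", call. = FALSE)

  n_prod <- sum(is_producer)
  if (!is.null(c_competition)) {
    stopifnot(is.matrix(c_competition),
              nrow(c_competition) == n_prod, ncol(c_competition) == n_prod)
  }

  structure(
    list(
      species = sp, n = n,
      category = stats::setNames(nodes$category, sp),
      harvested = stats::setNames(nodes$harvested, sp),
      M = stats::setNames(nodes$body_mass, sp),
      is_producer = is_producer,
      producer_idx = which(is_producer),
      plankton_idx = {
        pi <- which(nodes$is_plankton)
        if (length(pi)) pi else NA_integer_
      },
      r = rates$r, x = rates$x, y = rates$y, M_ref = rates$M_ref,
      a_r = a_r, a_x = a_x, a_y = a_y,
      links = lk, d = d_vec, q = q,
      f_a = f_a, f_m = f_m, K = K, s = s,
      F_max = fm_vec,
      c_competition = c_competition
    ),
    class = "atn_params"
  )
}

#' @export
print.atn_params <- function(x, ...) {
  cat("<atn_params> ", x$n, " dynamic species (", sum(x$is_producer),
      " producers), ", nrow(x$links), " links\n", sep = "")
  cat("  q=", x$q, " K=", x$K, " s=", x$s, " y=", signif(x$y, 4),
      " f_a=", x$f_a, " f_m=", x$f_m,
      "; fished species: ", sum(x$F_max > 0), "\n", sep = "")
  invisible(x)
}

#' Default initial biomasses
#'
#' Draws a seeded initial biomass for every dynamic species: a per-category
#' default scaled by a uniform factor in \[0.5, 1.5\]. Producers (and
#' plankton) start at `0.8 K / n_producers` each, so total producer biomass
#' starts near (but below) the shared carrying capacity; consumers start at
#' 0.05 biomass units.
#'
#' @param params An `atn_params`.
#' @param seed Integer seed.
#' @return Named numeric vector of initial biomasses.
#' @export
atn_initial_biomass <- function(params, seed = 1L) {
  base <- ifelse(params$is_producer,
                 0.8 * params$K / sum(params$is_producer),
                 0.05)
  withr::with_seed(seed, {
    stats::setNames(base * stats::runif(params$n, 0.5, 1.5), params$species)
  })
}

# Shallow-modify helpers used by the scenario machinery.
set_fmax <- function(params, F_max) {
  fm <- stats::setNames(rep(0, params$n), params$species)
  if (length(F_max) == 1 && is.null(names(F_max))) {
    fm[params$harvested] <- F_max
  } else {
    fm[names(F_max)] <- F_max
  }
  params$F_max <- fm
  params
}

set_subsidy <- function(params, s) {
  stopifnot(s >= 0)
  params$s <- s
  params
}
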