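#' Settings for the synthetic food-web generator
#'
#' Defaults emulate the structure of a well-resolved rocky-intertidal web:
#' about a hundred species of which ~44% are primary producers, a single
#' plankton node consumed exclusively by a clique of specialist
#' filter-feeders, a set of harvested species spanning macroalgae to
#' carnivores, and a highly omnivorous fisheries node linked to all of them.
#'
#' @param S Total species count, including the plankton and fisheries nodes
#'   (>= 5).
#' @param C Target directed connectance L/S^2, in (0, 0.5).
#' @param n_filter_feeders Number of specialist plankton consumers (>= 1).
#' @param n_harvested Number of harvested species (< S).
#' @param mass_ratio Mean consumer-resource body-mass ratio: body masses
#'   grow by this factor per trophic level.
#' @param prop_producers Fraction of dynamic species that are primary
#'   producers.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(S = 107, C = 0.12, n_filter_feeders = NULL,
                       n_harvested = NULL, mass_ratio = 100,
                       prop_producers = 0.44, seed = 1L) {
  if (is.null(n_filter_feeders)) n_filter_feeders <- max(1L, round(S * 15 / 107))
  if (is.null(n_harvested)) n_harvested <- max(1L, round(S * 22 / 107))
  stopifnot(S >= 5, C > 0, C < 0.5, n_filter_feeders >= 1, n_harvested < S,
            mass_ratio > 1, prop_producers > 0, prop_producers < 1)
  n_dyn <- S - 1L  # all but the fisheries node
  n_prod <- round(prop_producers * n_dyn)
  if (n_prod < 2 || n_prod + n_filter_feeders + 1 > n_dyn) {
    stop("infeasible spec: not enough species for the requested roles",
         call. = FALSE)
  }
  structure(list(S = as.integer(S), C = C,
                 n_filter_feeders = as.integer(n_filter_feeders),
                 n_harvested = as.integer(n_harvested),
                 mass_ratio = mass_ratio, prop_producers = prop_producers,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# Classic niche model: each species gets a niche value in [0,1] and consumes
# every species whose niche value falls in an interval below (mostly) its
# own. Returns a logical adjacency: a[i, j] TRUE when i consumes j.
niche_model_adjacency <- function(S, C) {
  beta <- 1 / (2 * C) - 1
  nv <- sort(stats::runif(S))
  rr <- nv * stats::rbeta(S, 1, beta)
  rr[1] <- 0  # smallest niche value is basal, guaranteeing a basal species
  centre <- stats::runif(S, rr / 2, pmin(nv, 1 - rr / 2))
  a <- outer(centre - rr / 2, nv, "<=") & outer(centre + rr / 2, nv, ">=")
  list(adj = a, niche = nv)
}

#' Generate a synthetic coastal food web with model parameters
#'
#' Draws a niche-model web at the requested size and connectance, then edits
#' it into the architecture of a subsidised intertidal web: the
#' lowest-niche-value species become primary producers (links to their own
#' resources stripped), one producer becomes the plankton node whose only
#' consumers are `n_filter_feeders` specialist filter-feeders, connectance
#' is steered back to the target by adding/removing ordinary feeding links,
#' trophic categories are assigned from the final diets, body masses
#' increase log-normally with trophic level at the requested
#' consumer-resource mass ratio, a harvested set is sampled across
#' categories (stratified towards macroalgae and omnivores, mirroring
#' typical artisanal-fishery landings) with catch ranks, and a fisheries
#' node is added consuming every harvested species. Model parameters are
#' filled with the package defaults of [atn_params()].
#'
#' @param spec A [synth_spec()].
#' @return List with elements `web` (a `food_web`), `params` (an
#'   `atn_params`) and `spec`.
#' @examples
#' gen <- generate_web(synth_spec(S = 30, seed = 7))
#' gen$web
#' @export
generate_web <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  withr::with_seed(spec$seed, generate_web_impl(spec))
}

generate_web_impl <- function(spec) {
  S <- spec$S
  n_dyn <- S - 1L
  nm <- niche_model_adjacency(n_dyn, spec$C)
  adj <- nm$adj
  diag(adj) <- FALSE  # no cannibalism in generated webs

  n_prod <- round(spec$prop_producers * n_dyn)
  producers <- seq_len(n_prod)           # lowest niche values
  adj[producers, ] <- FALSE
  consumers <- setdiff(seq_len(n_dyn), producers)

  plankton <- sample_one(producers)
  adj[, plankton] <- FALSE               # nobody eats plankton ...
  ff <- sample_k(consumers, spec$n_filter_feeders)
  adj[ff, ] <- FALSE                     # ... except the filter-feeders,
  adj[ff, plankton] <- TRUE              # which eat nothing else

  # every other consumer needs at least one resource below it
  for (i in setdiff(consumers, ff)) {
    if (!any(adj[i, ])) {
      k <- sample_one(setdiff(seq_len(i - 1), plankton))
      adj[i, k] <- TRUE
    }
  }

  # steer the link count to the target connectance (fisheries links count)
  target_L <- round(spec$C * S^2)
  protected <- matrix(FALSE, n_dyn, n_dyn)
  protected[ff, ] <- TRUE                # keep filter-feeders specialist
  free_cons <- setdiff(consumers, ff)
  for (iter in 1:2000) {
    L_now <- sum(adj) + spec$n_harvested
    if (L_now == target_L) break
    if (L_now < target_L) {
      i <- sample_one(free_cons)
      lower <- setdiff(seq_len(i - 1), plankton)
      cand <- lower[!adj[i, lower]]
      if (length(cand) > 0) adj[i, sample_one(cand)] <- TRUE
    } else {
      i <- sample_one(free_cons)
      res <- which(adj[i, ] & !protected[i, ])
      if (length(res) > 1) adj[i, sample_one(res)] <- FALSE
    }
  }

  # every consumer must have a directed path down to a basal node; consumers
  # stranded on cycles get a direct producer link
  basal_now <- which(rowSums(adj) == 0)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
  dd <- igraph::distances(g, to = basal_now, mode = "out")
  stranded <- which(!is.finite(apply(dd, 1, min)))
  for (i in stranded) {
    adj[i, sample_one(setdiff(producers, plankton))] <- TRUE
  }

  # categories from final diets: a consumer whose diet is at least 75%
  # animal prey counts as a carnivore (a strictly-animal diet is rare in a
  # dense niche web), a carnivore nobody eats is a top predator
  basal <- rowSums(adj) == 0
  frac_animal <- ifelse(rowSums(adj) > 0, (adj %*% (!basal)) / rowSums(adj), 0)
  has_consumer <- colSums(adj) > 0
  category <- rep("producer", n_dyn)
  category[!basal & frac_animal == 0] <- "herbivore"
  category[!basal & frac_animal > 0] <- "omnivore"
  category[!basal & frac_animal >= 0.75 & has_consumer] <- "carnivore"
  category[!basal & frac_animal >= 0.75 & !has_consumer] <- "top-predator"
  category[ff] <- "filter-feeder"
  category[plankton] <- "plankton"

  species <- sprintf("sp%03d", seq_len(n_dyn))
  links <- which(adj, arr.ind = TRUE)
  link_tbl <- tibble::tibble(consumer = species[links[, 1]],
                             resource = species[links[, 2]])

  # body masses increase with trophic level at the requested mass ratio
  web0 <- food_web(
    tibble::tibble(species = species, body_mass = 1, category = category),
    link_tbl
  )
  tl <- unname(swtl(web0))
  mass <- spec$mass_ratio^(tl - 1) * exp(stats::rnorm(n_dyn, 0, 0.3))

  # harvested set stratified across categories, mirroring artisanal landings
  strata <- c("producer" = 7, "filter-feeder" = 2, "herbivore" = 1,
              "omnivore" = 10, "carnivore" = 2)
  want <- round(spec$n_harvested * strata / sum(strata))
  harvested_idx <- integer(0)
  for (cat in names(strata)) {
    pool <- setdiff(which(category == cat), plankton)
    harvested_idx <- c(harvested_idx, sample_k(pool, min(want[[cat]], length(pool))))
  }
  short <- spec$n_harvested - length(harvested_idx)
  if (short > 0) {
    pool <- setdiff(seq_len(n_dyn), c(harvested_idx, plankton, which(category == "top-predator")))
    harvested_idx <- c(harvested_idx, sample_k(pool, short))
  } else if (short < 0) {
    harvested_idx <- harvested_idx[seq_len(spec$n_harvested)]
  }
  harvested <- seq_len(n_dyn) %in% harvested_idx
  catch_rank <- rep(NA_integer_, n_dyn)
  catch_rank[harvested_idx] <- sample(seq_along(harvested_idx))

  nodes <- tibble::tibble(
    species = species, body_mass = mass, category = category,
    harvested = harvested, catch_rank = catch_rank,
    is_plankton = seq_len(n_dyn) == plankton,
    is_fisheries = FALSE
  )
  nodes <- dplyr::bind_rows(nodes, tibble::tibble(
    species = "fisheries", body_mass = NA_real_, category = "fisheries",
    harvested = FALSE, catch_rank = NA_integer_,
    is_plankton = FALSE, is_fisheries = TRUE
  ))
  link_tbl <- dplyr::bind_rows(link_tbl, tibble::tibble(
    consumer = "fisheries", resource = species[harvested_idx]
  ))
  web <- food_web(nodes, link_tbl)
  params <- atn_params(web, K = 0.25 * sum(nodes$category %in% c("producer", "plankton")))
  list(web = web, params = params, spec = spec)
}

#' Hand-built micro-webs with known behaviour
#'
#' Deterministic fixtures used throughout the package tests, each with
#' closed-form or easily hand-checked behaviour.
#'
#' * `fixture_chain()`: three-link chain producer P -> herbivore H ->
#'   carnivore C; removing P statically collapses the chain.
#' * `fixture_star()`: one omnivorous hub consuming four producer leaves;
#'   the hub is the most-connected node.
#' * `fixture_plankton_ff()`: a subsidised plankton node and one specialist
#'   filter-feeder, parameterised (`y = 2`, `f_a = 0.5`, `f_m = 0.4`,
#'   `B0 = 2`, `K = 1`, `s = 5`) so the filter-feeder persists only while
#'   the subsidy keeps plankton biomass above its break-even density: the
#'   feeder's break-even plankton biomass (about 1.43) exceeds the
#'   carrying capacity, so cutting the subsidy to zero starves it.
#' * `fixture_producer_pair()`: two producers under a fully shared carrying
#'   capacity, producer A harvested; any fishing mortality on A releases B
#'   towards the full capacity K.
#'
#' @return `small_fixture_suite()` returns a named list of the four
#'   fixtures; each `fixture_*()` returns a `food_web` (with an
#'   `atn_params` attached as attribute `params` where dynamics matter).
#' @export
small_fixture_suite <- function() {
  list(
    chain = fixture_chain(),
    star = fixture_star(),
    plankton_ff = fixture_plankton_ff(),
    producer_pair = fixture_producer_pair()
  )
}

#' @rdname small_fixture_suite
#' @export
fixture_chain <- function() {
  food_web(
    tibble::tibble(species = c("P", "H", "C"), body_mass = c(1, 10, 100),
                   category = c("producer", "herbivore", "carnivore")),
    tibble::tibble(consumer = c("H", "C"), resource = c("P", "H"))
  )
}

#' @rdname small_fixture_suite
#' @export
fixture_star <- function() {
  food_web(
    tibble::tibble(species = c("hub", paste0("leaf", 1:4)),
                   body_mass = c(50, rep(1, 4)),
                   category = c("herbivore", rep("producer", 4))),
    tibble::tibble(consumer = "hub", resource = paste0("leaf", 1:4))
  )
}

#' @rdname small_fixture_suite
#' @export
fixture_plankton_ff <- function() {
  web <- food_web(
    tibble::tibble(species = c("plankton", "ff"), body_mass = c(1, 10),
                   category = c("plankton", "filter-feeder")),
    tibble::tibble(consumer = "ff", resource = "plankton")
  )
  attr(web, "params") <- atn_params(
    web, a_y = 2 * 0.314,        # y = a_y / a_x = 2
    f_a = 0.5, f_m = 0.4, B0 = 2, K = 1, s = 5
  )
  web
}

#' @rdname small_fixture_suite
#' @export
fixture_producer_pair <- function() {
  web <- food_web(
    tibble::tibble(species = c("A", "B"), body_mass = c(1, 1),
                   category = c("producer", "producer"),
                   harvested = c(TRUE, FALSE), catch_rank = c(1L, NA)),
    tibble::tibble(consumer = character(0), resource = character(0))
  )
  attr(web, "params") <- atn_params(web, K = 1, s = 0)
  web
}

# sample() falls back to sample.int semantics on length-1 vectors; these
# helpers always treat the first argument as the candidate set
sample_one <- function(x) x[sample.int(length(x), 1)]
sample_k <- function(x, k) x[sample.int(length(x), k)]
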