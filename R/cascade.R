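#' Secondary extinctions triggered by a primary removal (static rule)
#'
#' Computes the least fixed point of the bottom-up extinction rule: a
#' non-basal species is extinct once all of its resource species are extinct.
#' Basal species (including the plankton node, which obtains its resources
#' from outside the web) never go secondarily extinct, and neither does the
#' fisheries node. A cannibalistic self-link does not keep its owner alive.
#'
#' @param web A `food_web`.
#' @param removed Character vector of primarily removed species (subset of
#'   the web's species; may be empty).
#' @return Character vector of secondarily extinct species, excluding
#'   `removed`.
#' @examples
#' cascade(fixture_chain(), "P")  # herbivore and carnivore starve
#' @export
cascade <- function(web, removed) {
  removed <- unique(as.character(removed))
  unknown <- setdiff(removed, web$nodes$species)
  if (length(unknown) > 0) {
    stop("unknown node(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  idx <- fw_index(web)
  st <- cascade_state(idx)
  for (id in match(removed, idx$species)) st <- cascade_kill(st, idx, id, primary = TRUE)
  idx$species[st$status == 2L]
}

# status: 0 alive, 1 primary, 2 secondary
cascade_state <- function(idx) {
  list(status = integer(idx$n), res_alive = idx$n_res)
}

cascade_kill <- function(st, idx, id, primary, reclassify = TRUE) {
  if (st$status[id] != 0L) {
    # already dead: in a one-shot cascade the primary label wins; in a
    # sequential run a species that starved first stays counted secondary
    if (primary && reclassify) st$status[id] <- 1L
    return(st)
  }
  st$status[id] <- if (primary) 1L else 2L
  queue <- id
  while (length(queue) > 0) {
    j <- queue[[1]]
    queue <- queue[-1]
    for (i in idx$cons_of[[j]]) {
      if (st$status[i] == 0L) {
        st$res_alive[i] <- st$res_alive[i] - 1L
        if (st$res_alive[i] == 0L && !idx$basal[i] &&
            !identical(i, idx$fisheries)) {
          st$status[i] <- 2L
          queue <- c(queue, i)
        }
      }
    }
  }
  st
}

#' Harvesting deletion sequence
#'
#' Orders the harvested species by decreasing total catch: catch rank 1 (the
#' largest landings) is removed first. Ties in rank are broken at random
#' under the given seed.
#'
#' @param web A `food_web`.
#' @param seed Integer seed for tie-breaking (only used when ranks tie).
#' @return Character vector of harvested species in removal order (may be
#'   empty when nothing is harvested).
#' @export
harvesting_order <- function(web, seed = 1L) {
  h <- web$nodes[web$nodes$harvested, , drop = FALSE]
  if (nrow(h) == 0) return(character(0))
  if (anyNA(h$catch_rank)) {
    stop("harvested species without catch_rank: ",
         paste(h$species[is.na(h$catch_rank)], collapse = ", "), call. = FALSE)
  }
  withr::with_seed(seed, {
    jitter <- stats::runif(nrow(h))
    h$species[order(h$catch_rank, jitter)]
  })
}

# Greedy ordering engine shared by the connectivity-based sequences.
# score_fun(deg, cons_of_alive, basal, alive) -> numeric score per node;
# basal_first breaks score ties in favour of basal nodes.
greedy_order <- function(web, seed, score_fun, basal_first = FALSE) {
  idx <- fw_index(web)
  n <- idx$n
  alive <- rep(TRUE, n)
  removable <- rep(TRUE, n)
  if (!is.na(idx$fisheries)) removable[idx$fisheries] <- FALSE
  # adjacency over all links, self-links counted once
  ends <- cbind(idx$ci, idx$ri)
  withr::with_seed(seed, {
    order_out <- character(0)
    while (any(removable & alive)) {
      live_link <- alive[ends[, 1]] & alive[ends[, 2]]
      deg <- tabulate(ends[live_link, 1], nbins = n) +
        tabulate(ends[live_link & ends[, 1] != ends[, 2], 2], nbins = n)
      score <- score_fun(deg, idx, alive)
      score[!(removable & alive)] <- -Inf
      best <- which(score == max(score))
      if (basal_first && length(best) > 1) {
        # basal on the surviving web: no surviving resources
        bb <- vapply(best, function(i) {
          r <- idx$res_of[[i]]
          length(r) == 0 || !any(alive[r])
        }, logical(1))
        if (any(bb)) best <- best[bb]
      }
      pick <- if (length(best) == 1) best else sample(best, 1)
      order_out <- c(order_out, idx$species[pick])
      alive[pick] <- FALSE
    }
    order_out
  })
}

#' Most-connected deletion sequence
#'
#' Full deletion order over all removable species, repeatedly removing the
#' species with the highest degree; degree is recomputed on the surviving
#' web after each removal, and ties are broken at random under the seed.
#'
#' @param web A `food_web`.
#' @param seed Integer seed for tie-breaking.
#' @return Character vector: a permutation of [removable_species()].
#' @export
most_connected_order <- function(web, seed = 1L) {
  greedy_order(web, seed, function(deg, idx, alive) deg)
}

#' Supporting-basal deletion sequence
#'
#' Deletion order that targets well-connected species that trophically
#' support other highly connected species, prioritising basal nodes -- the
#' fastest known route of collapse. Each surviving node is scored as its own
#' degree times (1 + the summed degree of its surviving consumers); at equal
#' score basal nodes are removed first, remaining ties at random. Scores are
#' recomputed on the surviving web after each removal.
#'
#' @param web A `food_web`.
#' @param seed Integer seed for tie-breaking.
#' @return Character vector: a permutation of [removable_species()].
#' @export
supporting_basal_order <- function(web, seed = 1L) {
  greedy_order(web, seed, function(deg, idx, alive) {
    cons_deg <- vapply(seq_along(idx$cons_of), function(j) {
      cons <- idx$cons_of[[j]]
      sum(deg[cons[alive[cons]]])
    }, numeric(1))
    deg * (1 + cons_deg)
  }, basal_first = TRUE)
}

#' Run a static deletion sequence
#'
#' Removes the species of `order` one at a time and records, after each
#' primary removal, the cumulative secondary extinctions produced by the
#' static cascade rule on the cumulative removed set. The R50 robustness
#' index is the fraction of species that had to be primarily removed for
#' total losses (primary + secondary) to reach half the web; it is `NA` when
#' the sequence ends before half the web is extinct (e.g. the harvesting
#' sequence, where only the extinction counts are recorded).
#'
#' @param web A `food_web`.
#' @param order Character vector of distinct species to remove, in order.
#' @return A `deletion_run`: per-step tibble (`step`, `removed_species`,
#'   `n_primary`, `n_secondary`, `new_secondary`) plus fields `r50`, `mode`
#'   (`"static"`) and `S`. `n_secondary` is the cumulative count.
#' @examples
#' run <- run_static_sequence(fixture_chain(), "P")
#' tidy(run)
#' @export
run_static_sequence <- function(web, order) {
  order <- as.character(order)
  if (anyDuplicated(order)) stop("duplicated species in order", call. = FALSE)
  unknown <- setdiff(order, web$nodes$species)
  if (length(unknown) > 0) {
    stop("unknown node(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.na(fisheries_node(web)) && fisheries_node(web) %in% order) {
    stop("the fisheries node cannot be removed", call. = FALSE)
  }
  idx <- fw_index(web)
  st <- cascade_state(idx)
  S <- idx$n
  steps <- length(order)
  n_sec <- integer(steps)
  new_sec <- integer(steps)
  half <- ceiling(S / 2)
  r50 <- NA_real_
  prev <- 0L
  for (k in seq_len(steps)) {
    st <- cascade_kill(st, idx, match(order[k], idx$species),
                       primary = TRUE, reclassify = FALSE)
    n_sec[k] <- sum(st$status == 2L)
    new_sec[k] <- n_sec[k] - prev
    prev <- n_sec[k]
    total_dead <- sum(st$status != 0L)
    if (is.na(r50) && total_dead >= half) r50 <- k / S
  }
  new_deletion_run(
    tibble::tibble(step = seq_len(steps), removed_species = order,
                   n_primary = seq_len(steps), n_secondary = n_sec,
                   new_secondary = new_sec),
    r50 = r50, mode = "static", S = S
  )
}

new_deletion_run <- function(steps, r50, mode, S) {
  structure(list(steps = steps, r50 = r50, mode = mode, S = S),
            class = "deletion_run")
}

#' @export
print.deletion_run <- function(x, ...) {
  cat("<deletion_run> mode=", x$mode, " steps=", nrow(x$steps),
      " total secondary=", max(c(0L, x$steps$n_secondary)),
      " R50=", if (is.na(x$r50)) "NA" else signif(x$r50, 4), "\n", sep = "")
  invisible(x)
}

#' Random deletion sequences
#'
#' Runs `reps` uniformly shuffled full deletion orders through the static
#' cascade and summarises, per step, the mean cumulative secondary
#' extinctions with a percentile 95% confidence interval, plus the
#' distribution of R50 across replicates.
#'
#' @param web A `food_web`.
#' @param reps Number of replicates (>= 2).
#' @param seed Integer seed; the whole ensemble is reproducible.
#' @return A `deletion_ensemble`: fields `summary` (tibble `step`,
#'   `mean_secondary`, `ci_lo`, `ci_hi`), `r50` (numeric vector per
#'   replicate), `reps`, `S`, `mode`.
#' @export
random_sequences <- function(web, reps, seed) {
  stopifnot(reps >= 2)
  candidates <- removable_species(web)
  orders <- withr::with_seed(seed, {
    replicate(reps, sample(candidates), simplify = FALSE)
  })
  runs <- purrr::map(orders, ~ run_static_sequence(web, .x))
  sec <- vapply(runs, function(r) r$steps$n_secondary, numeric(length(candidates)))
  if (length(candidates) == 1) sec <- matrix(sec, nrow = 1)
  structure(
    list(
      summary = tibble::tibble(
        step = seq_along(candidates),
        mean_secondary = apply(sec, 1, mean),
        ci_lo = apply(sec, 1, stats::quantile, probs = 0.025),
        ci_hi = apply(sec, 1, stats::quantile, probs = 0.975)
      ),
      r50 = vapply(runs, function(r) r$r50, numeric(1)),
      reps = reps, S = n_species(web), mode = "static"
    ),
    class = "deletion_ensemble"
  )
}

#' @export
print.deletion_ensemble <- function(x, ...) {
  cat("<deletion_ensemble> ", x$reps, " random sequences, S=", x$S,
      ", mean R50=", signif(mean(x$r50, na.rm = TRUE), 4), "\n", sep = "")
  invisible(x)
}
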