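#' Short-weighted trophic level of every node
#'
#' The short-weighted trophic level (SWTL) of a node is the average of two
#' classical trophic-level measures: the shortest-chain trophic level (1 plus
#' the length of the shortest food chain to a basal node) and the
#' prey-averaged trophic level (1 plus the mean trophic level of the node's
#' resources, solved as a linear system). Basal nodes have SWTL exactly 1.
#' Cannibalistic self-links are ignored in both measures. The plankton and
#' fisheries nodes participate like any other node.
#'
#' @param web A `food_web`.
#' @return Named numeric vector of SWTL values in node order.
#' @details Errors when some node has no directed path to a basal node (a
#'   cycle-only component, on which trophic level is undefined).
#' @examples
#' swtl(fixture_chain())  # 1, 2, 3
#' @export
swtl <- function(web) {
  idx <- fw_index(web)
  n <- idx$n
  if (n == 0) return(stats::setNames(numeric(0), character(0)))
  basal <- idx$basal

  # shortest-chain trophic level: BFS along consumer -> resource edges
  sel <- idx$ci != idx$ri
  g <- igraph::make_empty_graph(n, directed = TRUE)
  if (any(sel)) {
    g <- igraph::add_edges(g, rbind(idx$ci[sel], idx$ri[sel]))
  }
  if (!any(basal)) stop("no basal node: trophic levels undefined", call. = FALSE)
  d <- igraph::distances(g, v = seq_len(n), to = which(basal), mode = "out")
  shortest <- apply(d, 1, min) + 1
  if (any(!is.finite(shortest))) {
    stop("node(s) with no path to a basal node: ",
         paste(idx$species[!is.finite(shortest)], collapse = ", "),
         call. = FALSE)
  }

  # prey-averaged trophic level: T = 1 + W T with W the row-normalised diet
  W <- matrix(0, n, n)
  sel <- idx$ci != idx$ri
  ci <- idx$ci[sel]
  ri <- idx$ri[sel]
  nres <- idx$n_res
  W[cbind(ci, ri)] <- 1 / nres[ci]
  prey_avg <- solve(diag(n) - W, rep(1, n))

  stats::setNames((shortest + prey_avg) / 2, idx$species)
}

#' Structural metrics of a food web
#'
#' Computes species and link counts, directed connectance L/S^2, per-node
#' degree (number of links the node participates in, self-links counted
#' once), per-node short-weighted trophic level and its mean over nodes.
#'
#' @param web A `food_web`.
#' @return An object of class `fw_metrics` with fields `S`, `L`,
#'   `connectance`, `mean_swtl` and a per-node tibble `nodes` (columns
#'   `species`, `category`, `degree`, `swtl`). Use [generics::tidy()] for the
#'   per-node table and [generics::glance()] for the one-row summary.
#' @examples
#' m <- structural_metrics(fixture_chain())
#' glance(m)
#' @export
structural_metrics <- function(web) {
  S <- n_species(web)
  L <- n_links(web)
  tl <- swtl(web)
  deg <- node_degree(web)
  nodes <- tibble::tibble(
    species = web$nodes$species,
    category = web$nodes$category,
    degree = deg[web$nodes$species],
    swtl = tl[web$nodes$species]
  )
  structure(
    list(S = S, L = L, connectance = L / S^2,
         mean_swtl = mean(nodes$swtl), nodes = nodes),
    class = "fw_metrics"
  )
}

#' @export
print.fw_metrics <- function(x, ...) {
  cat("<fw_metrics> S=", x$S, " L=", x$L,
      " connectance=", signif(x$connectance, 4),
      " MeanSWTL=", signif(x$mean_swtl, 4), "\n", sep = "")
  invisible(x)
}

#' Per-node degree
#'
#' Number of links each node participates in, as consumer or resource;
#' a cannibalistic self-link counts once.
#'
#' @param web A `food_web`.
#' @return Named integer vector in node order.
#' @export
node_degree <- function(web) {
  sp <- web$nodes$species
  self <- web$links$consumer == web$links$resource
  tab_c <- table(factor(web$links$consumer, levels = sp))
  tab_r <- table(factor(web$links$resource[!self], levels = sp))
  stats::setNames(as.integer(tab_c + tab_r), sp)
}

#' Structural null model: random removal of k species
#'
#' Builds the null distribution of structural metrics obtained by removing
#' `k` species sampled uniformly from all species except the fisheries node,
#' used to judge whether the loss of the harvested set removes more links
#' than expected by chance.
#'
#' @param web A `food_web`.
#' @param k Number of species removed per replicate.
#' @param reps Number of replicates (>= 1).
#' @param seed Integer seed; the whole distribution is reproducible.
#' @return A tibble with one row per replicate: `rep`, `S`, `L`,
#'   `connectance`, `links_lost`, `mean_swtl` (`NA` when removal leaves a
#'   consumer with no path to a basal node, where trophic level is
#'   undefined).
#' @examples
#' web <- fixture_chain()
#' random_removal_null(web, k = 1, reps = 5, seed = 1)
#' @export
random_removal_null <- function(web, k, reps, seed) {
  stopifnot(reps >= 1)
  candidates <- removable_species(web)
  if (k > n_species(web)) stop("k exceeds the number of species", call. = FALSE)
  if (k > length(candidates)) {
    stop("k exceeds the number of removable (non-fisheries) species", call. = FALSE)
  }
  L0 <- n_links(web)
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(reps), function(r) {
      drop <- sample(candidates, k)
      sub <- remove_nodes(web, drop)
      ms <- tryCatch(mean(swtl(sub)), error = function(e) NA_real_)
      tibble::tibble(
        rep = r, S = n_species(sub), L = n_links(sub),
        connectance = ifelse(n_species(sub) > 0, n_links(sub) / n_species(sub)^2, NA_real_),
        links_lost = L0 - n_links(sub),
        mean_swtl = ms
      )
    })
  })
}
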