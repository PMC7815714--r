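#' Trophic categories recognised by the package
#'
#' Node categories, ordered roughly from the base to the top of the web. The
#' `plankton` and `fisheries` labels are reserved for the (at most one each)
#' plankton and fisheries nodes.
#'
#' @export
fw_categories <- c(
  "producer", "plankton", "filter-feeder", "herbivore",
  "omnivore", "carnivore", "top-predator", "fisheries"
)

#' Construct a food web from node and link tables
#'
#' A food web is an ordered species list with node attributes plus a set of
#' directed consumer-to-resource links. Basal status is derived, never stored:
#' a node is basal when it has no resources of its own (no outgoing
#' consumer-to-resource link). Cannibalistic self-links are legal.
#'
#' @param nodes Data frame with columns `species`, `body_mass`, `category`,
#'   and optionally `harvested` (logical, default `FALSE`), `catch_rank`
#'   (positive integer, `NA` when unranked), `is_plankton` and `is_fisheries`
#'   (logical; default derived from `category`).
#' @param links Data frame with columns `consumer` and `resource`, both
#'   species identifiers present in `nodes`. Duplicated links are dropped
#'   with a warning.
#'
#' @return An object of class `food_web`: a list with tibbles `nodes` and
#'   `links`.
#'
#' @details Invariants enforced at construction: at most one plankton and one
#'   fisheries node; the fisheries node has resources but no consumers; every
#'   non-fisheries node has a positive body mass; when a fisheries node is
#'   present, every harvested species is one of its resources. A node whose
#'   category is `producer` or `plankton` but that has resources of its own
#'   triggers a warning (producers are expected to be basal).
#'
#' @examples
#' nodes <- data.frame(
#'   species = c("alga", "snail", "whelk"),
#'   body_mass = c(1, 10, 100),
#'   category = c("producer", "herbivore", "carnivore")
#' )
#' links <- data.frame(
#'   consumer = c("snail", "whelk"),
#'   resource = c("alga", "snail")
#' )
#' web <- food_web(nodes, links)
#' web
#' @export
food_web <- function(nodes, links) {
  nodes <- tibble::as_tibble(nodes)
  links <- tibble::as_tibble(links)

  required <- c("species", "body_mass", "category")
  missing_cols <- setdiff(required, names(nodes))
  if (length(missing_cols) > 0) {
    stop("node table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!all(c("consumer", "resource") %in% names(links))) {
    stop("link table must have columns 'consumer' and 'resource'", call. = FALSE)
  }
  nodes$species <- as.character(nodes$species)
  if (anyDuplicated(nodes$species)) {
    stop("duplicated species identifiers in node table", call. = FALSE)
  }
  if (!("harvested" %in% names(nodes))) nodes$harvested <- FALSE
  nodes$harvested <- isTRUE_vec(nodes$harvested)
  if (!("catch_rank" %in% names(nodes))) nodes$catch_rank <- NA_integer_
  nodes$catch_rank <- as.integer(nodes$catch_rank)
  if (!("is_plankton" %in% names(nodes))) {
    nodes$is_plankton <- nodes$category == "plankton"
  }
  if (!("is_fisheries" %in% names(nodes))) {
    nodes$is_fisheries <- nodes$category == "fisheries"
  }
  nodes$is_plankton <- isTRUE_vec(nodes$is_plankton)
  nodes$is_fisheries <- isTRUE_vec(nodes$is_fisheries)
  bad_cat <- setdiff(unique(nodes$category), fw_categories)
  if (length(bad_cat) > 0) {
    stop("unknown categories: ", paste(bad_cat, collapse = ", "), call. = FALSE)
  }
  if (sum(nodes$is_plankton) > 1) stop("more than one plankton node", call. = FALSE)
  if (sum(nodes$is_fisheries) > 1) stop("more than one fisheries node", call. = FALSE)

  links$consumer <- as.character(links$consumer)
  links$resource <- as.character(links$resource)
  unknown <- setdiff(unique(c(links$consumer, links$resource)), nodes$species)
  if (length(unknown) > 0) {
    stop("link endpoints not in node table: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  dup <- duplicated(paste(links$consumer, links$resource, sep = "\r"))
  if (any(dup)) {
    warning(sum(dup), " duplicated link(s) dropped", call. = FALSE)
    links <- links[!dup, , drop = FALSE]
  }

  no_mass <- !nodes$is_fisheries & (is.na(nodes$body_mass) | nodes$body_mass <= 0)
  if (any(no_mass)) {
    stop("missing or non-positive body mass for: ",
         paste(nodes$species[no_mass], collapse = ", "), call. = FALSE)
  }

  fisheries <- nodes$species[nodes$is_fisheries]
  if (length(fisheries) == 1) {
    if (fisheries %in% links$resource) {
      stop("the fisheries node must have no consumers", call. = FALSE)
    }
    if (!(fisheries %in% links$consumer)) {
      stop("the fisheries node must have at least one resource", call. = FALSE)
    }
    f_prey <- links$resource[links$consumer == fisheries]
    uncovered <- setdiff(nodes$species[nodes$harvested], f_prey)
    if (length(uncovered) > 0) {
      stop("harvested species not linked to the fisheries node: ",
           paste(uncovered, collapse = ", "), call. = FALSE)
    }
  }

  prod_like <- nodes$category %in% c("producer", "plankton")
  has_resources <- nodes$species %in% links$consumer
  if (any(prod_like & has_resources)) {
    warning("producer/plankton node(s) with resources of their own: ",
            paste(nodes$species[prod_like & has_resources], collapse = ", "),
            call. = FALSE)
  }

  structure(
    list(nodes = nodes[, c("species", "body_mass", "category", "harvested",
                           "catch_rank", "is_plankton", "is_fisheries")],
         links = links[, c("consumer", "resource")]),
    class = "food_web"
  )
}

isTRUE_vec <- function(x) {
  out <- as.logical(x)
  out[is.na(out)] <- FALSE
  out
}

#' @export
print.food_web <- function(x, ...) {
  b <- basal_species(x)
  cat("<food_web> ", n_species(x), " species, ", n_links(x), " links\n", sep = "")
  cat("  basal: ", length(b),
      "; harvested: ", sum(x$nodes$harvested),
      "; plankton node: ", if (any(x$nodes$is_plankton)) "yes" else "no",
      "; fisheries node: ", if (any(x$nodes$is_fisheries)) "yes" else "no",
      "\n", sep = "")
  invisible(x)
}

#' Number of species / links in a food web
#' @param web A `food_web`.
#' @return Integer count.
#' @export
n_species <- function(web) nrow(web$nodes)

#' @rdname n_species
#' @export
n_links <- function(web) nrow(web$links)

#' Basal species of a food web
#'
#' A species is basal when it has no resources of its own (no outgoing
#' consumer-to-resource link). The plankton node, which consumes nothing
#' locally, is basal by this rule.
#'
#' @param web A `food_web`.
#' @return Character vector of basal species identifiers.
#' @export
basal_species <- function(web) {
  setdiff(web$nodes$species, unique(web$links$consumer))
}

#' Species identifier of the plankton / fisheries node (or NA)
#' @param web A `food_web`.
#' @return Length-1 character, `NA` if the node is absent.
#' @export
plankton_node <- function(web) {
  s <- web$nodes$species[web$nodes$is_plankton]
  if (length(s) == 0) NA_character_ else s
}

#' @rdname plankton_node
#' @export
fisheries_node <- function(web) {
  s <- web$nodes$species[web$nodes$is_fisheries]
  if (length(s) == 0) NA_character_ else s
}

#' Species that can be primarily removed in deletion sequences
#'
#' All species except the fisheries node, which represents human exploitation
#' rather than a biological population and is never deleted or secondarily
#' extinct.
#'
#' @param web A `food_web`.
#' @return Character vector.
#' @export
removable_species <- function(web) {
  setdiff(web$nodes$species, fisheries_node(web))
}

#' Remove nodes from a food web
#'
#' Returns the induced sub-web on the surviving species: all links incident to
#' a removed node are dropped, every node attribute is preserved.
#'
#' @param web A `food_web`.
#' @param nodes Character vector of species to remove (may be empty).
#' @return A `food_web`.
#' @examples
#' web <- fixture_chain()
#' remove_nodes(web, "P")
#' @export
remove_nodes <- function(web, nodes) {
  nodes <- unique(as.character(nodes))
  unknown <- setdiff(nodes, web$nodes$species)
  if (length(unknown) > 0) {
    stop("unknown node(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  keep_nodes <- web$nodes[!(web$nodes$species %in% nodes), , drop = FALSE]
  keep_links <- web$links[!(web$links$consumer %in% nodes) &
                            !(web$links$resource %in% nodes), , drop = FALSE]
  out <- list(nodes = keep_nodes, links = keep_links)
  class(out) <- "food_web"
  out
}

#' Read a food web from edge-list and node-table CSV files
#'
#' The edge list has header `consumer,resource`; the node table has header
#' `species,body_mass,category,harvested,catch_rank,is_plankton,is_fisheries`
#' (the last four columns optional). Loading is order-stable: node order in
#' the file is the species order of the web.
#'
#' @param edge_file Path to the edge-list CSV.
#' @param node_file Path to the node-table CSV.
#' @return A `food_web`.
#' @seealso [write_foodweb()]
#' @export
load_foodweb <- function(edge_file, node_file) {
  if (!file.exists(edge_file)) stop("edge file not found: ", edge_file, call. = FALSE)
  if (!file.exists(node_file)) stop("node file not found: ", node_file, call. = FALSE)
  links <- readr::read_csv(edge_file, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  nodes <- readr::read_csv(node_file, show_col_types = FALSE)
  food_web(nodes, links)
}

#' Write a food web as edge-list and node-table CSV files
#'
#' @param web A `food_web`.
#' @param edge_file,node_file Output paths.
#' @return Invisibly, `web`.
#' @export
write_foodweb <- function(web, edge_file, node_file) {
  readr::write_csv(web$links, edge_file)
  readr::write_csv(web$nodes, node_file)
  invisible(web)
}

# Integer-indexed adjacency used by the cascade engine and the sequence
# generators. Self-links are excluded: a cannibal cannot sustain itself once
# every other resource is gone.
fw_index <- function(web) {
  sp <- web$nodes$species
  n <- length(sp)
  ci <- match(web$links$consumer, sp)
  ri <- match(web$links$resource, sp)
  keep <- ci != ri
  ci2 <- ci[keep]
  ri2 <- ri[keep]
  cons_of <- split(ci2, factor(ri2, levels = seq_len(n)))
  res_of <- split(ri2, factor(ci2, levels = seq_len(n)))
  n_res <- lengths(res_of)
  fid <- which(web$nodes$is_fisheries)
  list(
    species = sp, n = n,
    ci = ci, ri = ri,             # all links, self-links included
    cons_of = cons_of, res_of = res_of,
    n_res = n_res,
    basal = n_res == 0,
    fisheries = if (length(fid)) fid else NA_integer_
  )
}
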