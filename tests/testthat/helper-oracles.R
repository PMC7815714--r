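# Independent brute-force oracles and random-web helpers shared by the test
# files. These deliberately re-derive behaviour from first principles (naive
# set iteration over the raw link table) rather than reusing any package
# internals.

# Naive fixpoint of the bottom-up extinction rule: rescan every survivor
# until nothing changes. Self-links never sustain their owner.
naive_cascade <- function(web, removed) {
  fish <- fisheries_node(web)
  dead <- as.character(removed)
  repeat {
    grew <- FALSE
    for (s in setdiff(web$nodes$species, dead)) {
      if (identical(s, fish)) next
      res <- setdiff(web$links$resource[web$links$consumer == s], s)
      if (length(res) > 0 && all(res %in% dead)) {
        dead <- c(dead, s)
        grew <- TRUE
      }
    }
    if (!grew) break
  }
  setdiff(dead, as.character(removed))
}

# Naive sequential deletion run: cumulative secondary extinctions per step,
# where a species that starved before its own removal step stays counted as
# secondary.
naive_run_secondary <- function(web, order) {
  dead <- character(0)
  sec <- character(0)
  out <- integer(length(order))
  for (k in seq_along(order)) {
    prefix <- order[seq_len(k)]
    dead_k <- union(prefix, naive_cascade(web, prefix))
    sec <- union(sec, setdiff(setdiff(dead_k, dead), prefix))
    dead <- dead_k
    out[k] <- length(sec)
  }
  out
}

# Random test web: ns nodes, each non-basal node consumes a random subset of
# the others (possibly forming cycles, possibly cannibal). Node 1..n_basal
# are kept resource-free.
random_test_web <- function(ns, n_basal = max(1, round(ns / 3)), p = 0.3,
                            cannibals = FALSE, seed = NULL) {
  if (!is.null(seed)) return(withr::with_seed(seed, random_test_web(ns, n_basal, p, cannibals)))
  sp <- sprintf("n%02d", seq_len(ns))
  links <- NULL
  for (i in seq.int(n_basal + 1, ns)) {
    pool <- if (cannibals) sp else sp[-i]
    res <- pool[stats::runif(length(pool)) < p]
    if (length(res) == 0) res <- sample(sp[seq_len(i - 1)], 1)
    links <- rbind(links, data.frame(consumer = sp[i], resource = res))
  }
  has_res <- sp %in% links$consumer
  food_web(
    data.frame(species = sp, body_mass = 1,
               category = ifelse(has_res, "omnivore", "producer")),
    links
  )
}

# All permutations of a short character vector.
combinat_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in combinat_perms(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
  }
  out
}

# Small dynamic test helpers -------------------------------------------------

lone_producer_params <- function(K = 1, s = 0, category = "producer") {
  web <- food_web(
    tibble::tibble(species = "P", body_mass = 1, category = category),
    tibble::tibble(consumer = character(0), resource = character(0))
  )
  atn_params(web, K = K, s = s)
}
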