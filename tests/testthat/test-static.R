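test_that("cascade propagates starvation and matches the brute-force oracle", {
  chain <- fixture_chain()
  expect_equal(sort(cascade(chain, "P")), c("C", "H"))
  expect_equal(cascade(chain, character(0)), character(0))
  expect_equal(cascade(chain, "C"), character(0))   # top-down loss stops there

  # random webs with cycles and cannibals against the naive fixpoint
  for (s in 1:40) {
    web <- random_test_web(sample(4:12, 1), cannibals = s %% 2 == 0, seed = s)
    removed <- withr::with_seed(s, sample(web$nodes$species,
                                          sample.int(n_species(web) - 1, 1)))
    expect_equal(sort(cascade(web, removed)), sort(naive_cascade(web, removed)),
                 info = paste("seed", s))
  }
})

test_that("cascade is monotone and idempotent", {
  for (s in 1:15) {
    web <- random_test_web(10, seed = s)
    sp <- web$nodes$species
    r1 <- withr::with_seed(s, sample(sp, 2))
    r2 <- withr::with_seed(s + 100, c(r1, sample(setdiff(sp, r1), 2)))
    e1 <- cascade(web, r1)
    e2 <- cascade(web, r2)
    expect_true(all(e1 %in% union(e2, r2)))
    # idempotence: the closure is stable
    expect_equal(cascade(web, union(r1, e1)), character(0))
  }
})

test_that("plankton removal starves exactly the filter-feeder clique", {
  gen <- generate_web(synth_spec(S = 60, seed = 2))
  web <- gen$web
  ffs <- web$nodes$species[web$nodes$category == "filter-feeder"]
  sec <- cascade(web, plankton_node(web))
  expect_equal(sort(sec), sort(ffs))
})

test_that("harvesting order follows catch rank with seeded ties", {
  web <- food_web(
    tibble::tibble(species = c("a", "b", "c"), body_mass = 1,
                   category = "producer",
                   harvested = c(TRUE, TRUE, FALSE),
                   catch_rank = c(2L, 1L, NA)),
    tibble::tibble(consumer = character(0), resource = character(0))
  )
  expect_equal(harvesting_order(web), c("b", "a"))
  expect_equal(harvesting_order(remove_nodes(web, c("a", "b"))), character(0))

  noranked <- food_web(
    tibble::tibble(species = "a", body_mass = 1, category = "producer",
                   harvested = TRUE, catch_rank = NA_integer_),
    tibble::tibble(consumer = character(0), resource = character(0))
  )
  expect_error(harvesting_order(noranked), "catch_rank")

  gen <- generate_web(synth_spec(seed = 4))
  expect_length(harvesting_order(gen$web), 22)
})

test_that("most-connected order removes the hub first and is seed-stable", {
  star <- fixture_star()
  expect_equal(most_connected_order(star, 1)[1], "hub")
  expect_equal(most_connected_order(star, 5), most_connected_order(star, 5))
  # the fisheries node is never in any deletion order
  gen <- generate_web(synth_spec(S = 25, seed = 8))
  ord <- most_connected_order(gen$web, 3)
  expect_setequal(ord, removable_species(gen$web))
  expect_false(fisheries_node(gen$web) %in% ord)
})

test_that("ties in the most-connected order are broken uniformly", {
  # three leaves with identical degree under one hub: each should lead the
  # leaf-block equally often across seeds
  web <- food_web(
    tibble::tibble(species = c("hub", "l1", "l2", "l3"), body_mass = 1,
                   category = c("herbivore", rep("producer", 3))),
    tibble::tibble(consumer = "hub", resource = c("l1", "l2", "l3"))
  )
  firsts <- vapply(1:300, function(s) most_connected_order(web, s)[2], character(1))
  tab <- table(factor(firsts, levels = c("l1", "l2", "l3")))
  expect_gt(stats::chisq.test(tab)$p.value, 1e-4)
})

test_that("supporting-basal order targets basal species feeding hubs", {
  # star: each leaf scores deg 1 x (1 + hub degree 4) = 5, the hub only
  # 4 x (1 + 0) = 4, so a basal leaf leads despite the hub's higher degree
  expect_true(supporting_basal_order(fixture_star(), 1)[1] != "hub")

  # hand-scored 4-node web: hub 3*(1+1)=6 beats b1/b2 1*(1+3)=4 and k 1*(1+0)=1
  web <- food_web(
    tibble::tibble(species = c("b1", "b2", "hub", "k"), body_mass = 1,
                   category = c("producer", "producer", "omnivore", "carnivore")),
    tibble::tibble(consumer = c("hub", "hub", "k"),
                   resource = c("b1", "b2", "hub"))
  )
  expect_equal(supporting_basal_order(web, 1)[1], "hub")

  # on a subsidised synthetic web, no single removal is more damaging than
  # plankton, which starves the whole filter-feeder clique
  gen <- generate_web(synth_spec(S = 60, seed = 6))
  losses <- vapply(removable_species(gen$web),
                   function(s) length(cascade(gen$web, s)), numeric(1))
  expect_equal(names(which.max(losses)), plankton_node(gen$web))
  expect_setequal(supporting_basal_order(gen$web, 1), removable_species(gen$web))
})

test_that("static sequence bookkeeping matches the naive sequential oracle", {
  for (s in 1:10) {
    web <- random_test_web(9, seed = s)
    ord <- withr::with_seed(s, sample(removable_species(web)))
    run <- run_static_sequence(web, ord)
    expect_equal(run$steps$n_secondary, naive_run_secondary(web, ord))
    expect_true(all(diff(run$steps$n_secondary) >= 0))
  }
})

test_that("R50 is bounded and hits 0.5 exactly on consumer-free webs", {
  web <- food_web(
    tibble::tibble(species = letters[1:6], body_mass = 1, category = "producer"),
    tibble::tibble(consumer = character(0), resource = character(0))
  )
  run <- run_static_sequence(web, letters[1:6])
  expect_equal(run$r50, 0.5)
  expect_true(all(run$steps$n_secondary == 0))

  # chain: first removal kills everything
  run2 <- run_static_sequence(fixture_chain(), c("P", "H", "C"))
  expect_equal(run2$r50, 1 / 3)

  for (s in 1:10) {
    web <- random_test_web(10, seed = s)  # even S keeps the upper bound exact
    ord <- withr::with_seed(s, sample(removable_species(web)))
    r50 <- run_static_sequence(web, ord)$r50
    expect_gte(r50, 1 / n_species(web))
    expect_lte(r50, 0.5)
  }

  # a prefix sequence that never reaches half the web leaves R50 undefined
  gen <- generate_web(synth_spec(S = 40, seed = 2))
  hrun <- run_static_sequence(gen$web, harvesting_order(gen$web))
  expect_true(is.na(hrun$r50) ||
                max(hrun$steps$n_primary + hrun$steps$n_secondary) >=
                  ceiling(n_species(gen$web) / 2))
})

test_that("random-sequence summary matches exhaustive enumeration on a tiny web", {
  web <- food_web(
    tibble::tibble(species = c("p1", "p2", "h", "c"), body_mass = 1,
                   category = c("producer", "producer", "herbivore", "carnivore")),
    tibble::tibble(consumer = c("h", "h", "c"), resource = c("p1", "p2", "h"))
  )
  perms <- combinat_perms(web$nodes$species)
  exact <- rowMeans(vapply(perms, function(o) naive_run_secondary(web, o),
                           numeric(4)))
  rs <- random_sequences(web, reps = 3000, seed = 11)
  expect_lt(max(abs(rs$summary$mean_secondary - exact)), 0.05)
  # determinism and CI sanity
  rs2 <- random_sequences(web, reps = 50, seed = 9)
  expect_equal(rs2$summary, random_sequences(web, reps = 50, seed = 9)$summary)
  expect_true(all(rs2$summary$ci_lo <= rs2$summary$mean_secondary + 1e-12))

  # consumer-free web: zero secondary everywhere, zero-width CI
  flat <- food_web(
    tibble::tibble(species = letters[1:4], body_mass = 1, category = "producer"),
    tibble::tibble(consumer = character(0), resource = character(0))
  )
  rf <- random_sequences(flat, reps = 10, seed = 1)
  expect_true(all(rf$summary$mean_secondary == 0))
  expect_true(all(rf$summary$ci_hi == 0))
})
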