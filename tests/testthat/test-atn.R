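test_that("allometric rates follow the quarter-power normalisations", {
  # producers at 1x and 16x the reference mass; consumer at the reference mass
  rt <- build_rates(c(1, 16, 1), c(TRUE, TRUE, FALSE))
  expect_equal(rt$r[1], 1)            # reference producer
  expect_equal(rt$r[2], 16^(-0.25))   # = 0.5
  expect_equal(rt$x[3], 0.314 / 1)    # a_x / a_r at mass ratio 1
  expect_equal(rt$y, 2.512 / 0.314)

  expect_error(build_rates(c(1, 2), c(FALSE, FALSE)), "no producer")
  expect_error(build_rates(c(1, -2), c(TRUE, FALSE)), "mass")

  # y is the same for every consumer in any parameter set
  gen <- generate_web(synth_spec(S = 30, seed = 3))
  expect_length(gen$params$y, 1)
})

test_that("functional response satisfies its algebraic identities", {
  single <- food_web(
    tibble::tibble(species = c("r", "c"), body_mass = c(1, 10),
                   category = c("producer", "herbivore")),
    tibble::tibble(consumer = "c", resource = "r")
  )
  for (q in c(1, 1.2, 2)) {
    p <- atn_params(single, q = q, B0 = 0.7, d = 0, K = 1)
    # resource at half-saturation -> exactly 1/2, any exponent
    expect_equal(functional_response(c(r = 0.7, c = 1), p)$F, 0.5,
                 tolerance = 1e-12)
    # absent resource -> exactly zero
    expect_equal(functional_response(c(r = 0, c = 1), p)$F, 0)
  }

  # two equal resources at B0 with omega = 1/2 each, hand-evaluated
  two <- food_web(
    tibble::tibble(species = c("r1", "r2", "c"), body_mass = c(1, 1, 10),
                   category = c("producer", "producer", "herbivore")),
    tibble::tibble(consumer = c("c", "c"), resource = c("r1", "r2"))
  )
  q <- 1.2; B0 <- 0.5
  p2 <- atn_params(two, q = q, B0 = B0, d = 0, K = 1)
  Fv <- functional_response(c(r1 = B0, r2 = B0, c = 1), p2)$F
  hand <- 0.5 * B0^q / (B0^q + 0.5 * B0^q + 0.5 * B0^q)
  expect_equal(Fv, rep(hand, 2), tolerance = 1e-12)

  # interference raises the denominator
  p3 <- atn_params(single, d = 2, B0 = 0.7, K = 1)
  expect_lt(functional_response(c(r = 0.7, c = 1), p3)$F, 0.5)
  # response stays in [0, 1)
  for (B in list(c(5, 5), c(100, 0.1), c(0.01, 3))) {
    f <- functional_response(stats::setNames(c(B, 1), c("r1", "r2", "c")), p2)$F
    expect_true(all(f >= 0 & f < 1))
  }
})

test_that("derivatives match a term-by-term hand evaluation on a chain", {
  p <- atn_params(fixture_chain(), K = 2, B0 = 0.4, d = 0.3, q = 1.2)
  B <- c(P = 0.9, H = 0.3, C = 0.08)

  # independent scalar evaluation of the producer/consumer equations
  xH <- 0.314 * 10^(-0.25); xC <- 0.314 * 100^(-0.25); y <- 2.512 / 0.314
  F_HP <- 0.9^1.2 / (0.4^1.2 + 0.3 * 0.3 * 0.4 + 0.9^1.2)
  F_CH <- 0.3^1.2 / (0.4^1.2 + 0.3 * 0.08 * 0.4 + 0.3^1.2)
  dP <- 1 * 0.9 * (1 - 0.9 / 2) - xH * y * 0.3 * F_HP / 0.45
  dH <- 0.4 * xH * 0.3 * y * F_HP - 0.1 * xH * 0.3 - xC * y * 0.08 * F_CH / 0.85
  dC <- 0.4 * xC * 0.08 * y * F_CH - 0.1 * xC * 0.08

  got <- atn_derivatives(B, p)
  expect_equal(unname(got), c(dP, dH, dC), tolerance = 1e-12)

  # logistic equilibrium: lone producer at K has zero derivative
  lp <- lone_producer_params(K = 1)
  expect_equal(unname(atn_derivatives(c(P = 1), lp)), 0)

  # everything dead but a subsidised plankton: only the subsidy remains
  pk <- atn_params(fixture_plankton_ff(), s = 3, K = 1)
  d0 <- atn_derivatives(c(plankton = 0, ff = 0), pk)
  expect_equal(unname(d0), c(3, 0))

  expect_error(atn_derivatives(c(P = 1), p), "length")
})

test_that("fishing mortality enters producers and consumers as a linear loss", {
  lp <- lone_producer_params(K = 1)
  lpf <- coastweb:::set_fmax(lp, c(P = 0.2))
  expect_equal(unname(atn_derivatives(c(P = 0.5), lpf) -
                        atn_derivatives(c(P = 0.5), lp)), -0.2 * 0.5)
})

test_that("integration reaches the logistic and subsidised equilibria", {
  lp <- lone_producer_params(K = 1)
  tr <- atn_integrate(lp, c(P = 0.05), T = 400)
  expect_true(all(diff(tr$B[, 1]) >= -1e-10))      # monotone approach
  expect_lt(abs(final_biomass(tr)[["P"]] - 1), 1e-4)

  # subsidised plankton equilibrium against the root-finding oracle
  pp <- lone_producer_params(K = 1, s = 5, category = "plankton")
  eq <- equilibrate(pp, c(P = 0.1))
  root <- stats::uniroot(function(B) B * (1 - B) + 5, c(1, 1e3), tol = 1e-12)$root
  expect_lt(abs(eq$B[["P"]] - root), 1e-6)
  expect_true(eq$stationary)

  # without the subsidy the plankton node is an ordinary producer
  pp0 <- coastweb:::set_subsidy(pp, 0)
  lp2 <- lone_producer_params(K = 1, s = 0)
  expect_equal(unname(atn_derivatives(c(P = 0.3), pp0)),
               unname(atn_derivatives(c(P = 0.3), lp2)))
})

test_that("a consumer without resources starves, is logged and clamped", {
  p <- atn_params(fixture_chain(), K = 1)
  tr <- atn_integrate(p, c(P = 0, H = 0.5, C = 0.01), T = 3650)
  expect_setequal(tr$extinct$species, c("P", "H", "C"))
  expect_equal(tr$extinct$time[tr$extinct$species == "P"], 0)
  # once logged extinct, biomass is identically zero afterwards
  tH <- tr$extinct$time[tr$extinct$species == "H"]
  expect_true(all(tr$B[tr$times >= tH, "H"] == 0))
  # no negative biomass anywhere
  expect_true(all(tr$B >= 0))
})

test_that("trajectories are deterministic and reject bad input", {
  gen <- generate_web(synth_spec(S = 15, seed = 5))
  B0 <- atn_initial_biomass(gen$params, 2)
  t1 <- atn_integrate(gen$params, B0, T = 200)
  t2 <- atn_integrate(gen$params, B0, T = 200)
  expect_identical(t1$B, t2$B)
  expect_error(atn_integrate(gen$params, -B0, T = 10), "negative")
  expect_true(all(t1$B >= 0))
})

test_that("dynamic starvation includes every static secondary extinction", {
  # chain: static removal of P dooms H and C; dynamically they also starve
  p <- atn_params(fixture_chain(), K = 1)
  static_sec <- cascade(fixture_chain(), "P")
  tr <- atn_integrate(p, c(P = 0, H = 0.4, C = 0.05), T = 3650)
  expect_true(all(static_sec %in% tr$extinct$species))

  # plankton/filter-feeder pair: cutting the subsidy AND the plankton node
  web <- fixture_plankton_ff()
  pf <- attr(web, "params")
  expect_equal(cascade(web, "plankton"), "ff")
  trf <- atn_integrate(pf, c(plankton = 0, ff = 1), T = 3650)
  expect_true("ff" %in% trf$extinct$species)
})

test_that("the plankton+filter-feeder fixture needs its subsidy", {
  web <- fixture_plankton_ff()
  pf <- attr(web, "params")
  eq <- equilibrate(pf, c(plankton = 1, ff = 0.5))
  expect_true(all(eq$B > 0))
  # feeder equilibrium sits at its break-even plankton density: F = f_m/(f_a y)
  Fbe <- 0.4 / (0.5 * 2)
  B_be <- 2 * (Fbe / (1 - Fbe))^(1 / 1.2)   # solve F(B) = Fbe with B0 = 2
  expect_equal(eq$B[["plankton"]], B_be, tolerance = 1e-3)

  # s -> 0: plankton can never exceed K = 1 < break-even, the feeder starves
  eq0 <- equilibrate(coastweb:::set_subsidy(pf, 0), eq$B)
  expect_equal(eq0$B[["ff"]], 0)
  expect_gt(eq0$B[["plankton"]], 0)
})

test_that("a perturbed producer growth rate is recoverable from a trajectory", {
  gen <- generate_web(synth_spec(S = 10, C = 0.15, seed = 4))
  p <- gen$params
  prod1 <- p$species[p$producer_idx[1]]
  true_fac <- 1.3
  p_true <- p
  p_true$r[p$producer_idx[1]] <- p$r[p$producer_idx[1]] * true_fac
  B0 <- atn_initial_biomass(p, 3)
  obs <- atn_integrate(p_true, B0, T = 120)$B

  sse <- function(fac) {
    pf <- p
    pf$r[p$producer_idx[1]] <- p$r[p$producer_idx[1]] * fac
    sum((atn_integrate(pf, B0, T = 120)$B - obs)^2)
  }
  fit <- stats::optimize(sse, c(0.5, 2))
  expect_lt(abs(fit$minimum - true_fac) / true_fac, 0.05)
})
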