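test_that("the Gaussian niche function is max-normalized and scale invariant", {
  expect_identical(gauss(3, 2, 3), 1)
  expect_equal(gauss(0, 1, 1), exp(-0.5))
  expect_equal(gauss(0, 2, 2), gauss(0, 1, 1))
  expect_error(gauss(0, 0, 1), "positive")
  expect_error(gauss(0, -1, 1), "positive")
})

test_that("adaptation is the product of the two niche components", {
  isl <- build_island()
  patch <- patch_at(isl, 0, 2)
  tr <- trait_defaults
  tr["temp_opt"] <- patch$temperature
  tr["precip_opt"] <- patch$precipitation
  expect_equal(adaptation(tr, patch)$combined, 1)

  tr["precip_opt"] <- patch$precipitation + tr["precip_tol"]
  a <- adaptation(tr, patch)
  expect_equal(a$combined, exp(-0.5))

  set.seed(3)
  for (i in 1:50) {
    tr2 <- trait_defaults
    tr2["temp_opt"] <- runif(1, -10, 50)
    tr2["precip_opt"] <- runif(1, -10, 20)
    a2 <- adaptation(tr2, patch)
    expect_lte(a2$combined, min(a2$temp, a2$precip))
    expect_gt(a2$combined, 0)
  }
})

test_that("metabolic rates scale with mass and temperature", {
  cst <- mte_constants()
  # temperature-independent limit
  cst0 <- mte_constants(activation_energy = 0)
  expect_equal(mte_rate(256, 10, 0.75, 2, cst0), 2 * 256^0.75)
  # quarter-power scaling: a 16-fold mass gain halves the specific rate
  expect_equal(mte_rate(100, 20, -0.25, cst$m0, cst) /
                 mte_rate(1600, 20, -0.25, cst$m0, cst), 2)
  # Arrhenius monotonicity
  for (m in c(150, 1000, 1.2e6))
    expect_gt(mte_rate(m, 25, 0.75, cst$g0, cst),
              mte_rate(m, 15, 0.75, cst$g0, cst))
  # calibration anchor: the reference plant has the reference mortality
  expect_equal(mte_rate(1000, 20, -0.25, cst$m0, cst), 0.05)
})

test_that("survival mortality follows the binomial with the stated hazard", {
  isl <- build_island(side = 3, base_temperature = 20)
  cst <- mte_constants()
  # zero baseline hazard: nobody dies
  cst0 <- cst
  cst0$m0 <- 0
  pop <- make_pop(n = 500, mass = 1000)
  res <- survival_step(pop, isl, cst0)
  expect_equal(res$n_removed, 0L)

  # halving the temperature adaptation doubles the raw hazard
  p1 <- invasim:::survival_probability(make_pop(n = 1, mass = 1000, at = 1),
                                       isl, cst)
  p2 <- invasim:::survival_probability(make_pop(n = 1, mass = 1000, at = 0.5),
                                       isl, cst)
  expect_equal(p2 / p1, 2)

  # Monte-Carlo: 10,000 identical plants at p = 0.1
  cst1 <- cst
  cst1$m0 <- 0.1 * 1000^0.25 / exp(-cst$E / (cst$k * (20 + 273.15)))
  big <- make_pop(n = 10000, mass = 1000)
  set.seed(41)
  res <- survival_step(big, isl, cst1)
  expect_lt(abs(res$n_removed - 1000), 3 * sqrt(10000 * 0.1 * 0.9))
})

test_that("growth stops at reproductive size and accelerates with warmth", {
  isl <- build_island(side = 3, base_temperature = 20)
  cst <- mte_constants()
  adult <- make_pop(n = 1, mass = 1000)
  expect_equal(growth_step(adult, isl, cst)$mass, 1000)

  cst0 <- cst
  cst0$g0 <- 0
  juv <- make_pop(n = 1, mass = 10)
  expect_equal(growth_step(juv, isl, cst0)$mass, 10)

  # same juvenile in a warmer patch grows strictly faster
  warm <- build_island(side = 3, base_temperature = 30)
  expect_gt(growth_step(juv, warm, cst)$mass,
            growth_step(juv, isl, cst)$mass)

  # ten years take the reference 1 g seed to about the reference mass
  m <- 1
  for (y in 1:10) {
    p <- make_pop(n = 1, mass = m, adult_mass = 2000)
    m <- growth_step(p, isl, cst)$mass
  }
  expect_gt(m, 700)
  expect_lt(m, 1500)
})

test_that("competition enforces the biomass carrying capacity", {
  isl <- build_island(side = 3)
  # below capacity: nothing happens
  pop <- make_pop(n = 3, mass = 1000)
  expect_equal(competition_step(pop, isl)$n_removed, 0L)

  # two plants over capacity: the lower precipitation adaptation loses
  pop2 <- make_pop(n = 2, mass = 1.2e6, ap = c(0.9, 0.2))
  res <- competition_step(pop2, isl)
  expect_equal(res$n_removed, 1L)
  expect_equal(res$pop$ap, 0.9)

  # random overloaded patches always end at or below capacity (or 1 plant)
  set.seed(17)
  for (i in 1:20) {
    n <- sample(2:400, 1)
    pop3 <- make_pop(n = n, mass = runif(n, 100, 3e4),
                     ap = runif(n), patch = sample(1:9, n, replace = TRUE))
    pop3$mass <- pop3$mass * sample(c(1, 100), n, replace = TRUE)
    out <- competition_step(pop3, isl)
    bm <- invasim:::pop_biomass_by_patch(out$pop, 9)
    cnt <- tabulate(out$pop$patch, 9)
    expect_true(all(bm <= 2e6 | cnt <= 1))
  }
})

test_that("reproduction needs a local conspecific partner and scales with allocation", {
  isl <- build_island(side = 3, base_temperature = 20)
  cst <- mte_constants()
  arch <- invasim:::trait_architecture()

  # a lone adult produces nothing (no selfing)
  lone <- make_pop(n = 1, mass = 1000)
  expect_equal(invasim:::pop_size(reproduction_step(lone, isl, cst, arch)), 0L)
  # two adults of different species in one patch: still nothing
  mixed <- make_pop(n = 2, species = c(1L, 2L), mass = 1000)
  expect_equal(invasim:::pop_size(reproduction_step(mixed, isl, cst, arch)), 0L)
  # juveniles do not reproduce
  juv <- make_pop(n = 2, mass = 500)
  expect_equal(invasim:::pop_size(reproduction_step(juv, isl, cst, arch)), 0L)

  # seed count per mother matches the fecundity allocation
  pair <- make_pop(n = 2, mass = 1000)
  arr <- exp(-cst$E / (cst$k * (20 + 273.15)))
  expected <- round(cst$f0 * 1000^0.75 * arr / 10)
  set.seed(8)
  seeds <- reproduction_step(pair, isl, cst, arch)
  expect_equal(invasim:::pop_size(seeds), 2 * expected)
  expect_true(all(seeds$patch == 1L))

  # doubling the fecundity coefficient doubles the output
  cst2 <- cst
  cst2$f0 <- 2 * cst$f0
  set.seed(8)
  seeds2 <- reproduction_step(pair, isl, cst2, arch)
  expect_equal(invasim:::pop_size(seeds2), 2 * invasim:::pop_size(seeds))

  # halving seed mass doubles the seed count for the same allocation
  light <- make_pop(n = 2, mass = 1000, seed_mass = 5)
  set.seed(8)
  seeds3 <- reproduction_step(light, isl, cst, arch)
  expect_equal(invasim:::pop_size(seeds3), 2 * round(cst$f0 * 1000^0.75 * arr / 5))
})

test_that("disturbance removes the stated fraction at random", {
  expect_error(disturbance_step(make_pop(n = 2), 1.5))
  pop <- make_pop(n = 1000, mass = 500)
  expect_equal(disturbance_step(pop, 0)$n_removed, 0L)
  expect_equal(disturbance_step(pop, 1)$n_removed, 1000L)
  set.seed(12)
  big <- make_pop(n = 10000, mass = 500)
  res <- disturbance_step(big, 0.1)
  expect_lt(abs(res$n_removed - 1000), 3 * sqrt(10000 * 0.1 * 0.9))
})

test_that("transport introduces exactly P uniform draws from the alien pool", {
  isl <- build_island(side = 3)
  ranges <- default_trait_ranges(isl)
  set.seed(14)
  pool <- rbind(random_species_pool(5, ranges, "native"),
                random_species_pool(100, ranges, "alien"))

  tr <- transport_step(isl, pool, pressure = 10, year = 101, burn_in = 100)
  expect_equal(tr$attempted, 10L)
  expect_length(tr$species_drawn, 10)
  expect_true(all(pool$origin[tr$species_drawn] == "alien"))
  expect_true(all(tr$pop$patch == isl$entry_patch))
  expect_true(all(tr$pop$introduced))
  expect_lte(tr$n_established, 10)

  expect_error(transport_step(isl, pool, 10, year = 100, burn_in = 100),
               "burn-in")
  none <- transport_step(isl, pool, 0, year = 101, burn_in = 100)
  expect_equal(none$attempted, 0L)
  expect_length(none$species_drawn, 0)

  # species identities are independent uniform draws across years
  set.seed(15)
  draws <- unlist(lapply(1:10000, function(y)
    transport_step(isl, pool, 1, year = 100 + y, burn_in = 100)$species_drawn))
  counts <- tabulate(draws - 5L, nbins = 100)
  expect_true(all(abs(counts - 100) <= 3 * sqrt(100 * 0.99) + 1))
})

test_that("dispersal distances follow the log-logistic kernel", {
  expect_error(sample_dispersal_distance(10, scale = 1, shape = 1))
  expect_error(sample_dispersal_distance(10, scale = 0, shape = 2))
  set.seed(20)
  d <- sample_dispersal_distance(1e5, scale = 1, shape = 2)
  expect_true(all(d >= 0))
  expect_lt(abs(median(d) - 1), 0.02)
  # heavier tail for smaller shape
  set.seed(20)
  d2 <- sample_dispersal_distance(1e5, scale = 1, shape = 1.2)
  expect_gt(mean(d2 > 4), mean(d > 4))
  expect_equal(dispersal_cdf(1, 1, 2), 0.5)
})

test_that("seeds establish by adaptation where they land, die beyond the border", {
  isl <- build_island(side = 5, base_temperature = 20)
  cst <- mte_constants()
  arch <- invasim:::trait_architecture()
  center <- invasim:::patch_index_at(isl, 2, 2)

  # vanishing kernel scale keeps seeds in the natal patch
  stay <- make_pop(n = 200, patch = center, mass = 10,
                   dispersal_scale = 1e-3, temp_opt = 16, precip_opt = 5)
  set.seed(33)
  res <- dispersal_step(stay, isl)
  expect_equal(res$n_established, 200L)
  expect_true(all(res$pop$patch == center))

  # a hopelessly mismatched phenotype never establishes
  doomed <- make_pop(n = 200, patch = center, mass = 10,
                     temp_opt = 90, temp_tol = 0.02,
                     precip_opt = 90, precip_tol = 0.02)
  set.seed(34)
  res2 <- dispersal_step(doomed, isl)
  expect_equal(res2$n_established, 0L)

  # isotropy: landing directions from the center are uniform by quadrant
  wide <- make_pop(n = 40000, patch = center, mass = 10,
                   dispersal_scale = 1, dispersal_shape = 3,
                   temp_opt = 18, temp_tol = 20, precip_opt = 5,
                   precip_tol = 20)
  set.seed(35)
  res3 <- dispersal_step(wide, isl)
  landed <- res3$pop$patch
  rows <- isl$patches$row[landed]
  cols <- isl$patches$col[landed]
  quad <- c(sum(rows < 2 & cols < 2), sum(rows < 2 & cols > 2),
            sum(rows > 2 & cols < 2), sum(rows > 2 & cols > 2))
  expect_gt(chisq.test(quad)$p.value, 0.01)

  # seeds dispersing beyond the island border die
  corner <- invasim:::patch_index_at(isl, 0, 0)
  edge <- make_pop(n = 5000, patch = corner, mass = 10, dispersal_scale = 2,
                   temp_opt = 20, temp_tol = 20, precip_opt = 0,
                   precip_tol = 20)
  set.seed(36)
  res4 <- dispersal_step(edge, isl)
  expect_gt(res4$n_off_island, 0)
  expect_equal(res4$n_dispersed, 5000L)
  expect_equal(invasim:::pop_size(res4$pop), res4$n_established)
  expect_lte(res4$n_off_island + res4$n_established, 5000L)
})

test_that("a year's processes conserve biomass in the ledger sense", {
  isl <- build_island(side = 3, base_temperature = 20)
  cst <- mte_constants()
  arch <- invasim:::trait_architecture()
  set.seed(55)
  pop <- make_pop(n = 400, mass = runif(400, 10, 5000),
                  patch = sample(1:9, 400, replace = TRUE),
                  temp_opt = 20, precip_opt = 5)
  pop$ap <- runif(400)

  before <- pop_total_mass(pop)
  sv <- survival_step(pop, isl, cst)
  expect_equal(pop_total_mass(sv$pop) + pop_total_mass(sv$removed), before)

  grown <- growth_step(sv$pop, isl, cst)
  growth_gain <- pop_total_mass(grown) - pop_total_mass(sv$pop)
  expect_gte(growth_gain, 0)

  cp <- competition_step(grown, isl)
  expect_equal(pop_total_mass(cp$pop) + pop_total_mass(cp$removed),
               pop_total_mass(grown))

  seeds <- reproduction_step(cp$pop, isl, cst, arch)
  db <- disturbance_step(cp$pop, 0.1)
  expect_equal(pop_total_mass(db$pop) + pop_total_mass(db$removed),
               pop_total_mass(cp$pop))

  dp <- dispersal_step(seeds, isl)
  final <- invasim:::pop_bind(db$pop, dp$pop)
  expect_equal(pop_total_mass(final),
               pop_total_mass(db$pop) + pop_total_mass(dp$pop))
})
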