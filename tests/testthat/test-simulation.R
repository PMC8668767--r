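test_that("scenario configurations validate their keys", {
  cfg <- scenario_config()
  expect_equal(cfg$burn_in, 500L)
  expect_equal(cfg$horizon, 1500L)
  expect_equal(cfg$n_alien_pool, 100L)
  expect_error(scenario_config(propagule = 5), "unknown configuration key")
  expect_error(scenario_config(burn_in = 100, horizon = 50), "burn_in")
  expect_error(scenario_config(disturbance = 2), "disturbance")
})

test_that("YAML configuration files round-trip with loud failures on typos", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("side: 3", "burn_in: 10", "horizon: 20",
               "propagule_pressure: 10"), path)
  cfg <- read_config(path)
  expect_equal(cfg$side, 3)
  expect_equal(cfg$propagule_pressure, 10)
  expect_equal(cfg$disturbance, 0.01)

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("propagul_pressure: 10", bad)
  expect_error(read_config(bad), "unknown configuration key")
})

test_that("initialization fills patches by the inverse-mass founder rule", {
  cfg <- scenario_config(side = 3, n_native_pool = 8, seed = 3)
  world <- initialize_world(cfg)
  pop <- world_population(world)
  isl <- world$island
  natives <- world$pool[world$pool$origin == "native", ]

  expect_equal(sum(world$pool$origin == "alien"), 100)
  expect_equal(world$year, 0L)
  expect_false(any(pop$introduced))

  # oracle: founder count = floor(fill_fraction * capacity / adult_mass) in
  # every patch where the species' mean-trait adaptation clears the threshold
  tally <- table(factor(pop$species, levels = seq_len(nrow(world$pool))),
                 factor(pop$patch, levels = seq_len(nrow(isl$patches))))
  for (s in seq_len(nrow(natives))) {
    for (p in seq_len(nrow(isl$patches))) {
      aind <- gauss(natives$temp_opt[s], natives$temp_tol[s],
                    isl$patches$temperature[p]) *
        gauss(natives$precip_opt[s], natives$precip_tol[s],
              isl$patches$precipitation[p])
      want <- if (aind >= cfg$establishment_threshold)
        floor(cfg$fill_fraction * 2e6 / natives$adult_mass[s]) else 0
      expect_equal(unname(tally[s, p]), want)
    }
  }

  # founders start at adult size, at their own phenotype's adult mass
  expect_true(all(pop$mass == pop$phen[, "adult_mass"]))

  # the same configuration always builds the same initial world
  world2 <- initialize_world(cfg)
  expect_equal(world_population(world2), pop, tolerance = 0)
})

test_that("a fast-path year equals the step-by-step process pipeline", {
  cfg <- scenario_config(side = 3, burn_in = 5, horizon = 20,
                         propagule_pressure = 5L, disturbance = 0.1,
                         n_native_pool = 12, seed = 77)
  world <- initialize_world(cfg)
  for (i in 1:6) world <- run_year(world)
  snap <- world_population(world)
  rng <- .Random.seed

  world <- run_year(world)
  fast <- world_population(world)

  assign(".Random.seed", rng, envir = globalenv())
  isl <- world$island
  cst <- world$constants
  arch <- world$architecture
  sv <- survival_step(snap, isl, cst)
  gr <- growth_step(sv$pop, isl, cst)
  cp <- competition_step(gr, isl)
  seeds <- reproduction_step(cp$pop, isl, cst, arch)
  db <- disturbance_step(cp$pop, cfg$disturbance)
  tr <- transport_step(isl, world$pool, cfg$propagule_pressure, year = 7,
                       burn_in = cfg$burn_in, cv = cfg$cv,
                       architecture = arch,
                       threshold = cfg$establishment_threshold,
                       mode = cfg$establishment_mode)
  dp <- dispersal_step(seeds, isl, cfg$establishment_threshold,
                       cfg$establishment_mode)
  ref <- invasim:::pop_bind(db$pop, tr$pop, dp$pop)

  expect_equal(fast$species, ref$species)
  expect_equal(fast$patch, ref$patch)
  expect_equal(fast$mass, ref$mass, tolerance = 0)
  expect_equal(fast$introduced, ref$introduced)
  expect_equal(fast$h1, ref$h1, tolerance = 0)
  expect_equal(fast$h2, ref$h2, tolerance = 0)
  expect_equal(unname(fast$phen), unname(ref$phen), tolerance = 0)
  expect_equal(fast$at, ref$at, tolerance = 0)
  expect_equal(fast$ap, ref$ap, tolerance = 0)
})

test_that("burn-in shields the island from introductions and disturbance", {
  cfg <- scenario_config(side = 3, burn_in = 10, horizon = 25,
                         propagule_pressure = 10L, disturbance = 0.1,
                         n_native_pool = 10, seed = 9)
  res <- run_scenario(cfg)
  d <- world_diagnostics(res$world)

  expect_equal(d$introductions[d$year <= 10], rep(0, 10))
  expect_equal(d$deaths_disturbance[d$year <= 10], rep(0, 10))
  expect_equal(d$introductions[d$year > 10], rep(10, 15))
  expect_gt(sum(d$deaths_disturbance[d$year > 10]), 0)

  # during burn-in only native species are present
  burnin_census <- res$census[res$census$year <= 10, ]
  expect_true(all(burnin_census$origin == "native"))

  # a burn-in-only run never contains introduced individuals
  cfg2 <- scenario_config(side = 3, burn_in = 15, horizon = 15,
                          n_native_pool = 10, seed = 9)
  res2 <- run_scenario(cfg2)
  expect_false(any(world_population(res2$world)$introduced))
  expect_equal(sum(res2$world$intro_tally), 0L)
})

test_that("an empty island advances without error", {
  cfg <- scenario_config(side = 3, burn_in = 2, horizon = 10,
                         n_native_pool = 5, seed = 31)
  world <- initialize_world(cfg)
  world$pop <- invasim:::world_create_cpp(
    invasim:::pop_empty(world$architecture),
    world$architecture$n_genes, length(TRAIT_NAMES))
  world <- run_year(world)
  expect_equal(world$year, 1L)
  expect_equal(invasim:::world_size_cpp(world$pop), 0L)
})

test_that("census records are taken on schedule and add up", {
  cfg <- scenario_config(side = 3, burn_in = 5, horizon = 20,
                         census_interval = 5L, n_native_pool = 10, seed = 13)
  res <- run_scenario(cfg)
  expect_equal(sort(unique(res$census$year)), c(0, 5, 10, 15, 20))

  fin <- res$census[res$census$year == 20, ]
  expect_equal(sum(fin$abundance), invasim:::world_size_cpp(res$world$pop))
  expect_true(all(fin$abundance >= 1))
  # one row per extant species x patch
  expect_false(any(duplicated(fin[c("species_id", "row", "col")])))
  # map snapshots at the end of burn-in and at the horizon
  expect_equal(sort(unique(res$maps$year)), c(5, 20))
})

test_that("identical seeds give byte-identical run logs", {
  cfg <- scenario_config(side = 3, burn_in = 10, horizon = 30,
                         propagule_pressure = 5L, n_native_pool = 10,
                         seed = 23)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_scenario(cfg, out_dir = d1)
  run_scenario(cfg, out_dir = d2)
  for (f in c("census.tsv", "maps.tsv", "species_pool.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # the census log opens with a reproducibility header
  head1 <- readLines(file.path(d1, "census.tsv"), n = 1)
  expect_match(head1, "^# island:")
})

test_that("the factorial experiment enumerates scenarios and shares pools", {
  cfg <- scenario_config(side = 3, burn_in = 5, horizon = 10,
                         n_native_pool = 8, seed = 2)
  exp <- full_experiment(cfg, replicates = 1L, base_seed = 2)
  expect_equal(nrow(exp$manifest), 8)
  expect_equal(nrow(unique(exp$manifest[c("base_temperature",
                                          "propagule_pressure",
                                          "disturbance")])), 8)
  expect_true(all(table(exp$census$run_id) > 0))

  # scenarios differing only in disturbance share pools within a replicate
  ps <- derive_seed(2, 0L, 1L)
  c1 <- scenario_config(side = 3, disturbance = 0.01, seed = 101,
                        pool_seed = ps, n_native_pool = 8)
  c2 <- scenario_config(side = 3, disturbance = 0.10, seed = 202,
                        pool_seed = ps, n_native_pool = 8)
  expect_identical(initialize_world(c1)$pool, initialize_world(c2)$pool)

  # seed derivation is stable and below 2^31
  expect_identical(derive_seed(1, 3, 7), derive_seed(1, 3, 7))
  expect_true(derive_seed(2^20, 8, 60) < 2^31)
  expect_false(derive_seed(1, 1, 2) == derive_seed(1, 2, 1))

  # an experiment written to disk reloads into the same analysis
  dir <- withr::local_tempdir()
  exp2 <- full_experiment(cfg, replicates = 1L, base_seed = 2, out_dir = dir)
  reloaded <- load_experiment(dir)
  expect_equal(invasion_counts(reloaded), invasion_counts(exp2))
  tt1 <- export_trait_table(exp2)
  tt2 <- export_trait_table(reloaded)
  expect_equal(tt2$adaptation, tt1$adaptation, tolerance = 1e-9)
  expect_equal(tt2$category, tt1$category)
})

test_that("default burn-in reaches quasi-equilibrium richness", {
  reps <- 5
  stable <- logical(reps)
  richness <- integer(reps)
  for (r in seq_len(reps)) {
    cfg <- scenario_config(burn_in = 500L, horizon = 500L, seed = 100 + r)
    res <- run_scenario(cfg)
    r400 <- length(unique(res$census$species_id[res$census$year == 400]))
    r500 <- length(unique(res$census$species_id[res$census$year == 500]))
    stable[r] <- abs(r500 - r400) <= 1
    richness[r] <- r500
  }
  expect_gte(mean(stable), 0.8)
  # surviving native richness lands in the reported 1-15 band
  expect_true(all(richness >= 1 & richness <= 15))
})
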