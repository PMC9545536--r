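test_that("generated panels satisfy the data contract and are reproducible", {
  cfg <- sim_config(n_sites = 6, n_species = 12, seed = 77)
  sim <- generate_panel(cfg)
  expect_silent(validate_biomass_panel(sim$panel))
  expect_true(all(sim$panel$biomass > 0))              # occupancy 1 default
  expect_true(all(sim$climate$precipitation >= 0))
  sim2 <- generate_panel(cfg)
  expect_identical(sim$panel$biomass, sim2$panel$biomass)   # fixed seed
  expect_identical(sim$climate, sim2$climate)

  # 4-vs-5-year option: dropped first years produce shorter site runs
  cfg4 <- sim_config(n_sites = 10, n_species = 6, drop_first_year_frac = 0.5,
                     seed = 13)
  sim4 <- generate_panel(cfg4)
  lens <- vapply(sim4$panel$site_years, length, 1L)
  expect_true(all(lens %in% c(4L, 5L)))
  expect_silent(validate_biomass_panel(sim4$panel))
})

test_that("infeasible configurations are rejected by name", {
  expect_error(sim_config(n_sites = 21, rho_space = -0.5), "PSD")
  expect_error(sim_config(rho_species = -0.2), "rho_species")
  expect_error(sim_config(cv_env = -1), "cv_env")
  expect_error(sim_config(occupancy = 0), "occupancy")
})

test_that("the fully synchronous limit gives synchronies 1 and equal CVs", {
  sim <- generate_panel(sim_config(n_sites = 4, n_species = 6, sad_sigma = 0,
                                   rho_species = 1, rho_space = 1,
                                   site_sigma = 0, seed = 3))
  m <- estimate_moments(sim$panel)
  expect_equal(local_species_synchrony(m), 1, tolerance = 1e-10)
  expect_equal(regional_community_synchrony(m), 1, tolerance = 1e-10)
  expect_equal(regional_population_synchrony(m), 1, tolerance = 1e-10)
  expect_equal(regional_community_cv(m), local_population_cv(m),
               tolerance = 1e-10)
})

test_that("independent sites drive regional community synchrony to M^(-1/2)", {
  M <- 10
  est <- vapply(1:20, function(i) {
    sim <- generate_panel(sim_config(n_sites = M, n_species = 5,
                                     n_years = 150, sad_sigma = 0,
                                     rho_species = 0.5, rho_space = 0,
                                     site_sigma = 0, sigma_log = 0.1,
                                     seed = 100 + i))
    regional_community_synchrony(estimate_moments(sim$panel))
  }, numeric(1))
  expect_equal(mean(est), 1 / sqrt(M), tolerance = 0.05)
})

test_that("a strongly uneven abundance distribution yields a small dominant set", {
  sim <- generate_panel(sim_config(sad_sigma = 2, n_species = 40, seed = 19))
  mask <- dominant_mask(sim$panel, sim$panel$sites[1:2])
  expect_gt(length(mask$dominant), 0)
  expect_lt(length(mask$dominant), 15)
  # dominants carry most of the biomass despite being few
  expect_gt(sum(mask$share[mask$dominant]), 0.5)
})

test_that("estimated synchronies increase with their generating correlations", {
  syn_sp <- vapply(c(0.1, 0.5, 0.9), function(r) {
    mean(vapply(1:8, function(i) {
      sim <- generate_panel(sim_config(n_sites = 1, n_species = 8,
                                       n_years = 100, sad_sigma = 0,
                                       rho_species = r, rho_space = 0,
                                       site_sigma = 0, sigma_log = 0.1,
                                       seed = 1000 * r + i))
      local_species_synchrony(estimate_moments(sim$panel))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(syn_sp) > 0))

  syn_sp_reg <- vapply(c(0, 0.5, 0.95), function(rho) {
    mean(vapply(1:8, function(i) {
      sim <- generate_panel(sim_config(n_sites = 2, n_species = 6,
                                       n_years = 100, sad_sigma = 0,
                                       rho_species = 0.6, rho_space = rho,
                                       site_sigma = 0, sigma_log = 0.1,
                                       seed = 2000 * rho + i))
      regional_community_synchrony(estimate_moments(sim$panel))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(syn_sp_reg) > 0))
})

test_that("recovery_suite is deterministic and its report well-formed", {
  r1 <- recovery_suite(r_grid = c(0, 1), rho_space_grid = 0.5,
                       cv_env_grid = c(0.05, 0.3), n_reps = 20,
                       n_years = 50, seed = 7)
  r2 <- recovery_suite(r_grid = c(0, 1), rho_space_grid = 0.5,
                       cv_env_grid = c(0.05, 0.3), n_reps = 20,
                       n_years = 50, seed = 7)
  expect_identical(r1, r2)
  expect_true(all(c("quantity", "estimate", "expected", "covered")
                  %in% names(r1)))
  expect_true(all(r1$covered[r1$quantity == "cv_comm_local"]))
})
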