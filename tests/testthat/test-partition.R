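test_that("estimate_moments matches a brute-force covariance oracle", {
  # constant series: zero covariance, means recovered
  b <- array(rep(c(2, 5, 7), each = 1, times = 3), c(1, 3, 3))
  for (k in 1:3) b[1, k, ] <- c(2, 5, 7)[k]
  p <- biomass_panel(b, "s1", c("A", "B", "C"), 2001:2003)
  m <- estimate_moments(p)
  expect_equal(unname(m$V), matrix(0, 3, 3))
  expect_equal(unname(m$u[1, ]), c(2, 5, 7))

  # 1 site, 2 species, (1,2,3) vs (3,2,1): sample covariance -1
  b2 <- array(c(1, 3, 2, 2, 3, 1), c(1, 2, 3))
  p2 <- biomass_panel(b2, "s1", c("A", "B"), 2001:2003)
  m2 <- estimate_moments(p2)
  expect_equal(m2$V[1, 2], -1)

  # any panel: v(ij,kl) equals the explicit two-pass loop, all pairs
  p3 <- random_panel(2, 3, 5, seed = 4)
  m3 <- estimate_moments(p3)
  for (pi in seq_len(6)) for (pj in seq_len(6)) {
    i <- m3$site_of[pi]; k <- m3$sp_of[pi]
    j <- m3$site_of[pj]; l <- m3$sp_of[pj]
    expect_equal(m3$V[pi, pj],
                 brute_cov(p3$biomass[i, k, ], p3$biomass[j, l, ]))
  }

  # symmetry of the covariance tensor
  expect_equal(m3$V, t(m3$V))
})

test_that("moment estimation enforces its preconditions", {
  p <- random_panel(3, 4, 5, seed = 9)
  p$site_years$s1 <- 2001:2002
  expect_error(estimate_moments(p, c("s1", "s2")), "common to members")
  expect_error(estimate_moments(random_panel(2, 3, 4), members = "nope"),
               "unknown member")
})

test_that("degenerate communities give the textbook component values", {
  # single site, single species: all synchronies 1, all CVs equal
  set.seed(1)
  b <- array(stats::rlnorm(5, 2, 0.4), c(1, 1, 5))
  p <- biomass_panel(b, "s1", "A", 2001:2005)
  m <- estimate_moments(p)
  expect_equal(local_species_synchrony(m), 1)
  expect_equal(regional_community_synchrony(m), 1)
  expect_equal(regional_population_synchrony(m), 1)
  expect_equal(regional_species_synchrony(m), 1)
  cv <- stats::sd(b) / mean(b)
  expect_equal(local_population_cv(m), cv)
  expect_equal(regional_community_cv(m), cv)

  # mean 10 sd 2 -> CV 0.2; two populations with sds 2 and 4, u_total 30 -> 0.2
  x <- c(8, 10, 12); expect_equal(stats::sd(x), 2)
  p1 <- biomass_panel(array(x, c(1, 1, 3)), "s1", "A", 2001:2003)
  expect_equal(local_population_cv(estimate_moments(p1)), 0.2)
  b2 <- array(0, c(1, 2, 3))
  b2[1, 1, ] <- x; b2[1, 2, ] <- 20 + 2 * (x - 10)   # means 10 and 20, sds 2 and 4
  p2 <- biomass_panel(b2, "s1", c("A", "B"), 2001:2003)
  expect_equal(local_population_cv(estimate_moments(p2)), (2 + 4) / 30)

  # perfect compensation: correlation -1, equal sds -> local synchrony 0
  b3 <- array(0, c(1, 2, 3)); b3[1, 1, ] <- c(1, 2, 3); b3[1, 2, ] <- c(3, 2, 1)
  expect_equal(local_species_synchrony(estimate_moments(
    biomass_panel(b3, "s1", c("A", "B"), 2001:2003))), 0)

  # duplicated localities: perfect spatial synchrony
  p4 <- random_panel(1, 4, 5, seed = 3)
  b4 <- array(0, c(2, 4, 5)); b4[1, , ] <- p4$biomass[1, , ]
  b4[2, , ] <- p4$biomass[1, , ]
  m4 <- estimate_moments(biomass_panel(b4, c("s1", "s2"), p4$species,
                                       2001:2005))
  expect_equal(regional_community_synchrony(m4), 1)

  # species present in only one locality each: regional population synchrony 1
  b5 <- array(0, c(2, 2, 4))
  set.seed(8)
  b5[1, 1, ] <- stats::rlnorm(4); b5[2, 2, ] <- stats::rlnorm(4)
  m5 <- estimate_moments(biomass_panel(b5, c("s1", "s2"), c("A", "B"),
                                       2001:2004))
  expect_equal(regional_population_synchrony(m5), 1)
})

test_that("every CV matches its aggregate-then-CV oracle and identities hold", {
  for (seed in 1:25) {
    M <- sample(2:4, 1); S <- sample(2:6, 1); T_ <- sample(4:7, 1)
    p <- random_panel(M, S, T_, seed = seed)
    m <- estimate_moments(p)
    o <- oracle_components(p, p$sites)
    expect_equal(local_population_cv(m), o$cv_pop_local, tolerance = 1e-12)
    expect_equal(local_community_cv(m), o$cv_comm_local, tolerance = 1e-12)
    expect_equal(regional_population_cv(m), o$cv_pop_regional,
                 tolerance = 1e-12)
    expect_equal(regional_community_cv(m, pathway = "direct"),
                 o$cv_comm_regional, tolerance = 1e-12)
    # multiplicative identities of the two pathways
    expect_equal(local_community_cv(m),
                 local_species_synchrony(m) * local_population_cv(m))
    expect_equal(regional_community_cv(m, pathway = "I"),
                 regional_community_cv(m, pathway = "direct"),
                 tolerance = 1e-10)
    expect_equal(regional_community_cv(m, pathway = "II"),
                 regional_community_cv(m, pathway = "direct"),
                 tolerance = 1e-10)
  }
})

test_that("dominance is strict at the threshold and decided on pooled shares", {
  # pooled shares 0.60 / 0.35 / 0.05: exactly 5% is NOT dominant
  b <- array(0, c(1, 3, 3))
  b[1, 1, ] <- 60; b[1, 2, ] <- 35; b[1, 3, ] <- 5
  p <- biomass_panel(b, "s1", c("A", "B", "C"), 2001:2003)
  mask <- dominant_mask(p, threshold = 0.05)
  expect_equal(mask$dominant, c("A", "B"))
  expect_equal(unname(mask$share), c(0.60, 0.35, 0.05))

  # one species holding all biomass: only it is dominant
  b1 <- array(0, c(1, 2, 3)); b1[1, 1, ] <- c(1, 2, 3)
  expect_equal(dominant_mask(biomass_panel(b1, "s1", c("A", "B"),
                                           2001:2003))$dominant, "A")

  # 20 equal-share species (exactly 5% each): no dominants, flagged undefined
  b20 <- array(rep(c(1, 2, 3), each = 20), c(1, 20, 3))
  p20 <- biomass_panel(b20, "s1", paste0("sp", 1:20), 2001:2003)
  expect_equal(length(dominant_mask(p20)$dominant), 0L)
  pr <- partition_hierarchy(p20)
  expect_false(pr$dominant_defined)
  expect_true(all(is.na(pr$dominant)))
})

test_that("threshold 0 makes every dominant measure equal its all-species value", {
  for (convention in c("typeset", "masked")) {
    sim <- generate_panel(sim_config(n_sites = 4, n_species = 10, seed = 21))
    pr <- partition_hierarchy(sim$panel, sim$panel$sites[1:2], threshold = 0,
                              convention = convention)
    shared <- intersect(names(pr$all), names(pr$dominant))
    expect_equal(pr$dominant[shared], pr$all[shared])
    expect_equal(unname(pr$dominant["cv_comm_regional_I"]),
                 unname(pr$all["cv_comm_regional"]))
    expect_equal(unname(pr$dominant["cv_comm_regional_II"]),
                 unname(pr$all["cv_comm_regional"]))
  }
})

test_that("dominant-measure conventions behave as documented", {
  sim <- generate_panel(sim_config(n_sites = 6, n_species = 30,
                                   sad_sigma = 2, seed = 5))
  mem <- sim$panel$sites[1:2]
  # fully masked convention: the two pathway estimates coincide exactly
  prm <- partition_hierarchy(sim$panel, mem, convention = "masked")
  expect_equal(unname(prm$dominant["cv_comm_regional_I"]),
               unname(prm$dominant["cv_comm_regional_II"]),
               tolerance = 1e-12)
  # typeset convention: both reported; they need not coincide
  prt <- partition_hierarchy(sim$panel, mem, convention = "typeset")
  expect_true(is.finite(prt$dominant["cv_comm_regional_I"]))
  expect_true(is.finite(prt$dominant["cv_comm_regional_II"]))
  # all-species values identical under either convention
  expect_equal(prm$all, prt$all)
})

test_that("degenerate zero-variance communities raise flagged-undefined errors", {
  b <- array(5, c(2, 2, 3))   # constant everywhere: all variances 0
  p <- biomass_panel(b, c("s1", "s2"), c("A", "B"), 2001:2003)
  m <- estimate_moments(p)
  expect_equal(local_population_cv(m), 0)
  expect_error(local_species_synchrony(m), "undefined")
  expect_error(regional_community_synchrony(m), "undefined")

  expect_error(biomass_panel(array(0, c(1, 2, 3)), "s1", c("A", "B"),
                             2001:2003),
               "positive total biomass")
})
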