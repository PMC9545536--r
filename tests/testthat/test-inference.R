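test_that("per-set statistics recover exact and simulated relationships", {
  set.seed(5)
  n_sets <- 200; n_comm <- 10
  x <- stats::rnorm(n_sets * n_comm)
  df <- data.frame(set = rep(seq_len(n_sets), each = n_comm), x = x)
  df$y_same <- df$x
  df$y_indep <- stats::rnorm(nrow(df))
  df$y_slope <- 2 * df$x + 0.05 * stats::rnorm(nrow(df))
  coll <- fake_collection(df)

  ps <- per_set_statistics(coll, "x", "y_same")
  expect_true(all(abs(ps$stat - 1) < 1e-12))           # y = x: rho 1 per set

  pi_ <- per_set_statistics(coll, "x", "y_indep")
  expect_lt(abs(mean(pi_$stat)), 0.05)                 # independence: mean ~ 0
  rt <- randomized_examination(pi_)
  expect_true(abs(rt$P_minus - 0.5) < 0.1)
  expect_equal(rt$verdict, "ns")

  sl <- per_set_statistics(coll, "x", "y_slope", kind = "regression")
  expect_equal(mean(sl$stat), 2, tolerance = 0.01)     # OLS slope oracle

  # zero-variance sets are flagged and excluded with a count
  df2 <- df; df2$x[df2$set == 1] <- 3
  psz <- per_set_statistics(fake_collection(df2), "x", "y_indep")
  expect_false(psz$valid[1])
  expect_equal(randomized_examination(psz)$n_valid, n_sets - 1)
})

test_that("randomized examination applies the opposite-sign proportion rule", {
  all_pos <- randomized_examination(rep(0.5, 100))
  expect_equal(all_pos$verdict, "significant")
  expect_equal(all_pos$P_minus, 0)

  sym <- randomized_examination(rep(c(-0.4, 0.4), 50))
  expect_equal(sym$verdict, "ns")

  # negative mean judged by P_plus; marginal band at 0.10
  neg <- randomized_examination(c(rep(-0.5, 93), rep(0.5, 7)))
  expect_equal(neg$verdict, "marginal")
  neg2 <- randomized_examination(c(rep(-0.5, 96), rep(0.5, 4)))
  expect_equal(neg2$verdict, "significant")
  expect_error(randomized_examination(NA_real_), "fewer than 2")
})

test_that("AICc matches the small-sample correction formula", {
  # hand computation at n = 10, k = 2
  expect_equal(aicc(100, n = 10, k = 2), 100 + 2 * 2 * 3 / 7)
  set.seed(2)
  d <- data.frame(x = stats::rnorm(10)); d$y <- d$x + stats::rnorm(10)
  fit <- stats::lm(y ~ x, d)
  k <- attr(stats::logLik(fit), "df")
  expect_equal(aicc(fit),
               stats::AIC(fit) + 2 * k * (k + 1) / (10 - k - 1))
  expect_equal(aicc(1, n = 4, k = 3), Inf)   # undefined below n = k + 2
})

test_that("standardization makes single-predictor paths equal correlations", {
  coll <- chain_collection(n_sets = 50)
  pm <- fit_path_model(coll, data.frame(from = "x", to = "y"))
  ps <- per_set_statistics(coll, "x", "y")
  expect_equal(unname(pm$edges$coef), mean(ps$stat), tolerance = 1e-12)
  expect_equal(unname(pm$r2[["y"]]), mean(ps$r2), tolerance = 1e-12)
})

test_that("a generated chain model is recovered within Monte-Carlo error", {
  coll <- chain_collection(n_sets = 300, bx = 0.7, bm = 0.6, seed = 8)
  edges <- data.frame(from = c("x", "m_"), to = c("m_", "y"))
  pm <- fit_path_model(coll, edges)
  expect_equal(pm$edges$coef[pm$edges$from == "x"], 0.7, tolerance = 0.05)
  expect_equal(pm$edges$coef[pm$edges$from == "m_"], 0.6, tolerance = 0.05)
  expect_true(all(pm$edges$verdict == "significant"))
  expect_error(fit_path_model(coll, data.frame(from = c("x", "y"),
                                               to = c("y", "x"))), "cycle")
})

test_that("pruning removes noise edges, honors locks, never raises AICc", {
  set.seed(9)
  coll <- chain_collection(n_sets = 200, seed = 3)
  coll$results$noise <- stats::rnorm(nrow(coll$results))
  edges <- data.frame(from = c("x", "m_", "noise"),
                      to = c("m_", "y", "y"),
                      locked = c(TRUE, TRUE, FALSE))
  pm <- fit_path_model(coll, edges)
  pruned <- prune_path_model(pm)
  expect_false("noise" %in% pruned$edges$from)         # noise edge removed
  expect_lte(pruned$aicc, pm$aicc)
  expect_equal(pruned$provenance, "pruned")

  # all edges significant: fixed point, model unchanged
  pm2 <- fit_path_model(coll, data.frame(from = c("x", "m_"),
                                         to = c("m_", "y")))
  expect_equal(prune_path_model(pm2)$edges, pm2$edges)

  # a locked edge survives regardless of verdict
  edges_lock <- data.frame(from = c("x", "m_", "noise"),
                           to = c("m_", "y", "y"),
                           locked = c(TRUE, TRUE, TRUE))
  pl <- prune_path_model(fit_path_model(coll, edges_lock))
  expect_true("noise" %in% pl$edges$from)
})

test_that("dominant-species explanatory power is 1 at threshold 0", {
  sim <- generate_panel(sim_config(n_sites = 6, n_species = 8, seed = 4))
  coll <- build_collection(sim$panel, n_sets = 15, seed = 6, threshold = 0)
  for (comp in c("cv_pop_local", "cv_comm_regional")) {
    de <- dominance_explained(coll, comp)
    expect_equal(de$mean_r2, 1, tolerance = 1e-10)
  }
  expect_error(dominance_explained(coll, "no_such"), "not found")
})

test_that("default path-model specs reference collection variables and fit", {
  sim <- generate_panel(sim_config(n_sites = 16, n_species = 15, seed = 12))
  coll <- build_collection(sim$panel, n_sets = 30, seed = 2,
                           climate = sim$climate)
  for (pw in c("I", "II")) {
    spec <- path_model_spec(pw, climate = TRUE)
    pm <- fit_path_model(coll, spec)
    expect_true(all(is.finite(pm$edges$coef)))
    pruned <- prune_path_model(pm)
    expect_lte(pruned$aicc, pm$aicc)
    expect_true(all(pruned$edges$verdict != "ns" | pruned$edges$locked) ||
                  nrow(pruned$edges) < nrow(pm$edges))
  }
})
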