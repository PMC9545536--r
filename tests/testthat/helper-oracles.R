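# Fixtures and independent brute-force oracles used across test files.

# small random panel with positive biomass everywhere
random_panel <- function(M = 3, S = 5, T_ = 6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  b <- array(stats::rlnorm(M * S * T_, meanlog = 1, sdlog = 0.8),
             c(M, S, T_))
  biomass_panel(b, sites = paste0("s", seq_len(M)),
                species = paste0("sp", seq_len(S)),
                years = seq(2001, length.out = T_))
}

# two-pass sample covariance by explicit loop over year pairs
brute_cov <- function(x, y) {
  x <- unname(x); y <- unname(y)
  T_ <- length(x)
  mx <- sum(x) / T_
  my <- sum(y) / T_
  acc <- 0
  for (t in seq_len(T_)) acc <- acc + (x[t] - mx) * (y[t] - my)
  acc / (T_ - 1)
}

# aggregate-then-CV oracles computed from yearly series, never from moments
oracle_components <- function(panel, members) {
  yrs <- as.character(sort(Reduce(intersect, panel$site_years[members])))
  b <- panel$biomass[members, , yrs, drop = FALSE]
  u_total <- sum(apply(b, c(1, 2), mean))
  pop_sd <- apply(b, c(1, 2), stats::sd)
  comm_series <- apply(b, c(1, 3), sum)           # site x year totals
  sp_series <- apply(b, c(2, 3), sum)             # species x year regional
  tot_series <- colSums(comm_series)              # regional totals
  list(
    cv_pop_local = sum(pop_sd) / u_total,
    cv_comm_local = sum(apply(comm_series, 1, stats::sd)) / u_total,
    cv_pop_regional = sum(apply(sp_series, 1, stats::sd)) / u_total,
    cv_comm_regional = stats::sd(tot_series) / u_total)
}

# wrap a per-community results table as a resample_collection for inference
fake_collection <- function(results) {
  if (is.null(results$ok)) results$ok <- TRUE
  if (is.null(results$community)) results$community <- 1L
  structure(list(results = results, sets = NULL,
                 n_sets = length(unique(results$set)), m = 2L,
                 seed = NA_integer_, failed = 0L),
            class = "resample_collection")
}

# per-set table for a linear chain x -> m_ -> y with known coefficients
chain_collection <- function(n_sets = 300, n_comm = 10, bx = 0.7, bm = 0.6,
                             seed = 1) {
  set.seed(seed)
  n <- n_sets * n_comm
  x <- stats::rnorm(n)
  m_ <- bx * x + sqrt(1 - bx^2) * stats::rnorm(n)
  y <- bm * m_ + sqrt(1 - bm^2) * stats::rnorm(n)
  fake_collection(data.frame(set = rep(seq_len(n_sets), each = n_comm),
                             x = x, m_ = m_, y = y))
}

write_tmp_csv <- function(df) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE)
  f
}
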