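#' Temporal moments of a regional community
#'
#' For a regional community made of `members` sites, estimates the temporal
#' mean of every local population (site x species series) and the full
#' population-by-population covariance tensor over the years common to all
#' members.  Every CV and synchrony of the hierarchy is a function of these
#' moments only.
#'
#' Writing `N(i,k,t)` for the biomass of species `k` at site `i` in year `t`,
#' the moments are `u(i,k) = mean_t N(i,k,t)` and
#' `v(ij,kl) = cov(N(i,k,t), N(j,l,t))` (sample covariance, denominator
#' `T - 1`), together with the regional mean total `u_total = sum u(i,k)`.
#'
#' @param panel a [biomass_panel()].
#' @param members character vector of member sites (subset of `panel$sites`);
#'   default all sites.
#' @param min_years minimum number of common years required (default 3: the
#'   covariance needs 2, one more for stability).
#' @return object of class `hier_moments`: list with `u` (M x S mean matrix),
#'   `V` ((M*S) x (M*S) covariance matrix, populations ordered site-major),
#'   `u_total`, `sd_pop` (M x S matrix of population SDs), `site_of`/`sp_of`
#'   (population index maps), `sites`, `species`, `years` (common years),
#'   and cached aggregates `v_comm_local` (per site), `v_pop_regional`
#'   (per species), `v_comm_regional` (scalar).
#' @export
estimate_moments <- function(panel, members = panel$sites, min_years = 3L) {
  stopifnot(inherits(panel, "biomass_panel"))
  members <- as.character(members)
  if (!all(members %in% panel$sites))
    stop("unknown member site(s): ",
         paste(setdiff(members, panel$sites), collapse = ", "))
  yrs <- Reduce(intersect, panel$site_years[members])
  if (length(yrs) < min_years)
    stop(sprintf("only %d year(s) common to members; %d required",
                 length(yrs), min_years))
  yrs <- sort(yrs)
  S <- length(panel$species)
  M <- length(members)
  # Y: years x populations, populations ordered site-major (site 1 species
  # 1..S, site 2 species 1..S, ...)
  Y <- matrix(aperm(panel$biomass[members, , as.character(yrs), drop = FALSE],
                    c(3L, 2L, 1L)),
              nrow = length(yrs))
  u_vec <- colMeans(Y)
  u_total <- sum(u_vec)
  if (u_total <= 0) stop("community total biomass is zero; not analyzable")
  V <- stats::cov(Y)
  site_of <- rep(seq_len(M), each = S)
  sp_of <- rep(seq_len(S), times = M)
  sd_pop <- sqrt(pmax(diag(V), 0))
  v_comm_local <- vapply(seq_len(M), function(i) {
    p <- site_of == i
    sum(V[p, p])
  }, numeric(1))
  v_pop_regional <- vapply(seq_len(S), function(k) {
    p <- sp_of == k
    sum(V[p, p])
  }, numeric(1))
  structure(list(
    u = matrix(u_vec, M, S, byrow = TRUE,
               dimnames = list(members, panel$species)),
    V = V, u_total = u_total,
    sd_pop = matrix(sd_pop, M, S, byrow = TRUE,
                    dimnames = list(members, panel$species)),
    site_of = site_of, sp_of = sp_of,
    sites = members, species = panel$species, years = yrs,
    v_comm_local = pmax(v_comm_local, 0),
    v_pop_regional = pmax(v_pop_regional, 0),
    v_comm_regional = max(sum(V), 0)),
    class = "hier_moments")
}

#' Dominant species of a regional community
#'
#' A species is dominant when its biomass, pooled over the member sites and
#' their common years, exceeds `threshold` (strictly) as a fraction of the
#' community's pooled total biomass.  Dominance is decided at the
#' regional-community level: the indicator `d(i,k) = d(k)` is shared by all
#' member sites.
#'
#' @param panel a [biomass_panel()].
#' @param members member sites.
#' @param threshold dominance threshold as a fraction (default 0.05, i.e. the
#'   conventional >5% rule); the inequality is strict, so a species holding
#'   exactly 5% is not dominant.
#' @return object of class `dominance_mask`: list with `d` (M x S 0/1
#'   matrix), `dominant` (character vector of dominant species, possibly
#'   empty), `share` (per-species pooled biomass share), `threshold`.
#' @export
dominant_mask <- function(panel, members = panel$sites, threshold = 0.05) {
  stopifnot(inherits(panel, "biomass_panel"))
  members <- as.character(members)
  yrs <- sort(Reduce(intersect, panel$site_years[members]))
  b <- panel$biomass[members, , as.character(yrs), drop = FALSE]
  tot_sp <- apply(b, 2, sum)
  total <- sum(tot_sp)
  if (total <= 0) stop("empty community: total biomass is zero")
  share <- tot_sp / total
  dom <- share > threshold
  d <- matrix(as.numeric(dom), nrow = length(members),
              ncol = length(panel$species), byrow = TRUE,
              dimnames = list(members, panel$species))
  structure(list(d = d, dominant = panel$species[dom], share = share,
                 threshold = threshold),
            class = "dominance_mask")
}

# Shared denominators / masked sums for the component estimators.
# With a mask, the "typeset" convention keeps all-species denominators under
# dominant-species numerators (as the equations are printed); the "masked"
# convention masks denominators too, which makes the two upscaling pathways
# coincide exactly for dominant measures.
.mom_sums <- function(m, mask = NULL, convention = c("typeset", "masked")) {
  convention <- match.arg(convention)
  out <- list(
    sum_sd_all = sum(m$sd_pop),
    sum_sd_comm_all = sum(sqrt(m$v_comm_local)),
    sum_sd_popR_all = sum(sqrt(m$v_pop_regional)),
    v_CR_all = m$v_comm_regional)
  if (!is.null(mask)) {
    if (length(mask$dominant) == 0L)
      stop("no dominant species at threshold ", mask$threshold,
           "; dominant-species measures are undefined")
    w <- as.numeric(t(mask$d))          # population order is site-major
    Vm <- m$V * tcrossprod(w)
    M <- length(m$sites); S <- length(m$species)
    out$sum_sd_dom <- sum(m$sd_pop * mask$d)
    out$v_comm_local_dom <- pmax(vapply(seq_len(M), function(i)
      sum(Vm[m$site_of == i, m$site_of == i]), numeric(1)), 0)
    out$v_pop_regional_dom <- pmax(vapply(seq_len(S), function(k)
      sum(Vm[m$sp_of == k, m$sp_of == k]), numeric(1)), 0)
    out$v_CR_dom <- max(sum(Vm), 0)
    if (convention == "masked") {
      out$den_sd <- out$sum_sd_dom
      out$den_sd_comm <- sum(sqrt(out$v_comm_local_dom))
      out$den_sd_popR <- sum(sqrt(out$v_pop_regional_dom))
    } else {
      out$den_sd <- out$sum_sd_all
      out$den_sd_comm <- out$sum_sd_comm_all
      out$den_sd_popR <- out$sum_sd_popR_all
    }
  }
  out
}

.check_pos <- function(x, what) {
  if (!isTRUE(x > 0))
    stop(sprintf("undefined: %s is zero (degenerate 0/0 synchrony)", what),
         call. = FALSE)
}

#' Local population CV
#'
#' Biomass-weighted average CV of the local populations of a regional
#' community: `CV_PL = sum_{i,k} sd(i,k) / u_total`.  The dominant-species
#' variant restricts the numerator to dominant species; the denominator stays
#' the all-species regional mean total.
#'
#' @param m a `hier_moments` object from [estimate_moments()].
#' @param mask optional [dominant_mask()]; when given, the dominant-species
#'   variant is returned.
#' @param convention denominator convention for dominant-species synchronies,
#'   see [partition_hierarchy()].
#' @return a single nonnegative number.
#' @export
local_population_cv <- function(m, mask = NULL,
                                convention = c("typeset", "masked")) {
  s <- .mom_sums(m, mask, convention)
  num <- if (is.null(mask)) s$sum_sd_all else s$sum_sd_dom
  num / m$u_total
}

#' Local species synchrony
#'
#' Weighted average, over member sites, of the within-site synchrony between
#' species: `phi = sum_i sqrt(v_CL(ii)) / sum_{i,k} sd(i,k)`, where
#' `v_CL(ii)` is the temporal variance of the community biomass of site `i`.
#' Equals 1 when all species fluctuate in perfect proportion, 0 under perfect
#' compensation.
#'
#' @inheritParams local_population_cv
#' @return a number in \[0, 1\] (all-species variant).
#' @export
local_species_synchrony <- function(m, mask = NULL,
                                    convention = c("typeset", "masked")) {
  s <- .mom_sums(m, mask, convention)
  if (is.null(mask)) {
    .check_pos(s$sum_sd_all, "total population SD")
    s$sum_sd_comm_all / s$sum_sd_all
  } else {
    .check_pos(s$den_sd, "total population SD")
    sum(sqrt(s$v_comm_local_dom)) / s$den_sd
  }
}

#' Local community CV
#'
#' `CV_CL = phi_species_local * CV_PL`; for all species this equals
#' `sum_i sd(community biomass of site i) / u_total`.
#'
#' @inheritParams local_population_cv
#' @export
local_community_cv <- function(m, mask = NULL,
                               convention = c("typeset", "masked")) {
  local_species_synchrony(m, mask, convention) *
    local_population_cv(m, mask, convention)
}

#' Regional community synchrony
#'
#' Spatial synchrony between the community biomass series of the member
#' sites: `phi = sqrt(v_CR) / sum_i sqrt(v_CL(ii))`.
#'
#' @inheritParams local_population_cv
#' @export
regional_community_synchrony <- function(m, mask = NULL,
                                         convention = c("typeset", "masked")) {
  s <- .mom_sums(m, mask, convention)
  if (is.null(mask)) {
    .check_pos(s$sum_sd_comm_all, "total local community SD")
    sqrt(s$v_CR_all) / s$sum_sd_comm_all
  } else {
    .check_pos(s$den_sd_comm, "total local community SD")
    sqrt(s$v_CR_dom) / s$den_sd_comm
  }
}

#' Regional population synchrony
#'
#' Spatial synchrony of same-species populations across member sites:
#' `phi = sum_k sqrt(v_PR(kk)) / sum_{i,k} sd(i,k)`, where `v_PR(kk)` is the
#' temporal variance of species `k`'s biomass summed over sites.
#'
#' @inheritParams local_population_cv
#' @export
regional_population_synchrony <- function(m, mask = NULL,
                                          convention = c("typeset", "masked")) {
  s <- .mom_sums(m, mask, convention)
  if (is.null(mask)) {
    .check_pos(s$sum_sd_all, "total population SD")
    s$sum_sd_popR_all / s$sum_sd_all
  } else {
    .check_pos(s$den_sd, "total population SD")
    sum(sqrt(s$v_pop_regional_dom)) / s$den_sd
  }
}

#' Regional population CV
#'
#' `CV_PR = phi_pop_regional * CV_PL`; for all species this equals
#' `sum_k sd(regional biomass of species k) / u_total`.
#'
#' @inheritParams local_population_cv
#' @export
regional_population_cv <- function(m, mask = NULL,
                                   convention = c("typeset", "masked")) {
  regional_population_synchrony(m, mask, convention) *
    local_population_cv(m, mask, convention)
}

#' Regional species synchrony
#'
#' Synchrony between the regional populations of different species:
#' `phi = sqrt(v_CR) / sum_k sqrt(v_PR(kk))`.
#'
#' @inheritParams local_population_cv
#' @export
regional_species_synchrony <- function(m, mask = NULL,
                                       convention = c("typeset", "masked")) {
  s <- .mom_sums(m, mask, convention)
  if (is.null(mask)) {
    .check_pos(s$sum_sd_popR_all, "total regional population SD")
    sqrt(s$v_CR_all) / s$sum_sd_popR_all
  } else {
    .check_pos(s$den_sd_popR, "total regional population SD")
    sqrt(s$v_CR_dom) / s$den_sd_popR
  }
}

#' Regional community CV
#'
#' The CV of the regional community's total biomass.  Can be obtained along
#' pathway I (`phi_comm_regional * phi_species_local * CV_PL`), pathway II
#' (`phi_species_regional * phi_pop_regional * CV_PL`), or directly as
#' `sqrt(v_CR) / u_total` from the aggregated regional series.  For
#' all-species measures the three agree to numerical precision; for
#' dominant-species measures under the typeset convention the two pathway
#' values can differ slightly and are reported separately.
#'
#' @inheritParams local_population_cv
#' @param pathway `"direct"`, `"I"`, or `"II"`.
#' @export
regional_community_cv <- function(m, mask = NULL,
                                  pathway = c("direct", "I", "II"),
                                  convention = c("typeset", "masked")) {
  pathway <- match.arg(pathway)
  if (pathway == "direct" && is.null(mask))
    return(sqrt(m$v_comm_regional) / m$u_total)
  if (pathway == "direct") pathway <- "I"   # dominant: direct not defined; use pathway I
  if (pathway == "I")
    regional_community_synchrony(m, mask, convention) *
      local_community_cv(m, mask, convention)
  else
    regional_species_synchrony(m, mask, convention) *
      regional_population_cv(m, mask, convention)
}

#' Full hierarchical CV/synchrony partition of a regional community
#'
#' Computes, in one call, all eight components of the two upscaling pathways
#' (local population CV, local species synchrony, local community CV,
#' regional community synchrony, regional population synchrony, regional
#' population CV, regional species synchrony, regional community CV), each
#' with all species and with only dominant species.
#'
#' @param panel a [biomass_panel()].
#' @param members member sites of the regional community.
#' @param threshold dominance threshold (fraction of pooled regional biomass,
#'   strict inequality; default 0.05).
#' @param convention how dominant-species synchronies are normalized:
#'   `"typeset"` (default) keeps all-species denominators under
#'   dominant-species numerators, under which the two pathway estimates of
#'   the dominant regional community CV can differ slightly; `"masked"` masks
#'   denominators too, making them coincide.
#' @return object of class `partition_result`: list with elements `all` and
#'   `dominant` (named numeric vectors of the eight components; `dominant`
#'   additionally carries `cv_comm_regional_I` and `cv_comm_regional_II`),
#'   plus `dominant_defined`, `dominant_species`, `members`, `years`,
#'   `threshold`, `convention`.  When no species passes the threshold the
#'   dominant variants are `NA` and `dominant_defined` is `FALSE`.
#' @examples
#' cfg <- sim_config(n_sites = 4, n_species = 12, n_years = 5, seed = 1)
#' sim <- generate_panel(cfg)
#' partition_hierarchy(sim$panel, members = sim$panel$sites[1:2])
#' @export
partition_hierarchy <- function(panel, members = panel$sites,
                                threshold = 0.05,
                                convention = c("typeset", "masked")) {
  convention <- match.arg(convention)
  m <- estimate_moments(panel, members)
  mask <- dominant_mask(panel, members, threshold)
  all_comp <- c(
    cv_pop_local = local_population_cv(m),
    syn_species_local = local_species_synchrony(m),
    cv_comm_local = local_community_cv(m),
    syn_comm_regional = regional_community_synchrony(m),
    syn_pop_regional = regional_population_synchrony(m),
    cv_pop_regional = regional_population_cv(m),
    syn_species_regional = regional_species_synchrony(m),
    cv_comm_regional = regional_community_cv(m, pathway = "direct"))
  dom_defined <- length(mask$dominant) > 0L
  if (dom_defined) {
    dom_comp <- c(
      cv_pop_local = local_population_cv(m, mask, convention),
      syn_species_local = local_species_synchrony(m, mask, convention),
      cv_comm_local = local_community_cv(m, mask, convention),
      syn_comm_regional = regional_community_synchrony(m, mask, convention),
      syn_pop_regional = regional_population_synchrony(m, mask, convention),
      cv_pop_regional = regional_population_cv(m, mask, convention),
      syn_species_regional = regional_species_synchrony(m, mask, convention),
      cv_comm_regional_I = regional_community_cv(m, mask, "I", convention),
      cv_comm_regional_II = regional_community_cv(m, mask, "II", convention))
  } else {
    dom_comp <- stats::setNames(
      rep(NA_real_, 9),
      c("cv_pop_local", "syn_species_local", "cv_comm_local",
        "syn_comm_regional", "syn_pop_regional", "cv_pop_regional",
        "syn_species_regional", "cv_comm_regional_I", "cv_comm_regional_II"))
  }
  structure(list(all = all_comp, dominant = dom_comp,
                 dominant_defined = dom_defined,
                 dominant_species = mask$dominant,
                 members = m$sites, years = m$years,
                 threshold = threshold, convention = convention),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, digits = 3, ...) {
  cat(sprintf("<partition_result> community of %d site(s): %s (%d common years)\n",
              length(x$members), paste(x$members, collapse = "+"),
              length(x$years)))
  m <- matrix(NA_real_, 2, length(x$all),
              dimnames = list(c("all", "dominant"), names(x$all)))
  m["all", ] <- x$all
  shared <- intersect(names(x$all), names(x$dominant))
  m["dominant", shared] <- x$dominant[shared]
  print(round(t(m), digits))
  if (x$dominant_defined) {
    cat(sprintf("dominant species (> %.0f%% pooled biomass): %s\n",
                100 * x$threshold, paste(x$dominant_species, collapse = ", ")))
    cat(sprintf("dominant regional community CV: pathway I %.3f, pathway II %.3f\n",
                x$dominant["cv_comm_regional_I"],
                x$dominant["cv_comm_regional_II"]))
  } else {
    cat("no dominant species at threshold; dominant measures undefined\n")
  }
  invisible(x)
}
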