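#' Species richness across scales
#'
#' Alpha richness is the mean, over member sites, of the per-site multi-year
#' mean yearly species count (species with biomass > 0 in that site-year).
#' Gamma richness is the number of species with positive biomass in any
#' member site-year (multi-year pooled).  Beta richness is the ratio
#' `S_gamma / S_alpha`, a cross-locality dissimilarity in \[1, M\].
#'
#' @param panel a [biomass_panel()].
#' @param members member sites of the regional community.
#' @param species optional subset of species to consider (used for
#'   dominant-only diversity); default all.
#' @return named numeric vector `c(S_alpha, S_beta, S_gamma)`.
#' @export
richness <- function(panel, members = panel$sites, species = panel$species) {
  members <- as.character(members)
  yrs <- sort(Reduce(intersect, panel$site_years[members]))
  b <- panel$biomass[members, species, as.character(yrs), drop = FALSE]
  if (sum(b) <= 0) stop("empty community: no positive biomass")
  per_site <- vapply(seq_along(members), function(i) {
    counts <- apply(b[i, , , drop = FALSE] > 0, 3, sum)
    mean(counts)
  }, numeric(1))
  S_alpha <- mean(per_site)
  S_gamma <- sum(apply(b > 0, 2, any))
  c(S_alpha = S_alpha, S_beta = S_gamma / S_alpha, S_gamma = S_gamma)
}

.shannon_D <- function(x) {
  p <- x[x > 0] / sum(x)
  exp(-sum(p * log(p)))
}

#' Effective species richness (Shannon antilog) across scales
#'
#' Effective richness is `D = exp(H')` with `H' = -sum p log p` (nats) on
#' relative biomass: the number of equally abundant species producing the
#' same Shannon-Wiener diversity.  Alpha: `exp(H')` per site-year, averaged
#' over years then over sites (switchable to exponentiating the averaged
#' `H'`).  Gamma: `exp(H')` of the biomass distribution pooled over member
#' sites and years.  Beta: `D_gamma / D_alpha`.
#'
#' @inheritParams richness
#' @param alpha_method `"mean_D"` (default): average `exp(H')` over
#'   site-years; `"exp_mean_H"`: exponentiate the averaged `H'`.  Differences
#'   are small; both are reported in practice via this switch.
#' @return named numeric vector `c(D_alpha, D_beta, D_gamma)`.
#' @export
effective_richness <- function(panel, members = panel$sites,
                               species = panel$species,
                               alpha_method = c("mean_D", "exp_mean_H")) {
  alpha_method <- match.arg(alpha_method)
  members <- as.character(members)
  yrs <- sort(Reduce(intersect, panel$site_years[members]))
  b <- panel$biomass[members, species, as.character(yrs), drop = FALSE]
  if (sum(b) <= 0) stop("empty community: zero total biomass")
  site_alpha <- vapply(seq_along(members), function(i) {
    per_year <- vapply(seq_along(yrs), function(t) {
      x <- b[i, , t]
      if (sum(x) <= 0) return(NA_real_)
      if (alpha_method == "mean_D") .shannon_D(x) else log(.shannon_D(x))
    }, numeric(1))
    mean(per_year, na.rm = TRUE)
  }, numeric(1))
  D_alpha <- if (alpha_method == "mean_D") mean(site_alpha)
             else exp(mean(site_alpha))
  D_gamma <- .shannon_D(apply(b, 2, sum))
  c(D_alpha = D_alpha, D_beta = D_gamma / D_alpha, D_gamma = D_gamma)
}

#' All diversity indices of a regional community
#'
#' Species richness and effective species richness at alpha, beta, and gamma
#' levels, for all species and for dominant species only (relative abundances
#' re-normalized within the dominant subset).
#'
#' @inheritParams richness
#' @param threshold dominance threshold, see [dominant_mask()].
#' @param alpha_method see [effective_richness()].
#' @return object of class `diversity_result`: list with numeric vectors
#'   `all` and `dominant` (each `S_alpha, S_beta, S_gamma, D_alpha, D_beta,
#'   D_gamma`) and `dominant_defined`.
#' @export
diversity_indices <- function(panel, members = panel$sites, threshold = 0.05,
                              alpha_method = "mean_D") {
  allv <- c(richness(panel, members),
            effective_richness(panel, members, alpha_method = alpha_method))
  mask <- dominant_mask(panel, members, threshold)
  if (length(mask$dominant)) {
    domv <- c(richness(panel, members, species = mask$dominant),
              effective_richness(panel, members, species = mask$dominant,
                                 alpha_method = alpha_method))
  } else {
    domv <- stats::setNames(rep(NA_real_, 6), names(allv))
  }
  structure(list(all = allv, dominant = domv,
                 dominant_defined = length(mask$dominant) > 0L,
                 members = as.character(members), threshold = threshold),
            class = "diversity_result")
}

#' @export
print.diversity_result <- function(x, digits = 3, ...) {
  cat(sprintf("<diversity_result> community: %s\n",
              paste(x$members, collapse = "+")))
  print(round(rbind(all = x$all, dominant = x$dominant), digits))
  invisible(x)
}
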