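#' Construct a multisite biomass panel
#'
#' A `biomass_panel` holds aboveground biomass (g/m2) on a
#' site x species x year grid.  It is the raw input of every analysis in the
#' package: moment estimation, CV/synchrony partitioning, diversity indices,
#' and the resampling construction of regional communities all start from one.
#'
#' Species absent from a site-year are structural zeros (an absence in a
#' harvest is zero biomass, not missing data).  Sites may cover different
#' (consecutive) year runs; analyses of a multi-site community use the
#' intersection of the member sites' years.
#'
#' @param biomass numeric 3-D array, dimensions site x species x year,
#'   nonnegative and finite.
#' @param sites character vector of site labels (unique).
#' @param species character vector of species labels (unique).
#' @param years integer vector of calendar years, consecutive within the
#'   panel's span.
#' @param site_years optional named list giving, per site, the integer years
#'   actually observed there (defaults to all `years` for every site).  Years
#'   a site was not observed are carried as `NA`-masked: the biomass slice is
#'   present (zeros) but excluded from common-year computations.
#' @return an object of class `biomass_panel`: a list with elements `biomass`,
#'   `sites`, `species`, `years`, `site_years`.
#' @examples
#' b <- array(runif(2 * 3 * 4, 1, 10), c(2, 3, 4))
#' p <- biomass_panel(b, sites = c("s1", "s2"), species = c("A", "B", "C"),
#'                    years = 2012:2015)
#' p
#' @export
biomass_panel <- function(biomass, sites, species, years, site_years = NULL) {
  biomass <- as.array(biomass)
  if (length(dim(biomass)) != 3L)
    stop("`biomass` must be a 3-D array (site x species x year)")
  sites <- as.character(sites)
  species <- as.character(species)
  years <- as.integer(years)
  if (is.null(site_years))
    site_years <- stats::setNames(rep(list(years), length(sites)), sites)
  dimnames(biomass) <- list(site = sites, species = species, year = years)
  x <- structure(
    list(biomass = biomass, sites = sites, species = species,
         years = years, site_years = site_years),
    class = "biomass_panel")
  validate_biomass_panel(x)
  x
}

#' Validate a biomass panel
#'
#' Checks the structural invariants every downstream analysis relies on:
#' nonnegative finite biomass, unique labels, at least three observed years
#' per site, consecutive years within each site, and at least one species
#' with positive total biomass per site.
#'
#' @param x a [biomass_panel()].
#' @return `x`, invisibly, if valid; otherwise an error describing the first
#'   violated invariant (naming offending sites/cells).
#' @export
validate_biomass_panel <- function(x) {
  stopifnot(inherits(x, "biomass_panel"))
  b <- x$biomass
  if (dim(b)[1] != length(x$sites) || dim(b)[2] != length(x$species) ||
      dim(b)[3] != length(x$years))
    stop("biomass array dimensions do not match site/species/year labels")
  if (anyDuplicated(x$sites)) stop("site labels must be unique")
  if (anyDuplicated(x$species)) stop("species labels must be unique")
  if (any(!is.finite(b)))
    stop("biomass contains non-finite entries")
  if (any(b < 0)) {
    idx <- which(b < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative biomass at site %s, species %s, year %s",
                 x$sites[idx[1]], x$species[idx[2]], x$years[idx[3]]))
  }
  for (s in x$sites) {
    ys <- sort(x$site_years[[s]])
    if (length(ys) < 3L)
      stop(sprintf("site %s has %d observed year(s); at least 3 are required",
                   s, length(ys)))
    if (any(diff(ys) != 1L))
      stop(sprintf("observed years of site %s are not consecutive", s))
    if (sum(b[s, , as.character(ys)]) <= 0)
      stop(sprintf("site %s has no species with positive total biomass", s))
  }
  invisible(x)
}

#' @export
print.biomass_panel <- function(x, ...) {
  cat(sprintf("<biomass_panel> %d sites x %d species x %d years (%d-%d)\n",
              length(x$sites), length(x$species), length(x$years),
              min(x$years), max(x$years)))
  tot <- apply(x$biomass, 1, sum)
  cat(sprintf("  site total biomass (g/m2, summed over years): %.1f-%.1f\n",
              min(tot), max(tot)))
  invisible(x)
}

#' Construct a per-site climate panel
#'
#' Growing-season precipitation (mm) and mean temperature (degrees C) per
#' site and year.  The climate module applies the same CV/synchrony
#' estimators to these series that the partition module applies to biomass.
#'
#' @param precipitation numeric site x year matrix, mm, nonnegative.
#' @param temperature numeric site x year matrix, degrees C.
#' @param sites,years labels matching the matrix dimensions.
#' @return object of class `climate_panel`.
#' @export
climate_panel <- function(precipitation, temperature, sites, years) {
  sites <- as.character(sites)
  years <- as.integer(years)
  precipitation <- as.matrix(precipitation)
  temperature <- as.matrix(temperature)
  if (!all(dim(precipitation) == c(length(sites), length(years))) ||
      !all(dim(temperature) == c(length(sites), length(years))))
    stop("climate matrices must be site x year")
  if (any(!is.finite(precipitation)) || any(!is.finite(temperature)))
    stop("climate series contain non-finite entries")
  if (any(precipitation < 0)) stop("negative precipitation")
  dimnames(precipitation) <- dimnames(temperature) <-
    list(site = sites, year = years)
  structure(list(precipitation = precipitation, temperature = temperature,
                 sites = sites, years = years),
            class = "climate_panel")
}

#' @export
print.climate_panel <- function(x, ...) {
  cat(sprintf("<climate_panel> %d sites x %d years; MAP %.0f-%.0f mm, MAT %.1f-%.1f C\n",
              length(x$sites), length(x$years),
              min(rowMeans(x$precipitation)), max(rowMeans(x$precipitation)),
              min(rowMeans(x$temperature)), max(rowMeans(x$temperature))))
  invisible(x)
}

#' Construct a site coordinate table
#'
#' @param sites character site labels.
#' @param latitude,longitude decimal degrees.
#' @return object of class `site_coordinates` (a data.frame).
#' @export
site_coordinates <- function(sites, latitude, longitude) {
  if (any(abs(latitude) > 90)) stop("|latitude| must be <= 90")
  if (any(abs(longitude) > 180)) stop("|longitude| must be <= 180")
  structure(data.frame(site = as.character(sites),
                       latitude = as.numeric(latitude),
                       longitude = as.numeric(longitude),
                       stringsAsFactors = FALSE),
            class = c("site_coordinates", "data.frame"))
}
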