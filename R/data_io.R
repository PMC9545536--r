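#' Read a long-format biomass table
#'
#' Reads a CSV with columns `site`, `year`, `species`, `biomass` (optionally
#' `quadrat`) into a [biomass_panel()].  Replicate rows for the same
#' site-year-species (e.g. the three 1 m2 quadrats of a plot) are aggregated;
#' the default is the mean, which keeps per-m2 units.  Site-year-species
#' combinations absent from the file become structural zeros.
#'
#' @param path CSV file path (UTF-8, header row).
#' @param aggregation how replicate quadrat rows are combined: `"mean"`
#'   (default, preserves g/m2) or `"sum"`.
#' @return a validated [biomass_panel()].  Sites observed in different year
#'   runs keep their own `site_years`.
#' @export
read_biomass <- function(path, aggregation = c("mean", "sum")) {
  aggregation <- match.arg(aggregation)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "year", "species", "biomass")
  if (!all(need %in% names(df)))
    stop("biomass CSV must have columns site, year, species, biomass")
  bad <- which(!is.finite(df$biomass) | df$biomass < 0)
  if (length(bad))
    stop(sprintf("negative or non-finite biomass in row %d (site %s, year %s, species %s)",
                 bad[1], df$site[bad[1]], df$year[bad[1]], df$species[bad[1]]))
  agg <- stats::aggregate(
    biomass ~ site + year + species, data = df,
    FUN = if (aggregation == "mean") mean else sum)
  sites <- sort(unique(as.character(agg$site)))
  species <- sort(unique(as.character(agg$species)))
  years <- sort(unique(as.integer(agg$year)))
  b <- array(0, c(length(sites), length(species), length(years)),
             dimnames = list(site = sites, species = species, year = years))
  b[cbind(match(as.character(agg$site), sites),
          match(as.character(agg$species), species),
          match(as.integer(agg$year), years))] <- agg$biomass
  site_years <- lapply(sites, function(s)
    sort(unique(as.integer(agg$year[agg$site == s]))))
  names(site_years) <- sites
  short <- sites[vapply(site_years, length, 1L) < 3L]
  if (length(short))
    stop("site(s) with fewer than 3 observed years: ",
         paste(short, collapse = ", "))
  biomass_panel(b, sites, species, years, site_years = site_years)
}

.gs_months <- c("may", "jun", "jul", "aug", "sep", "oct")

#' Read a per-site climate table
#'
#' Reads a CSV with columns `site`, `year` and either yearly growing-season
#' values (`precipitation` in mm, `temperature` in degrees C) or monthly
#' May-October columns `prec_may`..`prec_oct` / `temp_may`..`temp_oct`.
#' Monthly precipitation is summed and monthly temperature averaged over the
#' May-October growing season (plants in the region are active only then).
#'
#' @param path CSV file path.
#' @return a [climate_panel()].
#' @export
read_climate <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("site", "year") %in% names(df)))
    stop("climate CSV must have columns site and year")
  pm <- paste0("prec_", .gs_months)
  tm <- paste0("temp_", .gs_months)
  if (all(pm %in% names(df)))
    df$precipitation <- rowSums(df[pm])
  if (all(tm %in% names(df)))
    df$temperature <- rowMeans(df[tm])
  if (!all(c("precipitation", "temperature") %in% names(df)))
    stop("climate CSV needs yearly precipitation/temperature columns, ",
         "or monthly prec_may..prec_oct and temp_may..temp_oct")
  if (any(!is.finite(df$precipitation)) || any(df$precipitation < 0))
    stop("negative or non-finite precipitation")
  sites <- sort(unique(as.character(df$site)))
  years <- sort(unique(as.integer(df$year)))
  full <- expand.grid(site = sites, year = years, stringsAsFactors = FALSE)
  key <- paste(df$site, df$year)
  miss <- full[!paste(full$site, full$year) %in% key, , drop = FALSE]
  if (nrow(miss))
    stop("missing climate site-year(s): ",
         paste(paste0(miss$site, ":", miss$year), collapse = ", "))
  P <- T_ <- matrix(NA_real_, length(sites), length(years))
  idx <- cbind(match(as.character(df$site), sites),
               match(as.integer(df$year), years))
  P[idx] <- df$precipitation
  T_[idx] <- df$temperature
  climate_panel(P, T_, sites, years)
}

#' Read a site coordinate table
#'
#' CSV with columns `site`, `latitude`, `longitude` (decimal degrees).
#'
#' @param path CSV file path.
#' @return a [site_coordinates()] table.
#' @export
read_coordinates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("site", "latitude", "longitude") %in% names(df)))
    stop("coordinate CSV must have columns site, latitude, longitude")
  site_coordinates(df$site, df$latitude, df$longitude)
}

#' Write an analysis result to disk
#'
#' Serializes package result objects losslessly: `read_results(write_results(x))`
#' returns an object with equal fields.  Partition, diversity, climate and
#' path-model results are written as JSON; resample-collection summary tables
#' as CSV (one row per set-community).
#'
#' @param results a result object (`partition_result`, `diversity_result`,
#'   `climate_summary`, `path_model`, `resample_collection`, or any list /
#'   data.frame).
#' @param path output file; extension `.json` or `.csv` selects the format
#'   (data.frames default to CSV, everything else to JSON).
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (inherits(results, "resample_collection")) results <- results$results
  if (is.data.frame(results) || grepl("\\.csv$", path)) {
    utils::write.csv(as.data.frame(results), path, row.names = FALSE)
  } else {
    cls <- class(results)
    # named atomic vectors as JSON objects so names survive the round-trip
    namify <- function(x) {
      if (is.list(x)) lapply(x, namify)
      else if (is.atomic(x) && !is.null(names(x))) as.list(x)
      else x
    }
    payload <- list(class = cls[1], data = namify(unclass(results)))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  }
  invisible(path)
}

#' Read back a result written by [write_results()]
#'
#' @param path file written by [write_results()].
#' @return the deserialized object; JSON results regain their class attribute.
#' @export
read_results <- function(path) {
  if (grepl("\\.csv$", path))
    return(utils::read.csv(path, stringsAsFactors = FALSE))
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- payload$data
  if (!is.null(payload$class) && payload$class != "list")
    class(out) <- payload$class
  out
}

#' Print a validation report for a biomass table
#'
#' Convenience wrapper over [read_biomass()] + [validate_biomass_panel()]:
#' reads the CSV, validates it, and prints a short report (dimensions, year
#' coverage per site, biomass range).
#'
#' @param path biomass CSV path.
#' @param aggregation passed to [read_biomass()].
#' @return the validated panel, invisibly.
#' @export
validate_biomass_file <- function(path, aggregation = "mean") {
  panel <- read_biomass(path, aggregation = aggregation)
  print(panel)
  yrs <- vapply(panel$site_years, length, 1L)
  cat(sprintf("  years per site: %s\n",
              paste(sprintf("%s=%d", names(yrs), yrs), collapse = " ")))
  cat("  validation: OK\n")
  invisible(panel)
}
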