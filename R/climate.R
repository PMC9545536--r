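#' Climate CV and spatial synchrony for a regional community
#'
#' Treats each member site's climate series (growing-season precipitation,
#' mean temperature) as a one-species community and applies the same
#' estimators used for biomass: local CV `sum_i sd_i / sum_i mean_i`,
#' spatial synchrony `sd(sum_i series_i) / sum_i sd_i`, regional CV their
#' product.  MAP/MAT are cross-site averages over the common years.
#'
#' @param cpanel a [climate_panel()].
#' @param members member sites (must be in `cpanel$sites`).
#' @param years optional integer years to use; default all years of the
#'   panel.  At least 3 are required.
#' @return object of class `climate_summary`: list with `MAP` (mm), `MAT`
#'   (degrees C), `CV_P_local`, `CV_P_regional`, `syn_P`, and the same for
#'   temperature (`_T`), plus `members`, `years`.
#' @export
climate_summary <- function(cpanel, members = cpanel$sites, years = NULL) {
  stopifnot(inherits(cpanel, "climate_panel"))
  members <- as.character(members)
  if (!all(members %in% cpanel$sites))
    stop("unknown member site(s): ",
         paste(setdiff(members, cpanel$sites), collapse = ", "))
  if (is.null(years)) years <- cpanel$years
  years <- sort(intersect(years, cpanel$years))
  if (length(years) < 3L)
    stop("at least 3 common years of climate data required")
  yc <- as.character(years)
  one <- function(X) {
    X <- X[members, yc, drop = FALSE]
    means <- rowMeans(X)
    sds <- apply(X, 1, stats::sd)
    tot <- sum(means)
    if (tot <= 0) stop("zero mean climate series over the community")
    cv_local <- sum(sds) / tot
    if (sum(sds) <= 0)
      stop("undefined: all member climate series are constant")
    syn <- stats::sd(colSums(X)) / sum(sds)
    list(mean = mean(means), cv_local = cv_local, syn = syn,
         cv_regional = syn * cv_local)
  }
  P <- one(cpanel$precipitation)
  T_ <- one(cpanel$temperature)
  structure(list(MAP = P$mean, MAT = T_$mean,
                 CV_P_local = P$cv_local, CV_P_regional = P$cv_regional,
                 syn_P = P$syn,
                 CV_T_local = T_$cv_local, CV_T_regional = T_$cv_regional,
                 syn_T = T_$syn,
                 members = members, years = years),
            class = "climate_summary")
}

#' @export
print.climate_summary <- function(x, digits = 3, ...) {
  cat(sprintf("<climate_summary> %s (%d years): MAP %.0f mm, MAT %.1f C\n",
              paste(x$members, collapse = "+"), length(x$years),
              x$MAP, x$MAT))
  cat(sprintf("  precipitation: CV_local %.3f, synchrony %.3f, CV_regional %.3f\n",
              x$CV_P_local, x$syn_P, x$CV_P_regional))
  cat(sprintf("  temperature:   CV_local %.3f, synchrony %.3f, CV_regional %.3f\n",
              x$CV_T_local, x$syn_T, x$CV_T_regional))
  invisible(x)
}
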