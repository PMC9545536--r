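#' Randomly partition sites into disjoint regional communities
#'
#' One resampled "set": the site pool is randomly separated, without
#' replacement, into `floor(n/m)` regional communities of `m` sites each
#' (default pairs), plus a remainder of leftover sites that are excluded from
#' that set.  Random disjoint grouping is uniform: every admissible grouping
#' is equally likely (a uniform random permutation is chunked into
#' consecutive blocks of `m`).
#'
#' @param sites character vector of available sites.
#' @param m community size (default 2; `m = 1` is allowed only for degenerate
#'   tests and triggers a warning).
#' @return list with `communities` (list of character vectors of length `m`)
#'   and `remainder` (character vector, possibly empty).
#' @export
pair_partition <- function(sites, m = 2L) {
  sites <- as.character(sites)
  m <- as.integer(m)
  if (m < 2L) warning("m < 2 builds single-site 'regional' communities; ",
                      "intended for degenerate tests only")
  if (length(sites) < m) stop("need at least m sites")
  perm <- sample(sites)
  n_comm <- length(sites) %/% m
  used <- perm[seq_len(n_comm * m)]
  communities <- split(used, rep(seq_len(n_comm), each = m))
  names(communities) <- NULL
  list(communities = communities,
       remainder = perm[-seq_len(n_comm * m)])
}

#' Great-circle distance between the sites of a community
#'
#' Haversine distance (km, mean Earth radius 6371.0088 km) between the two
#' member sites of a pair community; for `m > 2` the mean over all member
#' pairs is returned.
#'
#' @param coords a [site_coordinates()] table.
#' @param community character vector of member sites.
#' @return distance in km.
#' @export
pair_distance <- function(coords, community) {
  idx <- match(community, coords$site)
  if (anyNA(idx))
    stop("missing coordinates for site(s): ",
         paste(community[is.na(idx)], collapse = ", "))
  lat <- coords$latitude[idx] * pi / 180
  lon <- coords$longitude[idx] * pi / 180
  R <- 6371.0088
  hav <- function(i, j) {
    dlat <- lat[j] - lat[i]; dlon <- lon[j] - lon[i]
    a <- sin(dlat / 2)^2 + cos(lat[i]) * cos(lat[j]) * sin(dlon / 2)^2
    2 * R * asin(pmin(1, sqrt(a)))
  }
  pairs <- utils::combn(seq_along(community), 2)
  mean(hav(pairs[1, ], pairs[2, ]))
}

#' Build a collection of resampled regional-community sets
#'
#' Repeats the random disjoint pairing `n_sets` times (default 1000) and runs
#' the full per-community analysis for every community of every set:
#' hierarchical CV/synchrony partition ([partition_hierarchy()]), diversity
#' indices ([diversity_indices()]), and, when climate/coordinates are given,
#' climate summaries ([climate_summary()]) and between-site distances.  This
#' collection is the unit on which the randomized-examination significance
#' procedure operates.
#'
#' @param panel a [biomass_panel()].
#' @param n_sets number of resampled sets (default 1000).
#' @param m community size (default 2).
#' @param seed integer seed; recorded in the result.  `NULL` leaves the RNG
#'   state untouched.
#' @param threshold dominance threshold.
#' @param convention dominant-measure convention, see [partition_hierarchy()].
#' @param climate optional [climate_panel()].
#' @param coords optional [site_coordinates()].
#' @param alpha_method see [effective_richness()].
#' @return object of class `resample_collection`: list with `results` (one
#'   data.frame row per set-community: components as columns, dominant
#'   variants prefixed `dom_`, diversity, climate, distance), `sets` (the
#'   memberships), `n_sets`, `m`, `seed`, `failed` (count of communities that
#'   failed preconditions; they are recorded with `ok = FALSE`, not dropped).
#' @export
build_collection <- function(panel, n_sets = 1000L, m = 2L, seed = NULL,
                             threshold = 0.05,
                             convention = c("typeset", "masked"),
                             climate = NULL, coords = NULL,
                             alpha_method = "mean_D") {
  convention <- match.arg(convention)
  if (!is.null(seed)) set.seed(seed)
  sets <- vector("list", n_sets)
  rows <- list()
  for (s in seq_len(n_sets)) {
    part <- pair_partition(panel$sites, m)
    sets[[s]] <- part
    rows <- c(rows, lapply(seq_along(part$communities), function(ci) {
      comm <- part$communities[[ci]]
      base <- data.frame(set = s, community = ci,
                         members = paste(comm, collapse = "+"),
                         stringsAsFactors = FALSE)
      res <- tryCatch({
        pr <- partition_hierarchy(panel, comm, threshold, convention)
        dv <- diversity_indices(panel, comm, threshold, alpha_method)
        out <- c(as.list(pr$all),
                 stats::setNames(as.list(pr$dominant),
                                 paste0("dom_", names(pr$dominant))),
                 as.list(dv$all),
                 stats::setNames(as.list(dv$dominant),
                                 paste0("dom_", names(dv$dominant))))
        if (!is.null(climate)) {
          cs <- climate_summary(climate, comm)
          out <- c(out, unclass(cs)[c("MAP", "MAT", "CV_P_local", "CV_T_local",
                                      "CV_P_regional", "CV_T_regional",
                                      "syn_P", "syn_T")])
        }
        if (!is.null(coords))
          out$distance_km <- pair_distance(coords, comm)
        out$ok <- TRUE
        out$error <- NA_character_
        out
      }, error = function(e) list(ok = FALSE, error = conditionMessage(e)))
      for (nm in names(res)) base[[nm]] <- res[[nm]]
      base
    }))
  }
  # harmonize columns across failed/successful rows
  all_cols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(df) {
    for (nm in setdiff(all_cols, names(df))) df[[nm]] <- NA
    df[all_cols]
  })
  results <- do.call(rbind, rows)
  structure(list(results = results, sets = sets, n_sets = n_sets, m = m,
                 seed = seed, threshold = threshold, convention = convention,
                 failed = sum(!results$ok)),
            class = "resample_collection")
}

#' @export
print.resample_collection <- function(x, ...) {
  cat(sprintf("<resample_collection> %d sets x %d communities of %d site(s); seed %s\n",
              x$n_sets, length(x$sets[[1]]$communities), x$m,
              if (is.null(x$seed)) "<none>" else x$seed))
  if (x$failed) cat(sprintf("  %d community analyses failed preconditions\n",
                            x$failed))
  invisible(x)
}

#' Mean of each component across all resampled communities
#'
#' The per-collection analogue of reporting component means across the 1000
#' sets: averages every numeric column of the per-community table over all
#' successfully analyzed communities.
#'
#' @param collection a [build_collection()] result.
#' @return named numeric vector of means.
#' @export
collection_means <- function(collection) {
  df <- collection$results[collection$results$ok, , drop = FALSE]
  num <- vapply(df, is.numeric, logical(1))
  num[c("set", "community")] <- FALSE
  colMeans(df[num], na.rm = TRUE)
}
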