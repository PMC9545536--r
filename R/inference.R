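#' Per-set correlation or regression statistics
#'
#' Computes, within every resampled set of a collection (n = communities per
#' set, default 10), the Pearson correlation between two component variables,
#' or the OLS slope and R2 of `y ~ x`.  Sets in which either variable is
#' constant (zero variance) or contains missing values are flagged invalid
#' and excluded from the proportions of the randomized examination, with a
#' count retained.
#'
#' @param collection a [build_collection()] result.
#' @param x,y column names of `collection$results` (e.g. `"cv_comm_regional"`,
#'   `"syn_species_local"`, `"dom_cv_pop_local"`, `"D_alpha"`, `"CV_P_local"`).
#' @param kind `"correlation"` (default) or `"regression"`.
#' @return data.frame with one row per set: `set`, `stat` (rho or slope),
#'   `r2`, `n`, `valid`.
#' @export
per_set_statistics <- function(collection, x, y,
                               kind = c("correlation", "regression")) {
  kind <- match.arg(kind)
  df <- collection$results
  if (!all(c(x, y) %in% names(df)))
    stop("unknown variable(s): ",
         paste(setdiff(c(x, y), names(df)), collapse = ", "))
  out <- lapply(split(df, df$set), function(d) {
    d <- d[d$ok & is.finite(d[[x]]) & is.finite(d[[y]]), , drop = FALSE]
    n <- nrow(d)
    xs <- d[[x]]; ys <- d[[y]]
    valid <- n >= 3 && stats::sd(xs) > 0 && stats::sd(ys) > 0
    if (!valid)
      return(data.frame(set = d$set[1], stat = NA_real_, r2 = NA_real_,
                        n = n, valid = FALSE))
    r <- stats::cor(xs, ys)
    stat <- if (kind == "correlation") r else r * stats::sd(ys) / stats::sd(xs)
    data.frame(set = d$set[1], stat = stat, r2 = r^2, n = n, valid = TRUE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Randomized-examination significance of a per-set statistic
#'
#' The resampling significance rule: compute the statistic in each resampled
#' set, take the mean over sets, and call it significant when the proportion
#' of sets with the opposite sign is below `alpha` (marginally significant
#' below `alpha_marginal`).  For a positive mean the opposite-sign proportion
#' is `P_minus` (fraction of sets with statistic < 0); for a negative mean it
#' is `P_plus`.
#'
#' @param stats either a numeric vector of per-set statistics or the
#'   data.frame returned by [per_set_statistics()] (its `stat` column is
#'   used; invalid sets are excluded).
#' @param alpha significance threshold on the opposite-sign proportion
#'   (default 0.05).
#' @param alpha_marginal marginal threshold (default 0.10).
#' @return object of class `randomized_test`: list with `mean_stat`,
#'   `P_minus`, `P_plus`, `P_zero`, `verdict` (`"significant"`, `"marginal"`,
#'   or `"ns"`), `n_sets`, `n_valid`.
#' @export
randomized_examination <- function(stats, alpha = 0.05,
                                   alpha_marginal = 0.10) {
  if (is.data.frame(stats)) {
    n_sets <- nrow(stats)
    v <- stats$stat[stats$valid]
  } else {
    n_sets <- length(stats)
    v <- stats[is.finite(stats)]
  }
  if (length(v) < 2L) stop("fewer than 2 valid sets")
  m <- mean(v)
  P_minus <- mean(v < 0)
  P_plus <- mean(v > 0)
  P_opp <- if (m > 0) P_minus else if (m < 0) P_plus else 1
  verdict <- if (P_opp < alpha) "significant"
             else if (P_opp < alpha_marginal) "marginal" else "ns"
  structure(list(mean_stat = m, P_minus = P_minus, P_plus = P_plus,
                 P_zero = mean(v == 0), verdict = verdict,
                 n_sets = n_sets, n_valid = length(v),
                 alpha = alpha, alpha_marginal = alpha_marginal),
            class = "randomized_test")
}

#' @export
print.randomized_test <- function(x, ...) {
  cat(sprintf("<randomized_test> mean = %.3f, P- = %.3f, P+ = %.3f -> %s (%d/%d valid sets)\n",
              x$mean_stat, x$P_minus, x$P_plus, x$verdict, x$n_valid,
              x$n_sets))
  invisible(x)
}

#' Explanatory power of dominant-species components
#'
#' For a hierarchy component, regresses the all-species value on its
#' dominant-species counterpart within each set and averages the R2 across
#' sets (R-bar-squared): how much of the all-species dynamics the dominant
#' species alone explain.
#'
#' @param collection a [build_collection()] result.
#' @param component component name without prefix, e.g. `"cv_comm_local"`;
#'   the dominant counterpart column `dom_<component>` must exist (for the
#'   regional community CV use e.g. `"cv_comm_regional"` which is paired with
#'   `dom_cv_comm_regional_I` via `dominant_column`).
#' @param dominant_column optional explicit dominant-variant column name.
#' @return list with `mean_r2`, `per_set` (the [per_set_statistics()] table),
#'   `component`.
#' @export
dominance_explained <- function(collection, component,
                                dominant_column = NULL) {
  if (is.null(dominant_column)) {
    dominant_column <- paste0("dom_", component)
    if (!dominant_column %in% names(collection$results) &&
        component == "cv_comm_regional")
      dominant_column <- "dom_cv_comm_regional_I"
  }
  if (!dominant_column %in% names(collection$results))
    stop("dominant variant column not found: ", dominant_column)
  ps <- per_set_statistics(collection, x = dominant_column, y = component,
                           kind = "regression")
  list(mean_r2 = mean(ps$r2[ps$valid]), per_set = ps, component = component,
       dominant_column = dominant_column)
}

#' Small-sample corrected AIC
#'
#' `AICc = AIC + 2 k (k + 1) / (n - k - 1)` with `k` the number of estimated
#' parameters (regression coefficients plus the residual variance) and `n`
#' the number of observations.
#'
#' @param fit an `lm` fit, or a numeric AIC value.
#' @param n number of observations (required when `fit` is numeric).
#' @param k number of parameters (required when `fit` is numeric).
#' @return the AICc value.
#' @export
aicc <- function(fit, n = NULL, k = NULL) {
  if (inherits(fit, "lm")) {
    ll <- stats::logLik(fit)
    k <- attr(ll, "df")
    n <- stats::nobs(fit)
    aic <- -2 * as.numeric(ll) + 2 * k
  } else {
    aic <- fit
    if (is.null(n) || is.null(k)) stop("numeric AIC needs n and k")
  }
  if (n - k - 1 <= 0) return(Inf)
  aic + 2 * k * (k + 1) / (n - k - 1)
}

#' Default initial path-model edge lists
#'
#' The two pathway-specific initial structural models relating the
#' (all-species) regional community CV to its hierarchical components, with
#' optional diversity and climate predictors.  Pathway I explains the
#' regional community CV by the local community CV and regional community
#' synchrony, the local community CV by the local population CV and local
#' species synchrony.  Pathway II explains it by the regional population CV
#' and regional species synchrony, the regional population CV by the local
#' population CV and regional population synchrony (a theory-mandated path,
#' shipped locked).
#'
#' @param pathway `"I"` or `"II"`.
#' @param dominant use the dominant-species components (prefixed `dom_`) as
#'   predictors of the all-species regional community CV.
#' @param diversity add effective-richness predictors (alpha on local terms,
#'   beta/gamma on regional terms).
#' @param climate add precipitation mean/variability predictors (requires a
#'   collection built with a climate panel).
#' @return data.frame with columns `from`, `to`, `locked`.
#' @export
path_model_spec <- function(pathway = c("I", "II"), dominant = FALSE,
                            diversity = TRUE, climate = FALSE) {
  pathway <- match.arg(pathway)
  p <- function(x) if (dominant) paste0("dom_", x) else x
  if (pathway == "I") {
    e <- rbind(
      c(p("cv_comm_local"), "cv_comm_regional", TRUE),
      c(p("syn_comm_regional"), "cv_comm_regional", TRUE),
      c(p("cv_pop_local"), p("cv_comm_local"), TRUE),
      c(p("syn_species_local"), p("cv_comm_local"), TRUE))
    if (diversity) e <- rbind(e,
      c("D_alpha", p("cv_pop_local"), FALSE),
      c("D_alpha", p("syn_species_local"), FALSE),
      c("D_beta", p("syn_comm_regional"), FALSE))
    if (climate) e <- rbind(e,
      c("MAP", p("cv_pop_local"), FALSE),
      c("CV_P_local", p("syn_species_local"), FALSE),
      c("syn_P", p("syn_comm_regional"), FALSE))
  } else {
    e <- rbind(
      c(p("cv_pop_regional"), "cv_comm_regional", TRUE),
      c(p("syn_species_regional"), "cv_comm_regional", TRUE),
      c(p("cv_pop_local"), p("cv_pop_regional"), TRUE),
      c(p("syn_pop_regional"), p("cv_pop_regional"), TRUE))
    if (diversity) e <- rbind(e,
      c("D_alpha", p("cv_pop_local"), FALSE),
      c("D_gamma", p("syn_species_regional"), FALSE),
      c("D_gamma", p("cv_pop_regional"), FALSE))
    if (climate) e <- rbind(e,
      c("MAP", p("cv_pop_local"), FALSE),
      c("syn_P", p("syn_pop_regional"), FALSE))
  }
  data.frame(from = e[, 1], to = e[, 2], locked = as.logical(e[, 3]),
             stringsAsFactors = FALSE)
}

.check_acyclic <- function(edges) {
  nodes <- union(edges$from, edges$to)
  ord <- character(0)
  rem <- edges
  repeat {
    src <- setdiff(nodes, rem$to)
    src <- setdiff(src, ord)
    if (!length(src)) break
    ord <- c(ord, src)
    rem <- rem[!rem$from %in% src, , drop = FALSE]
    nodes <- setdiff(nodes, src)
    if (!nrow(rem)) { ord <- c(ord, nodes); nodes <- character(0); break }
  }
  if (length(nodes)) stop("path-model edge list contains a cycle")
  invisible(TRUE)
}

#' Fit a piecewise path model across resampled sets
#'
#' Each endogenous node (a node with at least one incoming edge) is fitted by
#' ordinary least squares on its parents, within every resampled set, on
#' variables z-scored within the set (so coefficients are standardized, and a
#' single-predictor slope equals the correlation).  Coefficients are averaged
#' over sets; each edge gets a randomized-examination verdict from its
#' per-set coefficient distribution; per-equation AICc values are summed per
#' set and averaged.
#'
#' @param collection a [build_collection()] result.
#' @param edges data.frame with columns `from`, `to` and optionally `locked`
#'   (see [path_model_spec()]).
#' @param alpha,alpha_marginal randomized-examination thresholds.
#' @return object of class `path_model`: list with `edges` (adds `coef`
#'   = mean standardized coefficient, `P_opposite`, `verdict`), `r2` (mean R2
#'   per endogenous node), `aicc` (mean total AICc across sets), `n_valid`
#'   (valid sets), `coef_sets` (per-set coefficient matrix), `provenance`.
#' @export
fit_path_model <- function(collection, edges, alpha = 0.05,
                           alpha_marginal = 0.10) {
  if (is.null(edges$locked)) edges$locked <- FALSE
  .check_acyclic(edges)
  vars <- union(edges$from, edges$to)
  df <- collection$results
  missing_vars <- setdiff(vars, names(df))
  if (length(missing_vars))
    stop("variables not in collection: ", paste(missing_vars, collapse = ", "))
  endo <- unique(edges$to)
  sets <- split(df, df$set)
  edge_id <- paste(edges$from, "->", edges$to)
  coef_sets <- matrix(NA_real_, length(sets), nrow(edges),
                      dimnames = list(names(sets), edge_id))
  r2_sets <- matrix(NA_real_, length(sets), length(endo),
                    dimnames = list(names(sets), endo))
  aicc_sets <- rep(NA_real_, length(sets))
  for (s in seq_along(sets)) {
    d <- sets[[s]]
    d <- d[d$ok, , drop = FALSE]
    X <- d[vars]
    if (nrow(X) < 4 || anyNA(X) || any(!is.finite(as.matrix(X)))) next
    sds <- vapply(X, stats::sd, numeric(1))
    if (any(sds == 0)) next                       # singular design: flagged
    Z <- as.data.frame(scale(X))
    tot_aicc <- 0
    ok <- TRUE
    for (node in endo) {
      parents <- edges$from[edges$to == node]
      fit <- stats::lm(stats::reformulate(parents, response = node), data = Z)
      cf <- stats::coef(fit)[parents]
      if (anyNA(cf)) { ok <- FALSE; break }
      coef_sets[s, edges$to == node] <-
        cf[match(edges$from[edges$to == node], parents)]
      r2_sets[s, node] <- summary(fit)$r.squared
      tot_aicc <- tot_aicc + aicc(fit)
    }
    if (ok) aicc_sets[s] <- tot_aicc else coef_sets[s, ] <- NA_real_
  }
  valid <- is.finite(aicc_sets)
  if (!any(valid))
    stop("no valid sets: path model could not be fitted ",
         "(each equation needs at least k + 2 communities per set, ",
         "k = parents + 2, and non-constant variables)")
  tests <- lapply(seq_len(nrow(edges)), function(e)
    randomized_examination(coef_sets[valid, e], alpha, alpha_marginal))
  edges$coef <- vapply(tests, function(t) t$mean_stat, numeric(1))
  edges$P_opposite <- vapply(tests, function(t)
    if (t$mean_stat >= 0) t$P_minus else t$P_plus, numeric(1))
  edges$verdict <- vapply(tests, function(t) t$verdict, character(1))
  structure(list(edges = edges,
                 r2 = colMeans(r2_sets[valid, , drop = FALSE]),
                 aicc = mean(aicc_sets[valid]),
                 n_valid = sum(valid),
                 coef_sets = coef_sets,
                 alpha = alpha, alpha_marginal = alpha_marginal,
                 provenance = "initial",
                 collection = collection),
            class = "path_model")
}

#' @export
print.path_model <- function(x, digits = 2, ...) {
  cat(sprintf("<path_model> (%s) %d edges, mean total AICc %.2f, %d valid sets\n",
              x$provenance, nrow(x$edges), x$aicc, x$n_valid))
  e <- x$edges
  mark <- ifelse(e$verdict == "significant", "*",
                 ifelse(e$verdict == "marginal", "#", " "))
  cat(sprintf("  %s -> %s: %.2f%s%s\n", e$from, e$to, e$coef, mark,
              ifelse(e$locked, " [locked]", "")), sep = "")
  cat("  R2:", paste(sprintf("%s %.2f", names(x$r2), x$r2), collapse = ", "),
      "\n")
  invisible(x)
}

#' Prune nonsignificant paths from a path model
#'
#' Iteratively removes the weakest nonsignificant, unlocked edge — largest
#' opposite-sign proportion first, ties broken by smallest |coefficient| and
#' then alphabetically — refitting after each removal, as long as the mean
#' total AICc does not increase.  Stops when only significant or marginally
#' significant paths remain, when removal would increase AICc, or when only
#' locked edges are left.  Locked (theory-mandated) edges are never removed.
#'
#' @param model a fitted [fit_path_model()] result.
#' @return the pruned `path_model` (provenance `"pruned"`); the input model
#'   unchanged if nothing is removable.
#' @export
prune_path_model <- function(model) {
  coll <- model$collection
  current <- model
  repeat {
    e <- current$edges
    cand <- which(e$verdict == "ns" & !e$locked)
    if (!length(cand)) break
    ord <- cand[order(-e$P_opposite[cand], abs(e$coef[cand]),
                      e$from[cand], e$to[cand])]
    drop <- ord[1]
    reduced <- e[-drop, c("from", "to", "locked")]
    # dropping the last incoming edge of a node removes that equation
    refit <- fit_path_model(coll, reduced, model$alpha, model$alpha_marginal)
    if (refit$aicc > current$aicc) break
    refit$provenance <- "pruned"
    current <- refit
  }
  if (identical(current$provenance, "initial") &&
      !identical(current, model)) current$provenance <- "pruned"
  current
}
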