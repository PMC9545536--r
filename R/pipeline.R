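#' Run the full hierarchical stability analysis pipeline
#'
#' Orchestrates the stages validate -> ingest (or simulate) -> resample ->
#' partition/diversity/climate -> infer -> report as one reproducible,
#' seed-stamped run.  Inputs are either file paths (CSV dialects of
#' [read_biomass()] / [read_climate()] / [read_coordinates()]) or in-memory
#' panels; alternatively a [sim_config()] generates synthetic inputs.
#' Outputs written under `out_dir`: the per-set community table
#' (`communities.csv`), component means over sets (`summary_means.json`),
#' randomized-examination verdicts for the hierarchy steps
#' (`randomized_tests.csv`), fitted and pruned path models
#' (`path_model_*.json`), dominance explanatory power
#' (`dominance_explained.csv`), a config snapshot (`run_config.json`), and a
#' plain-text log with per-stage timing (`run.log`).
#'
#' @param biomass a [biomass_panel()] or path to a biomass CSV.  Ignored if
#'   `sim` is given.
#' @param out_dir output directory (created if needed).
#' @param climate optional [climate_panel()] or CSV path.
#' @param coords optional [site_coordinates()] or CSV path.
#' @param sim optional [sim_config()]; when given, inputs are simulated.
#' @param n_sets number of resampled sets (default 1000).
#' @param m community size (default 2).
#' @param threshold dominance threshold (default 0.05).
#' @param seed integer seed governing resampling (and simulation, unless the
#'   sim config carries its own).
#' @param convention dominant-measure convention (see [partition_hierarchy()]).
#' @param models named list of path-model edge lists to fit and prune;
#'   default the pathway I and II specs of [path_model_spec()] (with climate
#'   terms when a climate panel is available).
#' @return (invisibly) list with `collection`, `means`, `tests`, `models`
#'   (each entry: `initial` and `pruned` path models), `out_dir`.
#' @export
run_pipeline <- function(biomass = NULL, out_dir, climate = NULL,
                         coords = NULL, sim = NULL, n_sets = 1000L, m = 2L,
                         threshold = 0.05, seed = 1L,
                         convention = c("typeset", "masked"),
                         models = NULL) {
  convention <- match.arg(convention)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)
  t0 <- proc.time()[["elapsed"]]
  say <- function(fmt, ...) {
    msg <- sprintf("[%7.2fs] %s", proc.time()[["elapsed"]] - t0,
                   sprintf(fmt, ...))
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }

  stage <- "ingest"
  res <- tryCatch({
    if (!is.null(sim)) {
      say("simulate: generating synthetic panel (%d sites x %d species x %d years)",
          sim$n_sites, sim$n_species, sim$n_years)
      if (is.null(sim$seed)) sim$seed <- seed
      g <- generate_panel(sim)
      biomass <- g$panel
      if (is.null(climate)) climate <- g$climate
    }
    if (is.character(biomass)) biomass <- read_biomass(biomass)
    if (is.null(biomass)) stop("no biomass input: give `biomass` or `sim`")
    if (is.character(climate)) climate <- read_climate(climate)
    if (is.character(coords)) coords <- read_coordinates(coords)
    validate_biomass_panel(biomass)
    say("validate: %d sites, %d species, %d years OK",
        length(biomass$sites), length(biomass$species),
        length(biomass$years))

    stage <- "resample"
    coll <- build_collection(biomass, n_sets = n_sets, m = m, seed = seed,
                             threshold = threshold, convention = convention,
                             climate = climate, coords = coords)
    say("resample: %d sets x %d communities (%d failed)", coll$n_sets,
        length(coll$sets[[1]]$communities), coll$failed)
    write_results(coll, file.path(out_dir, "communities.csv"))

    stage <- "summarize"
    means <- collection_means(coll)
    jsonlite::write_json(
      c(list(seed = seed, n_sets = n_sets, m = m, threshold = threshold,
             package_version = as.character(utils::packageVersion("hierstab"))),
        as.list(means)),
      file.path(out_dir, "summary_means.json"), auto_unbox = TRUE,
      digits = NA)

    stage <- "infer"
    steps <- rbind(
      c("cv_comm_local", "cv_comm_regional"),
      c("syn_comm_regional", "cv_comm_regional"),
      c("cv_pop_local", "cv_comm_local"),
      c("syn_species_local", "cv_comm_local"),
      c("cv_pop_regional", "cv_comm_regional"),
      c("syn_species_regional", "cv_comm_regional"),
      c("cv_pop_local", "cv_pop_regional"),
      c("syn_pop_regional", "cv_pop_regional"))
    tests <- do.call(rbind, lapply(seq_len(nrow(steps)), function(i) {
      rt <- randomized_examination(
        per_set_statistics(coll, steps[i, 1], steps[i, 2]))
      data.frame(x = steps[i, 1], y = steps[i, 2],
                 mean_rho = rt$mean_stat, P_minus = rt$P_minus,
                 P_plus = rt$P_plus, verdict = rt$verdict,
                 n_valid = rt$n_valid)
    }))
    write_results(tests, file.path(out_dir, "randomized_tests.csv"))
    comp <- c("cv_pop_local", "syn_species_local", "cv_comm_local",
              "syn_comm_regional", "syn_pop_regional", "cv_pop_regional",
              "syn_species_regional", "cv_comm_regional")
    dom <- do.call(rbind, lapply(comp, function(cc) {
      de <- dominance_explained(coll, cc)
      data.frame(component = cc, mean_r2 = de$mean_r2)
    }))
    write_results(dom, file.path(out_dir, "dominance_explained.csv"))

    if (is.null(models))
      models <- list(
        pathway_I = path_model_spec("I", climate = !is.null(climate)),
        pathway_II = path_model_spec("II", climate = !is.null(climate)),
        pathway_I_dominant = path_model_spec("I", dominant = TRUE,
                                             climate = !is.null(climate)),
        pathway_II_dominant = path_model_spec("II", dominant = TRUE,
                                              climate = !is.null(climate)))
    fitted <- lapply(names(models), function(nm) {
      say("infer: fitting path model %s", nm)
      init <- fit_path_model(coll, models[[nm]])
      pruned <- prune_path_model(init)
      for (tag in c("initial", "pruned")) {
        mdl <- if (tag == "initial") init else pruned
        jsonlite::write_json(
          list(model = nm, provenance = tag, seed = seed,
               edges = mdl$edges, r2 = as.list(mdl$r2), aicc = mdl$aicc,
               n_valid = mdl$n_valid),
          file.path(out_dir, sprintf("path_model_%s_%s.json", nm, tag)),
          auto_unbox = TRUE, digits = NA)
      }
      list(initial = init, pruned = pruned)
    })
    names(fitted) <- names(models)

    stage <- "report"
    jsonlite::write_json(
      list(seed = seed, n_sets = n_sets, m = m, threshold = threshold,
           convention = convention,
           package_version = as.character(utils::packageVersion("hierstab")),
           simulated = !is.null(sim),
           sim_config = if (!is.null(sim)) unclass(sim)),
      file.path(out_dir, "run_config.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
    say("done")
    list(collection = coll, means = means, tests = tests, models = fitted,
         out_dir = out_dir)
  }, error = function(e) {
    say("ERROR in stage '%s': %s", stage, conditionMessage(e))
    stop(sprintf("pipeline failed in stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}
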