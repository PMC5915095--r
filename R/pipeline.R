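# End-to-end orchestration: one config in, a reproducible report bundle out.

#' Build a run configuration
#'
#' @param peaks,panel,compounds,assays input file paths (peak list TSV/CSV,
#'   panel CSV, store CSVs).
#' @param keys optional key-list CSV; defaults to the packaged starter list.
#' @param out_dir output directory for the report bundle.
#' @param ppm_tol formula assignment tolerance in ppm (default 1).
#' @param inhibition_threshold panel significance threshold in percent
#'   (default 50).
#' @param potency_cutoff_nm,percent_cutoff activity hashing cutoffs
#'   (defaults 10000 nM / 50 percent).
#' @param well_fitted_threshold minimum fit score for the well-fitted set
#'   (default 1).
#' @param seed integer recorded in the manifest (the pipeline itself is
#'   deterministic; the seed documents upstream data generation).
#' @return list of class `"runConfig"`.
#' @export
runConfig <- function(peaks, panel, compounds, assays, keys = NULL,
                      out_dir = tempfile("massderep-run-"),
                      ppm_tol = 1, inhibition_threshold = 50,
                      potency_cutoff_nm = 10000, percent_cutoff = 50,
                      well_fitted_threshold = 1, seed = NA_integer_) {
  cfg <- list(peaks = peaks, panel = panel, compounds = compounds,
              assays = assays, keys = keys, out_dir = out_dir,
              ppm_tol = ppm_tol, inhibition_threshold = inhibition_threshold,
              potency_cutoff_nm = potency_cutoff_nm,
              percent_cutoff = percent_cutoff,
              well_fitted_threshold = well_fitted_threshold, seed = seed)
  class(cfg) <- "runConfig"
  cfg
}

#' Read a run configuration from JSON
#' @param file JSON file with the fields of [runConfig()].
#' @return a `"runConfig"` list.
#' @export
readRunConfig <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  do.call(runConfig, x)
}

.validateConfig <- function(config) {
  stopifnot(inherits(config, "runConfig"))
  with(config, stopifnot(ppm_tol > 0, inhibition_threshold > 0,
                         potency_cutoff_nm > 0, percent_cutoff > 0))
  for (f in c("peaks", "panel", "compounds", "assays")) {
    if (!file.exists(config[[f]]))
      stop("config error: input file for '", f, "' not found: ", config[[f]])
  }
  if (!is.null(config$keys) && !file.exists(config$keys))
    stop("config error: key list not found: ", config$keys)
  invisible(config)
}

.stage <- function(name, ...) message("[", name, "] ", ...)

#' Run the full dereplication pipeline
#'
#' Executes every stage in order — formula assignment, Van Krevelen
#' classification, panel profile construction, store mining, fit scoring,
#' per-target tallies and scaffold distributions — and writes the report
#' bundle plus a manifest (config, package version, seed) to
#' `config$out_dir`. Outputs are pure functions of the inputs and the
#' config, so re-runs are byte-identical.
#'
#' @param config a [runConfig()] object (or JSON path).
#' @return invisibly, a list with all in-memory stage results and `files`,
#'   the named vector of written paths.
#' @export
runAll <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  .validateConfig(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  outfile <- function(name) file.path(config$out_dir, name)

  .stage("assign", "reading peaks and assigning CHO formulas")
  peaks <- readPeaklist(config$peaks)
  assignments <- assignPeaklist(peaks, tol_ppm = config$ppm_tol)
  writeAssignments(assignments, outfile("assignments.tsv"))
  files["assignments"] <- outfile("assignments.tsv")
  .stage("assign", sum(assignments$assigned), " of ", nrow(assignments),
         " peaks assigned")

  .stage("vk", "Van Krevelen classification")
  vk <- vkTable(assignments)
  utils::write.table(vk, outfile("vk_table.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files["vk_table"] <- outfile("vk_table.tsv")

  .stage("profile", "building panel target profile")
  profile <- buildProfile(readPanel(config$panel),
                          threshold = config$inhibition_threshold)
  ps <- profileSummary(profile)
  utils::write.csv(profile@data, outfile("profile.csv"), row.names = FALSE)
  files["profile"] <- outfile("profile.csv")
  .stage("profile", ps$n_active, " active / ", ps$n_inactive, " inactive / ",
         ps$n_excluded, " excluded")

  .stage("mine", "matching formulas and building fingerprints")
  store <- readStore(config$compounds, config$assays)
  keys <- if (is.null(config$keys)) panelKeyList() else
    readKeyList(config$keys)
  ms_formulas <- unique(assignments[assignments$assigned, c("c", "h", "o")])
  mined <- mineActivities(ms_formulas, store, keys,
                          panel_targets = panelTargets(profile),
                          potency_cutoff_nm = config$potency_cutoff_nm,
                          percent_cutoff = config$percent_cutoff)
  fpm <- fingerprintMatrix(mined$fingerprints)
  utils::write.csv(data.frame(compound_id = rownames(fpm), fpm,
                              check.names = FALSE, stringsAsFactors = FALSE),
                   outfile("fingerprints.csv"), row.names = FALSE)
  files["fingerprints"] <- outfile("fingerprints.csv")
  .stage("mine", nrow(mined$compounds), " formula-matched compounds, ",
         nrow(mined$hits), " assay hits")

  .stage("score", "fit scoring against the panel profile")
  results <- scoreFingerprints(mined$fingerprints, profile,
                               well_fitted_threshold =
                                 config$well_fitted_threshold)
  wf <- selectWellFitted(results, config$well_fitted_threshold)
  writeFitResults(results, outfile("fit_results.csv"))
  files["fit_results"] <- outfile("fit_results.csv")
  tally <- perTargetTally(results)
  utils::write.csv(tally, outfile("per_target_tally.csv"), row.names = FALSE)
  files["tally"] <- outfile("per_target_tally.csv")
  totals <- matchMismatchTotals(results)
  .stage("score", length(wf), " well-fitted compounds; ",
         totals["total_matching"], " matching / ",
         totals["total_mismatching"], " mismatching records")

  .stage("scaffold", "Murcko scaffold distributions")
  comp <- mined$compounds
  smiles_all <- comp$smiles[!is.na(comp$smiles)]
  wf_ids <- rownames(fitMatrix(wf))
  smiles_wf <- comp$smiles[comp$compound_id %in% wf_ids & !is.na(comp$smiles)]
  sc_all <- scaffoldDistribution(smiles_all, cohort_label = "all")
  sc_wf <- scaffoldDistribution(smiles_wf, cohort_label = "well_fitted")
  utils::write.csv(sc_all, outfile("scaffolds_all.csv"), row.names = FALSE)
  utils::write.csv(sc_wf, outfile("scaffolds_well_fitted.csv"),
                   row.names = FALSE)
  files["scaffolds_all"] <- outfile("scaffolds_all.csv")
  files["scaffolds_well_fitted"] <- outfile("scaffolds_well_fitted.csv")

  exportTargetList(profile, outfile("target_symbols.txt"))
  files["target_list"] <- outfile("target_symbols.txt")

  summary <- list(
    n_peaks = nrow(assignments),
    n_assigned = sum(assignments$assigned),
    n_assigned_z1 = sum(assignments$assigned & assignments$z == 1L),
    n_assigned_z2 = sum(assignments$assigned & assignments$z == 2L),
    number_averaged_composition =
      as.list(numberAveragedComposition(assignments[assignments$assigned, ])),
    panel = ps,
    n_matched_compounds = nrow(mined$compounds),
    n_assay_hits = nrow(mined$hits),
    n_scored_compounds = length(results),
    max_fit_score = if (length(results)) max(fitScores(results)) else NA,
    n_well_fitted = length(wf),
    total_matching = unname(totals["total_matching"]),
    total_mismatching = unname(totals["total_mismatching"]))
  jsonlite::write_json(summary, outfile("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files["summary"] <- outfile("summary.json")

  manifest <- list(config = unclass(config),
                   package = "massderep",
                   version = as.character(utils::packageVersion("massderep")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."))
  jsonlite::write_json(manifest, outfile("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files["manifest"] <- outfile("manifest.json")

  invisible(list(assignments = assignments, vk = vk, profile = profile,
                 mined = mined, results = results, well_fitted = wf,
                 tally = tally, totals = totals, scaffolds_all = sc_all,
                 scaffolds_well_fitted = sc_wf, summary = summary,
                 files = files))
}

#' Export a gene-symbol list for external network tools
#'
#' Writes the member gene symbols of the profile's targets in the requested
#' states (default: active only) as a newline-delimited file, the input
#' format of protein-association tools such as STRING. Interference-excluded
#' targets are always omitted.
#'
#' @param profile a [TargetProfile-class] object.
#' @param file output path; `NULL` returns the symbols without writing.
#' @param states profile states to include (default `"active"`).
#' @return character vector of gene symbols, invisibly when written.
#' @export
exportTargetList <- function(profile, file = NULL, states = "active") {
  states <- setdiff(states, "excluded")
  d <- profile@data[profile@data$state %in% states, , drop = FALSE]
  symbols <- unique(unlist(strsplit(d$members, ";", fixed = TRUE)))
  if (is.null(file)) return(symbols)
  writeLines(symbols, file)
  invisible(symbols)
}
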