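# Seeded synthetic inputs with known ground truth for every pipeline stage:
# formula sets inside the enumeration constraint box, ppm-perturbed peak
# lists with mixed charge states, radioligand panel records, and a
# ChEMBL-like compound/assay store with planted boolean activity profiles.

# all CHO formulas in the constraint box with neutral mass inside mass_range
.formulaGrid <- function(mass_range, constraints = formulaConstraints()) {
  cmax <- min(constraints$max_c, floor(mass_range[2] / 12))
  cs <- seq_len(cmax)
  omax <- pmin(constraints$max_o, floor(cs * constraints$max_oc))
  cc <- rep.int(cs, omax + 1L)
  oo <- unlist(lapply(omax, function(m) 0:m), use.names = FALSE)
  hmax <- pmin(constraints$max_h, floor(cc * constraints$max_hc))
  cc <- rep.int(cc, hmax + 1L)
  oo <- rep.int(oo, hmax + 1L)
  hh <- unlist(lapply(hmax, function(m) 0:m), use.names = FALSE)
  mass <- monoisotopicMass(cc, hh, oo)
  keep <- mass >= mass_range[1] & mass <= mass_range[2]
  data.frame(c = cc[keep], h = hh[keep], o = oo[keep], mass = mass[keep])
}

#' Simulate a set of CHO molecular formulas
#'
#' Draws `n` distinct formulas uniformly from the full constraint box
#' (C <= 120, H <= 200, O <= 60, O/C <= 1, H/C <= 2) restricted to a neutral
#' mass window, mimicking the composition space of an oxidised lignin
#' hydrolysate. Identical seeds give identical sets.
#'
#' @param n number of formulas.
#' @param seed integer RNG seed.
#' @param mass_range neutral monoisotopic mass window in Da (default
#'   `c(200, 800)`, the window used for database formula generation).
#' @param constraints a [formulaConstraints()] object.
#' @return data.frame with columns `c`, `h`, `o`, `mass`.
#' @export
simulateFormulaSet <- function(n, seed, mass_range = c(200, 800),
                               constraints = formulaConstraints()) {
  stopifnot(n >= 1)
  grid <- .formulaGrid(mass_range, constraints)
  if (n > nrow(grid)) stop("requested more formulas than the box contains")
  set.seed(seed)
  out <- grid[sample.int(nrow(grid), n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a negative-mode peak list from known formulas
#'
#' Each formula is emitted once as a deprotonated ion, [M-H]- or [M-2H]2-,
#' with a Gaussian relative m/z error of `ppm_sigma` (truncated at 3 sigma:
#' a calibrated instrument's accuracy window bounds the error, so tail draws
#' are redrawn) and log-normal intensity.
#'
#' @param formulas data.frame with columns `c`, `h`, `o` (e.g. from
#'   [simulateFormulaSet()]).
#' @param ppm_sigma standard deviation of the mass error in ppm (default 0.3,
#'   comfortably inside a 1 ppm assignment window).
#' @param frac_doubly fraction of peaks carrying charge 2 (default 0.43, the
#'   doubly-charged share observed in the motivating FTICR spectrum,
#'   1602 of 3748 assigned ions).
#' @param seed integer RNG seed.
#' @return list with `peaks` (data.frame `mz`, `intensity`, `z`) and
#'   `peak_map` (the peaks plus the source formula columns).
#' @export
simulatePeaklist <- function(formulas, ppm_sigma = 0.3, frac_doubly = 0.43,
                             seed = 1L) {
  stopifnot(frac_doubly >= 0, frac_doubly <= 1, ppm_sigma >= 0)
  n <- nrow(formulas)
  set.seed(seed)
  z <- rep(1L, n)
  n2 <- round(frac_doubly * n)
  if (n2 > 0) z[sample.int(n, n2)] <- 2L
  mass <- monoisotopicMass(formulas)
  mz0 <- (mass - z * 1.007276) / z
  eps <- stats::rnorm(n, 0, ppm_sigma)
  while (any(bad <- abs(eps) > 3 * ppm_sigma))
    eps[bad] <- stats::rnorm(sum(bad), 0, ppm_sigma)
  mz <- mz0 * (1 + eps * 1e-6)
  peaks <- data.frame(mz = mz,
                      intensity = stats::rlnorm(n, meanlog = 13, sdlog = 1.2),
                      z = z)
  map <- cbind(peaks, formulas[, c("c", "h", "o")],
               formula = formulaString(formulas))
  list(peaks = peaks, peak_map = map)
}

#' Simulate radioligand panel records realizing a known truth
#'
#' Generates raw measured/control specific-binding pairs whose percent
#' inhibition lands in (55, 95) for intended actives and (5, 45) for intended
#' inactives, plus `n_interference` extra interference-flagged rows.
#'
#' @param panel_truth named character vector target_symbol ->
#'   `"active"`/`"inactive"`.
#' @param seed integer RNG seed.
#' @param n_interference number of interference rows appended (symbols
#'   `INTF01`, ...).
#' @param control control specific-binding signal (arbitrary units).
#' @return data.frame of panel records for [buildProfile()].
#' @export
simulatePanel <- function(panel_truth, seed = 1L, n_interference = 2L,
                          control = 1000) {
  stopifnot(all(panel_truth %in% c("active", "inactive")))
  set.seed(seed)
  n <- length(panel_truth)
  inh <- ifelse(panel_truth == "active",
                stats::runif(n, 55, 95), stats::runif(n, 5, 45))
  rec <- data.frame(target_symbol = names(panel_truth),
                    family = NA_character_,
                    members = names(panel_truth),
                    measured = control * (1 - inh / 100),
                    control = control,
                    interference = 0L, stringsAsFactors = FALSE)
  if (n_interference > 0L) {
    ii <- data.frame(target_symbol = sprintf("INTF%02d", seq_len(n_interference)),
                     family = NA_character_,
                     members = sprintf("INTF%02d", seq_len(n_interference)),
                     measured = control *
                       (1 - stats::runif(n_interference, 0, 100) / 100),
                     control = control,
                     interference = 1L, stringsAsFactors = FALSE)
    rec <- rbind(rec, ii)
  }
  rec
}

# small template library so scaffold distributions have nontrivial structure:
# benzene-, flavane(2-phenylchromane)-, phenanthrene-, cyclohexane-based and
# acyclic molecules
.STRUCTURE_TEMPLATES <- c(
  benzene = "Cc1ccc(O)cc1",
  flavane = "OC1Cc2ccccc2OC1c1ccccc1",
  phenanthrene = "Cc1ccc2ccc3ccccc3c2c1",
  cyclohexane = "OC1CCCCC1",
  acyclic = "CCCCC(O)=O")

#' Simulate a ChEMBL-like compound/assay store with planted activity profiles
#'
#' A fraction `match_frac` of the compounds share a formula with the planted
#' MS formula set (the rest get decoy CHO formulas outside it). Every matched
#' compound receives a planted boolean activity profile over a random subset
#' of panel targets; assay rows realize each planted flag with potency values
#' straddling the documented cutoffs (actives: Ki/IC50 well below 10 uM;
#' inactives: well above), descriptions embedding the panel key substrings so
#' the whole mining stage can be exercised. Structures come from a small
#' template library (benzene-, flavane-, phenanthrene-, cyclohexane-based and
#' acyclic) so scaffold distributions are nontrivial.
#'
#' @param formulas planted MS formula set (data.frame `c`, `h`, `o`).
#' @param n_compounds total number of store compounds.
#' @param match_frac fraction of compounds whose formula is in the planted
#'   set.
#' @param panel_truth named character vector target -> `"active"`/`"inactive"`
#'   (the intended experimental profile the planted scores refer to).
#' @param keys key list mapping search substrings to panel targets (default
#'   the packaged starter list, subset to the targets of `panel_truth`).
#' @param seed integer RNG seed.
#' @param targets_per_compound range of panel targets with planted data per
#'   matched compound.
#' @return list with `compounds`, `assays` (store tables), and ground truth:
#'   `profiles` (matrix compound x target of 1/0/NA), `planted_scores`
#'   (named integer), `well_fitted` (character ids with score >= 1).
#' @export
simulateStore <- function(formulas, n_compounds = 120L, match_frac = 0.5,
                          panel_truth, keys = panelKeyList(), seed = 1L,
                          targets_per_compound = c(2L, 6L)) {
  stopifnot(match_frac >= 0, match_frac <= 1, n_compounds >= 1,
            all(panel_truth %in% c("active", "inactive")))
  targets <- names(panel_truth)
  keys <- keys[keys$panel_target %in% targets, , drop = FALSE]
  if (!all(targets %in% keys$panel_target))
    stop("key list lacks substrings for some panel targets")
  key_of <- keys$key[match(targets, keys$panel_target)]
  names(key_of) <- targets

  set.seed(seed)
  n_match <- round(match_frac * n_compounds)
  ids <- sprintf("CPD%04d", seq_len(n_compounds))
  is_match <- seq_len(n_compounds) <= n_match

  fstr <- character(n_compounds)
  if (n_match > 0)
    fstr[is_match] <- formulaString(
      formulas[sample.int(nrow(formulas), n_match, replace = TRUE), ])
  if (n_match < n_compounds) {
    # decoy formulas: drawn from the same box but disjoint from the planted set
    grid <- .formulaGrid(c(200, 800))
    planted_key <- paste(formulas$c, formulas$h, formulas$o)
    decoys <- grid[!(paste(grid$c, grid$h, grid$o) %in% planted_key), ]
    fstr[!is_match] <- formulaString(
      decoys[sample.int(nrow(decoys), n_compounds - n_match, replace = TRUE), ])
  }
  structures <- unname(.STRUCTURE_TEMPLATES[
    (seq_len(n_compounds) - 1L) %% length(.STRUCTURE_TEMPLATES) + 1L])
  compounds <- data.frame(compound_id = ids, formula_string = fstr,
                          smiles = structures, stringsAsFactors = FALSE)

  profiles <- matrix(NA_integer_, nrow = n_match, ncol = length(targets),
                     dimnames = list(ids[seq_len(n_match)], targets))
  rows <- list()
  for (i in seq_len(n_match)) {
    k <- sample(seq.int(targets_per_compound[1], targets_per_compound[2]), 1L)
    tsel <- sample(targets, min(k, length(targets)))
    flags <- stats::rbinom(length(tsel), 1L, 0.5)
    profiles[i, tsel] <- flags
    for (j in seq_along(tsel)) {
      act <- flags[j] == 1L
      in_um <- stats::runif(1) < 0.3        # mix units to exercise conversion
      val <- if (act) stats::runif(1, 10, 1000) else stats::runif(1, 5e4, 5e5)
      if (in_um) val <- val / 1e3
      rows[[length(rows) + 1L]] <- data.frame(
        assay_id = NA_character_, compound_id = ids[i],
        target_name = paste(key_of[tsel[j]], "receptor"),
        description = paste0("Displacement binding assay at the ",
                             key_of[tsel[j]], " site"),
        activity_type = sample(c("Ki", "IC50"), 1L),
        relation = "=", value = val,
        units = if (in_um) "uM" else "nM", stringsAsFactors = FALSE)
    }
  }
  # a few assays for decoy compounds (removed upstream by formula matching)
  for (i in seq.int(n_match + 1L, length.out = min(5L, n_compounds - n_match))) {
    rows[[length(rows) + 1L]] <- data.frame(
      assay_id = NA_character_, compound_id = ids[i],
      target_name = paste(key_of[1L], "receptor"),
      description = "Displacement binding assay",
      activity_type = "Ki", relation = "=",
      value = stats::runif(1, 10, 1000), units = "nM",
      stringsAsFactors = FALSE)
  }
  assays <- do.call(rbind, rows)
  assays$assay_id <- sprintf("ASSAY%05d", seq_len(nrow(assays)))

  ref <- ifelse(panel_truth == "active", 1L, 0L)
  score <- vapply(seq_len(n_match), function(i) {
    def <- !is.na(profiles[i, ])
    sum(profiles[i, def] == ref[def]) - sum(profiles[i, def] != ref[def])
  }, integer(1))
  names(score) <- ids[seq_len(n_match)]

  list(compounds = compounds, assays = assays, profiles = profiles,
       planted_scores = score,
       well_fitted = names(score)[score >= 1L])
}

#' Simulate a complete pipeline input bundle
#'
#' Chains [simulateFormulaSet()], [simulatePeaklist()], [simulatePanel()] and
#' [simulateStore()] under sub-seeds derived from one master seed, using the
#' packaged panel targets, and optionally writes the standard input files
#' (`peaks.tsv`, `panel.csv`, `compounds.csv`, `assays.csv`,
#' `ground_truth.json`) to a directory.
#'
#' @param seed master integer seed.
#' @param out_dir optional output directory (created if needed).
#' @param n_formulas,n_compounds,match_frac,ppm_sigma,frac_doubly,n_interference
#'   generator parameters, passed through.
#' @param active_frac fraction of panel targets planted active (default 0.6).
#' @return list with `formulas`, `peaks`, `peak_map`, `panel` (records),
#'   `panel_truth`, `store` (the [simulateStore()] result), and `files`
#'   (paths, when `out_dir` is given).
#' @export
simulateAll <- function(seed, out_dir = NULL, n_formulas = 300L,
                        n_compounds = 120L, match_frac = 0.5,
                        ppm_sigma = 0.3, frac_doubly = 0.43,
                        n_interference = 2L, active_frac = 0.6) {
  seed <- as.integer(seed)
  targets <- diversityPanel()$target_symbol
  set.seed(seed)
  truth <- stats::setNames(
    ifelse(stats::runif(length(targets)) < active_frac, "active", "inactive"),
    targets)
  formulas <- simulateFormulaSet(n_formulas, seed = seed + 1L)
  pk <- simulatePeaklist(formulas, ppm_sigma = ppm_sigma,
                         frac_doubly = frac_doubly, seed = seed + 2L)
  panel <- simulatePanel(truth, seed = seed + 3L,
                         n_interference = n_interference)
  store <- simulateStore(formulas, n_compounds = n_compounds,
                         match_frac = match_frac, panel_truth = truth,
                         seed = seed + 4L)
  out <- list(formulas = formulas, peaks = pk$peaks, peak_map = pk$peak_map,
              panel = panel, panel_truth = truth, store = store)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(peaks = file.path(out_dir, "peaks.tsv"),
               panel = file.path(out_dir, "panel.csv"),
               compounds = file.path(out_dir, "compounds.csv"),
               assays = file.path(out_dir, "assays.csv"),
               ground_truth = file.path(out_dir, "ground_truth.json"))
    utils::write.table(pk$peaks, files["peaks"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.csv(panel, files["panel"], row.names = FALSE, quote = FALSE)
    utils::write.csv(store$compounds, files["compounds"], row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(store$assays, files["assays"], row.names = FALSE)
    gt <- list(seed = seed,
               panel_truth = as.list(truth),
               planted_formulas = formulaString(formulas),
               planted_scores = as.list(store$planted_scores),
               well_fitted = store$well_fitted)
    jsonlite::write_json(gt, files["ground_truth"], auto_unbox = TRUE,
                         digits = NA)
    out$files <- files
  }
  out
}
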