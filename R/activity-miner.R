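# Formula-keyed mining of a ChEMBL-like compound/assay store and construction
# of boolean bioactivity fingerprints over the panel targets.

# canonical column name -> accepted aliases (genuine ChEMBL dumps plug in
# unchanged via these, or via an explicit mapping argument)
.COMPOUND_ALIASES <- list(
  compound_id = c("compound_id", "molregno", "chembl_id"),
  formula_string = c("formula_string", "full_molformula", "molformula"),
  smiles = c("smiles", "canonical_smiles", "structure"))
.ASSAY_ALIASES <- list(
  assay_id = c("assay_id"),
  compound_id = c("compound_id", "molregno", "chembl_id"),
  target_name = c("target_name", "pref_name"),
  description = c("description", "assay_description"),
  activity_type = c("activity_type", "standard_type", "type"),
  relation = c("relation", "standard_relation"),
  value = c("value", "standard_value"),
  units = c("units", "standard_units"))

.renameColumns <- function(x, aliases, mapping = NULL, what) {
  for (canon in names(aliases)) {
    have <- if (!is.null(mapping) && canon %in% names(mapping))
      mapping[[canon]] else intersect(aliases[[canon]], names(x))[1]
    if (is.na(have) || is.null(have)) {
      if (canon %in% c("smiles"))
        x[[canon]] <- NA_character_
      else stop(sprintf("%s table lacks a recognisable '%s' column", what, canon))
    } else if (have != canon) {
      names(x)[names(x) == have] <- canon
    }
  }
  x
}

#' Load a compound/assay store from CSV tables
#'
#' The store mirrors a minimal ChEMBL schema subset: a compound table
#' (id, molecular formula string, optional SMILES) and an assay/activity table
#' (assay id, compound id, target preferred name, assay description, activity
#' type, relation, value, units). Genuine ChEMBL column names (`molregno`,
#' `full_molformula`, `pref_name`, `description`, `standard_*`) are recognised
#' automatically; other layouts can supply `compound_mapping` /
#' `assay_mapping` as named character vectors canonical-name -> actual-name.
#'
#' @param compounds_file,assays_file CSV paths.
#' @param compound_mapping,assay_mapping optional column-name mappings.
#' @return list with data.frames `compounds` and `assays` in canonical form.
#' @export
readStore <- function(compounds_file, assays_file,
                      compound_mapping = NULL, assay_mapping = NULL) {
  comp <- utils::read.csv(compounds_file, stringsAsFactors = FALSE)
  assay <- utils::read.csv(assays_file, stringsAsFactors = FALSE)
  comp <- .renameColumns(comp, .COMPOUND_ALIASES, compound_mapping, "compound")
  assay <- .renameColumns(assay, .ASSAY_ALIASES, assay_mapping, "assay")
  comp$compound_id <- as.character(comp$compound_id)
  assay$compound_id <- as.character(assay$compound_id)
  list(compounds = comp[, names(.COMPOUND_ALIASES)],
       assays = assay[, names(.ASSAY_ALIASES)])
}

#' Read a key-substring list for assay selection
#'
#' @param file CSV with columns `key` (search substring) and `panel_target`
#'   (panel target symbol the key maps to).
#' @return data.frame with columns `key`, `panel_target`.
#' @export
readKeyList <- function(file) {
  x <- utils::read.csv(file, stringsAsFactors = FALSE)
  stopifnot(all(c("key", "panel_target") %in% names(x)))
  x
}

#' Starter key-substring list covering the packaged panel targets
#' @return data.frame with columns `key`, `panel_target`.
#' @export
panelKeyList <- function() {
  readKeyList(system.file("extdata", "panel_keys.csv",
                          package = "massderep", mustWork = TRUE))
}

#' Match MS-derived formulas against the compound store
#'
#' Returns every CHO-only compound whose molecular formula equals (exact
#' C/H/O counts) one of the MS-derived formulas; isomers sharing a formula
#' are all returned. Compounds whose formula string cannot be parsed as a
#' pure CHO formula are skipped with a warning.
#'
#' @param ms_formulas data.frame with columns `c`, `h`, `o`, or a character
#'   vector of formula strings.
#' @param compounds compound table from [readStore()].
#' @return subset of `compounds` with added integer columns `c`, `h`, `o`.
#' @export
matchFormulas <- function(ms_formulas, compounds) {
  if (is.character(ms_formulas)) ms_formulas <- parseFormulaString(ms_formulas)
  stopifnot(is.data.frame(ms_formulas),
            all(c("c", "h", "o") %in% names(ms_formulas)))
  key <- function(d) paste(d$c, d$h, d$o, sep = "_")
  wanted <- unique(key(ms_formulas[stats::complete.cases(
    ms_formulas[, c("c", "h", "o")]), , drop = FALSE]))
  parsed <- parseFormulaString(compounds$formula_string)
  bad <- is.na(parsed$c)
  if (any(bad))
    warning(sum(bad), " compound formula string(s) not parseable as CHO; skipped")
  out <- cbind(compounds, parsed)
  out <- out[!bad & key(parsed) %in% wanted, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select assays by case-insensitive key-substring search
#'
#' An assay is selected when any key occurs (case-insensitively, as a fixed
#' substring) in its target preferred name or its description. Each hit is
#' annotated with the panel target its key maps to; an assay matching keys of
#' several panel targets yields one row per panel target.
#'
#' @param assays assay table from [readStore()].
#' @param keys data.frame with columns `key`, `panel_target`
#'   (see [readKeyList()]).
#' @return subset of `assays` with an added `panel_target` column.
#' @export
searchAssays <- function(assays, keys) {
  stopifnot(is.data.frame(keys), nrow(keys) >= 1L,
            all(c("key", "panel_target") %in% names(keys)))
  if (nrow(assays) == 0L) {
    assays$panel_target <- character(0)
    return(assays)
  }
  corpus <- tolower(paste(assays$target_name, assays$description))
  pieces <- lapply(seq_len(nrow(keys)), function(i) {
    hit <- grepl(tolower(keys$key[i]), corpus, fixed = TRUE)
    if (!any(hit)) return(NULL)
    cbind(assays[hit, , drop = FALSE],
          panel_target = keys$panel_target[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- assays[0, , drop = FALSE]
    out$panel_target <- character(0)
    return(out)
  }
  # one assay can match several keys of the same panel target: keep one row
  out <- out[!duplicated(out[, c("assay_id", "compound_id", "panel_target")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hash activity records to boolean flags
#'
#' Potency endpoints (Ki, Kd, IC50, EC50) are converted to nM and flagged
#' active (1) when the value is at or below `potency_cutoff_nm` with relation
#' in {=, <, <=}, inactive (0) when above the cutoff with relation in
#' {=, >, >=}; censored values that cannot decide the comparison (e.g.
#' "> 50 nM") are undetermined (NA). Percent-effect endpoints (inhibition,
#' activity, efficacy, or `%` units) are flagged by `percent_cutoff`,
#' mirroring the experimental panel's significance convention. Unknown types
#' or units give NA with a warning.
#'
#' @param activity_type,relation,value,units vectors of equal length.
#' @param potency_cutoff_nm potency threshold in nM (default 10000 = 10 uM).
#' @param percent_cutoff percent-effect threshold (default 50).
#' @return integer vector with values 1, 0 or NA (undetermined).
#' @export
standardizeActivity <- function(activity_type, relation, value, units,
                                potency_cutoff_nm = 10000,
                                percent_cutoff = 50) {
  n <- length(value)
  stopifnot(length(activity_type) == n, length(relation) == n,
            length(units) == n)
  type <- tolower(trimws(activity_type))
  rel <- trimws(relation)
  rel[rel == ""] <- "="
  rel[rel == "≤"] <- "<="
  rel[rel == "≥"] <- ">="
  u <- tolower(trimws(units))
  flag <- rep(NA_integer_, n)

  is_potency <- type %in% c("ki", "kd", "ic50", "ec50")
  scale <- rep(NA_real_, n)
  scale[u %in% c("nm")] <- 1
  scale[u %in% c("um", "µm", "μm")] <- 1e3
  scale[u %in% c("mm")] <- 1e6
  pot <- is_potency & !is.na(scale) & !is.na(value)
  vnm <- value * scale
  act <- pot & vnm <= potency_cutoff_nm & rel %in% c("=", "<", "<=")
  inact <- pot & vnm > potency_cutoff_nm & rel %in% c("=", ">", ">=")
  flag[act] <- 1L
  flag[inact] <- 0L

  is_percent <- grepl("inhibition|activity|efficacy|effect", type) |
    u %in% c("%", "percent")
  pct <- !is_potency & is_percent & !is.na(value)
  flag[pct & value >= percent_cutoff & rel %in% c("=", ">", ">=")] <- 1L
  flag[pct & value < percent_cutoff & rel %in% c("=", "<", "<=")] <- 0L

  unknown <- !is_potency & !is_percent
  if (any(unknown))
    warning(sum(unknown), " activity record(s) with unrecognised type/units ",
            "left undetermined")
  flag
}

#' ActivityFingerprints: boolean bioactivity profiles over the panel targets
#'
#' A compounds x panel-targets integer matrix with values 1 (active), 0
#' (inactive) and NA (no data). Columns are exactly the panel targets, so
#' `defined + missing = panel size` holds for every compound.
#'
#' @slot fp integer matrix, rownames compound ids, colnames panel targets.
#' @aliases ActivityFingerprints-class
#' @exportClass ActivityFingerprints
setClass("ActivityFingerprints", representation(fp = "matrix"))

setValidity("ActivityFingerprints", function(object) {
  v <- object@fp
  if (!all(v %in% c(0L, 1L, NA_integer_))) return("values must be 1, 0 or NA")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("fingerprint matrix needs compound rownames and target colnames")
  TRUE
})

#' @exportMethod show
setMethod("show", "ActivityFingerprints", function(object) {
  v <- object@fp
  cat("ActivityFingerprints:", nrow(v), "compounds x", ncol(v),
      "panel targets\n")
  cat(sprintf("  defined entries: %d active, %d inactive, %d missing\n",
              sum(v == 1L, na.rm = TRUE), sum(v == 0L, na.rm = TRUE),
              sum(is.na(v))))
})

#' @describeIn ActivityFingerprints-class number of compounds.
#' @param x,object an `ActivityFingerprints`.
#' @export
setMethod("length", "ActivityFingerprints", function(x) nrow(x@fp))

#' Fingerprint matrix accessor
#' @param fingerprints an [ActivityFingerprints-class] object.
#' @return the compounds x targets integer matrix (1/0/NA).
#' @export
fingerprintMatrix <- function(fingerprints) fingerprints@fp

#' Build per-compound bioactivity fingerprints from flagged assay hits
#'
#' Aggregates boolean flags per compound-target pair: under the default
#' `"any"` rule a pair is active if any of its flags is 1, inactive if all
#' defined flags are 0, missing when no flag is defined (undetermined NA flags
#' are ignored). `"majority"` instead takes the majority vote of defined
#' flags, ties counting as active.
#'
#' @param hits data.frame with columns `compound_id`, `panel_target`, `flag`
#'   (1/0/NA), e.g. [searchAssays()] output plus [standardizeActivity()].
#' @param panel_targets character vector: the full panel target universe
#'   (fingerprint columns), e.g. [panelTargets()] of the profile.
#' @param aggregate `"any"` or `"majority"`.
#' @return an [ActivityFingerprints-class] object.
#' @export
buildFingerprints <- function(hits, panel_targets,
                              aggregate = c("any", "majority")) {
  aggregate <- match.arg(aggregate)
  stopifnot(is.data.frame(hits),
            all(c("compound_id", "panel_target", "flag") %in% names(hits)),
            length(panel_targets) >= 1L, !anyDuplicated(panel_targets))
  extra <- setdiff(unique(hits$panel_target), panel_targets)
  if (length(extra))
    stop("hits reference targets outside the panel: ",
         paste(extra, collapse = ", "))
  ids <- sort(unique(as.character(hits$compound_id)))
  fp <- matrix(NA_integer_, nrow = length(ids), ncol = length(panel_targets),
               dimnames = list(ids, panel_targets))
  def <- hits[!is.na(hits$flag), , drop = FALSE]
  if (nrow(def) > 0L) {
    # separator that cannot occur in compound ids or target symbols
    grp <- paste(def$compound_id, def$panel_target, sep = "\r")
    n1 <- tapply(def$flag == 1L, grp, sum)
    n0 <- tapply(def$flag == 0L, grp, sum)
    cid <- sub("\r.*$", "", names(n1))
    tgt <- sub("^.*\r", "", names(n1))
    val <- if (aggregate == "any") as.integer(n1 > 0)
           else as.integer(n1 >= n0)
    fp[cbind(match(cid, ids), match(tgt, panel_targets))] <- val
  }
  methods::new("ActivityFingerprints", fp = fp)
}

#' End-to-end mining: formulas -> matched compounds -> fingerprints
#'
#' Convenience wrapper chaining [matchFormulas()], [searchAssays()] (restricted
#' to matched compounds), [standardizeActivity()] and [buildFingerprints()].
#' Family panel rows match an assay hit on any member symbol through the key
#' list, which maps keys to panel row symbols directly.
#'
#' @param ms_formulas data.frame (`c`,`h`,`o`) or character formula strings.
#' @param store list from [readStore()].
#' @param keys key list (see [readKeyList()]); default packaged starter list.
#' @param panel_targets the fingerprint column universe.
#' @param potency_cutoff_nm,percent_cutoff passed to [standardizeActivity()].
#' @param aggregate passed to [buildFingerprints()].
#' @return list with `compounds` (matched compound table), `hits` (flagged
#'   assay hits) and `fingerprints` ([ActivityFingerprints-class]).
#' @export
mineActivities <- function(ms_formulas, store, keys = panelKeyList(),
                           panel_targets,
                           potency_cutoff_nm = 10000, percent_cutoff = 50,
                           aggregate = "any") {
  matched <- matchFormulas(ms_formulas, store$compounds)
  assays <- store$assays[store$assays$compound_id %in% matched$compound_id, ,
                         drop = FALSE]
  hits <- searchAssays(assays, keys)
  hits$flag <- standardizeActivity(hits$activity_type, hits$relation,
                                   hits$value, hits$units,
                                   potency_cutoff_nm, percent_cutoff)
  fp <- if (nrow(hits) > 0L)
    buildFingerprints(hits, panel_targets, aggregate)
  else methods::new("ActivityFingerprints",
                    fp = matrix(NA_integer_, 0, length(panel_targets),
                                dimnames = list(character(0), panel_targets)))
  list(compounds = matched, hits = hits, fingerprints = fp)
}
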