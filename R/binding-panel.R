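# Radioligand binding panel -> boolean reference target profile.

#' TargetProfile: boolean activity of the test substance across a panel
#'
#' Holds one row per panel target with its receptor family, member gene
#' symbols (family rows may cover several proteins), the percent inhibition of
#' control specific binding, and the derived state: `active` (inhibition
#' strictly greater than the threshold), `inactive`, or `excluded` (assay
#' interference). This is the experimental reference that database-derived
#' bioactivity fingerprints are scored against.
#'
#' @slot data data.frame with columns `target_symbol`, `family`, `members`
#'   (semicolon-separated gene symbols), `inhibition_pct`, `interference`,
#'   `state`.
#' @slot threshold numeric, percent inhibition above which a target is active.
#' @aliases TargetProfile-class
#' @exportClass TargetProfile
setClass("TargetProfile",
         representation(data = "data.frame", threshold = "numeric"))

setValidity("TargetProfile", function(object) {
  d <- object@data
  need <- c("target_symbol", "family", "members", "inhibition_pct",
            "interference", "state")
  if (!all(need %in% names(d)))
    return(paste("missing columns:", paste(setdiff(need, names(d)), collapse = ", ")))
  if (anyDuplicated(d$target_symbol))
    return("duplicate target symbols")
  if (!all(d$state %in% c("active", "inactive", "excluded")))
    return("states must be active/inactive/excluded")
  if (any(d$interference & d$state != "excluded"))
    return("interference records must be excluded")
  if (length(object@threshold) != 1L || object@threshold <= 0)
    return("threshold must be a single positive number")
  TRUE
})

#' @describeIn TargetProfile-class number of panel targets.
#' @param x,object a `TargetProfile`.
#' @export
setMethod("length", "TargetProfile", function(x) nrow(x@data))

#' @exportMethod show
setMethod("show", "TargetProfile", function(object) {
  d <- object@data
  cat("TargetProfile with", nrow(d), "panel targets",
      sprintf("(threshold %g%% inhibition)\n", object@threshold))
  cat("  active:", sum(d$state == "active"),
      " inactive:", sum(d$state == "inactive"),
      " excluded:", sum(d$state == "excluded"), "\n")
  if (any(d$state == "active")) {
    a <- d[d$state == "active", ]
    top <- a[order(-a$inhibition_pct), ][seq_len(min(3L, nrow(a))), ]
    cat("  top actives:",
        paste(sprintf("%s (%.1f%%)", top$target_symbol, top$inhibition_pct),
              collapse = ", "), "\n")
  }
})

#' Panel target symbols of a profile
#' @param profile a `TargetProfile`.
#' @return character vector of target symbols (panel keys).
#' @export
panelTargets <- function(profile) profile@data$target_symbol

#' Per-target states of a profile
#' @param profile a `TargetProfile`.
#' @param drop_excluded drop interference-excluded targets.
#' @return named character vector target_symbol -> state.
#' @export
profileStates <- function(profile, drop_excluded = FALSE) {
  s <- stats::setNames(profile@data$state, profile@data$target_symbol)
  if (drop_excluded) s[s != "excluded"] else s
}

#' Member gene symbols for each panel target
#'
#' Family rows (e.g. the 5-HT1 serotonin receptors) cover several proteins;
#' an in-silico assay hit on any member counts for the panel row.
#'
#' @param profile a `TargetProfile`.
#' @return named list target_symbol -> character vector of member symbols.
#' @export
panelMembers <- function(profile) {
  stats::setNames(strsplit(profile@data$members, ";", fixed = TRUE),
                  profile@data$target_symbol)
}

#' Percent inhibition of control specific binding
#'
#' 100 - (measured specific binding / control specific binding) x 100.
#' Negative values (stimulation) are returned as-is.
#'
#' @param measured specific binding in presence of the test substance (>= 0).
#' @param control control specific binding (> 0).
#' @return percent inhibition, vectorised.
#' @export
percentInhibition <- function(measured, control) {
  stopifnot(length(measured) == length(control))
  if (any(control <= 0)) stop("control specific binding must be positive")
  if (any(measured < 0)) stop("measured specific binding must be non-negative")
  100 - (measured / control) * 100
}

#' Build the boolean target profile from panel records
#'
#' A target is `active` iff its percent inhibition is strictly greater than
#' the threshold and the record is not flagged as assay interference;
#' interference records are `excluded`; everything else (including negative
#' inhibition, i.e. stimulation) is `inactive`.
#'
#' @param records data.frame with columns `target_symbol` and either
#'   `inhibition_pct` or both `measured` and `control`; optional `family`,
#'   `members`, `interference` (0/1 or logical).
#' @param threshold significance threshold in percent (default 50).
#' @return a [TargetProfile-class] object.
#' @export
buildProfile <- function(records, threshold = 50) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L,
            "target_symbol" %in% names(records))
  if (anyDuplicated(records$target_symbol))
    stop("duplicate target symbols in panel records: ",
         paste(unique(records$target_symbol[duplicated(records$target_symbol)]),
               collapse = ", "))
  inh <- if ("inhibition_pct" %in% names(records))
    as.numeric(records$inhibition_pct) else rep(NA_real_, nrow(records))
  need_raw <- is.na(inh)
  if (any(need_raw)) {
    if (!all(c("measured", "control") %in% names(records)))
      stop("records lacking inhibition_pct need measured and control columns")
    inh[need_raw] <- percentInhibition(records$measured[need_raw],
                                       records$control[need_raw])
  }
  interference <- if ("interference" %in% names(records))
    as.logical(as.integer(records$interference)) else rep(FALSE, nrow(records))
  interference[is.na(interference)] <- FALSE
  state <- ifelse(interference, "excluded",
                  ifelse(inh > threshold, "active", "inactive"))
  d <- data.frame(
    target_symbol = as.character(records$target_symbol),
    family = if ("family" %in% names(records))
      as.character(records$family) else NA_character_,
    members = if ("members" %in% names(records) &&
                  !all(is.na(records$members)))
      as.character(records$members) else as.character(records$target_symbol),
    inhibition_pct = inh,
    interference = interference,
    state = state,
    stringsAsFactors = FALSE)
  empty <- is.na(d$members) | d$members == ""
  d$members[empty] <- d$target_symbol[empty]
  methods::new("TargetProfile", data = d, threshold = threshold)
}

#' Summary counts and extrema of a target profile
#'
#' @param profile a [TargetProfile-class] object.
#' @return list with `n_targets`, `n_active`, `n_inactive`, `n_excluded`, and
#'   `max_inhibition_active` / `min_inhibition_active` (NA when no target is
#'   active).
#' @export
profileSummary <- function(profile) {
  d <- profile@data
  if (nrow(d) == 0L) stop("empty profile")
  act <- d$inhibition_pct[d$state == "active"]
  list(n_targets = nrow(d),
       n_active = sum(d$state == "active"),
       n_inactive = sum(d$state == "inactive"),
       n_excluded = sum(d$state == "excluded"),
       max_inhibition_active = if (length(act)) max(act) else NA_real_,
       min_inhibition_active = if (length(act)) min(act) else NA_real_)
}

#' Read panel records from CSV
#'
#' Expected columns: `target_symbol`, optional `family`, `members`
#' (semicolon-separated), `inhibition_pct` or `measured` + `control`,
#' `interference` (0/1).
#'
#' @param file CSV path.
#' @return data.frame of panel records suitable for [buildProfile()].
#' @export
readPanel <- function(file) {
  x <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!"target_symbol" %in% names(x))
    stop("panel CSV must have a target_symbol column")
  x
}

#' Packaged diversity-panel binding results
#'
#' The 24 significantly bound targets (percent inhibition of control specific
#' binding > 50%) reported for the lignin-derived polyphenolic test substance
#' on a commercial radioligand diversity panel (receptors, ion channels and
#' transporters). Family rows carry their member gene symbols.
#'
#' @return data.frame of panel records (see [readPanel()]).
#' @export
diversityPanel <- function() {
  readPanel(system.file("extdata", "diversity_panel.csv",
                        package = "massderep", mustWork = TRUE))
}
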