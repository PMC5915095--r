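# Exact-mass CHO formula assignment for negative-mode FTICR-MS peak lists.

# CODATA monoisotopic masses (Da)
.MASS_C <- 12.000000
.MASS_H <- 1.0078250319
.MASS_O <- 15.9949146221
# mass of a proton, added back once per lost proton in [M - zH]^z-
.MASS_PROTON <- 1.007276

#' Constraint box for CHO formula enumeration
#'
#' Defaults reproduce the validation rules conventionally applied to
#' lignin-derived organic matter: element counts C <= 120, H <= 200, O <= 60,
#' atomic ratios O/C <= 1 and H/C <= 2.
#'
#' @param max_c,max_h,max_o maximum element counts.
#' @param max_oc,max_hc maximum atomic O/C and H/C ratios.
#' @return A named list of class `"formulaConstraints"`.
#' @export
formulaConstraints <- function(max_c = 120L, max_h = 200L, max_o = 60L,
                               max_oc = 1, max_hc = 2) {
  stopifnot(max_c >= 1, max_h >= 0, max_o >= 0, max_oc > 0, max_hc > 0)
  structure(list(max_c = as.integer(max_c), max_h = as.integer(max_h),
                 max_o = as.integer(max_o), max_oc = max_oc, max_hc = max_hc),
            class = "formulaConstraints")
}

#' Monoisotopic mass of a CHO formula
#'
#' @param c,h,o integer element counts (vectorised). Alternatively `c` may be
#'   a data.frame with columns `c`, `h`, `o`.
#' @return Numeric vector of monoisotopic masses in Da.
#' @examples
#' monoisotopicMass(9, 10, 2)   # ~150.068
#' @export
monoisotopicMass <- function(c, h = NULL, o = NULL) {
  if (is.data.frame(c)) {
    h <- c$h; o <- c$o; c <- c$c
  }
  stopifnot(length(c) == length(h), length(h) == length(o))
  if (any(c < 0 | h < 0 | o < 0)) stop("element counts must be non-negative")
  c * .MASS_C + h * .MASS_H + o * .MASS_O
}

#' Neutral mass of a deprotonated negative-mode ion
#'
#' Reconstructs the neutral monoisotopic mass from an observed m/z under the
#' deprotonation model [M - zH]^z-: M = z * mz + z * 1.007276. The electron
#' mass is neglected (< 0.004 ppm at m/z 200, well inside a 1 ppm window).
#'
#' @param mz observed mass-to-charge ratio (Da), vectorised.
#' @param z charge magnitude, 1 or 2.
#' @return Neutral mass in Da.
#' @export
neutralMass <- function(mz, z) {
  if (length(z) == 1L) z <- rep(z, length(mz))
  stopifnot(length(mz) == length(z))
  if (!all(z %in% c(1L, 2L)))
    stop("unsupported charge state: z must be 1 or 2 (negative mode, [M - zH]^z-)")
  if (any(mz <= 0)) stop("mz must be positive")
  z * mz + z * .MASS_PROTON
}

#' Format and parse CHO formula strings
#'
#' `formulaString` renders counts as `"CcHhOo"` (zero-count elements omitted,
#' except carbon which is always present). `parseFormulaString` inverts it and
#' returns `NA` counts for strings containing elements other than C/H/O.
#'
#' @param c,h,o element counts, or a data.frame with those columns.
#' @param x character vector of formula strings such as `"C15H10O5"`.
#' @return `formulaString`: character vector. `parseFormulaString`: data.frame
#'   with integer columns `c`, `h`, `o` (NA for unparseable rows).
#' @export
formulaString <- function(c, h = NULL, o = NULL) {
  if (is.data.frame(c)) {
    h <- c$h; o <- c$o; c <- c$c
  }
  paste0("C", c,
         ifelse(h > 0, paste0("H", h), ""),
         ifelse(o > 0, paste0("O", o), ""))
}

#' @rdname formulaString
#' @export
parseFormulaString <- function(x) {
  x <- trimws(x)
  out <- data.frame(c = rep(NA_integer_, length(x)), h = NA_integer_,
                    o = NA_integer_)
  # valid strings contain only C/H/O element tokens
  ok <- grepl("^([CHO][0-9]*)+$", x)
  grab <- function(s, el) {
    m <- regmatches(s, regexpr(paste0(el, "[0-9]*"), s))
    if (length(m) == 0L) return(0L)
    n <- sub(el, "", m)
    if (n == "") 1L else as.integer(n)
  }
  for (i in which(ok)) {
    out$c[i] <- grab(x[i], "C")
    out$h[i] <- grab(x[i], "H")
    out$o[i] <- grab(x[i], "O")
  }
  out$c[out$c == 0L] <- NA_integer_   # no carbon: not a CHO formula of interest
  out
}

#' Enumerate CHO formulas matching a neutral mass
#'
#' Exhaustively enumerates every formula inside the constraint box whose
#' monoisotopic mass lies within `tol_ppm` of `neutral_mass`. The search is
#' complete: for each feasible (C, O) pair the hydrogen count is bounded
#' exactly by the mass window, so no candidate can be missed.
#'
#' @param neutral_mass target neutral monoisotopic mass (Da), scalar.
#' @param tol_ppm relative mass tolerance in ppm (default 1).
#' @param constraints a [formulaConstraints()] object.
#' @return data.frame with columns `c`, `h`, `o`, `formula`, `mass`,
#'   `error_ppm`, sorted by `abs(error_ppm)` (ties: fewer O, then fewer H).
#'   Zero rows when no candidate exists.
#' @export
enumerateFormulas <- function(neutral_mass, tol_ppm = 1,
                              constraints = formulaConstraints()) {
  stopifnot(length(neutral_mass) == 1L, neutral_mass > 0, tol_ppm > 0)
  lo <- neutral_mass * (1 - tol_ppm * 1e-6)
  hi <- neutral_mass * (1 + tol_ppm * 1e-6)

  cmax <- min(constraints$max_c, floor(hi / .MASS_C))
  if (cmax < 1) return(.emptyFormulaTable())
  cs <- seq_len(cmax)
  omax <- pmin(constraints$max_o, floor(cs * constraints$max_oc),
               floor((hi - cs * .MASS_C) / .MASS_O))
  omax <- pmax(omax, -1L)
  cc <- rep.int(cs, omax + 1L)
  oo <- unlist(lapply(omax, function(m) if (m < 0) integer(0) else 0:m),
               use.names = FALSE)
  if (length(cc) == 0L) return(.emptyFormulaTable())

  base <- cc * .MASS_C + oo * .MASS_O
  hmin <- pmax(ceiling((lo - base) / .MASS_H), 0)
  hmax <- pmin(floor((hi - base) / .MASS_H), constraints$max_h,
               floor(cc * constraints$max_hc))
  keep <- hmin <= hmax
  cc <- cc[keep]; oo <- oo[keep]
  hmin <- hmin[keep]; hmax <- hmax[keep]
  if (length(cc) == 0L) return(.emptyFormulaTable())

  nh <- hmax - hmin + 1L        # almost always 1 inside a ppm-scale window
  cc <- rep.int(cc, nh); oo <- rep.int(oo, nh)
  hh <- unlist(mapply(seq.int, hmin, hmax, SIMPLIFY = FALSE), use.names = FALSE)

  mass <- monoisotopicMass(cc, hh, oo)
  ppm <- (mass - neutral_mass) / neutral_mass * 1e6
  ord <- order(abs(ppm), oo, hh)
  data.frame(c = as.integer(cc[ord]), h = as.integer(hh[ord]),
             o = as.integer(oo[ord]),
             formula = formulaString(cc[ord], hh[ord], oo[ord]),
             mass = mass[ord], error_ppm = ppm[ord],
             stringsAsFactors = FALSE)
}

.emptyFormulaTable <- function() {
  data.frame(c = integer(0), h = integer(0), o = integer(0),
             formula = character(0), mass = numeric(0),
             error_ppm = numeric(0), stringsAsFactors = FALSE)
}

#' Assign CHO formulas to a centroided negative-mode peak list
#'
#' Each peak's neutral mass is reconstructed from its charge state and the
#' best-matching formula is selected (smallest absolute ppm error; ties broken
#' by fewer oxygens, then fewer hydrogens). Peaks with no candidate within the
#' tolerance are retained with `assigned = FALSE` and NA formula columns, so
#' the result always has one row per input peak and can be split by charge.
#'
#' @param peaks data.frame with columns `mz`, `intensity`, `z`.
#' @param tol_ppm mass tolerance in ppm (default 1, applied to both charge
#'   states).
#' @param constraints a [formulaConstraints()] object.
#' @return data.frame with the peak columns plus `neutral_mass`, `c`, `h`,
#'   `o`, `formula`, `error_ppm`, `assigned`.
#' @export
assignPeaklist <- function(peaks, tol_ppm = 1,
                           constraints = formulaConstraints()) {
  stopifnot(is.data.frame(peaks), nrow(peaks) >= 1L,
            all(c("mz", "intensity", "z") %in% names(peaks)))
  if (any(peaks$intensity < 0)) stop("intensities must be non-negative")
  nm <- neutralMass(peaks$mz, peaks$z)
  out <- peaks[, c("mz", "intensity", "z")]
  out$neutral_mass <- nm
  out$c <- NA_integer_; out$h <- NA_integer_; out$o <- NA_integer_
  out$formula <- NA_character_
  out$error_ppm <- NA_real_
  out$assigned <- FALSE
  for (i in seq_len(nrow(out))) {
    cand <- enumerateFormulas(nm[i], tol_ppm, constraints)
    if (nrow(cand) > 0L) {
      out$c[i] <- cand$c[1L]; out$h[i] <- cand$h[1L]; out$o[i] <- cand$o[1L]
      out$formula[i] <- cand$formula[1L]
      out$error_ppm[i] <- cand$error_ppm[1L]
      out$assigned[i] <- TRUE
    }
  }
  rownames(out) <- NULL
  out
}

#' Read a peak list from TSV/CSV
#'
#' Expects a header with columns `mz`, `intensity`, `z`. The delimiter is
#' taken from the file extension (`.tsv` = tab, otherwise comma).
#'
#' @param file path to the peak list.
#' @return data.frame with columns `mz`, `intensity`, `z`.
#' @export
readPeaklist <- function(file) {
  sep <- if (grepl("\\.tsv$", file, ignore.case = TRUE)) "\t" else ","
  x <- utils::read.table(file, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("mz", "intensity", "z")
  if (!all(need %in% names(x)))
    stop("peak list must have header columns mz, intensity, z")
  x$z <- as.integer(x$z)
  x[, need]
}

#' Write a formula assignment report
#'
#' @param assignments result of [assignPeaklist()].
#' @param file output TSV path.
#' @return `file`, invisibly.
#' @export
writeAssignments <- function(assignments, file) {
  utils::write.table(assignments, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

# round half away from zero (R's round() is banker's rounding)
.roundHalfAway <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Atomic H/C and O/C ratios from bulk mass fractions
#'
#' Uses nominal integer atomic masses (12/1/16): this is the convention under
#' which bulk elemental-analysis fractions of lignin preparations reproduce
#' the customarily reported two-decimal ratios. Values are rounded half away
#' from zero to 2 decimals.
#'
#' @param c_pct,h_pct,o_pct elemental mass fractions in percent (ash-free).
#' @return named numeric vector `c(h_c =, o_c =)`.
#' @examples
#' nominalRatios(66.7, 4.82, 28.48)  # h_c 0.87, o_c 0.32
#' @export
nominalRatios <- function(c_pct, h_pct, o_pct) {
  stopifnot(c_pct > 0, h_pct >= 0, o_pct >= 0)
  h_c <- (h_pct / 1) / (c_pct / 12)
  o_c <- (o_pct / 16) / (c_pct / 12)
  c(h_c = .roundHalfAway(h_c, 2), o_c = .roundHalfAway(o_c, 2))
}

#' Oxygen mass fraction by difference
#'
#' For a CHO substance analysed on an ash-free basis, oxygen is computed as
#' the balance after carbon and hydrogen (nitrogen treated as zero).
#'
#' @param c_pct,h_pct carbon and hydrogen mass fractions in percent, already
#'   ash-corrected.
#' @return oxygen mass fraction in percent.
#' @export
oxygenByDifference <- function(c_pct, h_pct) {
  stopifnot(c_pct >= 0, h_pct >= 0)
  o <- 100 - c_pct - h_pct
  if (any(o < 0)) stop("C + H exceed 100%: not a valid ash-free composition")
  o
}

#' Number-averaged elemental composition of an assigned formula set
#'
#' Each formula's elemental mass fractions (nominal masses 12/1/16) are
#' averaged with equal weight per formula ("number-averaged"); an
#' intensity-weighted mean is available via `weights`.
#'
#' @param formulas data.frame with columns `c`, `h`, `o` (NA rows dropped).
#' @param weights optional non-negative weights, one per formula row.
#' @return named numeric vector `c(c_pct =, h_pct =, o_pct =)`, summing to 100.
#' @export
numberAveragedComposition <- function(formulas, weights = NULL) {
  stopifnot(is.data.frame(formulas))
  keep <- stats::complete.cases(formulas[, c("c", "h", "o")])
  formulas <- formulas[keep, , drop = FALSE]
  if (nrow(formulas) == 0L) stop("no complete formulas to average")
  if (!is.null(weights)) {
    weights <- weights[keep]
    stopifnot(length(weights) == nrow(formulas), all(weights >= 0),
              sum(weights) > 0)
  }
  m <- 12 * formulas$c + 1 * formulas$h + 16 * formulas$o
  frac <- cbind(c_pct = 100 * 12 * formulas$c / m,
                h_pct = 100 * 1 * formulas$h / m,
                o_pct = 100 * 16 * formulas$o / m)
  if (is.null(weights)) colMeans(frac)
  else colSums(frac * weights) / sum(weights)
}
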