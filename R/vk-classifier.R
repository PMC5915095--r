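# Van Krevelen coordinates and molecular-class labels for CHO formulas.

#' Van Krevelen class regions
#'
#' The three regions the analysis quantifies, applied in precedence order
#' aliphatic -> condensed aromatic -> lignin-like -> unclassified. Aliphatic
#' and condensed-aromatic bounds are strict inequalities on H/C; the
#' lignin-like window is closed on both axes.
#'
#' @param aliphatic_hc H/C above which a formula is called aliphatic.
#' @param condensed_hc H/C below which a formula is called condensed aromatic.
#' @param lignin_hc,lignin_oc closed `[lo, hi]` windows of the lignin-like
#'   region on the H/C and O/C axes.
#' @return list of class `"vkRegions"`.
#' @export
vkRegions <- function(aliphatic_hc = 1.2, condensed_hc = 0.5,
                      lignin_hc = c(0.5, 1.0), lignin_oc = c(0.3, 0.5)) {
  structure(list(aliphatic_hc = aliphatic_hc, condensed_hc = condensed_hc,
                 lignin_hc = lignin_hc, lignin_oc = lignin_oc),
            class = "vkRegions")
}

#' Van Krevelen coordinates of CHO formulas
#'
#' Atomic ratios computed from element counts (not mass fractions):
#' O/C = o/c, H/C = h/c.
#'
#' @param formulas data.frame with columns `c`, `h`, `o`.
#' @return data.frame with columns `o_c`, `h_c`, `mw` (monoisotopic Da).
#' @export
vkCoordinates <- function(formulas) {
  stopifnot(is.data.frame(formulas), all(c("c", "h", "o") %in% names(formulas)))
  if (any(formulas$c < 1, na.rm = TRUE)) stop("formulas must contain carbon")
  data.frame(o_c = formulas$o / formulas$c,
             h_c = formulas$h / formulas$c,
             mw = monoisotopicMass(formulas))
}

#' Classify Van Krevelen points into molecular classes
#'
#' @param o_c,h_c atomic ratios (vectorised).
#' @param regions a [vkRegions()] object.
#' @return character vector with values `"aliphatic"`, `"condensed_aromatic"`,
#'   `"lignin_like"` or `"unclassified"` — exactly one label per point.
#' @export
vkClassify <- function(o_c, h_c, regions = vkRegions()) {
  stopifnot(length(o_c) == length(h_c))
  lab <- rep("unclassified", length(h_c))
  lig <- h_c >= regions$lignin_hc[1] & h_c <= regions$lignin_hc[2] &
         o_c >= regions$lignin_oc[1] & o_c <= regions$lignin_oc[2]
  lab[lig] <- "lignin_like"
  lab[h_c < regions$condensed_hc] <- "condensed_aromatic"
  lab[h_c > regions$aliphatic_hc] <- "aliphatic"
  lab
}

#' Plot-ready Van Krevelen table for a set of formula assignments
#'
#' One labelled point per assigned peak, carrying the charge state so singly
#' and doubly charged populations can be distinguished downstream.
#'
#' @param assignments result of [assignPeaklist()] (unassigned rows dropped),
#'   or any data.frame with columns `c`, `h`, `o` and optionally `z`.
#' @param regions a [vkRegions()] object.
#' @return data.frame with columns `formula`, `o_c`, `h_c`, `mw`, `charge`,
#'   `label`.
#' @export
vkTable <- function(assignments, regions = vkRegions()) {
  stopifnot(is.data.frame(assignments))
  if ("assigned" %in% names(assignments))
    assignments <- assignments[assignments$assigned, , drop = FALSE]
  if (nrow(assignments) == 0L)
    return(data.frame(formula = character(0), o_c = numeric(0),
                      h_c = numeric(0), mw = numeric(0), charge = integer(0),
                      label = character(0), stringsAsFactors = FALSE))
  vk <- vkCoordinates(assignments)
  data.frame(formula = formulaString(assignments),
             o_c = vk$o_c, h_c = vk$h_c, mw = vk$mw,
             charge = if ("z" %in% names(assignments))
               as.integer(assignments$z) else NA_integer_,
             label = vkClassify(vk$o_c, vk$h_c, regions),
             stringsAsFactors = FALSE)
}
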