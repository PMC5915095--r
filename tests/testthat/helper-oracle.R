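# Independent brute-force oracle for the formula enumerator: materialise the
# full constraint box (C <= 120, H <= 200, O <= 60 cross product, then filter
# O/C <= 1, H/C <= 2) once, and answer mass queries by direct filtering.
# Shares no code with enumerateFormulas().

.oracle_env <- new.env(parent = emptyenv())

oracleBox <- function() {
  if (!is.null(.oracle_env$box)) return(.oracle_env$box)
  cc <- rep(1:120, each = 61 * 201)
  oo <- rep(rep(0:60, each = 201), times = 120)
  hh <- rep(0:200, times = 120 * 61)
  keep <- oo / cc <= 1 & hh / cc <= 2
  cc <- cc[keep]; oo <- oo[keep]; hh <- hh[keep]
  mass <- cc * 12 + hh * 1.0078250319 + oo * 15.9949146221
  .oracle_env$box <- data.frame(c = cc, h = hh, o = oo, mass = mass)
  .oracle_env$box
}

oracleEnumerate <- function(neutral_mass, tol_ppm = 1) {
  box <- oracleBox()
  hit <- abs(box$mass - neutral_mass) / neutral_mass * 1e6 <= tol_ppm
  box[hit, c("c", "h", "o")]
}

# order-independent key set for comparing formula tables
formulaKey <- function(d) sort(paste(d$c, d$h, d$o, sep = "_"))
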