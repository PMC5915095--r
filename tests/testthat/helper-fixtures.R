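# Tiny in-code fixtures shared across the miner/scoring tests.

# three-target mini panel profile: two actives, one inactive
miniProfile <- function() {
  buildProfile(data.frame(
    target_symbol = c("ADORA1", "DRD4", "OPRK1"),
    inhibition_pct = c(62.1, 62.7, 23),
    interference = 0L), threshold = 50)
}

# store with two isomers of a flavone formula and one decoy compound
miniStore <- function() {
  compounds <- data.frame(
    compound_id = c("A", "B", "C"),
    formula_string = c("C15H10O5", "C15H10O5", "C20H30O2"),
    smiles = c("Cc1ccccc1", "OC1Cc2ccccc2OC1c1ccccc1", "CCCCCC"),
    stringsAsFactors = FALSE)
  assays <- data.frame(
    assay_id = sprintf("AS%02d", 1:5),
    compound_id = c("A", "A", "B", "B", "C"),
    target_name = c("Adenosine A1 receptor", "Dopamine D4 receptor",
                    "Adenosine A1 receptor", "Kappa opioid receptor",
                    "Adenosine A1 receptor"),
    description = c("Binding to human Adenosine A1 receptor",
                    "Displacement assay, dopamine D4",
                    "Radioligand binding, adenosine A1 site",
                    "Kappa opioid displacement",
                    "Decoy assay"),
    activity_type = c("Ki", "IC50", "Ki", "Ki", "Ki"),
    relation = "=",
    value = c(50, 100000, 2, 500, 10),
    units = c("nM", "nM", "uM", "nM", "nM"),
    stringsAsFactors = FALSE)
  list(compounds = compounds, assays = assays)
}

miniKeys <- function() {
  data.frame(key = c("adenosine a1", "dopamine d4", "kappa opioid"),
             panel_target = c("ADORA1", "DRD4", "OPRK1"),
             stringsAsFactors = FALSE)
}

# fingerprints built directly from a 1/0/NA matrix
fpFromMatrix <- function(m) {
  methods::new("ActivityFingerprints", fp = m)
}
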