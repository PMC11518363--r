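# SummarizedExperiment builder for ranking tests
makeSe <- function(mat, condition) {
  SummarizedExperiment::SummarizedExperiment(
    assays = list(relexpr = mat),
    colData = S4Vectors::DataFrame(condition = condition))
}

# Cq record rows in the canonical table shape
cqRec <- function(sample_id, assay_name, cq, well_class, plate_id = "p1") {
  data.frame(sample_id = sample_id, assay_name = assay_name, cq = cq,
             well_class = well_class, plate_id = plate_id,
             stringsAsFactors = FALSE)
}

noiselessParams <- function(k = 1) {
  p <- defaultCurveParams()
  p$k <- k
  p$noiseSd <- 0
  p
}

panelMirnas <- function() {
  lay <- makeDefaultLayout()
  wells(lay)$assay_name[wells(lay)$well_class == "mirna_assay"]
}
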