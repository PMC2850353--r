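# The combined golden-mole matrix ("gmole-comb-feb10.nex", with its 8 MP trees
# in a TREES block) is published supplementary data and is not redistributed
# with this package. Placing a copy at inst/extdata/gmole-comb-feb10.nex (or
# next to the installed extdata) enables the full empirical checks.

study_matrix_path <- function() {
  p <- system.file("extdata", "gmole-comb-feb10.nex", package = "parsmix")
  if (nzchar(p)) return(p)
  file.path(system.file("extdata", package = "parsmix"),
            "gmole-comb-feb10.nex")
}

chrysochlorid_genera <- c(
  "Amblysomus", "Neamblysomus", "Carpitalpa", "Chlorotalpa", "Huetia",
  "Calcochloris", "Chrysochloris", "Cryptochloris", "Chrysospalax",
  "Eremitalpa"
)

tenrecid_genera <- c(
  "Echinops", "Geogale", "Hemicentetes", "Microgale", "Limnogale",
  "Micropotamogale", "Oryzorictes", "Potamogale", "Setifer", "Tenrec"
)

taxa_matching <- function(taxa, genera) {
  taxa[grepl(paste(genera, collapse = "|"), taxa, ignore.case = TRUE)]
}
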