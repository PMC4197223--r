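#' Published pairwise FST matrix for ten dairy-sheep breeds
#'
#' A 10 x 10 symmetric matrix of pairwise Weir-Cockerham FST among ten
#' sheep breeds — three Sicilian dairy breeds (PIN Pinzirita, COM Comisana,
#' VDB Valle del Belice) together with SAB/SAW Sarda black/white, CHI
#' Chios, CAS Castellana, MER Merino, LAC Lacaune and LEC Leccese — typical
#' published 50K-chip estimates for Mediterranean and European sheep.
#' Bundled as the worked-example input for ordination ([classical_mds()])
#' and split networks ([neighbor_net()]): Chios is the most divergent breed
#' on both.
#'
#' @return Named symmetric numeric matrix with zero diagonal.
#' @export
sheep_breed_fst <- function() {
  path <- system.file("extdata", "sheep_breed_fst.tsv", package = "popgenpipe")
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE)
  as.matrix(tab)
}
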