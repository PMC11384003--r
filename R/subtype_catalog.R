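#' Catalog of neurosecretory-cell subtypes in the central brain
#'
#' Reference table of NSC classes defined by soma position (pars
#' intercerebralis, pars lateralis, subesophageal zone) and the hormone(s)
#' they produce, with the number of cells per class in larvae, the number
#' expected in adults from earlier anatomical work, and the number observed in
#' the adult whole-brain connectome. The larval-only classes (eclosion hormone
#' and PTTH neurons) are retained with zero adult counts; the classes without
#' a known hormone have counts only for the adult connectome.
#'
#' @return A data frame with columns `name`, `soma`, `peptides`,
#'   `n_larva`, `n_adult_expected`, `n_adult_observed`.
#' @examples
#' cat <- nsc_subtype_catalog()
#' sum(cat$n_adult_observed)   # total NSC identified in the adult brain
#' @export
nsc_subtype_catalog <- function() {
  data.frame(
    name = c("m-NSC^DMS", "m-NSC^DH44", "m-NSC^DILP", "NSC^EH",
             "l-NSC^CRZ", "l-NSC^ITP", "l-NSC^DH31", "l-NSC^PTTH",
             "SEZ-NSC^CAPA", "SEZ-NSC^Hugin",
             "m-NSC^unknown", "l-NSC^unknown"),
    soma = c("medial", "medial", "medial", "medial",
             "lateral", "lateral", "lateral", "lateral",
             "subesophageal", "subesophageal", "medial", "lateral"),
    peptides = c("Ms", "Dh44", "Ilp2;Ilp3;Ilp5", "Eh",
                 "Crz;sNPF", "ITP;Tk;sNPF", "Dh31;ITP", "Ptth",
                 "Capa;Ms", "Hug", "", ""),
    n_larva = c(4L, 6L, 14L, 2L, 6L, 8L, 6L, 4L, 2L, 4L, NA, NA),
    n_adult_expected = c(4L, 6L, 14L, 0L, 14L, 8L, 6L, 0L, 2L, 4L, NA, NA),
    n_adult_observed = c(6L, 6L, 18L, 0L, 6L, 8L, 6L, 0L, 2L, 4L, 10L, 14L),
    stringsAsFactors = FALSE
  )
}
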