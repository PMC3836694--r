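# Published DnaK NBD reference tables shipped with the package: the
# conservation percentages of the II-A/II-B hinge-region residues by taxon
# group, the multimodal (multi-cluster phi/psi) residue list, and the
# nucleotide-correlated residue list from the original LD study. These are
# literature inputs, used for filter arithmetic and as defaults for the
# synthetic generator.

hs_extdata <- function(name) {
  f <- system.file("extdata", name, package = "hingescan")
  if (f == "") f <- file.path("inst", "extdata", name)  # pre-install fallback
  if (!file.exists(f)) stopf("packaged table not found: %s", name)
  f
}

#' Published DnaK hinge-region tables
#'
#' `dnak_conservation_table()` returns the published per-residue identity
#' and conservative-substitution percentages for the II-A/II-B hinge region
#' across bacteria (1714 orthologs), animals (1388) and plants (597), in
#' [conservation_profile()] layout. `dnak_multimodal_residues()` returns
#' the residues reported to occupy multiple phi-psi clusters in the LD
#' simulations; `dnak_correlated_residues()` those reported significantly
#' correlated to the nucleotide (top-60 in at least 4 of 10 runs).
#'
#' @return data.frames (see each description).
#' @export
dnak_conservation_table <- function() {
  x <- utils::read.csv(hs_extdata("dnak_hinge_conservation.csv"),
                       stringsAsFactors = FALSE)
  x$combined_pct <- x$identity_pct + x$conservative_pct
  class(x) <- c("conservation_profile", "data.frame")
  x
}

#' @rdname dnak_conservation_table
#' @export
dnak_multimodal_residues <- function() {
  utils::read.csv(hs_extdata("dnak_multimodal_residues.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname dnak_conservation_table
#' @export
dnak_correlated_residues <- function() {
  utils::read.csv(hs_extdata("dnak_nucleotide_correlated.csv"),
                  stringsAsFactors = FALSE)
}
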