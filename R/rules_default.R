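# Default chromosome-4 rule set: the loci, allele registry and deficiency
# registry needed to represent the bundled stock-center stocks.
#
# What each Df(4)ED* deficiency actually removes is not resolved at the gene
# level here; each deficiency deletes a private essential "region" locus
# (making it homozygous lethal and viable over a normal homolog), none of
# them removes RpS3A or l(4)102EFf (their heterozygotes with RpS3A[57g] and
# l(4)102EFf[1] are viable), and Df(4)ED6380 additionally removes ey (its
# heterozygotes with ey[1] are eyeless). The fixture files flag this
# assumption.

#' Default chromosome-4 phenotype rules and registries
#'
#' Declares *RpS3A* (essential, haploinsufficient, dominant label
#' `"Minute"`), the essential lethal *l(4)102EFf*, recessive *ey*
#' (`"eyeless"`), *ci* with the dominant `ci[D]` marker, *unc-13* with the
#' GFP-marked `P{ActGFP}unc-13[GJ]` insertion, the `In(4)ci[D]` balancer
#' lethality, and a private essential region locus per bundled deficiency.
#' Default viabilities: disomic and trisomic 1, monosomic 0.5, nullosomic
#' and tetrasomic 0, Minute classes scaled by 0.7.
#'
#' @param minute_viability Relative viability of Minute classes, in `[0,1]`.
#' @param monosomic_viability Relative viability of haplo-4 zygotes.
#' @param trisomic_viability Relative viability of triplo-4 zygotes.
#' @return A [phenotype_rules()] object.
#' @export
default_rules <- function(minute_viability = 0.7,
                          monosomic_viability = 0.5,
                          trisomic_viability = 1) {
  loci <- list(
    locus("RpS3A", essential = TRUE, haploinsufficient = TRUE,
          dominant_phenotype = "Minute"),
    locus("l(4)102EFf", essential = TRUE),
    locus("ey", recessive_phenotype = "eyeless"),
    locus("ci", essential = TRUE),
    locus("pan", essential = TRUE),
    locus("unc-13"),
    locus("Crk"),
    locus("Gat"),
    locus("In(4)ciD-lethal", essential = TRUE),
    locus("RS5-element"),
    locus("ED6369-region", essential = TRUE),
    locus("ED6380-region", essential = TRUE),
    locus("ED6382-region", essential = TRUE),
    locus("ED6384-region", essential = TRUE)
  )
  reg <- function(locus, functional = TRUE, marker = NA_character_)
    list(locus = locus, functional = functional, marker = marker)
  alleles <- list(
    "RpS3A[57g]"             = reg("RpS3A", FALSE),
    "ey[1]"                  = reg("ey", FALSE),
    "l(4)102EFf[1]"          = reg("l(4)102EFf", FALSE),
    "In(4)ci[D]"             = reg("In(4)ciD-lethal", FALSE),
    "ci[D]"                  = reg("ci", TRUE, "ci-D"),
    "pan[ciD]"               = reg("pan", TRUE),
    "P{ActGFP}unc-13[GJ]"    = reg("unc-13", FALSE, "GFP"),
    "TI{TI}Crk[dsRed]"       = reg("Crk", TRUE, "dsRed"),
    "TI{GMR-HMS04515}Gat[eya]" = reg("Gat", TRUE),
    # the P{RS5} elements ride on the deficiency chromosomes; inert here
    "P{3'.RS5+3.3'}ED6369"   = reg("RS5-element", TRUE),
    "P{3'.RS5+3.3'}ED6380"   = reg("RS5-element", TRUE),
    "P{3'.RS5+3.3'}ED6382"   = reg("RS5-element", TRUE),
    "P{3'.RS5+3.3'}ED6384"   = reg("RS5-element", TRUE)
  )
  deficiencies <- list(
    "Df(4)ED6369" = "ED6369-region",
    "Df(4)ED6380" = c("ED6380-region", "ey"),
    "Df(4)ED6382" = "ED6382-region",
    "Df(4)ED6384" = "ED6384-region"
  )
  phenotype_rules(
    loci, alleles = alleles, deficiencies = deficiencies,
    copy_class_viability = c(nullosomic = 0,
                             monosomic = monosomic_viability,
                             disomic = 1,
                             trisomic = trisomic_viability,
                             tetrasomic = 0),
    phenotype_viability = c(Minute = minute_viability))
}
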