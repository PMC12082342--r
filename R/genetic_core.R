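# Karyotypes, loci, alleles, and the genotype -> phenotype/viability rules
# engine. Chromosome-4 copies are opaque labelled objects carrying allele
# states at named loci; loci not listed on a copy are implicitly functional
# wild type unless the copy deletes them.

#' Declare a chromosome-4 locus
#'
#' A locus is the unit at which functional gene copies are counted.
#' Essential loci are lethal at zero functional copies; haploinsufficient
#' loci (the Minute ribosomal-protein genes such as *RpS3A*) show a dominant
#' phenotype when exactly one functional copy is present.
#'
#' @param name Unique locus identifier.
#' @param essential Logical; zero functional copies is lethal.
#' @param haploinsufficient Logical; exactly one functional copy shows
#'   `dominant_phenotype` (which must then be supplied).
#' @param recessive_phenotype Optional label shown when the functional copy
#'   count is zero at a non-essential locus (e.g. `"eyeless"` for *ey*).
#' @param dominant_phenotype Optional label; for haploinsufficient loci this
#'   is the phenotype at copy number one (e.g. `"Minute"`).
#' @return An object of class `"locus"`.
#' @examples
#' locus("RpS3A", essential = TRUE, haploinsufficient = TRUE,
#'       dominant_phenotype = "Minute")
#' @export
locus <- function(name, essential = FALSE, haploinsufficient = FALSE,
                  recessive_phenotype = NA_character_,
                  dominant_phenotype = NA_character_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (isTRUE(haploinsufficient) && is.na(dominant_phenotype))
    stop("haploinsufficient locus '", name,
         "' must declare the dominant phenotype shown at copy number 1")
  structure(
    list(name = name, essential = isTRUE(essential),
         haploinsufficient = isTRUE(haploinsufficient),
         recessive_phenotype = as.character(recessive_phenotype),
         dominant_phenotype = as.character(dominant_phenotype)),
    class = "locus")
}

#' Declare an allele carried on a chromosome copy
#'
#' @param locus Name of the locus the allele belongs to.
#' @param functional Logical; does the allele provide locus function?
#' @param marker_label Optional dominant visible marker expressed whenever
#'   the allele is present on at least one copy (e.g. `"GFP"`, `"ci-D"`).
#' @return An object of class `"allele"`.
#' @export
allele <- function(locus, functional = TRUE, marker_label = NA_character_) {
  stopifnot(is.character(locus), length(locus) == 1L, nzchar(locus))
  structure(list(locus = locus, functional = isTRUE(functional),
                 marker_label = as.character(marker_label)),
            class = "allele")
}

#' Construct one labelled fourth-chromosome homolog
#'
#' @param label Identifier for the copy (e.g. `"Df(4)ED6382"`); copies with
#'   equal labels are treated as identical throughout the package.
#' @param alleles List of [allele()] objects carried on this copy; loci not
#'   listed default to a functional wild-type allele.
#' @param deleted_loci Character vector of locus names removed by this copy
#'   (deficiencies); contributes zero functional copies there.
#' @return An object of class `"chromosome_copy"`.
#' @examples
#' chromosome_copy("RpS3A[57g]", alleles = list(allele("RpS3A", FALSE)))
#' @export
chromosome_copy <- function(label, alleles = list(),
                            deleted_loci = character()) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  if (length(alleles) && !all(vapply(alleles, inherits, TRUE, "allele")))
    stop("'alleles' must be a list of allele() objects")
  names(alleles) <- vapply(alleles, `[[`, "", "locus")
  if (anyDuplicated(names(alleles)))
    stop("copy '", label, "' lists more than one allele at the same locus")
  bad <- intersect(names(alleles), deleted_loci)
  if (length(bad))
    stop("copy '", label, "' lists locus both as allele and deleted: ",
         paste(bad, collapse = ", "))
  structure(list(label = label, alleles = alleles,
                 deleted_loci = as.character(deleted_loci)),
            class = "chromosome_copy")
}

#' Construct a karyotype (the unit of genotype)
#'
#' A karyotype is a multiset of 0-4 chromosome-4 copies plus inert background
#' labels (other-chromosome genotype elements carried along for bookkeeping
#' only). Copy number 1 is monosomic (haplo-4), 2 disomic, 3 trisomic
#' (triplo-4), 4 tetrasomic.
#'
#' @param chr4_copies List of [chromosome_copy()] objects, length 0-4.
#' @param background Character vector of inert labels (e.g. `"w[1118]"`).
#' @param sex `"female"`, `"male"`, or `"unspecified"` (progeny classes with
#'   sex marginalized out).
#' @return An object of class `"karyotype"`.
#' @export
karyotype <- function(chr4_copies = list(), background = character(),
                      sex = c("unspecified", "female", "male")) {
  sex <- match.arg(sex)
  if (!is.list(chr4_copies) ||
      (length(chr4_copies) &&
       !all(vapply(chr4_copies, inherits, TRUE, "chromosome_copy"))))
    stop("'chr4_copies' must be a list of chromosome_copy() objects")
  if (length(chr4_copies) > 4L)
    stop("unsupported karyotype: more than four chromosome-4 copies")
  structure(list(chr4 = chr4_copies, background = as.character(background),
                 sex = sex),
            class = "karyotype")
}

copy_labels <- function(kar) vapply(kar$chr4, `[[`, "", "label")

#' Canonical identity key of a karyotype
#'
#' Copies are sorted by label, so parental origin and listing order are
#' ignored: `Df/M` from a Df-bearing mother equals `Df/M` from a Df-bearing
#' father.
#'
#' @param kar A [karyotype()].
#' @return A single string.
#' @export
karyotype_key <- function(kar) {
  lab <- copy_labels(kar)
  if (!length(lab)) "(nullosomic)" else paste(sort(lab), collapse = " / ")
}

#' Phenotype and viability rule set
#'
#' Holds the declared loci, the allele and deficiency registries used by the
#' genotype grammar, and viability weights. The viability of a non-lethal
#' class is the product of a copy-number-class base weight and one weight per
#' emitted phenotype label (labels without an entry weigh 1); essential loci
#' at zero functional copies are lethal regardless.
#'
#' @param loci List of [locus()] objects (unique names).
#' @param alleles Named list (designator -> `list(locus, functional, marker)`)
#'   used by [parse_genotype()].
#' @param deficiencies Named list (deficiency designator -> character vector
#'   of deleted locus names).
#' @param copy_class_viability Named numeric in `[0,1]` for the five copy
#'   classes; at least one must equal 1 (the reference class).
#' @param phenotype_viability Named numeric in `[0,1]`, multiplicative per
#'   phenotype label (default: Minute 0.7).
#' @param monosomic_label Label attached to monosomic (haplo-4) karyotypes.
#' @return An object of class `"phenotype_rules"`.
#' @export
phenotype_rules <- function(loci,
                            alleles = list(),
                            deficiencies = list(),
                            copy_class_viability = c(nullosomic = 0,
                                                     monosomic = 0.5,
                                                     disomic = 1,
                                                     trisomic = 1,
                                                     tetrasomic = 0),
                            phenotype_viability = c(Minute = 0.7),
                            monosomic_label = "haplo-4") {
  if (!is.list(loci) || !all(vapply(loci, inherits, TRUE, "locus")))
    stop("'loci' must be a list of locus() objects")
  names(loci) <- vapply(loci, `[[`, "", "name")
  if (anyDuplicated(names(loci)))
    stop("locus names must be unique within a rule set")
  need <- c("nullosomic", "monosomic", "disomic", "trisomic", "tetrasomic")
  if (!all(need %in% names(copy_class_viability)))
    stop("copy_class_viability must name all five copy-number classes")
  w <- c(copy_class_viability, phenotype_viability)
  if (any(w < 0 | w > 1)) stop("viability weights must lie in [0, 1]")
  if (max(copy_class_viability) < 1)
    stop("at least one copy-number class must have viability 1 (reference)")
  structure(list(loci = loci, alleles = alleles, deficiencies = deficiencies,
                 copy_class_viability = copy_class_viability,
                 phenotype_viability = phenotype_viability,
                 monosomic_label = as.character(monosomic_label)),
            class = "phenotype_rules")
}

copy_classes <- c("nullosomic", "monosomic", "disomic", "trisomic",
                  "tetrasomic")

# functional contribution of the karyotype at one locus, no declaration check
functional_count <- function(kar, locus_name) {
  n <- 0L
  for (cp in kar$chr4) {
    if (locus_name %in% cp$deleted_loci) next
    al <- cp$alleles[[locus_name]]
    n <- n + if (is.null(al)) 1L else as.integer(al$functional)
  }
  n
}

#' Count functional gene copies at a locus
#'
#' Deleted loci and non-functional alleles contribute 0; loci not listed on
#' a copy contribute 1 per copy (implicit wild type).
#'
#' @param kar A [karyotype()].
#' @param locus_name Name of a locus declared in `rules`.
#' @param rules A [phenotype_rules()] object.
#' @return Integer count in `0:length(kar$chr4)`.
#' @examples
#' rules <- default_rules()
#' tester <- karyotype(list(
#'   chromosome_copy("RpS3A[57g]", list(allele("RpS3A", FALSE))),
#'   chromosome_copy("+")))
#' count_functional_copies(tester, "RpS3A", rules)  # 1 -> Minute
#' @export
count_functional_copies <- function(kar, locus_name, rules) {
  stopifnot(inherits(kar, "karyotype"), inherits(rules, "phenotype_rules"))
  if (!locus_name %in% names(rules$loci))
    stop("locus '", locus_name, "' is not declared in the rule set")
  functional_count(kar, locus_name)
}

hi_labels <- function(rules) {
  unlist(lapply(rules$loci, function(l)
    if (l$haploinsufficient) l$dominant_phenotype else NULL),
    use.names = FALSE)
}

#' Classify the phenotype and viability of a karyotype
#'
#' Applies the rules engine: a haploinsufficient locus at functional copy
#' count 1 emits its dominant label (Minute); an essential locus at count 0
#' is lethal; a non-essential locus at count 0 emits its recessive label;
#' dominant marker labels are emitted when the marker allele is present on
#' any copy; monosomic karyotypes additionally carry the haplo-4 label.
#' Viability is 0 for lethal classes, otherwise the copy-class base weight
#' times the per-label weights.
#'
#' @param kar A [karyotype()] with 0-4 chromosome-4 copies.
#' @param rules A [phenotype_rules()] object.
#' @return A list with elements `phenotypes` (sorted character vector),
#'   `viability` (numeric in `[0,1]`), `lethal` (logical), and `copy_class`.
#' @examples
#' rules <- default_rules()
#' m <- chromosome_copy("RpS3A[57g]", list(allele("RpS3A", FALSE)))
#' wt <- chromosome_copy("+")
#' classify_phenotype(karyotype(list(m, wt)), rules)$phenotypes        # Minute
#' classify_phenotype(karyotype(list(m, wt, wt)), rules)$phenotypes    # none
#' @export
classify_phenotype <- function(kar, rules) {
  stopifnot(inherits(kar, "karyotype"), inherits(rules, "phenotype_rules"))
  n <- length(kar$chr4)
  if (n > 4L) stop("unsupported karyotype: more than four chromosome-4 copies")
  cls <- copy_classes[n + 1L]
  labels <- character()
  lethal <- FALSE
  for (loc in rules$loci) {
    cnt <- functional_count(kar, loc$name)
    if (loc$essential && cnt == 0L) lethal <- TRUE
    if (loc$haploinsufficient && cnt == 1L)
      labels <- c(labels, loc$dominant_phenotype)
    if (!loc$essential && cnt == 0L && n > 0L &&
        !is.na(loc$recessive_phenotype))
      labels <- c(labels, loc$recessive_phenotype)
  }
  for (cp in kar$chr4)
    for (al in cp$alleles)
      if (!is.na(al$marker_label)) labels <- c(labels, al$marker_label)
  if (n == 1L && length(rules$monosomic_label) &&
      !is.na(rules$monosomic_label))
    labels <- c(labels, rules$monosomic_label)
  labels <- sort(unique(labels))
  viability <- if (lethal) 0 else {
    w <- unname(rules$copy_class_viability[[cls]])
    for (lb in labels)
      if (lb %in% names(rules$phenotype_viability))
        w <- w * unname(rules$phenotype_viability[[lb]])
    w
  }
  list(phenotypes = labels, viability = viability,
       lethal = lethal || viability == 0, copy_class = cls)
}

# does the karyotype carry a Minute-causing lesion (non-functional allele or
# deletion at a haploinsufficient locus)?
carries_minute_lesion <- function(kar, rules) {
  hi <- names(Filter(function(l) l$haploinsufficient, rules$loci))
  if (!length(hi)) return(FALSE)
  for (cp in kar$chr4) {
    if (any(hi %in% cp$deleted_loci)) return(TRUE)
    for (al in cp$alleles)
      if (al$locus %in% hi && !al$functional) return(TRUE)
  }
  FALSE
}

#' @export
print.karyotype <- function(x, ...) {
  n <- length(x$chr4)
  geno <- format_genotype(x)
  cat(sprintf("<karyotype> %s  [%s, %s]\n",
              if (nzchar(geno)) geno else "(nullosomic)",
              copy_classes[n + 1L], x$sex))
  invisible(x)
}

#' @export
print.phenotype_rules <- function(x, ...) {
  cat(sprintf("<phenotype_rules> %d loci, %d registered alleles, %d deficiencies\n",
              length(x$loci), length(x$alleles), length(x$deficiencies)))
  for (l in x$loci)
    cat(sprintf("  %-14s %s%s%s%s\n", l$name,
                if (l$essential) "essential " else "",
                if (l$haploinsufficient)
                  paste0("haploinsufficient->", l$dominant_phenotype, " ")
                else "",
                if (!is.na(l$recessive_phenotype))
                  paste0("recessive->", l$recessive_phenotype, " ") else "",
                if (!l$haploinsufficient && !is.na(l$dominant_phenotype))
                  paste0("dominant->", l$dominant_phenotype) else ""))
  invisible(x)
}
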