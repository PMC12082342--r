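# Exact progeny-class distributions: outer product of the two parents'
# gamete distributions, merged over canonical (unordered, origin-free)
# zygote karyotypes, with phenotype labels and viability weighting from the
# rules engine.

# Combine two gamete distributions into merged zygote classes.
# Returns list(classes = data.frame, karyotypes = named list).
combine_gamete_distributions <- function(mdist, fdist, rules,
                                         background = character()) {
  prob <- numeric()
  kars <- list()
  mk <- names(mdist$prob); fk <- names(fdist$prob)
  for (i in seq_along(mk)) {
    for (j in seq_along(fk)) {
      cps <- c(mdist$copies[[mk[i]]], fdist$copies[[fk[j]]])
      kar <- karyotype(cps, background = background)
      key <- karyotype_key(kar)
      if (is.null(kars[[key]])) {
        kars[[key]] <- kar
        prob[key] <- 0
      }
      prob[key] <- prob[key] + mdist$prob[[mk[i]]] * fdist$prob[[fk[j]]]
    }
  }
  keys <- names(prob)
  hi <- hi_labels(rules)
  cls <- lapply(kars[keys], classify_phenotype, rules = rules)
  viability <- vapply(cls, `[[`, 0, "viability")
  phen <- lapply(cls, `[[`, "phenotypes")
  n_copies <- vapply(kars[keys], function(k) length(k$chr4), 0L)
  raw <- unname(prob)
  mass <- raw * viability
  adjusted <- if (sum(mass) > 0) mass / sum(mass) else rep(0, length(mass))
  classes <- data.frame(
    class = keys,
    n_copies = n_copies,
    frequency_raw = raw,
    frequency_adjusted = adjusted,
    viability = unname(viability),
    phenotypes = vapply(phen, paste, "", collapse = ";"),
    lethal = vapply(cls, `[[`, TRUE, "lethal"),
    carries_minute_allele = vapply(kars[keys], carries_minute_lesion, TRUE,
                                   rules = rules),
    minute_phenotype = vapply(phen, function(p) any(p %in% hi), TRUE),
    disomic = n_copies == 2L,
    trisomic = n_copies == 3L,
    stringsAsFactors = FALSE, row.names = NULL)
  classes <- classes[order(-classes$frequency_raw, classes$class), ]
  row.names(classes) <- NULL
  list(classes = classes, karyotypes = kars)
}

#' Exact cross between two parents
#'
#' Computes the outer product of the parents' gamete distributions, merges
#' identical (unordered) zygote karyotypes, labels phenotypes, and weights
#' by viability. Lethal classes are retained with adjusted frequency 0 so
#' that balanced-lethal stock structure stays visible; a both-gametes-nullo
#' zygote is reported as the nullosomic class (viability 0), not an error.
#' Progeny sex is marginalized out (no chromosome-4-linked sex effects are
#' modeled); background labels of both parents are pooled.
#'
#' @param mother,father [karyotype()] objects with 1-3 chromosome-4 copies.
#' @param model A [segregation_model()], applied to both parents
#'   (chromosome-4 meiosis is modeled identically in the two sexes).
#' @param rules A [phenotype_rules()] object.
#' @return An object of class `"cross_result"`: list with `classes` (data
#'   frame of progeny classes with raw and viability-adjusted frequencies,
#'   phenotypes and diagnostic flags), `karyotypes` (named list keyed by
#'   class), `mother`, `father`, `model`, `rules`.
#' @examples
#' rules <- default_rules()
#' tester <- parse_genotype("RpS3A[57g] / In(4)ci[D], ci[D], pan[ciD]", rules)
#' df <- parse_genotype(
#'   "Df(4)ED6382, P{3'.RS5+3.3'}ED6382 / P{ActGFP}unc-13[GJ]", rules)
#' cross(df, tester, segregation_model(nondisjunction_rate = 0), rules)
#' @export
cross <- function(mother, father, model = segregation_model(),
                  rules = default_rules()) {
  stopifnot(inherits(mother, "karyotype"), inherits(father, "karyotype"))
  for (p in list(mother, father))
    if (length(p$chr4) < 1L || length(p$chr4) > 3L)
      stop("parents must carry 1-3 chromosome-4 copies")
  mdist <- gamete_distribution(mother, model)
  fdist <- gamete_distribution(father, model)
  bg <- unique(c(mother$background, father$background))
  out <- combine_gamete_distributions(mdist, fdist, rules, background = bg)
  structure(list(classes = out$classes, karyotypes = out$karyotypes,
                 mother = mother, father = father,
                 model = model, rules = rules),
            class = "cross_result")
}

#' @export
print.cross_result <- function(x, digits = 4, ...) {
  cat(sprintf("<cross_result>  %s  x  %s\n",
              format_genotype(x$mother), format_genotype(x$father)))
  df <- x$classes
  flag <- ifelse(df$lethal, "lethal",
                 ifelse(df$carries_minute_allele & !df$minute_phenotype &
                          df$viability > 0, "diagnostic", ""))
  tab <- data.frame(class = df$class,
                    raw = round(df$frequency_raw, digits),
                    adjusted = round(df$frequency_adjusted, digits),
                    phenotypes = ifelse(nzchar(df$phenotypes),
                                        df$phenotypes, "-"),
                    note = flag)
  print(tab, row.names = FALSE, right = FALSE)
  invisible(x)
}

#' Detect the trisomy signature of a cross
#'
#' A parent from a trisomic stock crossed to the haploinsufficient tester
#' (`RpS3A[57g]`) produces viable progeny that carry the tester lesion yet are
#' *not* Minute — they received two chromosome-4 copies from the trisomic
#' parent. Disomic parents cannot produce this class (absent
#' nondisjunction), so its presence is diagnostic of parental trisomy.
#'
#' @param result A [cross()] result in which at least one parent carries a
#'   non-functional allele or deletion at a haploinsufficient locus.
#' @return List with `detected` (logical) and `classes` (data frame of the
#'   diagnostic viable, tester-bearing, non-Minute classes).
#' @export
detect_trisomy_signature <- function(result) {
  stopifnot(inherits(result, "cross_result"))
  has_tester <- vapply(list(result$mother, result$father),
                       carries_minute_lesion, TRUE, rules = result$rules)
  if (!any(has_tester))
    stop("neither parent carries a haploinsufficient tester allele; ",
         "the trisomy signature is undefined for this cross")
  df <- result$classes
  diag <- df$viability > 0 & df$carries_minute_allele & !df$minute_phenotype
  list(detected = any(diag), classes = df[diag, , drop = FALSE])
}

#' Select disomic founder classes carrying a target chromosome
#'
#' The disomic, Minute progeny carrying the chromosome of interest are the
#' ones to cross to balancer-bearing flies when founding a new disomic
#' stock. Returns those classes sorted by adjusted frequency (largest
#' first).
#'
#' @param result A [cross()] result.
#' @param target_label Label of a chromosome copy present in a parent
#'   (e.g. `"Df(4)ED6382, P{3'.RS5+3.3'}ED6382"`).
#' @return Data frame of viable, disomic, Minute, target-bearing classes.
#' @export
select_disomic_founders <- function(result, target_label) {
  stopifnot(inherits(result, "cross_result"))
  parent_labels <- unique(c(copy_labels(result$mother),
                            copy_labels(result$father)))
  if (!target_label %in% parent_labels)
    stop("target label '", target_label,
         "' is not carried by either parent")
  df <- result$classes
  carries <- vapply(result$karyotypes[df$class], function(k)
    target_label %in% copy_labels(k), TRUE)
  sel <- df$disomic & df$minute_phenotype & df$viability > 0 & carries
  out <- df[sel, , drop = FALSE]
  out <- out[order(-out$frequency_adjusted, out$class), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Write the progeny-class table of a cross as TSV
#'
#' @param result A [cross()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cross_tsv <- function(result, path) {
  utils::write.table(result$classes, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Monte-Carlo mating simulation (stochastic counterpart of [cross()])
#'
#' Samples gametes from each parent, forms zygotes, and accepts each with
#' probability equal to its viability weight. Used as an independent check
#' of the exact enumeration and for teaching-scale experiments.
#'
#' @inheritParams cross
#' @param n Number of zygotes to simulate.
#' @param seed Optional integer seed (RNG state restored afterwards).
#' @return List with `counts` (named integer vector of accepted progeny per
#'   class key), `n_zygotes`, `n_accepted`.
#' @export
simulate_mating <- function(mother, father, model = segregation_model(),
                            rules = default_rules(), n = 10000,
                            seed = NULL) {
  mdist <- gamete_distribution(mother, model)
  fdist <- gamete_distribution(father, model)
  with_seed(seed, {
    mg <- sample_gametes(mdist, n)
    fg <- sample_gametes(fdist, n)
    # zygote key and viability looked up per unique gamete-key pair
    pair <- paste(mg, fg, sep = "\r")
    upair <- unique(pair)
    zkey <- character(length(upair))
    zvia <- numeric(length(upair))
    for (i in seq_along(upair)) {
      gk <- strsplit(upair[i], "\r", fixed = TRUE)[[1]]
      kar <- karyotype(c(mdist$copies[[gk[1]]], fdist$copies[[gk[2]]]))
      zkey[i] <- karyotype_key(kar)
      zvia[i] <- classify_phenotype(kar, rules)$viability
    }
    idx <- match(pair, upair)
    keep <- stats::runif(n) < zvia[idx]
    counts <- table(zkey[idx][keep])
    list(counts = stats::setNames(as.integer(counts), names(counts)),
         n_zygotes = n, n_accepted = sum(keep))
  })
}
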