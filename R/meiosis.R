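# Meiosis-I segregation of chromosome 4. Trisomic parents form one paired
# bivalent plus an unpaired univalent in three ways; the bivalent partners
# segregate from each other and the univalent joins either pole, so six
# segregation patterns produce six gamete classes, each from exactly two
# patterns. Chromosome 4 is achiasmate: no recombination anywhere.

#' Segregation model for chromosome-4 meiosis
#'
#' Parameterizes pairing and segregation in trisomic meiosis plus spontaneous
#' nondisjunction in disomic meiosis. For a trisomic parent whose copies are
#' sorted by label as (1, 2, 3), the three bivalent|univalent configurations
#' are, in canonical order, `1-2|3`, `1-3|2`, `2-3|1`; `pairing_weights[i]`
#' is the probability of configuration i, and `univalent_bias[i]` the
#' probability that the univalent segregates with the *first* (label-sorted)
#' bivalent partner of configuration i. The uniform defaults give random
#' pairing and segregation; Sturtevant-style preferential pairing and
#' directed univalent segregation are expressed by moving these away from
#' (1/3, 1/3, 1/3) and 0.5.
#'
#' @param pairing_weights Numeric length 3, non-negative, summing to 1
#'   (tolerance 1e-12).
#' @param univalent_bias Numeric in `[0,1]`, length 1 (recycled) or 3.
#' @param nondisjunction_rate Probability per disomic meiosis that the two
#'   homologs fail to separate (default 0.002, i.e. 1 in 500), split evenly
#'   between diplo and nullo gametes.
#' @param transmission_weights Optional named numeric in `(0,1]`, one entry
#'   per gamete-class key, applied multiplicatively to gamete frequencies and
#'   renormalized (meiotic drive / gamete competition). This is the only
#'   mechanism in the model that can break the half-disomic law.
#' @return An object of class `"segregation_model"`.
#' @examples
#' segregation_model()                                  # random model
#' segregation_model(pairing_weights = c(1, 0, 0))     # obligate 1-2 pairing
#' @export
segregation_model <- function(pairing_weights = rep(1 / 3, 3),
                              univalent_bias = 0.5,
                              nondisjunction_rate = 0.002,
                              transmission_weights = NULL) {
  pairing_weights <- as.numeric(pairing_weights)
  if (length(pairing_weights) != 3L || any(pairing_weights < 0) ||
      abs(sum(pairing_weights) - 1) > 1e-12)
    stop("pairing_weights must be 3 non-negative values summing to 1")
  univalent_bias <- rep_len(as.numeric(univalent_bias), 3L)
  if (any(univalent_bias < 0 | univalent_bias > 1))
    stop("univalent_bias must lie in [0, 1]")
  if (length(nondisjunction_rate) != 1L || nondisjunction_rate < 0 ||
      nondisjunction_rate >= 1)
    stop("nondisjunction_rate must lie in [0, 1)")
  if (!is.null(transmission_weights)) {
    if (is.null(names(transmission_weights)) ||
        any(transmission_weights <= 0 | transmission_weights > 1))
      stop("transmission_weights must be named and lie in (0, 1]")
  }
  structure(list(pairing_weights = pairing_weights,
                 univalent_bias = univalent_bias,
                 nondisjunction_rate = nondisjunction_rate,
                 transmission_weights = transmission_weights),
            class = "segregation_model")
}

#' @export
print.segregation_model <- function(x, ...) {
  cat("<segregation_model>\n")
  cat(sprintf("  pairing weights   : %s\n",
              paste(signif(x$pairing_weights, 4), collapse = ", ")))
  cat(sprintf("  univalent bias    : %s\n",
              paste(signif(x$univalent_bias, 4), collapse = ", ")))
  cat(sprintf("  nondisjunction d  : %g\n", x$nondisjunction_rate))
  if (!is.null(x$transmission_weights))
    cat(sprintf("  transmission wts  : %s\n",
                paste(names(x$transmission_weights),
                      signif(x$transmission_weights, 4),
                      sep = "=", collapse = ", ")))
  invisible(x)
}

NULLO_KEY <- "(nullo)"

gamete_key <- function(labels) {
  if (!length(labels)) NULLO_KEY else paste(sort(labels), collapse = " + ")
}

new_gamete_distribution <- function(prob, copies) {
  keep <- prob > 0
  prob <- prob[keep]
  copies <- copies[names(prob)]
  if (any(prob < 0) || abs(sum(prob) - 1) > 1e-12)
    stop("gamete-class probabilities must be non-negative and sum to 1")
  structure(list(prob = prob, copies = copies),
            class = "gamete_distribution")
}

apply_transmission <- function(prob, weights) {
  if (is.null(weights)) return(prob)
  w <- weights[names(prob)]
  w[is.na(w)] <- 1
  prob <- prob * w
  prob / sum(prob)
}

#' @export
print.gamete_distribution <- function(x, digits = 4, ...) {
  cat("<gamete_distribution>\n")
  for (k in names(x$prob))
    cat(sprintf("  %-28s %.*f\n", k, digits, x$prob[[k]]))
  invisible(x)
}

#' @export
as.data.frame.gamete_distribution <- function(x, ...) {
  data.frame(class = names(x$prob), probability = unname(x$prob),
             n_copies = vapply(x$copies, length, 0L),
             stringsAsFactors = FALSE, row.names = NULL)
}

sorted_copies <- function(kar) {
  kar$chr4[order(copy_labels(kar), method = "radix")]
}

#' Enumerate bivalent + univalent pairing configurations of a trisomic
#'
#' The three chromosomes of a trisomic can pair into one bivalent plus one
#' univalent in exactly three ways. Configurations are enumerated over the
#' label-sorted copies in the canonical order `1-2|3`, `1-3|2`, `2-3|1`
#' (the order in which [segregation_model()] pairing weights apply), even
#' when copies share a label.
#'
#' @param kar A trisomic [karyotype()] (exactly 3 chromosome-4 copies).
#' @return A list of 3 configurations, each
#'   `list(bivalent = <2 copies>, univalent = <1 copy>, label = "X-Y | Z")`.
#' @export
enumerate_pairing_configs <- function(kar) {
  stopifnot(inherits(kar, "karyotype"))
  if (length(kar$chr4) != 3L)
    stop("pairing configurations are defined for trisomic karyotypes only ",
         "(got ", length(kar$chr4), " copies)")
  cp <- sorted_copies(kar)
  idx <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 3L, 1L))
  lapply(idx, function(i) {
    biv <- cp[i[1:2]]
    uni <- cp[[i[3]]]
    list(bivalent = biv, univalent = uni,
         label = sprintf("%s-%s | %s", biv[[1]]$label, biv[[2]]$label,
                         uni$label))
  })
}

#' Enumerate the six segregation patterns of a trisomic
#'
#' Each pairing configuration yields two patterns: the bivalent partners go
#' to opposite poles and the univalent joins either one, giving a disomic
#' pole (2-set) and a monosomic pole (1-set). Across the six patterns every
#' gamete class is produced by exactly two patterns.
#'
#' @param kar A trisomic [karyotype()].
#' @return A data frame with one row per pattern: `config` (1-3),
#'   `direction` (`"with_first"`/`"with_second"` bivalent partner),
#'   `disomic_class` and `monosomic_class` (gamete-class keys).
#' @export
enumerate_segregation_patterns <- function(kar) {
  cfgs <- enumerate_pairing_configs(kar)
  rows <- lapply(seq_along(cfgs), function(i) {
    cf <- cfgs[[i]]
    bl <- vapply(cf$bivalent, `[[`, "", "label")
    ul <- cf$univalent$label
    data.frame(
      config = i,
      direction = c("with_first", "with_second"),
      disomic_class = c(gamete_key(c(bl[1], ul)), gamete_key(c(bl[2], ul))),
      monosomic_class = c(gamete_key(bl[2]), gamete_key(bl[1])),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Exact gamete distribution of a trisomic parent
#'
#' Configuration i (bivalent X-Y, univalent Z, weight p_i, bias u_i)
#' produces pattern `{X,Z} | {Y}` with probability `p_i * u_i` and pattern
#' `{Y,Z} | {X}` with `p_i * (1 - u_i)`; each pattern sends half its mass to
#' each pole's gamete class. Transmission weights, if any, are applied
#' multiplicatively and the distribution renormalized. Under the uniform
#' model all six classes occur at 1/6, and for any pairing/bias values with
#' unit transmission weights exactly half the gametes are disomic.
#'
#' @param kar A trisomic [karyotype()].
#' @param model A [segregation_model()].
#' @return A `"gamete_distribution"` object (probabilities plus the
#'   chromosome copies behind each class key).
#' @examples
#' tri <- karyotype(list(chromosome_copy("A"), chromosome_copy("B"),
#'                       chromosome_copy("C")))
#' gamete_distribution_trisomic(tri, segregation_model())
#' @export
gamete_distribution_trisomic <- function(kar, model) {
  stopifnot(inherits(model, "segregation_model"))
  cfgs <- enumerate_pairing_configs(kar)
  prob <- numeric()
  copies <- list()
  add <- function(cps, p) {
    k <- gamete_key(vapply(cps, `[[`, "", "label"))
    if (is.null(copies[[k]])) {
      copies[[k]] <<- cps
      prob[k] <<- 0
    }
    prob[k] <<- prob[k] + p
  }
  u <- model$univalent_bias
  for (i in seq_along(cfgs)) {
    cf <- cfgs[[i]]
    p <- model$pairing_weights[i]
    x <- cf$bivalent[[1]]; y <- cf$bivalent[[2]]; z <- cf$univalent
    add(list(x, z), p * u[i] / 2)       # {X,Z} pole
    add(list(y),    p * u[i] / 2)       # opposite {Y} pole
    add(list(y, z), p * (1 - u[i]) / 2) # {Y,Z} pole
    add(list(x),    p * (1 - u[i]) / 2) # opposite {X} pole
  }
  prob <- apply_transmission(prob, model$transmission_weights)
  new_gamete_distribution(prob, copies)
}

#' Exact gamete distribution of a disomic parent
#'
#' With copies A and B and nondisjunction rate d: `P(A) = P(B) = (1 - d)/2`,
#' `P(AB) = d/2`, `P(nullo) = d/2`.
#'
#' @inheritParams gamete_distribution_trisomic
#' @param kar A disomic [karyotype()].
#' @return A `"gamete_distribution"` object.
#' @export
gamete_distribution_disomic <- function(kar, model) {
  stopifnot(inherits(kar, "karyotype"), inherits(model, "segregation_model"))
  if (length(kar$chr4) != 2L)
    stop("disomic gamete distribution requires exactly 2 chromosome-4 ",
         "copies (got ", length(kar$chr4), ")")
  cp <- sorted_copies(kar)
  d <- model$nondisjunction_rate
  prob <- numeric()
  copies <- list()
  add <- function(cps, p) {
    k <- gamete_key(vapply(cps, `[[`, "", "label"))
    if (is.null(copies[[k]])) {
      copies[[k]] <<- cps
      prob[k] <<- 0
    }
    prob[k] <<- prob[k] + p
  }
  add(cp[1], (1 - d) / 2)
  add(cp[2], (1 - d) / 2)
  add(cp, d / 2)
  add(list(), d / 2)
  prob <- apply_transmission(prob, model$transmission_weights)
  new_gamete_distribution(prob, copies)
}

#' Exact gamete distribution of a monosomic parent
#'
#' The single chromosome is a univalent free to join either pole, so half
#' the gametes carry it and half are nullosomic.
#'
#' @inheritParams gamete_distribution_trisomic
#' @param kar A monosomic [karyotype()].
#' @return A `"gamete_distribution"` object.
#' @export
gamete_distribution_monosomic <- function(kar, model) {
  stopifnot(inherits(kar, "karyotype"), inherits(model, "segregation_model"))
  if (length(kar$chr4) != 1L)
    stop("monosomic gamete distribution requires exactly 1 chromosome-4 copy")
  cp <- kar$chr4[[1]]
  prob <- c(0.5, 0.5)
  names(prob) <- c(gamete_key(cp$label), NULLO_KEY)
  copies <- list(list(cp), list())
  names(copies) <- names(prob)
  prob <- apply_transmission(prob, model$transmission_weights)
  new_gamete_distribution(prob, copies)
}

#' Gamete distribution of a parent (dispatch on copy number)
#'
#' @param kar A [karyotype()] with 1-3 chromosome-4 copies.
#' @param model A [segregation_model()].
#' @return A `"gamete_distribution"` object.
#' @export
gamete_distribution <- function(kar, model = segregation_model()) {
  stopifnot(inherits(kar, "karyotype"))
  switch(as.character(length(kar$chr4)),
         "1" = gamete_distribution_monosomic(kar, model),
         "2" = gamete_distribution_disomic(kar, model),
         "3" = gamete_distribution_trisomic(kar, model),
         stop("gametes are modeled for parents with 1-3 chromosome-4 ",
              "copies (got ", length(kar$chr4), ")"))
}

#' Sample gametes from a distribution
#'
#' @param dist A `"gamete_distribution"`.
#' @param n Number of gametes to draw.
#' @param seed Optional integer; when given, sampling is reproducible and
#'   the caller's RNG state is left untouched.
#' @return Character vector of length `n` of gamete-class keys (the copies
#'   behind each key are in `dist$copies`).
#' @export
sample_gametes <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "gamete_distribution"), n >= 0)
  if (n == 0) return(character())
  with_seed(seed, sample(names(dist$prob), n, replace = TRUE,
                         prob = unname(dist$prob)))
}

#' Write a gamete distribution as TSV
#'
#' Columns: `class`, `probability`, `n_copies`.
#'
#' @param dist A `"gamete_distribution"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_distribution_tsv <- function(dist, path) {
  utils::write.table(as.data.frame(dist), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# evaluate `code` under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else suppressWarnings(rm(".Random.seed", envir = env))
  }, add = TRUE)
  set.seed(seed)
  force(code)
}
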