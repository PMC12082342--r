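# Shared fixtures: rule sets, karyotypes, and independent oracles.

neutral_rules <- function() default_rules(minute_viability = 1)

wt_copy <- function(label) chromosome_copy(label)

tester_copy <- function(label = "RpS3A[57g]")
  chromosome_copy(label, alleles = list(allele("RpS3A", functional = FALSE)))

abc_trisomic <- function(labels = c("A", "B", "C"))
  karyotype(lapply(labels, wt_copy))

# parents for the published example crosses (figure-style tester crosses)
fig_disomic_parent <- function(rules)
  parse_genotype(paste0("w[1118] ; Df(4)ED6382, P{3'.RS5+3.3'}ED6382",
                        " / P{ActGFP}unc-13[GJ]"), rules)

fig_trisomic_parent <- function(rules) stock_karyotype("Kyoto_150531", rules)

tester_parent <- function(rules) stock_karyotype("BDSC_1229", rules)

df_label <- "Df(4)ED6382, P{3'.RS5+3.3'}ED6382"

no_nd <- function(...) segregation_model(..., nondisjunction_rate = 0)

# Brute-force oracle for the trisomic gamete distribution: enumerate every
# (configuration x univalent direction x pole) outcome as a weighted row and
# aggregate. Independent of the package's accumulation code path.
oracle_trisomic_dist <- function(labels, pairing, u) {
  labs <- sort(labels)
  u <- rep_len(u, 3)
  cfg <- list(c(1, 2, 3), c(1, 3, 2), c(2, 3, 1))
  rows <- list()
  for (i in 1:3) {
    X <- labs[cfg[[i]][1]]; Y <- labs[cfg[[i]][2]]; Z <- labs[cfg[[i]][3]]
    # direction 1: univalent with X; direction 2: with Y; pole picked 50:50
    rows[[length(rows) + 1]] <- list(g = c(X, Z), w = pairing[i] * u[i] / 2)
    rows[[length(rows) + 1]] <- list(g = Y,       w = pairing[i] * u[i] / 2)
    rows[[length(rows) + 1]] <- list(g = c(Y, Z),
                                     w = pairing[i] * (1 - u[i]) / 2)
    rows[[length(rows) + 1]] <- list(g = X,
                                     w = pairing[i] * (1 - u[i]) / 2)
  }
  keys <- vapply(rows, function(r) paste(sort(r$g), collapse = " + "), "")
  w <- vapply(rows, `[[`, 0, "w")
  out <- tapply(w, keys, sum)
  out <- stats::setNames(as.numeric(out), names(out))
  out <- out[out > 0]
  out[order(names(out))]
}

dist_as_vector <- function(dist) {
  p <- dist$prob[order(names(dist$prob))]
  p
}

disomic_mass <- function(dist)
  sum(dist$prob[vapply(dist$copies, length, 0L) == 2L])
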