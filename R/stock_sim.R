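# Forward-time simulation of a closed laboratory stock. Non-overlapping
# generations, fixed census size N with an enforced (near-)even sex ratio,
# random mating, meiosis through the segregation model (including
# spontaneous nondisjunction), and viability selection on zygotes.
#
# Each offspring draws its mother and father independently from the
# fecundity-weighted parental frequency distributions, so the per-generation
# offspring distribution is the exact mixture of viability-weighted cross
# distributions over parental karyotype pairs; N offspring per sex stratum
# are then resampled multinomially. This is equivalent to per-individual
# Wright-Fisher sampling with viability rejection but runs in time
# proportional to the number of distinct karyotype classes.

#' Population state of a stock
#'
#' @param females,males Named integer vectors of individual counts keyed by
#'   [karyotype_key()].
#' @param karyotypes Named list of [karyotype()] objects covering every key.
#' @param generation Generation index (0 = founding).
#' @param extinct Logical terminal flag (no viable offspring possible).
#' @return An object of class `"population_state"`.
#' @export
population_state <- function(females, males, karyotypes, generation = 0L,
                             extinct = FALSE) {
  keys <- union(names(females), names(males))
  if (!all(keys %in% names(karyotypes)))
    stop("every population key must have a karyotype entry")
  structure(list(females = females, males = males,
                 karyotypes = karyotypes,
                 generation = as.integer(generation),
                 extinct = isTRUE(extinct)),
            class = "population_state")
}

#' Found a population from a list of karyotypes
#'
#' Both sexes receive the same composition; counts are assigned by largest
#' remainder so the census size is met exactly.
#'
#' @param founders List of [karyotype()] objects.
#' @param N Census size (>= 2; split `ceiling(N/2)` females, rest males).
#' @param prop Founder proportions (default equal).
#' @return A `"population_state"` at generation 0.
#' @export
init_population <- function(founders, N, prop = NULL) {
  stopifnot(is.list(founders), length(founders) >= 1L, N >= 2)
  if (is.null(prop)) prop <- rep(1, length(founders))
  stopifnot(length(prop) == length(founders), all(prop >= 0), sum(prop) > 0)
  prop <- prop / sum(prop)
  keys <- vapply(founders, karyotype_key, "")
  kars <- stats::setNames(founders, keys)
  alloc <- function(n) {
    x <- floor(prop * n)
    rem <- n - sum(x)
    if (rem > 0) {
      extra <- order(prop * n - x, decreasing = TRUE)[seq_len(rem)]
      x[extra] <- x[extra] + 1L
    }
    stats::setNames(as.integer(x), keys)
  }
  nf <- ceiling(N / 2)
  population_state(alloc(nf), alloc(N - nf), kars)
}

#' Simulation configuration
#'
#' @param N Census size per generation (>= 2).
#' @param generations Number of generations to advance (>= 1).
#' @param seed Integer seed for the whole simulation.
#' @param model A [segregation_model()].
#' @param rules A [phenotype_rules()].
#' @param replicates Number of independent replicate stocks.
#' @param fecundity Optional named numeric parent-sampling weights keyed by
#'   karyotype key (default 1 everywhere); models reduced fertility, e.g.
#'   of Minute parents.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(N, generations, seed = 1L,
                       model = segregation_model(),
                       rules = default_rules(),
                       replicates = 1L, fecundity = NULL) {
  stopifnot(N >= 2, generations >= 1, replicates >= 1)
  structure(list(N = as.integer(N), generations = as.integer(generations),
                 seed = as.integer(seed), model = model, rules = rules,
                 replicates = as.integer(replicates),
                 fecundity = fecundity),
            class = "sim_config")
}

# viability-weighted zygote distribution of one parent pair, cached
pair_offspring <- function(mkey, fkey, state, config, cache) {
  id <- paste(mkey, fkey, sep = "\r")
  hit <- cache$pairs[[id]]
  if (!is.null(hit)) return(hit)
  mdist <- cache$gametes[[mkey]]
  if (is.null(mdist))
    mdist <- cache$gametes[[mkey]] <-
      gamete_distribution(state$karyotypes[[mkey]], config$model)
  fdist <- cache$gametes[[fkey]]
  if (is.null(fdist))
    fdist <- cache$gametes[[fkey]] <-
      gamete_distribution(state$karyotypes[[fkey]], config$model)
  out <- combine_gamete_distributions(mdist, fdist, config$rules)
  mass <- out$classes$frequency_raw * out$classes$viability
  names(mass) <- out$classes$class
  for (k in names(out$karyotypes))
    if (is.null(cache$kars[[k]])) cache$kars[[k]] <- out$karyotypes[[k]]
  cache$pairs[[id]] <- mass[mass > 0]
  cache$pairs[[id]]
}

parent_probs <- function(counts, fecundity) {
  w <- as.numeric(counts)
  if (!is.null(fecundity)) {
    f <- fecundity[names(counts)]
    f[is.na(f)] <- 1
    w <- w * f
  }
  if (sum(w) <= 0) return(NULL)
  stats::setNames(w / sum(w), names(counts))
}

#' Advance a population by one generation
#'
#' Samples N offspring (stratified by sex into `ceiling(N/2)` females and
#' the rest males) from the exact viability-weighted offspring distribution
#' implied by random mating among the current parents. If no viable
#' offspring are possible the state is returned flagged `extinct` rather
#' than raising an error.
#'
#' @param state A `"population_state"`.
#' @param config A [sim_config()].
#' @param cache Optional environment reused across calls to memoize gamete
#'   and cross distributions.
#' @return The next `"population_state"`.
#' @export
advance_generation <- function(state, config, cache = NULL) {
  stopifnot(inherits(state, "population_state"),
            inherits(config, "sim_config"))
  if (state$extinct) return(state)
  if (is.null(cache)) {
    cache <- new.env(parent = emptyenv())
    cache$pairs <- list(); cache$gametes <- list(); cache$kars <- list()
  }
  pm <- parent_probs(state$females, config$fecundity)
  pf <- parent_probs(state$males, config$fecundity)
  if (is.null(pm) || is.null(pf))
    return(population_state(state$females[0], state$males[0],
                            state$karyotypes, state$generation + 1L,
                            extinct = TRUE))
  dist <- numeric()
  for (mkey in names(pm)[pm > 0]) {
    for (fkey in names(pf)[pf > 0]) {
      mass <- pair_offspring(mkey, fkey, state, config, cache)
      if (!length(mass)) next
      w <- pm[[mkey]] * pf[[fkey]]
      for (k in names(mass)) dist[k] <- (if (is.na(dist[k])) 0
                                         else dist[k]) + w * mass[[k]]
    }
  }
  dist <- dist[!is.na(dist) & dist > 0]
  if (!length(dist) || sum(dist) <= 0)
    return(population_state(state$females[0], state$males[0],
                            state$karyotypes, state$generation + 1L,
                            extinct = TRUE))
  p <- dist / sum(dist)
  nf <- as.integer(ceiling(config$N / 2))
  nm <- config$N - nf
  draw <- function(n) stats::setNames(
    as.integer(stats::rmultinom(1, n, p)), names(p))
  kars <- state$karyotypes
  for (k in names(p)) if (is.null(kars[[k]])) kars[[k]] <- cache$kars[[k]]
  population_state(draw(nf), draw(nm), kars, state$generation + 1L)
}

state_frequencies <- function(state) {
  keys <- union(names(state$females), names(state$males))
  n <- vapply(keys, function(k)
    sum(state$females[k], state$males[k], na.rm = TRUE), 0)
  tot <- sum(n)
  if (tot == 0) return(stats::setNames(numeric(0), character(0)))
  n / tot
}

#' Trisomic (triplo-4) frequency of a population state
#'
#' @param state A `"population_state"`.
#' @return Fraction of individuals carrying three chromosome-4 copies
#'   (0 for an extinct population).
#' @export
trisomic_frequency <- function(state) {
  fr <- state_frequencies(state)
  if (!length(fr)) return(0)
  tri <- vapply(names(fr), function(k)
    length(state$karyotypes[[k]]$chr4) == 3L, TRUE)
  sum(fr[tri])
}

#' Simulate a stock forward in time
#'
#' Runs `config$replicates` independent replicates of
#' [advance_generation()] for `config$generations` generations from the
#' same initial state, all driven by `config$seed`.
#'
#' @param init Initial `"population_state"` (see [init_population()]).
#' @param config A [sim_config()].
#' @return An object of class `"stock_sim"`: `summary` (data frame
#'   generation x class with mean and sd of frequencies across replicates),
#'   `trisomic` (replicates x (generations+1) matrix of triplo-4
#'   frequencies), `extinct` (logical per replicate), and `config`.
#' @export
simulate_stock <- function(init, config) {
  stopifnot(inherits(init, "population_state"),
            inherits(config, "sim_config"))
  G <- config$generations
  R <- config$replicates
  with_seed(config$seed, {
    cache <- new.env(parent = emptyenv())
    cache$pairs <- list(); cache$gametes <- list(); cache$kars <- list()
    tri <- matrix(0, nrow = R, ncol = G + 1L)
    extinct <- logical(R)
    freq_acc <- list()  # per-generation list of per-replicate freq vectors
    record <- function(gen, rep, fr) {
      g <- as.character(gen)
      if (is.null(freq_acc[[g]])) freq_acc[[g]] <<- list()
      freq_acc[[g]][[rep]] <<- fr
    }
    for (r in seq_len(R)) {
      state <- init
      tri[r, 1L] <- trisomic_frequency(state)
      record(0L, r, state_frequencies(state))
      for (g in seq_len(G)) {
        state <- advance_generation(state, config, cache)
        tri[r, g + 1L] <- trisomic_frequency(state)
        record(g, r, state_frequencies(state))
      }
      extinct[r] <- state$extinct
    }
    rows <- lapply(names(freq_acc), function(g) {
      frs <- freq_acc[[g]]
      keys <- unique(unlist(lapply(frs, names)))
      if (!length(keys)) return(NULL)
      m <- vapply(frs, function(fr) {
        v <- fr[keys]; v[is.na(v)] <- 0; v
      }, numeric(length(keys)))
      m <- matrix(m, nrow = length(keys))
      data.frame(generation = as.integer(g), class = keys,
                 mean = rowMeans(m),
                 sd = apply(m, 1, stats::sd),
                 stringsAsFactors = FALSE)
    })
    summary <- do.call(rbind, rows)
    summary <- summary[order(summary$generation, -summary$mean), ]
    row.names(summary) <- NULL
    structure(list(summary = summary, trisomic = tri, extinct = extinct,
                   config = config),
              class = "stock_sim")
  })
}

#' @export
print.stock_sim <- function(x, ...) {
  G <- ncol(x$trisomic) - 1L
  cat(sprintf("<stock_sim> N=%d, %d generations, %d replicate(s)\n",
              x$config$N, G, nrow(x$trisomic)))
  cat(sprintf("  triplo-4 frequency: start %.3f -> end %.3f (mean)\n",
              mean(x$trisomic[, 1]), mean(x$trisomic[, G + 1L])))
  if (any(x$extinct))
    cat(sprintf("  %d replicate(s) went extinct\n", sum(x$extinct)))
  invisible(x)
}

#' Probability that trisomy invades a stock
#'
#' Fraction of replicate stocks in which the triplo-4 frequency reaches a
#' threshold within a time horizon, with a normal-approximation Monte-Carlo
#' confidence interval.
#'
#' @param init Initial `"population_state"`.
#' @param config A [sim_config()] (its `replicates` sets the Monte-Carlo
#'   sample size; fewer than 10 triggers a warning).
#' @param horizon Number of generations scanned (default all simulated).
#' @param threshold Triplo-4 frequency defining "invaded" (default 0.5).
#' @param conf Confidence level for the interval.
#' @return List with `estimate`, `se`, `ci` (length 2), `replicates`.
#' @export
trisomy_invasion_probability <- function(init, config,
                                         horizon = config$generations,
                                         threshold = 0.5, conf = 0.95) {
  stopifnot(horizon >= 1, horizon <= config$generations,
            threshold > 0, threshold <= 1)
  if (config$replicates < 10)
    warning("fewer than 10 replicates: the invasion-probability estimate ",
            "will be unstable")
  sim <- simulate_stock(init, config)
  hit <- apply(sim$trisomic[, seq_len(horizon + 1L), drop = FALSE], 1,
               function(tr) any(tr >= threshold))
  p <- mean(hit)
  se <- sqrt(p * (1 - p) / length(hit))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(estimate = p, se = se,
       ci = c(max(0, p - z * se), min(1, p + z * se)),
       replicates = length(hit))
}
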