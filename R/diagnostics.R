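# Experimental-design math: power of the tester cross to reveal a trisomic
# parent, success probability of the blind disomic-founder scheme, and
# maximum-likelihood estimation of pairing/segregation-bias parameters from
# observed progeny-class counts.

#' Power to detect a trisomic parent with the tester cross
#'
#' Scoring `n` progeny of a suspect parent crossed to the haploinsufficient
#' tester, the parent is revealed as trisomic by the first viable,
#' tester-bearing, non-Minute offspring. Progeny are treated as i.i.d.
#' draws from the viability-adjusted class distribution, so the power is
#' `1 - (1 - q)^n` with `q` the summed adjusted frequency of the diagnostic
#' classes.
#'
#' @param n_progeny Number of progeny scored (vectorized, >= 0).
#' @param mother,father Parent [karyotype()]s; exactly the cross to be
#'   scored, with the tester allele in one parent.
#' @param model A [segregation_model()].
#' @param rules A [phenotype_rules()].
#' @return Numeric vector of detection probabilities.
#' @examples
#' rules <- default_rules(minute_viability = 1)
#' tri <- stock_karyotype("Kyoto_150531", rules)   # trisomic deletion stock
#' tester <- stock_karyotype("BDSC_1229", rules)   # RpS3A[57g]/balancer
#' trisomy_detection_power(10, tri, tester,
#'                         segregation_model(nondisjunction_rate = 0), rules)
#' @export
trisomy_detection_power <- function(n_progeny, mother, father,
                                    model = segregation_model(),
                                    rules = default_rules()) {
  stopifnot(all(n_progeny >= 0))
  res <- cross(mother, father, model, rules)
  sig <- detect_trisomy_signature(res)
  q <- sum(sig$classes$frequency_adjusted)
  1 - (1 - q)^n_progeny
}

#' Success probability of the blind brute-force scheme
#'
#' Setting up `k` independent lines, each founded by one blindly chosen
#' candidate that is disomic with probability `p`, at least one line has a
#' disomic founder with probability `1 - (1 - p)^k`. With strong
#' preferential co-segregation of the target chromosome with its trisomic
#' partners, `p` approaches 0 and so does the success probability — every
#' line ends up trisomic.
#'
#' @param k_lines Number of lines established (vectorized, >= 0).
#' @param founder_disomic_prob Probability `p` in `[0,1]` that a single
#'   founder candidate is disomic; compute it from a cross with
#'   [founder_disomic_prob()].
#' @return Numeric vector of success probabilities.
#' @export
blind_scheme_success_probability <- function(k_lines, founder_disomic_prob) {
  stopifnot(all(k_lines >= 0),
            length(founder_disomic_prob) == 1L,
            founder_disomic_prob >= 0, founder_disomic_prob <= 1)
  1 - (1 - founder_disomic_prob)^k_lines
}

#' Fraction of target-bearing founder candidates that are disomic
#'
#' Among viable progeny carrying the target chromosome (the candidates a
#' blind scheme would propagate), the conditional probability of being
#' disomic.
#'
#' @param result A [cross()] result.
#' @param target_label Label of a chromosome copy present in a parent.
#' @return Probability in `[0,1]`.
#' @export
founder_disomic_prob <- function(result, target_label) {
  stopifnot(inherits(result, "cross_result"))
  parent_labels <- unique(c(copy_labels(result$mother),
                            copy_labels(result$father)))
  if (!target_label %in% parent_labels)
    stop("target label '", target_label,
         "' is not carried by either parent")
  df <- result$classes
  carries <- vapply(result$karyotypes[df$class], function(k)
    target_label %in% copy_labels(k), TRUE)
  denom <- sum(df$frequency_adjusted[carries])
  if (denom <= 0) return(0)
  sum(df$frequency_adjusted[carries & df$disomic]) / denom
}

#' Simulate a progeny-count table from a cross
#'
#' Multinomial sample of scored (viable) progeny from the adjusted class
#' distribution; input format for [fit_segregation_params()].
#'
#' @inheritParams cross
#' @param n Number of progeny scored.
#' @param seed Optional integer seed.
#' @return Named integer vector keyed by progeny-class key.
#' @export
simulate_progeny_counts <- function(mother, father,
                                    model = segregation_model(),
                                    rules = default_rules(),
                                    n = 1000, seed = NULL) {
  res <- cross(mother, father, model, rules)
  df <- res$classes[res$classes$frequency_adjusted > 0, ]
  cnt <- with_seed(seed,
                   stats::rmultinom(1, n, df$frequency_adjusted)[, 1])
  stats::setNames(as.integer(cnt), df$class)
}

# predicted viability-adjusted class probabilities as a function of the
# trisomic parent's gamete distribution; precomputes the linear map once
make_class_predictor <- function(trisomic, other, other_first, model, rules) {
  tri_uniform <- gamete_distribution_trisomic(
    trisomic, segregation_model(rep(1 / 3, 3), 0.5,
                                model$nondisjunction_rate,
                                model$transmission_weights))
  gkeys <- names(tri_uniform$prob)
  odist <- gamete_distribution(other, model)
  combine <- function(tdist) {
    if (other_first) combine_gamete_distributions(odist, tdist, rules)
    else combine_gamete_distributions(tdist, odist, rules)
  }
  # column j of A: viability-weighted class masses from unit mass on gamete j
  cols <- lapply(gkeys, function(k) {
    unit <- structure(list(prob = stats::setNames(1, k),
                           copies = tri_uniform$copies[k]),
                      class = "gamete_distribution")
    out <- combine(unit)$classes
    stats::setNames(out$frequency_raw * out$viability, out$class)
  })
  ckeys <- unique(unlist(lapply(cols, names)))
  A <- vapply(cols, function(v) {
    x <- v[ckeys]; x[is.na(x)] <- 0; x
  }, numeric(length(ckeys)))
  A <- matrix(A, nrow = length(ckeys), dimnames = list(ckeys, gkeys))
  list(
    gamete_keys = gkeys, class_keys = ckeys,
    predict = function(pairing, bias) {
      m <- segregation_model(pairing, bias, model$nondisjunction_rate,
                             model$transmission_weights)
      g <- gamete_distribution_trisomic(trisomic, m)$prob
      gv <- stats::setNames(numeric(length(gkeys)), gkeys)
      gv[names(g)] <- g
      pr <- drop(A %*% gv)
      s <- sum(pr)
      if (s <= 0) return(pr)
      pr / s
    })
}

softmax3 <- function(a) {
  e <- exp(c(a, 0) - max(a, 0))
  e / sum(e)
}

#' Fit segregation parameters by maximum likelihood
#'
#' Estimates the pairing weights (and optionally the univalent biases) of a
#' trisomic parent from observed progeny-class counts of a specified cross,
#' under the multinomial likelihood of the viability-adjusted class
#' probabilities. Viability weights and the other parent's segregation are
#' held fixed. The simplex is reparameterized through a softmax (biases
#' through a logit) and optimized by BFGS from several seeded random
#' starts. By default the biases are fixed at 0.5 (`fix_bias = TRUE`): with
#' only six observable gamete classes the full six-parameter model is close
#' to non-identifiable, so freeing the biases is opt-in. Estimates on the
#' simplex boundary and flat likelihood directions are flagged.
#'
#' @param counts Named non-negative integer vector keyed by progeny-class
#'   key ([karyotype_key()] strings; see [read_counts()]).
#' @param mother,father Parent [karyotype()]s; exactly one must be trisomic.
#' @param model A [segregation_model()] supplying the fixed nondisjunction
#'   rate and transmission weights (its pairing/bias entries are ignored).
#' @param rules A [phenotype_rules()].
#' @param fix_bias Keep univalent biases at 0.5 (default) or fit them.
#' @param restarts Number of optimizer starts (first start is the uniform
#'   model).
#' @param seed Integer seed controlling the random restarts (and the
#'   bootstrap, if requested).
#' @param ci `"none"` or `"bootstrap"` (parametric bootstrap percentile
#'   intervals for the pairing weights).
#' @param bootstrap_reps Bootstrap replicates when `ci = "bootstrap"`.
#' @return An object of class `"segregation_fit"`: `pairing_weights`,
#'   `univalent_bias`, `model` (fitted [segregation_model()]), `logLik`,
#'   `boundary` (logical), `flat` (logical, near-singular Hessian),
#'   `convergence`, `n` (total count), and `ci` (matrix or `NULL`).
#' @export
fit_segregation_params <- function(counts, mother, father,
                                   model = segregation_model(),
                                   rules = default_rules(),
                                   fix_bias = TRUE, restarts = 10L,
                                   seed = 1L,
                                   ci = c("none", "bootstrap"),
                                   bootstrap_reps = 100L) {
  ci <- match.arg(ci)
  stopifnot(is.numeric(counts), !is.null(names(counts)),
            all(counts >= 0), sum(counts) >= 1)
  is_tri <- c(length(mother$chr4) == 3L, length(father$chr4) == 3L)
  if (sum(is_tri) != 1L)
    stop("exactly one parent must be trisomic to fit segregation parameters")
  trisomic <- if (is_tri[1]) mother else father
  other <- if (is_tri[1]) father else mother
  pred <- make_class_predictor(trisomic, other, other_first = !is_tri[1],
                               model, rules)
  unknown <- setdiff(names(counts), pred$class_keys)
  if (length(unknown))
    stop("count table keys not among the observable progeny classes: ",
         paste(unknown, collapse = ", "))
  y <- stats::setNames(numeric(length(pred$class_keys)), pred$class_keys)
  y[names(counts)] <- counts
  npar <- if (fix_bias) 2L else 5L
  unpack <- function(par) {
    list(pairing = softmax3(par[1:2]),
         bias = if (fix_bias) 0.5 else stats::plogis(par[3:5]))
  }
  nll <- function(par) {
    th <- unpack(par)
    p <- pred$predict(th$pairing, th$bias)
    -sum(y * log(pmax(p, 1e-12)))
  }
  fit_from <- function(start) {
    stats::optim(start, nll, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12))
  }
  best <- with_seed(seed, {
    starts <- c(list(numeric(npar)),
                lapply(seq_len(max(0L, restarts - 1L)),
                       function(i) stats::rnorm(npar, 0, 1.5)))
    fits <- lapply(starts, function(s)
      tryCatch(fit_from(s), error = function(e) NULL))
    fits <- Filter(Negate(is.null), fits)
    if (!length(fits)) stop("optimization failed from every start")
    fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
  })
  th <- unpack(best$par)
  boundary <- any(th$pairing < 0.01 | th$pairing > 0.99) ||
    (!fix_bias && any(th$bias < 0.01 | th$bias > 0.99))
  flat <- tryCatch({
    H <- stats::optimHess(best$par, nll)
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    any(!is.finite(ev)) || min(ev) < 1e-6 * max(abs(ev))
  }, error = function(e) TRUE)
  if (boundary)
    warning("segregation-parameter estimate lies on the simplex boundary")
  if (flat)
    warning("likelihood surface is flat along some parameter direction; ",
            "estimates may be non-identifiable")
  ci_mat <- NULL
  if (ci == "bootstrap") {
    phat <- pred$predict(th$pairing, th$bias)
    n_tot <- sum(y)
    draws <- with_seed(seed + 1L, {
      vapply(seq_len(bootstrap_reps), function(b) {
        yb <- stats::rmultinom(1, n_tot, phat)[, 1]
        names(yb) <- names(phat)
        nll_b <- function(par) {
          th_b <- unpack(par)
          p <- pred$predict(th_b$pairing, th_b$bias)
          -sum(yb * log(pmax(p, 1e-12)))
        }
        ob <- tryCatch(
          stats::optim(best$par, nll_b, method = "BFGS",
                       control = list(maxit = 500)),
          error = function(e) NULL)
        if (is.null(ob)) rep(NA_real_, 3) else unpack(ob$par)$pairing
      }, numeric(3))
    })
    qs <- apply(draws, 1, stats::quantile, probs = c(0.025, 0.975),
                na.rm = TRUE)
    ci_mat <- t(qs)
    dimnames(ci_mat) <- list(paste0("pairing", 1:3), c("2.5%", "97.5%"))
  }
  structure(list(
    pairing_weights = th$pairing,
    univalent_bias = rep_len(th$bias, 3L),
    model = segregation_model(th$pairing, th$bias,
                              model$nondisjunction_rate,
                              model$transmission_weights),
    logLik = -best$value, boundary = boundary, flat = flat,
    convergence = best$convergence, n = sum(y), ci = ci_mat,
    fix_bias = fix_bias), class = "segregation_fit")
}

#' @export
print.segregation_fit <- function(x, ...) {
  cat("<segregation_fit>\n")
  cat(sprintf("  pairing weights : %s\n",
              paste(sprintf("%.4f", x$pairing_weights), collapse = ", ")))
  cat(sprintf("  univalent bias  : %s%s\n",
              paste(sprintf("%.4f", x$univalent_bias), collapse = ", "),
              if (x$fix_bias) " (fixed)" else ""))
  cat(sprintf("  log-likelihood  : %.3f   (n = %d)\n", x$logLik, x$n))
  if (x$boundary) cat("  note: estimate on simplex boundary\n")
  if (x$flat) cat("  note: flat likelihood direction(s)\n")
  if (!is.null(x$ci)) {
    cat("  bootstrap 95% CI:\n")
    print(round(x$ci, 4))
  }
  invisible(x)
}

#' Grid-search segregation fit (reference oracle)
#'
#' Exhaustive search of the pairing-weight simplex on a fixed grid with
#' biases held at 0.5. Slower and coarser than
#' [fit_segregation_params()] but free of optimizer assumptions; intended
#' as an independent check.
#'
#' @inheritParams fit_segregation_params
#' @param step Grid step on the simplex (default 0.05).
#' @return List with `pairing_weights`, `logLik`.
#' @export
fit_segregation_grid <- function(counts, mother, father,
                                 model = segregation_model(),
                                 rules = default_rules(), step = 0.05) {
  is_tri <- c(length(mother$chr4) == 3L, length(father$chr4) == 3L)
  if (sum(is_tri) != 1L)
    stop("exactly one parent must be trisomic")
  trisomic <- if (is_tri[1]) mother else father
  other <- if (is_tri[1]) father else mother
  pred <- make_class_predictor(trisomic, other, other_first = !is_tri[1],
                               model, rules)
  y <- stats::setNames(numeric(length(pred$class_keys)), pred$class_keys)
  y[names(counts)] <- counts
  grid <- seq(0, 1, by = step)
  best <- list(ll = -Inf, p = NULL)
  for (p1 in grid) for (p2 in grid[grid <= 1 - p1 + 1e-9]) {
    p3 <- max(0, 1 - p1 - p2)
    pr <- pred$predict(c(p1, p2, p3) / sum(c(p1, p2, p3)), 0.5)
    ll <- sum(y * log(pmax(pr, 1e-12)))
    if (ll > best$ll) best <- list(ll = ll, p = c(p1, p2, p3))
  }
  list(pairing_weights = best$p / sum(best$p), logLik = best$ll)
}
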