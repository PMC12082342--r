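# Exact cross enumeration, diagnostic flags, and founder selection.

test_that("disomic x tester cross: four classes, all tester-bearing are Minute", {
  rules <- default_rules()
  res <- cross(fig_disomic_parent(rules), tester_parent(rules),
               no_nd(), rules)
  expect_equal(nrow(res$classes), 4L)
  expect_equal(res$classes$frequency_raw, rep(0.25, 4))
  expect_equal(sum(res$classes$frequency_raw), 1)
  m_bearing <- res$classes$carries_minute_allele
  expect_equal(sum(m_bearing), 2L)
  expect_true(all(res$classes$minute_phenotype[m_bearing]))
  sig <- detect_trisomy_signature(res)
  expect_false(sig$detected)
  expect_equal(nrow(sig$classes), 0L)
})

test_that("trisomic x tester cross reproduces the derived twelfths and signature", {
  rules <- default_rules()
  res <- cross(fig_trisomic_parent(rules), tester_parent(rules),
               no_nd(), rules)
  raw <- setNames(res$classes$frequency_raw, res$classes$class)
  u <- "P{ActGFP}unc-13[GJ]"
  m <- "RpS3A[57g]"
  expect_equal(raw[[paste(df_label, m, sep = " / ")]], 1 / 12)
  expect_equal(raw[[paste(df_label, u, m, sep = " / ")]], 2 / 12)
  expect_equal(raw[[paste(u, u, m, sep = " / ")]], 1 / 12)
  expect_equal(sum(raw), 1)
  sig <- detect_trisomy_signature(res)
  expect_true(sig$detected)
  expect_setequal(sig$classes$class,
                  c(paste(df_label, u, m, sep = " / "),
                    paste(u, u, m, sep = " / ")))
  expect_true(all(sig$classes$trisomic))
})

test_that("a plain Mendelian cross gives the 1:1:1:1 Punnett square", {
  rules <- neutral_rules()
  ab <- karyotype(list(wt_copy("A"), wt_copy("B")))
  cd <- karyotype(list(wt_copy("C"), wt_copy("D")))
  res <- cross(ab, cd, no_nd(), rules)
  expect_equal(nrow(res$classes), 4L)
  expect_equal(res$classes$frequency_raw, rep(0.25, 4))
  expect_equal(res$classes$frequency_adjusted, rep(0.25, 4))
})

test_that("cross is symmetric in parent order and origin-free in class identity", {
  rules <- default_rules()
  model <- segregation_model()
  p <- fig_disomic_parent(rules)
  q <- tester_parent(rules)
  r1 <- cross(p, q, model, rules)
  r2 <- cross(q, p, model, rules)
  o1 <- r1$classes[order(r1$classes$class), ]
  o2 <- r2$classes[order(r2$classes$class), ]
  expect_equal(o1$class, o2$class)
  expect_equal(o1$frequency_raw, o2$frequency_raw, tolerance = 1e-12)
  expect_equal(o1$frequency_adjusted, o2$frequency_adjusted,
               tolerance = 1e-12)
})

test_that("nullosomic zygotes are reported as a lethal class, not an error", {
  rules <- neutral_rules()
  mono <- karyotype(list(wt_copy("A")))
  res <- cross(mono, mono, no_nd(), rules)
  expect_true("(nullosomic)" %in% res$classes$class)
  nul <- res$classes[res$classes$class == "(nullosomic)", ]
  expect_equal(nul$frequency_raw, 0.25)
  expect_equal(nul$viability, 0)
  expect_equal(nul$frequency_adjusted, 0)
  expect_equal(sum(res$classes$frequency_raw), 1)
  expect_equal(sum(res$classes$frequency_adjusted), 1)
})

test_that("lethal balanced-stock classes stay visible with adjusted frequency 0", {
  rules <- default_rules()
  bal_stock <- tester_parent(rules)  # RpS3A[57g] / In(4)ci[D] balancer
  res <- cross(bal_stock, bal_stock, no_nd(), rules)
  bal_label <- "In(4)ci[D], ci[D], pan[ciD]"
  balbal <- res$classes[res$classes$class ==
                          paste(bal_label, bal_label, sep = " / "), ]
  mm <- res$classes[res$classes$class ==
                      paste("RpS3A[57g]", "RpS3A[57g]", sep = " / "), ]
  expect_equal(balbal$frequency_adjusted, 0)  # balancer homozygous lethal
  expect_equal(mm$frequency_adjusted, 0)      # RpS3A null homozygous lethal
  expect_true(balbal$lethal && mm$lethal)
  # the stock is maintained as the balanced heterozygote
  het <- res$classes[res$classes$minute_phenotype & res$classes$disomic, ]
  expect_equal(het$frequency_adjusted, 1)
})

test_that("exact frequencies match Monte-Carlo mating on a biased example", {
  rules <- default_rules()
  model <- segregation_model(c(0.6, 0.1, 0.3), c(0.9, 0.4, 0.5), 0.004)
  res <- cross(fig_trisomic_parent(rules), tester_parent(rules),
               model, rules)
  mc <- simulate_mating(fig_trisomic_parent(rules), tester_parent(rules),
                        model, rules, n = 50000, seed = 11)
  freq <- mc$counts / mc$n_accepted
  for (k in names(freq)) {
    p <- res$classes$frequency_adjusted[res$classes$class == k]
    se <- sqrt(p * (1 - p) / mc$n_accepted)
    expect_lt(abs(freq[[k]] - p), 4 * se + 1e-9)
  }
  # no class should be observed that the exact cross says is impossible
  expect_true(all(names(freq) %in%
                    res$classes$class[res$classes$frequency_adjusted > 0]))
})

test_that("trisomy signature is sound over randomized parents", {
  rules <- default_rules()
  set.seed(23)
  labs <- c("A", "B", "C")
  for (i in 1:15) {
    pairing <- runif(3); pairing <- pairing / sum(pairing)
    model <- segregation_model(pairing, runif(3), 0)
    dis <- karyotype(lapply(sample(labs, 2), wt_copy))
    tri <- karyotype(lapply(sample(labs, 3, replace = TRUE), wt_copy))
    expect_false(detect_trisomy_signature(
      cross(dis, tester_parent(rules), model, rules))$detected)
    expect_true(detect_trisomy_signature(
      cross(tri, tester_parent(rules), model, rules))$detected)
  }
  # nondisjunction lets even a disomic parent produce rare diagnostic progeny
  res_nd <- cross(karyotype(lapply(labs[1:2], wt_copy)),
                  tester_parent(rules), segregation_model(), rules)
  sig <- detect_trisomy_signature(res_nd)
  expect_true(sig$detected)
  expect_lt(sum(sig$classes$frequency_adjusted), 0.01)
  expect_error(detect_trisomy_signature(
    cross(karyotype(lapply(labs[1:2], wt_copy)),
          karyotype(lapply(labs[1:2], wt_copy)),
          segregation_model(), rules)), "tester")
})

test_that("founder selection returns the disomic Minute target classes", {
  rules <- default_rules()
  res_c <- cross(fig_disomic_parent(rules), tester_parent(rules),
                 no_nd(), rules)
  found_c <- select_disomic_founders(res_c, df_label)
  expect_equal(found_c$class, paste(df_label, "RpS3A[57g]", sep = " / "))
  expect_equal(found_c$frequency_raw, 0.25)

  res_d <- cross(fig_trisomic_parent(rules), tester_parent(rules),
                 no_nd(), rules)
  found_d <- select_disomic_founders(res_d, df_label)
  expect_equal(found_d$class, paste(df_label, "RpS3A[57g]", sep = " / "))
  expect_true(all(found_d$minute_phenotype & found_d$disomic))

  # the balancer never co-occurs with the tester, so no balancer-bearing
  # class can be a disomic Minute founder
  expect_equal(nrow(select_disomic_founders(
    res_d, "In(4)ci[D], ci[D], pan[ciD]")), 0L)
  expect_error(select_disomic_founders(res_d, "NotAChromosome"),
               "not carried")
})
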