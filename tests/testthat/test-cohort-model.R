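test_that("registry has the fixed 20-domain composition in layout order", {
  reg <- domainRegistry()
  e <- registryEntries(reg)
  expect_identical(nrow(e), 20L)
  expect_identical(anyDuplicated(e$abbreviation), 0L)
  expect_identical(as.integer(table(e$instrument)[c("TOUWEN", "MABC2",
                                                    "SIPT", "NEPSY2")]),
                   c(1L, 3L, 6L, 10L))
  expect_identical(layoutOrder(reg)[1:10],
                   c("MND", "MD", "AC", "BAL", "MFP", "FI", "DC", "MAc",
                     "PPr", "BMC"))
  expect_identical(layoutOrder(reg)[11:20],
                   c("AuAttn", "VisAttn", "MemoD", "MemoF", "MemoN", "ImHP",
                     "Arrows", "BloC", "DeCo", "GeoP"))
  expect_identical(length(scoreDomains(reg)), 19L)
  expect_false("MND" %in% scoreDomains(reg))
})

test_that("invalid synthetic configs are rejected naming the field", {
  expect_error(syntheticConfig(n_ept = 1, seed = 1), "n_ept")
  expect_error(syntheticConfig(missing_rate = 1, seed = 1), "missing_rate")
  expect_error(syntheticConfig(seed = NULL), "seed")
  bad <- calibrateLoadings()$loadings
  bad["FI"] <- 1.4
  expect_error(syntheticConfig(loadings = bad, seed = 1), "loadings")
})

test_that("generation is reproducible from the seed", {
  cfg <- syntheticConfig(n_ept = 25, n_term = 20, seed = 42)
  c1 <- generateCohort(cfg)
  c2 <- generateCohort(cfg)
  expect_identical(childData(c1), childData(c2))
  c3 <- generateCohort(syntheticConfig(n_ept = 25, n_term = 20, seed = 43))
  expect_false(identical(childData(c1), childData(c3)))
})

test_that("zero loadings give independent scores at native mean/SD", {
  z <- setNames(rep(0, 20), layoutOrder(domainRegistry()))
  off <- setNames(rep(0, 19), scoreDomains(domainRegistry()))
  cfg <- syntheticConfig(n_ept = 2000, n_term = 2000, latent_shift = 0,
                         loadings = z, offsets = off,
                         touwen_base_rate = 0.05, missing_rate = 0, seed = 1)
  ch <- childData(generateCohort(cfg))
  expect_lt(abs(mean(ch$FI)), 0.05)          # SIPT native mean 0
  expect_lt(abs(sd(ch$FI) - 1), 0.05)        # native SD 1
  expect_lt(abs(mean(ch$MD) - 10), 0.15)     # MABC-2 native mean 10
  # independence between domains
  expect_lt(abs(cor(ch$FI, ch$DC)), 0.05)
  expect_lt(abs(cor(ch$MD, ch$DeCo)), 0.05)
  # and no group difference
  expect_lt(abs(mean(ch$FI[ch$group == "EPT"]) -
                  mean(ch$FI[ch$group == "TERM"])), 0.1)
})

test_that("EPT impairment rates match the closed-form convolution", {
  lam <- setNames(rep(0.7, 20), layoutOrder(domainRegistry()))
  off <- setNames(rep(0, 19), scoreDomains(domainRegistry()))
  cfg <- syntheticConfig(n_ept = 5000, n_term = 5000, latent_shift = 1,
                         loadings = lam, offsets = off,
                         touwen_base_rate = 0.05, missing_rate = 0, seed = 7)
  im <- buildImpairmentMatrix(generateCohort(cfg))
  rates <- impairmentRateTable(im)
  cut <- registryEntries(domainRegistry())$cutoff_z
  names(cut) <- layoutOrder(domainRegistry())
  for (d in c("FI", "MFP", "MD", "DeCo")) {
    expected <- oracle_impair_prob(0.7, 0, cut[[d]], -1)
    expect_lt(abs(rates[d, "ept_rate"] - expected), 0.03)
    # package closed form agrees with the integration oracle
    expect_equal(impairmentProbability(0.7, 0, cut[[d]], -1), expected,
                 tolerance = 1e-6)
  }
})

test_that("common loading induces lambda^2 inter-domain correlation", {
  lam <- setNames(rep(0.7, 20), layoutOrder(domainRegistry()))
  off <- setNames(rep(0, 19), scoreDomains(domainRegistry()))
  cfg <- syntheticConfig(n_ept = 5000, n_term = 2, latent_shift = 0,
                         loadings = lam, offsets = off,
                         touwen_base_rate = 0.05, missing_rate = 0, seed = 9)
  ch <- childData(generateCohort(cfg))
  ept <- ch[ch$group == "EPT", ]
  # continuous (SIPT) domains: correlation converges to lambda^2 = 0.49
  for (pair in list(c("MFP", "FI"), c("DC", "PPr"), c("FI", "BMC")))
    expect_lt(abs(cor(ept[[pair[1]]], ept[[pair[2]]]) - 0.49), 0.03)
})

test_that("calibration hits feasible targets and reports infeasible ones", {
  # symmetric case: equal rates with zero shift -> smallest loading (0)
  t0 <- referenceImpairmentRates()
  t0$ept_rate <- t0$term_rate <- 0.5
  cal0 <- calibrateLoadings(t0, latentShift = 0)
  expect_true(all(cal0$loadings[scoreDomains(domainRegistry())] == 0))
  # offsets put the cutoff at the median of the score distribution
  expect_equal(unname(cal0$offsets[["FI"]]), -1, tolerance = 1e-12)

  # infeasible: term rate above EPT rate under a positive shift
  t1 <- referenceImpairmentRates()
  t1[t1$domain == "FI", c("ept_rate", "term_rate")] <- c(0.2, 0.6)
  cal1 <- calibrateLoadings(t1, latentShift = 1)
  expect_false(cal1$feasibility["FI", "feasible"])
  expect_match(cal1$feasibility["FI", "note"], "term rate exceeds")
  expect_true(is.na(cal1$loadings[["FI"]]))

  # infeasible: loading above 1 when the user fixes a too-small shift
  cal2 <- calibrateLoadings(referenceImpairmentRates(), latentShift = 0.5)
  expect_false(all(cal2$feasibility$feasible))
})

test_that("calibrated generator reproduces MND and design-copying targets", {
  # MND (0.64, 0.28) and NEPSY-II design copying (0.67, 0.35)
  cfg <- syntheticConfig(n_ept = 5000, n_term = 5000, missing_rate = 0,
                         seed = 7)
  rates <- impairmentRateTable(buildImpairmentMatrix(generateCohort(cfg)))
  expect_lt(abs(rates["MND", "ept_rate"] - 36 / 56), 0.03)
  expect_lt(abs(rates["MND", "term_rate"] - 10 / 36), 0.03)
  expect_lt(abs(rates["DeCo", "ept_rate"] - 33 / 49), 0.03)
  expect_lt(abs(rates["DeCo", "term_rate"] - 12 / 34), 0.03)
})

test_that("zero latent shift is a null: equal rates, OR near 1", {
  cal <- calibrateLoadings()
  cfg <- syntheticConfig(n_ept = 5000, n_term = 5000, latent_shift = 0,
                         loadings = setNames(rep(0.6, 20),
                                             names(cal$loadings)),
                         offsets = cal$offsets, touwen_base_rate = 0.1,
                         missing_rate = 0, seed = 21)
  rates <- impairmentRateTable(buildImpairmentMatrix(generateCohort(cfg)))
  common <- !is.na(rates$or)
  expect_true(any(common))
  expect_true(all(abs(rates$or[common] - 1) < 0.35))
  expect_lt(median(abs(rates$or[common] - 1)), 0.1)
})

test_that("cohort files round-trip and reject malformed input", {
  coh <- generateCohort(syntheticConfig(n_ept = 3, n_term = 3,
                                        missing_rate = 0.2, seed = 5))
  for (ext in c(".csv", ".tsv")) {
    f <- tempfile(fileext = ext)
    writeCohort(coh, f)
    back <- readCohort(f)
    expect_equal(childData(back), childData(coh))
  }
  # unknown score column is rejected with the list of valid codes
  f <- tempfile(fileext = ".csv")
  ch <- childData(coh)
  names(ch)[names(ch) == "FI"] <- "XYZ"
  write.csv(ch, f, row.names = FALSE, na = "")
  expect_error(readCohort(f), "XYZ")
  expect_error(readCohort(f), "DeCo")   # message lists valid codes
  # non-numeric score cell names row and column
  ch <- childData(coh)
  ch$FI <- as.character(ch$FI); ch$FI[2] <- "oops"
  write.csv(ch, f, row.names = FALSE, na = "")
  expect_error(readCohort(f), "row 2, column FI")
  # empty cell is missing, never zero
  ch <- childData(coh)
  ch$FI[1] <- NA
  write.csv(ch, f, row.names = FALSE, na = "")
  expect_true(is.na(childData(readCohort(f))$FI[1]))
})

test_that("cohort validity catches duplicate ids and raw MND columns", {
  coh <- generateCohort(syntheticConfig(n_ept = 3, n_term = 3, seed = 5))
  ch <- childData(coh)
  ch$child_id[2] <- ch$child_id[1]
  expect_error(Cohort(ch), "unique")
  ch <- childData(coh)
  ch$MND <- 1
  expect_error(Cohort(ch), "MND")
})
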