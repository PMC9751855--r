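test_that("burden counts equal per-cell brute-force row sums", {
  # worked 2-child example over 3 domains
  im <- make_im(rbind(A = c(1, 0), B = c(1, 0), C = c(0, 1)),
                group = c("EPT", "TERM"))
  b <- burdenTable(burdenProfile(im))
  expect_identical(b$burden, c(2L, 1L))
  # all-false matrix: histogram mass at 0
  im0 <- make_im(matrix(0, 3, 4), group = rep(c("EPT", "TERM"), 2))
  h <- burdenHistogram(burdenProfile(im0))
  expect_true(all(h$burden == 0))
  expect_identical(sum(h$n), 4L)
  # random 50 x 20 matrix vs independent loop
  set.seed(11)
  calls <- matrix(runif(50 * 20) < 0.3, nrow = 20)
  rownames(calls) <- layoutOrder(domainRegistry())
  imr <- make_im(calls, group = rep(c("EPT", "TERM"), each = 25))
  expected <- integer(50)
  for (ch in 1:50) for (d in 1:20)
    if (calls[d, ch]) expected[ch] <- expected[ch] + 1L
  expect_identical(burdenTable(burdenProfile(imr))$burden, expected)
  # histogram masses sum to the group sizes
  hr <- burdenHistogram(burdenProfile(imr))
  expect_identical(as.integer(tapply(hr$n, hr$group, sum)[c("EPT", "TERM")]),
                   c(25L, 25L))
})

test_that("exceeding the reference maximum uses a strict inequality", {
  im <- make_im(rbind(A = c(1, 1, 1, 0), B = c(1, 1, 0, 0),
                      C = c(1, 0, 0, 0)),
                group = c("EPT", "EPT", "TERM", "TERM"))
  # term max burden = 1; EPT burdens 3 and 2
  ex <- exceedsReferenceMax(burdenProfile(im), "TERM")
  expect_identical(ex$reference_max, 1L)
  expect_identical(unname(ex$flagged), c(TRUE, TRUE))
  expect_equal(ex$proportion, 1)
  # equal burden is not flagged
  im2 <- make_im(rbind(A = c(1, 1), B = c(0, 1)), group = c("EPT", "TERM"))
  ex2 <- exceedsReferenceMax(burdenProfile(im2), "TERM")
  expect_identical(ex2$count, 0L)
  expect_error(exceedsReferenceMax(burdenProfile(im2), "XX"), "absent")
})

test_that("pair counts match the worked example and the exhaustive oracle", {
  calls <- rbind(A = c(1, 1, 1), B = c(1, 0, 1), C = c(0, 1, 1))
  im <- make_im(calls, group = rep("EPT", 3))
  g <- pairCounts(im, "EPT")
  expect_identical(unname(nodeCounts(g)), c(3L, 2L, 2L))
  pc <- pairCountMatrix(g)
  expect_identical(pc["A", "B"], 2L)
  expect_identical(pc["A", "C"], 2L)
  expect_identical(pc["B", "C"], 1L)
  expect_true(is.na(pc["A", "A"]))
  # oracle equivalence on random matrices up to 100 x 20, with missingness
  set.seed(12)
  for (rep in 1:5) {
    n <- sample(20:100, 1)
    calls <- matrix(runif(20 * n) < runif(1, 0.1, 0.5), nrow = 20)
    obs <- matrix(runif(20 * n) < 0.9, nrow = 20)
    rownames(calls) <- layoutOrder(domainRegistry())
    im <- make_im(calls, group = rep("EPT", n), observed = obs)
    g <- pairCounts(im, "EPT")
    oracle <- oracle_pair_counts(impairmentCalls(im))
    off <- !diag(TRUE, 20)
    expect_identical(unname(pairCountMatrix(g))[off], unname(oracle)[off])
    # boundedness: pair count never exceeds either node count
    lim <- outer(nodeCounts(g), nodeCounts(g), pmin)
    expect_true(all(pairCountMatrix(g)[off] <= lim[off]))
  }
})

test_that("children missing either domain of a pair do not count", {
  calls <- rbind(A = c(1, 1), B = c(1, 1))
  obs <- rbind(A = c(1, 1), B = c(1, 0))   # child 2 unobserved in B
  im <- make_im(calls, group = rep("EPT", 2), observed = obs)
  expect_identical(pairCountMatrix(pairCounts(im, "EPT"))["A", "B"], 1L)
})

test_that("thresholded edges are monotone and deterministically ordered", {
  calls <- rbind(A = c(1, 1, 1), B = c(1, 0, 1), C = c(0, 1, 1))
  im <- make_im(calls, group = rep("EPT", 3))
  g <- pairCounts(im, "EPT")
  e1 <- edgesAtThreshold(g, 1)
  expect_identical(nrow(e1), 3L)
  expect_identical(nrow(edgesAtThreshold(g, 3)), 0L)
  e2 <- edgesAtThreshold(g, 2)
  expect_identical(paste(e2$domain_a, e2$domain_b), c("A B", "A C"))
  # edge sets nest as the threshold rises; totals are non-increasing
  set.seed(13)
  calls <- matrix(runif(20 * 60) < 0.3, nrow = 20)
  rownames(calls) <- layoutOrder(domainRegistry())
  g <- pairCounts(make_im(calls, group = rep("EPT", 60)), "EPT")
  prev <- NULL
  for (k in 1:8) {
    ek <- edgesAtThreshold(g, k)
    key <- paste(ek$domain_a, ek$domain_b)
    if (!is.null(prev)) expect_true(all(key %in% prev))
    prev <- key
    expect_identical(nrow(ek), totalImpairedPairs(g, k))
  }
})

test_that("total impaired pairs counts distinct pairs, capped at C(20,2)", {
  im0 <- make_im(matrix(0, 20, 3,
                        dimnames = list(layoutOrder(domainRegistry()), NULL)),
                 group = rep("EPT", 3))
  expect_identical(totalImpairedPairs(pairCounts(im0, "EPT")), 0L)
  im1 <- make_im(matrix(1, 20, 1,
                        dimnames = list(layoutOrder(domainRegistry()), NULL)),
                 group = "EPT")
  expect_identical(totalImpairedPairs(pairCounts(im1, "EPT")), 190L)
  calls <- rbind(A = c(1, 1, 1), B = c(1, 0, 1), C = c(0, 1, 1))
  g <- pairCounts(make_im(calls, group = rep("EPT", 3)), "EPT")
  expect_identical(totalImpairedPairs(g, 1), 3L)
  # incidence-sum variant: sum of the per-pair counts
  expect_identical(incidenceSum(g, 1), 5L)
})

test_that("joint impairment is the conjunction over listed domains", {
  calls <- rbind(MND = c(1, 1, 0), DC = c(1, 1, 1), FI = c(1, 0, 1))
  im <- make_im(calls, group = c("EPT", "EPT", "TERM"))
  ji <- jointImpairment(im, c("MND", "DC", "FI"))
  expect_identical(unname(ji$perChild), c(TRUE, FALSE, FALSE))
  expect_identical(ji$counts, c(EPT = 1L, TERM = 0L))
  expect_identical(unname(ji$table), c(1L, 1L, 0L, 1L))
  expect_equal(unname(ji$conditional["EPT"]), 0.5)
  expect_error(jointImpairment(im, c("MND", "ZZ")), "ZZ")
  # subset monotonicity on random matrices
  set.seed(14)
  for (rep in 1:5) {
    calls <- matrix(runif(20 * 40) < 0.4, nrow = 20)
    rownames(calls) <- layoutOrder(domainRegistry())
    im <- make_im(calls, group = rep(c("EPT", "TERM"), 20))
    trio <- sample(rownames(calls), 3)
    jt <- sum(jointImpairment(im, trio)$counts)
    for (pair in combn(trio, 2, simplify = FALSE))
      expect_lte(jt, sum(jointImpairment(im, pair)$counts))
  }
})

test_that("relationship maps render deterministically with correct geometry", {
  calls <- matrix(0, 20, 3,
                  dimnames = list(layoutOrder(domainRegistry()), NULL))
  calls[c("MND", "DeCo"), 1] <- 1
  calls[c("MND", "DeCo", "FI"), 2] <- 1
  g <- pairCounts(make_im(calls, group = rep("EPT", 3)), "EPT")
  f1 <- tempfile(fileext = ".pdf")
  r1 <- renderRelationshipMap(g, 1, f1)
  r2 <- renderRelationshipMap(g, 1, tempfile(fileext = ".pdf"))
  expect_true(file.exists(f1) && file.size(f1) > 0)
  expect_identical(r1, r2)
  expect_identical(nrow(r1$layout), 20L)
  # semicircle split: first 10 in the upper half, last 10 in the lower
  expect_true(all(r1$layout$y[1:10] > 0))
  expect_true(all(r1$layout$y[11:20] < 0))
  expect_identical(r1$totalPairs, 3L)   # MND-DeCo, MND-FI, DeCo-FI
  expect_identical(nrow(r1$edges), 3L)
  # empty graph still renders all 20 labelled nodes
  g0 <- pairCounts(make_im(matrix(0, 20, 2,
                                  dimnames = list(layoutOrder(domainRegistry()),
                                                  NULL)),
                           group = rep("EPT", 2)), "EPT")
  r0 <- renderRelationshipMap(g0, 1, tempfile(fileext = ".pdf"))
  expect_identical(nrow(r0$edges), 0L)
  expect_error(renderRelationshipMap(g, 1, "/nonexistent/dir/x.pdf"),
               "cannot write")
})

test_that("edge lists serialise with group and threshold annotations", {
  calls <- rbind(A = c(1, 1, 1), B = c(1, 0, 1), C = c(0, 1, 1))
  g <- pairCounts(make_im(calls, group = rep("EPT", 3)), "EPT",
                  thresholds = c(1L, 2L))
  f <- tempfile(fileext = ".tsv")
  writeEdgeList(g, f, header = "test-header")
  lines <- readLines(f)
  expect_match(lines[1], "^# test-header")
  tab <- read.delim(f, comment.char = "#")
  expect_identical(names(tab), c("domain_a", "domain_b", "n_cooccurring",
                                 "group", "threshold"))
  expect_identical(nrow(tab), 5L)   # 3 edges at k=1 + 2 at k=2
})
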