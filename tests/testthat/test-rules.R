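test_that("leaf probabilities follow the binary-tree decomposition", {
  # (1-A)*B at leaf index 1 (pattern 01)
  expect_equal(leafProbability(c(0.3, 0.8), 1), 0.56)
  # deterministic indicator: state (1,1) puts all mass on leaf 3
  expect_equal(allLeafProbabilities(c(1, 1)), c(0, 0, 0, 1))
  # normalization
  expect_equal(sum(allLeafProbabilities(c(0.3, 0.8))), 1)
  expect_equal(sum(allLeafProbabilities(runif(4))), 1)
  expect_error(leafProbability(c(0.3, 0.8), 4), "out of range")
})

test_that("hand-derived rule fits are exact", {
  # no observations: maximal uncertainty everywhere
  r <- fitRule(matrix(numeric(0), 0, 2), numeric(0), c("A", "B"))
  expect_identical(ruleV(r), rep(0.5, 4))
  expect_identical(ruleU(r), rep(1, 4))

  # one deterministic observation pins its leaf, others stay 0.5
  r <- fitRule(matrix(c(1, 0), 1, 2), 1, c("A", "B"))
  expect_identical(ruleV(r), c(0.5, 0.5, 1, 0.5))
  expect_equal(ruleU(r), c(1, 1, 0, 1))

  # two conflicting observations on one leaf average to 0.5
  r <- fitRule(matrix(c(1, 1, 0, 0), 2, 2), c(0, 1), c("A", "B"))
  expect_identical(ruleV(r), rep(0.5, 4))

  # half-uncertain observation: w = 0.25, u = 0.75 on every leaf
  r <- fitRule(matrix(c(0.5, 0.5), 1, 2), 1, c("A", "B"))
  expect_equal(ruleV(r), rep(0.625, 4))
  expect_equal(ruleW(r)[1, ], rep(0.25, 4))
})

test_that("fitRule agrees with the naive loop oracle on random instances", {
  set.seed(11)
  for (rep in 1:40) {
    m <- sample(0:20, 1)
    n <- sample(1:4, 1)
    Rp <- matrix(runif(m * n), m, n)
    Tp <- runif(m)
    fit <- fitRule(Rp, Tp, sort(sprintf("g%d", seq_len(n))))
    oracle <- naiveFitRule(Rp, Tp)
    expect_lt(max(abs(ruleV(fit) - oracle$V)), 1e-12)
    expect_lt(max(abs(ruleU(fit) - oracle$U)), 1e-12)
    if (m > 0) expect_lt(max(abs(ruleW(fit) - oracle$W)), 1e-12)
  }
})

test_that("rule invariants hold: W rows sum to 1, permutation invariance,
           monotone absorption, untouched leaves at 0.5", {
  set.seed(12)
  Rp <- matrix(runif(12 * 3), 12, 3)
  Tp <- runif(12)
  regs <- c("a", "b", "c")
  fit <- fitRule(Rp, Tp, regs)
  expect_equal(rowSums(ruleW(fit)), rep(1, 12))

  perm <- sample(12)
  fitPerm <- fitRule(Rp[perm, ], Tp[perm], regs)
  expect_equal(ruleV(fitPerm), ruleV(fit), tolerance = 1e-12)

  # adding a t'=1 observation at leaf 5 (pattern 101) never lowers v_5
  extra <- fitRule(rbind(Rp, c(1, 0, 1)), c(Tp, 1), regs)
  expect_gte(ruleV(extra)[6], ruleV(fit)[6])

  # leaves with zero observation weight are exactly 0.5
  hard <- fitRule(matrix(c(1, 0, 1), 1, 3), 1, regs)
  expect_identical(ruleV(hard)[-6], rep(0.5, 7))
})

test_that("fitRules covers all nodes including zero-regulator nodes", {
  net <- TFNetwork(c("A", "B", "C"), data.frame(
    source = c("A", "B"), target = c("B", "A")
  ))
  prob <- rbind(A = c(1, 0, 1, 0), B = c(0, 1, 0, 1), C = c(1, 1, 1, 1))
  colnames(prob) <- paste0("S", 1:4)
  rs <- fitRules(net, prob)
  expect_named(rulesOf(rs), c("A", "B", "C"))
  expect_length(ruleV(rulesOf(rs)$A), 2L)
  # zero-regulator node: single leaf, every observation weight 1, u = 0
  expect_identical(ruleV(rulesOf(rs)$C), 1)
  expect_identical(ruleU(rulesOf(rs)$C), 0)
  expect_error(fitRules(TFNetwork("Z", data.frame(source = "Z",
                                                  target = "Z")), prob),
               "unknown node")
})

test_that("deterministic data covering all leaves recovers the truth table", {
  net <- TFNetwork(c("A", "B", "X"), data.frame(
    source = c("A", "B"), target = c("X", "X")
  ))
  # X = A AND B, observed at every regulator configuration
  Rp <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  truthV <- c(0, 0, 0, 1)
  prob <- rbind(A = Rp[, 1], B = Rp[, 2], X = truthV)
  colnames(prob) <- paste0("S", 1:4)
  rs <- fitRules(net, prob)
  expect_identical(ruleV(rulesOf(rs)$X), truthV)
})

test_that("predictions are convex combinations of leaf confidences", {
  r <- fitRule(matrix(c(0.5, 0.5), 1, 2), 1, c("A", "B"))
  # binary input collapses to the single active leaf
  expect_equal(predictRule(r, c(1, 0)), ruleV(r)[3])
  # uniform input averages the leaves
  expect_equal(predictRule(r, c(0.5, 0.5)), mean(ruleV(r)))
  set.seed(13)
  for (i in 1:10) {
    p <- predictRule(r, runif(2))
    expect_true(p >= 0 && p <= 1)
  }
  expect_error(predictRule(r, c(0.5)), "length")
})

test_that("cross-validation splits correctly and does not overfit
           noiseless leaf-covering data", {
  net <- TFNetwork(c("A", "B", "X"), data.frame(
    source = c("A", "B", "A", "B"), target = c("X", "X", "A", "B")
  ))
  set.seed(14)
  m <- 40
  A <- rep(c(0, 1), each = m / 2)
  B <- rep(c(0, 1), times = m / 2)
  prob <- rbind(A = A, B = B, X = as.numeric(A & B))
  colnames(prob) <- paste0("S", 1:m)
  cv <- crossValidateRules(net, prob, iterations = 10, seed = 5)
  expect_equal(sum(cv$pairs$partition == "train") /
                 sum(cv$pairs$partition == "test"), 4, tolerance = 1e-9)
  expect_lt(mean(cv$mse$train_mse), 0.01)
  expect_lt(mean(cv$mse$test_mse), 0.01)
  expect_lt(abs(mean(cv$mse$train_mse) - mean(cv$mse$test_mse)), 0.05)
  expect_error(crossValidateRules(net, prob[, 1:4], seed = 1),
               "at least 5 samples")
})

test_that("in the noisy regime, confident predictions correlate better
           with the truth than unfiltered ones", {
  ds <- simulateDataset(syntheticSpec(sigma = 1.5, seed = 3))
  be <- binarizeExpression(ds$expression)
  cv <- crossValidateRules(ds$network, be, iterations = 20, seed = 4)
  cc <- confidenceCorrelation(cv$pairs, grid = seq(0.1, 0.5, by = 0.1))
  expect_true(all(is.finite(cc$correlation)))
  # tightening the window from 0.5 to 0.1 raises the correlation
  expect_gt(cc$correlation[1], cc$correlation[5])
  # and the overall trend across the grid is decreasing in x
  expect_lt(cor(cc$x, cc$correlation, method = "spearman"), 0)
  # test error exceeds train error only mildly (no gross overfit)
  expect_lt(abs(mean(cv$mse$train_mse) - mean(cv$mse$test_mse)), 0.05)
})
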