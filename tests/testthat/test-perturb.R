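test_that("walks census, force and censor as the semantics dictate", {
  fx <- bbFixtures()

  # absorbing state: all flip probabilities 0 -> censored at the cap
  ts <- fx$toggle_switch$rules
  cfg <- walkConfig(escapeRadius = 0, nWalks = 1, maxSteps = 40, seed = 1L)
  expect_equal(randomWalk(ts, c(A = 1L, B = 0L), config = cfg), 40L)

  # all flip probabilities 1 with radius 0: first update escapes
  expect_equal(randomWalk(ts, c(A = 0L, B = 0L), config = cfg), 1L)

  # escape must be possible: radius >= free TFs errors
  expect_error(
    randomWalk(ts, c(A = 1L, B = 0L), perturbation("A", "knockdown"),
               walkConfig(escapeRadius = 1, nWalks = 1)),
    "escape impossible"
  )

  # ensemble and single-walk semantics agree in distribution
  cf <- fx$independent_coinflip$rules
  start <- setNames(rep(0L, 5), paste0("N", 1:5))
  ens <- stabilityScore(cf, start, perturbation(),
                        walkConfig(escapeRadius = 2, nWalks = 400,
                                   seed = 2L))
  singles <- vapply(1:200, function(i) {
    randomWalk(cf, start, config = walkConfig(escapeRadius = 2,
                                              nWalks = 1,
                                              seed = 1000L + i))
  }, integer(1))
  se <- sqrt(var(ens$steps) / 400 + var(singles) / 200)
  expect_lt(abs(mean(ens$steps) - mean(singles)), 4 * se)
})

test_that("Monte Carlo escape times match the absorbing-chain solve", {
  fx <- bbFixtures()
  cf <- fx$independent_coinflip$rules
  start <- setNames(rep(0L, 5), paste0("N", 1:5))

  # package linear solve cross-checked against an independent
  # birth-death solve on the Hamming-distance levels
  exact <- expectedEscapeSteps(cf, start, escapeRadius = 3L)
  expect_equal(exact, birthDeathEscapeSteps(5, 0.5, 3), tolerance = 1e-10)

  mc <- walkEnsemble(cf, start, perturbation(),
                     walkConfig(escapeRadius = 3, nWalks = 1500,
                                seed = 3L))
  expect_lt(abs(mean(mc) - exact), 3 * sd(mc) / sqrt(1500))

  # perturbed condition: clamping one coin leaves a 4-coin chain
  kd <- perturbation("N1", "knockdown")
  exactKd <- expectedEscapeSteps(cf, start, kd, escapeRadius = 3L)
  expect_equal(exactKd, birthDeathEscapeSteps(4, 0.5, 3),
               tolerance = 1e-10)
  mcKd <- walkEnsemble(cf, start, kd,
                       walkConfig(escapeRadius = 3, nWalks = 1500,
                                  seed = 4L))
  expect_lt(abs(mean(mcKd) - exactKd), 3 * sd(mcKd) / sqrt(1500))
})

test_that("stability scores compare perturbed and reference means", {
  fx <- bbFixtures()$self_activator_hub
  cfg <- walkConfig(escapeRadius = 3, nWalks = 600, seed = 5L)

  # null perturbation scores ~0 (within Monte-Carlo error)
  null <- stabilityScore(fx$rules, "11111", perturbation(), cfg)
  nullSE <- sqrt(var(null$steps) / 600 + var(null$referenceSteps) / 600) /
    null$referenceMeanSteps
  expect_lt(abs(null$score), 3 * nullSE)

  # hub knockdown destabilizes its ON attractor (exact solve agrees)
  kd <- stabilityScore(fx$rules, "11111", perturbation("H", "knockdown"),
                       cfg)
  expect_lt(kd$score, 0)
  exactRef <- expectedEscapeSteps(fx$rules, "11111", escapeRadius = 3L)
  exactKd <- expectedEscapeSteps(fx$rules, "11111",
                                 perturbation("H", "knockdown"),
                                 escapeRadius = 3L)
  expect_lt(exactKd, exactRef)
  expect_lt(abs(kd$meanSteps - exactKd), 3 * sd(kd$steps) / sqrt(600))

  # hub activation removes the hub's own escape channel: score >= 0
  act <- stabilityScore(fx$rules, "11111",
                        perturbation("H", "activation"), cfg)
  exactAct <- expectedEscapeSteps(fx$rules, "11111",
                                  perturbation("H", "activation"),
                                  escapeRadius = 3L)
  expect_gt(exactAct, exactRef)
  expect_gt(act$score, 0)

  # score arithmetic
  expect_equal(kd$score,
               (kd$meanSteps - kd$referenceMeanSteps) /
                 kd$referenceMeanSteps)
})

test_that("the perturbation scan covers every TF, mode and attractor", {
  fx <- bbFixtures()$toggle_switch
  aset <- findPseudoAttractors(fx$rules, c(A = 0L, B = 0L),
                               searchConfig(radius = 2))
  cfg <- walkConfig(escapeRadius = 0, nWalks = 80, maxSteps = 300,
                    seed = 6L)
  scores <- scanPerturbations(fx$rules, aset, cfg)
  expect_equal(sum(scores$mode != "none"), 2 * 2 * 2)
  expect_equal(sum(scores$mode == "none"), 2)

  # knockdown of A at (A=1, B=0): forcing A off makes B's flip prob 1
  kdA <- scores[scores$tf == "A" & scores$mode == "knockdown" &
                  scores$start_attractor == "10", ]
  expect_lt(kdA$score, 0)
  # activation of A at its own ON attractor cannot destabilize it
  actA <- scores[scores$tf == "A" & scores$mode == "activation" &
                   scores$start_attractor == "10", ]
  expect_gte(actA$score, 0)
})

test_that("per-cluster aggregation and master classification apply the
           -0.2 cutoff", {
  perCluster <- data.frame(
    cluster = c("NE", "NE", "NE", "NE"),
    tf = c("X", "Y", "X", "Z"),
    mode = c("knockdown", "knockdown", "activation", "activation"),
    score = c(-0.25, -0.1, -0.05, -0.3)
  )
  masters <- classifyMasters(perCluster)
  expect_equal(masters$NE$master_regulators, "X")
  expect_equal(masters$NE$master_destabilizers, "Z")
  # exactly at the threshold qualifies (score <= -0.2)
  perCluster$score[2] <- -0.2
  masters <- classifyMasters(perCluster)
  expect_equal(masters$NE$master_regulators, c("X", "Y"))

  # aggregation is the unweighted mean over a cluster's attractors
  scores <- data.frame(
    tf = c("A", "A"), mode = c("knockdown", "knockdown"),
    start_attractor = c("10", "01"), cluster = c("k", "k"),
    mean_steps = c(10, 30), reference_mean_steps = c(20, 40),
    score = c(-0.5, -0.25), n_walks = 10L, n_censored = 0L, seed = 1L
  )
  agg <- clusterScores(scores)
  expect_equal(agg$score, -0.375)
  expect_equal(agg$n_attractors, 2)
})

test_that("clamping a TF at its attractor value removes escape channels,
           never adds them", {
  set.seed(41)
  for (rep in 1:5) {
    rs <- randomRuleSet(5)
    nodes <- networkNodes(rs@network)
    st <- setNames(sample(c(0L, 1L), 5, replace = TRUE), nodes)
    base <- vapply(nodes, function(tf) flipProbability(rs, st, tf),
                   numeric(1))
    baseChannels <- names(base)[base >= 0.5]
    for (tf in nodes) {
      mode <- if (st[[tf]] == 1L) "activation" else "knockdown"
      fixedSt <- st # clamp at the current value: state unchanged
      clamped <- vapply(setdiff(nodes, tf), function(x) {
        flipProbability(rs, fixedSt, x)
      }, numeric(1))
      clampedChannels <- names(clamped)[clamped >= 0.5]
      expect_true(all(clampedChannels %in% baseChannels))
    }
  }
})
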