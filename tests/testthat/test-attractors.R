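test_that("canonical fixtures yield their known attractor inventories", {
  fx <- bbFixtures()

  ts <- findPseudoAttractors(fx$toggle_switch$rules, c(A = 0L, B = 0L),
                             searchConfig(radius = 2))
  expect_equal(attractorStates(ts), c("01", "10"))
  expect_true(all(lengths(lapply(ts@attractors, `[[`, "members")) == 1L))

  rp <- findPseudoAttractors(fx$repressilator$rules,
                             c(A = 0L, B = 0L, C = 0L),
                             searchConfig(radius = 3))
  expect_equal(nAttractors(rp), 1L)
  expect_equal(rp@attractors[[1L]]$members, fx$repressilator$cycle)

  cf <- findPseudoAttractors(fx$independent_coinflip$rules,
                             setNames(rep(0L, 5), paste0("N", 1:5)),
                             searchConfig(radius = 4))
  expect_equal(nAttractors(cf), 0L)

  hub <- findPseudoAttractors(fx$self_activator_hub$rules,
                              setNames(rep(1L, 5),
                                       c("H", paste0("T", 1:4))),
                              searchConfig(radius = 5))
  expect_equal(attractorStates(hub), c("00000", "11111"))
})

test_that("constant-ON rules give a single all-ON attractor", {
  nodes <- c("A", "B", "C")
  net <- TFNetwork(nodes, data.frame(source = character(0),
                                     target = character(0),
                                     sign = character(0)))
  rules <- setNames(lapply(nodes, function(nd) {
    new("BooleanRule", target = nd, regulators = character(0), V = 1,
        W = matrix(numeric(0), 0, 1), U = 1)
  }), nodes)
  rs <- new("RuleSet", network = net, rules = rules)
  aset <- findPseudoAttractors(rs, c(A = 1L, B = 1L, C = 1L),
                               searchConfig(radius = 2))
  expect_equal(attractorStates(aset), "111")
})

test_that("bounded search at R = g matches the exhaustive pruned-STG oracle", {
  set.seed(31)
  for (rep in 1:10) {
    g <- sample(3:6, 1)
    rs <- randomRuleSet(g)
    nodes <- networkNodes(rs@network)
    start <- setNames(sample(c(0L, 1L), g, replace = TRUE), nodes)
    found <- findPseudoAttractors(rs, start, searchConfig(radius = g))
    oracle <- oracleTerminalSCCs(rs)
    expect_equal(lapply(found@attractors, `[[`, "members"), oracle)
  }
})

test_that("every singleton attractor has all flip probabilities below
           threshold and non-members do not", {
  # known singletons: both hub fixture attractors
  hub <- bbFixtures()$self_activator_hub$rules
  hnodes <- networkNodes(hub@network)
  for (key in c("00000", "11111")) {
    st <- stateFromString(key, hnodes)
    fp <- vapply(hnodes, function(tf) flipProbability(hub, st, tf),
                 numeric(1))
    expect_true(all(fp < 0.5))
  }

  set.seed(32)
  rs <- randomRuleSet(5)
  nodes <- networkNodes(rs@network)
  start <- setNames(rep(0L, 5), nodes)
  aset <- findPseudoAttractors(rs, start, searchConfig(radius = 5))
  members <- unlist(lapply(aset@attractors, `[[`, "members"))
  for (a in aset@attractors) {
    if (length(a$members) == 1L) {
      st <- stateFromString(a$members, nodes)
      fp <- vapply(nodes, function(tf) flipProbability(rs, st, tf),
                   numeric(1))
      expect_true(all(fp < 0.5))
    }
  }
  # non-member states either have a retained escape edge or are transient
  allKeys <- apply(expand.grid(rep(list(0:1), 5)), 1, paste, collapse = "")
  nonMembers <- setdiff(allKeys, members)
  for (key in sample(nonMembers, min(10, length(nonMembers)))) {
    st <- stateFromString(key, nodes)
    fp <- vapply(nodes, function(tf) flipProbability(rs, st, tf),
                 numeric(1))
    # a non-member with all flips < 0.5 would be a missed singleton
    expect_false(all(fp < 0.5))
  }
})

test_that("random restarts find the full attractor set, deduplicated,
           and are seed-reproducible", {
  fx <- bbFixtures()$toggle_switch
  cfg <- searchConfig(radius = 2, nRandomStarts = 50, seed = 8L)
  a1 <- randomRestartSearch(fx$rules, cfg)
  expect_equal(attractorStates(a1), c("01", "10"))
  expect_equal(nrow(attr(a1, "log")), 50L)
  a2 <- randomRestartSearch(fx$rules, cfg)
  expect_identical(attractorStates(a1), attractorStates(a2))

  # radius 0: only initial states that are already pseudo-attractors found
  cfg0 <- searchConfig(radius = 0, nRandomStarts = 60, seed = 9L)
  a0 <- randomRestartSearch(fx$rules, cfg0)
  expect_true(all(attractorStates(a0) %in% c("01", "10")))
})

test_that("cluster means discretize with ties going to 0 and recover
           generating states", {
  net <- TFNetwork(c("A", "B", "C"), data.frame(
    source = c("A", "B", "C"), target = c("B", "C", "A")
  ))
  prob <- rbind(A = c(0.9, 0.9), B = c(0.1, 0.1), C = c(0.5, 0.5))
  colnames(prob) <- c("S1", "S2")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = prob * 6, prob = prob),
    rowData = S4Vectors::DataFrame(
      muOff = rep(1, 3), muOn = 6, sigma = 0.5, wOff = 0.5, wOn = 0.5,
      degenerate = FALSE, row.names = rownames(prob)
    )
  )
  be <- new("BinarizedExperiment", se)
  refs <- discretizeClusterMeans(be, c(S1 = "k", S2 = "k"), net)
  expect_equal(refs$k, c(A = 1L, B = 0L, C = 0L))
  expect_error(discretizeClusterMeans(be, c(S9 = "k"), net), "absent")

  # generating-state recovery at 10-sigma separation
  set.seed(33)
  states <- list(c1 = c(A = 1L, B = 0L, C = 1L),
                 c2 = c(A = 0L, B = 1L, C = 0L))
  sim <- makeBimodalMatrix(states, nPerCluster = 12, sigma = 0.5)
  be2 <- binarizeExpression(sim$mat)
  refs2 <- discretizeClusterMeans(be2, sim$labels, net)
  expect_equal(refs2$c1, states$c1)
  expect_equal(refs2$c2, states$c2)
})

test_that("attractors assign to nearest cluster reference with tie flags", {
  fx <- bbFixtures()$toggle_switch
  aset <- findPseudoAttractors(fx$rules, c(A = 0L, B = 0L),
                               searchConfig(radius = 2))
  refs <- list(zOn = c(A = 1L, B = 0L), aOff = c(A = 0L, B = 1L))
  assigned <- assignAttractors(aset, refs)
  byState <- setNames(assigned@attractors,
                      attractorStates(assigned))
  expect_equal(byState[["10"]]$cluster, "zOn")
  expect_equal(byState[["10"]]$distances$zOn, 0)
  expect_equal(byState[["10"]]$distances$aOff, 2)
  expect_false(byState[["10"]]$ambiguous)

  # equidistant references: alphabetically first label, flagged
  refsTie <- list(b = c(A = 1L, B = 1L), a = c(A = 0L, B = 0L))
  tie <- assignAttractors(aset, refsTie)
  expect_equal(tie@attractors[[1L]]$cluster, "a")
  expect_true(tie@attractors[[1L]]$ambiguous)
})

test_that("baseline schemes transcribe their quoted logic", {
  net <- TFNetwork(c("ACT", "INH", "X"), data.frame(
    source = c("ACT", "INH"), target = c("X", "X"),
    sign = c("+", "-")
  ))
  inh <- baselineRules(net, "inhibitory_dominant")
  vX <- ruleV(rulesOf(inh)$X)
  # regulators sorted: ACT (msb), INH (lsb)
  expect_equal(vX, c(0, 0, 1, 0)) # ON only when ACT=1, INH=0

  maj <- baselineRules(net, "majority")
  expect_equal(ruleV(rulesOf(maj)$X), c(0, 0, 1, 0))

  net3 <- TFNetwork(c("A1", "A2", "I1", "X"), data.frame(
    source = c("A1", "A2", "I1"), target = c("X", "X", "X"),
    sign = c("+", "+", "-")
  ))
  maj3 <- baselineRules(net3, "majority")
  v3 <- ruleV(rulesOf(maj3)$X)
  # 2 activators ON, 1 inhibitor ON (pattern 111) -> ON
  expect_equal(v3[8], 1)
  # equal counts (pattern 101: A1 on, I1 on) -> OFF ("more" is strict)
  expect_equal(v3[6], 0)
  # unsigned edges are rejected
  netU <- TFNetwork(c("A", "X"), data.frame(source = "A", target = "X"))
  expect_error(baselineRules(netU, "majority"), "unsigned")
})

test_that("attractor set is invariant to the exploration origin", {
  fx <- bbFixtures()$toggle_switch
  a1 <- findPseudoAttractors(fx$rules, c(A = 0L, B = 0L),
                             searchConfig(radius = 2))
  a2 <- findPseudoAttractors(fx$rules, c(A = 1L, B = 1L),
                             searchConfig(radius = 2))
  expect_identical(attractorStates(a1), attractorStates(a2))
})
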