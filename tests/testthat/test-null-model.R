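test_that("switch proposals follow the head-exchange case analysis exactly", {
  # disjoint pair: swap always possible
  net <- two_disjoint()
  pr <- switchProposal(net, 1, 2)
  expect_true(pr$accepted)
  expect_equal(canonicalKey(pr$network), "A>D|C>B")

  # reciprocal pair: proposal creates two loops, rejected
  rec <- LabeledNetwork(c("A", "B"), rbind(c("A", "B"), c("B", "A")))
  pr <- switchProposal(rec, 1, 2)
  expect_false(pr$accepted)
  expect_equal(pr$reason, "loop")
  expect_true(net_equal(pr$network, rec))

  # shared head: proposal equals the current edge set, accepted no-op
  shared <- LabeledNetwork(c("A", "B", "C"), rbind(c("A", "B"), c("C", "B")))
  pr <- switchProposal(shared, 1, 2)
  expect_true(pr$accepted)
  expect_equal(pr$reason, "self")
  expect_true(net_equal(pr$network, shared))

  # multi-edge conflict
  conf <- LabeledNetwork(c("A", "B", "C", "D"),
                         rbind(c("A", "B"), c("C", "D"), c("A", "D")))
  pr <- switchProposal(conf, 1, 2)  # proposes A>D which already exists
  expect_false(pr$accepted)
  expect_equal(pr$reason, "multi-edge")

  single <- LabeledNetwork(c("A", "B"), rbind(c("A", "B")))
  expect_error(switchProposal(single, 1, 2), "chain undefined")
  expect_error(attemptEdgeSwitch(single), "chain undefined")
})

test_that("the directed 3-cycle is a fixed point of the chain", {
  tri <- tri_cycle()
  # exhaustively: all three unordered edge pairs propose loops
  for (i in 1:2) for (j in (i + 1):3) {
    pr <- switchProposal(tri, i, j)
    expect_false(pr$accepted)
    expect_equal(pr$reason, "loop")
  }
  expect_equal(switchSpace(tri), canonicalKey(tri))
  # sampled chains agree
  for (seed in 1:5)
    expect_true(net_equal(randomizeNetwork(tri, 100, seed = seed), tri))
  ens <- generateEnsemble(tri, M = 20, Q = 50, seed = 3)
  expect_true(all(vapply(realizations(ens), net_equal, logical(1), b = tri)))
})

test_that("the two-edge disjoint network has exactly two reachable states", {
  two <- two_disjoint()
  expect_equal(switchSpace(two), c("A>B|C>D", "A>D|C>B"))
  # with attempt counts of both parities the sampler reaches both states
  d <- estimateDistinctLowerBound(two, Qgrid = c(0.5, 1), NperQ = 30, seed = 2)
  expect_equal(d$nDistinct, 2L)
  # Q = 0 performs no attempts
  expect_true(net_equal(randomizeNetwork(two, 0, seed = 1), two))
})

test_that("randomization preserves degree sequences and simplicity exactly", {
  set.seed(71)
  for (r in 1:40) {
    net <- rnet(sample(5:9, 1), runif(1, 0.1, 0.5))
    if (edgeCount(net) < 2) next
    Q <- sample(c(1, 10, 100), 1)
    out <- randomizeNetwork(net, Q, seed = 1000 + r)
    expect_identical(degreeSequence(out), degreeSequence(net))
    # simplicity: constructor validity would reject loops/multi-edges, so
    # recheck on the raw edge matrix
    e <- out@edges
    expect_false(any(e[, 1] == e[, 2]))
    expect_false(anyDuplicated(paste(e[, 1], e[, 2])) > 0)
  }
  # m < 2: chain undefined, input returned with a warning
  single <- LabeledNetwork(c("A", "B", "C"), rbind(c("A", "B")))
  expect_warning(out <- randomizeNetwork(single, 10, seed = 1), "fewer than 2")
  expect_true(net_equal(out, single))
})

test_that("ensembles are deterministic under a seed and consistent across code paths", {
  net <- rnet(7, 0.3)
  e1 <- generateEnsemble(net, M = 5, Q = 20, seed = 42)
  e2 <- generateEnsemble(net, M = 5, Q = 20, seed = 42)
  for (r in 1:5)
    expect_true(net_equal(realizations(e1)[[r]], realizations(e2)[[r]]))
  # realization r of an ensemble equals a single chain run on stream r
  for (r in 1:5)
    expect_true(net_equal(realizations(e1)[[r]],
                          randomizeNetwork(net, 20, seed = 42, stream = r - 1)))
  e3 <- generateEnsemble(net, M = 5, Q = 20, seed = 43)
  expect_false(all(vapply(1:5, function(r)
    net_equal(realizations(e1)[[r]], realizations(e3)[[r]]), logical(1))))
  # degree sequences identical to the input across a larger ensemble
  big <- generateEnsemble(rnet(9, 0.35), M = 100, Q = 30, seed = 7)
  src_ds <- degreeSequence(realizations(big)[[1]])
  expect_true(all(vapply(realizations(big), function(x)
    identical(degreeSequence(x), src_ds), logical(1))))
})

test_that("representative selection minimizes the max-norm distance to the mean degrees", {
  labs <- c("A", "B", "C")
  n1 <- LabeledNetwork(labs, rbind(c("A", "B")))
  n2 <- LabeledNetwork(labs, rbind(c("A", "B"), c("B", "C")))
  n3 <- LabeledNetwork(labs, rbind(c("A", "B"), c("B", "C"), c("C", "A")))
  expect_equal(selectRepresentative(NetworkSample(list(n1, n2, n3))), 2L)
  expect_equal(selectRepresentative(NetworkSample(list(n2, n2, n2))), 1L)
  expect_equal(selectRepresentative(NetworkSample(list(n3))), 1L)
})

test_that("the performance index follows the goodness-of-fit formula", {
  expect_equal(performanceIndex(c(2, 2), 4, 0.5), 0)
  expect_equal(performanceIndex(c(3, 1), 4, 0.5), 1.0)
  expect_equal(performanceIndex(c(4, 0), 4, 0.5), 4.0)
  # unobserved categories contribute their expected count
  expect_equal(performanceIndex(c(4), 4, 0.5), 4.0)
  expect_equal(performanceIndex(c(10, 5, 3), 18, 1 / 6),
               sum((c(10, 5, 3, 0, 0, 0) - 3)^2 / 3))
  expect_error(performanceIndex(c(1), 0, 0.5), "N must be positive")
  expect_error(performanceIndex(c(1), 4, 0), "p0")
})

test_that("Monte-Carlo quantiles approach the chi-squared limit and are reproducible", {
  q <- mcQuantile(2, 10000, 0.5, 0.05, reps = 10000, seed = 1)
  expect_lt(abs(q - stats::qchisq(0.95, df = 1)), 0.15)
  expect_identical(q, mcQuantile(2, 10000, 0.5, 0.05, reps = 10000, seed = 1))
  expect_gte(mcQuantile(3, 50, 1 / 3, 1, reps = 500, seed = 2), 0)
})

test_that("mixing calibration certifies uniformity on a brute-forced space", {
  # all in/out degrees 1 on 4 vertices: the space is the 9 derangements
  cyc4 <- four_cycle()
  space <- oracle_degseq_space(cyc4)
  expect_length(space, 9)
  d <- estimateDistinctLowerBound(cyc4, Qgrid = 100, NperQ = 450, seed = 11)
  expect_setequal(unique(c(names(d$perQ[[1]]), d$inputKey)), space)
  um <- estimateMixingParameter(cyc4, Qgrid = 100, NperQ = 450,
                                alpha = 0.05, reps = 2000, seed = 11)
  expect_true(um$uniform)
  expect_equal(um$chosen_Q, 100)
  expect_equal(um$n_distinct, 9L)

  # degenerate single-category space
  um_tri <- estimateMixingParameter(tri_cycle(), Qgrid = c(10, 100),
                                    NperQ = 50, seed = 3)
  expect_true(um_tri$uniform)
  expect_equal(um_tri$n_distinct, 1L)
  expect_true(all(um_tri$X2_per_Q == 0))

  # Q = 0 on a switchable network: the chain never moves, which must not be
  # mistaken for a genuinely one-state space
  um0 <- estimateMixingParameter(two_disjoint(), Qgrid = 0, NperQ = 100, seed = 5)
  expect_equal(um0$n_distinct, 1L)  # pooled set is just the input network
  expect_false(um0$uniform)
  expect_equal(um0$chosen_Q, 0)
})

test_that("ensemble-size estimation accepts the smallest converged bootstrap count", {
  # identity randomization (3-cycles): all distributions coincide
  tris <- NetworkSample(list(tri_cycle(), tri_cycle(), tri_cycle()), name = "tris")
  es <- estimateEnsembleSize(tris, k = 2, Q = 50, Bgrid = c(2, 5), Bmax = 10,
                             epsilon = 0.01, seed = 1)
  expect_equal(es$Bstar, 2L)
  expect_true(all(es$distances == 0))

  s <- generateSample(sampleSize = 6, pBase = 0.2, seed = 8)
  # epsilon = 1 is always satisfied by relative frequencies
  es1 <- estimateEnsembleSize(s, k = 2, Q = 10, Bgrid = c(2, 4), Bmax = 8,
                              epsilon = 1, seed = 2)
  expect_equal(es1$Bstar, 2L)
  # epsilon ~ 0 on a stochastic ensemble forces the reference size
  es0 <- estimateEnsembleSize(s, k = 2, Q = 10, Bgrid = c(2, 4), Bmax = 8,
                              epsilon = 1e-12, seed = 2)
  expect_equal(es0$Bstar, 8L)
  expect_false(es0$accepted)
})

test_that("random-digraph nulls preserve what they claim and nothing more", {
  net <- rnet(9, 0.3)
  m <- edgeCount(net)
  gm <- gnpNull(net, "gnm", seed = 4)
  expect_equal(edgeCount(gm), m)

  empty <- LabeledNetwork(LETTERS[1:5])
  expect_equal(edgeCount(gnpNull(empty, "gnp", seed = 1)), 0L)

  labs <- eegLabels()
  pairs <- as.matrix(expand.grid(t = labs, h = labs, stringsAsFactors = FALSE))
  pairs <- pairs[pairs[, 1] != pairs[, 2], ]
  complete <- LabeledNetwork(labs, pairs)
  expect_equal(edgeCount(gnpNull(complete, "gnp", seed = 1)), 72L)

  # gnp mean edge count equals m within 3 standard errors
  ms <- vapply(1:1000, function(s) edgeCount(gnpNull(net, "gnp", seed = s)),
               integer(1))
  p <- m / 72
  se <- sqrt(72 * p * (1 - p) / 1000)
  expect_lt(abs(mean(ms) - m), 3 * se)
})
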