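test_that("network validation accepts simple digraphs and reports violations", {
  ok <- validateNetwork(c("A", "B"), rbind(c("A", "B")))
  expect_true(ok$valid)
  expect_length(ok$violations, 0)

  loop <- validateNetwork(c("A", "B"), rbind(c("A", "A")))
  expect_false(loop$valid)
  expect_match(loop$violations, "loop", all = FALSE)

  unknown <- validateNetwork(c("A", "B"), rbind(c("A", "X")))
  expect_false(unknown$valid)
  expect_match(unknown$violations, "unknown", all = FALSE)

  multi <- validateNetwork(c("A", "B", "C"),
                           rbind(c("A", "B"), c("A", "B"), c("B", "C")))
  expect_false(multi$valid)
  expect_match(multi$violations, "duplicate edges", all = FALSE)

  # constructors enforce the same invariants
  expect_error(LabeledNetwork(c("A", "B"), rbind(c("A", "A"))), "loop")
  expect_error(LabeledNetwork(c("A", "B"), rbind(c("A", "X"))), "unknown")
  expect_warning(net <- LabeledNetwork(c("A", "B"), rbind(c("A", "B"), c("A", "B"))),
                 "duplicate")
  expect_equal(edgeCount(net), 1L)
})

test_that("degree sequences sum to the edge count and match hand values", {
  net <- LabeledNetwork(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  ds <- degreeSequence(net)
  expect_equal(ds$out_deg, c(A = 1L, B = 1L, C = 0L))
  expect_equal(ds$in_deg, c(A = 0L, B = 1L, C = 1L))

  empty <- LabeledNetwork(c("A", "B", "C"))
  ds0 <- degreeSequence(empty)
  expect_true(all(ds0$in_deg == 0) && all(ds0$out_deg == 0))

  # complete digraph on the 9-electrode geometry: 72 possible directed
  # interactions, every in- and out-degree 8
  labs <- eegLabels()
  pairs <- as.matrix(expand.grid(t = labs, h = labs, stringsAsFactors = FALSE))
  pairs <- pairs[pairs[, 1] != pairs[, 2], ]
  complete <- LabeledNetwork(labs, pairs)
  expect_equal(edgeCount(complete), 72L)
  dsc <- degreeSequence(complete)
  expect_true(all(dsc$in_deg == 8L) && all(dsc$out_deg == 8L))

  # invariant over random networks
  set.seed(11)
  for (r in 1:20) {
    net <- rnet(sample(3:8, 1), runif(1, 0, 0.5))
    ds <- degreeSequence(net)
    expect_equal(sum(ds$in_deg), edgeCount(net))
    expect_equal(sum(ds$out_deg), edgeCount(net))
  }
})

test_that("induced subnetworks follow induced-edge-set semantics with weak connectivity", {
  net <- LabeledNetwork(c("F3", "Fz", "F4"), rbind(c("F3", "Fz"), c("Fz", "F4")))
  sub <- inducedSubnetwork(net, c("F3", "Fz"))
  expect_s4_class(sub, "LabeledSubnetwork")
  expect_equal(canonicalKey(sub), "F3>Fz")

  expect_null(inducedSubnetwork(net, c("F3", "F4")))  # no edges, not connected

  sub3 <- inducedSubnetwork(net, c("F3", "Fz", "F4"))
  expect_equal(canonicalKey(sub3), "F3>Fz|Fz>F4")

  expect_error(inducedSubnetwork(net, c("F3", "XX")), "unknown")
  expect_error(inducedSubnetwork(net, c("F3", "F3")), "duplicate")
  expect_error(inducedSubnetwork(net, "F3"), "at least 2")
})

test_that("weak connectivity matches the definition and an igraph recheck", {
  expect_true(isWeaklyConnected(c("A", "B", "C"), rbind(c("A", "B"), c("C", "B"))))
  expect_false(isWeaklyConnected(c("A", "B", "C"), rbind(c("A", "B"))))
  expect_false(isWeaklyConnected(c("A", "B"), matrix(character(), ncol = 2)))

  # induced_subnetwork is absent exactly when an independent undirected
  # connectivity check fails
  set.seed(23)
  for (r in 1:25) {
    n <- sample(4:7, 1)
    net <- rnet(n, runif(1, 0.1, 0.5))
    k <- sample(2:min(4, n), 1)
    verts <- sample(vertexLabels(net), k)
    el <- edgeLabels(net)
    keep <- el[, 1] %in% verts & el[, 2] %in% verts
    g <- igraph::graph_from_data_frame(
      data.frame(from = el[keep, 1], to = el[keep, 2]), directed = FALSE,
      vertices = data.frame(name = verts))
    oracle_connected <- igraph::is_connected(g)
    expect_identical(is.null(inducedSubnetwork(net, verts)), !oracle_connected)
  }
})

test_that("canonical keys are order-independent, direction-aware and collision-free", {
  expect_equal(canonicalKey(rbind(c("Fz", "F4"), c("F3", "Fz"))), "F3>Fz|Fz>F4")
  expect_equal(canonicalKey(rbind(c("F3", "Fz"), c("Fz", "F4"))), "F3>Fz|Fz>F4")
  expect_false(canonicalKey(rbind(c("A", "B"))) == canonicalKey(rbind(c("B", "A"))))

  # injectivity: random pairs of distinct edge sets over <= 9 labels never collide
  set.seed(7)
  labs <- eegLabels()
  pairs <- as.matrix(expand.grid(t = labs, h = labs, stringsAsFactors = FALSE))
  pairs <- pairs[pairs[, 1] != pairs[, 2], ]
  for (r in 1:100) {
    i1 <- sort(sample(nrow(pairs), sample(1:8, 1)))
    i2 <- sort(sample(nrow(pairs), sample(1:8, 1)))
    e1 <- pairs[i1, , drop = FALSE]
    e2 <- pairs[i2, , drop = FALSE]
    if (identical(i1, i2)) next
    expect_false(canonicalKey(e1) == canonicalKey(e2))
  }
})

test_that("edge-list and fixture round trips preserve edge and label sets", {
  dir <- withr::local_tempdir()
  labs <- c("F3", "Fz", "F4")
  net <- LabeledNetwork(labs, rbind(c("F3", "Fz"), c("Fz", "F4"), c("F4", "F3")))
  p <- file.path(dir, "net.tsv")
  writeNetworkEdgelist(net, p)
  back <- readNetworkEdgelist(p, labs)
  expect_true(net_equal(net, back))

  # empty edge set and isolated vertices survive via the manifest label set
  empty <- LabeledNetwork(labs)
  writeNetworkEdgelist(empty, p)
  expect_equal(edgeCount(readNetworkEdgelist(p, labs)), 0L)

  sample1 <- generateSample(sampleSize = 16, pBase = 0.15, seed = 99, name = "rt")
  manifest <- writeFixture(sample1, file.path(dir, "fix"))
  back2 <- readSample(manifest)
  expect_equal(sampleName(back2), "rt")
  expect_equal(sampleSize(back2), 16L)
  expect_identical(vertexLabels(back2), vertexLabels(sample1))
  for (i in seq_len(16))
    expect_true(net_equal(sample1[[i]], back2[[i]]))
})

test_that("malformed edge lists and manifests fail with descriptive errors", {
  dir <- withr::local_tempdir()
  labs <- c("F3", "Fz", "F4")

  p <- file.path(dir, "bad.tsv")
  writeLines("F3", p)
  expect_error(readNetworkEdgelist(p, labs), "line 1")

  writeLines(c("# comment", "F3\tF3"), p)
  expect_error(readNetworkEdgelist(p, labs), "loop")

  writeLines(c("F3\tFz", "F3\tFz"), p)
  expect_warning(net <- readNetworkEdgelist(p, labs), "duplicate")
  expect_equal(edgeCount(net), 1L)

  writeLines("F3\tXX", p)
  expect_error(readNetworkEdgelist(p, labs), "unknown label")

  man <- file.path(dir, "man.yaml")
  yaml::write_yaml(list(name = "s", labels = as.list(labs),
                        networks = list()), man)
  expect_error(readSample(man), "empty sample")

  # a failing network aborts the whole sample load
  writeLines("F3\tF3", file.path(dir, "n1.tsv"))
  yaml::write_yaml(list(name = "s", labels = as.list(labs),
                        networks = list("n1.tsv")), man)
  expect_error(readSample(man), "loop")
})
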