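# Independent oracles and small fixture builders used across the suite.
# Oracles deliberately avoid the package's own code paths: enumeration goes
# through igraph, tail probabilities through outcome enumeration, topology
# counts through the component recurrence, degree-sequence spaces through
# arc-subset generation.

# random simple digraph on n labeled vertices with edge probability p
rnet <- function(n, p, labels = LETTERS[seq_len(n)]) {
  pairs <- as.matrix(expand.grid(seq_len(n), seq_len(n)))
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  keep <- stats::runif(nrow(pairs)) < p
  e <- matrix(labels[pairs[keep, , drop = FALSE]], ncol = 2)
  LabeledNetwork(labels, e)
}

key_of <- function(edgeChar) {
  if (nrow(edgeChar) == 0) return("")
  paste(sort(paste0(edgeChar[, 1], ">", edgeChar[, 2]), method = "radix"),
        collapse = "|")
}

# igraph-based subset-scan enumeration oracle with an independent
# weak-connectivity check
oracle_enumerate <- function(net, k) {
  labs <- vertexLabels(net)
  el <- edgeLabels(net)
  g <- igraph::graph_from_data_frame(
    data.frame(from = el[, 1], to = el[, 2]), directed = TRUE,
    vertices = data.frame(name = labs))
  combs <- utils::combn(labs, k)
  keys <- character()
  for (ci in seq_len(ncol(combs))) {
    sg <- igraph::induced_subgraph(g, combs[, ci])
    if (igraph::ecount(sg) == 0) next
    if (!igraph::is_connected(sg, mode = "weak")) next
    sel <- igraph::as_edgelist(sg)
    keys <- c(keys, key_of(matrix(sel, ncol = 2)))
  }
  sort(unique(keys), method = "radix")
}

# exact Poisson-binomial upper tail by enumerating all 2^n outcomes
oracle_pb_tail <- function(q, cObs) {
  n <- length(q)
  total <- 0
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    if (sum(bits) < cObs) next
    total <- total + prod(ifelse(bits == 1, q, 1 - q))
  }
  total
}

# weakly connected labeled digraph counts via the component recurrence:
# C(k) = D(k) - sum_j C(j) * choose(k-1, j-1) * D(k-j), D(k) = 2^(k(k-1))
oracle_connected_counts <- function(kmax) {
  D <- function(k) 2^(k * (k - 1))
  C <- numeric(kmax)
  C[1] <- 1
  for (k in 2:kmax)
    C[k] <- D(k) - sum(vapply(1:(k - 1), function(j)
      C[j] * choose(k - 1, j - 1) * D(k - j), numeric(1)))
  C
}

# all simple digraphs sharing the degree sequence of `net`, as full-network
# canonical keys, by exhaustive generation over arc subsets of size m
oracle_degseq_space <- function(net) {
  labs <- vertexLabels(net)
  n <- length(labs)
  m <- edgeCount(net)
  ds <- degreeSequence(net)
  arcs <- as.matrix(expand.grid(seq_len(n), seq_len(n)))
  arcs <- arcs[arcs[, 1] != arcs[, 2], , drop = FALSE]
  combs <- utils::combn(nrow(arcs), m)
  keys <- character()
  for (ci in seq_len(ncol(combs))) {
    idx <- combs[, ci]
    out_deg <- tabulate(arcs[idx, 1], nbins = n)
    in_deg <- tabulate(arcs[idx, 2], nbins = n)
    if (all(out_deg == unname(ds$out_deg)) &&
        all(in_deg == unname(ds$in_deg)))
      keys <- c(keys, key_of(matrix(labs[arcs[idx, , drop = FALSE]], ncol = 2)))
  }
  sort(keys, method = "radix")
}

# frequently used toy networks
tri_cycle <- function()
  LabeledNetwork(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C"), c("C", "A")))
two_disjoint <- function()
  LabeledNetwork(c("A", "B", "C", "D"), rbind(c("A", "B"), c("C", "D")))
four_cycle <- function()
  LabeledNetwork(c("A", "B", "C", "D"),
                 rbind(c("A", "B"), c("B", "C"), c("C", "D"), c("D", "A")))

net_equal <- function(a, b) {
  identical(vertexLabels(a), vertexLabels(b)) &&
    identical(canonicalKey(a), canonicalKey(b))
}
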