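# Degree-sequence-preserving null model by edge switching, and the
# calibration procedures for its mixing parameter Q and the ensemble size.
#
# The chain move picks two distinct directed edges uniformly at random and
# exchanges their heads; the proposal is rejected (a self-transition, still
# counted as an attempt) if it would create a loop or a multi-edge. One
# randomization performs round(Q * m) attempts, m the number of edges.
# The chain preserves the in- and out-degree sequence exactly but is not
# irreducible for every degree sequence (the directed 3-cycle never moves);
# Q is therefore calibrated empirically with a uniformity check rather than
# assumed adequate.

# deterministic per-(element, purpose) seed derivation, kept below 2^31
.deriveSeed <- function(seed, i, j = 0) {
  ((seed %% 2147483647) + 2654435761 * (i %% 65536) + 97561 * j) %% 2147483647
}

#' Evaluate one edge-switch proposal deterministically
#'
#' Applies the head-exchange move to the edge pair (i, j) of the network:
#' edges (t1,h1), (t2,h2) become (t1,h2), (t2,h1). The proposal is rejected
#' if it would create a loop or a multi-edge; a proposal identical to the
#' current edge set (shared head or shared tail) is accepted as a
#' self-transition. Exposed so the move's case analysis can be verified
#' exhaustively (e.g. the directed 3-cycle is a fixed point: all three edge
#' pairs propose loops).
#'
#' @param x a [LabeledNetwork-class] with at least 2 edges.
#' @param i,j distinct edge indices in 1..m.
#' @return list with `accepted` (logical), `reason` ("ok", "self",
#'   "loop" or "multi-edge") and `network` (the post-move network; equal to
#'   the input when rejected or when the accepted proposal is a no-op).
#' @export
switchProposal <- function(x, i, j) {
  stopifnot(is(x, "LabeledNetwork"))
  m <- nrow(x@edges)
  if (m < 2L) stop("chain undefined: fewer than 2 edges")
  stopifnot(i != j, i >= 1L, j >= 1L, i <= m, j <= m)
  e <- x@edges
  t1 <- e[i, 1L]; h1 <- e[i, 2L]
  t2 <- e[j, 1L]; h2 <- e[j, 2L]
  if (t1 == h2 || t2 == h1)
    return(list(accepted = FALSE, reason = "loop", network = x))
  if (h1 == h2 || t1 == t2)
    return(list(accepted = TRUE, reason = "self", network = x))
  pairs <- paste(e[, 1L], e[, 2L])
  if (paste(t1, h2) %in% pairs || paste(t2, h1) %in% pairs)
    return(list(accepted = FALSE, reason = "multi-edge", network = x))
  e[i, 2L] <- h2
  e[j, 2L] <- h1
  list(accepted = TRUE, reason = "ok",
       network = new("LabeledNetwork", labels = x@labels, edges = e))
}

#' Perform one random switch attempt
#'
#' Selects two distinct edges uniformly at random (using R's RNG) and
#' evaluates the head-exchange proposal via [switchProposal].
#'
#' @param x a [LabeledNetwork-class] with at least 2 edges.
#' @return as [switchProposal], plus `pair`, the selected edge indices.
#' @export
attemptEdgeSwitch <- function(x) {
  m <- edgeCount(x)
  if (m < 2L) stop("chain undefined: fewer than 2 edges")
  pair <- sample.int(m, 2L)
  out <- switchProposal(x, pair[1L], pair[2L])
  out$pair <- pair
  out
}

#' Exact reachable state space of the switch chain
#'
#' Breadth-first search over the chain's proposal graph: from each reached
#' state every unordered edge pair's head-exchange proposal is evaluated
#' with [switchProposal]. Returns the canonical keys of all reachable
#' networks — the chain's communicating class containing the input. Because
#' the chain is not irreducible for every degree sequence (the directed
#' 3-cycle reaches only itself), this can be a strict subset of all networks
#' with the input's degree sequence.
#'
#' @param x a [LabeledNetwork-class] with at least 2 edges.
#' @param maxStates safety cap; exceeding it is an error (the space is only
#'   enumerable for small, sparse networks).
#' @return sorted character vector of full-network canonical keys.
#' @export
switchSpace <- function(x, maxStates = 10000L) {
  stopifnot(is(x, "LabeledNetwork"), edgeCount(x) >= 2L)
  seen <- new.env(parent = emptyenv())
  queue <- list(x)
  assign(canonicalKey(x), TRUE, envir = seen)
  while (length(queue)) {
    cur <- queue[[1L]]
    queue <- queue[-1L]
    m <- edgeCount(cur)
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      prop <- switchProposal(cur, i, j)
      if (!prop$accepted || prop$reason == "self") next
      key <- canonicalKey(prop$network)
      if (!exists(key, envir = seen)) {
        if (length(ls(seen)) >= maxStates)
          stop("switch space exceeds maxStates")
        assign(key, TRUE, envir = seen)
        queue[[length(queue) + 1L]] <- prop$network
      }
    }
  }
  sort(ls(seen), method = "radix")
}

#' Randomize a network by edge switching
#'
#' Runs round(Q * m) switch attempts (rejections included) from a fresh copy
#' of the network. The in- and out-degree sequence of the result equals the
#' input's exactly, and the result is always a simple digraph.
#'
#' @param x a [LabeledNetwork-class].
#' @param Q mixing parameter: attempts per edge.
#' @param seed integer seed; identical (x, Q, seed) give identical output.
#' @param stream internal stream index (realization number), used so that
#'   [generateEnsemble] realization r equals `randomizeNetwork(..., stream = r)`.
#' @return a [LabeledNetwork-class]. Networks with fewer than 2 edges are
#'   returned unchanged with a warning (no switch is possible).
#' @export
randomizeNetwork <- function(x, Q, seed = 1L, stream = 0L) {
  stopifnot(is(x, "LabeledNetwork"), Q >= 0)
  m <- nrow(x@edges)
  if (m < 2L) {
    warning("fewer than 2 edges: chain undefined, returning the input unchanged")
    return(x)
  }
  att <- round(Q * m)
  e <- cpp_run_chain(x@edges, length(x@labels), att, as.double(seed),
                     as.integer(stream))
  colnames(e) <- c("tail", "head")
  new("LabeledNetwork", labels = x@labels, edges = e)
}

#' Generate a null ensemble for one network
#'
#' M independent edge-switching chains, each restarted from the source
#' network and run for round(Q * m) attempts, with per-realization random
#' streams derived deterministically from `seed`.
#'
#' @param x a [LabeledNetwork-class].
#' @param M ensemble size (>= 1).
#' @param Q mixing parameter.
#' @param seed integer seed.
#' @param sourceIndex index of `x` within its sample (bookkeeping only).
#' @return a [NullEnsemble-class].
#' @export
generateEnsemble <- function(x, M, Q, seed = 1L, sourceIndex = 1L) {
  stopifnot(is(x, "LabeledNetwork"), M >= 1L)
  m <- nrow(x@edges)
  n <- length(x@labels)
  if (m < 2L) {
    warning("fewer than 2 edges: ensemble realizations equal the input")
    nets <- rep(list(x), M)
  } else {
    att <- round(Q * m)
    stacked <- cpp_ensemble_edges(x@edges, n, as.integer(M), att,
                                  as.double(seed))
    nets <- lapply(seq_len(M), function(r) {
      e <- stacked[((r - 1L) * m + 1L):(r * m), , drop = FALSE]
      colnames(e) <- c("tail", "head")
      new("LabeledNetwork", labels = x@labels, edges = e)
    })
  }
  new("NullEnsemble", sourceIndex = as.integer(sourceIndex), Q = as.numeric(Q),
      realizations = nets, seed = as.integer(seed))
}

#' @describeIn generateEnsemble list of realization networks
#' @export
setMethod("realizations", "NullEnsemble", function(x) x@realizations)

setMethod("show", "NullEnsemble", function(object) {
  cat(sprintf("NullEnsemble: %d realizations of element %d (Q = %g, seed = %d)\n",
              length(object@realizations), object@sourceIndex, object@Q,
              object@seed))
})

# full-network canonical keys of M realizations, without materializing
# LabeledNetwork objects (used by the calibration procedures)
.ensembleKeys <- function(x, M, Q, seed) {
  m <- nrow(x@edges)
  if (m < 2L) return(rep(canonicalKey(x), M))
  att <- round(Q * m)
  stacked <- cpp_ensemble_edges(x@edges, length(x@labels), as.integer(M),
                                att, as.double(seed))
  toks <- paste0(x@labels[stacked[, 1L]], ">", x@labels[stacked[, 2L]])
  tokmat <- matrix(toks, nrow = m)
  vapply(seq_len(M), function(r) .keyFromTokens(tokmat[, r]), character(1))
}

# does any edge pair admit an accepted, state-changing switch?
.canSwitch <- function(x) {
  m <- edgeCount(x)
  if (m < 2L) return(FALSE)
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m)
    if (switchProposal(x, i, j)$reason == "ok") return(TRUE)
  FALSE
}

#' Select the sample's representative network
#'
#' Computes the per-label mean in-degree and mean out-degree over the sample
#' and returns the index of the element whose concatenated (in, out) degree
#' vector is closest to the mean vector in the maximum norm; ties are broken
#' by the lowest index. The representative is used to calibrate the mixing
#' parameter once per sample instead of per element.
#'
#' @param sample a [NetworkSample-class].
#' @return integer index into the sample (1-based).
#' @export
selectRepresentative <- function(sample) {
  stopifnot(is(sample, "NetworkSample"))
  degs <- lapply(sample@networks, function(net) {
    d <- degreeSequence(net)
    c(d$in_deg, d$out_deg)
  })
  degmat <- do.call(rbind, degs)
  meanvec <- colMeans(degmat)
  dists <- apply(abs(sweep(degmat, 2L, meanvec)), 1L, max)
  which.min(dists)  # which.min takes the first minimum: lowest-index tie-break
}

#' Chi-square-style uniformity performance index
#'
#' Goodness-of-fit statistic for the hypothesis that the randomization
#' generates every network with the prescribed degree sequence equally often:
#' X2 = sum over all categories (observed - N p0)^2 / (N p0), where each
#' category is one distinct network, p0 is the common category probability
#' under uniformity (1 / number of distinct networks) and categories never
#' observed contribute (0 - N p0)^2 / (N p0). The total number of categories
#' is round(1 / p0).
#'
#' @param counts integer vector of observed category counts (observed
#'   categories only; zero-count categories are implied by p0).
#' @param N total number of generated networks.
#' @param p0 assumed common category probability under uniformity.
#' @return the performance index X2.
#' @export
performanceIndex <- function(counts, N, p0) {
  if (N <= 0) stop("N must be positive")
  if (p0 <= 0 || p0 > 1) stop("p0 must lie in (0, 1]")
  C <- round(1 / p0)
  counts <- as.numeric(counts)
  if (length(counts) > C)
    stop("more observed categories than 1/p0 allows")
  exp0 <- N * p0
  sum((counts - exp0)^2 / exp0) + (C - length(counts)) * exp0
}

#' Monte-Carlo quantile of the performance index under uniformity
#'
#' The index is not guaranteed to be chi-squared distributed (expected
#' category counts are often far below the usual rules of thumb), so its
#' (1 - alpha) quantile under the uniform hypothesis is estimated by
#' simulating multinomial draws of N networks over `numCategories`
#' equiprobable categories.
#'
#' @param numCategories number of categories (distinct networks).
#' @param N networks per simulated draw.
#' @param p0 common category probability used in the index (normally
#'   1 / numCategories).
#' @param alpha significance level; the empirical (1 - alpha) quantile is
#'   returned (alpha = 1 gives the simulated minimum).
#' @param reps number of Monte-Carlo draws (>= 1000 recommended).
#' @param seed integer seed.
#' @return the empirical quantile.
#' @export
mcQuantile <- function(numCategories, N, p0, alpha, reps = 10000L, seed = 1L) {
  stopifnot(numCategories >= 1L, N >= 1L, reps >= 1L,
            alpha >= 0, alpha <= 1)
  set.seed(as.integer(seed))
  exp0 <- N * p0
  x2 <- numeric(reps)
  done <- 0L
  chunk <- max(1L, min(reps, floor(2e6 / numCategories)))
  while (done < reps) {
    nb <- min(chunk, reps - done)
    draws <- rmultinom(nb, N, rep(1 / numCategories, numCategories))
    x2[(done + 1L):(done + nb)] <- colSums((draws - exp0)^2) / exp0
    done <- done + nb
  }
  quantile(x2, probs = 1 - alpha, names = FALSE, type = 7)
}

#' Pooled lower bound on the number of networks with a degree sequence
#'
#' Generates `NperQ` realizations of the network for every Q in `Qgrid`,
#' pools all realizations together with the input network, and counts the
#' pairwise-different networks by full-network canonical key. Chains started
#' with different Q values explore different regions of the configuration
#' space, so pooling across Q gives a better lower bound than any single Q.
#' The input network is included in the pooled distinct set but excluded
#' from the per-Q category counts.
#'
#' @param x a [LabeledNetwork-class].
#' @param Qgrid mixing-parameter grid.
#' @param NperQ realizations per grid value.
#' @param seed integer seed.
#' @return list with `nDistinct`, `perQ` (one named count table per Q, by
#'   canonical key) and `inputKey`.
#' @export
estimateDistinctLowerBound <- function(x, Qgrid, NperQ, seed = 1L) {
  stopifnot(is(x, "LabeledNetwork"), length(Qgrid) >= 1L, NperQ >= 1L)
  perQ <- vector("list", length(Qgrid))
  names(perQ) <- as.character(Qgrid)
  all_keys <- character()
  for (qi in seq_along(Qgrid)) {
    keys <- .ensembleKeys(x, NperQ, Qgrid[qi], .deriveSeed(seed, qi))
    tab <- table(keys)
    perQ[[qi]] <- setNames(as.integer(tab), names(tab))
    all_keys <- unique(c(all_keys, names(tab)))
  }
  inputKey <- canonicalKey(x)
  list(nDistinct = length(unique(c(all_keys, inputKey))),
       perQ = perQ, inputKey = inputKey)
}

#' Calibrate the mixing parameter Q
#'
#' For each Q in the (ascending) grid, `NperQ` realizations are generated
#' and their category counts over the distinct generated networks are scored
#' with [performanceIndex], using p0 = 1 / (pooled distinct-network count) —
#' a lower bound on the true space size, so the index is conservative in an
#' unknown direction. The smallest Q whose index falls below the Monte-Carlo
#' (1 - alpha) quantile is selected; if no Q passes, the Q minimizing the
#' index is returned with `uniform = FALSE`. A degenerate single-category
#' space (the chain cannot move) short-circuits to uniform with X2 = 0.
#'
#' @inheritParams estimateDistinctLowerBound
#' @param alpha level for the uniformity check.
#' @param reps Monte-Carlo draws for the quantile.
#' @return a `uniformityReport` list: `Q_grid`, `X2_per_Q`, `quantile`,
#'   `chosen_Q`, `uniform`, `n_distinct`, `p0`, `N_per_Q`.
#' @export
estimateMixingParameter <- function(x, Qgrid = c(1, 3, 10, 30, 100, 300),
                                    NperQ = 1000L, alpha = 0.05,
                                    reps = 2000L, seed = 1L) {
  stopifnot(!is.unsorted(Qgrid))
  pooled <- estimateDistinctLowerBound(x, Qgrid, NperQ, seed = seed)
  S <- pooled$nDistinct
  if (S == 1L) {
    # one observed category: either the chain genuinely cannot move (a
    # single communicating class, e.g. the directed 3-cycle — trivially
    # uniform) or it was never given the chance (e.g. Q = 0 on a network
    # with available switches — non-uniform, lowest Q by the fallback rule)
    stuck <- !.canSwitch(x)
    rep_out <- list(Q_grid = Qgrid, X2_per_Q = rep(0, length(Qgrid)),
                    quantile = 0, chosen_Q = Qgrid[1L], uniform = stuck,
                    n_distinct = 1L, p0 = 1, N_per_Q = NperQ)
    class(rep_out) <- "uniformityReport"
    return(rep_out)
  }
  p0 <- 1 / S
  x2 <- vapply(pooled$perQ, performanceIndex, numeric(1), N = NperQ, p0 = p0)
  qtl <- mcQuantile(S, NperQ, p0, alpha, reps = reps,
                    seed = .deriveSeed(seed, 0L, 1L))
  pass <- x2 <= qtl
  if (any(pass)) {
    chosen <- Qgrid[which(pass)[1L]]
    uniform <- TRUE
  } else {
    chosen <- Qgrid[which.min(x2)]
    uniform <- FALSE
  }
  out <- list(Q_grid = Qgrid, X2_per_Q = unname(x2), quantile = qtl,
              chosen_Q = chosen, uniform = uniform, n_distinct = S,
              p0 = p0, N_per_Q = NperQ)
  class(out) <- "uniformityReport"
  out
}

#' @export
print.uniformityReport <- function(x, ...) {
  cat("Edge-switching uniformity calibration\n")
  cat(sprintf("  distinct networks (pooled lower bound): %d\n", x$n_distinct))
  cat(sprintf("  MC (1-alpha) quantile of X2: %.3f\n", x$quantile))
  for (i in seq_along(x$Q_grid))
    cat(sprintf("  Q = %6g: X2 = %.3f\n", x$Q_grid[i], x$X2_per_Q[i]))
  cat(sprintf("  chosen Q = %g (uniform sampling %s)\n", x$chosen_Q,
              if (x$uniform) "supported" else "NOT supported; minimal-X2 fallback"))
  invisible(x)
}

#' Estimate the required ensemble size by bootstrap convergence
#'
#' Builds a reference distribution of relative k-subnetwork frequencies from
#' `Bmax` bootstrap ensembles of the sample (each bootstrap ensemble = one
#' degree-preserving randomization of every sample element) and compares it
#' to the distributions obtained from the first B bootstrap ensembles for
#' each B in `Bgrid`. The smallest B whose sup-norm distance to the
#' reference is at most `epsilon` is returned; if none passes, `Bmax`.
#'
#' @param sample a [NetworkSample-class].
#' @param k subnetwork size for the frequency distributions.
#' @param Q mixing parameter for the randomizations.
#' @param Bgrid ascending candidate ensemble sizes, all < Bmax.
#' @param Bmax reference ensemble size.
#' @param epsilon sup-norm acceptance bound on relative frequencies.
#' @param seed integer seed.
#' @return list with `Bstar`, `distances` (named by Bgrid), `accepted`
#'   (logical), `epsilon`.
#' @export
estimateEnsembleSize <- function(sample, k, Q, Bgrid, Bmax, epsilon,
                                 seed = 1L) {
  stopifnot(is(sample, "NetworkSample"), !is.unsorted(Bgrid),
            max(Bgrid) < Bmax, epsilon > 0)
  S <- length(sample@networks)
  n <- length(sample@labels)
  # per-bootstrap-ensemble key tallies
  tallies <- vector("list", Bmax)
  for (b in seq_len(Bmax)) {
    keys <- unlist(lapply(seq_len(S), function(i) {
      net <- sample@networks[[i]]
      if (nrow(net@edges) < 2L) rnd <- net
      else {
        e <- cpp_run_chain(net@edges, n, round(Q * nrow(net@edges)),
                           .deriveSeed(seed, i, b), 0L)
        colnames(e) <- c("tail", "head")
        rnd <- new("LabeledNetwork", labels = net@labels, edges = e)
      }
      enumerateSubnetworks(rnd, k)
    }))
    tab <- table(keys)
    tallies[[b]] <- setNames(as.integer(tab), names(tab))
  }
  all_keys <- unique(as.character(unlist(lapply(tallies, names))))
  cum <- matrix(0, nrow = length(all_keys), ncol = Bmax,
                dimnames = list(all_keys, NULL))
  run <- setNames(numeric(length(all_keys)), all_keys)
  for (b in seq_len(Bmax)) {
    tb <- tallies[[b]]
    if (length(tb)) run[names(tb)] <- run[names(tb)] + tb
    cum[, b] <- run
  }
  dref <- cum[, Bmax] / (Bmax * S)
  distances <- vapply(Bgrid, function(B) {
    if (!length(all_keys)) return(0)
    max(abs(cum[, B] / (B * S) - dref))
  }, numeric(1))
  names(distances) <- as.character(Bgrid)
  pass <- distances <= epsilon
  list(Bstar = if (any(pass)) as.integer(Bgrid[which(pass)[1L]]) else as.integer(Bmax),
       distances = distances, accepted = any(pass), epsilon = epsilon)
}

#' Random-digraph alternatives to the degree-preserving null
#'
#' Erdos-Renyi-style null models that preserve less structure than edge
#' switching: `"gnp"` includes each of the n(n-1) possible arcs independently
#' with p = m / (n(n-1)); `"gnm"` draws a uniform simple digraph with exactly
#' m arcs. The degree sequence is NOT preserved; these are provided for
#' comparison only (they tend to flag many more, less interpretable
#' patterns).
#'
#' @param x a [LabeledNetwork-class] supplying n and m.
#' @param variant `"gnp"` or `"gnm"`.
#' @param seed integer seed.
#' @return a [LabeledNetwork-class].
#' @export
gnpNull <- function(x, variant = c("gnp", "gnm"), seed = 1L) {
  stopifnot(is(x, "LabeledNetwork"))
  variant <- match.arg(variant)
  set.seed(as.integer(seed))
  n <- length(x@labels)
  m <- nrow(x@edges)
  pairs <- as.matrix(expand.grid(tail = seq_len(n), head = seq_len(n)))
  pairs <- pairs[pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  if (variant == "gnp") {
    p <- m / (n * (n - 1))
    keep <- runif(nrow(pairs)) < p
    e <- pairs[keep, , drop = FALSE]
  } else {
    e <- pairs[sample.int(nrow(pairs), m), , drop = FALSE]
  }
  e <- matrix(as.integer(e), ncol = 2L)
  colnames(e) <- c("tail", "head")
  new("LabeledNetwork", labels = x@labels, edges = e)
}

#' Number of bidirectional vertex pairs in a network
#'
#' Edge switching does not preserve this quantity; it is reported in run
#' metadata as a diagnostic rather than corrected.
#'
#' @param x a [LabeledNetwork-class].
#' @return integer count of unordered pairs connected in both directions.
#' @export
countBidirectional <- function(x) {
  stopifnot(is(x, "LabeledNetwork"))
  adj <- adjacencyMatrix(x)
  sum(adj & t(adj)) / 2L
}
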