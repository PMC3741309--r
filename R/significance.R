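# Significance assignment: per-element null occurrence probabilities, exact
# Poisson-binomial tail p-values, Bonferroni-Holm familywise control.
#
# The sample count of a candidate subnetwork is modelled as a sum of
# independent Bernoulli variables, one per sample element (elements are
# independent subjects), with each element's null occurrence probability
# estimated from its OWN degree-preserving ensemble. This respects
# per-network degree sequences and reduces to a binomial when all
# probabilities coincide. Testing is one-sided: only overrepresentation.

# candidate key -> (sorted vertex indices, induced-pattern bitmask) in the
# shared R/C++ convention: bits run over ordered pairs (i, j), i != j, of the
# sorted vertex list in row-major order
.candidateSpec <- function(keys, labels) {
  k <- length(.keyVertices(keys[1L]))
  V <- matrix(0L, nrow = length(keys), ncol = k)
  mask <- integer(length(keys))
  for (c in seq_along(keys)) {
    verts <- .keyVertices(keys[c])
    if (length(verts) != k)
      stop("candidate keys have inconsistent subnetwork sizes")
    vi <- sort(match(verts, labels))
    if (anyNA(vi)) stop("candidate key uses labels outside the sample's label set")
    edges <- .keyToEdges(keys[c])
    ti <- match(match(edges[, 1L], labels), vi)
    hi <- match(match(edges[, 2L], labels), vi)
    b <- 0L
    mk <- 0L
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i == j) next
      if (any(ti == i & hi == j)) mk <- bitwOr(mk, bitwShiftL(1L, b))
      b <- b + 1L
    }
    V[c, ] <- vi
    mask[c] <- mk
  }
  list(V = V, mask = mask, k = k)
}

# does network `net` contain candidate key as an *induced* subnetwork?
.containsInduced <- function(net, key) {
  verts <- .keyVertices(key)
  sub <- inducedSubnetwork(net, verts)
  !is.null(sub) && sub@key == key
}

#' Null occurrence probabilities of a subnetwork across a sample
#'
#' For each sample element i, q_i is the fraction of its ensemble
#' realizations whose induced subnetwork on the key's vertices equals the
#' key. Frequencies are clamped to [1/(M+1), M/(M+1)] to avoid zero- or
#' one-probability artifacts of finite ensembles.
#'
#' @param key canonical subnetwork key.
#' @param ensembles list of [NullEnsemble-class], one per sample element,
#'   all of the same size M >= 1.
#' @return numeric vector of clamped per-element probabilities.
#' @export
occurrenceProbabilities <- function(key, ensembles) {
  stopifnot(length(ensembles) >= 1L)
  M <- length(ensembles[[1L]]@realizations)
  if (M < 1L) stop("empty ensemble")
  q <- vapply(ensembles, function(ens) {
    if (length(ens@realizations) != M)
      stop("ensembles differ in size")
    hits <- vapply(ens@realizations, .containsInduced, logical(1), key = key)
    mean(hits)
  }, numeric(1))
  pmin(pmax(q, 1 / (M + 1)), M / (M + 1))
}

#' Exact upper tail of the Poisson-binomial distribution
#'
#' P(X >= cObs) for X the sum of independent Bernoulli(q_i) variables,
#' computed exactly by dynamic programming over the count distribution.
#'
#' @param q vector of success probabilities in [0, 1].
#' @param cObs observed count, 0 <= cObs <= length(q).
#' @return the tail probability.
#' @examples
#' poissonBinomialTail(c(0.5, 0.5), 2)   # 0.25
#' poissonBinomialTail(c(0.2, 0.7), 1)   # 1 - 0.8 * 0.3
#' @export
poissonBinomialTail <- function(q, cObs) {
  stopifnot(all(q >= 0), all(q <= 1), cObs >= 0, cObs <= length(q))
  if (cObs == 0) return(1)
  dist <- 1  # P(X = 0) over zero variables
  for (p in q)
    dist <- c(dist * (1 - p), 0) + c(0, dist * p)
  sum(dist[(cObs + 1L):length(dist)])
}

#' Bonferroni-Holm step-down adjustment
#'
#' Step-down familywise error control over the candidate family: p-values
#' are sorted ascending and hypotheses rejected while
#' p_(j) <= alpha / (m - j + 1), stopping at the first failure. Backed by
#' `stats::p.adjust(method = "holm")`, which implements the same rule.
#'
#' @param p named numeric vector of raw p-values (names = candidate keys).
#' @param alpha multiple significance level in (0, 1); alpha = 0 rejects
#'   nothing.
#' @return data.frame with columns key, p_raw, p_adj, holm_rank,
#'   significant, ordered by ascending p.
#' @export
holmAdjust <- function(p, alpha) {
  stopifnot(alpha >= 0, alpha < 1)
  if (!length(p))
    return(data.frame(key = character(), p_raw = numeric(),
                      p_adj = numeric(), holm_rank = integer(),
                      significant = logical()))
  keys <- if (is.null(names(p))) as.character(seq_along(p)) else names(p)
  ord <- order(p)
  padj <- p.adjust(p, method = "holm")
  out <- data.frame(key = keys, p_raw = as.numeric(p),
                    p_adj = as.numeric(padj),
                    holm_rank = rank(p, ties.method = "first"),
                    significant = padj <= alpha & alpha > 0,
                    row.names = NULL)
  out[ord, , drop = FALSE]
}

#' Detect sample-specific labeled network motifs
#'
#' Full pipeline on one sample: exhaustive induced k-subnetwork counting,
#' candidate filtering by minimum sample count, degree-preserving null
#' ensembles per sample element (fused edge-switching and containment
#' counting), exact Poisson-binomial tail p-values for the observed sample
#' counts, and Bonferroni-Holm familywise error control. Candidates flagged
#' significant are the sample's motifs.
#'
#' @param sample a [NetworkSample-class].
#' @param k subnetwork size (default 3).
#' @param minCount candidate filter: keys must occur in at least `minCount`
#'   element networks (default 4; use 1 to test every observed key).
#' @param alpha multiple significance level (default 0.05).
#' @param Q mixing parameter, or `"estimate"` to calibrate it on the
#'   sample's representative network via [estimateMixingParameter].
#' @param M ensemble size per element, or `"estimate"` to calibrate via
#'   [estimateEnsembleSize].
#' @param seed integer seed governing all randomness.
#' @param candidates optional explicit candidate key family (e.g. the union
#'   of filtered candidates over several samples); overrides `minCount`
#'   filtering. Candidates unobserved in this sample get observed count 0.
#' @param calibration list of settings used when Q or M is `"estimate"`:
#'   `Qgrid`, `NperQ`, `reps`, `Bgrid`, `Bmax`, `epsilon`.
#' @return a [MotifAnalysis-class].
#' @export
detectMotifs <- function(sample, k = 3L, minCount = 4L, alpha = 0.05,
                         Q = 100, M = 1000L, seed = 1L, candidates = NULL,
                         calibration = list()) {
  stopifnot(is(sample, "NetworkSample"))
  k <- as.integer(k)
  seed <- as.integer(seed)
  cal <- utils::modifyList(
    list(Qgrid = c(1, 3, 10, 30, 100, 300), NperQ = 1000L, reps = 2000L,
         Bgrid = c(25L, 50L, 100L, 200L), Bmax = 400L, epsilon = 0.02),
    calibration)
  calReports <- list()
  if (identical(Q, "estimate")) {
    ri <- selectRepresentative(sample)
    ur <- estimateMixingParameter(sample[[ri]], Qgrid = cal$Qgrid,
                                  NperQ = cal$NperQ, alpha = alpha,
                                  reps = cal$reps,
                                  seed = .deriveSeed(seed, 0L, 2L))
    Q <- ur$chosen_Q
    calReports$uniformity <- ur
    calReports$representative <- ri
  }
  if (identical(M, "estimate")) {
    es <- estimateEnsembleSize(sample, k = k, Q = Q, Bgrid = cal$Bgrid,
                               Bmax = cal$Bmax, epsilon = cal$epsilon,
                               seed = .deriveSeed(seed, 0L, 3L))
    M <- es$Bstar
    calReports$ensembleSize <- es
  }
  M <- as.integer(M)

  counts <- countOverSample(sample, k)
  if (is.null(candidates))
    candidates <- filterCandidates(list(counts), minCount)
  meta <- list(sample = sampleName(sample), k = k, minCount = minCount,
               alpha = alpha, Q = Q, M = M, seed = seed,
               sampleSize = sampleSize(sample),
               nCandidates = length(candidates),
               bidirectionalObserved =
                 vapply(sample@networks, countBidirectional, numeric(1)),
               package = as.character(packageVersion("samplemotifs")),
               calibration = calReports)
  if (!length(candidates)) {
    return(new("MotifAnalysis",
               results = data.frame(key = character(), k = integer(),
                                    observed_count = integer(),
                                    sample_size = integer(),
                                    mean_q = numeric(), p_raw = numeric(),
                                    p_adj = numeric(), holm_rank = integer(),
                                    significant = logical()),
               metadata = meta))
  }

  spec <- .candidateSpec(candidates, sample@labels)
  if (spec$k != k) stop("candidate keys do not have k vertices")
  S <- sampleSize(sample)
  n <- length(sample@labels)
  qmat <- matrix(0, nrow = length(candidates), ncol = S)
  for (i in seq_len(S)) {
    net <- sample@networks[[i]]
    m <- nrow(net@edges)
    if (m < 2L) {
      hits <- vapply(candidates, .containsInduced, logical(1), net = net)
      qmat[, i] <- as.numeric(hits) * M
    } else {
      qmat[, i] <- cpp_ensemble_counts(net@edges, n, M, round(Q * m),
                                       .deriveSeed(seed, i), spec$V,
                                       spec$mask)
    }
  }
  qmat <- pmin(pmax(qmat / M, 1 / (M + 1)), M / (M + 1))

  obs <- setNames(integer(length(candidates)), candidates)
  present <- intersect(candidates, names(counts@counts))
  obs[present] <- counts@counts[present]
  praw <- vapply(seq_along(candidates), function(c) {
    poissonBinomialTail(qmat[c, ], obs[c])
  }, numeric(1))
  names(praw) <- candidates
  adj <- holmAdjust(praw, alpha)
  res <- data.frame(key = adj$key, k = k,
                    observed_count = as.integer(obs[adj$key]),
                    sample_size = S,
                    mean_q = rowMeans(qmat)[match(adj$key, candidates)],
                    p_raw = adj$p_raw, p_adj = adj$p_adj,
                    holm_rank = adj$holm_rank,
                    significant = adj$significant, row.names = NULL)
  new("MotifAnalysis", results = res, metadata = meta)
}

#' @describeIn detectMotifs full per-candidate results table
#' @param x a MotifAnalysis.
#' @export
setMethod("motifResults", "MotifAnalysis", function(x) x@results)

#' @describeIn detectMotifs resolved run configuration and calibration reports
#' @export
setMethod("runMetadata", "MotifAnalysis", function(x) x@metadata)

#' @describeIn detectMotifs rows flagged significant (the motifs)
#' @export
setMethod("significantMotifs", "MotifAnalysis", function(x) {
  x@results[x@results$significant, , drop = FALSE]
})

setMethod("show", "MotifAnalysis", function(object) {
  md <- object@metadata
  cat(sprintf("MotifAnalysis of sample \"%s\" (k = %d, alpha = %g, Q = %g, M = %d)\n",
              md$sample, md$k, md$alpha, md$Q, md$M))
  cat(sprintf("  %d candidate subnetworks, %d significant motif(s)\n",
              nrow(object@results), sum(object@results$significant)))
  sig <- significantMotifs(object)
  if (nrow(sig))
    for (i in seq_len(nrow(sig)))
      cat(sprintf("  %s  count %d/%d  p_adj %.3g\n", sig$key[i],
                  sig$observed_count[i], sig$sample_size[i], sig$p_adj[i]))
})

#' Write a motif analysis as TSV plus a JSON metadata sidecar
#'
#' @param x a [MotifAnalysis-class].
#' @param path output TSV path; metadata goes to `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
writeMotifResults <- function(x, path) {
  stopifnot(is(x, "MotifAnalysis"))
  write.table(motifResults(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  md <- runMetadata(x)
  md$calibration <- lapply(md$calibration, unclass)
  jsonlite::write_json(md, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
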