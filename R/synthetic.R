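# Synthetic ECN-like sample generator.
#
# Emulates the geometry of EEG effective-connectivity network samples: a
# fixed label set (default the nine 10-20-system electrodes F3, Fz, F4, C3,
# Cz, C4, P3, Pz, P4), a sample of 15-16 subjects, sparse directed background
# connectivity, and optional planted subnetworks that make specific labeled
# patterns overrepresented. Planting ADDS edges on top of the base draw, so
# elements stay simple digraphs while their degree sequences vary across the
# sample as in real data.

#' The nine-electrode label set
#'
#' Electrode names of the extended 10-20 placement commonly used for
#' EEG connectivity analyses over frontal, central and parietal sites;
#' the default vertex label set of [generateSample].
#'
#' @return character vector of 9 labels.
#' @export
eegLabels <- function() c("F3", "Fz", "F4", "C3", "Cz", "C4", "P3", "Pz", "P4")

#' Generate a synthetic network sample with optional planted patterns
#'
#' Each element network is drawn as a directed G(n, pBase) over the label
#' set (every ordered distinct-label pair present independently with
#' probability `pBase`); afterwards each planted pattern is added in full to
#' the element with its planting probability.
#'
#' @param labels ordered vertex label set (default [eegLabels]).
#' @param sampleSize number of element networks (default 16, the typical
#'   subject count of an EEG group sample; 15 is a common variant).
#' @param pBase background edge probability in [0, 1].
#' @param planted list of planted patterns, each a list with `edges` (a
#'   2-column character matrix of (tail, head) label pairs, loop-free) and
#'   `prob` (per-element planting probability in [0, 1]).
#' @param seed integer seed; identical configurations and seeds give
#'   identical samples.
#' @param name sample name.
#' @return a [NetworkSample-class].
#' @examples
#' s <- generateSample(pBase = 0.05,
#'                     planted = list(list(edges = rbind(c("Fz", "F4"),
#'                                                       c("F4", "Fz")),
#'                                         prob = 1)),
#'                     seed = 7)
#' sampleSize(s)
#' @export
generateSample <- function(labels = eegLabels(), sampleSize = 16L,
                           pBase = 0.1, planted = list(), seed = 1L,
                           name = "synthetic") {
  stopifnot(pBase >= 0, pBase <= 1, sampleSize >= 1L)
  for (pl in planted) {
    stopifnot(is.list(pl), !is.null(pl$edges), !is.null(pl$prob),
              pl$prob >= 0, pl$prob <= 1)
    pe <- pl$edges
    if (any(!(pe %in% labels))) stop("planted edge uses an unknown label")
    if (any(pe[, 1L] == pe[, 2L])) stop("planted edge set contains a loop")
  }
  set.seed(as.integer(seed))
  n <- length(labels)
  pairs <- as.matrix(expand.grid(tail = seq_len(n), head = seq_len(n)))
  pairs <- pairs[pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  nets <- lapply(seq_len(sampleSize), function(i) {
    keep <- runif(nrow(pairs)) < pBase
    e <- pairs[keep, , drop = FALSE]
    for (pl in planted) {
      if (runif(1) < pl$prob) {
        pidx <- cbind(match(pl$edges[, 1L], labels),
                      match(pl$edges[, 2L], labels))
        e <- rbind(e, pidx)
      }
    }
    e <- matrix(as.integer(e), ncol = 2L)
    e <- e[!duplicated(paste(e[, 1L], e[, 2L])), , drop = FALSE]
    colnames(e) <- c("tail", "head")
    new("LabeledNetwork", labels = labels, edges = e)
  })
  NetworkSample(nets, name = name)
}
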