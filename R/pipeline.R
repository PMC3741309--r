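# Workflow entry points wiring the modules together. These back the
# command-line wrapper in inst/scripts/motifscan.R; the functions are the
# interface and the script is a thin argument parser over them.

.resolveConfig <- function(config = list()) {
  defaults <- list(k = 3L, minCount = 4L, alpha = 0.05, Q = 100, M = 1000L,
                   seed = 1L,
                   Qgrid = c(1, 3, 10, 30, 100, 300), NperQ = 1000L,
                   reps = 10000L, Bgrid = c(25L, 50L, 100L, 200L),
                   Bmax = 400L, epsilon = 0.02)
  utils::modifyList(defaults, config[!vapply(config, is.null, logical(1))])
}

#' Run motif detection over one or more sample manifests
#'
#' Reads every sample, builds the candidate family as the union of keys that
#' pass the minimum-count filter in at least one sample, runs [detectMotifs]
#' per sample against that shared family, and writes one results TSV (plus a
#' JSON metadata sidecar) per sample. When `Q = "estimate"` the mixing
#' parameter is calibrated once, on the representative network of the pooled
#' samples.
#'
#' @param manifests paths of sample manifests (see [readSample]).
#' @param outDir output directory.
#' @param config named list overriding the defaults: k = 3, minCount = 4,
#'   alpha = 0.05, Q = 100, M = 1000, seed = 1, plus calibration settings
#'   (Qgrid, NperQ, reps, Bgrid, Bmax, epsilon). Defaults are method-inspired
#'   and deliberately overridable; resolved values are embedded in every
#'   output's metadata.
#' @return invisible list of [MotifAnalysis-class], one per sample.
#' @export
runDetect <- function(manifests, outDir, config = list()) {
  stopifnot(length(manifests) >= 1L)
  cfg <- .resolveConfig(config)
  samples <- lapply(manifests, readSample)
  labels0 <- vertexLabels(samples[[1L]])
  for (s in samples)
    if (!identical(vertexLabels(s), labels0))
      stop("samples do not share one vertex label set")
  if (identical(cfg$Q, "estimate")) {
    pooled <- NetworkSample(unlist(lapply(samples, function(s) s@networks),
                                   recursive = FALSE), name = "pooled")
    ri <- selectRepresentative(pooled)
    ur <- estimateMixingParameter(pooled[[ri]], Qgrid = cfg$Qgrid,
                                  NperQ = cfg$NperQ, alpha = cfg$alpha,
                                  reps = cfg$reps,
                                  seed = .deriveSeed(cfg$seed, 0L, 2L))
    cfg$Q <- ur$chosen_Q
    cfg$uniformity <- unclass(ur)
  }
  tables <- lapply(samples, countOverSample, k = cfg$k)
  family <- filterCandidates(tables, cfg$minCount)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  analyses <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    analyses[[i]] <- detectMotifs(samples[[i]], k = cfg$k,
                                  minCount = cfg$minCount,
                                  alpha = cfg$alpha, Q = cfg$Q, M = cfg$M,
                                  seed = .deriveSeed(cfg$seed, 0L, 10L + i),
                                  candidates = family,
                                  calibration = cfg[c("Qgrid", "NperQ",
                                                      "reps", "Bgrid",
                                                      "Bmax", "epsilon")])
    writeMotifResults(analyses[[i]],
                      file.path(outDir, paste0(sampleName(samples[[i]]),
                                               "_motifs.tsv")))
  }
  meta <- cfg
  meta$uniformity <- if (!is.null(cfg$uniformity)) cfg$uniformity else "fixed Q"
  meta$manifests <- as.character(manifests)
  meta$candidateFamily <- family
  jsonlite::write_json(meta, file.path(outDir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(analyses)
}

#' Calibrate the null model for one or more samples
#'
#' Selects the representative network over the pooled samples, estimates the
#' mixing parameter Q (skipped and reported as "fixed" when `config$Q` is
#' numeric) and the required ensemble size B*, and writes a JSON report.
#'
#' @inheritParams runDetect
#' @return invisible list with `representative`, `uniformity`, `ensembleSize`.
#' @export
runCalibrate <- function(manifests, outDir = NULL, config = list()) {
  stopifnot(length(manifests) >= 1L)
  cfg <- .resolveConfig(config)
  samples <- lapply(manifests, readSample)
  pooled <- NetworkSample(unlist(lapply(samples, function(s) s@networks),
                                 recursive = FALSE), name = "pooled")
  ri <- selectRepresentative(pooled)
  if (is.numeric(cfg$Q)) {
    uniformity <- list(chosen_Q = cfg$Q, fixed = TRUE)
    Q <- cfg$Q
  } else {
    ur <- estimateMixingParameter(pooled[[ri]], Qgrid = cfg$Qgrid,
                                  NperQ = cfg$NperQ, alpha = cfg$alpha,
                                  reps = cfg$reps,
                                  seed = .deriveSeed(cfg$seed, 0L, 2L))
    uniformity <- unclass(ur)
    uniformity$fixed <- FALSE
    Q <- ur$chosen_Q
  }
  es <- estimateEnsembleSize(samples[[1L]], k = cfg$k, Q = Q,
                             Bgrid = cfg$Bgrid, Bmax = cfg$Bmax,
                             epsilon = cfg$epsilon,
                             seed = .deriveSeed(cfg$seed, 0L, 3L))
  report <- list(representative = ri, uniformity = uniformity,
                 ensembleSize = es, config = cfg,
                 manifests = as.character(manifests))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(outDir, "calibration.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}

#' Generate and write a synthetic sample fixture
#'
#' Thin wrapper over [generateSample] + [writeFixture].
#'
#' @param outDir output directory for the edge lists and manifest.
#' @param ... passed to [generateSample].
#' @return the manifest path, invisibly.
#' @export
runSimulate <- function(outDir, ...) {
  writeFixture(generateSample(...), outDir)
}
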