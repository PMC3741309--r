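# Edge-list and sample-manifest I/O.
#
# Edge lists are 2-column TSV (tail TAB head), '#' comment lines and blank
# lines ignored, an optional "tail<TAB>head" header allowed. The label set
# travels in the sample manifest, not in the edge files, so networks with
# isolated vertices survive round trips.

#' Read a network from a 2-column TSV edge list
#'
#' @param path edge-list file: one "tail\\tab head" pair per line, optional
#'   `tail\\tab head` header, `#` comments and blank lines skipped.
#' @param labels the ordered vertex label set (supplied by the sample
#'   manifest; edge files do not carry it).
#' @return a [LabeledNetwork-class]. Duplicate edges are collapsed with a
#'   warning; loops or unknown labels are errors naming the offending line.
#' @export
readNetworkEdgelist <- function(path, labels) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(LabeledNetwork(labels, NULL))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 2L)) {
    bad <- which(nfield != 2L)[1L]
    stop(sprintf("%s: line %d: expected 2 tab-separated fields, found %d",
                 path, lineno[bad], nfield[bad]))
  }
  em <- matrix(trimws(unlist(parts)), ncol = 2L, byrow = TRUE)
  if (identical(tolower(em[1L, ]), c("tail", "head"))) {
    em <- em[-1L, , drop = FALSE]
    lineno <- lineno[-1L]
  }
  if (!nrow(em)) return(LabeledNetwork(labels, NULL))
  unknown <- !(em %in% labels)
  if (any(unknown)) {
    bad <- which(matrix(unknown, ncol = 2L), arr.ind = TRUE)[1L, "row"]
    stop(sprintf("%s: line %d: unknown label \"%s\"", path, lineno[bad],
                 em[bad, ][!(em[bad, ] %in% labels)][1L]))
  }
  loops <- em[, 1L] == em[, 2L]
  if (any(loops))
    stop(sprintf("%s: line %d: loop at vertex \"%s\"", path,
                 lineno[which(loops)[1L]], em[which(loops)[1L], 1L]))
  dup <- duplicated(paste(em[, 1L], em[, 2L]))
  if (any(dup)) {
    warning(sprintf("%s: %d duplicate edge(s) collapsed", path, sum(dup)))
    em <- em[!dup, , drop = FALSE]
  }
  LabeledNetwork(labels, em)
}

#' Write a network as a 2-column TSV edge list
#'
#' Edges are written in canonical (radix-sorted token) order with a
#' `tail\\tab head` header, so write/read round trips are stable.
#'
#' @param x a [LabeledNetwork-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeNetworkEdgelist <- function(x, path) {
  stopifnot(is(x, "LabeledNetwork"))
  el <- edgeLabels(x)
  if (nrow(el))
    el <- el[order(.edgeTokens(el), method = "radix"), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("tail\thead", con)
  if (nrow(el)) writeLines(paste(el[, 1L], el[, 2L], sep = "\t"), con)
  invisible(path)
}

#' Read a network sample from a manifest
#'
#' The manifest is YAML (or JSON, which yaml parses) with fields `name`,
#' `labels` (ordered vertex label set) and `networks` (edge-list paths,
#' relative to the manifest's directory). Any network failing validation
#' aborts the load with a descriptive error.
#'
#' @param path manifest file.
#' @return a [NetworkSample-class].
#' @export
readSample <- function(path) {
  man <- yaml::read_yaml(path)
  for (field in c("name", "labels", "networks"))
    if (is.null(man[[field]]))
      stop(sprintf("%s: manifest is missing field \"%s\"", path, field))
  labels <- as.character(unlist(man$labels))
  if (length(man$networks) < 1L)
    stop(sprintf("%s: empty sample (no networks listed)", path))
  base <- dirname(normalizePath(path))
  nets <- lapply(as.character(unlist(man$networks)), function(p) {
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
    readNetworkEdgelist(p, labels)
  })
  NetworkSample(nets, name = as.character(man$name))
}

#' Write a sample as edge-list files plus a manifest
#'
#' Inverse of [readSample]: writes one TSV edge list per element network and
#' a YAML manifest carrying the sample name and the ordered label set.
#'
#' @param sample a [NetworkSample-class].
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
writeFixture <- function(sample, dir) {
  stopifnot(is(sample, "NetworkSample"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("net%03d.tsv", seq_len(sampleSize(sample)))
  for (i in seq_along(files))
    writeNetworkEdgelist(sample[[i]], file.path(dir, files[i]))
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(name = sampleName(sample),
                        labels = as.list(vertexLabels(sample)),
                        networks = as.list(files)),
                   manifest)
  invisible(manifest)
}

#' Write a subnetwork count table as TSV
#'
#' Columns: key, count, sample_size, k.
#'
#' @param x a [SubnetworkCounts-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCountTable <- function(x, path) {
  stopifnot(is(x, "SubnetworkCounts"))
  df <- data.frame(key = names(x@counts), count = as.integer(x@counts),
                   sample_size = x@sampleSize, k = x@k)
  df <- df[order(df$key, method = "radix"), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
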