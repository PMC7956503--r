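#' DAve: differential average of two spectral-count abundances
#'
#' DAve = (X - Y) / ((X + Y) / 2) = 2(X - Y)/(X + Y), the difference of two
#' group-average spectral counts normalized by their mean. It is bounded in
#' [-2, 2]; the bounds are attained exactly when one side is absent. When
#' both sides are 0 the protein carries no differential signal and DAve is
#' defined as 0.
#'
#' @param x,y non-negative aSpC values (vectorized).
#' @return DAve value(s) in [-2, 2].
#' @export
dave <- function(x, y) {
  if (any(x < 0) || any(y < 0))
    stop("dave: inputs must be non-negative")
  s <- x + y
  out <- ifelse(s == 0, 0, 2 * (x - y) / s)
  unname(out)
}

#' DCI: differential coefficient index
#'
#' DCI = (X + Y)(X - Y)/2 weights the abundance difference by the total
#' abundance, so that equal fold changes score higher for well-sampled
#' proteins than for proteins near the detection floor.
#'
#' @param x,y non-negative aSpC values (vectorized).
#' @return DCI value(s).
#' @export
dci <- function(x, y) {
  if (any(x < 0) || any(y < 0))
    stop("dci: inputs must be non-negative")
  unname((x + y) * (x - y) / 2)
}

#' Extract differentially expressed proteins over all pairwise comparisons
#'
#' For every unordered pair of groups, computes each protein's group-mean
#' aSpC, DAve and DCI, and flags proteins passing both strict thresholds
#' |DAve| > \code{daveThreshold} and |DCI| > \code{dciThreshold}. The DEP
#' set is the union of passers over all comparisons. Comparisons are
#' reported in canonical (sorted) label order, X vs Y with X < Y, so
#' positive DAve/DCI mean up in X.
#'
#' @param x a subject-level [SpcExperiment-class] of aSpC values.
#' @param groups named vector or factor mapping every subject id to its
#'   group label.
#' @param daveThreshold strict threshold on |DAve| (default 0.2).
#' @param dciThreshold strict threshold on |DCI| (default 5).
#' @return a [DepSet-class].
#' @export
pairwiseDeps <- function(x, groups, daveThreshold = 0.2, dciThreshold = 5) {
  stopifnot(is(x, "SpcExperiment"))
  if (spcLevel(x) != "subject")
    stop("pairwiseDeps expects a subject-level (aSpC) matrix")
  groups <- checkGroups(x, groups)
  labs <- levels(groups)
  if (length(labs) < 2L)
    stop("at least 2 groups are required")
  m <- spc(x)
  gmeans <- vapply(labs, function(g) rowMeans(m[, groups == g, drop = FALSE]),
                   numeric(nrow(m)))
  gmeans <- matrix(gmeans, nrow = nrow(m),
                   dimnames = list(rownames(m), labs))
  sym <- rowData(x)$gene_symbol
  if (is.null(sym)) sym <- NA_character_
  pairs <- utils::combn(labs, 2, simplify = FALSE)
  res <- do.call(rbind, lapply(pairs, function(pr) {
    ax <- gmeans[, pr[1]]
    ay <- gmeans[, pr[2]]
    dv <- dave(ax, ay)
    dc <- dci(ax, ay)
    data.frame(
      accession   = rownames(m),
      gene_symbol = sym,
      comparison  = paste(pr[1], "vs", pr[2]),
      aspc_x      = unname(ax),
      aspc_y      = unname(ay),
      dave        = dv,
      dci         = dc,
      pass        = abs(dv) > daveThreshold & abs(dc) > dciThreshold,
      stringsAsFactors = FALSE
    )
  }))
  rownames(res) <- NULL
  new("DepSet", results = res,
      proteins = unique(res$accession[res$pass]),
      daveThreshold = daveThreshold, dciThreshold = dciThreshold)
}

# normalizes a subject->label mapping against the matrix columns; returns a
# factor aligned with colnames(x), levels in sorted label order
checkGroups <- function(x, groups) {
  subjects <- colnames(x)
  if (is.factor(groups)) {
    g <- as.character(groups)
    names(g) <- names(groups)
    groups <- g
  }
  if (is.null(names(groups))) {
    if (length(groups) != length(subjects))
      stop("unnamed groups vector must have one label per subject column")
    names(groups) <- subjects
  }
  missing <- setdiff(subjects, names(groups))
  if (length(missing))
    stop("no group label for subject(s): ", paste(missing, collapse = ", "))
  factor(unname(groups[subjects]), levels = sort(unique(unname(groups))))
}

#' CD-marker differential table at a stricter DCI threshold
#'
#' Restricts a [DepSet-class] to a list of cluster-of-differentiation (CD)
#' surface-marker accessions and re-evaluates the pass flags at a stricter
#' DCI threshold (default |DCI| > 10 instead of the global 5), keeping the
#' DAve threshold of the parent DepSet.
#'
#' @param deps a [DepSet-class].
#' @param cdAccessions character vector of CD protein accessions (see
#'   [readCdList()]).
#' @param dciThreshold strict |DCI| threshold for the CD table (default 10).
#' @return data.frame of per-comparison DAve/DCI rows for the CD proteins,
#'   with pass flags at the stricter threshold. CD accessions absent from
#'   the matrix are omitted with a warning.
#' @export
cdMarkerTable <- function(deps, cdAccessions, dciThreshold = 10) {
  stopifnot(is(deps, "DepSet"))
  cdAccessions <- unique(cdAccessions)
  known <- unique(deps@results$accession)
  absent <- setdiff(cdAccessions, known)
  if (length(absent))
    warning("CD accession(s) absent from the matrix, omitted: ",
            paste(absent, collapse = ", "))
  res <- deps@results[deps@results$accession %in% cdAccessions, , drop = FALSE]
  res$pass <- abs(res$dave) > deps@daveThreshold & abs(res$dci) > dciThreshold
  rownames(res) <- NULL
  res
}

#' Read a CD accession list
#'
#' Plain-text file, one accession per line; blank lines and '#' comments
#' are ignored.
#'
#' @param path path to the list.
#' @return character vector of accessions.
#' @export
readCdList <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Write the DEP report as TSV
#'
#' @param deps a [DepSet-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeDepReport <- function(deps, path) {
  utils::write.table(depResults(deps), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
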