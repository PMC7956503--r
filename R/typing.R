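#' Per-subject alpha-value profiles over a marker panel
#'
#' The alpha value of panel protein p in subject i is that protein's share
#' of the subject's total panel abundance:
#' alpha_i(p) = aSpC_i(p) / sum over the panel of aSpC_i(q).
#' Each subject's profile sums to 1 and is invariant under any positive
#' rescaling of the subject's column, so it captures the within-subject
#' balance of the markers rather than absolute abundance. A subject with
#' zero total panel signal is flagged degenerate and given the uniform
#' profile.
#'
#' @param x a subject-level [SpcExperiment-class].
#' @param panel a [MarkerPanel-class] or character vector of accessions;
#'   all panel proteins must be present in \code{x}.
#' @return data.frame with subject_id, one alpha column per panel protein,
#'   and a degenerate flag.
#' @export
alphaProfile <- function(x, panel) {
  stopifnot(is(x, "SpcExperiment"))
  if (is(panel, "MarkerPanel")) panel <- panelProteins(panel)
  panel <- as.character(panel)
  if (!length(panel)) stop("panel is empty")
  missing <- setdiff(panel, rownames(x))
  if (length(missing))
    stop("panel protein(s) absent from the matrix: ",
         paste(missing, collapse = ", "))
  m <- spc(x)[panel, , drop = FALSE]
  totals <- colSums(m)
  degenerate <- totals == 0
  alpha <- sweep(m, 2, ifelse(degenerate, 1, totals), "/")
  alpha[, degenerate] <- 1 / length(panel)
  out <- data.frame(subject_id = colnames(m), t(alpha),
                    degenerate = unname(degenerate),
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Group alpha centroids
#'
#' Mean alpha profile of each group's non-degenerate members, renormalized
#' to sum to 1. These reference profiles let new subjects be typed by
#' nearest-centroid matching in alpha space ([assignByAlpha()]).
#'
#' @param x a subject-level [SpcExperiment-class].
#' @param panel a [MarkerPanel-class] or accession vector.
#' @param groups named subject-to-label mapping (e.g. from [cutTree()]).
#' @return groups x panel matrix of centroid alpha profiles.
#' @export
alphaCentroids <- function(x, panel, groups) {
  profiles <- alphaProfile(x, panel)
  if (is(panel, "MarkerPanel")) panel <- panelProteins(panel)
  grp <- checkGroups(x, groups)
  labs <- levels(grp)
  cent <- vapply(labs, function(g) {
    keep <- grp == g & !profiles$degenerate
    if (!any(keep))
      stop("group ", g, " has no non-degenerate subject")
    v <- colMeans(as.matrix(profiles[keep, panel, drop = FALSE]))
    v / sum(v)
  }, numeric(length(panel)))
  t(matrix(cent, nrow = length(panel),
           dimnames = list(panel, labs)))
}

#' Type subjects by nearest alpha centroid
#'
#' Assigns each subject to the group whose reference alpha profile is
#' nearest in Euclidean distance, recording the margin (distance gap
#' between runner-up and best). Exact ties go to the first group in
#' canonical order and are reported with a warning.
#'
#' @param profiles data.frame from [alphaProfile()].
#' @param centroids groups x panel matrix from [alphaCentroids()] (or any
#'   reference profiles on the same panel).
#' @return data.frame with subject_id, assigned, margin, degenerate.
#' @export
assignByAlpha <- function(profiles, centroids) {
  panel <- colnames(centroids)
  if (!all(panel %in% names(profiles)))
    stop("centroid panel does not match the alpha profiles")
  A <- as.matrix(profiles[, panel, drop = FALSE])
  labs <- rownames(centroids)
  d <- vapply(labs, function(g)
    sqrt(rowSums(sweep(A, 2, centroids[g, ])^2)), numeric(nrow(A)))
  d <- matrix(d, nrow = nrow(A), dimnames = list(profiles$subject_id, labs))
  assigned <- character(nrow(d))
  margin <- numeric(nrow(d))
  for (i in seq_len(nrow(d))) {
    row <- sort(d[i, ])
    hits <- which(d[i, ] == row[1])
    if (length(hits) > 1L)
      warning("alpha-space tie for subject ", rownames(d)[i],
              "; assigned to first group in canonical order")
    assigned[i] <- labs[hits[1]]
    margin[i] <- if (length(row) > 1L) row[2] - row[1] else 0
  }
  data.frame(subject_id = profiles$subject_id, assigned = assigned,
             margin = margin, degenerate = profiles$degenerate,
             stringsAsFactors = FALSE)
}

#' Write the alpha-typing report as TSV
#'
#' @param profiles data.frame from [alphaProfile()].
#' @param assignment data.frame from [assignByAlpha()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeAlphaReport <- function(profiles, assignment, path) {
  out <- merge(profiles, assignment[c("subject_id", "assigned", "margin")],
               by = "subject_id", sort = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
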