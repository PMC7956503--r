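#' Screen discriminant proteins by one-way ANOVA F ratio
#'
#' For each protein, computes the one-way ANOVA F statistic of its aSpC
#' values across the proteome groups (between-group over within-group mean
#' square, df G-1 and N-G) and the corresponding p-value from the F
#' distribution. Proteins with F >= \code{fMin} and p <= \code{pMax} are
#' selected as discriminants. A protein constant across all subjects has
#' both variances zero: its F is undefined (NaN) and it is never selected.
#' A protein with zero within-group variance but distinct group means
#' separates the groups perfectly (F = Inf) and is selected.
#'
#' @param x a subject-level [SpcExperiment-class].
#' @param groups named subject-to-label mapping.
#' @param fMin selection threshold on F (default 5, non-strict).
#' @param pMax selection threshold on p (default 0.01, non-strict).
#' @return data.frame with accession, f_ratio, p_value, one mean_<label>
#'   column per group, and selected.
#' @export
fRatioSelect <- function(x, groups, fMin = 5, pMax = 0.01) {
  stopifnot(is(x, "SpcExperiment"))
  if (spcLevel(x) != "subject")
    stop("fRatioSelect expects a subject-level (aSpC) matrix")
  groups <- checkGroups(x, groups)
  labs <- levels(groups)
  G <- length(labs)
  if (G < 2L)
    stop("at least 2 groups are required")
  sizes <- table(groups)
  if (any(sizes < 2))
    stop("group(s) with fewer than 2 subjects (within-group variance ",
         "undefined): ", paste(names(sizes)[sizes < 2], collapse = ", "))
  m <- spc(x)
  N <- ncol(m)
  gmeans <- vapply(labs, function(g) rowMeans(m[, groups == g, drop = FALSE]),
                   numeric(nrow(m)))
  gmeans <- matrix(gmeans, nrow = nrow(m),
                   dimnames = list(rownames(m), labs))
  grand <- rowMeans(m)
  ssb <- as.vector((gmeans - grand)^2 %*% as.numeric(sizes))
  ssw <- rowSums((m - gmeans[, as.integer(groups), drop = FALSE])^2)
  f <- (ssb / (G - 1)) / (ssw / (N - G))   # 0/0 -> NaN for constant proteins
  p <- stats::pf(f, G - 1, N - G, lower.tail = FALSE)
  sel <- !is.na(f) & f >= fMin & !is.na(p) & p <= pMax
  out <- data.frame(accession = rownames(m), f_ratio = f, p_value = p,
                    stringsAsFactors = FALSE)
  for (g in labs) out[[paste0("mean_", g)]] <- unname(gmeans[, g])
  out$selected <- sel
  rownames(out) <- NULL
  out
}

#' Fit a linear discriminant model with common covariance
#'
#' Estimates group centroids and the pooled within-group covariance shared
#' by all groups, shrinks the covariance toward its diagonal with mixing
#' weight \code{lambda} (needed because the number of screened proteins
#' typically exceeds the number of subjects, making the raw pooled
#' covariance singular), and derives canonical discriminant axes for
#' visualization. Classification uses Mahalanobis distance under the common
#' covariance ([classifyLda()]).
#'
#' @param x a subject-level [SpcExperiment-class].
#' @param groups named subject-to-label mapping.
#' @param proteins optional accessions to restrict the model to (typically
#'   the [fRatioSelect()] survivors); default all rows of \code{x}.
#' @param lambda shrinkage weight in [0, 1] toward diag(S) (default 0.5).
#' @return an [SpcLdaModel-class].
#' @export
fitLda <- function(x, groups, proteins = NULL, lambda = 0.5) {
  stopifnot(is(x, "SpcExperiment"))
  groups <- checkGroups(x, groups)
  labs <- levels(groups)
  G <- length(labs)
  if (G < 2L) stop("at least 2 groups are required")
  if (!is.null(proteins)) {
    missing <- setdiff(proteins, rownames(x))
    if (length(missing))
      stop("protein(s) absent from the matrix: ",
           paste(missing, collapse = ", "))
    x <- x[proteins, ]
  }
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  X <- t(spc(x))                       # subjects x proteins
  N <- nrow(X); p <- ncol(X)
  if (N <= G)
    stop("fewer subjects than needed: require more subjects than groups")
  centroids <- do.call(rbind, lapply(labs, function(g)
    colMeans(X[groups == g, , drop = FALSE])))
  rownames(centroids) <- labs
  # pooled within-group covariance, df = N - G
  Xc <- X - centroids[as.integer(groups), , drop = FALSE]
  S <- crossprod(Xc) / (N - G)
  d <- diag(S)
  if (any(d == 0)) {
    # zero-variance features would keep the shrunken matrix singular
    d[d == 0] <- 1e-8 * max(mean(d[d > 0]), 1)
  }
  Sreg <- (1 - lambda) * S + lambda * diag(d, nrow = p)
  # canonical axes: eigenvectors of S^-1 B via the symmetric whitened form
  sizes <- as.numeric(table(groups))
  grand <- colMeans(X)
  Cc <- sweep(centroids, 2, grand)
  B <- crossprod(Cc * sqrt(sizes)) / (G - 1)
  eS <- eigen(Sreg, symmetric = TRUE)
  Wisqrt <- eS$vectors %*% (t(eS$vectors) / sqrt(pmax(eS$values, 1e-12)))
  M <- Wisqrt %*% B %*% Wisqrt
  eM <- eigen((M + t(M)) / 2, symmetric = TRUE)
  r <- min(G - 1, p)
  scaling <- Wisqrt %*% eM$vectors[, seq_len(r), drop = FALSE]
  colnames(scaling) <- paste0("LD", seq_len(r))
  rownames(scaling) <- colnames(X)
  scoresMat <- X %*% scaling
  scores <- data.frame(subject_id = rownames(X),
                       scoresMat,
                       group = as.character(groups),
                       stringsAsFactors = FALSE, check.names = FALSE)
  rownames(scores) <- NULL
  new("SpcLdaModel", proteins = colnames(X), groups = labs,
      centroids = centroids, covariance = Sreg, lambda = lambda,
      scaling = scaling, scores = scores)
}

#' Classify subjects by Mahalanobis distance to group centroids
#'
#' Assigns every column of \code{x} to the group whose centroid is nearest
#' in Mahalanobis distance under the model's common covariance. Exact ties
#' are broken in favor of the first group in canonical label order and
#' reported with a warning.
#'
#' @param model an [SpcLdaModel-class].
#' @param x a subject-level [SpcExperiment-class] containing the model's
#'   proteins.
#' @return named character vector subject -> assigned label, with the
#'   groups x subjects squared-distance matrix in attribute
#'   \code{"distance"}.
#' @export
classifyLda <- function(model, x) {
  stopifnot(is(model, "SpcLdaModel"), is(x, "SpcExperiment"))
  missing <- setdiff(model@proteins, rownames(x))
  if (length(missing))
    stop("matrix is missing model protein(s): ",
         paste(missing, collapse = ", "))
  X <- t(spc(x)[model@proteins, , drop = FALSE])
  Sinv <- solve(model@covariance)
  d2 <- vapply(model@groups, function(g) {
    D <- sweep(X, 2, model@centroids[g, ])
    rowSums((D %*% Sinv) * D)
  }, numeric(nrow(X)))
  d2 <- matrix(d2, nrow = nrow(X),
               dimnames = list(rownames(X), model@groups))
  assigned <- vapply(seq_len(nrow(d2)), function(i) {
    row <- d2[i, ]
    hits <- which(row == min(row))
    if (length(hits) > 1L)
      warning("Mahalanobis tie for subject ", rownames(d2)[i],
              "; assigned to first group in canonical order")
    model@groups[hits[1]]
  }, character(1))
  names(assigned) <- rownames(d2)
  attr(assigned, "distance") <- t(d2)
  assigned
}

#' Intersect LDA discriminants with the DEP set
#'
#' The overlap of the F-ratio/LDA discriminant list with the DAve/DCI DEP
#' set is the pool of proteins supported by both selection routes, from
#' which compact marker panels are drawn.
#'
#' @param ldaSelected accessions selected by the discriminant screen.
#' @param deps a [DepSet-class].
#' @param x optional subject-level [SpcExperiment-class] to attach
#'   per-group mean aSpC values.
#' @param groups required with \code{x}: subject-to-label mapping.
#' @return a [MarkerPanel-class] with source \code{"intersection"} and
#'   counts of lda-only / dep-only / shared proteins.
#' @export
intersectPanels <- function(ldaSelected, deps, x = NULL, groups = NULL) {
  stopifnot(is(deps, "DepSet"))
  ldaSelected <- unique(as.character(ldaSelected))
  common <- intersect(ldaSelected, depProteins(deps))
  counts <- c(lda_only = length(setdiff(ldaSelected, depProteins(deps))),
              dep_only = length(setdiff(depProteins(deps), ldaSelected)),
              intersection = length(common))
  gm <- matrix(numeric(), 0, 0)
  if (!is.null(x) && length(common)) {
    grp <- checkGroups(x, groups)
    m <- spc(x)[common, , drop = FALSE]
    gm <- vapply(levels(grp), function(g)
      rowMeans(m[, grp == g, drop = FALSE]), numeric(length(common)))
    gm <- matrix(gm, nrow = length(common),
                 dimnames = list(common, levels(grp)))
  }
  new("MarkerPanel", proteins = common, source = "intersection",
      groupMeans = gm, counts = as.integer(counts) |>
        stats::setNames(names(counts)))
}

#' Select a compact marker panel by differential strength
#'
#' Ranks the intersection proteins by their maximal |DAve| over all
#' pairwise comparisons and keeps the top \code{k} (default 6), breaking
#' ties alphabetically by accession for determinism. When the panel
#' carries per-group mean aSpC values, selection is balanced across
#' groups: each protein is attributed to the group where its mean is
#' highest and the groups are drafted round-robin in canonical order, so
#' the panel covers every proteome group rather than collapsing onto the
#' markers of the single most differential one — a panel typing subjects
#' into k groups must separate all of them.
#'
#' @param panel a [MarkerPanel-class] (typically from [intersectPanels()]).
#' @param deps the [DepSet-class] supplying the DAve values.
#' @param k panel size (default 6).
#' @return a [MarkerPanel-class] with the top-k proteins in rank order.
#' @export
selectMarkerPanel <- function(panel, deps, k = 6) {
  stopifnot(is(panel, "MarkerPanel"), is(deps, "DepSet"))
  res <- depResults(deps)
  res <- res[res$accession %in% panelProteins(panel), , drop = FALSE]
  if (nrow(res) == 0L)
    stop("no panel protein present in the DepSet results")
  score <- tapply(abs(res$dave), res$accession, max)
  ord <- order(-score, names(score))
  ranked <- names(score)[ord]
  if (nrow(panel@groupMeans)) {
    gm <- panel@groupMeans[ranked, , drop = FALSE]
    home <- colnames(gm)[apply(gm, 1, which.max)]
    byGroup <- split(ranked, factor(home, levels = colnames(gm)))
    top <- character()
    while (length(top) < min(k, length(ranked))) {
      for (g in names(byGroup)) {
        if (length(byGroup[[g]]) && length(top) < k) {
          top <- c(top, byGroup[[g]][1])
          byGroup[[g]] <- byGroup[[g]][-1]
        }
      }
    }
  } else {
    top <- ranked[seq_len(min(k, length(ranked)))]
  }
  gm <- panel@groupMeans
  if (nrow(gm)) gm <- gm[top, , drop = FALSE]
  new("MarkerPanel", proteins = top, source = panel@source,
      groupMeans = gm, counts = panel@counts)
}

#' Write the discriminant report as TSV
#'
#' @param disc data.frame from [fRatioSelect()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeDiscriminantReport <- function(disc, path) {
  utils::write.table(disc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-subject canonical LDA scores as TSV
#'
#' @param model an [SpcLdaModel-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeCanonicalScores <- function(model, path) {
  utils::write.table(model@scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
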