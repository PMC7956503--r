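# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# long run-table data.frame from a proteins x runs matrix; zeros are
# dropped (a protein absent from a run's list), mirroring real protein
# lists
runTableFromMatrix <- function(m, subjects = NULL, replicates = NULL) {
  runs <- colnames(m)
  if (is.null(subjects)) subjects <- sub("_r[12]$", "", runs)
  if (is.null(replicates))
    replicates <- as.integer(sub("^.*_r", "", runs))
  idx <- which(m > 0, arr.ind = TRUE)
  data.frame(
    run_id = runs[idx[, 2]],
    subject_id = subjects[idx[, 2]],
    replicate = replicates[idx[, 2]],
    accession = rownames(m)[idx[, 1]],
    gene_symbol = NA_character_,
    spc = m[idx],
    stringsAsFactors = FALSE
  )
}

# subject-level SpcExperiment straight from a matrix
subjectSe <- function(m) {
  SpcExperiment(m,
                colData = S4Vectors::DataFrame(subject_id = colnames(m),
                                               row.names = colnames(m)),
                level = "subject")
}

# run-level SpcExperiment: each subject gets two replicate columns
runSe <- function(m, subjects, replicates) {
  SpcExperiment(m,
                colData = S4Vectors::DataFrame(subject_id = subjects,
                                               replicate = replicates,
                                               row.names = colnames(m)),
                level = "run")
}

# three well-separated Gaussian blobs for clustering tests: subjects x 0
# features matrix is never useful, so features = 5 informative dims
blobMatrix <- function(sizes = c(3, 3, 2), centers = c(0, 30, 60),
                       sd = 1, nProteins = 5, seed = 11) {
  set.seed(seed)
  n <- sum(sizes)
  grp <- rep(seq_along(sizes), sizes)
  m <- vapply(seq_len(n),
              function(i) abs(stats::rnorm(nProteins, centers[grp[i]], sd)),
              numeric(nProteins))
  dimnames(m) <- list(sprintf("P%02d", seq_len(nProteins)),
                      sprintf("S%02d", seq_len(n)))
  list(m = m, groups = stats::setNames(LETTERS[grp], colnames(m)))
}

# total within-cluster sum of squares of a partition (Ward objective)
withinSS <- function(X, labels) {
  sum(vapply(unique(labels), function(l) {
    sub <- X[labels == l, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }, numeric(1)))
}

# every bipartition of n items as a logical membership vector
allBipartitions <- function(n) {
  out <- list()
  for (code in seq_len(2^(n - 1) - 1)) {
    v <- as.logical(bitwAnd(code, 2^(seq_len(n) - 1)) > 0)
    out[[length(out) + 1L]] <- v
  }
  out
}
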