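#' Read a run-level protein identification table
#'
#' Reads the per-run protein lists produced downstream of a database search:
#' one row per protein per LC-MS/MS run with its spectral count (SpC, the
#' number of MS/MS spectra assigned to the protein in that run).
#'
#' Two layouts are supported. \code{"long_tsv"} is a tab-delimited file with
#' header columns \code{run_id}, \code{subject_id}, \code{replicate},
#' \code{accession}, \code{gene_symbol} (optional) and \code{spc}.
#' \code{"wide_csv"} is a proteins x runs CSV whose first column is
#' \code{accession} and whose remaining columns are run ids; a sidecar
#' run-map (TSV with columns \code{run_id}, \code{subject_id},
#' \code{replicate}, or an equivalent data.frame) supplies the run metadata.
#' Empty cells in the wide layout are read as zero counts; zeros are kept as
#' explicit records.
#'
#' @param path path to the table.
#' @param format \code{"long_tsv"} or \code{"wide_csv"}.
#' @param runMap for \code{"wide_csv"}: path to the sidecar TSV mapping
#'   run_id to (subject_id, replicate), or a data.frame with those columns.
#' @return a validated run-table data.frame with columns run_id, subject_id,
#'   replicate, accession, gene_symbol, spc.
#' @export
readRunTable <- function(path, format = c("long_tsv", "wide_csv"),
                         runMap = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("file not found: ", path)
  if (format == "long_tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    required <- c("run_id", "subject_id", "replicate", "accession", "spc")
    missing <- setdiff(required, names(df))
    if (length(missing))
      stop("format error: missing required column(s): ",
           paste(missing, collapse = ", "))
    if (!"gene_symbol" %in% names(df))
      df$gene_symbol <- NA_character_
    df <- df[c("run_id", "subject_id", "replicate",
               "accession", "gene_symbol", "spc")]
  } else {
    if (is.null(runMap))
      stop("wide_csv format requires a runMap sidecar")
    if (is.character(runMap))
      runMap <- utils::read.delim(runMap, stringsAsFactors = FALSE)
    need <- c("run_id", "subject_id", "replicate")
    if (!all(need %in% names(runMap)))
      stop("format error: runMap must have columns ",
           paste(need, collapse = ", "))
    wide <- utils::read.csv(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (names(wide)[1] != "accession")
      stop("format error: first wide_csv column must be 'accession'")
    runs <- names(wide)[-1]
    unknown <- setdiff(runs, runMap$run_id)
    if (length(unknown))
      stop("format error: run(s) absent from runMap: ",
           paste(unknown, collapse = ", "))
    vals <- as.matrix(wide[-1])
    vals[is.na(vals)] <- 0  # empty cells are structural zeros
    idx <- match(runs, runMap$run_id)
    df <- data.frame(
      run_id      = rep(runs, each = nrow(wide)),
      subject_id  = rep(runMap$subject_id[idx], each = nrow(wide)),
      replicate   = rep(runMap$replicate[idx], each = nrow(wide)),
      accession   = rep(wide$accession, times = length(runs)),
      gene_symbol = NA_character_,
      spc         = as.vector(vals),
      stringsAsFactors = FALSE
    )
  }
  validateRunTable(df)
}

#' Validate run-table invariants
#'
#' Checks the contract every downstream operation relies on: non-negative
#' counts, unique (run_id, accession) records, and a single
#' (subject_id, replicate) identity per run.
#'
#' @param df a run-table data.frame.
#' @return the data.frame, invisibly unchanged, if valid.
#' @export
validateRunTable <- function(df) {
  if (!is.numeric(df$spc))
    stop("validation error: spc must be numeric")
  bad <- which(is.na(df$spc) | df$spc < 0)
  if (length(bad))
    stop("validation error: negative or missing spc at row ", bad[1])
  key <- paste(df$run_id, df$accession, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))[1]
    stop("validation error: duplicate (run_id, accession) record at row ", dup)
  }
  ident <- unique(df[c("run_id", "subject_id", "replicate")])
  if (anyDuplicated(ident$run_id))
    stop("validation error: run_id mapped to more than one ",
         "(subject_id, replicate) pair")
  df
}

#' Align run-level protein lists into a single SpC matrix
#'
#' Builds the proteins x runs matrix over the union of all accessions seen
#' in any run. A protein absent from a run's list was not identified there:
#' its cell is a structural zero, not a missing value. Column order follows
#' the run order of the input; row order follows first appearance.
#'
#' @param runs a run-table data.frame (see [readRunTable()]).
#' @return an [SpcExperiment-class] at run level.
#' @export
alignRuns <- function(runs) {
  runs <- validateRunTable(runs)
  runIds <- unique(runs$run_id)
  if (length(runIds) < 2L)
    stop("at least 2 runs are required for alignment")
  accs <- unique(runs$accession)
  m <- matrix(0, nrow = length(accs), ncol = length(runIds),
              dimnames = list(accs, runIds))
  m[cbind(match(runs$accession, accs), match(runs$run_id, runIds))] <- runs$spc
  ident <- unique(runs[c("run_id", "subject_id", "replicate")])
  ident <- ident[match(runIds, ident$run_id), ]
  cd <- DataFrame(subject_id = ident$subject_id,
                  replicate  = ident$replicate,
                  row.names  = runIds)
  sym <- runs$gene_symbol[match(accs, runs$accession)]
  rd <- DataFrame(gene_symbol = sym, row.names = accs)
  se <- SpcExperiment(m, colData = cd, rowData = rd, level = "run")
  addProvenance(se, sprintf(
    "aligned %d runs over the union of %d accessions (absent = 0)",
    length(runIds), length(accs)))
}

#' Total-spectral-count normalization
#'
#' Scales every column so that its total equals the grand mean of the
#' original column totals: column j is multiplied by
#' mean(totals) / totals[j]. This removes run-to-run differences in overall
#' MS/MS sampling depth while leaving within-column protein ranks untouched.
#' The pre-normalization counts are retained in the \code{"raw"} assay.
#'
#' @param x an [SpcExperiment-class].
#' @return the normalized SpcExperiment (\code{isNormalized(x)} is TRUE).
#' @export
normalizeTotalSpc <- function(x) {
  stopifnot(is(x, "SpcExperiment"))
  m <- spc(x)
  totals <- colSums(m)
  if (any(totals == 0))
    stop("zero-total column(s): ",
         paste(colnames(m)[totals == 0], collapse = ", "))
  target <- mean(totals)
  scaled <- sweep(m, 2, target / totals, "*")
  if (!"raw" %in% assayNames(x))
    assays(x)$raw <- m
  assay(x, "spc") <- scaled
  x@normalized <- TRUE
  addProvenance(x, sprintf(
    "total-SpC normalization: each column scaled to the grand mean total %.6g",
    target))
}

#' Detection-frequency filter
#'
#' Retains proteins identified (raw SpC > 0) in strictly more than
#' \code{minFrac} of the runs. Detection is always evaluated on the
#' pre-normalization counts, so the result does not depend on whether
#' normalization has been applied.
#'
#' @param x an [SpcExperiment-class] at run level.
#' @param minFrac minimum detection fraction, default 0.25 (strictly
#'   greater than 25\% of runs; with 42 runs this keeps proteins detected
#'   in at least 11).
#' @return the row-filtered SpcExperiment.
#' @export
filterByFrequency <- function(x, minFrac = 0.25) {
  stopifnot(is(x, "SpcExperiment"))
  if (spcLevel(x) != "run")
    stop("frequency filtering is defined at run level")
  if (minFrac < 0 || minFrac >= 1)
    stop("minFrac must be in [0, 1)")
  raw <- rawSpc(x)
  freq <- rowSums(raw > 0) / ncol(raw)
  keep <- freq > minFrac
  if (!any(keep))
    warning("no protein exceeds the detection-frequency threshold")
  out <- x[keep, ]
  addProvenance(out, sprintf(
    "frequency filter: kept %d/%d proteins detected in > %g%% of %d runs",
    sum(keep), nrow(x), 100 * minFrac, ncol(x)))
}

#' Technical-replicate quality control
#'
#' For each subject's pair of technical replicates, computes the Pearson
#' correlation and the least-squares slope of replicate 2 regressed on
#' replicate 1, over the proteins detected in at least one of the two runs.
#' Well-behaved replicates show correlation near 1 and slope close to the
#' theoretical value of 1. QC is flag-only: no run is ever dropped
#' automatically.
#'
#' @param x an [SpcExperiment-class] at run level (raw counts are used).
#' @param minCorrelation pass threshold on the correlation (default 0.8).
#' @param slopeRange pass window on the slope (default c(0.8, 1.25)).
#' @return data.frame with one row per subject: subject_id, correlation,
#'   slope, n_shared_proteins, pass.
#' @export
replicateQc <- function(x, minCorrelation = 0.8, slopeRange = c(0.8, 1.25)) {
  stopifnot(is(x, "SpcExperiment"))
  if (spcLevel(x) != "run")
    stop("replicate QC is defined at run level")
  pairing <- replicatePairing(x)
  raw <- rawSpc(x)
  out <- lapply(names(pairing), function(s) {
    r1 <- raw[, pairing[[s]][1]]
    r2 <- raw[, pairing[[s]][2]]
    det <- r1 > 0 | r2 > 0
    n <- sum(det)
    if (n >= 2 && stats::sd(r1[det]) > 0) {
      cc <- suppressWarnings(stats::cor(r1[det], r2[det]))
      slope <- stats::cov(r1[det], r2[det]) / stats::var(r1[det])
    } else {
      cc <- NaN
      slope <- NaN
    }
    pass <- !is.na(cc) && !is.na(slope) &&
      cc >= minCorrelation && slope >= slopeRange[1] && slope <= slopeRange[2]
    data.frame(subject_id = s, correlation = cc, slope = slope,
               n_shared_proteins = n, pass = pass,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# subject -> c(run of replicate 1, run of replicate 2); errors unless every
# subject has exactly two replicate runs
replicatePairing <- function(x) {
  cd <- colData(x)
  subjects <- unique(cd$subject_id)
  pairing <- lapply(subjects, function(s) {
    runs <- rownames(cd)[cd$subject_id == s]
    if (length(runs) != 2L)
      stop("subject ", s, " has ", length(runs),
           " runs; exactly 2 technical replicates are required")
    runs[order(cd[runs, "replicate"])]
  })
  names(pairing) <- subjects
  pairing
}

#' Average technical replicates into per-subject aSpC profiles
#'
#' Collapses the run-level matrix to one column per subject holding the
#' arithmetic mean of its two technical replicates (the average spectral
#' count, aSpC). Fractional values are expected after averaging and
#' normalization.
#'
#' @param x an [SpcExperiment-class] at run level with complete replicate
#'   pairing.
#' @return an [SpcExperiment-class] at subject level.
#' @export
averageReplicates <- function(x) {
  stopifnot(is(x, "SpcExperiment"))
  if (spcLevel(x) != "run")
    stop("replicate averaging starts from a run-level matrix")
  pairing <- replicatePairing(x)
  m <- spc(x)
  avg <- vapply(pairing, function(rr) (m[, rr[1]] + m[, rr[2]]) / 2,
                numeric(nrow(m)))
  rownames(avg) <- rownames(m)
  cd <- DataFrame(subject_id = names(pairing), row.names = names(pairing))
  out <- SpcExperiment(avg, colData = cd, rowData = rowData(x),
                       level = "subject", normalized = isNormalized(x),
                       provenance = provenance(x))
  addProvenance(out, sprintf(
    "replicates averaged to aSpC over %d subjects", length(pairing)))
}

#' Write an SpC matrix as TSV with provenance header
#'
#' Writes the working matrix with accessions as the first column and the
#' provenance log as '#'-prefixed comment lines above the header.
#'
#' @param x an [SpcExperiment-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSpcMatrix <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in provenance(x)) writeLines(paste("#", p), con)
  df <- data.frame(accession = rownames(x), spc(x), check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
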