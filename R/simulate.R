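#' Simulation configuration for synthetic SpC cohorts
#'
#' Bundles and validates the parameters of the synthetic-data generator.
#' The defaults reproduce the scale and structure of the study cohort the
#' pipeline was designed for: 21 subjects in three latent groups of 9, 6
#' and 6, two technical replicates each (42 runs), ~1200 proteins with a
#' long-tailed (log-normal) baseline abundance distribution, 1\% of
#' proteins planted as group-specific markers at fold change 4, and
#' moderate negative-binomial overdispersion so that technical replicates
#' show correlation near 1 and regression slope close to 1.
#'
#' @param nGroups number of latent subject groups (default 3).
#' @param subjectsPerGroup subjects in each group (default c(9, 6, 6)).
#' @param replicates technical replicates per subject (default 2).
#' @param nProteins proteins simulated (default 1200).
#' @param markerFracPerGroup fraction of proteins planted as markers of
#'   each group (default 0.01).
#' @param foldChange expected-abundance multiplier of a marker in its own
#'   group (default 4; 1 = null simulation with no group structure).
#' @param baselineLogMean,baselineLogSd meanlog/sdlog of the log-normal
#'   baseline expected SpC per protein (defaults -0.5 and 2: a long
#'   low-abundance tail, so the >25% detection filter removes roughly a
#'   third of the proteins, as a real detection filter does).
#' @param dispersion negative-binomial dispersion phi, with
#'   variance = mu + phi * mu^2 (default 0.08).
#' @param runSizeFactorSd sdlog of the per-run log-normal sampling-depth
#'   factor (default 0.1).
#' @param fotNoiseSd residual SD of the simulated impedance Z-scores
#'   (default 1).
#' @param seed integer seed; all randomness flows from it.
#' @return validated configuration list of class \code{SimConfig}.
#' @export
simConfig <- function(nGroups = 3, subjectsPerGroup = c(9, 6, 6),
                      replicates = 2, nProteins = 1200,
                      markerFracPerGroup = 0.01, foldChange = 4,
                      baselineLogMean = -0.5, baselineLogSd = 2,
                      dispersion = 0.08, runSizeFactorSd = 0.1,
                      fotNoiseSd = 1, seed = 1) {
  if (length(subjectsPerGroup) != nGroups)
    stop("subjectsPerGroup must have one entry per group")
  if (any(subjectsPerGroup < 1) || nProteins < 1 || replicates < 1)
    stop("counts must be positive")
  if (foldChange < 1)
    stop("foldChange must be >= 1")
  if (markerFracPerGroup * nGroups >= 1)
    stop("config error: markerFracPerGroup x nGroups must be < 1")
  if (dispersion <= 0)
    stop("dispersion must be > 0")
  structure(list(
    nGroups = as.integer(nGroups),
    subjectsPerGroup = as.integer(subjectsPerGroup),
    replicates = as.integer(replicates),
    nProteins = as.integer(nProteins),
    markerFracPerGroup = markerFracPerGroup,
    foldChange = foldChange,
    baselineLogMean = baselineLogMean,
    baselineLogSd = baselineLogSd,
    dispersion = dispersion,
    runSizeFactorSd = runSizeFactorSd,
    fotNoiseSd = fotNoiseSd,
    seed = as.integer(seed)
  ), class = "SimConfig")
}

#' Simulate a run-level spectral-count cohort
#'
#' Draws per-protein baseline expected counts from a log-normal, plants
#' disjoint group-specific marker sets whose expectation is multiplied by
#' \code{foldChange} in their own group only (one-vs-rest up-regulation),
#' applies an independent log-normal sampling-depth factor to every run,
#' and draws counts from a negative binomial with the configured
#' dispersion. Both technical replicates of a subject share the subject's
#' expected profile but have independent depth factors and counts, so
#' replicate pairs show realistic correlation below 1 with slope near 1.
#' Marker proteins are drawn from the proteins with baseline expectation
#' >= 2 spectra, reflecting that usable panel markers are reliably
#' quantified proteins, not ones at the detection floor.
#'
#' @param cfg a [simConfig()] object.
#' @return list with \code{runs} (a long run-table data.frame consumable
#'   by [alignRuns()]) and \code{truth} (planted groups, marker sets,
#'   baseline means, size factors and the seed).
#' @export
simulateSpc <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  P <- cfg$nProteins
  accs <- sprintf("P%04d", seq_len(P))
  mu <- stats::rlnorm(P, cfg$baselineLogMean, cfg$baselineLogSd)
  names(mu) <- accs

  groupsLab <- LETTERS[seq_len(cfg$nGroups)]
  nMark <- round(cfg$markerFracPerGroup * P)
  candidates <- accs[mu >= 2]
  if (length(candidates) < nMark * cfg$nGroups)
    stop("too few marker candidates; raise baselineLogMean or lower ",
         "markerFracPerGroup")
  markerPool <- sample(candidates, nMark * cfg$nGroups)
  markers <- split(markerPool, rep(groupsLab, each = nMark))

  subjIds <- sprintf("S%02d", seq_len(sum(cfg$subjectsPerGroup)))
  subjGroup <- stats::setNames(rep(groupsLab, cfg$subjectsPerGroup), subjIds)

  size <- 1 / cfg$dispersion            # NB size: var = mu + phi mu^2
  rows <- vector("list", length(subjIds) * cfg$replicates)
  sizeFactors <- numeric(0)
  i <- 0L
  for (s in subjIds) {
    expProfile <- mu
    gmark <- markers[[subjGroup[[s]]]]
    expProfile[gmark] <- expProfile[gmark] * cfg$foldChange
    for (r in seq_len(cfg$replicates)) {
      i <- i + 1L
      runId <- sprintf("%s_r%d", s, r)
      sf <- stats::rlnorm(1, 0, cfg$runSizeFactorSd)
      sizeFactors[runId] <- sf
      counts <- stats::rnbinom(P, size = size, mu = expProfile * sf)
      det <- counts > 0
      rows[[i]] <- data.frame(
        run_id = runId, subject_id = s, replicate = r,
        accession = accs[det],
        gene_symbol = sub("^P", "GENE", accs[det]),
        spc = counts[det], stringsAsFactors = FALSE)
    }
  }
  runs <- do.call(rbind, rows)
  rownames(runs) <- NULL
  truth <- structure(list(
    groups = subjGroup, markers = markers, baselineMeans = mu,
    sizeFactors = sizeFactors, foldChange = cfg$foldChange,
    seed = cfg$seed), class = "SimTruth")
  list(runs = runs, truth = truth)
}

#' Default group shifts for the simulated impedance phenotype
#'
#' Emulates the phenotype contrast the pipeline is meant to detect: the
#' first group has higher resistance (Rrs) and AX Z-scores and lower
#' reactance (Xrs) Z-scores, the last group the opposite pattern, and
#' middle groups sit at zero.
#'
#' @param nGroups number of groups.
#' @return groups x 7 matrix of Z-score offsets (columns z_rrs6 ... z_ax).
#' @export
defaultFotShifts <- function(nGroups = 3) {
  vars <- fotZVars()
  shifts <- matrix(0, nGroups, length(vars),
                   dimnames = list(LETTERS[seq_len(nGroups)], vars))
  pattern <- c(1, 1, 1, -1, -1, -1, 1)   # rrs up, xrs down, ax up
  shifts[1, ] <- pattern
  if (nGroups > 1) shifts[nGroups, ] <- -pattern
  shifts
}

#' Simulate per-subject FOT Z-scores with planted group shifts
#'
#' Each subject's seven impedance Z-scores are its group's shift vector
#' plus independent Gaussian noise. Two binary covariates (female sex,
#' late-preterm birth) are drawn independently of group for cohort-table
#' exercises.
#'
#' @param truth the \code{truth} component of [simulateSpc()].
#' @param shifts groups x 7 matrix of Z-score offsets; default
#'   [defaultFotShifts()] for the truth's groups.
#' @param noiseSd residual SD (default 1).
#' @param seed integer seed.
#' @return data.frame with subject_id, z_rrs6 ... z_ax, sex_female,
#'   preterm.
#' @export
simulateFot <- function(truth, shifts = NULL, noiseSd = 1, seed = 1) {
  stopifnot(inherits(truth, "SimTruth"))
  labs <- sort(unique(unname(truth$groups)))
  if (is.null(shifts))
    shifts <- defaultFotShifts(length(labs))
  if (!all(labs %in% rownames(shifts)))
    stop("shifts must have one row per planted group")
  set.seed(seed)
  subjects <- names(truth$groups)
  vars <- fotZVars()
  z <- shifts[truth$groups[subjects], vars, drop = FALSE] +
    matrix(stats::rnorm(length(subjects) * length(vars), 0, noiseSd),
           length(subjects), length(vars))
  out <- data.frame(subject_id = subjects, z,
                    sex_female = stats::runif(length(subjects)) < 0.4,
                    preterm = stats::runif(length(subjects)) < 0.55,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items:
#' 1 for identical partitions (up to label names), ~0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return the adjusted Rand index.
#' @export
adjustedRand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  sumIj <- sum(choose(tab, 2))
  sumI <- sum(choose(rowSums(tab), 2))
  sumJ <- sum(choose(colSums(tab), 2))
  expected <- sumI * sumJ / choose(length(a), 2)
  maxIdx <- (sumI + sumJ) / 2
  if (maxIdx == expected) return(ifelse(sumIj == expected, 1, 0))
  (sumIj - expected) / (maxIdx - expected)
}

# best achievable accuracy over all bijective relabelings (groups are
# identified only up to permutation)
bestLabelAccuracy <- function(pred, truth) {
  labsP <- unique(pred); labsT <- unique(truth)
  perms <- allPermutations(labsT)
  best <- 0
  for (pm in perms) {
    map <- stats::setNames(pm, labsT[seq_along(pm)])
    if (length(labsP) > length(pm)) next
    acc <- mean(map[truth] == pred)
    best <- max(best, acc)
  }
  best
}

allPermutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(allPermutations(v[-i]), function(p) c(v[i], p)))
  out
}

#' Run the full pipeline on one simulation and score recovery
#'
#' Generates a cohort with [simulateSpc()], runs ingest (align, normalize,
#' QC, frequency filter, replicate averaging), Ward clustering, the
#' F-ratio/LDA discriminant screen, DAve/DCI differential analysis,
#' marker-panel alpha typing and the FOT linkage, then scores every stage
#' against the planted truth.
#'
#' Marker recall and precision are scored on the pipeline's nominated
#' marker pool — the intersection of the F/LDA discriminant list with the
#' DAve/DCI DEP set — against the planted markers that survive the
#' detection-frequency filter (the screen can only select proteins it
#' sees). Two false-selection rates are reported for the F screen itself:
#' one conditioned on the clustering-derived groups (which includes the
#' selection bias of testing on groups found in the same data) and one
#' conditioned on the planted groups (the screen's intrinsic calibration;
#' this is the relevant null-simulation quantity).
#'
#' @param cfg a [simConfig()] object.
#' @param minFrac,fMin,pMax,daveThreshold,dciThreshold,panelSize,transform,
#'   lambda pipeline parameters (defaults as in the study configuration).
#' @param k number of clusters to cut (default: the number of planted
#'   groups).
#' @return list of recovery metrics and intermediate objects.
#' @export
endToEndRecovery <- function(cfg = simConfig(), minFrac = 0.25,
                             k = cfg$nGroups, fMin = 5, pMax = 0.01,
                             daveThreshold = 0.2, dciThreshold = 5,
                             panelSize = 6, transform = "log2p1",
                             lambda = 0.5) {
  sim <- simulateSpc(cfg)
  se <- alignRuns(sim$runs)
  qc <- replicateQc(se)
  se <- normalizeTotalSpc(se)
  se <- filterByFrequency(se, minFrac)
  subj <- averageReplicates(se)

  hc <- clusterSubjects(subj, transform)
  clusterGroups <- cutTree(hc, k)
  truthGroups <- sim$truth$groups[colnames(subj)]
  clusterAgreement <- adjustedRand(clusterGroups[colnames(subj)], truthGroups)

  planted <- unlist(sim$truth$markers, use.names = FALSE)
  plantedRetained <- intersect(planted, rownames(subj))
  nNull <- nrow(subj) - length(plantedRetained)

  screen <- function(grouping) {
    ok <- all(table(grouping[colnames(subj)]) >= 2) &&
      length(unique(grouping[colnames(subj)])) >= 2
    if (!ok) return(NULL)
    d <- fRatioSelect(subj, grouping, fMin, pMax)
    d$accession[d$selected]
  }
  selected <- screen(clusterGroups)
  screenFpRate <- if (!is.null(selected) && nNull > 0)
    length(setdiff(selected, plantedRetained)) / nNull else NA_real_
  selectedTrue <- screen(truthGroups)
  screenFpRateTrueGroups <- if (!is.null(selectedTrue) && nNull > 0)
    length(setdiff(selectedTrue, plantedRetained)) / nNull else NA_real_

  deps <- pairwiseDeps(subj, clusterGroups, daveThreshold, dciThreshold)
  panel <- intersectPanels(if (is.null(selected)) character() else selected,
                           deps, subj, clusterGroups)
  pool <- panelProteins(panel)
  tp <- length(intersect(pool, plantedRetained))
  markerRecall <- if (length(plantedRetained)) tp / length(plantedRetained)
                  else NA_real_
  markerPrecision <- if (length(pool)) tp / length(pool) else NA_real_

  alphaAccuracy <- NA_real_
  panelTop <- NULL
  if (length(pool) >= 2) {
    panelTop <- selectMarkerPanel(panel, deps, panelSize)
    profiles <- alphaProfile(subj, panelTop)
    centroids <- alphaCentroids(subj, panelTop, clusterGroups)
    assigned <- assignByAlpha(profiles, centroids)
    pred <- stats::setNames(assigned$assigned, assigned$subject_id)
    alphaAccuracy <- bestLabelAccuracy(pred[colnames(subj)], truthGroups)
  }

  fot <- simulateFot(sim$truth, noiseSd = cfg$fotNoiseSd,
                     seed = cfg$seed + 1L)
  fotReport <- compareGroupsFot(fot, clusterGroups)

  list(
    qc = qc,
    nIdentified = length(unique(sim$runs$accession)),
    nRetained = nrow(subj),
    nDiscriminants = length(selected),
    nDeps = length(depProteins(deps)),
    nOverlap = length(pool),
    clusterGroups = clusterGroups,
    clusterAgreement = clusterAgreement,
    markerRecall = markerRecall,
    markerPrecision = markerPrecision,
    screenFpRate = screenFpRate,
    screenFpRateTrueGroups = screenFpRateTrueGroups,
    panel = panelTop,
    alphaAccuracy = alphaAccuracy,
    fotSummary = fotReport$summary,
    fotPairwise = fotReport$pairwise
  )
}
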