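#' Read a per-subject FOT phenotype table
#'
#' Tab-delimited file with a \code{subject_id} column, the seven impedance
#' Z-score columns (\code{z_rrs6}, \code{z_rrs8}, \code{z_rrs10},
#' \code{z_xrs6}, \code{z_xrs8}, \code{z_xrs10}, \code{z_ax}) and any
#' number of free covariate columns. Missing covariate values are allowed;
#' Z-scores must be finite.
#'
#' @param path path to the TSV.
#' @return a validated data.frame.
#' @export
readFotTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(df))
    stop("format error: missing required column: subject_id")
  if (anyDuplicated(df$subject_id))
    stop("validation error: duplicate subject_id")
  zc <- intersect(fotZVars(), names(df))
  if (!length(zc))
    stop("format error: no FOT Z-score column found (expected z_rrs6 ... z_ax)")
  for (v in zc)
    if (any(!is.finite(df[[v]])))
      stop("validation error: non-finite Z-score in column ", v)
  df
}

fotZVars <- function() {
  c("z_rrs6", "z_rrs8", "z_rrs10", "z_xrs6", "z_xrs8", "z_xrs10", "z_ax")
}

#' Kruskal-Wallis rank test
#'
#' Rank-based comparison of a quantitative variable across >= 2 groups,
#' with tie correction; the H statistic is referred to a chi-squared
#' distribution with G - 1 degrees of freedom (via
#' \code{stats::kruskal.test}).
#'
#' @param values numeric vector.
#' @param groups group label for each value.
#' @return list with elements H, df and p.
#' @export
kruskalWallis <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L)
    stop("at least 2 groups are required")
  if (length(values) < 2L)
    stop("at least 2 observations are required")
  G <- nlevels(droplevels(groups))
  if (length(unique(values)) == 1L)   # all observations tied: no evidence
    return(list(H = 0, df = G - 1, p = 1))
  kt <- stats::kruskal.test(values, droplevels(groups))
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Dunn's post hoc pairwise comparisons with Holm adjustment
#'
#' The standard follow-up to a Kruskal-Wallis test: for each pair of
#' groups, a z statistic on the difference of mean pooled ranks with the
#' tie-corrected variance, and two-sided p-values adjusted across the
#' G(G-1)/2 pairs by Holm's step-down method.
#'
#' @param values numeric vector.
#' @param groups group label for each value.
#' @param method adjustment pipeline; only \code{"dunn_holm"} is
#'   implemented.
#' @return data.frame with group_x, group_y, z, p and p_adj, pairs in
#'   canonical label order.
#' @export
posthocPairwise <- function(values, groups, method = c("dunn_holm")) {
  method <- match.arg(method)
  groups <- droplevels(as.factor(groups))
  labs <- sort(levels(groups))
  if (length(labs) < 2L)
    stop("at least 2 groups are required")
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  varTerm <- N * (N + 1) / 12 - tieCorr
  rbar <- tapply(r, groups, mean)
  n <- table(groups)
  pairs <- utils::combn(labs, 2, simplify = FALSE)
  out <- do.call(rbind, lapply(pairs, function(pr) {
    se2 <- varTerm * (1 / n[[pr[1]]] + 1 / n[[pr[2]]])
    z <- if (se2 <= 0) 0 else (rbar[[pr[1]]] - rbar[[pr[2]]]) / sqrt(se2)
    data.frame(group_x = pr[1], group_y = pr[2], z = z,
               p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  }))
  out$p_adj <- stats::p.adjust(out$p, method = "holm")
  rownames(out) <- NULL
  out
}

#' Chi-squared test for a 2x2 table with Yates continuity correction
#'
#' chi2 = sum over the four cells of (max(|O - E| - 0.5, 0))^2 / E, with
#' expected counts from the margins and p from the chi-squared distribution
#' with 1 df (this is exactly \code{stats::chisq.test(correct = TRUE)} for
#' a 2x2 table). The truncation at zero means small deviations yield
#' chi2 = 0 and p = 1.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @return list with elements chi2 and p.
#' @export
chi2Yates <- function(tab) {
  tab <- as.matrix(tab)
  if (!identical(dim(tab), c(2L, 2L)))
    stop("a 2x2 table is required")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row or column margin: expected counts undefined")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  list(chi2 = unname(ct$statistic), p = ct$p.value)
}

#' Compare FOT Z-scores across proteome groups
#'
#' For every impedance Z-score variable present in the phenotype table:
#' per-group median and IQR, the Kruskal-Wallis H and p across the
#' proteome-defined groups, and Dunn-Holm post hoc pairwise adjusted
#' p-values.
#'
#' @param fot data.frame from [readFotTable()].
#' @param groups named subject-to-label mapping (e.g. from [cutTree()]).
#' @return list with \code{summary} (one row per variable: H, df, p and
#'   per-group median/IQR columns) and \code{pairwise} (per variable and
#'   group pair: z, p, p_adj).
#' @export
compareGroupsFot <- function(fot, groups) {
  subjects <- names(groups)
  missing <- setdiff(subjects, fot$subject_id)
  if (length(missing))
    stop("no FOT record for subject(s): ", paste(missing, collapse = ", "))
  labs <- sort(unique(unname(groups)))
  if (length(labs) < 2L)
    stop("at least 2 groups are required")
  fot <- fot[match(subjects, fot$subject_id), , drop = FALSE]
  g <- factor(unname(groups[subjects]), levels = labs)
  zvars <- intersect(fotZVars(), names(fot))
  summ <- list(); pw <- list()
  for (v in zvars) {
    vals <- fot[[v]]
    kw <- kruskalWallis(vals, g)
    row <- data.frame(variable = v, H = kw$H, df = kw$df, p = kw$p,
                      stringsAsFactors = FALSE)
    for (lab in labs) {
      gv <- vals[g == lab]
      row[[paste0("median_", lab)]] <- stats::median(gv)
      row[[paste0("iqr_", lab)]] <- stats::IQR(gv)
    }
    summ[[v]] <- row
    ph <- posthocPairwise(vals, g)
    ph <- cbind(variable = v, ph)
    pw[[v]] <- ph
  }
  list(summary = do.call(rbind, c(summ, list(make.row.names = FALSE))),
       pairwise = do.call(rbind, c(pw, list(make.row.names = FALSE))))
}

#' Cohort characteristics table split by a binary covariate
#'
#' Reproduces the usual "Table 1" layout comparing two study arms: logical
#' (or two-level categorical) covariates are summarized as n (%) with a
#' Yates-corrected chi-squared p-value, numeric covariates as mean (SD)
#' with a Kruskal-Wallis p-value. Missing values are dropped per row
#' (pairwise-complete), and the per-arm denominators actually used are
#' reported.
#'
#' @param records data.frame with subject_id, the split column, and
#'   covariate columns.
#' @param split name of the binary covariate defining the two arms.
#' @return data.frame with one row per covariate: variable, type, the two
#'   formatted arm summaries, per-arm n, and p.
#' @export
cohortTable <- function(records, split) {
  if (!split %in% names(records))
    stop("split covariate not found: ", split)
  arm <- as.factor(records[[split]])
  arm <- droplevels(arm)
  if (nlevels(arm) != 2L)
    stop("split covariate must be binary; found ", nlevels(arm), " level(s)")
  arms <- levels(arm)
  vars <- setdiff(names(records), c("subject_id", split))
  rows <- lapply(vars, function(v) {
    val <- records[[v]]
    ok <- !is.na(val)
    a <- arm[ok]; x <- val[ok]
    n1 <- sum(a == arms[1]); n2 <- sum(a == arms[2])
    if (is.numeric(x) && !is.logical(x)) {
      p <- if (length(unique(x)) == 1L) 1 else kruskalWallis(x, a)$p
      fmt <- function(aa) sprintf("%.2f (%.2f)", mean(x[a == aa]),
                                  stats::sd(x[a == aa]))
      type <- "quantitative"
    } else {
      if (is.logical(x)) {
        x <- factor(x, levels = c(FALSE, TRUE))
      } else {
        x <- droplevels(as.factor(x))
        if (nlevels(x) > 2L)
          stop("covariate ", v, " has more than 2 levels; only binary ",
               "categorical covariates are supported")
      }
      pos <- levels(x)[nlevels(x)]
      tab <- table(a, x)
      # a level absent from an arm or the whole cohort degenerates the
      # 2x2 test; report p = 1 (no evidence of imbalance)
      p <- if (nlevels(x) < 2L || any(rowSums(tab) == 0) ||
               any(colSums(tab) == 0)) 1 else chi2Yates(tab)$p
      fmt <- function(aa) {
        k <- sum(x[a == aa] == pos)
        sprintf("%d (%.2f)", k, 100 * k / sum(a == aa))
      }
      type <- "categorical"
    }
    out <- data.frame(variable = v, type = type,
                      arm1 = fmt(arms[1]), arm2 = fmt(arms[2]),
                      n1 = n1, n2 = n2, p = round(p, 3),
                      stringsAsFactors = FALSE)
    names(out)[3:4] <- arms
    out
  })
  do.call(rbind, rows)
}
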