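test_that("long TSV reading validates schema and contracts", {
  tsv <- tempfile(fileext = ".tsv")
  df <- data.frame(run_id = "S01_r1", subject_id = "S01", replicate = 1,
                   accession = c("P1", "P2", "P3"),
                   gene_symbol = c("A", "B", "C"), spc = c(5, 3, 1))
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  rt <- readRunTable(tsv, "long_tsv")
  expect_equal(nrow(rt), 3)
  expect_equal(rt$spc, c(5, 3, 1))

  # missing column is named in the error
  bad <- tsv
  write.table(df[setdiff(names(df), "spc")], bad, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(readRunTable(bad, "long_tsv"), "spc")

  # negative count reported with its row
  df2 <- df; df2$spc[2] <- -1
  write.table(df2, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readRunTable(tsv, "long_tsv"), "row 2")

  # duplicate (run, accession) record
  df3 <- rbind(df, df[1, ])
  write.table(df3, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readRunTable(tsv, "long_tsv"), "duplicate")
})

test_that("wide CSV reading keeps explicit zeros and needs a run map", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("accession,R1,R2", "P1,5,0", "P2,,3"), csv)
  rmap <- data.frame(run_id = c("R1", "R2"), subject_id = c("S1", "S1"),
                     replicate = 1:2)
  rt <- readRunTable(csv, "wide_csv", runMap = rmap)
  expect_equal(nrow(rt), 4)                    # zeros retained as records
  expect_equal(rt$spc[rt$run_id == "R2" & rt$accession == "P1"], 0)
  expect_equal(rt$spc[rt$run_id == "R1" & rt$accession == "P2"], 0)
  expect_error(readRunTable(csv, "wide_csv"), "runMap")
})

test_that("alignRuns builds the union matrix with structural zeros", {
  rt <- data.frame(run_id = c("r1", "r2"), subject_id = c("s1", "s2"),
                   replicate = 1L, accession = c("P1", "P2"),
                   gene_symbol = NA, spc = c(5, 3))
  se <- alignRuns(rt)
  expect_equal(unname(spc(se)), matrix(c(5, 0, 0, 3), 2))
  expect_equal(rownames(se), c("P1", "P2"))

  # identical runs give identical columns
  m <- matrix(c(4, 2, 4, 2), 2, dimnames = list(c("P1", "P2"),
                                                c("a_r1", "a_r2")))
  se2 <- alignRuns(runTableFromMatrix(m))
  expect_equal(spc(se2)[, 1], spc(se2)[, 2])
})

test_that("union row count matches a set-union oracle on random run sets", {
  set.seed(42)
  for (rep in 1:5) {
    pools <- lapply(1:3, function(i)
      sample(sprintf("P%02d", 1:20), sample(3:12, 1)))
    rt <- do.call(rbind, lapply(1:3, function(i)
      data.frame(run_id = paste0("r", i), subject_id = paste0("s", i),
                 replicate = 1L, accession = pools[[i]], gene_symbol = NA,
                 spc = seq_along(pools[[i]]))))
    se <- alignRuns(rt)
    expect_equal(nrow(se), length(Reduce(union, pools)))
  }
})

test_that("alignRuns is column-order equivariant", {
  set.seed(7)
  m <- matrix(rpois(40, 3), 5, 8,
              dimnames = list(paste0("P", 1:5),
                              paste0("S", rep(1:4, each = 2), "_r", 1:2)))
  rt <- runTableFromMatrix(m)
  se <- alignRuns(rt)
  perm <- sample(unique(rt$run_id))
  rtp <- rt[order(match(rt$run_id, perm)), ]
  sep <- alignRuns(rtp)
  expect_equal(spc(sep)[rownames(se), colnames(se)], spc(se))
})

test_that("total-SpC normalization equalizes column totals to the grand mean", {
  m <- matrix(c(60, 40, 120, 80), 2,
              dimnames = list(c("P1", "P2"), c("r1", "r2")))
  se <- runSe(m, c("s1", "s1"), 1:2)
  nse <- normalizeTotalSpc(se)
  expect_true(isNormalized(nse))
  expect_equal(unname(colSums(spc(nse))), c(150, 150))
  expect_equal(unname(spc(nse)[, "r1"]), c(60, 40) * 1.5)
  expect_equal(unname(spc(nse)[, "r2"]), c(120, 80) * 0.75)
  expect_equal(rawSpc(nse), m)                 # raw counts preserved

  # equal totals: identity
  meq <- matrix(c(6, 4, 7, 3), 2, dimnames = list(c("P1", "P2"),
                                                  c("r1", "r2")))
  expect_equal(spc(normalizeTotalSpc(runSe(meq, c("s", "s"), 1:2))), meq)

  # zero-total column names the run
  mz <- m; mz[, 2] <- 0
  expect_error(normalizeTotalSpc(runSe(mz, c("s", "s"), 1:2)), "r2")
})

test_that("normalization is idempotent and preserves within-column ranks", {
  set.seed(3)
  m <- matrix(rpois(60, 10) + 1, 10, 6,
              dimnames = list(paste0("P", 1:10),
                              paste0("S", rep(1:3, each = 2), "_r", 1:2)))
  se <- runSe(m, rep(paste0("S", 1:3), each = 2), rep(1:2, 3))
  n1 <- normalizeTotalSpc(se)
  n2 <- normalizeTotalSpc(n1)
  expect_equal(spc(n2), spc(n1), tolerance = 1e-9)
  for (j in seq_len(ncol(m)))
    expect_equal(rank(spc(n1)[, j]), rank(m[, j]))
})

test_that("frequency filter uses strict > on raw detection counts", {
  set.seed(5)
  n <- 42
  m <- matrix(0, 3, n, dimnames = list(c("keep11", "drop10", "always"),
                                       sprintf("S%02d_r%d",
                                               rep(1:21, each = 2),
                                               rep(1:2, 21))))
  m["keep11", 1:11] <- 5       # 11/42 = 26.2% > 25%
  m["drop10", 1:10] <- 5       # 10/42 = 23.8%
  m["always", ] <- 2
  se <- runSe(m, rep(sprintf("S%02d", 1:21), each = 2), rep(1:2, 21))
  filt <- filterByFrequency(se, 0.25)
  expect_setequal(rownames(filt), c("keep11", "always"))

  # minFrac = 0 keeps everything with >= 1 detection
  expect_equal(nrow(filterByFrequency(se, 0)), 3)

  # detection is evaluated on raw counts: same result after normalization
  filtN <- filterByFrequency(normalizeTotalSpc(se), 0.25)
  expect_setequal(rownames(filtN), rownames(filt))

  # empty result warns rather than errors
  sparse <- m[c("keep11", "drop10"), , drop = FALSE]
  seSparse <- runSe(sparse, rep(sprintf("S%02d", 1:21), each = 2),
                    rep(1:2, 21))
  expect_warning(filterByFrequency(seSparse, 0.5), "no protein")
})

test_that("replicate QC computes correlation and regression slope", {
  set.seed(9)
  base <- rpois(30, 8)
  m <- cbind(s1_r1 = base, s1_r2 = base,           # identical
             s2_r1 = base, s2_r2 = 2 * base)       # doubled
  rownames(m) <- paste0("P", 1:30)
  se <- runSe(m, c("s1", "s1", "s2", "s2"), c(1, 2, 1, 2))
  qc <- replicateQc(se)
  expect_equal(qc$correlation, c(1, 1))
  expect_equal(qc$slope, c(1, 2))
  expect_equal(qc$pass, c(TRUE, FALSE))            # slope 2 outside window

  # degenerate: no shared detected protein -> NaN, fail
  mz <- cbind(s1_r1 = c(0, 0), s1_r2 = c(0, 0),
              s2_r1 = c(1, 2), s2_r2 = c(1, 2))
  rownames(mz) <- c("P1", "P2")
  sez <- runSe(mz, c("s1", "s1", "s2", "s2"), c(1, 2, 1, 2))
  qcz <- replicateQc(sez)
  expect_true(is.nan(qcz$correlation[qcz$subject_id == "s1"]))
  expect_false(qcz$pass[qcz$subject_id == "s1"])

  # a subject without exactly 2 runs is an error
  se3 <- runSe(m[, 1:3], c("s1", "s1", "s2"), c(1, 2, 1))
  expect_error(replicateQc(se3), "exactly 2")
})

test_that("replicate averaging gives aSpC and conserves half the mass", {
  m <- cbind(s1_r1 = c(4, 0), s1_r2 = c(6, 0))
  rownames(m) <- c("P1", "P2")
  se <- runSe(m, c("s1", "s1"), 1:2)
  avg <- averageReplicates(se)
  expect_equal(spcLevel(avg), "subject")
  expect_equal(unname(spc(avg)[, "s1"]), c(5, 0))

  set.seed(13)
  m2 <- matrix(rpois(10, 6), 5, 2,
               dimnames = list(paste0("P", 1:5), c("x_r1", "x_r2")))
  se2 <- runSe(m2, c("x", "x"), 1:2)
  avg2 <- averageReplicates(se2)
  expect_equal(unname(spc(avg2)[, 1]), unname(rowMeans(m2)))  # oracle
  expect_equal(sum(spc(avg2)), sum(m2) / 2)
})
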