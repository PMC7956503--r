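test_that("Kruskal-Wallis reproduces the hand-ranked example and edge cases", {
  kw <- kruskalWallis(1:9, rep(c("A", "B", "C"), each = 3))
  expect_equal(kw$H, 7.2)           # rank sums 6/15/24, 12/(N(N+1)) sum - 3(N+1)
  expect_equal(kw$df, 2)

  # all observations equal: no evidence
  kw0 <- kruskalWallis(rep(4, 9), rep(c("A", "B", "C"), each = 3))
  expect_equal(kw0$H, 0)
  expect_equal(kw0$p, 1)

  expect_error(kruskalWallis(1:5, rep("A", 5)), "2 groups")

  # invariance under strictly monotone transforms
  set.seed(71)
  x <- rnorm(18)
  g <- rep(c("A", "B", "C"), 6)
  expect_equal(kruskalWallis(exp(x), g)$H, kruskalWallis(x, g)$H)
})

test_that("two-group Kruskal-Wallis agrees with the rank-sum normal
          approximation", {
  set.seed(73)
  for (rep in 1:5) {
    x <- c(rnorm(8), rnorm(7, 1))
    g <- rep(c("A", "B"), c(8, 7))
    kw <- kruskalWallis(x, g)
    wt <- wilcox.test(x[g == "A"], x[g == "B"], exact = FALSE,
                      correct = FALSE)
    expect_equal(kw$p, wt$p.value, tolerance = 1e-10)
  }
})

test_that("Dunn-Holm post hoc behaves on null, shifted and tied data", {
  g <- rep(c("A", "B", "C"), each = 5)
  # identical groups: adjusted p all 1
  ph0 <- posthocPairwise(rep(1:5, 3), g)
  expect_equal(ph0$p_adj, rep(1, 3), tolerance = 1e-9)

  # one extreme group: its two pairs carry the smallest adjusted p
  set.seed(79)
  x <- c(rnorm(5), rnorm(5), rnorm(5, 10))
  ph <- posthocPairwise(x, g)
  withC <- ph$group_x == "C" | ph$group_y == "C"
  expect_true(max(ph$p_adj[withC]) <= min(ph$p_adj[!withC]))

  # Holm never adjusts below raw, and adjusted p is monotone
  # (non-strictly, ties allowed) in raw p
  for (s in 1:5) {
    set.seed(80 + s)
    xr <- rnorm(15)
    phr <- posthocPairwise(xr, g)
    expect_true(all(phr$p_adj >= phr$p - 1e-12))
    expect_true(all(diff(phr$p_adj[order(phr$p)]) >= -1e-12))
  }
})

test_that("Yates chi-squared is symmetric and rejects degenerate tables", {
  expect_equal(chi2Yates(matrix(c(1, 1, 1, 1), 2))$chi2, 0)
  expect_equal(chi2Yates(matrix(c(1, 1, 1, 1), 2))$p, 1)
  tab <- matrix(c(5, 2, 7, 7), 2)
  expect_equal(chi2Yates(t(tab)), chi2Yates(tab))
  expect_equal(chi2Yates(tab[2:1, 2:1]), chi2Yates(tab))
  expect_error(chi2Yates(matrix(c(0, 0, 3, 4), 2)), "margin")
  expect_error(chi2Yates(matrix(c(1.5, 1, 1, 1), 2)), "integers")
})

test_that("FOT comparison detects a planted shift and validates inputs", {
  makeFot <- function(shiftVar = NULL, shift = 0, seed = 1, n = 21) {
    set.seed(seed)
    df <- data.frame(subject_id = sprintf("S%02d", 1:n))
    for (v in c("z_rrs6", "z_rrs8", "z_rrs10", "z_xrs6", "z_xrs8",
                "z_xrs10", "z_ax"))
      df[[v]] <- rnorm(n)
    if (!is.null(shiftVar))
      df[[shiftVar]][1:7] <- df[[shiftVar]][1:7] + shift
    df
  }
  g <- setNames(rep(c("A", "B", "C"), each = 7), sprintf("S%02d", 1:21))

  # planted 1.5-SD shift: that variable has the smallest p in a majority
  # of seeded replicates
  hits <- sum(vapply(1:20, function(s) {
    rep <- compareGroupsFot(makeFot("z_xrs8", 1.5, seed = s), g)
    rep$summary$variable[which.min(rep$summary$p)] == "z_xrs8"
  }, logical(1)))
  expect_gt(hits, 10)

  # medians/IQRs are reported per group for every variable
  rep1 <- compareGroupsFot(makeFot(seed = 3), g)
  expect_equal(nrow(rep1$summary), 7)
  expect_true(all(c("median_A", "iqr_C") %in% names(rep1$summary)))
  expect_equal(nrow(rep1$pairwise), 21)           # 7 variables x 3 pairs

  # single group and missing subjects are contract errors
  expect_error(compareGroupsFot(makeFot(), g[1:7]), "2 groups")
  expect_error(compareGroupsFot(makeFot()[-1, ], g), "S01")
})

test_that("cohort table summarizes binary and quantitative covariates", {
  rec <- data.frame(
    subject_id = sprintf("S%02d", 1:21),
    birth = rep(c("LP", "T"), c(12, 9)),
    female = c(rep(TRUE, 5), rep(FALSE, 7), rep(TRUE, 2), rep(FALSE, 7)),
    smoke = c(rep(TRUE, 4), rep(FALSE, 8), rep(FALSE, 9)),
    height_z = c(rnorm(12, -0.9), rnorm(9, 0.2)),
    constant = rep(TRUE, 21)
  )
  tab <- cohortTable(rec, "birth")
  expect_equal(tab$p[tab$variable == "female"], 0.640)
  expect_equal(tab$p[tab$variable == "smoke"], 0.173)
  expect_equal(tab$LP[tab$variable == "female"], "5 (41.67)")
  expect_equal(tab$p[tab$variable == "constant"], 1)
  expect_equal(tab$type[tab$variable == "height_z"], "quantitative")

  expect_error(cohortTable(rec, "subject_id"), "binary")

  # missing values fall out pairwise with reported denominators
  rec$female[1] <- NA
  tab2 <- cohortTable(rec, "birth")
  expect_equal(tab2$n1[tab2$variable == "female"], 11)
})

test_that("FOT table reader enforces schema", {
  f <- tempfile(fileext = ".tsv")
  df <- data.frame(subject_id = c("S1", "S2"), z_rrs6 = c(0.5, -1),
                   z_ax = c(1, 2), sex = c("F", "M"))
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(nrow(readFotTable(f)), 2)
  df$z_rrs6[1] <- Inf
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readFotTable(f), "z_rrs6")
})
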