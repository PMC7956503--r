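test_that("F-ratio screen reproduces hand-computed ANOVA and its edge cases", {
  m <- rbind(X = c(1, 2, 3, 4, 5, 6, 7, 8, 9),
             CONST = rep(5, 9))
  colnames(m) <- paste0("S", 1:9)
  g <- setNames(rep(c("A", "B", "C"), each = 3), colnames(m))
  disc <- fRatioSelect(subjectSe(m), g)
  rx <- disc[disc$accession == "X", ]
  expect_equal(rx$f_ratio, 27)                    # SSB 54 / 2 over SSW 6 / 6
  expect_equal(rx$p_value, 1.0e-3, tolerance = 0.05)
  expect_true(rx$selected)
  rc <- disc[disc$accession == "CONST", ]
  expect_true(is.nan(rc$f_ratio))
  expect_false(rc$selected)

  # a group of one subject is rejected
  expect_error(fRatioSelect(subjectSe(m[, 1:7]), g[1:7]), "fewer than 2")
})

test_that("F statistic agrees with aov and with t-squared at two groups", {
  set.seed(17)
  for (rep in 1:5) {
    m <- matrix(rpois(48, 9) + rnorm(48, 0, 0.5)^2, 4, 12,
                dimnames = list(paste0("P", 1:4), paste0("S", 1:12)))
    g <- setNames(rep(c("A", "B", "C"), each = 4), colnames(m))
    disc <- fRatioSelect(subjectSe(m), g)
    for (i in 1:4) {
      fit <- anova(lm(m[i, ] ~ factor(g)))          # independent route
      expect_equal(disc$f_ratio[i], fit$`F value`[1])
      expect_equal(disc$p_value[i], fit$`Pr(>F)`[1])
    }
    # G = 2: F equals the square of the pooled-variance t statistic
    g2 <- setNames(rep(c("A", "B"), each = 6), colnames(m))
    disc2 <- fRatioSelect(subjectSe(m), g2)
    for (i in 1:4) {
      tt <- t.test(m[i, g2 == "A"], m[i, g2 == "B"], var.equal = TRUE)
      expect_equal(disc2$f_ratio[i], unname(tt$statistic)^2)
    }
  }
})

test_that("F screen is invariant to protein-wide affine transforms and
          monotone in its thresholds", {
  set.seed(19)
  m <- matrix(rpois(60, 7), 5, 12,
              dimnames = list(paste0("P", 1:5), paste0("S", 1:12)))
  g <- setNames(rep(c("A", "B", "C"), each = 4), colnames(m))
  base <- fRatioSelect(subjectSe(m), g)
  shifted <- fRatioSelect(subjectSe(m + 100), g)
  scaled <- fRatioSelect(subjectSe(m * 7), g)
  expect_equal(shifted$f_ratio, base$f_ratio)
  expect_equal(scaled$f_ratio, base$f_ratio)

  nSel <- function(fMin, pMax)
    sum(fRatioSelect(subjectSe(m), g, fMin, pMax)$selected)
  expect_true(nSel(1, 0.2) >= nSel(5, 0.2))
  expect_true(nSel(1, 0.2) >= nSel(1, 0.05))
})

test_that("LDA separates planted groups and tolerates collinearity", {
  blob <- blobMatrix(sizes = c(4, 4), centers = c(2, 40), nProteins = 2,
                     seed = 23)
  se <- subjectSe(blob$m)
  model <- fitLda(se, blob$groups)
  expect_equal(as.character(classifyLda(model, se)),
               unname(blob$groups))

  # duplicated protein column: shrinkage absorbs the singularity
  m2 <- rbind(blob$m, DUP = blob$m[1, ])
  model2 <- fitLda(subjectSe(m2), blob$groups)
  expect_s4_class(model2, "SpcLdaModel")

  # canonical axis count is min(G-1, p) on random instances
  set.seed(29)
  for (G in 2:3) {
    sizes <- rep(3, G)
    bm <- blobMatrix(sizes = sizes, centers = seq(0, 40, length.out = G),
                     nProteins = 4, seed = 29 + G)
    mod <- fitLda(subjectSe(bm$m), bm$groups)
    expect_equal(ncol(mod@scaling), min(G - 1, 4))
  }

  # fewer subjects than groups is rejected
  tiny <- blobMatrix(sizes = c(1, 1, 1), centers = c(0, 10, 20), seed = 5)
  expect_error(fitLda(subjectSe(tiny$m), tiny$groups), "subjects")
})

test_that("Mahalanobis assignment matches brute-force distances and MASS", {
  blob <- blobMatrix(sizes = c(5, 5, 5), centers = c(0, 15, 30),
                     nProteins = 3, seed = 31)
  se <- subjectSe(blob$m)
  model <- fitLda(se, blob$groups, lambda = 0.2)
  pred <- classifyLda(model, se)

  # oracle: naive per-subject stats::mahalanobis enumeration
  X <- t(spc(se))
  for (s in rownames(X)) {
    d2 <- vapply(model@groups, function(g)
      stats::mahalanobis(X[s, ], model@centroids[g, ], model@covariance),
      numeric(1))
    expect_equal(unname(pred[s]), names(which.min(d2)))
    expect_equal(unname(attr(pred, "distance")[, s]), unname(d2))
  }

  # subject placed exactly on a centroid goes to that group
  mC <- cbind(spc(se), CTR = model@centroids["B", ])
  seC <- subjectSe(mC)
  expect_equal(unname(classifyLda(model, seC)["CTR"]), "B")

  # cross-check against MASS lda with equal priors (unregularized case)
  skip_if_not_installed("MASS")
  model0 <- fitLda(se, blob$groups, lambda = 0)
  fit <- MASS::lda(X, grouping = factor(blob$groups),
                   prior = rep(1 / 3, 3))
  expect_equal(as.character(classifyLda(model0, se)),
               as.character(predict(fit, X)$class))

  # missing protein row is a named error
  expect_error(classifyLda(model, subjectSe(blob$m[-1, ])), "P01")
})

test_that("equidistant subjects fall to the first canonical group with a
          warning", {
  centroids <- rbind(A = c(0, 0), B = c(2, 0))
  model <- new("SpcLdaModel", proteins = c("P1", "P2"), groups = c("A", "B"),
               centroids = centroids, covariance = diag(2), lambda = 0,
               scaling = matrix(1, 2, 1), scores = data.frame())
  m <- matrix(c(1, 0), 2, 1, dimnames = list(c("P1", "P2"), "mid"))
  expect_warning(pred <- classifyLda(model, subjectSe(m)), "tie")
  expect_equal(as.character(pred), "A")
})

test_that("panel intersection matches the naive set oracle", {
  res <- data.frame(accession = c("P1", "P2"), comparison = "A vs B",
                    aspc_x = c(10, 1), aspc_y = c(1, 1),
                    dave = c(1.6, 0), dci = c(49.5, 0),
                    pass = c(TRUE, FALSE))
  deps <- new("DepSet", results = res, proteins = "P1",
              daveThreshold = 0.2, dciThreshold = 5)
  expect_length(panelProteins(intersectPanels("P9", deps)), 0)  # disjoint
  p2 <- intersectPanels("P1", deps)
  expect_equal(panelProteins(p2), "P1")                          # identical
  expect_equal(p2@counts[["dep_only"]], 0L)

  set.seed(37)
  for (rep in 1:5) {
    a <- sample(paste0("P", 1:30), 12)
    b <- sample(paste0("P", 1:30), 12)
    resB <- data.frame(accession = b, comparison = "A vs B", aspc_x = 1,
                       aspc_y = 1, dave = 1, dci = 10, pass = TRUE)
    d <- new("DepSet", results = resB, proteins = b,
             daveThreshold = 0.2, dciThreshold = 5)
    expect_setequal(panelProteins(intersectPanels(a, d)), intersect(a, b))
  }
})

test_that("marker panel selection covers every group when possible", {
  # 4 candidate markers per group, strongest DAve all in group A
  set.seed(41)
  labs <- rep(c("A", "B", "C"), each = 4)
  prot <- sprintf("M%02d", 1:12)
  m <- matrix(2, 12, 9, dimnames = list(prot, paste0("S", 1:9)))
  g <- setNames(rep(c("A", "B", "C"), each = 3), colnames(m))
  for (i in seq_along(prot))
    m[i, g == labs[i]] <- c(60, 30, 20, 12)[((i - 1) %% 4) + 1]
  deps <- pairwiseDeps(subjectSe(m), g)
  pool <- intersectPanels(prot, deps, subjectSe(m), g)
  panel <- selectMarkerPanel(pool, deps, k = 6)
  home <- colnames(pool@groupMeans)[apply(pool@groupMeans[panelProteins(panel), ],
                                          1, which.max)]
  expect_setequal(unique(home), c("A", "B", "C"))
  expect_length(panelProteins(panel), 6)
})
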