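## Small complete matrix with two groups for the statistic tests.
completeMatrix <- function(p = 50, reps = 4, seed = 1, sd = 0.5) {
  set.seed(seed)
  v <- matrix(rnorm(p * 2 * reps, 25, sd), p)
  rownames(v) <- sprintf("P%03d", seq_len(p))
  ProteinMatrix(v, groups = rep(c("a", "b"), each = reps))
}

test_that("missing-value filtering honours the 30 percent boundary", {
  v <- matrix(25, 3, 10)
  v[1, 1:4] <- NA     # 40% missing -> out
  v[2, 1:3] <- NA     # 30% missing -> kept ("30% or less")
  pm <- ProteinMatrix(v, groups = rep(c("a", "b"), each = 5))
  out <- filterMatrix(pm, max_missing_frac = 0.30)
  expect_equal(rownames(out), rownames(pm)[2:3])

  ## zeros are treated as missing before the filter
  vz <- matrix(25, 2, 10); vz[1, 1:4] <- 0
  pmz <- ProteinMatrix(vz, groups = rep(c("a", "b"), each = 5))
  expect_equal(nrow(filterMatrix(pmz)), 1)

  ## decoy/contaminant flags drop rows regardless of missingness
  pmf <- ProteinMatrix(matrix(25, 3, 4), groups = rep(c("a", "b"), 2),
                       reverse = c(TRUE, FALSE, FALSE),
                       contaminant = c(FALSE, TRUE, FALSE))
  expect_equal(nrow(filterMatrix(pmf)), 1)

  ## fully observed matrix passes through unchanged
  pm2 <- completeMatrix()
  expect_equal(intensities(filterMatrix(pm2)), intensities(pm2))
})

test_that("downshifted imputation draws from the stated distribution", {
  ## degenerate parameters: every imputed cell equals the column mean
  v <- matrix(rnorm(40, 25, 2), 20, 2)
  v[1:5, 1] <- NA
  pm <- ProteinMatrix(v, groups = c("a", "b"))
  out <- imputeDownshift(pm, width = 0, downshift = 0, seed = 1)
  mu <- mean(v[6:20, 1])
  expect_equal(unname(intensities(out)[1:5, 1]), rep(mu, 5))

  ## moments at the defaults
  set.seed(2)
  big <- matrix(rnorm(4000, 25, 2), ncol = 2)
  big[1:1000, 1] <- NA
  pmb <- ProteinMatrix(big, groups = c("a", "b"))
  outb <- imputeDownshift(pmb, seed = 7)
  imp <- intensities(outb)[1:1000, 1]
  obs <- big[1001:2000, 1]
  expect_equal(mean(imp), mean(obs) - 1.8 * sd(obs), tolerance = 0.1)
  expect_equal(sd(imp), 0.3 * sd(obs), tolerance = 0.05)

  ## determinism and error on unusable columns
  expect_identical(intensities(imputeDownshift(pm, seed = 3)),
                   intensities(imputeDownshift(pm, seed = 3)))
  bad <- matrix(c(NA, NA, 1, 2), 2)
  expect_error(imputeDownshift(ProteinMatrix(bad, groups = c("a", "b")),
                               seed = 1),
               "fewer than 2 observed")
})

test_that("s0 = 0 recovers the classical two-sample t statistic", {
  pm <- completeMatrix(p = 30, seed = 5)
  res <- s0Ttest(pm, c("a", "b"), s0 = 0)
  v <- intensities(pm)
  g <- sampleGroups(pm)
  tref <- apply(v, 1, function(x)
    stats::t.test(x[g == "a"], x[g == "b"], var.equal = TRUE)$statistic)
  expect_equal(res$statistic, unname(tref), tolerance = 1e-12)
})

test_that("the s0 statistic matches hand arithmetic on a toy example", {
  v <- rbind(c(10, 11, 12, 14, 15, 16))
  rownames(v) <- "toy"
  pm <- ProteinMatrix(v, groups = rep(c("a", "b"), each = 3))
  res <- s0Ttest(pm, c("a", "b"), s0 = 0.1)
  se <- sqrt(1 * (1 / 3 + 1 / 3))     # pooled variance is exactly 1
  expect_equal(res$statistic, -4 / (0.1 + se), tolerance = 1e-12)
  expect_equal(res$diff, -4)

  ## zero mean difference gives zero regardless of s0
  v2 <- rbind(c(5, 6, 7, 5, 6, 7))
  pm2 <- ProteinMatrix(v2, groups = rep(c("a", "b"), each = 3))
  expect_equal(s0Ttest(pm2, c("a", "b"), s0 = 0.3)$statistic, 0)
})

test_that("one-way F matches aov and the t-squared identity", {
  set.seed(6)
  v <- matrix(rnorm(9 * 5, 20, 1), 5)
  pm <- ProteinMatrix(v, groups = rep(c("a", "b", "c"), each = 3))
  res <- anovaF(pm)
  for (i in 1:5) {
    fit <- stats::aov(v[i, ] ~ factor(rep(c("a", "b", "c"), each = 3)))
    fref <- summary(fit)[[1]]$`F value`[1]
    expect_equal(res$F[i], fref, tolerance = 1e-6)
  }

  pm2 <- completeMatrix(p = 40, seed = 8)
  fres <- anovaF(pm2)
  tres <- s0Ttest(pm2, c("a", "b"), s0 = 0)
  expect_equal(fres$F, tres$statistic^2, tolerance = 1e-9)

  same <- ProteinMatrix(matrix(rep(c(1, 2, 3, 4), each = 6), 4, 6,
                               byrow = TRUE),
                        groups = rep(c("a", "b", "c"), 2))
  expect_true(all(anovaF(same)$F < 1e-6))
})

test_that("permuting labels among identical columns finds nothing", {
  v <- matrix(rep(rnorm(50, 25), 8), 50)
  pm <- ProteinMatrix(v, groups = rep(c("a", "b"), each = 4))
  res <- permutationFDR(pm, "s0_ttest", seed = 1)
  expect_equal(sum(res$significant), 0)
})

test_that("permutation q-values are monotone in the absolute statistic", {
  fx <- makeProteomeFixture(proteomeFixtureSpec(
    n_proteins = 300, n_true_effects = 30, effect_log2fc = 1.5,
    dropout_logistic_midpoint = 0, seed = 14))
  res <- permutationFDR(fx$matrix, "s0_ttest", seed = 2)
  ord <- order(abs(res$statistic), decreasing = TRUE)
  expect_true(all(diff(res$q[ord]) >= -1e-12))
  expect_true(all(res$q >= 0 & res$q <= 1))
})

test_that("planted effects are detected with controlled error", {
  fx <- makeProteomeFixture(proteomeFixtureSpec(
    n_proteins = 400, n_true_effects = 40, effect_log2fc = 2,
    within_group_sd = 0.3, dropout_logistic_midpoint = 0, seed = 20))
  res <- permutationFDR(fx$matrix, "s0_ttest", seed = 3)
  sens <- mean(fx$truth$protein %in% res$protein[res$significant])
  fdp <- sum(res$significant &
             !(res$protein %in% fx$truth$protein)) /
    max(1, sum(res$significant))
  expect_gte(sens, 0.9)
  expect_lte(fdp, 0.1)
})

test_that("Fisher enrichment p equals the hypergeometric tail oracle", {
  bg <- sprintf("P%02d", 1:40)
  sig <- bg[1:10]
  terms <- list(hit = bg[1:8], half = bg[5:24], cold = bg[31:40])
  res <- fisherEnrichment(sig, bg, terms)
  for (i in seq_len(nrow(res)))
    expect_equal(res$p[i],
                 oracleHyperTail(res$k[i], res$K[i], res$n[i], res$N[i]),
                 tolerance = 1e-12)
  expect_equal(res$q, p.adjust(res$p, "BH"))

  ## empty significant set: nothing can be enriched
  res0 <- fisherEnrichment(character(), bg, terms)
  expect_true(all(!res0$enriched))
  expect_warning(fisherEnrichment(sig, bg, list(off = c("X1", "X2"))),
                 "no background overlap")
  expect_error(fisherEnrichment(c("ZZZ"), bg, terms), "subset")
})

test_that("random term membership yields near-uniform enrichment p-values", {
  set.seed(30)
  bg <- sprintf("P%04d", 1:500)
  sig <- sample(bg, 100)
  terms <- lapply(1:200, function(i) sample(bg, 25))
  names(terms) <- paste0("t", 1:200)
  res <- fisherEnrichment(sig, bg, terms)
  ## conservative one-sided p on a discrete table: at most ~5% below 0.05
  expect_lte(mean(res$p < 0.05), 0.08)
  expect_gte(mean(res$p > 0.5), 0.3)
})

test_that("row z-scoring standardizes exactly and rejects constants", {
  expect_equal(as.numeric(zscoreRows(rbind(c(1, 2, 3)))), c(-1, 0, 1))
  set.seed(9)
  m <- matrix(rnorm(200, 10, 3), 20)
  z <- zscoreRows(m)
  expect_true(all(abs(rowMeans(z)) < 1e-12))
  expect_true(all(abs(apply(z, 1, sd) - 1) < 1e-12))
  expect_equal(zscoreRows(z), z, tolerance = 1e-12)
  expect_error(zscoreRows(rbind(c(1, 1, 1))), "constant")
})

test_that("wide tables and GMT files round-trip through the readers", {
  dir <- withr::local_tempdir()
  tab <- data.frame(protein = c("P1", "P2"), s1 = c(25, 26), s2 = c(24, 27),
                    s3 = c(23, 25), s4 = c(26, 24))
  write.table(tab, file.path(dir, "m.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  ann <- data.frame(sample = paste0("s", 1:4),
                    group = rep(c("a", "b"), each = 2))
  write.table(ann, file.path(dir, "ann.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  pm <- readProteinMatrix(file.path(dir, "m.tsv"), file.path(dir, "ann.tsv"))
  expect_equal(dim(intensities(pm)), c(2L, 4L))
  expect_equal(sampleGroups(pm), rep(c("a", "b"), each = 2))

  writeLines(c("term1\tdesc\tP1\tP2", "term2\tdesc\tP2"),
             file.path(dir, "t.gmt"))
  gmt <- readGMT(file.path(dir, "t.gmt"))
  expect_equal(gmt, list(term1 = c("P1", "P2"), term2 = "P2"))
})
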