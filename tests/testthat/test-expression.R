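# Tissue-pattern classification, rank-test oracles, WGT retention
# stratification and per-chromosome summaries.

test_that("tissue patterns classify per the breadth definition", {
  mat <- rbind(a = c(0, 0, 0, 5, 0, 0),
               b = c(2, 3, 4, 5, 6, 7),
               c = c(0.2, 0, 0, 0.5, 0, 0),
               d = c(2, 3, 0, 0, 0, 0))
  colnames(mat) <- TISSUES
  cls <- classifyTissuePattern(mat, expressedThreshold = 1)
  expect_equal(cls$class, c("specific", "constitutive", "silent",
                            "intermediate"))
  expect_equal(cls$specific_tissue, c("flower", NA, NA, NA))
  expect_equal(cls$n_expressed_tissues, c(1, 6, 0, 2))
})

test_that("classes partition the universe and respect joint rescaling", {
  e <- simulateExpression(sprintf("g%03d", 1:80), seed = 1)
  cls <- classifyTissuePattern(e$matrix, 1)
  expect_equal(sum(table(cls$class)), 80)
  scaled <- classifyTissuePattern(e$matrix * 7, expressedThreshold = 7)
  expect_equal(scaled$class, cls$class)
})

test_that("group comparisons behave at the extremes", {
  set.seed(2)
  a <- rlnorm(30)
  same <- compareExpressionGroups(a, a, test = "mann_whitney")
  expect_gte(same$p, 0.99)
  shifted <- compareExpressionGroups(a, a + 10, test = "mann_whitney")
  expect_lt(shifted$p, 1e-6)
  expect_error(compareExpressionGroups(numeric(0), a), "empty")
  # Welch direction: groupA clearly above groupB under "greater"
  w <- compareExpressionGroups(a + 5, a, test = "welch_t_one_sided",
                               alternative = "greater")
  expect_lt(w$p, 1e-6)
  wWrong <- compareExpressionGroups(a, a + 5, test = "welch_t_one_sided",
                                    alternative = "greater")
  expect_gt(wWrong$p, 0.99)
})

test_that("rank tests agree with an independent reimplementation", {
  set.seed(3)
  for (i in 1:20) {
    a <- sample(1:20, sample(4:10, 1), replace = TRUE)
    b <- sample(1:20, sample(4:10, 1), replace = TRUE)
    got <- compareExpressionGroups(a, b, test = "mann_whitney")
    # U from first principles: pairwise wins plus half-ties
    U <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    expect_equal(got$statistic, U)
    gotKW <- compareExpressionGroups(list(a, b), test = "kruskal_wallis")
    # H with tie correction from first principles
    x <- c(a, b)
    g <- rep(1:2, c(length(a), length(b)))
    r <- rank(x)
    N <- length(x)
    H <- 12 / (N * (N + 1)) *
      sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (N + 1)
    ties <- table(x)
    H <- H / (1 - sum(ties^3 - ties) / (N^3 - N))
    expect_equal(gotKW$statistic, H)
  }
})

test_that("null calibration of the rank test is honest", {
  set.seed(4)
  rejections <- 0
  nRep <- 200
  for (r in seq_len(nRep)) {
    a <- rlnorm(25)
    b <- rlnorm(25)
    if (compareExpressionGroups(a, b, test = "mann_whitney")$p < 0.05) {
      rejections <- rejections + 1
    }
  }
  expect_gte(rejections / nRep, 0.02)
  expect_lte(rejections / nRep, 0.09)
})

test_that("Dunn post-hoc comparisons find the separated group", {
  set.seed(5)
  vals <- c(rnorm(20, 0), rnorm(20, 0.2), rnorm(20, 5))
  grp <- rep(c("x", "y", "z"), each = 20)
  out <- posthocDunn(vals, grp)
  expect_equal(nrow(out), 3)
  expect_lt(out$q[out$group1 == "x" & out$group2 == "z"], 0.001)
  expect_gt(out$q[out$group1 == "x" & out$group2 == "y"], 0.05)
})

test_that("planted PSG fractions per retention class are recovered", {
  set.seed(6)
  nPer <- 3000
  fracs <- c(0.01, 0.02, 0.03)
  ids <- sprintf("g%05d", seq_len(3 * nPer))
  retention <- data.frame(gene_id = ids,
                          retention_class = rep(1:3, each = nPer))
  isPsg <- unlist(lapply(1:3, function(cl)
    rbinom(nPer, 1, fracs[cl]) == 1))
  results <- data.frame(gene_id = ids, is_psg = isPsg,
                        psg_status = ifelse(isPsg, "PSG", "non-PSG"))
  mat <- matrix(rlnorm(3 * nPer * 6, log(5), 1), ncol = 6,
                dimnames = list(ids, TISSUES))
  out <- wgtRetentionAnalysis(results, retention, mat)
  expect_lt(max(abs(out$summary$psg_fraction - fracs)), 0.01)
  expect_true(is.finite(out$fisher_p))
  expect_true(is.finite(out$kw_p))
})

test_that("empty retention classes are flagged, empty PSG set gives zeros", {
  ids <- sprintf("g%02d", 1:10)
  retention <- data.frame(gene_id = ids, retention_class = 1L)
  results <- data.frame(gene_id = ids, is_psg = FALSE,
                        psg_status = "non-PSG")
  mat <- matrix(1, 10, 6, dimnames = list(ids, TISSUES))
  out <- wgtRetentionAnalysis(results, retention, mat)
  expect_equal(out$summary$flag, c("", "no_genes", "no_genes"))
  expect_true(all(is.na(out$summary$psg_fraction[2:3])))
  expect_equal(out$summary$psg_fraction[1], 0)
})

test_that("per-chromosome expression summaries rank a planted chromosome first", {
  set.seed(7)
  ids <- sprintf("g%03d", 1:100)
  map <- data.frame(gene_id = ids,
                    chrom = rep(sprintf("Chr%02d", 1:5), each = 20))
  mat <- matrix(rlnorm(600, log(4), 0.3), 100, 6,
                dimnames = list(ids, TISSUES))
  mat[map$chrom == "Chr03", ] <- mat[map$chrom == "Chr03", ] * 2
  out <- expressionByChromosome(mat, map)
  byChrom <- tapply(out$summary$mean_fpkm, out$summary$chrom, mean)
  expect_equal(names(which.max(byChrom)), "Chr03")
  expect_lt(out$kw_p, 0.01)
})

test_that("degenerate chromosome layouts are handled", {
  ids <- sprintf("g%02d", 1:10)
  map <- data.frame(gene_id = ids, chrom = "Chr01")
  mat <- matrix(0, 10, 6, dimnames = list(ids, TISSUES))
  expect_message(out <- expressionByChromosome(mat, map), "skipped")
  expect_true(is.na(out$kw_p))
  expect_true(all(out$summary$mean_fpkm == 0))
})
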