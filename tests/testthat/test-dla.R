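test_that("standardized beta equals Pearson r without covariates", {
    set.seed(101)
    for (r in 1:100) {
        n <- sample(10:60, 1)
        x <- rnorm(n); y <- rnorm(n)
        fit <- fitFeatureAssociation(x, y)
        expect_lt(abs(fit$beta_std - cor(x, y)), 1e-10)
        # and the p-value matches the exact correlation test
        expect_lt(abs(fit$p - cor.test(x, y)$p.value), 1e-12)
    }
})

test_that("a feature identical to the outcome gives beta 1", {
    x <- rnorm(40)
    # lm warns about an essentially perfect fit; that is the point here
    fit <- suppressWarnings(fitFeatureAssociation(x, x))
    expect_equal(fit$beta_std, 1, tolerance = 1e-12)
    expect_lt(fit$p, 1e-10)
})

test_that("covariate adjustment removes a confound-driven association", {
    set.seed(7)
    n <- 1000
    cov <- rnorm(n)
    y <- cov                       # outcome is the covariate
    x <- rnorm(n)                  # feature independent of both
    fit <- fitFeatureAssociation(x, y + rnorm(n, sd = 1e-8), cbind(cov))
    expect_lt(abs(fit$beta_std), 0.1)
    # p roughly uniform over replicates
    ps <- replicate(50, {
        x <- rnorm(200); yy <- cov[1:200] + rnorm(200, sd = 0.01)
        fitFeatureAssociation(x, yy, cbind(cov[1:200]))$p
    })
    expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("degenerate inputs are refused", {
    expect_error(fitFeatureAssociation(rep(1, 20), rnorm(20)),
                 "zero-variance feature")
    expect_error(fitFeatureAssociation(rnorm(20), rep(2, 20)),
                 "zero-variance outcome")
    expect_error(fitFeatureAssociation(rnorm(2), rnorm(2)), "too few")
})

test_that("bonferroni threshold is family alpha over m", {
    expect_identical(bonferroniThreshold(0.001, 20000), 5e-8)
    expect_identical(bonferroniThreshold(0.05, 1), 0.05)
    expect_identical(bonferroniThreshold(0.001, 10), 1e-4)
    expect_error(bonferroniThreshold(0.001, 0), "m must be")
})

test_that("BH step-up matches a brute-force check and dominates bonferroni", {
    expect_identical(sum(benjaminiHochberg(c(0.0001, 0.002, 0.03, 0.9),
                                           0.05)), 3L)
    expect_identical(sum(benjaminiHochberg(rep(1, 6), 0.05)), 0L)
    set.seed(11)
    for (r in 1:100) {
        m <- sample(1:10, 1)
        p <- round(runif(m), 3)
        q <- runif(1, 0.01, 0.2)
        expect_identical(benjaminiHochberg(p, q), bhStepUpOracle(p, q))
        bonf <- p < bonferroniThreshold(q, m)
        expect_true(all(benjaminiHochberg(p, q)[bonf]))
    }
})

test_that("runDLA agrees with the single-feature route and ranks planted signal", {
    set.seed(23)
    spec <- syntheticSpec(120, seed = 31, meanMessages = 15, meanWords = 12,
                          plantedEffects = data.frame(
                              feature = "w0005", outcome = "extraversion",
                              effect = 0.9))
    g <- generateCorpus(spec)
    corp <- aggregateAuthors(g$messages)
    fm <- ngramFeatureMatrix(corp)
    res <- runDLA(fm, g$outcomes, "extraversion", c("gender", "age"))
    # fast path equals the lm-based single-feature fit
    df <- as.data.frame(res)
    ids <- intersect(authorIds(fm), g$outcomes$author_id)
    om <- g$outcomes[match(ids, g$outcomes$author_id), ]
    for (f in df$feature[c(1, 5, 20)]) {
        single <- fitFeatureAssociation(
            featureValues(fm)[f, ids], om$extraversion,
            om[c("gender", "age")])
        expect_equal(df$beta_std[df$feature == f], single$beta_std,
                     tolerance = 1e-10)
        expect_equal(df$p[df$feature == f], single$p, tolerance = 1e-10)
    }
    # the planted word is recovered at the top
    expect_lte(which(df$feature == "w0005"), 5)
    # invariance to row/column order
    fm2 <- fm[rev(seq_len(nrow(fm))), rev(seq_len(ncol(fm)))]
    res2 <- runDLA(fm2, g$outcomes, "extraversion", c("gender", "age"))
    expect_equal(as.data.frame(res2)$beta_std[
                     match(df$feature, as.data.frame(res2)$feature)],
                 df$beta_std, tolerance = 1e-10)
})

test_that("one-feature families use the raw alpha and errors are informative", {
    set.seed(4)
    msgs <- data.frame(author_id = sprintf("a%02d", 1:30),
                       text = paste("x", sample(c("u", "v"), 30, TRUE)))
    g <- data.frame(author_id = sprintf("a%02d", 1:30), y = rnorm(30))
    corp <- aggregateAuthors(msgs)
    fm <- buildFeatureMatrix(corp, "u")
    res <- runDLA(fm, g, "y", familyAlpha = 0.05)
    md <- S4Vectors::metadata(res)
    expect_identical(md$threshold, 0.05)
    expect_error(runDLA(fm, g, "nope"), "nope")
    expect_error(runDLA(fm[0, ], g, "y"), "empty feature set")
})

test_that("zero-variance features land in the skip log, not the results", {
    set.seed(6)
    msgs <- data.frame(author_id = sprintf("a%02d", 1:30),
                       text = paste("base", sample(c("u", "v"), 30, TRUE)))
    g <- data.frame(author_id = sprintf("a%02d", 1:30), y = rnorm(30))
    corp <- aggregateAuthors(msgs)
    fm <- buildFeatureMatrix(corp, c("base", "u"))  # base used by all
    res <- runDLA(fm, g, "y", familyAlpha = 0.05)
    md <- S4Vectors::metadata(res)
    expect_identical(md$skipped, "base")
    expect_false("base" %in% res$feature)
    expect_identical(md$m_tests, 1L)
})

test_that("power analysis is degenerate at the full corpus and near zero under the null", {
    spec <- syntheticSpec(80, seed = 13, meanMessages = 10, meanWords = 12)
    g <- generateCorpus(spec)
    corp <- aggregateAuthors(g$messages)
    fm <- ngramFeatureMatrix(corp)
    full <- runDLA(fm, g$outcomes, "extraversion",
                   correction = "benjamini_hochberg", familyAlpha = 0.05)
    pa <- powerAnalysis(corp, g$outcomes, "extraversion",
                        sampleSizes = 80, reps = 1,
                        correction = "benjamini_hochberg",
                        familyAlpha = 0.05, seed = 2)
    expect_identical(pa$mean_significant, as.numeric(sum(full$significant)))
    # null corpus: essentially nothing at any size
    pa0 <- powerAnalysis(corp, g$outcomes, "extraversion",
                         sampleSizes = c(40, 80), reps = 3,
                         familyAlpha = 0.001, seed = 3)
    expect_true(all(pa0$mean_significant <= 1))
})
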