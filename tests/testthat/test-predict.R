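test_that("author splits are disjoint, exhaustive, and seeded", {
    ids <- sprintf("a%04d", 1:1000)
    sp <- splitAuthors(ids, seed = 3)
    expect_identical(length(sp$test), 250L)
    expect_identical(length(sp$train), 750L)
    expect_length(intersect(sp$train, sp$test), 0)
    expect_setequal(c(sp$train, sp$test), ids)
    expect_identical(splitAuthors(ids, seed = 3), sp)
    expect_false(identical(splitAuthors(ids, seed = 4), sp))
})

test_that("PCA reduces to half the training users, capped at the rank", {
    set.seed(2)
    tr <- matrix(rnorm(100 * 200), 100)
    te <- matrix(rnorm(20 * 200), 20)
    red <- reducePCA(tr, te)
    expect_identical(red$nComponents, 50L)
    expect_identical(ncol(red$train), 50L)
    expect_identical(ncol(red$test), 50L)
    # fewer features than half the users: capped
    red2 <- reducePCA(tr[, 1:30], te[, 1:30])
    expect_identical(red2$nComponents, 30L)
    # full-rank projection reconstructs the centered training data
    sm <- matrix(rnorm(20 * 5), 20)
    redF <- reducePCA(sm, sm, nComponents = 5)
    rec <- redF$train %*% t(redF$rotation)
    expect_equal(rec, scale(sm, scale = FALSE), tolerance = 1e-9,
                 ignore_attr = TRUE)
})

test_that("the linear SVM nails separable data and stays at chance on noise", {
    set.seed(5)
    n <- 400
    X <- rbind(matrix(rnorm(n, 5), n / 2, 2), matrix(rnorm(n, -5), n / 2, 2))
    y <- rep(c(1, 0), each = n / 2)
    idx <- sample(n)
    X <- X[idx, ]; y <- y[idx]
    model <- fitClassifier(X[1:300, ], y[1:300], seed = 1)
    ev <- evaluateModel(model, X[301:400, ], y[301:400])
    expect_identical(ev$metric, "accuracy")
    expect_equal(ev$value, 1.0)
    expect_true(model$cost %in% model$grid)
    # permuted labels: chance-level out of sample
    yPerm <- sample(y)
    mP <- fitClassifier(X[1:300, ], yPerm[1:300], seed = 1)
    evP <- evaluateModel(mP, X[301:400, ], yPerm[301:400])
    expect_gte(evP$value, 0.4)
    expect_lte(evP$value, 0.6)
    expect_error(fitClassifier(X, rep(1, n)), "single class")
})

test_that("ridge recovers a noiseless linear signal and matches an oracle", {
    set.seed(9)
    X <- matrix(rnorm(200 * 4), 200)
    y <- 3 * X[, 1] - 2 * X[, 2]
    model <- fitRegressor(X[1:150, ], y[1:150],
                          grid = c(1e-6, 1e-2, 1), seed = 1)
    ev <- evaluateModel(model, X[151:200, ], y[151:200])
    expect_identical(ev$metric, "R")
    expect_gte(ev$value, 0.99)
    expect_true(model$lambda %in% model$grid)
    # independent oracle: minimize the penalized least-squares objective
    # directly instead of solving the normal equations
    lam <- 0.5
    fit <- dlatools:::.ridgeFit(X, y, lam)
    Xc <- scale(X, scale = FALSE)
    obj <- function(b) sum((y - mean(y) - Xc %*% b)^2) + lam * sum(b^2)
    opt <- optim(rep(0, 4), obj, method = "BFGS",
                 control = list(reltol = 1e-15, maxit = 2000))
    expect_equal(unname(fit$coef[, 1]), opt$par, tolerance = 1e-5)
    expect_lte(obj(fit$coef[, 1]), opt$value + 1e-8)
    # null outcome: R pinned at 0 by clipping
    yN <- rnorm(200)
    mN <- fitRegressor(X[1:150, ], yN[1:150], seed = 1)
    evN <- evaluateModel(mN, X[151:200, ], yN[151:200])
    expect_lte(evN$value, 0.35)
    expect_gte(evN$value, 0)
})

test_that("evaluation metrics follow their definitions", {
    m <- list(task = "regression",
              fit = list(coef = matrix(1), xm = 0, ym = 0))
    X <- matrix(c(1, 2, 3, 4), 4)
    # predictions equal y: R = 1; R^2 = 0.64 => R = 0.8 via constructed y
    y <- as.vector(X)
    expect_equal(evaluateModel(m, X, y)$value, 1)
    expect_error(evaluateModel(m, X, rep(1, 4)), "SST")
    set.seed(1)
    yy <- as.vector(X) + rnorm(4)
    r2 <- 1 - sum((yy - as.vector(X))^2) / sum((yy - mean(yy))^2)
    expect_equal(evaluateModel(m, X, yy)$value, sqrt(max(0, r2)))
    expect_equal(sqrt(0.64), 0.8)
})

test_that("open-vocabulary features beat an uninformative lexicon out of sample", {
    g <- generateCorpus(plantedGenderSpec())
    corp <- aggregateAuthors(g$messages)
    lex <- loadLexicon(demoLexiconPath("csv"))
    builders <- list(liwc = lexiconFeatureBuilder(corp, lex),
                     wordphrases = ngramFeatureBuilder(corp))
    builders$wordphrases_liwc <- unionBuilder(builders$wordphrases,
                                              builders$liwc)
    rep1 <- compareFeatureSets(builders, g$outcomes, "gender", seed = 5,
                               nBoot = 1000)
    acc <- setNames(rep1$value, rep1$feature_set)
    expect_gt(acc[["wordphrases"]], acc[["liwc"]])
    expect_lt(rep1$improvement_p[rep1$feature_set == "wordphrases"], 0.01)
    # adding the lexicon on top of open vocabulary gains nothing
    rep2 <- compareFeatureSets(
        builders[c("wordphrases", "wordphrases_liwc")],
        g$outcomes, "gender", seed = 5, nBoot = 1000)
    expect_gte(rep2$improvement_p[
        rep2$feature_set == "wordphrases_liwc"], 0.05)
})

test_that("a feature set compared with itself shows no improvement", {
    g <- generateCorpus(plantedGenderSpec(nAuthors = 120, seed = 19))
    corp <- aggregateAuthors(g$messages)
    b <- ngramFeatureBuilder(corp)
    rep <- compareFeatureSets(list(base = b, same = b), g$outcomes,
                              "gender", seed = 2, nBoot = 500)
    expect_gte(rep$improvement_p[rep$feature_set == "same"], 0.05)
    # union of a set with itself deduplicates to the same metric
    repU <- compareFeatureSets(list(base = b, union = unionBuilder(b, b)),
                               g$outcomes, "gender", seed = 2, nBoot = 50)
    expect_equal(repU$value[1], repU$value[2], tolerance = 1e-6)
})

test_that("test authors never influence training artifacts", {
    g <- generateCorpus(plantedGenderSpec(nAuthors = 100, seed = 23))
    corp <- aggregateAuthors(g$messages)
    sp <- splitAuthors(authorIds(corp), seed = 7)
    b <- ngramFeatureBuilder(corp)
    m1 <- b(sp$train, sp$test)
    # scrambling the test authors' outcomes / using a different test set
    # leaves the training matrix untouched
    m2 <- b(sp$train, rev(sp$test))
    expect_identical(m1$train, m2$train)
    half <- sp$test[1:10]
    m3 <- b(sp$train, half)
    expect_identical(colnames(m3$train), colnames(m1$train))
    expect_identical(m1$train, m3$train)
})
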