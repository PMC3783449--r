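sigResults <- function(features, beta, freq) {
    data.frame(feature = features, beta_std = beta, p = 1e-9,
               corpus_frequency = freq, significant = TRUE,
               stringsAsFactors = FALSE)
}

test_that("phrase pruning reproduces the day / beautiful day / the day case", {
    res <- sigResults(c("day", "beautiful_day", "the_day"),
                      c(0.30, 0.25, 0.20), c(500, 60, 400))
    wf <- c(the = 1000, day = 500, beautiful = 50)
    kept <- prunePhrases(res, wf)
    expect_identical(kept$feature, c("day", "beautiful_day"))
})

test_that("phrase pruning keeps disjoint features and is idempotent", {
    res <- sigResults(c("cat", "dog_park", "fish"), c(0.3, 0.2, 0.1),
                      c(10, 5, 8))
    wf <- c(cat = 10, dog = 7, park = 5, fish = 8)
    kept <- prunePhrases(res, wf)
    expect_identical(kept$feature, res$feature)
    expect_identical(prunePhrases(kept, wf), kept)
    # order is preserved and output is a subset
    res2 <- sigResults(c("day", "the_day", "sunny_day"),
                       c(0.3, 0.2, 0.1), c(500, 400, 20))
    wf2 <- c(the = 1000, day = 500, sunny = 30)
    kept2 <- prunePhrases(res2, wf2)
    expect_identical(kept2$feature, c("day", "sunny_day"))
    # equal frequency drops the candidate (conservative tie rule)
    res3 <- sigResults(c("day", "tie_day"), c(0.3, 0.2), c(500, 100))
    expect_identical(prunePhrases(res3, c(day = 500, tie = 500))$feature,
                     "day")
})

test_that("topic pruning drops at 4/15 overlap and keeps at 3/15", {
    tws <- list(topic_1 = paste0("w", 1:15),
                topic_2 = c(paste0("w", 1:4), paste0("x", 1:11)),
                topic_3 = c(paste0("w", 1:3), paste0("y", 1:12)))
    res <- sigResults(names(tws), c(0.4, 0.3, 0.2), c(1, 1, 1))
    kept <- pruneTopics(res, tws)
    expect_identical(kept$feature, c("topic_1", "topic_3"))
    # identical topics: only the higher-ranked survives
    tws2 <- list(topic_1 = paste0("w", 1:15), topic_2 = paste0("w", 1:15))
    res2 <- sigResults(names(tws2), c(0.4, 0.3), c(1, 1))
    expect_identical(pruneTopics(res2, tws2)$feature, "topic_1")
    # idempotent
    expect_identical(pruneTopics(kept, tws), kept)
})

test_that("cloud rendering is deterministic, monotone, and validated", {
    res <- sigResults(c("party", "love_you", "xbox", "meh"),
                      c(0.31, -0.22, 0.18, 0.05), c(900, 300, 150, 40))
    f1 <- withr::local_tempfile(fileext = ".svg")
    f2 <- withr::local_tempfile(fileext = ".svg")
    renderCloud(res, f1, seed = 9)
    renderCloud(res, f2, seed = 9)
    expect_identical(readLines(f1), readLines(f2))
    # provenance sidecar carries sizes monotone in |beta|
    side <- jsonlite::read_json(paste0(f1, ".json"), simplifyVector = TRUE)
    expect_identical(side$feature[order(-abs(side$beta_std))],
                     side$feature)
    expect_true(all(diff(side$size[order(-abs(side$beta_std))]) <= 0))
    # non-significant rows are rejected
    bad <- res; bad$significant[2] <- FALSE
    expect_error(renderCloud(bad, f1), "significant")
    expect_error(renderCloud(res[0, ], f1), "no significant")
    # png route writes a file
    f3 <- withr::local_tempfile(fileext = ".png")
    renderCloud(res, f3, fmt = "png", seed = 1)
    expect_gt(file.info(f3)$size, 0)
})

test_that("topic panels cap at the 6 most distinguishing topics", {
    tc <- generateTopicCorpus(nAuthors = 10, K = 2, wordsPerBlock = 10,
                              meanMessages = 8, meanWords = 8, seed = 5)
    model <- fitLDA(tokenize(tc$messages$text), K = 2, nIter = 50,
                    seed = 2)
    words <- sigResults(c("hello", "world"), c(0.3, 0.2), c(10, 5))
    topics <- sigResults(paste0("topic_", c(1, 2, 1, 2, 1, 2, 1, 2)),
                         seq(0.8, 0.1, length.out = 8), rep(1, 8))
    f <- withr::local_tempfile(fileext = ".svg")
    renderTopicPanel(words, topics, model, f, seed = 3)
    side <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
    expect_lte(length(setdiff(names(side), "words")), 6)
    # topic cloud word order matches topWords
    expect_identical(side$topic_1$word[1:5], topWords(model, 1, 5))
    expect_warning(
        renderTopicPanel(words, topics[0, ], model,
                         withr::local_tempfile(fileext = ".svg")),
        "no topics")
})

test_that("loess trend reproduces a global line and refuses extrapolation", {
    set.seed(8)
    age <- runif(100, 15, 60)
    gender <- rbinom(100, 1, 0.5)
    feat <- 2 * age
    grid <- seq(20, 55, length.out = 10)
    tr <- loessTrend(feat, age, gender, grid = grid)
    truth <- (2 * grid - mean(feat)) / sd(feat)
    expect_equal(tr$fitted, truth, tolerance = 1e-6)
    expect_error(loessTrend(feat, age, gender, grid = c(10, 30)),
                 "outside")
    expect_error(loessTrend(rep(1, 100), age, gender), "zero-variance")
    expect_error(loessTrend(feat[1:10], age[1:10], gender[1:10]),
                 "at least 20")
})

test_that("evaluation at the gender mean averages the two group fits", {
    set.seed(15)
    n <- 200
    age <- runif(n, 20, 50)
    gender <- rep(c(0, 1), each = n / 2)   # balanced: mean exactly 0.5
    feat <- 1.5 * age + 4 * gender + rnorm(n, sd = 0.1)
    grid <- c(30, 40)
    tr <- loessTrend(feat, age, gender, grid = grid, span = 0.9)
    z <- as.vector(scale(feat))
    for (i in seq_along(grid)) {
        # direct local fit, evaluated at gender 0 and gender 1
        d <- abs(age - grid[i])
        q <- ceiling(0.9 * n)
        h <- sort(d)[q]
        w <- (1 - pmin(d / h, 1)^3)^3
        cf <- lm(z ~ age + gender, weights = w)$coefficients
        pm <- sum(cf * c(1, grid[i], 0))
        pf <- sum(cf * c(1, grid[i], 1))
        expect_equal(tr$fitted[i], (pm + pf) / 2, tolerance = 1e-8)
    }
})
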