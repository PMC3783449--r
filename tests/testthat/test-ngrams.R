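test_that("n-gram enumeration is exhaustive within one message", {
    expect_setequal(extractNgrams(c("i", "love", "you")),
                    c("i", "love", "you", "i_love", "love_you",
                      "i_love_you"))
    expect_identical(extractNgrams("hi", 3), "hi")
    expect_identical(extractNgrams(character(0)), character(0))
    # multiplicities are preserved
    expect_identical(sum(extractNgrams(c("a", "a", "a")) == "a_a"), 2L)
})

test_that("pmi matches hand-computed log ratios", {
    probs <- data.frame(feature = c("a", "b", "a_b"),
                        order = c(1L, 1L, 2L),
                        count = c(2, 4, 2), n_authors = 1,
                        prob = c(0.02, 0.04, 0.02))
    expect_equal(pmi("a_b", probs), log(25), tolerance = 1e-12)
    # independence => 0
    probs2 <- data.frame(feature = c("a", "b", "a_b"),
                         order = c(1L, 1L, 2L), count = 1, n_authors = 1,
                         prob = c(0.1, 0.1, 0.01))
    expect_equal(pmi("a_b", probs2), 0, tolerance = 1e-12)
    # p(phrase) = e * prod p(words) => exactly 1
    probs3 <- data.frame(feature = c("a", "b", "a_b"),
                         order = c(1L, 1L, 2L), count = 1, n_authors = 1,
                         prob = c(0.1, 0.1, 0.01 * exp(1)))
    expect_equal(pmi("a_b", probs3), 1, tolerance = 1e-12)
    # unseen phrase: -Inf sentinel
    expect_identical(pmi("b_a", probs), -Inf)
    # independence product ignores word order
    probs4 <- probs
    probs4$feature[3] <- "b_a"
    expect_equal(pmi("b_a", probs4), log(25), tolerance = 1e-12)
})

test_that("collocation filter keeps unigrams and true collocations only", {
    # new york always co-occurs: p(xy) = p(x) = p(y) = 0.01 => pmi = ln 100
    msgs <- data.frame(
        author_id = "a",
        text = c(rep("new york", 4),
                 rep(paste(rep(c("alpha", "beta"), 50), collapse = " "),
                     4)))
    corp <- aggregateAuthors(msgs)
    kept <- collocationFilter(corp)
    expect_true("new_york" %in% kept)
    expect_true(all(c("new", "york", "alpha", "beta") %in% kept))
    # alternating independent words: pmi(alpha_beta) ~ ln 2 < 4 => dropped
    expect_false("alpha_beta" %in% kept)
    # threshold above ln(100) removes even the deterministic phrase
    kept2 <- collocationFilter(corp, function(n) 2.5 * n)
    expect_false("new_york" %in% kept2)
})

test_that("anscombe transform has the closed-form endpoints and is monotone", {
    expect_equal(anscombe(0), 2 * sqrt(3 / 8), tolerance = 1e-12)
    expect_equal(anscombe(1), 2 * sqrt(11 / 8), tolerance = 1e-12)
    p <- sort(runif(50))
    expect_true(all(diff(anscombe(p)) > 0))
    expect_error(anscombe(-0.1), "0, 1")
    expect_error(anscombe(1.1), "0, 1")
})

test_that("relative frequencies use the author word total as denominator", {
    msgs <- data.frame(author_id = "a",
                       text = "w w x y w x x w w w w w w w w w w w w w")
    corp <- aggregateAuthors(msgs)
    rf <- relativeFrequency(corp)
    expect_equal(rf$relfreq[rf$feature == "x"], 3 / 20)
    # unigram relative frequencies sum to 1
    expect_equal(sum(rf$relfreq[rf$order == 1]), 1)
    # phrases share the unigram denominator
    expect_equal(rf$relfreq[rf$feature == "w_w"], 13 / 20)
    # zero-word authors are rejected
    bad <- aggregateAuthors(data.frame(author_id = "z", text = ""))
    expect_error(relativeFrequency(bad), "zero words")
})

test_that("minimum-usage filter drops rare features at the ceiling rule", {
    msgs <- data.frame(author_id = sprintf("a%03d", 1:200),
                       text = c("rare common", rep("common", 199)))
    corp <- aggregateAuthors(msgs, nMax = 1)
    kept <- minUsageFilter(corp, minAuthorFraction = 0.01)
    expect_false("rare" %in% kept)  # 1 author < ceiling(2)
    expect_true("common" %in% kept)
    expect_setequal(minUsageFilter(corp, minAuthorFraction = 0),
                    c("rare", "common"))
})

test_that("feature matrix cells are anscombe relative frequencies", {
    corp <- aggregateAuthors(tinyMessages())
    fm <- buildFeatureMatrix(corp, c("hi", "good", "day"))
    v <- featureValues(fm)
    expect_identical(dim(v), c(3L, 3L))
    expect_identical(valueType(fm), "anscombe_relfreq")
    # author a used only hi (3 of 3 words)
    expect_equal(v["hi", "a"], anscombe(1))
    expect_equal(v["good", "a"], anscombe(0))   # absent => anscombe(0)
    expect_equal(v["day", "b"], anscombe(2 / 8))  # 8 words over 2 messages
    # rows carry corpus frequencies
    rd <- SummarizedExperiment::rowData(fm)
    expect_identical(rd["day", "corpus_frequency"], 4L)
})

test_that("collocation and usage filters commute on phrase sets", {
    spec <- syntheticSpec(40, seed = 9, meanMessages = 10, meanWords = 12)
    corp <- aggregateAuthors(generateCorpus(spec)$messages)
    a <- minUsageFilter(corp, collocationFilter(corp), 0.05)
    b <- intersect(collocationFilter(corp),
                   minUsageFilter(corp, minAuthorFraction = 0.05))
    expect_setequal(a, b)
})

test_that("single-word messages yield no phrases after filtering", {
    msgs <- data.frame(author_id = rep(c("a", "b"), each = 5),
                       text = rep(c("x", "y"), 5))
    corp <- aggregateAuthors(msgs)
    kept <- collocationFilter(corp)
    expect_true(all(!grepl("_", kept)))
})

test_that("feature matrices survive a disk round-trip", {
    corp <- aggregateAuthors(tinyMessages())
    fm <- ngramFeatureMatrix(corp, minAuthorFraction = 0)
    f <- withr::local_tempfile(fileext = ".csv")
    writeFeatureMatrix(fm, f)
    back <- readFeatureMatrix(f)
    expect_equal(featureValues(back)[rownames(fm), colnames(fm)],
                 featureValues(fm), tolerance = 1e-12)
    expect_identical(valueType(back), valueType(fm))
})
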