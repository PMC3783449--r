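# Shared fixture builders; everything is generated in code at test time.

tinyMessages <- function() {
    data.frame(
        author_id = c("a", "a", "b", "b", "c"),
        message_id = c("m1", "m2", "m3", "m4", "m5"),
        text = c("hi hi", "hi", "good day :-) good day", "love you !",
                 "the day was a good day"),
        stringsAsFactors = FALSE)
}

demoLexiconPath <- function(dialect = "csv") {
    system.file("extdata", paste0("demo_lexicon.", dialect),
                package = "dlatools")
}

# planted-gender corpus used by several predictive tests
plantedGenderSpec <- function(nAuthors = 240, seed = 11) {
    pe <- data.frame(
        feature = sprintf("w%04d", c(15, 25, 40, 60, 80, 120, 150, 200)),
        outcome = "gender",
        effect = rep(c(0.8, -0.8), 4))
    syntheticSpec(nAuthors, seed = seed, meanMessages = 25, meanWords = 15,
                  plantedEffects = pe)
}

# brute-force step-up oracle (independent of stats::p.adjust)
bhStepUpOracle <- function(p, q) {
    m <- length(p)
    o <- order(p)
    k <- 0L
    for (i in seq_len(m)) if (p[o][i] <= i * q / m) k <- i
    rej <- rep(FALSE, m)
    if (k > 0) rej[o[seq_len(k)]] <- TRUE
    rej
}
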