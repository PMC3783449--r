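#' Construct a synthetic-corpus specification
#'
#' Defaults emulate the statistical shape of a large status-update corpus:
#' a mean of 206 messages per author with a mean of 20 words each (about
#' 4,100 words per author), a 2,000-word Zipf(1.1) background vocabulary,
#' gender drawn Bernoulli(0.62) coded 0 = male / 1 = female, age from a
#' shifted log-normal matched to mean 23.43 and SD 8.96 (floored at 13),
#' and five standard-normal personality traits.  Planted effects shift a
#' feature's log emission rate by `effect` per standard deviation of the
#' outcome, keeping rates positive and effects multiplicative.
#'
#' @param nAuthors number of authors.
#' @param seed RNG seed.
#' @param meanMessages,meanWords Poisson means of messages per author and
#'   words per message.
#' @param vocabSize,zipfExponent background vocabulary settings.
#' @param collocations phrases (words joined by `_`) emitted as intact
#'   word sequences; each gets a base emission probability.
#' @param emoticons emoticon tokens added to the vocabulary.
#' @param plantedEffects data.frame `feature`, `outcome`, `effect`
#'   (log-rate shift per SD of the outcome), or `NULL`.
#' @param outcomeNames names of standard-normal trait outcomes.
#' @param genderP,ageMean,ageSD demographic distribution parameters.
#' @return a [SyntheticSpec-class].
#' @export
syntheticSpec <- function(nAuthors, seed = 1L,
                          meanMessages = 206, meanWords = 20,
                          vocabSize = 2000L, zipfExponent = 1.1,
                          collocations = c("new_york", "happy_birthday",
                                           "ice_cream"),
                          emoticons = c(":)", ":-)", ":(", "<3", "^_^"),
                          plantedEffects = NULL,
                          outcomeNames = c("extraversion", "neuroticism"),
                          genderP = 0.62, ageMean = 23.43, ageSD = 8.96) {
    new("SyntheticSpec", nAuthors = as.integer(nAuthors),
        seed = as.integer(seed), meanMessages = meanMessages,
        meanWords = meanWords, vocabSize = as.integer(vocabSize),
        zipfExponent = zipfExponent, collocations = collocations,
        emoticons = emoticons, plantedEffects = plantedEffects,
        outcomeNames = outcomeNames, genderP = genderP,
        ageMean = ageMean, ageSD = ageSD)
}

# shifted log-normal age: age = 13 + lognormal matched to the target
# moments of (age - 13)
.drawAges <- function(n, mean, sd, floor = 13) {
    m <- mean - floor
    s2 <- log(1 + (sd / m)^2)
    mu <- log(m) - s2 / 2
    floor + stats::rlnorm(n, mu, sqrt(s2))
}

# emission inventory: background words w0001.. (Zipf), emoticons and
# collocation units with small fixed base probabilities
.emissionUnits <- function(spec) {
    words <- sprintf("w%04d", seq_len(spec@vocabSize))
    p <- seq_len(spec@vocabSize)^(-spec@zipfExponent)
    p <- p / sum(p)
    units <- c(words, spec@emoticons, spec@collocations)
    pe <- rep(0.004, length(spec@emoticons))
    pc <- rep(0.003, length(spec@collocations))
    probs <- c(p * (1 - sum(pe) - sum(pc)), pe, pc)
    nWordsPerUnit <- c(rep(1L, length(words)), rep(1L, length(spec@emoticons)),
                       lengths(strsplit(spec@collocations, "_", fixed = TRUE)))
    list(units = units, probs = probs, nWords = nWordsPerUnit)
}

#' Generate a synthetic corpus with planted language-outcome effects
#'
#' Per author: draw outcomes (gender, age, traits); shift the log emission
#' rate of every planted feature by `effect * z(outcome)`; draw message
#' lengths and fill messages by sampling emission units (words, emoticons,
#' and collocations emitted as intact word sequences).  Deterministic
#' given the spec's seed.
#'
#' @param spec a [SyntheticSpec-class].
#' @return list with `messages` (author_id, message_id, text), `outcomes`
#'   (author_id, gender, age, traits) and `groundTruth` (the planted
#'   effects plus generator settings).
#' @export
generateCorpus <- function(spec) {
    stopifnot(methods::validObject(spec))
    set.seed(spec@seed)
    n <- spec@nAuthors
    ids <- sprintf("a%05d", seq_len(n))
    out <- data.frame(author_id = ids,
                      gender = stats::rbinom(n, 1, spec@genderP),
                      age = round(.drawAges(n, spec@ageMean, spec@ageSD), 1))
    for (nm in spec@outcomeNames) out[[nm]] <- stats::rnorm(n)
    em <- .emissionUnits(spec)
    logp0 <- log(em$probs)
    pe <- spec@plantedEffects
    zOut <- NULL
    if (!is.null(pe) && nrow(pe)) {
        miss <- setdiff(pe$feature, em$units)
        if (length(miss))
            stop("planted feature(s) not in the emission inventory: ",
                 paste(miss, collapse = ", "))
        zOut <- lapply(unique(pe$outcome), function(o) {
            v <- out[[o]]
            if (is.null(v)) stop("planted outcome not generated: ", o)
            as.vector(scale(v))
        })
        names(zOut) <- unique(pe$outcome)
    }
    msgs <- vector("list", n)
    for (a in seq_len(n)) {
        lp <- logp0
        if (!is.null(pe) && nrow(pe))
            for (r in seq_len(nrow(pe))) {
                j <- match(pe$feature[r], em$units)
                lp[j] <- lp[j] + pe$effect[r] * zOut[[pe$outcome[r]]][a]
            }
        pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
        nMsg <- max(1L, stats::rpois(1, spec@meanMessages))
        lens <- pmax(1L, stats::rpois(nMsg, spec@meanWords))
        # draw units, expand collocations into their words, then assign
        # tokens to messages in sequence (collocations stay intact inside
        # one message; expansion can only lengthen the last message)
        total <- sum(lens)
        draw <- sample.int(length(em$units), total, replace = TRUE,
                           prob = pr)
        toks <- em$units[draw]
        multi <- em$nWords[draw] > 1L
        if (any(multi)) {
            tl <- as.list(toks)
            tl[multi] <- strsplit(toks[multi], "_", fixed = TRUE)
            msgIdx <- rep(rep(seq_len(nMsg), lens), em$nWords[draw])
            toks <- unlist(tl, use.names = FALSE)
        } else {
            msgIdx <- rep(seq_len(nMsg), lens)
        }
        texts <- vapply(split(toks, factor(msgIdx,
                                           levels = seq_len(nMsg))),
                        paste, collapse = " ", character(1))
        msgs[[a]] <- data.frame(author_id = ids[a],
                                message_id = sprintf("%s_m%04d", ids[a],
                                                     seq_len(nMsg)),
                                text = texts)
    }
    messages <- do.call(rbind, msgs)
    gt <- list(seed = spec@seed, n_authors = n,
               mean_messages = spec@meanMessages,
               mean_words = spec@meanWords,
               vocab_size = spec@vocabSize,
               zipf_exponent = spec@zipfExponent,
               collocations = spec@collocations,
               emoticons = spec@emoticons,
               planted_effects = if (is.null(pe)) list() else pe)
    list(messages = messages, outcomes = out, groundTruth = gt)
}

#' Generate a topic-structured synthetic corpus
#'
#' K topic blocks with disjoint word vocabularies; every author has a
#' topic mixture, optionally tied to an outcome (`mixEffects`: logit shift
#' of the block's mixture weight per SD of the outcome); each message
#' samples one topic from the author's mixture and draws all its words
#' from that block's (within-block Zipf) distribution.
#'
#' @param nAuthors number of authors.
#' @param K number of topic blocks (>= 2).
#' @param wordsPerBlock vocabulary size per block.
#' @param meanMessages,meanWords Poisson means.
#' @param mixEffects optional data.frame `block`, `outcome`, `effect`.
#' @param outcomeNames standard-normal trait outcomes to generate.
#' @param seed RNG seed.
#' @return list `messages`, `outcomes`, `groundTruth` (incl. the
#'   block-word distributions as the true topic-word matrix).
#' @export
generateTopicCorpus <- function(nAuthors, K = 2L, wordsPerBlock = 25L,
                                meanMessages = 50, meanWords = 20,
                                mixEffects = NULL,
                                outcomeNames = "extraversion",
                                seed = 1L) {
    stopifnot(K >= 2)
    set.seed(as.integer(seed))
    ids <- sprintf("a%05d", seq_len(nAuthors))
    out <- data.frame(author_id = ids,
                      gender = stats::rbinom(nAuthors, 1, 0.62),
                      age = round(.drawAges(nAuthors, 23.43, 8.96), 1))
    for (nm in outcomeNames) out[[nm]] <- stats::rnorm(nAuthors)
    vocab <- lapply(seq_len(K), function(k)
        sprintf("t%02dw%03d", k, seq_len(wordsPerBlock)))
    wordP <- lapply(seq_len(K), function(k) {
        p <- seq_len(wordsPerBlock)^(-1.05); p / sum(p)
    })
    phiTrue <- matrix(0, K, K * wordsPerBlock,
                      dimnames = list(NULL, unlist(vocab)))
    for (k in seq_len(K))
        phiTrue[k, vocab[[k]]] <- wordP[[k]]
    msgs <- vector("list", nAuthors)
    mixes <- matrix(NA_real_, nAuthors, K)
    for (a in seq_len(nAuthors)) {
        logit <- rep(0, K)
        if (!is.null(mixEffects) && nrow(mixEffects))
            for (r in seq_len(nrow(mixEffects))) {
                z <- as.vector(scale(out[[mixEffects$outcome[r]]]))[a]
                logit[mixEffects$block[r]] <-
                    logit[mixEffects$block[r]] + mixEffects$effect[r] * z
            }
        theta <- exp(logit) / sum(exp(logit))
        mixes[a, ] <- theta
        nMsg <- max(1L, stats::rpois(1, meanMessages))
        lens <- pmax(1L, stats::rpois(nMsg, meanWords))
        topics <- sample.int(K, nMsg, replace = TRUE, prob = theta)
        texts <- vapply(seq_len(nMsg), function(m)
            paste(sample(vocab[[topics[m]]], lens[m], replace = TRUE,
                         prob = wordP[[topics[m]]]), collapse = " "),
            character(1))
        msgs[[a]] <- data.frame(author_id = ids[a],
                                message_id = sprintf("%s_m%04d", ids[a],
                                                     seq_len(nMsg)),
                                text = texts)
    }
    list(messages = do.call(rbind, msgs), outcomes = out,
         groundTruth = list(seed = seed, K = K,
                            phi = phiTrue, mixtures = mixes,
                            mix_effects = if (is.null(mixEffects)) list()
                                          else mixEffects))
}

#' Write a generated corpus to disk
#'
#' Emits the standard corpus formats: messages CSV, outcomes CSV, and the
#' ground truth as JSON.
#'
#' @param generated output of [generateCorpus()] or
#'   [generateTopicCorpus()].
#' @param dir destination directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeSyntheticCorpus <- function(generated, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeMessages(generated$messages, file.path(dir, "messages.csv"))
    data.table::fwrite(generated$outcomes, file.path(dir, "outcomes.csv"))
    gt <- generated$groundTruth
    if (!is.null(gt$phi)) gt$phi <- as.data.frame(gt$phi)
    if (!is.null(gt$mixtures)) gt$mixtures <- as.data.frame(gt$mixtures)
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(dir)
}
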