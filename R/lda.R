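#' @useDynLib dlatools, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Fit an LDA topic model by collapsed Gibbs sampling
#'
#' Documents are individual messages (status updates are short, so the
#' document-topic prior `alpha` defaults to a small value favoring few
#' topics per message).  After the final sweep, the topic-word distribution
#' is smoothed: `p(w|t) = (c_wt + beta) / (c_t + V*beta)`.  Fully
#' deterministic given `seed`.
#'
#' @param documents list of character vectors (tokenized messages).
#' @param K number of topics (>= 2 and at most the vocabulary size).
#' @param alpha document-topic concentration; default `0.3 / K`.
#' @param beta topic-word concentration; default `0.01`.
#' @param nIter Gibbs sweeps; default 1000.
#' @param seed integer RNG seed.
#' @param nRestarts independent chains run from different random
#'   initializations (all driven by `seed`); the final state with the
#'   highest collapsed joint log-likelihood is kept.  Restarting guards
#'   against the sampler's merge/split local modes; default 5.
#' @param stopwords optional tokens to exclude from the vocabulary.
#' @return a [TopicModel-class].
#' @export
fitLDA <- function(documents, K, alpha = 0.3 / K, beta = 0.01,
                   nIter = 1000L, seed = 1L, nRestarts = 5L,
                   stopwords = NULL) {
    stopifnot(K >= 2, length(documents) > 0)
    if (!is.null(stopwords))
        documents <- lapply(documents, function(d) d[!d %in% stopwords])
    documents <- documents[lengths(documents) > 0]
    if (!length(documents)) stop("no non-empty documents")
    vocab <- sort(unique(unlist(documents, use.names = FALSE)))
    V <- length(vocab)
    if (K > V) stop("K (", K, ") exceeds vocabulary size (", V, ")")
    ids <- lapply(documents, function(d) match(d, vocab) - 1L)
    lens <- lengths(ids)
    starts <- c(0L, cumsum(lens)[-length(lens)])
    flat <- unlist(ids, use.names = FALSE)
    set.seed(as.integer(seed))
    res <- NULL
    for (r in seq_len(max(1L, nRestarts))) {
        cand <- .gibbsLda(flat, as.integer(starts), as.integer(lens),
                          as.integer(K), V, alpha, beta,
                          as.integer(nIter))
        if (is.null(res) || cand$logLik > res$logLik) res <- cand
    }
    cwt <- res$wordTopic
    dimnames(cwt) <- list(vocab, NULL)
    ct <- colSums(cwt)
    phi <- t(sweep(cwt + beta, 2, ct + V * beta, "/"))
    rownames(phi) <- NULL
    colnames(phi) <- vocab
    new("TopicModel", K = as.integer(K), phi = phi, wordTopicCounts = cwt,
        alpha = alpha, beta = beta, nIter = as.integer(nIter),
        seed = as.integer(seed))
}

#' p(topic | word)
#'
#' Derived from the final-sweep assignment counts:
#' `p(t|w) = c_wt / sum_t c_wt`.  Words never assigned (zero total count)
#' are excluded.
#'
#' @param model a [TopicModel-class].
#' @return matrix words x topics; each row sums to 1.
#' @export
topicGivenWord <- function(model) {
    cwt <- model@wordTopicCounts
    tot <- rowSums(cwt)
    cwt <- cwt[tot > 0, , drop = FALSE]
    sweep(cwt, 1, rowSums(cwt), "/")
}

#' Per-author topic usage
#'
#' An author's probability of using each topic:
#' `usage_t = sum_w p(t|w) * p(w|author)`, where `p(w|author)` is the
#' author's relative word use restricted to (and renormalized over) the
#' model vocabulary.
#'
#' @param model a [TopicModel-class].
#' @param corpus an [AuthorCorpus-class].
#' @return matrix authors x topics; rows sum to 1.
#' @export
topicUsage <- function(model, corpus) {
    ptw <- topicGivenWord(model)
    uni <- ngramCounts(corpus, order = 1L)
    uni <- uni[uni$feature %in% rownames(ptw), , drop = FALSE]
    ids <- authorIds(corpus)
    missing <- setdiff(ids, unique(uni$author_id))
    if (length(missing))
        stop("author(s) share no word with the model vocabulary: ",
             paste(utils::head(missing, 3), collapse = ", "))
    W <- matrix(0, nrow = length(ids), ncol = nrow(ptw),
                dimnames = list(ids, rownames(ptw)))
    W[cbind(match(uni$author_id, ids), match(uni$feature, rownames(ptw)))] <-
        uni$count
    W <- W / rowSums(W)
    usage <- W %*% ptw
    colnames(usage) <- paste0("topic_", seq_len(ncol(usage)))
    usage
}

#' Top words of a topic
#'
#' The `n` words with highest `p(w|t)` in descending order (ties broken
#' lexicographically) — the ordering used when displaying a topic.
#'
#' @param model a [TopicModel-class].
#' @param t topic index.
#' @param n number of words (default 15).
#' @return character vector.
#' @export
topWords <- function(model, t, n = 15L) {
    p <- topicWordProbs(model)[t, ]
    w <- names(p)[order(-p, names(p))]
    utils::head(w, n)
}

#' Topic-usage feature matrix
#'
#' Wraps [topicUsage()] as a [FeatureMatrix-class] (`topic_prob`
#' semantics, topics as rows).
#'
#' @inheritParams topicUsage
#' @return a [FeatureMatrix-class].
#' @export
topicFeatureMatrix <- function(model, corpus) {
    m <- t(topicUsage(model, corpus))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(value = m))
    S4Vectors::metadata(se)$valueType <- "topic_prob"
    new("FeatureMatrix", se)
}

#' Persist / load a topic model
#'
#' CSV of `topic,word,p_word_given_topic` (plus the assignment counts
#' needed for p(topic|word)), with a JSON sidecar recording K, alpha, beta,
#' nIter and seed.
#'
#' @param model a [TopicModel-class].
#' @param path destination CSV.
#' @export
writeTopicModel <- function(model, path) {
    phi <- topicWordProbs(model)
    cwt <- model@wordTopicCounts
    df <- data.frame(
        topic = rep(seq_len(nrow(phi)), each = ncol(phi)),
        word = rep(colnames(phi), nrow(phi)),
        p_word_given_topic = as.vector(t(phi)))
    # assignment counts laid out to match the (topic, word) row order
    df$assignment_count <- as.vector(vapply(seq_len(nrow(phi)),
                                            function(t) cwt[colnames(phi), t],
                                            numeric(ncol(phi))))
    data.table::fwrite(df, path)
    jsonlite::write_json(
        list(K = model@K, alpha = model@alpha, beta = model@beta,
             n_iter = model@nIter, seed = model@seed),
        paste0(path, ".json"), auto_unbox = TRUE)
    invisible(path)
}

#' @rdname writeTopicModel
#' @export
readTopicModel <- function(path) {
    df <- data.table::fread(path, data.table = FALSE)
    meta <- jsonlite::read_json(paste0(path, ".json"),
                                simplifyVector = TRUE)
    importTopicModel(df, alpha = meta$alpha, beta = meta$beta,
                     nIter = meta$n_iter, seed = meta$seed)
}

#' Import an externally estimated topic-word table
#'
#' Accepts a data.frame or CSV path with columns `topic`, `word` and a
#' weight column (`p_word_given_topic`, `weight` or `count`), e.g. an
#' export from an external topic-modeling toolkit.  Weights are used both
#' for p(w|t) (normalized per topic) and as pseudo-assignment-counts for
#' p(t|w).
#'
#' @param x data.frame or CSV path.
#' @param alpha,beta,nIter,seed metadata to record on the model.
#' @return a [TopicModel-class].
#' @export
importTopicModel <- function(x, alpha = NA_real_, beta = 0,
                             nIter = 0L, seed = 0L) {
    if (is.character(x)) x <- data.table::fread(x, data.table = FALSE)
    wcol <- intersect(c("p_word_given_topic", "weight", "count"), names(x))
    if (!length(wcol)) stop("no weight column found")
    wcol <- wcol[1]
    if ("assignment_count" %in% names(x)) ccol <- "assignment_count"
    else ccol <- wcol
    topics <- sort(unique(x$topic))
    vocab <- sort(unique(x$word))
    K <- length(topics)
    phi <- matrix(0, K, length(vocab), dimnames = list(NULL, vocab))
    cwt <- matrix(0, length(vocab), K, dimnames = list(vocab, NULL))
    phi[cbind(match(x$topic, topics), match(x$word, vocab))] <- x[[wcol]]
    cwt[cbind(match(x$word, vocab), match(x$topic, topics))] <- x[[ccol]]
    phi <- phi / rowSums(phi)
    new("TopicModel", K = as.integer(K), phi = phi, wordTopicCounts = cwt,
        alpha = as.numeric(alpha), beta = as.numeric(beta),
        nIter = as.integer(nIter), seed = as.integer(seed))
}

#' Export top words per topic
#'
#' One row per topic listing its `n` most prevalent words, mirroring the
#' usual supplementary "top words" format.
#'
#' @param model a [TopicModel-class].
#' @param path destination CSV.
#' @param n words per topic (default 15).
#' @export
writeTopWords <- function(model, path, n = 15L) {
    rows <- lapply(seq_len(nTopics(model)), function(t)
        data.frame(topic = t,
                   words = paste(topWords(model, t, n), collapse = " ")))
    data.table::fwrite(do.call(rbind, rows), path, quote = TRUE)
    invisible(path)
}
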