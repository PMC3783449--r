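#' Enumerate n-grams of one tokenized message
#'
#' All contiguous token subsequences of length 1..`nMax`, joined with `_`
#' (the display convention for multiword phrases).  N-grams are only ever
#' formed within a single message.
#'
#' @param tokens character vector of tokens.
#' @param nMax maximum length (default 3).
#' @return character vector of n-grams (with multiplicity).
#' @examples
#' extractNgrams(c("i", "love", "you"))
#' @export
extractNgrams <- function(tokens, nMax = 3L) {
    stopifnot(nMax >= 1)
    L <- length(tokens)
    if (!L) return(character(0))
    out <- vector("list", min(nMax, L))
    for (n in seq_len(min(nMax, L))) {
        k <- L - n + 1L
        g <- tokens[seq_len(k)]
        if (n > 1L)
            for (j in seq_len(n - 1L))
                g <- paste(g, tokens[j + seq_len(k)], sep = "_")
        out[[n]] <- g
    }
    unlist(out, use.names = FALSE)
}

#' Corpus-level n-gram probabilities
#'
#' For each n-gram order, the probability of an n-gram is its total corpus
#' count divided by the total corpus count of all n-grams of that order.
#'
#' @param corpus an [AuthorCorpus-class].
#' @return data.frame `feature`, `order`, `count`, `n_authors`, `prob`.
#' @export
corpusProbabilities <- function(corpus) {
    cnt <- data.table::as.data.table(ngramCounts(corpus))
    tot <- cnt[, list(count = sum(count), n_authors = .N),
               by = c("feature", "order")]
    tot[, `:=`(prob = count / sum(count)), by = "order"]
    data.table::setDF(tot[order(tot$order, -tot$count, tot$feature)])
}

#' Pointwise mutual information of a phrase
#'
#' `log( p(phrase) / prod_i p(word_i) )` in natural-log units: the joint
#' probability of observing the word sequence against the probability under
#' independence.  0 means the words co-occur exactly as often as chance;
#' a deterministic collocation whose words appear nowhere else has
#' PMI `log(1/p)` for marginal probability `p`.
#'
#' @param phrase phrase string, words joined by `_` (or a character vector
#'   of phrases).
#' @param probs data.frame from [corpusProbabilities()].
#' @return numeric PMI per phrase; `-Inf` for a phrase never observed.
#' @export
pmi <- function(phrase, probs) {
    p1 <- probs[probs$order == 1L, ]
    lookup1 <- stats::setNames(p1$prob, p1$feature)
    vapply(phrase, function(ph) {
        words <- strsplit(ph, "_", fixed = TRUE)[[1]]
        n <- length(words)
        pw <- lookup1[words]
        if (anyNA(pw) || any(pw <= 0))
            stop("component word without corpus probability in ", sQuote(ph))
        row <- probs$feature == ph & probs$order == n
        pp <- if (any(row)) probs$prob[row][1] else 0
        if (pp <= 0) -Inf else log(pp) - sum(log(pw))
    }, numeric(1), USE.NAMES = !is.null(names(phrase)) || length(phrase) > 1)
}

#' Collocation filter
#'
#' Keeps every unigram; keeps an n-gram of length n >= 2 iff its PMI
#' exceeds `thresholdFn(n)`.  The default threshold `2 * n` (natural-log
#' units) grows with phrase length, so chance juxtapositions of independent
#' words (PMI near 0) are discarded while genuine collocations pass.
#'
#' @param corpus an [AuthorCorpus-class].
#' @param thresholdFn function n -> threshold; default `function(n) 2 * n`.
#' @param probs optional precomputed [corpusProbabilities()] table.
#' @return character vector of retained feature names.
#' @export
collocationFilter <- function(corpus, thresholdFn = function(n) 2 * n,
                              probs = NULL) {
    if (is.null(probs)) probs <- corpusProbabilities(corpus)
    keep1 <- probs$feature[probs$order == 1L]
    ph <- probs[probs$order > 1L, , drop = FALSE]
    if (!nrow(ph)) return(keep1)
    # vectorized PMI over all phrases
    p1 <- probs[probs$order == 1L, ]
    words <- strsplit(ph$feature, "_", fixed = TRUE)
    wu <- unlist(words, use.names = FALSE)
    lw <- log(p1$prob)[match(wu, p1$feature)]
    indep <- rowsum(lw, rep(seq_along(words), lengths(words)))[, 1]
    pmiv <- log(ph$prob) - indep
    uo <- sort(unique(ph$order))
    thr <- vapply(uo, thresholdFn, numeric(1))[match(ph$order, uo)]
    c(keep1, ph$feature[is.finite(pmiv) & pmiv > thr])
}

#' Per-author relative frequencies
#'
#' Every word and phrase count is normalized by the author's total word use
#' (unigram token count) — phrases included, so all features share a common
#' denominator.
#'
#' @param corpus an [AuthorCorpus-class].
#' @param features optional feature subset.
#' @return data.frame `author_id`, `feature`, `order`, `count`, `relfreq`.
#' @export
relativeFrequency <- function(corpus, features = NULL) {
    st <- authorStats(corpus)
    if (any(st$n_words <= 0))
        stop("author(s) with zero words: ",
             paste(utils::head(st$author_id[st$n_words <= 0], 3),
                   collapse = ", "),
             " (filter them out first)")
    cnt <- ngramCounts(corpus)
    if (!is.null(features))
        cnt <- cnt[cnt$feature %in% features, , drop = FALSE]
    nw <- stats::setNames(st$n_words, st$author_id)
    cnt$relfreq <- cnt$count / nw[cnt$author_id]
    cnt
}

#' Anscombe variance-stabilizing transform
#'
#' `2 * sqrt(p + 3/8)`, the classical variance stabilizer for count-derived
#' frequencies; maps `[0, 1]` onto `[2*sqrt(3/8), 2*sqrt(11/8)]`.
#'
#' @param p numeric in `[0, 1]`.
#' @return transformed values.
#' @export
anscombe <- function(p) {
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
        stop("p must lie in [0, 1]")
    2 * sqrt(p + 3 / 8)
}

#' Minimum-usage feature filter
#'
#' Restricts analysis to common language: drops any feature used by fewer
#' than `ceiling(minAuthorFraction * nAuthors)` authors (default: at least
#' 1% of subjects).
#'
#' @param corpus an [AuthorCorpus-class].
#' @param features candidate feature names (default: all).
#' @param minAuthorFraction minimum fraction of authors using the feature.
#' @return retained feature names.
#' @export
minUsageFilter <- function(corpus, features = NULL,
                           minAuthorFraction = 0.01) {
    stopifnot(minAuthorFraction >= 0)
    cnt <- data.table::as.data.table(ngramCounts(corpus))
    if (!is.null(features)) cnt <- cnt[cnt$feature %in% features, ]
    nA <- nrow(authorStats(corpus))
    usage <- cnt[cnt$count > 0, list(n_authors = .N), by = "feature"]
    minN <- ceiling(minAuthorFraction * nA)
    usage$feature[usage$n_authors >= minN]
}

#' Assemble the open-vocabulary feature matrix
#'
#' Builds a [FeatureMatrix-class] of Anscombe-transformed relative
#' frequencies: rows are features, columns authors; an author who never
#' uses a feature gets `anscombe(0) = 2*sqrt(3/8)`.
#'
#' @param corpus an [AuthorCorpus-class].
#' @param features retained feature names (from the collocation and usage
#'   filters).
#' @param transform `"anscombe"` (default) or `"relfreq"` (untransformed).
#' @return a [FeatureMatrix-class].
#' @export
buildFeatureMatrix <- function(corpus, features,
                               transform = c("anscombe", "relfreq")) {
    transform <- match.arg(transform)
    features <- unique(features)
    ids <- authorIds(corpus)
    rf <- relativeFrequency(corpus, features)
    m <- matrix(0, nrow = length(features), ncol = length(ids),
                dimnames = list(features, ids))
    m[cbind(match(rf$feature, features), match(rf$author_id, ids))] <-
        rf$relfreq
    if (transform == "anscombe") m <- anscombe(m)
    cnt <- data.table::as.data.table(ngramCounts(corpus))
    cnt <- cnt[cnt$feature %in% features, ]
    tot <- cnt[, list(corpus_frequency = sum(count), n_authors = .N),
               by = "feature"]
    rd <- S4Vectors::DataFrame(
        corpus_frequency = tot$corpus_frequency[match(features, tot$feature)],
        n_authors = tot$n_authors[match(features, tot$feature)],
        row.names = features)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(value = m), rowData = rd)
    S4Vectors::metadata(se)$valueType <-
        if (transform == "anscombe") "anscombe_relfreq" else "relfreq"
    new("FeatureMatrix", se)
}

#' One-call open-vocabulary extraction
#'
#' Convenience wrapper running the full words-and-phrases pipeline:
#' collocation filter, minimum-usage filter, relative frequencies, Anscombe
#' transform.
#'
#' @inheritParams buildFeatureMatrix
#' @param pmiThresholdCoef coefficient c in the phrase threshold `c * n`.
#' @param minAuthorFraction minimum fraction of authors using a feature.
#' @return a [FeatureMatrix-class] of `anscombe_relfreq` values.
#' @export
ngramFeatureMatrix <- function(corpus, pmiThresholdCoef = 2,
                               minAuthorFraction = 0.01) {
    feats <- collocationFilter(corpus,
                               function(n) pmiThresholdCoef * n)
    feats <- minUsageFilter(corpus, feats, minAuthorFraction)
    if (!length(feats)) stop("no features survive the filters")
    buildFeatureMatrix(corpus, feats)
}

#' Persist / load a feature matrix
#'
#' Sparse triplet CSV (`author_id`, `feature`, `value`): only cells whose
#' value differs from the absent-feature baseline are stored.
#'
#' @param fm a [FeatureMatrix-class].
#' @param path destination CSV.
#' @export
writeFeatureMatrix <- function(fm, path) {
    v <- featureValues(fm)
    base <- if (identical(valueType(fm), "anscombe_relfreq"))
        anscombe(0) else 0
    idx <- which(abs(v - base) > 1e-12, arr.ind = TRUE)
    trip <- data.frame(author_id = colnames(v)[idx[, 2]],
                       feature = rownames(v)[idx[, 1]],
                       value = v[idx])
    trip <- trip[order(trip$author_id, trip$feature), ]
    data.table::fwrite(trip, path, quote = TRUE)
    sidecar <- paste0(path, ".json")
    jsonlite::write_json(
        list(valueType = valueType(fm), features = rownames(v),
             authors = colnames(v)),
        sidecar, auto_unbox = TRUE)
    invisible(path)
}

#' @rdname writeFeatureMatrix
#' @param path CSV written by [writeFeatureMatrix()].
#' @export
readFeatureMatrix <- function(path) {
    meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    trip <- data.table::fread(path, data.table = FALSE)
    base <- if (identical(meta$valueType, "anscombe_relfreq"))
        anscombe(0) else 0
    m <- matrix(base, nrow = length(meta$features),
                ncol = length(meta$authors),
                dimnames = list(meta$features, meta$authors))
    m[cbind(match(trip$feature, meta$features),
            match(trip$author_id, meta$authors))] <- trip$value
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(value = m))
    S4Vectors::metadata(se)$valueType <- meta$valueType
    new("FeatureMatrix", se)
}
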