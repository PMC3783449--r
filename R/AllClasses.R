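#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom S4Vectors DFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

# data.table syntax (:=, .N) is used internally
.datatable.aware <- TRUE

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' AuthorCorpus: per-author n-gram counts
#'
#' Holds the result of tokenizing a message corpus and pooling token and
#' n-gram counts per author (the analysis is always subject-level: all of an
#' author's messages are counted together, while n-grams never cross a
#' message boundary).
#'
#' @slot counts data.frame with columns `author_id`, `feature` (words joined
#'   by `_` for phrases), `order` (n-gram length, 1-3) and `count`.
#' @slot authors data.frame with one row per author: `author_id`,
#'   `n_messages`, `n_words` (total unigram tokens).
#' @slot nMax maximum n-gram order extracted.
#'
#' @export
setClass("AuthorCorpus",
    representation(counts = "data.frame", authors = "data.frame",
                   nMax = "integer"),
    prototype(counts = data.frame(), authors = data.frame(), nMax = 3L))

setValidity("AuthorCorpus", function(object) {
    msg <- character()
    need <- c("author_id", "feature", "order", "count")
    if (!all(need %in% names(object@counts)))
        msg <- c(msg, paste("counts must have columns",
                            paste(need, collapse = ", ")))
    if (!all(c("author_id", "n_messages", "n_words") %in%
             names(object@authors)))
        msg <- c(msg, "authors must have author_id, n_messages, n_words")
    if (nrow(object@counts) && any(object@counts$count < 0))
        msg <- c(msg, "counts must be non-negative")
    if (nrow(object@authors) && any(object@authors$n_words < 0))
        msg <- c(msg, "n_words must be non-negative")
    if (length(msg)) msg else TRUE
})

#' FeatureMatrix: authors-by-features value container
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] with features as rows
#' and authors as columns.  The single assay `"value"` carries one of four
#' value semantics, recorded in `metadata()$valueType`:
#' `"anscombe_relfreq"` (2*sqrt(relative frequency + 3/8)), `"relfreq"`,
#' `"topic_prob"` (p(topic | author)) or `"category_relfreq"` (closed-
#' vocabulary category proportion).
#'
#' @export
setClass("FeatureMatrix", contains = "SummarizedExperiment")

.valueTypes <- c("anscombe_relfreq", "relfreq", "topic_prob",
                 "category_relfreq")

setValidity("FeatureMatrix", function(object) {
    msg <- character()
    vt <- S4Vectors::metadata(object)$valueType
    if (is.null(vt) || !vt %in% .valueTypes)
        msg <- c(msg, paste("metadata()$valueType must be one of",
                            paste(.valueTypes, collapse = ", ")))
    if (!"value" %in% names(SummarizedExperiment::assays(object)))
        msg <- c(msg, "assay 'value' is required")
    else {
        v <- SummarizedExperiment::assay(object, "value")
        if (any(!is.finite(v)))
            msg <- c(msg, "values must be finite")
        else if (identical(vt, "anscombe_relfreq")) {
            lo <- 2 * sqrt(3 / 8) - 1e-9
            hi <- 2 * sqrt(11 / 8) + 1e-9
            if (any(v < lo) || any(v > hi))
                msg <- c(msg, "anscombe_relfreq values out of [2*sqrt(3/8), 2*sqrt(11/8)]")
        }
    }
    if (length(msg)) msg else TRUE
})

#' TopicModel: LDA topic-word model
#'
#' Result of collapsed-Gibbs LDA estimation (or of importing an externally
#' estimated topic-word table).  `phi` rows are topics, columns the model
#' vocabulary; each row is p(word | topic).  `wordTopicCounts` keeps the raw
#' final-sweep assignment counts from which p(topic | word) is derived.
#'
#' @slot K number of topics.
#' @slot phi K x V matrix, rows summing to 1.
#' @slot wordTopicCounts V x K matrix of token-assignment counts.
#' @slot alpha,beta Dirichlet concentration parameters used in fitting.
#' @slot nIter Gibbs sweeps run.
#' @slot seed RNG seed used.
#'
#' @export
setClass("TopicModel",
    representation(K = "integer", phi = "matrix", wordTopicCounts = "matrix",
                   alpha = "numeric", beta = "numeric", nIter = "integer",
                   seed = "integer"))

setValidity("TopicModel", function(object) {
    msg <- character()
    if (nrow(object@phi) != object@K)
        msg <- c(msg, "phi must have K rows")
    rs <- rowSums(object@phi)
    if (any(abs(rs - 1) > 1e-9))
        msg <- c(msg, "phi rows must sum to 1")
    if (any(object@wordTopicCounts < 0))
        msg <- c(msg, "assignment counts must be non-negative")
    if (is.null(colnames(object@phi)))
        msg <- c(msg, "phi must have vocabulary colnames")
    if (length(msg)) msg else TRUE
})

#' Lexicon: closed-vocabulary category word lists
#'
#' @slot categories named list; each element a character vector of patterns
#'   (a literal token, or a stem wildcard with trailing `*`).
#'
#' @export
setClass("Lexicon", representation(categories = "list"))

setValidity("Lexicon", function(object) {
    msg <- character()
    nm <- names(object@categories)
    if (length(object@categories)) {
        if (is.null(nm) || anyDuplicated(nm) || any(nm == ""))
            msg <- c(msg, "category names must be unique and non-empty")
        if (any(!vapply(object@categories, length, 1L)))
            msg <- c(msg, "categories must have at least one pattern")
    }
    if (length(msg)) msg else TRUE
})

#' AssociationResults: ranked differential-language-analysis output
#'
#' A [S4Vectors::DataFrame] subclass with one row per tested feature:
#' `feature`, `outcome`, `beta_std` (standardized coefficient of the feature
#' in an OLS of the outcome on the feature plus covariates), `p` (two-tailed),
#' `n`, `corpus_frequency` and `significant`.  `metadata()` records the
#' correction method, family alpha, number of tests, the per-test threshold
#' (Bonferroni) and any features skipped for zero variance.
#'
#' @export
setClass("AssociationResults", contains = "DFrame")

#' SyntheticSpec: planted-effect corpus description
#'
#' Describes a synthetic message corpus whose statistical shape follows a
#' large social-media status-update study: many short messages per author
#' (default mean 206 messages of mean 20 words, about 4,100 words/author), a
#' Zipf-tailed background vocabulary, fixed multiword collocations, emoticon
#' tokens, and per-author log-rate shifts of planted tokens proportional to
#' standardized outcome values.
#'
#' @slot nAuthors number of authors.
#' @slot seed RNG seed.
#' @slot meanMessages,meanWords Poisson means for messages per author and
#'   words per message.
#' @slot vocabSize background vocabulary size.
#' @slot zipfExponent Zipf exponent of background word frequencies.
#' @slot collocations character vector of phrases (words joined by `_`)
#'   always emitted as intact word sequences.
#' @slot emoticons emoticon tokens mixed into the background vocabulary.
#' @slot plantedEffects data.frame (`feature`, `outcome`, `effect`): the
#'   feature's log emission rate is shifted by `effect` per SD of the outcome.
#' @slot outcomeNames continuous trait names generated as standard normals.
#' @slot genderP Bernoulli probability of gender = 1 (female).
#' @slot ageMean,ageSD target moments of the (shifted log-normal) age
#'   distribution.
#'
#' @export
setClass("SyntheticSpec",
    representation(nAuthors = "integer", seed = "integer",
                   meanMessages = "numeric", meanWords = "numeric",
                   vocabSize = "integer", zipfExponent = "numeric",
                   collocations = "character", emoticons = "character",
                   plantedEffects = "data.frameOrNULL",
                   outcomeNames = "character", genderP = "numeric",
                   ageMean = "numeric", ageSD = "numeric"))

setValidity("SyntheticSpec", function(object) {
    msg <- character()
    if (object@nAuthors < 1) msg <- c(msg, "nAuthors must be >= 1")
    if (!is.null(object@plantedEffects)) {
        need <- c("feature", "outcome", "effect")
        if (!all(need %in% names(object@plantedEffects)))
            msg <- c(msg, "plantedEffects needs feature, outcome, effect")
        else if (any(!is.finite(object@plantedEffects$effect)))
            msg <- c(msg, "effect sizes must be finite")
    }
    if (length(msg)) msg else TRUE
})
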