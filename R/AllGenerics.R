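#' @include AllClasses.R
NULL

#' Accessors
#'
#' Small accessor layer over the core classes so downstream code never
#' touches slots directly.
#'
#' @param x an object.
#' @param ... passed to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("authorIds", function(x, ...) standardGeneric("authorIds"))

#' @rdname accessors
#' @export
setGeneric("authorStats", function(x, ...) standardGeneric("authorStats"))

#' @rdname accessors
#' @export
setGeneric("ngramCounts", function(x, ...) standardGeneric("ngramCounts"))

#' @rdname accessors
#' @export
setGeneric("featureValues", function(x, ...) standardGeneric("featureValues"))

#' @rdname accessors
#' @export
setGeneric("valueType", function(x, ...) standardGeneric("valueType"))

#' @rdname accessors
#' @export
setGeneric("nTopics", function(x, ...) standardGeneric("nTopics"))

#' @rdname accessors
#' @export
setGeneric("topicWordProbs", function(x, ...) standardGeneric("topicWordProbs"))

#' @rdname accessors
#' @export
setGeneric("modelVocabulary", function(x, ...) standardGeneric("modelVocabulary"))

#' @rdname accessors
#' @export
setGeneric("lexiconCategories", function(x, ...) standardGeneric("lexiconCategories"))

## ---- AuthorCorpus ----

#' @rdname accessors
#' @export
setMethod("authorIds", "AuthorCorpus", function(x, ...)
    x@authors$author_id)

#' @rdname accessors
#' @export
setMethod("authorStats", "AuthorCorpus", function(x, ...) x@authors)

#' @rdname accessors
#' @param order optional n-gram orders to keep (default: all).
#' @export
setMethod("ngramCounts", "AuthorCorpus", function(x, order = NULL, ...) {
    cnt <- x@counts
    if (!is.null(order)) cnt <- cnt[cnt$order %in% order, , drop = FALSE]
    cnt
})

setMethod("show", "AuthorCorpus", function(object) {
    cat("AuthorCorpus:", nrow(object@authors), "authors,",
        length(unique(object@counts$feature)), "distinct features",
        sprintf("(n-grams up to order %d)\n", object@nMax))
    cat("  total words:", sum(object@authors$n_words),
        " total messages:", sum(object@authors$n_messages), "\n")
})

## ---- FeatureMatrix ----

#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureMatrix", function(x, ...)
    SummarizedExperiment::assay(x, "value"))

#' @rdname accessors
#' @export
setMethod("valueType", "FeatureMatrix", function(x, ...)
    S4Vectors::metadata(x)$valueType)

#' @rdname accessors
#' @export
setMethod("authorIds", "FeatureMatrix", function(x, ...) colnames(x))

setMethod("show", "FeatureMatrix", function(object) {
    cat("FeatureMatrix:", nrow(object), "features x", ncol(object),
        "authors  [", S4Vectors::metadata(object)$valueType, "]\n")
    if (nrow(object))
        cat("  features:", paste(utils::head(rownames(object), 5),
                                 collapse = ", "),
            if (nrow(object) > 5) "...", "\n")
})

## ---- TopicModel ----

#' @rdname accessors
#' @export
setMethod("nTopics", "TopicModel", function(x, ...) x@K)

#' @rdname accessors
#' @export
setMethod("topicWordProbs", "TopicModel", function(x, ...) x@phi)

#' @rdname accessors
#' @export
setMethod("modelVocabulary", "TopicModel", function(x, ...) colnames(x@phi))

setMethod("show", "TopicModel", function(object) {
    cat("TopicModel:", object@K, "topics over",
        ncol(object@phi), "words",
        sprintf("(alpha=%.4g, beta=%.4g, %d sweeps, seed=%d)\n",
                object@alpha, object@beta, object@nIter, object@seed))
    for (t in seq_len(min(object@K, 3)))
        cat(sprintf("  topic %d: %s\n", t,
                    paste(topWords(object, t, 8), collapse = " ")))
    if (object@K > 3) cat("  ...\n")
})

## ---- Lexicon ----

#' @rdname accessors
#' @export
setMethod("lexiconCategories", "Lexicon", function(x, ...) x@categories)

setMethod("show", "Lexicon", function(object) {
    cat("Lexicon:", length(object@categories), "categories\n")
    for (nm in utils::head(names(object@categories), 6))
        cat(sprintf("  %s (%d patterns)\n", nm,
                    length(object@categories[[nm]])))
})

setMethod("show", "AssociationResults", function(object) {
    md <- S4Vectors::metadata(object)
    cat("AssociationResults:", nrow(object), "features for outcome",
        sQuote(md$outcome), "\n")
    cat(sprintf("  correction: %s (family alpha %g, %d tests); %d significant\n",
                md$correction, md$family_alpha, md$m_tests,
                sum(object$significant)))
    if (length(md$skipped))
        cat("  skipped (zero variance):", length(md$skipped), "features\n")
})
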