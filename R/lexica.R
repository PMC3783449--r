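#' Load a closed-vocabulary lexicon
#'
#' Two dialects:
#' * `"csv"`: rows `category,term`.
#' * `"dic"`: the classic word-count format — a `%`-delimited header mapping
#'   numeric ids to category names, then `term<TAB>id[<TAB>id...]` lines.
#'
#' Patterns are single tokens, optionally stem wildcards with a trailing
#' `*` (`happ*` matches every token with prefix `happ`).  Category matching
#' is unigram-only; multiword entries are dropped with a warning.
#'
#' @param path lexicon file.
#' @param dialect `"csv"` or `"dic"` (default: by extension).
#' @return a [Lexicon-class].
#' @export
loadLexicon <- function(path, dialect = c("auto", "csv", "dic")) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("file not found: ", path)
    if (dialect == "auto")
        dialect <- if (grepl("\\.dic$", path)) "dic" else "csv"
    if (dialect == "csv") {
        df <- data.table::fread(path, header = TRUE, data.table = FALSE,
                                colClasses = "character")
        if (!all(c("category", "term") %in% names(df)))
            stop("csv lexicon needs columns category,term")
        cats <- split(df$term, df$category)
    } else {
        ln <- readLines(path, warn = FALSE)
        ln <- trimws(ln)
        ln <- ln[nzchar(ln)]
        pct <- which(ln == "%")
        if (length(pct) < 2)
            stop("dic lexicon needs a %%-delimited header")
        hdr <- ln[(pct[1] + 1):(pct[2] - 1)]
        body <- ln[-seq_len(pct[2])]
        hsplit <- strsplit(hdr, "[ \t]+")
        idmap <- stats::setNames(vapply(hsplit, `[`, "", 2),
                                 vapply(hsplit, `[`, "", 1))
        cats <- stats::setNames(vector("list", length(idmap)),
                                unname(idmap))
        for (row in strsplit(body, "[ \t]+")) {
            term <- row[1]
            for (id in row[-1]) {
                nm <- unname(idmap[id])
                if (is.na(nm))
                    stop("unknown category id ", sQuote(id), " for term ",
                         sQuote(term))
                cats[[nm]] <- c(cats[[nm]], term)
            }
        }
        cats <- cats[!vapply(cats, is.null, TRUE)]
    }
    multi <- lapply(cats, function(p) p[grepl("[ _]", p)])
    if (any(lengths(multi) > 0)) {
        warning("dropping multiword lexicon entr(ies): ",
                paste(utils::head(unlist(multi), 5), collapse = ", "))
        cats <- lapply(cats, function(p) p[!grepl("[ _]", p)])
        cats <- cats[lengths(cats) > 0]
    }
    new("Lexicon", categories = cats)
}

# which of the unigram tokens `words` match any pattern of `patterns`
.matchCategory <- function(words, patterns) {
    hit <- rep(FALSE, length(words))
    wild <- endsWith(patterns, "*")
    for (p in patterns[!wild]) hit <- hit | words == p
    for (p in patterns[wild])
        hit <- hit | startsWith(words, substr(p, 1, nchar(p) - 1L))
    hit
}

#' Category relative frequency
#'
#' The proportion of an author's words belonging to a category: the summed
#' counts of unigrams matching any of the category's patterns, divided by
#' the author's total word count.  A token matching several patterns of one
#' category is counted once; overlapping categories are independent.
#'
#' @param corpus an [AuthorCorpus-class].
#' @param lexicon a [Lexicon-class].
#' @return numeric matrix authors x categories, entries in `[0, 1]`.
#' @export
categoryRelativeFrequency <- function(corpus, lexicon) {
    st <- authorStats(corpus)
    if (any(st$n_words <= 0))
        stop("author(s) with zero words; filter them out first")
    uni <- ngramCounts(corpus, order = 1L)
    words <- unique(uni$feature)
    cats <- lexiconCategories(lexicon)
    out <- matrix(0, nrow = nrow(st), ncol = length(cats),
                  dimnames = list(st$author_id, names(cats)))
    uniDT <- data.table::as.data.table(uni)
    for (ci in seq_along(cats)) {
        mw <- words[.matchCategory(words, cats[[ci]])]
        if (!length(mw)) next
        sub <- uniDT[uniDT$feature %in% mw,
                     list(n = sum(count)), by = "author_id"]
        out[match(sub$author_id, st$author_id), ci] <- sub$n
    }
    sweep(out, 1, st$n_words, "/")
}

#' Closed-vocabulary feature matrix
#'
#' Wraps [categoryRelativeFrequency()] as a [FeatureMatrix-class]
#' (`category_relfreq` semantics, categories as rows).
#'
#' @inheritParams categoryRelativeFrequency
#' @return a [FeatureMatrix-class].
#' @export
lexiconFeatureMatrix <- function(corpus, lexicon) {
    m <- t(categoryRelativeFrequency(corpus, lexicon))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(value = m))
    S4Vectors::metadata(se)$valueType <- "category_relfreq"
    new("FeatureMatrix", se)
}
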