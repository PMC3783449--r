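#' @importFrom data.table fread fwrite data.table setDT setDF as.data.table
#' @importFrom jsonlite fromJSON toJSON write_json read_json
NULL

#' Read a message corpus
#'
#' Reads person-level message records (`author_id`, `text`, optional
#' `message_id`).  CSV uses RFC-4180 quoting; JSON-lines has one object per
#' line.  Duplicate (`author_id`, `message_id`) rows are dropped with a
#' warning so re-ingesting the same export is idempotent.
#'
#' @param path file path.
#' @param format `"csv"` or `"jsonl"` (default: guessed from the extension).
#' @return data.frame with columns `author_id`, `text` and, when present,
#'   `message_id`, in file order.
#' @export
readMessages <- function(path, format = c("auto", "csv", "jsonl")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    if (format == "auto")
        format <- if (grepl("\\.jsonl$|\\.ndjson$", path)) "jsonl" else "csv"
    if (format == "csv") {
        # base read.csv for full RFC-4180 quote unescaping
        df <- utils::read.csv(path, colClasses = "character",
                              encoding = "UTF-8", check.names = FALSE)
        need <- c("author_id", "text")
        miss <- setdiff(need, names(df))
        if (length(miss))
            stop("messages file lacks column(s): ", paste(miss, collapse = ", "))
    } else {
        lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
        lines <- lines[nzchar(lines)]
        recs <- vector("list", length(lines))
        for (i in seq_along(lines)) {
            rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                            error = function(e)
                                stop("malformed JSON at row ", i, ": ",
                                     conditionMessage(e)))
            if (is.null(rec$author_id) || is.null(rec$text))
                stop("row ", i, " lacks author_id or text")
            recs[[i]] <- data.frame(
                author_id = as.character(rec$author_id),
                text = as.character(rec$text),
                message_id = if (!is.null(rec$message_id))
                    as.character(rec$message_id) else NA_character_,
                stringsAsFactors = FALSE)
        }
        df <- do.call(rbind, recs)
        if (is.null(df)) df <- data.frame(author_id = character(),
                                          text = character())
        if (all(is.na(df$message_id))) df$message_id <- NULL
    }
    if (any(!nzchar(df$author_id) | is.na(df$author_id))) {
        bad <- which(!nzchar(df$author_id) | is.na(df$author_id))[1]
        stop("empty author_id at row ", bad)
    }
    if (anyNA(df$text)) {
        bad <- which(is.na(df$text))[1]
        stop("missing text at row ", bad)
    }
    if ("message_id" %in% names(df)) {
        dup <- duplicated(df[c("author_id", "message_id")]) &
            !is.na(df$message_id)
        if (any(dup)) {
            warning("dropping ", sum(dup),
                    " duplicate (author_id, message_id) row(s)")
            df <- df[!dup, , drop = FALSE]
            rownames(df) <- NULL
        }
    }
    df
}

#' Write a message corpus
#'
#' @param messages data.frame with `author_id`, `text` (and optionally
#'   `message_id`).
#' @param path destination file.
#' @param format `"csv"` or `"jsonl"`.
#' @export
writeMessages <- function(messages, path, format = c("csv", "jsonl")) {
    format <- match.arg(format)
    if (format == "csv") {
        data.table::fwrite(messages, path, quote = TRUE)
    } else {
        con <- file(path, open = "w", encoding = "UTF-8")
        on.exit(close(con))
        for (i in seq_len(nrow(messages)))
            writeLines(jsonlite::toJSON(as.list(messages[i, , drop = FALSE]),
                                        auto_unbox = TRUE), con)
    }
    invisible(path)
}

#' Read an outcomes table
#'
#' One row per author; the header names the outcomes.  Blank cells become
#' missing values.  By convention gender is coded 0 (male) to 1 (female) and
#' age is in years.
#'
#' @param path CSV file with an `author_id` column and numeric outcome
#'   columns.
#' @param covariates character vector of column names to designate as
#'   covariates (must be present in the header); stored in the
#'   `"covariates"` attribute of the result.
#' @return data.frame with `author_id` plus numeric outcome columns.
#' @export
readOutcomes <- function(path, covariates = character()) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- data.table::fread(path, data.table = FALSE, encoding = "UTF-8")
    if (!"author_id" %in% names(df))
        stop("outcomes file lacks an author_id column")
    df$author_id <- as.character(df$author_id)
    if (anyDuplicated(df$author_id))
        stop("duplicate author_id: ",
             df$author_id[duplicated(df$author_id)][1])
    bad <- setdiff(covariates, names(df))
    if (length(bad))
        stop("covariate(s) not in header: ", paste(bad, collapse = ", "))
    for (cn in setdiff(names(df), "author_id")) {
        v <- df[[cn]]
        if (is.character(v)) {
            v[!nzchar(trimws(v))] <- NA
            num <- suppressWarnings(as.numeric(v))
            if (any(is.na(num) & !is.na(v)))
                stop("non-numeric value in outcome ", sQuote(cn), ": ",
                     sQuote(v[which(is.na(num) & !is.na(v))[1]]))
            df[[cn]] <- num
        } else df[[cn]] <- as.numeric(v)
    }
    attr(df, "covariates") <- covariates
    df
}

#' Aggregate a message corpus per author
#'
#' Tokenizes every message and pools n-gram counts per author (the unit of
#' analysis is the person, not the message).  N-grams are extracted within
#' messages only, so no phrase ever spans a message boundary; `n_words`
#' counts unigram tokens.
#'
#' @param messages data.frame from [readMessages()].
#' @param nMax maximum n-gram order (default 3).
#' @param extraEmoticons passed to [tokenize()].
#' @return an [AuthorCorpus-class] object.
#' @export
aggregateAuthors <- function(messages, nMax = 3L, extraEmoticons = NULL) {
    stopifnot(nMax >= 1)
    nMax <- as.integer(nMax)
    toks <- tokenize(messages$text, extraEmoticons)
    lens <- lengths(toks)
    authors <- data.table::data.table(author_id = messages$author_id,
                                      len = lens)
    astats <- authors[, list(n_messages = .N, n_words = sum(len)),
                      by = "author_id"]
    keep <- lens > 0L
    if (any(keep)) {
        tokDT <- data.table::data.table(
            author_id = rep(messages$author_id[keep], lens[keep]),
            msg = rep(which(keep), lens[keep]),
            token = unlist(toks[keep], use.names = FALSE))
        pieces <- vector("list", nMax)
        for (n in seq_len(nMax)) {
            if (n == 1L) {
                g <- tokDT[, list(author_id, msg, feature = token)]
            } else {
                # shift within message: an n-gram exists when the n tokens
                # share a message
                tk <- tokDT
                feat <- tk$token
                ok <- rep(TRUE, nrow(tk))
                for (j in seq_len(n - 1L)) {
                    nxt <- c(tk$token[-seq_len(j)], rep(NA, j))
                    nxtmsg <- c(tk$msg[-seq_len(j)], rep(NA, j))
                    ok <- ok & !is.na(nxtmsg) & nxtmsg == tk$msg
                    feat <- paste(feat, nxt, sep = "_")
                }
                if (!any(ok)) next
                g <- data.table::data.table(author_id = tk$author_id[ok],
                                            msg = tk$msg[ok],
                                            feature = feat[ok])
            }
            g <- g[, list(count = .N), by = c("author_id", "feature")]
            g$order <- n
            pieces[[n]] <- g
        }
        counts <- data.table::rbindlist(pieces[!vapply(pieces, is.null, TRUE)])
        data.table::setcolorder(counts,
                                c("author_id", "feature", "order", "count"))
    } else {
        counts <- data.table::data.table(author_id = character(),
                                         feature = character(),
                                         order = integer(),
                                         count = integer())
    }
    new("AuthorCorpus", counts = data.table::setDF(counts),
        authors = data.table::setDF(astats), nMax = nMax)
}

#' Author inclusion filter
#'
#' Keeps authors who wrote at least `minWords` words, are younger than
#' `maxAge` (strict: an author aged exactly `maxAge` is excluded), and have
#' every required outcome present.  Defaults follow the usual social-media
#' study criteria: at least 1,000 words and age below 65.
#'
#' @param records data.frame holding at least `author_id` and `n_words`
#'   (e.g. [authorStats()] merged with outcomes).
#' @param minWords minimum total word count (inclusive).
#' @param maxAge exclusive upper age bound; ignored when `NULL` or when the
#'   records have no `age` column.
#' @param requiredOutcomes outcome columns that must be non-missing.
#' @param ageColumn name of the age column.
#' @return the kept subset of `records` (same columns, original order).
#' @export
filterAuthors <- function(records, minWords = 1000, maxAge = 65,
                          requiredOutcomes = character(),
                          ageColumn = "age") {
    stopifnot(minWords >= 0)
    keep <- records$n_words >= minWords
    if (!is.null(maxAge) && ageColumn %in% names(records)) {
        age <- records[[ageColumn]]
        keep <- keep & !is.na(age) & age < maxAge
    }
    for (oc in requiredOutcomes) {
        if (!oc %in% names(records))
            stop("required outcome not in records: ", oc)
        keep <- keep & !is.na(records[[oc]])
    }
    records[keep, , drop = FALSE]
}

#' Subset an AuthorCorpus to a set of authors
#'
#' @param corpus an [AuthorCorpus-class].
#' @param ids author ids to keep.
#' @return the reduced corpus.
#' @export
subsetAuthors <- function(corpus, ids) {
    new("AuthorCorpus",
        counts = corpus@counts[corpus@counts$author_id %in% ids, ,
                               drop = FALSE],
        authors = corpus@authors[corpus@authors$author_id %in% ids, ,
                                 drop = FALSE],
        nMax = corpus@nMax)
}
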