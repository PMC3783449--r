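#' Train/test author split
#'
#' Seeded random partition of authors: `round(testFraction * n)` authors
#' form the held-out test set (default 25%), the rest train.
#'
#' @param ids author ids.
#' @param testFraction held-out fraction (default 0.25).
#' @param seed RNG seed.
#' @return list with `train` and `test` id vectors.
#' @export
splitAuthors <- function(ids, testFraction = 0.25, seed = 1L) {
    n <- length(ids)
    stopifnot(n >= 8)
    set.seed(as.integer(seed))
    shuffled <- sample(ids)
    nTest <- round(testFraction * n)
    list(test = shuffled[seq_len(nTest)],
         train = shuffled[-seq_len(nTest)])
}

#' PCA dimension reduction fitted on training authors only
#'
#' Principal components are estimated from the training matrix alone
#' (centered, not whitened) and both matrices are projected; the number of
#' components is half the number of training users, capped at the number
#' of features (and at the rank limit n_train - 1).
#'
#' @param train,test numeric matrices (authors x features, columns
#'   aligned).
#' @param nComponents override for the component count.
#' @return list `train`, `test` (projected matrices), `rotation`,
#'   `center`, `nComponents`.
#' @export
reducePCA <- function(train, test, nComponents = NULL) {
    stopifnot(ncol(train) == ncol(test))
    if (is.null(nComponents))
        nComponents <- floor(nrow(train) / 2)
    nComponents <- as.integer(min(nComponents, ncol(train),
                                  nrow(train) - 1L))
    pc <- stats::prcomp(train, center = TRUE, scale. = FALSE,
                        rank. = nComponents)
    k <- min(nComponents, ncol(pc$rotation))
    rot <- pc$rotation[, seq_len(k), drop = FALSE]
    list(train = pc$x[, seq_len(k), drop = FALSE],
         test = scale(test, center = pc$center, scale = FALSE) %*% rot,
         rotation = rot, center = pc$center, nComponents = k)
}

# hold out 10% of the training authors as a validation set, score each
# hyperparameter there, refit the winner on the full training set
.validationSplit <- function(n, seed) {
    set.seed(as.integer(seed))
    idx <- sample(n)
    nVal <- max(1L, round(0.1 * n))
    list(val = idx[seq_len(nVal)], fit = idx[-seq_len(nVal)])
}

#' Linear SVM classifier with validated regularization
#'
#' Linear support vector machine for a binary outcome; the cost parameter
#' is chosen by fitting on 90% of the training set and scoring accuracy on
#' the held-out 10%, then refitting the winner on the full training set.
#'
#' @param X training matrix (authors x features).
#' @param y binary labels (coerced to factor).
#' @param grid candidate cost values (default 7 log-spaced values).
#' @param seed RNG seed for the validation split.
#' @return list `model` (an [e1071::svm] fit), `cost`, `grid`,
#'   `task = "classification"`.
#' @export
fitClassifier <- function(X, y, grid = 10^seq(-3, 3, length.out = 7),
                          seed = 1L) {
    y <- factor(y)
    if (nlevels(y) < 2) stop("training labels contain a single class")
    sp <- .validationSplit(nrow(X), seed)
    if (length(unique(y[sp$fit])) < 2 || length(unique(y[sp$val])) < 1)
        sp <- list(fit = seq_len(nrow(X)), val = seq_len(nrow(X)))
    acc <- vapply(grid, function(cost) {
        m <- e1071::svm(X[sp$fit, , drop = FALSE], y[sp$fit],
                        kernel = "linear", cost = cost, scale = FALSE)
        mean(stats::predict(m, X[sp$val, , drop = FALSE]) == y[sp$val])
    }, numeric(1))
    best <- grid[which.max(acc)]
    model <- e1071::svm(X, y, kernel = "linear", cost = best,
                        scale = FALSE)
    list(model = model, cost = best, grid = grid,
         task = "classification")
}

# closed-form ridge: center X and y on training means, solve
# (X'X + lambda I) b = X'y
.ridgeFit <- function(X, y, lambda) {
    xm <- colMeans(X); ym <- mean(y)
    Xc <- scale(X, center = xm, scale = FALSE)
    A <- crossprod(Xc)
    diag(A) <- diag(A) + lambda
    b <- solve(A, crossprod(Xc, y - ym))
    list(coef = b, xm = xm, ym = ym)
}

.ridgePredict <- function(fit, X) {
    drop(scale(X, center = fit$xm, scale = FALSE) %*% fit$coef) + fit$ym
}

#' Ridge regressor with validated regularization
#'
#' Ridge regression for continuous outcomes, with the penalty chosen by
#' the same 10%-of-training validation protocol as the classifier
#' (scored by validation mean squared error).
#'
#' @param X training matrix.
#' @param y continuous outcome (must have positive variance).
#' @param grid candidate penalties (default 7 log-spaced values).
#' @param seed RNG seed for the validation split.
#' @return list `fit`, `lambda`, `grid`, `task = "regression"`.
#' @export
fitRegressor <- function(X, y, grid = 10^seq(-3, 3, length.out = 7),
                         seed = 1L) {
    if (stats::sd(y) == 0) stop("outcome has zero variance")
    sp <- .validationSplit(nrow(X), seed)
    mse <- vapply(grid, function(lam) {
        f <- .ridgeFit(X[sp$fit, , drop = FALSE], y[sp$fit], lam)
        mean(((.ridgePredict(f, X[sp$val, , drop = FALSE])) - y[sp$val])^2)
    }, numeric(1))
    best <- grid[which.min(mse)]
    list(fit = .ridgeFit(X, y, best), lambda = best, grid = grid,
         task = "regression")
}

#' Out-of-sample evaluation
#'
#' Classification: the fraction of test authors predicted correctly.
#' Regression: `R = sqrt(max(0, 1 - SSE/SST))`, the square root of the
#' out-of-sample coefficient of determination (negative R-squared is
#' clipped to zero before the root).
#'
#' @param model result of [fitClassifier()] or [fitRegressor()].
#' @param X test matrix.
#' @param y test outcome.
#' @return list `metric` (`"accuracy"` or `"R"`), `value`, and
#'   `perAuthor` (correctness flags or squared errors, for paired tests).
#' @export
evaluateModel <- function(model, X, y) {
    stopifnot(nrow(X) > 0)
    if (model$task == "classification") {
        pred <- stats::predict(model$model, X)
        correct <- as.character(pred) == as.character(y)
        list(metric = "accuracy", value = mean(correct),
             perAuthor = as.numeric(correct))
    } else {
        pred <- .ridgePredict(model$fit, X)
        sst <- sum((y - mean(y))^2)
        if (sst == 0) stop("test outcome has zero variance (SST = 0)")
        err <- (y - pred)^2
        r2 <- 1 - sum(err) / sst
        list(metric = "R", value = sqrt(max(0, r2)), perAuthor = err)
    }
}

# one-sided paired bootstrap over test authors: p that the candidate's
# advantage over baseline is explained by resampling noise
.pairedBootstrapP <- function(candidate, baseline, task, nBoot, seed) {
    stopifnot(length(candidate) == length(baseline))
    set.seed(as.integer(seed))
    n <- length(candidate)
    wins <- 0L
    for (b in seq_len(nBoot)) {
        idx <- sample.int(n, n, replace = TRUE)
        if (task == "classification")
            delta <- mean(candidate[idx]) - mean(baseline[idx])
        else  # lower squared error is better
            delta <- mean(baseline[idx]) - mean(candidate[idx])
        if (delta <= 0) wins <- wins + 1L
    }
    (wins + 1) / (nBoot + 1)
}

#' Compare feature sets in out-of-sample prediction
#'
#' Reproduces the open- versus closed-vocabulary evaluation protocol: one
#' identical author split for every feature set; per set, features are
#' computed from training-set statistics only, reduced by PCA to half the
#' number of training users, fed to a linear SVM (binary outcome) or ridge
#' regression (continuous), with regularization validated on 10% of the
#' training set; the test set scores accuracy or R.  Improvement over the
#' designated baseline is tested by a paired bootstrap over test authors.
#'
#' @param builders named list of feature-set builders; each is
#'   `function(trainIds, testIds)` returning `list(train = , test = )`
#'   numeric matrices (authors x features, rows in the given id order).
#'   Union sets concatenate builder outputs column-wise before PCA — see
#'   [unionBuilder()].
#' @param outcomes outcomes data.frame (needs `author_id`).
#' @param outcome outcome column name.
#' @param ids authors to use (default: all in `outcomes`).
#' @param task `"classification"` or `"regression"` (default: guessed —
#'   classification iff the outcome takes exactly two values).
#' @param baseline name of the baseline builder (default: first).
#' @param testFraction,seed split parameters.
#' @param grid regularization grid.
#' @param nBoot paired-bootstrap resamples (default 2000).
#' @return data.frame, one row per feature set: `feature_set`, `metric`,
#'   `value`, `n_train`, `n_test`, `hyperparameter`,
#'   `improvement_p` (vs baseline; `NA` for the baseline itself).
#' @export
compareFeatureSets <- function(builders, outcomes, outcome, ids = NULL,
                               task = NULL, baseline = NULL,
                               testFraction = 0.25, seed = 1L,
                               grid = 10^seq(-3, 3, length.out = 7),
                               nBoot = 2000L) {
    stopifnot(length(builders) >= 1, !is.null(names(builders)))
    if (is.null(ids)) ids <- outcomes$author_id
    y <- outcomes[[outcome]][match(ids, outcomes$author_id)]
    keep <- is.finite(y)
    ids <- ids[keep]; y <- y[keep]
    if (is.null(task))
        task <- if (length(unique(y)) == 2) "classification"
                else "regression"
    if (is.null(baseline)) baseline <- names(builders)[1]
    stopifnot(baseline %in% names(builders))
    sp <- splitAuthors(ids, testFraction, seed)
    yTr <- y[match(sp$train, ids)]
    yTe <- y[match(sp$test, ids)]
    rows <- list(); perAuthor <- list()
    for (nm in names(builders)) {
        mats <- builders[[nm]](sp$train, sp$test)
        red <- reducePCA(mats$train, mats$test)
        model <- if (task == "classification")
            fitClassifier(red$train, yTr, grid, seed)
        else fitRegressor(red$train, yTr, grid, seed)
        ev <- evaluateModel(model, red$test, yTe)
        perAuthor[[nm]] <- ev$perAuthor
        rows[[nm]] <- data.frame(
            feature_set = nm, metric = ev$metric, value = ev$value,
            n_train = length(sp$train), n_test = length(sp$test),
            hyperparameter = if (task == "classification") model$cost
                             else model$lambda)
    }
    out <- do.call(rbind, rows)
    out$improvement_p <- NA_real_
    for (nm in setdiff(names(builders), baseline))
        out$improvement_p[out$feature_set == nm] <-
            .pairedBootstrapP(perAuthor[[nm]], perAuthor[[baseline]],
                              task, nBoot, seed)
    rownames(out) <- NULL
    attr(out, "baseline") <- baseline
    attr(out, "seed") <- seed
    out
}

#' Feature-set builders for the predictive evaluation
#'
#' Builders close over the raw corpus and compute every corpus-level
#' statistic (collocation probabilities, usage thresholds, the topic
#' model, lexicon normalization) from the training authors only, then
#' apply the frozen feature set to the test authors — test authors never
#' influence feature selection.
#'
#' @param corpus an [AuthorCorpus-class] covering all authors.
#' @param pmiThresholdCoef,minAuthorFraction open-vocabulary settings.
#' @return `function(trainIds, testIds) -> list(train, test)`.
#' @export
ngramFeatureBuilder <- function(corpus, pmiThresholdCoef = 2,
                                minAuthorFraction = 0.01) {
    force(corpus)
    function(trainIds, testIds) {
        sub <- subsetAuthors(corpus, trainIds)
        feats <- collocationFilter(sub, function(n) pmiThresholdCoef * n)
        feats <- minUsageFilter(sub, feats, minAuthorFraction)
        full <- buildFeatureMatrix(subsetAuthors(corpus,
                                                 c(trainIds, testIds)),
                                   feats)
        v <- featureValues(full)
        list(train = t(v[, trainIds, drop = FALSE]),
             test = t(v[, testIds, drop = FALSE]))
    }
}

#' @rdname ngramFeatureBuilder
#' @param lexicon a [Lexicon-class].
#' @export
lexiconFeatureBuilder <- function(corpus, lexicon) {
    force(corpus); force(lexicon)
    function(trainIds, testIds) {
        m <- categoryRelativeFrequency(
            subsetAuthors(corpus, c(trainIds, testIds)), lexicon)
        list(train = m[trainIds, , drop = FALSE],
             test = m[testIds, , drop = FALSE])
    }
}

#' @rdname ngramFeatureBuilder
#' @param messages optional raw message data.frame; when given, the topic
#'   model is fitted on the training authors' individual messages (the
#'   document unit for status updates), otherwise on pooled per-author
#'   pseudo-documents.
#' @param K,alpha,beta,nIter,seed LDA settings; the topic model is fitted
#'   on training authors only.
#' @export
topicFeatureBuilder <- function(corpus, messages = NULL, K = 50L,
                                alpha = 0.3 / K, beta = 0.01,
                                nIter = 200L, seed = 1L) {
    force(corpus)
    msgDocs <- NULL
    if (!is.null(messages)) {
        msgDocs <- tokenize(messages$text)
        names(msgDocs) <- NULL
        msgAuthors <- messages$author_id
    }
    function(trainIds, testIds) {
        docs <- if (is.null(msgDocs))
            .corpusUnigramDocs(subsetAuthors(corpus, trainIds))
        else msgDocs[msgAuthors %in% trainIds]
        model <- fitLDA(docs, K = K, alpha = alpha, beta = beta,
                        nIter = nIter, seed = seed)
        u <- topicUsage(model, subsetAuthors(corpus,
                                             c(trainIds, testIds)))
        list(train = u[trainIds, , drop = FALSE],
             test = u[testIds, , drop = FALSE])
    }
}

# author-level pseudo-documents from pooled unigram counts (used when the
# original per-message corpus is not needed for topic fitting)
.corpusUnigramDocs <- function(corpus) {
    uni <- ngramCounts(corpus, order = 1L)
    split(rep(uni$feature, uni$count), rep(uni$author_id, uni$count))
}

#' @rdname ngramFeatureBuilder
#' @param ... builders to concatenate column-wise (deduplicating repeated
#'   columns).
#' @export
unionBuilder <- function(...) {
    parts <- list(...)
    function(trainIds, testIds) {
        mats <- lapply(parts, function(b) b(trainIds, testIds))
        tr <- do.call(cbind, lapply(mats, `[[`, "train"))
        te <- do.call(cbind, lapply(mats, `[[`, "test"))
        dup <- duplicated(t(tr))
        list(train = tr[, !dup, drop = FALSE],
             test = te[, !dup, drop = FALSE])
    }
}
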