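#' Single feature-outcome association
#'
#' Ordinary least squares of the outcome on one language feature plus
#' covariates (all regressors and the outcome z-scored, so the feature
#' coefficient is a standardized beta; with no covariates it equals the
#' Pearson correlation).  The p-value is the two-tailed t-test of the
#' feature coefficient with `n - n_covariates - 2` degrees of freedom.
#' Authors with missing outcome or covariates are dropped pairwise.
#'
#' @param feature numeric vector of feature values per author.
#' @param outcome numeric outcome per author.
#' @param covariates optional numeric matrix / data.frame of covariates.
#' @return list with `beta_std`, `p`, `n`, `t`.
#' @export
fitFeatureAssociation <- function(feature, outcome, covariates = NULL) {
    if (!is.null(covariates)) covariates <- as.matrix(covariates)
    ok <- is.finite(feature) & is.finite(outcome)
    if (!is.null(covariates)) ok <- ok & apply(is.finite(covariates), 1, all)
    x <- feature[ok]; y <- outcome[ok]
    cv <- if (!is.null(covariates)) covariates[ok, , drop = FALSE]
    n <- length(x)
    p <- 1L + if (is.null(cv)) 0L else ncol(cv)
    if (n < p + 2L) stop("too few complete observations (n=", n, ")")
    if (stats::sd(x) == 0) stop("zero-variance feature")
    if (stats::sd(y) == 0) stop("zero-variance outcome")
    zx <- as.vector(scale(x)); zy <- as.vector(scale(y))
    if (is.null(cv)) {
        fit <- stats::lm(zy ~ zx)
    } else {
        zc <- scale(cv)
        zc[, apply(cv, 2, stats::sd) == 0] <- 0  # constant covariate: no-op
        fit <- stats::lm(zy ~ zx + zc)
    }
    sm <- summary(fit)$coefficients
    list(beta_std = unname(sm["zx", "Estimate"]),
         t = unname(sm["zx", "t value"]),
         p = unname(sm["zx", "Pr(>|t|)"]),
         n = n)
}

#' Bonferroni per-test threshold
#'
#' The family-wise threshold `family_alpha / m`: with 20,000 features at a
#' two-tailed family alpha of 0.001, a passing p-value must be below 5e-8.
#'
#' @param familyAlpha family-wise alpha.
#' @param m number of tests (>= 1).
#' @return per-test significance threshold.
#' @export
bonferroniThreshold <- function(familyAlpha, m) {
    stopifnot(familyAlpha > 0, familyAlpha < 1)
    if (m < 1) stop("m must be >= 1")
    familyAlpha / m
}

#' Benjamini-Hochberg rejections
#'
#' Standard step-up procedure: sort p-values ascending, find the largest i
#' with `p_(i) <= i * q / m`, reject all ranks up to i.
#'
#' @param pValues numeric p-values in `[0, 1]`.
#' @param q target false-discovery rate.
#' @return logical rejection flags aligned with `pValues`.
#' @export
benjaminiHochberg <- function(pValues, q) {
    stopifnot(all(pValues >= 0 & pValues <= 1))
    stats::p.adjust(pValues, method = "BH") <= q
}

# Vectorized mass-univariate OLS via residualization: each feature's
# standardized coefficient and t-test are identical to the full per-feature
# regression with intercept + covariates (Frisch-Waugh-Lovell), computed
# for all features at once.
.massUnivariate <- function(X, y, C = NULL) {
    # X: n x m features (columns), y: n outcome, C: n x k covariates
    n <- length(y)
    k <- if (is.null(C)) 0L else ncol(C)
    Z <- cbind(rep(1, n), C)
    qrz <- qr(Z)
    ry <- qr.resid(qrz, y)
    RX <- qr.resid(qrz, X)
    df <- n - k - 2L
    sdx <- sqrt(colSums(RX^2))
    sdy <- sqrt(sum(ry^2))
    zero <- sdx < .Machine$double.eps^0.5 * sqrt(n)
    r <- colSums(RX * ry) / (sdx * sdy)
    r[zero] <- NA
    tval <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
    pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
    # standardized beta of the full regression = partial r * sd ratio of
    # residualized variables over sd ratio of raw standardized variables
    beta <- colSums(RX * ry) / colSums(RX^2) *
        apply(X, 2, stats::sd) / stats::sd(y)
    beta[zero] <- NA
    list(beta_std = beta, t = tval, p = pval, df = df, zero = zero)
}

#' Differential language analysis
#'
#' Runs one independent covariate-adjusted OLS per feature (never a joint
#' model: a feature collinear with others still gets its own coefficient),
#' applies the multiple-testing correction over the whole feature family
#' for this outcome, and ranks results by `|beta_std|`.
#'
#' @param fm a [FeatureMatrix-class] (features x authors).
#' @param outcomes data.frame from [readOutcomes()] (needs `author_id`).
#' @param outcome name of the outcome column to analyze.
#' @param covariates character vector of covariate column names (e.g.
#'   `c("gender", "age")`).
#' @param correction `"bonferroni"` or `"benjamini_hochberg"`.
#' @param familyAlpha family-wise alpha / FDR level (default 0.001,
#'   two-tailed).
#' @return an [AssociationResults-class], ranked significant-first by
#'   `|beta_std|` descending.
#' @export
runDLA <- function(fm, outcomes, outcome,
                   covariates = character(),
                   correction = c("bonferroni", "benjamini_hochberg"),
                   familyAlpha = 0.001) {
    correction <- match.arg(correction)
    if (!nrow(fm)) stop("empty feature set")
    if (!outcome %in% names(outcomes))
        stop("unknown outcome: ", sQuote(outcome))
    miss <- setdiff(covariates, names(outcomes))
    if (length(miss))
        stop("unknown covariate(s): ", paste(miss, collapse = ", "))
    ids <- intersect(authorIds(fm), outcomes$author_id)
    om <- outcomes[match(ids, outcomes$author_id), , drop = FALSE]
    y <- om[[outcome]]
    C <- if (length(covariates))
        as.matrix(om[covariates]) else NULL
    ok <- is.finite(y)
    if (!is.null(C)) ok <- ok & apply(is.finite(C), 1, all)
    ids <- ids[ok]; y <- y[ok]
    if (!is.null(C)) C <- C[ok, , drop = FALSE]
    if (stats::sd(y) == 0) stop("zero-variance outcome")
    X <- t(featureValues(fm)[, ids, drop = FALSE])
    res <- .massUnivariate(X, y, C)
    rd <- SummarizedExperiment::rowData(fm)
    cf <- if ("corpus_frequency" %in% names(rd))
        rd$corpus_frequency else rep(NA_integer_, nrow(fm))
    keep <- !res$zero
    p <- res$p[keep]
    thr <- NA_real_
    if (correction == "bonferroni") {
        thr <- bonferroniThreshold(familyAlpha, sum(keep))
        sig <- p < thr
    } else sig <- benjaminiHochberg(p, familyAlpha)
    df <- S4Vectors::DataFrame(
        feature = rownames(fm)[keep],
        outcome = outcome,
        beta_std = unname(res$beta_std[keep]),
        p = unname(p),
        n = length(y),
        corpus_frequency = cf[keep],
        significant = unname(sig))
    ord <- order(-df$significant, -abs(df$beta_std))
    df <- df[ord, ]
    rownames(df) <- NULL
    S4Vectors::metadata(df) <- list(
        outcome = outcome, covariates = covariates,
        correction = correction, family_alpha = familyAlpha,
        m_tests = sum(keep), threshold = thr,
        skipped = rownames(fm)[!keep])
    new("AssociationResults", df)
}

#' Write DLA results
#'
#' One CSV row per (feature, outcome) pair plus a JSON manifest recording
#' the correction spec, covariates and feature-set hash.
#'
#' @param results an [AssociationResults-class].
#' @param path destination CSV.
#' @export
writeAssociationResults <- function(results, path) {
    df <- as.data.frame(results)
    data.table::fwrite(df, path, quote = TRUE)
    md <- S4Vectors::metadata(results)
    md$feature_set_hash <- featureSetHash(df$feature)
    md$skipped <- as.list(md$skipped)
    jsonlite::write_json(md, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
    invisible(path)
}

#' Hash of a feature set (run-manifest provenance)
#' @param features character vector.
#' @return hex string.
#' @export
featureSetHash <- function(features) {
    f <- tempfile(); on.exit(unlink(f))
    writeLines(sort(features), f)
    unname(tools::md5sum(f))
}

#' Power analysis by subsampling
#'
#' Reruns the analysis on reduced random author samples: for each sample
#' size, authors are drawn without replacement, the minimum-usage feature
#' set is recomputed on the subsample, the mass-univariate analysis is run,
#' and the number of significant features is counted; counts are averaged
#' over `reps` draws.
#'
#' @param corpus an [AuthorCorpus-class].
#' @param outcomes outcomes data.frame.
#' @param outcome outcome name.
#' @param sampleSizes integer vector of author sample sizes.
#' @param reps replicates per size.
#' @param covariates covariate names.
#' @param correction,familyAlpha passed to [runDLA()].
#' @param pmiThresholdCoef,minAuthorFraction feature-extraction settings.
#' @param seed RNG seed.
#' @return data.frame `size`, `mean_significant`.
#' @export
powerAnalysis <- function(corpus, outcomes, outcome, sampleSizes,
                          reps = 10L, covariates = character(),
                          correction = "benjamini_hochberg",
                          familyAlpha = 0.001,
                          pmiThresholdCoef = 2, minAuthorFraction = 0.01,
                          seed = 1L) {
    ids <- authorIds(corpus)
    stopifnot(all(sampleSizes <= length(ids)))
    set.seed(as.integer(seed))
    out <- lapply(sampleSizes, function(sz) {
        cnt <- vapply(seq_len(reps), function(r) {
            sub <- subsetAuthors(corpus, sample(ids, sz))
            fm <- tryCatch(
                ngramFeatureMatrix(sub, pmiThresholdCoef, minAuthorFraction),
                error = function(e) NULL)
            if (is.null(fm)) return(0)
            res <- runDLA(fm, outcomes, outcome, covariates,
                          correction, familyAlpha)
            sum(res$significant)
        }, numeric(1))
        data.frame(size = sz, mean_significant = mean(cnt))
    })
    do.call(rbind, out)
}
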