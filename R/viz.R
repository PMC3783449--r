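#' Prune redundant phrases for display
#'
#' Scans results in descending correlation-strength order and keeps a
#' phrase only if it adds information over what is already shown, using
#' corpus frequency as a proxy for informative value: a single word is
#' always kept; a phrase sharing a word with any previously retained
#' feature is kept iff every one of its non-shared words is strictly less
#' frequent (more informative) than the shared word(s); phrases sharing
#' nothing are kept.  E.g. with 'day' retained, 'beautiful_day' survives
#' ('beautiful' is rarer than 'day') while 'the_day' is dropped ('the' is
#' more frequent).  Ties in frequency drop the candidate, keeping clouds
#' sparse.
#'
#' @param results an [AssociationResults-class] or data.frame with
#'   `feature` ordered by descending `|beta_std|`.
#' @param wordFrequencies named numeric vector of corpus word frequencies.
#' @return the retained subset, original order preserved.
#' @export
prunePhrases <- function(results, wordFrequencies) {
    feats <- results$feature
    kept <- character(0)
    keptWords <- list()
    keepRow <- logical(length(feats))
    for (i in seq_along(feats)) {
        words <- strsplit(feats[i], "_", fixed = TRUE)[[1]]
        if (length(words) == 1L) {
            keepRow[i] <- TRUE
        } else {
            shared <- unique(words[words %in% unlist(keptWords)])
            if (!length(shared)) {
                keepRow[i] <- TRUE
            } else {
                nonShared <- setdiff(words, shared)
                fShared <- min(wordFrequencies[shared], na.rm = TRUE)
                fNew <- wordFrequencies[nonShared]
                keepRow[i] <- length(nonShared) > 0 &&
                    all(!is.na(fNew)) && all(fNew < fShared)
            }
        }
        if (keepRow[i]) keptWords <- c(keptWords, list(words))
    }
    results[keepRow, , drop = FALSE]
}

#' Prune overlapping topics for display
#'
#' A lower-ranking topic is not displayed if more than 25% of its top 15
#' words also appear in the top 15 words of any retained higher-ranking
#' topic: 4 or more shared words out of 15 trigger the drop, 3 do not.
#'
#' @param results results ordered by descending `|beta_std|`, with a
#'   `feature` column naming topics.
#' @param topWordSets named list (by topic feature name) of top-15 word
#'   vectors.
#' @param maxOverlap overlap fraction above which a topic is dropped
#'   (default 0.25, strict).
#' @return the retained subset, order preserved.
#' @export
pruneTopics <- function(results, topWordSets, maxOverlap = 0.25) {
    feats <- results$feature
    keepRow <- logical(length(feats))
    keptSets <- list()
    for (i in seq_along(feats)) {
        w <- topWordSets[[feats[i]]]
        drop <- FALSE
        for (ks in keptSets) {
            if (length(intersect(w, ks)) > maxOverlap * length(w)) {
                drop <- TRUE; break
            }
        }
        keepRow[i] <- !drop
        if (!drop) keptSets <- c(keptSets, list(w))
    }
    results[keepRow, , drop = FALSE]
}

## ---- cloud geometry ----

# deterministic spiral layout; returns placements with no overlaps
.layoutCloud <- function(labels, sizes, width = 800, height = 500,
                         seed = 1L) {
    set.seed(as.integer(seed))
    n <- length(labels)
    # crude text metrics: width ~ 0.6 * fontsize * nchar
    w <- 0.62 * sizes * nchar(labels) + 4
    h <- sizes * 1.15 + 4
    boxes <- matrix(NA_real_, n, 4)  # x0, y0, x1, y1 (centered boxes)
    cx <- width / 2; cy <- height / 2
    ord <- order(-sizes)
    for (i in ord) {
        theta <- stats::runif(1, 0, 2 * pi)
        placed <- FALSE
        step <- 0
        while (!placed && step < 4000) {
            r <- 2.2 * sqrt(step)
            a <- theta + 0.35 * step
            x <- cx + r * cos(a)
            y <- cy + r * sin(a)
            box <- c(x - w[i] / 2, y - h[i] / 2, x + w[i] / 2, y + h[i] / 2)
            clash <- FALSE
            for (j in seq_len(n)) {
                if (is.na(boxes[j, 1])) next
                if (box[1] < boxes[j, 3] && box[3] > boxes[j, 1] &&
                    box[2] < boxes[j, 4] && box[4] > boxes[j, 2]) {
                    clash <- TRUE; break
                }
            }
            if (!clash && box[1] >= 0 && box[2] >= 0 &&
                box[3] <= width && box[4] <= height) {
                boxes[i, ] <- box
                placed <- TRUE
            }
            step <- step + 1
        }
        if (!placed)  # give up gracefully: park outside spiral center
            boxes[i, ] <- c(cx - w[i] / 2, cy - h[i] / 2,
                            cx + w[i] / 2, cy + h[i] / 2)
    }
    data.frame(label = labels, size = sizes,
               x = (boxes[, 1] + boxes[, 3]) / 2,
               y = (boxes[, 2] + boxes[, 4]) / 2)
}

# dark-to-light blue ramp over frequency quartiles (darker = more frequent)
.freqColors <- c("#9ecae1", "#6baed6", "#3182bd", "#08519c")

.freqBin <- function(freq) {
    if (length(freq) == 1L) return(4L)
    q <- stats::quantile(freq, c(0.25, 0.5, 0.75), na.rm = TRUE,
                         names = FALSE)
    findInterval(freq, q) + 1L
}

.cloudEntries <- function(results, minSize = 12, maxSize = 48,
                          maxItems = 50) {
    if (!all(results$significant))
        stop("only significant features may be rendered")
    res <- utils::head(results, maxItems)
    b <- abs(res$beta_std)
    rng <- range(b)
    sw <- if (diff(rng) < 1e-12) rep(1, length(b))
          else (b - rng[1]) / diff(rng)
    data.frame(feature = res$feature,
               beta_std = res$beta_std,
               p = res$p,
               frequency = res$corpus_frequency,
               size_weight = pmax(sw, 1e-3),
               size = minSize + sw * (maxSize - minSize),
               color_bin = .freqBin(res$corpus_frequency),
               polarity = sign(res$beta_std))
}

.svgCloud <- function(layout, colors, width, height, title = NULL) {
    esc <- function(s) {
        s <- gsub("&", "&amp;", s, fixed = TRUE)
        s <- gsub("<", "&lt;", s, fixed = TRUE)
        gsub(">", "&gt;", s, fixed = TRUE)
    }
    out <- c(sprintf(
        '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
        round(width), round(height)),
        '<rect width="100%" height="100%" fill="white"/>')
    if (!is.null(title))
        out <- c(out, sprintf(
            '<text x="%d" y="18" font-size="14" font-family="sans-serif" fill="#444">%s</text>',
            8, esc(title)))
    out <- c(out, sprintf(
        '<text x="%.1f" y="%.1f" text-anchor="middle" dominant-baseline="middle" font-family="sans-serif" font-size="%.1f" fill="%s">%s</text>',
        layout$x, layout$y, layout$size, colors, esc(layout$label)))
    c(out, "</svg>")
}

#' Render a correlation-scaled word cloud
#'
#' Word size is affine in `|beta_std|` between `minSize` and `maxSize`
#' (larger = more strongly correlated); color encodes corpus frequency
#' quartile on a dark-to-light ramp (darker = more frequent).  Placement is
#' a seeded Archimedean spiral, so the same seed gives a byte-identical
#' SVG.  A JSON sidecar lists every rendered feature with its statistics
#' (figure provenance).
#'
#' @param results significant, pruned [AssociationResults-class] rows,
#'   ranked by `|beta_std|`.
#' @param path output file.
#' @param fmt `"svg"` or `"png"`.
#' @param maxItems maximum features rendered.
#' @param minSize,maxSize font-size range (px).
#' @param width,height canvas (px).
#' @param seed layout seed.
#' @param title optional caption.
#' @return the output path, invisibly.
#' @export
renderCloud <- function(results, path, fmt = c("svg", "png"),
                        maxItems = 50, minSize = 12, maxSize = 48,
                        width = 800, height = 500, seed = 1L,
                        title = NULL) {
    fmt <- match.arg(fmt)
    if (!nrow(results))
        stop("no significant features to render; consider a larger family ",
             "alpha or a less strict correction")
    entries <- .cloudEntries(results, minSize, maxSize, maxItems)
    layout <- .layoutCloud(entries$feature, entries$size, width, height,
                           seed)
    colors <- .freqColors[entries$color_bin]
    if (fmt == "svg") {
        writeLines(.svgCloud(layout, colors, width, height, title), path)
    } else {
        grDevices::png(path, width = width, height = height)
        on.exit(grDevices::dev.off())
        graphics::par(mar = c(0, 0, 0, 0))
        graphics::plot.new()
        graphics::plot.window(c(0, width), c(height, 0))
        graphics::text(layout$x, layout$y, layout$label,
                       cex = layout$size / 15, col = colors)
        if (!is.null(title))
            graphics::text(8, 18, title, adj = 0, col = "#444444")
    }
    jsonlite::write_json(entries, paste0(path, ".json"), digits = NA)
    invisible(path)
}

#' Render a word cloud with perimeter topic clouds
#'
#' Central words-and-phrases cloud with up to the 6 most distinguishing
#' topics placed on the perimeter; within a topic cloud, word size is
#' proportional to the word's prevalence p(w|t) in the topic.
#'
#' @param wordResults pruned significant word/phrase results.
#' @param topicResults pruned significant topic results (`feature` column
#'   naming topics like `topic_3`).
#' @param model the [TopicModel-class] behind the topic features.
#' @param path output SVG file.
#' @param seed layout seed.
#' @param nTop words per topic cloud (default 15).
#' @return output path, invisibly.
#' @export
renderTopicPanel <- function(wordResults, topicResults, model, path,
                             seed = 1L, nTop = 15L) {
    panelW <- 1400; panelH <- 900
    centerW <- 700; centerH <- 500
    if (nrow(topicResults) == 0)
        warning("no topics retained; rendering central cloud only")
    topicResults <- utils::head(topicResults, 6L)
    entries <- .cloudEntries(wordResults)
    cl <- .layoutCloud(entries$feature, entries$size, centerW, centerH,
                       seed)
    cl$x <- cl$x + (panelW - centerW) / 2
    cl$y <- cl$y + (panelH - centerH) / 2
    cols <- .freqColors[entries$color_bin]
    slots <- list(c(20, 20), c(panelW - 360, 20), c(20, panelH - 300),
                  c(panelW - 360, panelH - 300), c(530, 10),
                  c(530, panelH - 290))
    svgBody <- character(0)
    provenance <- list(words = entries)
    for (i in seq_len(nrow(topicResults))) {
        tid <- as.integer(sub("topic_", "", topicResults$feature[i]))
        tw <- topWords(model, tid, nTop)
        pw <- topicWordProbs(model)[tid, tw]
        sizes <- 10 + 26 * pw / max(pw)
        tl <- .layoutCloud(tw, sizes, 340, 280, seed + i)
        tl$x <- tl$x + slots[[i]][1]
        tl$y <- tl$y + slots[[i]][2]
        svgBody <- c(svgBody, sprintf(
            '<rect x="%d" y="%d" width="340" height="280" fill="none" stroke="#cccccc"/>',
            slots[[i]][1], slots[[i]][2]),
            sprintf(
            '<text x="%.1f" y="%.1f" text-anchor="middle" dominant-baseline="middle" font-family="sans-serif" font-size="%.1f" fill="#555555">%s</text>',
            tl$x, tl$y, tl$size, tl$label))
        provenance[[topicResults$feature[i]]] <-
            data.frame(word = tw, p_word_given_topic = as.numeric(pw))
    }
    svg <- c(sprintf(
        '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
        panelW, panelH),
        '<rect width="100%" height="100%" fill="white"/>',
        sprintf(
        '<text x="%.1f" y="%.1f" text-anchor="middle" dominant-baseline="middle" font-family="sans-serif" font-size="%.1f" fill="%s">%s</text>',
        cl$x, cl$y, cl$size, cols, cl$label),
        svgBody, "</svg>")
    writeLines(svg, path)
    jsonlite::write_json(provenance, paste0(path, ".json"), digits = NA)
    invisible(path)
}

#' Covariate-adjusted LOESS trend of a feature over a continuous outcome
#'
#' Fits first-order (locally linear) LOESS of the z-scored feature on age,
#' including gender as a covariate in each local regression, with tricube
#' weights over age-distance; the curve is evaluated on the grid at a
#' neutral gender value (the sample mean), i.e. the trend is controlled
#' for gender.
#'
#' @param feature numeric feature values per author.
#' @param age continuous outcome (x-axis).
#' @param gender covariate (0/1 coded; any numeric works).
#' @param grid evaluation points (default: 100 equally spaced points over
#'   the observed age range); must lie inside the observed range (no
#'   extrapolation).
#' @param span LOESS span in (0, 1] (default 0.75).
#' @return data.frame `grid`, `fitted` (standardized-frequency scale),
#'   with attributes `span` and `gender_value`.
#' @export
loessTrend <- function(feature, age, gender, grid = NULL, span = 0.75) {
    ok <- is.finite(feature) & is.finite(age) & is.finite(gender)
    feature <- feature[ok]; age <- age[ok]; gender <- gender[ok]
    n <- length(feature)
    if (n < 20) stop("need at least 20 observations")
    stopifnot(span > 0, span <= 1)
    if (stats::sd(feature) == 0) stop("zero-variance feature")
    z <- as.vector(scale(feature))
    if (is.null(grid))
        grid <- seq(min(age), max(age), length.out = 100)
    if (any(grid < min(age)) || any(grid > max(age)))
        stop("grid outside the observed age range (no extrapolation)")
    gbar <- mean(gender)
    q <- max(2L, ceiling(span * n))
    hasG <- stats::sd(gender) > 0
    fitted <- vapply(grid, function(x0) {
        d <- abs(age - x0)
        h <- sort(d, partial = q)[q]
        w <- (1 - pmin(d / max(h, 1e-12), 1)^3)^3
        use <- w > 0
        X <- if (hasG) cbind(1, age[use], gender[use])
             else cbind(1, age[use])
        fit <- stats::lm.wfit(X, z[use], w[use])
        cf <- fit$coefficients
        cf[is.na(cf)] <- 0
        if (hasG) sum(cf * c(1, x0, gbar)) else sum(cf * c(1, x0))
    }, numeric(1))
    out <- data.frame(grid = grid, fitted = fitted)
    attr(out, "span") <- span
    attr(out, "gender_value") <- gbar
    out
}

#' Plot LOESS trends to a PNG
#'
#' @param trends named list of [loessTrend()] outputs.
#' @param path output PNG.
#' @param xlab,ylab axis labels.
#' @return path, invisibly.
#' @export
plotTrends <- function(trends, path, xlab = "age",
                       ylab = "standardized frequency") {
    grDevices::png(path, width = 700, height = 480)
    on.exit(grDevices::dev.off())
    xs <- range(unlist(lapply(trends, `[[`, "grid")))
    ys <- range(unlist(lapply(trends, `[[`, "fitted")))
    graphics::plot(NA, xlim = xs, ylim = ys, xlab = xlab, ylab = ylab)
    cols <- grDevices::hcl.colors(max(length(trends), 2), "Dark 3")
    for (i in seq_along(trends))
        graphics::lines(trends[[i]]$grid, trends[[i]]$fitted,
                        col = cols[i], lwd = 2)
    if (!is.null(names(trends)))
        graphics::legend("topright", legend = names(trends),
                         col = cols[seq_along(trends)], lwd = 2, bty = "n")
    invisible(path)
}
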