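#' Prior specifications for the two inference models
#'
#' `demographicPrior()`: the two-epoch neutral model.  `N_anc` and `N_cur`
#' are loguniform on \[10, 50,000\] diploids and the change time `tau` is
#' loguniform on \[10, N_cur\] generations -- the upper bound of `tau` is
#' tied to the drawn `N_cur`.  `sweepPrior()`: the equilibrium
#' recurrent-sweep model with `gamma` loguniform on \[0.1, 10,000\] and
#' `f_pos` loguniform on \[1e-5, 1e-2\]; the inferred quantities are `gamma`
#' and the realized beneficial substitution rate `d_a` (recorded per table
#' row), from which lambda is derived.
#'
#' @param NancRange,NcurRange,tauMin bounds of the demographic priors.
#' @param gammaRange,fposRange bounds of the sweep priors.
#' @return a prior specification list.
#' @export
demographicPrior <- function(NancRange = c(10, 50000),
                             NcurRange = c(10, 50000), tauMin = 10) {
    list(model = "demographic",
         params = list(
             Nanc = list(dist = "loguniform", min = NancRange[1],
                         max = NancRange[2]),
             Ncur = list(dist = "loguniform", min = NcurRange[1],
                         max = NcurRange[2]),
             tau = list(dist = "loguniform", min = tauMin, max = "Ncur")),
         infer = c("Nanc", "Ncur", "tau"),
         inferExtras = character(0))
}

#' @rdname demographicPrior
#' @export
sweepPrior <- function(gammaRange = c(0.1, 10000),
                       fposRange = c(1e-5, 1e-2)) {
    list(model = "sweep",
         params = list(
             gamma = list(dist = "loguniform", min = gammaRange[1],
                          max = gammaRange[2]),
             fpos = list(dist = "loguniform", min = fposRange[1],
                         max = fposRange[2])),
         infer = "gamma",
         inferExtras = "dA")
}

#' Draw parameters from a prior specification
#'
#' Loguniform draws via R's RNG; linked bounds (e.g. `tau <= N_cur`) are
#' resolved row-wise against the already drawn columns.
#'
#' @param prior a prior specification (see [demographicPrior]).
#' @param n number of draws.
#' @return data.frame of parameter draws, one column per parameter.
#' @export
drawPrior <- function(prior, n) {
    out <- list()
    for (p in names(prior$params)) {
        spec <- prior$params[[p]]
        lo <- spec$min
        hi <- if (is.character(spec$max)) out[[spec$max]] else spec$max
        if (spec$dist != "loguniform") stop("unsupported prior: ", spec$dist)
        out[[p]] <- exp(runif(n, log(lo), rep(log(hi), length.out = n)))
    }
    as.data.frame(out)
}

#' Build an ABC reference table
#'
#' Draws `draws` parameter combinations from the prior, runs the supplied
#' simulator `replicates` times per draw and aggregates each draw's
#' replicate statistics into one feature vector.  The simulator is a
#' function `function(params, seed, replicates)` returning
#' `list(stats = <named numeric>, extras = <named list or NULL>)`; a
#' simulator error skips that row with a warning (never silent imputation).
#'
#' @param prior a prior specification.
#' @param simulator simulator callback, see Details.
#' @param draws number of parameter draws.
#' @param replicates simulations aggregated per draw.
#' @param seed master seed (R RNG).
#' @return a [ReferenceTable].
#' @export
buildReferenceTable <- function(prior, simulator, draws, replicates = 1L,
                                seed = NULL) {
    if (draws < 1) stop("draws must be >= 1")
    if (!is.null(seed)) set.seed(seed)
    params <- drawPrior(prior, draws)
    rowSeeds <- sample.int(.Machine$integer.max, draws)
    statRows <- vector("list", draws)
    extraRows <- vector("list", draws)
    ok <- logical(draws)
    for (i in seq_len(draws)) {
        res <- tryCatch(
            simulator(as.list(params[i, , drop = FALSE]), seed = rowSeeds[i],
                      replicates = replicates),
            error = function(e) e)
        if (inherits(res, "error")) {
            warning("simulator failed for draw ", i, ": ",
                    conditionMessage(res), " (row skipped)")
            next
        }
        statRows[[i]] <- res$stats
        extraRows[[i]] <- if (is.null(res$extras)) list() else res$extras
        ok[i] <- TRUE
    }
    if (!any(ok)) stop("all simulator calls failed")
    stats <- do.call(rbind, statRows[ok])
    extras <- if (length(extraRows[[which(ok)[1L]]]))
        as.data.frame(do.call(rbind, lapply(extraRows[ok], as.data.frame)))
    else data.frame(row.names = seq_len(sum(ok)))
    new("ReferenceTable", params = params[ok, , drop = FALSE], stats = stats,
        extras = extras, model = prior$model,
        replicates = as.integer(replicates), prior = prior)
}

# transforms for the inferred targets of a table
targetSpec <- function(table) {
    prior <- table@prior
    specs <- list()
    for (p in prior$infer) {
        sp <- prior$params[[p]]
        hi <- if (is.character(sp$max)) NA_real_ else log(sp$max)
        specs[[p]] <- list(values = log(table@params[[p]]),
                           lower = log(sp$min), upper = hi,
                           linked = if (is.character(sp$max)) sp$max else NA,
                           bwd = exp)
    }
    for (e in prior$inferExtras) {
        v <- table@extras[[e]]
        pos <- v[v > 0]
        d0 <- if (length(pos)) min(pos) / 2 else 1e-8
        specs[[e]] <- local({
            off <- d0
            list(values = log(v + off), lower = log(off), upper = NA_real_,
                 linked = NA, bwd = function(z) pmax(0, exp(z) - off))
        })
    }
    specs
}

#' ABC rejection step
#'
#' Features are standardized by their median absolute deviation across the
#' table (columns with zero spread are dropped with a warning); the
#' `ceiling(tolerance * rows)` rows closest to the observed vector in
#' Euclidean distance are accepted.
#'
#' @param table a [ReferenceTable].
#' @param observed observed feature vector (same names/order as the table).
#' @param tolerance accepted fraction in (0, 1].
#' @return an `abcRejection` list: accepted row indices, their distances,
#'   the feature scaling, and the standardized design used downstream.
#' @export
abcReject <- function(table, observed, tolerance = 0.05) {
    if (tolerance <= 0 || tolerance > 1)
        stop("tolerance must be in (0, 1]")
    stats <- table@stats
    if (is.null(colnames(stats))) stop("reference table lacks feature names")
    observed <- observed[colnames(stats)]
    if (anyNA(observed)) stop("observed vector is missing features")
    scale <- apply(stats, 2, mad)
    fallback <- apply(stats, 2, stats::sd)
    scale[scale == 0] <- fallback[scale == 0]
    keep <- scale > 0
    if (!all(keep))
        warning("dropping zero-variance feature(s): ",
                paste(colnames(stats)[!keep], collapse = ", "))
    if (!any(keep)) stop("no informative features left")
    X <- sweep(stats[, keep, drop = FALSE], 2, scale[keep], "/")
    xObs <- observed[keep] / scale[keep]
    d <- sqrt(rowSums(sweep(X, 2, xObs, "-")^2))
    nAcc <- ceiling(tolerance * nrow(stats))
    acc <- order(d)[seq_len(nAcc)]
    structure(list(table = table, accepted = acc, distances = d[acc],
                   X = X[acc, , drop = FALSE], xObs = xObs,
                   features = colnames(stats)[keep]),
              class = "abcRejection")
}

epanechnikovWeights <- function(d) {
    dmax <- max(d)
    if (dmax == 0) return(rep(1, length(d)))
    w <- 1 - (d / dmax)^2
    if (all(w <= 0) || sum(w) == 0) rep(1, length(d)) else w
}

#' Regression adjustment of accepted ABC draws
#'
#' `"loclinear"`: weighted linear regression of each (transformed) target on
#' the standardized statistics with Epanechnikov kernel weights on distance,
#' correcting each accepted draw by its residual projected to the observed
#' point.  `"neuralnet"`: the same correction with a single-hidden-layer
#' feed-forward regression (median of several seeded restarts) replacing the
#' linear fit, to accommodate nonlinearity between statistics and
#' parameters.  `"rejection"` skips adjustment.  Targets are regressed on
#' log scale (priors are loguniform) and back-transformed; adjusted draws
#' are clamped to the prior support, with linked bounds (tau <= N_cur)
#' enforced row-wise.  A singular local-linear design falls back to pure
#' rejection with a warning.  For sweep tables the adjusted `d_a` is
#' converted to lambda via the Methods formula with the neutral expectation
#' `mu T` recorded in the prior.
#'
#' @param rejection result of [abcReject].
#' @param method adjustment method.
#' @param hiddenUnits hidden-layer width for `"neuralnet"`.
#' @param restarts seeded restarts for `"neuralnet"`.
#' @return a [Posterior].
#' @export
regressionAdjust <- function(rejection, method = c("loclinear", "neuralnet",
                                                   "rejection"),
                             hiddenUnits = 5L, restarts = 3L) {
    method <- match.arg(method)
    table <- rejection$table
    acc <- rejection$accepted
    specs <- targetSpec(table)
    w <- epanechnikovWeights(rejection$distances)
    X <- rejection$X
    xObs <- rejection$xObs
    nAcc <- length(acc)

    adjT <- matrix(NA_real_, nAcc, length(specs),
                   dimnames = list(NULL, names(specs)))
    usedMethod <- method
    if (method == "rejection") {
        for (p in names(specs)) adjT[, p] <- specs[[p]]$values[acc]
        w <- rep(1, nAcc)
    } else if (method == "loclinear") {
        if (nAcc <= ncol(X) + 1L) {
            warning("accepted count <= feature count: falling back to rejection")
            usedMethod <- "rejection"
            for (p in names(specs)) adjT[, p] <- specs[[p]]$values[acc]
        } else {
            D <- cbind(1, X)
            for (p in names(specs)) {
                y <- specs[[p]]$values[acc]
                fit <- lm.wfit(D, y, w)
                beta <- fit$coefficients
                beta[is.na(beta)] <- 0
                pred <- drop(D %*% beta)
                predObs <- drop(c(1, xObs) %*% beta)
                adjT[, p] <- y - pred + predObs
            }
        }
    } else { # neuralnet
        for (p in names(specs)) {
            y <- specs[[p]]$values[acc]
            yr <- range(y)
            span <- if (diff(yr) > 0) diff(yr) else 1
            y01 <- (y - yr[1]) / span
            preds <- matrix(NA_real_, nAcc + 1L, restarts)
            for (r in seq_len(restarts)) {
                fit <- nnet::nnet(x = X, y = y01, weights = w,
                                  size = hiddenUnits, linout = TRUE,
                                  decay = 1e-2, maxit = 500, trace = FALSE)
                preds[, r] <- predict(fit, rbind(X, xObs))
            }
            pred <- apply(preds, 1, median) * span + yr[1]
            adjT[, p] <- y - pred[seq_len(nAcc)] + pred[nAcc + 1L]
        }
    }

    # clamp to (transformed) prior support, linked bounds last
    for (p in names(specs)) {
        sp <- specs[[p]]
        adjT[, p] <- pmax(adjT[, p], sp$lower)
        if (!is.na(sp$upper)) adjT[, p] <- pmin(adjT[, p], sp$upper)
    }
    for (p in names(specs)) {
        sp <- specs[[p]]
        if (!is.na(sp$linked) && sp$linked %in% colnames(adjT))
            adjT[, p] <- pmin(adjT[, p], adjT[, sp$linked])
    }

    adjusted <- adjT
    for (p in names(specs)) adjusted[, p] <- specs[[p]]$bwd(adjT[, p])

    draws <- as.matrix(table@params[acc, table@prior$infer, drop = FALSE])
    if (length(table@prior$inferExtras))
        draws <- cbind(draws, as.matrix(
            table@extras[acc, table@prior$inferExtras, drop = FALSE]))

    extras <- data.frame(row.names = seq_len(nAcc))
    if ("dA" %in% colnames(adjusted) && !is.null(table@prior$muT))
        extras$lambda <- adjusted[, "dA"] /
            (adjusted[, "dA"] + table@prior$muT)

    wn <- w / sum(w)
    new("Posterior", draws = draws, adjusted = adjusted, weights = wn,
        distances = rejection$distances, method = usedMethod,
        prior = table@prior, extras = extras)
}

#' One-call ABC fit
#'
#' Rejection at `tolerance` followed by [regressionAdjust].
#'
#' @inheritParams abcReject
#' @inheritParams regressionAdjust
#' @param ... passed to [regressionAdjust].
#' @return a [Posterior].
#' @export
abcFit <- function(table, observed, tolerance = 0.05,
                   method = "loclinear", ...) {
    regressionAdjust(abcReject(table, observed, tolerance), method = method,
                     ...)
}

weightedQuantile <- function(x, w, probs) {
    o <- order(x)
    cw <- cumsum(w[o]) / sum(w)
    vapply(probs, function(p) x[o][which(cw >= p)[1L]], numeric(1))
}

#' @rdname pointEstimate
#' @export
setMethod("pointEstimate", "Posterior", function(object, ...) {
    M <- object@adjusted
    if (ncol(object@extras)) M <- cbind(M, as.matrix(object@extras))
    apply(M, 2, weightedQuantile, w = object@weights, probs = 0.5)
})

#' @rdname credibleInterval
#' @export
setMethod("credibleInterval", "Posterior", function(object, level = 0.95, ...) {
    M <- object@adjusted
    if (ncol(object@extras)) M <- cbind(M, as.matrix(object@extras))
    a <- (1 - level) / 2
    t(apply(M, 2, weightedQuantile, w = object@weights,
            probs = c(a, 1 - a))) |>
        `colnames<-`(c("lower", "upper"))
})

#' Cross-validate the ABC tolerance
#'
#' Leave-one-out cross-validation over `folds` randomly chosen table rows:
#' each is treated as pseudo-observed, the remaining rows are fitted at each
#' candidate tolerance, and the prediction error is the squared error of the
#' point estimate against the truth on the transformed (log) scale, summed
#' over inferred targets and averaged over folds.  The
#' smallest-error tolerance wins; ties go to the larger tolerance.
#' Deterministic for a fixed `seed`.
#'
#' @param table a [ReferenceTable].
#' @param tolerances candidate tolerances (default `c(0.01, 0.05, 0.1, 0.2)`).
#' @param folds number of held-out rows.
#' @param method adjustment method used during validation.
#' @param seed integer seed.
#' @return list with `tolerance` (chosen), `errors` (named per-candidate
#'   mean errors) and `folds`.
#' @export
crossValidateTolerance <- function(table, tolerances = c(0.01, 0.05, 0.1, 0.2),
                                   folds = 100L, method = "loclinear",
                                   seed = NULL) {
    nr <- nrow(table@params)
    if (folds > nr) stop("folds exceeds table rows")
    if (length(tolerances) == 1L)
        return(list(tolerance = tolerances, errors = setNames(NA_real_,
            tolerances), folds = 0L))
    if (!is.null(seed)) set.seed(seed)
    rows <- sample.int(nr, folds)
    specs <- targetSpec(table)
    err <- matrix(NA_real_, folds, length(tolerances))
    for (f in seq_len(folds)) {
        i <- rows[f]
        sub <- new("ReferenceTable",
                   params = table@params[-i, , drop = FALSE],
                   stats = table@stats[-i, , drop = FALSE],
                   extras = table@extras[-i, , drop = FALSE],
                   model = table@model, replicates = table@replicates,
                   prior = table@prior)
        obs <- table@stats[i, ]
        for (k in seq_along(tolerances)) {
            post <- tryCatch(
                suppressWarnings(abcFit(sub, obs, tolerance = tolerances[k],
                                        method = method)),
                error = function(e) NULL)
            if (is.null(post)) next
            pe <- pointEstimate(post)
            e2 <- 0
            for (p in names(specs)) {
                truth <- specs[[p]]$values[i]  # transformed scale
                est <- if (p %in% table@prior$inferExtras)
                    log(pe[p] + exp(specs[[p]]$lower))  # same offset transform
                else log(pmax(pe[p], 1e-300))
                e2 <- e2 + (est - truth)^2
            }
            err[f, k] <- e2
        }
    }
    mean_err <- colMeans(err, na.rm = TRUE)
    names(mean_err) <- as.character(tolerances)
    best <- which(mean_err == min(mean_err, na.rm = TRUE))
    best <- best[which.max(tolerances[best])]
    list(tolerance = tolerances[best], errors = mean_err, folds = folds)
}
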