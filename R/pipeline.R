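#' Desk-scale experiment settings
#'
#' Problem sizes for the figure-level experiments.  The defaults are
#' desk-scale: true-scenario data are generated at an additional rescale of
#' `rescaleQ` (N = 500 from the standard N = 5,000), the demographic
#' reference table uses a few hundred coalescent draws, and the sweep
#' reference table -- which requires forward simulation per row -- runs at a
#' stronger additional rescale `sweepRescaleQ`.  All sizes are recorded in
#' the experiment output.
#'
#' @param rescaleQ additional rescale applied to the true scenario.
#' @param trueReps replicates of the true-scenario simulation.
#' @param demTableDraws,demTableReps demographic reference-table size.
#' @param sweepTableDraws,sweepTableReps,sweepRescaleQ sweep reference-table
#'   size and scale.
#' @param tolerance ABC acceptance fraction (or `"cv"` to cross-validate).
#' @param cvTolerances candidate grid when `tolerance = "cv"`.
#' @param method regression-adjustment method.
#' @param windowWidth summary-statistic window in bp.
#' @param ldMaxPairs LD pair cap per window.
#' @param ppcReps posterior-predictive replicates.
#' @param pooling feature aggregation policy (see [aggregateStats]).  The
#'   pipeline default is `"flat"` (pool windows across replicates): it makes
#'   the feature definition invariant to the replicate count, so reference
#'   tables and observed data built with different replicate numbers remain
#'   directly comparable.
#' @return a list of settings.
#' @export
experimentControl <- function(rescaleQ = 10, trueReps = 5,
                              demTableDraws = 400L, demTableReps = 2L,
                              sweepTableDraws = 120L, sweepTableReps = 1L,
                              sweepRescaleQ = 50, tolerance = 0.1,
                              cvTolerances = c(0.05, 0.1, 0.2),
                              method = "loclinear", windowWidth = 2000L,
                              ldMaxPairs = 500L, ppcReps = 20L,
                              pooling = "flat") {
    list(rescaleQ = rescaleQ, trueReps = trueReps,
         demTableDraws = demTableDraws, demTableReps = demTableReps,
         sweepTableDraws = sweepTableDraws, sweepTableReps = sweepTableReps,
         sweepRescaleQ = sweepRescaleQ, tolerance = tolerance,
         cvTolerances = cvTolerances, method = method,
         windowWidth = windowWidth, ldMaxPairs = ldMaxPairs,
         ppcReps = ppcReps, pooling = pooling)
}

# apply the observation operator of a scenario and compute windowed stats
observeAndSummarize <- function(sample, config, control,
                                ascertain = TRUE) {
    s <- maskExons(sample, config@layout)
    if (ascertain && config@singletonDrop > 0)
        s <- ascertainSingletons(s, config@singletonDrop)
    windowStats(s, width = control$windowWidth,
                maxPairs = control$ldMaxPairs)
}

#' Reference-table builders for the two misspecified inference models
#'
#' `buildDemographicTable` draws (N_anc, N_cur, tau) from the loguniform
#' priors and simulates the strictly neutral coalescent with the scenario's
#' mean mutation and recombination rates (assumed constant); exons are
#' masked before statistics, as for the observed data.
#' `buildSweepTable` draws (gamma, f_pos) and runs the constant-size
#' neutral-plus-beneficial forward model at an additional rescale
#' `control$sweepRescaleQ`, recording each row's realized beneficial
#' substitution rate `d_a` and lambda.
#'
#' @param config the (data-scale) [ScenarioConfig] being analyzed.
#' @param control an [experimentControl] list.
#' @param seed integer seed.
#' @return a [ReferenceTable].
#' @export
buildDemographicTable <- function(config, control = experimentControl(),
                                  seed = NULL) {
    mu <- weightedMeanRate(config@rates)
    recMean <- mean(config@rates@rec)
    layout <- config@layout
    n <- config@sampleSize
    # prior bounds live in units of the simulated population: at an
    # additional rescale Q the same theta range maps to bounds / Q
    Q <- max(1, control$rescaleQ)
    prior <- demographicPrior(NancRange = pmax(2, c(10, 50000) / Q),
                              NcurRange = pmax(2, c(10, 50000) / Q),
                              tauMin = max(2, 10 / Q))
    sim <- function(params, seed, replicates) {
        dem <- demographyTwoEpoch(params$Nanc, params$Ncur, params$tau)
        sims <- simulateNeutral(dem, layout, n, mu, recMean,
                                replicates = replicates, seed = seed)
        if (replicates == 1L) sims <- list(sims)
        ws <- lapply(sims, function(s)
            windowStats(maskExons(s, layout), width = control$windowWidth,
                        maxPairs = control$ldMaxPairs))
        list(stats = aggregateStats(ws, pooling = control$pooling),
             extras = NULL)
    }
    buildReferenceTable(prior, sim, draws = control$demTableDraws,
                        replicates = control$demTableReps, seed = seed)
}

#' @rdname buildDemographicTable
#' @export
buildSweepTable <- function(config, control = experimentControl(),
                            seed = NULL) {
    base <- scenarioPreset("eqm_pos", sampleSize = config@sampleSize)
    base <- rescaleScenario(base, control$sweepRescaleQ)
    totalGens <- totalGenerations(base)
    muT <- weightedMeanRate(base@rates) * totalGens
    layout <- base@layout
    sim <- function(params, seed, replicates) {
        dfe <- dfeConfig(deleterious = FALSE, gamma = params$gamma,
                         fpos = params$fpos,
                         Nanc = base@demography@epochs$size[1L])
        cfg <- new("ScenarioConfig", name = "sweep_table",
                   layout = layout, rates = base@rates,
                   demography = base@demography, dfe = dfe,
                   psi = 0, singletonDrop = 0,
                   sampleSize = base@sampleSize, seed = NA_integer_)
        set.seed(seed)
        repSeeds <- sample.int(.Machine$integer.max, replicates)
        ws <- vector("list", replicates)
        dA <- numeric(replicates)
        for (r in seq_len(replicates)) {
            simr <- runForward(cfg, seed = repSeeds[r])
            dA[r] <- simr@dA
            ws[[r]] <- windowStats(maskExons(simr@sample, layout),
                                   width = control$windowWidth,
                                   maxPairs = control$ldMaxPairs)
        }
        list(stats = aggregateStats(ws, pooling = control$pooling),
             extras = list(dA = mean(dA),
                           lambda = mean(dA) / (mean(dA) + muT)))
    }
    prior <- sweepPrior()
    prior$muT <- muT
    buildReferenceTable(prior, sim, draws = control$sweepTableDraws,
                        replicates = control$sweepTableReps, seed = seed)
}

#' Run one figure-level mis-inference experiment
#'
#' Generates a "true scenario" dataset, applies the observation layer
#' (exon masking, optional singleton ascertainment), computes the windowed
#' summary-statistic panel, fits the two deliberately misspecified models by
#' ABC (a strictly neutral two-epoch demographic model and an equilibrium
#' recurrent-sweep model), and runs posterior predictive checks at the
#' weighted-median point estimates.  Deterministic for a fixed `seed`.
#'
#' @param scenario a preset name (see [scenarioPreset]) or a
#'   [ScenarioConfig] at the standard scale.
#' @param seed master seed; every random stage derives its own stream
#'   from it.
#' @param control an [experimentControl] list.
#' @param models which inference models to fit.
#' @param demTable,sweepTable optional prebuilt reference tables (reused
#'   across the scenarios of a battery).
#' @param outDir optional directory; when given, observed statistics,
#'   posterior draws, check reports and the serialized scenario are written
#'   there as TSV/YAML.
#' @return list with elements `scenario` (the rescaled config), `truth`
#'   (true parameter values and realized lambda), `observed` (feature
#'   vector), `posteriors`, `checks`, `tables` and `control`.
#' @export
runExperiment <- function(scenario, seed = 1L,
                          control = experimentControl(),
                          models = c("demographic", "sweep"),
                          demTable = NULL, sweepTable = NULL,
                          outDir = NULL) {
    if (is.character(scenario)) scenario <- scenarioPreset(scenario)
    set.seed(seed)
    stageSeeds <- sample.int(.Machine$integer.max, 6L)
    cfg <- rescaleScenario(scenario, control$rescaleQ)

    # --- true-scenario data ------------------------------------------------
    needForward <- cfg@dfe@deleterious || cfg@dfe@fpos > 0 || cfg@psi > 0
    set.seed(stageSeeds[1L])
    repSeeds <- sample.int(.Machine$integer.max, control$trueReps)
    lambdaTrue <- NA_real_
    ws <- vector("list", control$trueReps)
    if (needForward) {
        lam <- numeric(control$trueReps)
        for (r in seq_len(control$trueReps)) {
            simr <- runForward(cfg, seed = repSeeds[r])
            lam[r] <- simr@lambda
            ws[[r]] <- observeAndSummarize(simr@sample, cfg, control)
        }
        lambdaTrue <- mean(lam)
    } else {
        sims <- simulateNeutral(cfg@demography, cfg@layout, cfg@sampleSize,
                                weightedMeanRate(cfg@rates),
                                mean(cfg@rates@rec),
                                replicates = control$trueReps,
                                seed = repSeeds[1L])
        ws <- lapply(sims, observeAndSummarize, config = cfg,
                     control = control)
        lambdaTrue <- 0
    }
    observed <- aggregateStats(ws, pooling = control$pooling)
    truth <- list(Ncur = cfg@demography@epochs$size[1L],
                  Nanc = cfg@demography@epochs$size[nrow(cfg@demography@epochs)],
                  lambda = lambdaTrue, psi = cfg@psi,
                  gamma = cfg@dfe@gamma, fpos = cfg@dfe@fpos)

    posteriors <- list(); checks <- list(); tables <- list()
    tol <- control$tolerance

    if ("demographic" %in% models) {
        if (is.null(demTable))
            demTable <- buildDemographicTable(cfg, control,
                                              seed = stageSeeds[2L])
        if (identical(tol, "cv"))
            tol <- crossValidateTolerance(demTable, control$cvTolerances,
                folds = min(50L, nrow(demTable@params)),
                method = control$method, seed = stageSeeds[3L])$tolerance
        set.seed(stageSeeds[3L])
        posteriors$demographic <- abcFit(demTable, observed, tolerance = tol,
                                         method = control$method)
        checks$demographic <- posteriorPredictiveCheck(
            posteriors$demographic, "demographic", cfg, control,
            reps = control$ppcReps, seed = stageSeeds[5L])
        tables$demographic <- demTable
    }
    if ("sweep" %in% models) {
        if (is.null(sweepTable))
            sweepTable <- buildSweepTable(cfg, control,
                                          seed = stageSeeds[4L])
        set.seed(stageSeeds[4L] %% 1000000L + 1L)
        posteriors$sweep <- abcFit(sweepTable, observed,
                                   tolerance = if (identical(tol, "cv"))
                                       0.1 else tol,
                                   method = control$method)
        checks$sweep <- posteriorPredictiveCheck(
            posteriors$sweep, "sweep", cfg, control,
            reps = control$ppcReps, seed = stageSeeds[6L])
        tables$sweep <- sweepTable
    }

    result <- list(scenario = cfg, truth = truth, observed = observed,
                   posteriors = posteriors, checks = checks, tables = tables,
                   control = control, seed = seed)
    if (!is.null(outDir)) writeExperiment(result, outDir)
    result
}

#' Posterior predictive check
#'
#' Simulates `reps` datasets at the weighted-median point estimate of the
#' posterior under the inference model's own generative process (neutral
#' two-epoch coalescent, or equilibrium sweep forward model with `f_pos`
#' recovered from the inferred lambda via [fposFromLambda]), applies the
#' same masking and windowing, and compares the observed panel means to the
#' 0.025/0.975 quantiles of their predictive distribution.  With `reps = 2`
#' the interval degenerates to the min/max of the two values.
#'
#' @param posterior a [Posterior].
#' @param model "demographic" or "sweep".
#' @param config the data-scale [ScenarioConfig] (for layout, rates, n).
#' @param control an [experimentControl] list.
#' @param reps predictive replicates (>= 2).
#' @param seed integer seed.
#' @param observed optional observed feature vector to flag against.
#' @return a check-report data.frame: statistic, observed,
#'   predictive mean, lower, upper, inside.
#' @export
posteriorPredictiveCheck <- function(posterior, model, config,
                                     control = experimentControl(),
                                     reps = 20L, seed = NULL,
                                     observed = NULL) {
    if (reps < 2) stop("reps must be >= 2")
    if (!is.null(seed)) set.seed(seed)
    pe <- pointEstimate(posterior)
    repSeeds <- sample.int(.Machine$integer.max, reps)
    panel <- statPanel()
    repMeans <- matrix(NA_real_, reps, length(panel),
                       dimnames = list(NULL, panel))
    if (model == "demographic") {
        dem <- demographyTwoEpoch(pe["Nanc"], pe["Ncur"],
                                  max(1, round(pe["tau"])))
        n <- min(config@sampleSize, 2 * round(pe["Ncur"]))
        sims <- simulateNeutral(dem, config@layout, n,
                                weightedMeanRate(config@rates),
                                mean(config@rates@rec),
                                replicates = reps, seed = repSeeds[1L])
        for (r in seq_len(reps)) {
            w <- observeAndSummarize(sims[[r]], config, control,
                                     ascertain = FALSE)
            repMeans[r, ] <- colMeans(as.matrix(w[, panelColumn]),
                                      na.rm = TRUE)
        }
    } else if (model == "sweep") {
        base <- scenarioPreset("eqm_pos", sampleSize = config@sampleSize)
        base <- rescaleScenario(base, control$sweepRescaleQ)
        Ns <- base@demography@epochs$size[1L]
        lambdaHat <- if ("lambda" %in% names(pe)) pe["lambda"] else 0
        fposHat <- if (lambdaHat > 0)
            fposFromLambda(lambdaHat, sbar = pe["gamma"] / Ns, N = Ns)
        else 0
        dfe <- dfeConfig(deleterious = FALSE, gamma = pe["gamma"],
                         fpos = min(1, fposHat), Nanc = Ns)
        cfg <- new("ScenarioConfig", name = "ppc_sweep",
                   layout = base@layout, rates = base@rates,
                   demography = base@demography, dfe = dfe, psi = 0,
                   singletonDrop = 0, sampleSize = base@sampleSize,
                   seed = NA_integer_)
        for (r in seq_len(reps)) {
            simr <- runForward(cfg, seed = repSeeds[r])
            w <- observeAndSummarize(simr@sample, cfg, control,
                                     ascertain = FALSE)
            repMeans[r, ] <- colMeans(as.matrix(w[, panelColumn]),
                                      na.rm = TRUE)
        }
    } else stop("unknown model: ", model)

    lo <- apply(repMeans, 2, quantile, probs = 0.025, na.rm = TRUE,
                type = 1)
    hi <- apply(repMeans, 2, quantile, probs = 0.975, na.rm = TRUE,
                type = 1)
    obs <- if (!is.null(observed)) observed[paste0("mean_", panel)]
           else rep(NA_real_, length(panel))
    data.frame(statistic = panel,
               observed = as.numeric(obs),
               predMean = colMeans(repMeans, na.rm = TRUE),
               lower = lo, upper = hi,
               inside = !is.na(obs) & obs >= lo & obs <= hi,
               row.names = NULL)
}

#' Write experiment artifacts
#'
#' Serializes an experiment result as plain-text artifacts: the scenario
#' YAML, the observed feature vector, posterior draws and weights, and the
#' check reports, all TSV.  Every directory so written is sufficient to
#' re-run the experiment (scenario + control + seed).
#'
#' @param result a [runExperiment] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeExperiment <- function(result, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    scenarioToYaml(result$scenario, file.path(dir, "scenario.yaml"))
    ctrl <- result$control
    ctrl$seed <- result$seed
    writeLines(yaml::as.yaml(ctrl), file.path(dir, "control.yaml"))
    write.table(data.frame(feature = names(result$observed),
                           value = as.numeric(result$observed)),
                file.path(dir, "observed_stats.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (m in names(result$posteriors)) {
        post <- result$posteriors[[m]]
        df <- as.data.frame(post@adjusted)
        if (ncol(post@extras)) df <- cbind(df, post@extras)
        df$weight <- post@weights
        write.table(df, file.path(dir, paste0("posterior_", m, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        write.table(result$checks[[m]],
                    file.path(dir, paste0("check_", m, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(dir)
}

#' Reproduce a figure-level scenario battery at reduced scale
#'
#' Runs the scenario set behind each conceptual figure: `fig1` (equilibrium
#' BGS, BGS + sweeps, bottleneck + BGS + sweeps), `fig2` (growth + BGS +
#' sweeps with and without singleton ascertainment), `fig3` (progeny skew
#' psi = 0.05 / 0.1), `fig4` (BGS + sweeps under equilibrium / decline /
#' growth, each with constant and heterogeneous rate maps).  Reference
#' tables are built once per battery and shared across its scenarios.  The
#' `"full"` scale uses the study-scale settings and is far beyond desk
#' runtime (a warning is emitted, not an error).
#'
#' @param which "fig1" .. "fig4".
#' @param scale "desk" or "full".
#' @param seed master seed.
#' @param control optional [experimentControl] override.
#' @param models inference models to fit.
#' @return named list of [runExperiment] results.
#' @export
reproduceFigure <- function(which = c("fig1", "fig2", "fig3", "fig4"),
                            scale = c("desk", "full"), seed = 1L,
                            control = NULL,
                            models = c("demographic", "sweep")) {
    which <- match.arg(which)
    scale <- match.arg(scale)
    if (is.null(control)) {
        control <- experimentControl()
        if (scale == "full") {
            warning("full-scale battery requested: this is a cluster-scale ",
                    "computation, not a desk run")
            control <- experimentControl(rescaleQ = 1, trueReps = 100,
                demTableDraws = 10000L, demTableReps = 100L,
                sweepTableDraws = 10000L, sweepTableReps = 100L,
                sweepRescaleQ = 1, tolerance = "cv", method = "neuralnet",
                ldMaxPairs = Inf)
        }
    }
    presets <- switch(which,
        fig1 = c("eqm_bgs", "eqm_bgs_pos", "bottleneck_bgs_pos"),
        fig2 = c("growth_bgs_pos", "growth_bgs_pos_ascert"),
        fig3 = c("eqm_psi05", "eqm_psi10"),
        fig4 = c("eqm_bgs_pos", "eqm_bgs_pos_varrates", "decline_bgs_pos",
                 "decline_bgs_pos_varrates", "growth_bgs_pos",
                 "growth_bgs_pos_varrates"))
    cfg0 <- rescaleScenario(scenarioPreset(presets[1L]), control$rescaleQ)
    set.seed(seed)
    tabSeeds <- sample.int(.Machine$integer.max, 2L)
    demTable <- if ("demographic" %in% models)
        buildDemographicTable(cfg0, control, seed = tabSeeds[1L]) else NULL
    sweepTable <- if ("sweep" %in% models)
        buildSweepTable(cfg0, control, seed = tabSeeds[2L]) else NULL
    out <- list()
    for (k in seq_along(presets))
        out[[presets[k]]] <- runExperiment(presets[k], seed = seed + k,
                                           control = control,
                                           models = models,
                                           demTable = demTable,
                                           sweepTable = sweepTable)
    out
}

#' Joint-posterior plot with the true value marked
#'
#' Scatter of two posterior dimensions with point size proportional to
#' weight and a red cross at the true value -- the publication-style view of
#' an ABC joint posterior.  Requires ggplot2.
#'
#' @param posterior a [Posterior].
#' @param params two column names of the adjusted draws (or `extras`).
#' @param truth optional named vector of true values.
#' @param log log-scale axes specification ("xy", "x", "y" or "").
#' @return a ggplot object.
#' @export
plotPosterior <- function(posterior, params = NULL, truth = NULL,
                          log = "xy") {
    if (!requireNamespace("ggplot2", quietly = TRUE))
        stop("plotPosterior requires ggplot2")
    M <- posterior@adjusted
    if (ncol(posterior@extras))
        M <- cbind(M, as.matrix(posterior@extras))
    if (is.null(params)) params <- colnames(M)[1:2]
    df <- data.frame(x = M[, params[1L]], y = M[, params[2L]],
                     w = posterior@weights)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y)) +
        ggplot2::geom_point(ggplot2::aes(size = w), alpha = 0.4,
                            show.legend = FALSE) +
        ggplot2::labs(x = params[1L], y = params[2L]) +
        ggplot2::theme_minimal()
    if (grepl("x", log)) p <- p + ggplot2::scale_x_log10()
    if (grepl("y", log)) p <- p + ggplot2::scale_y_log10()
    if (!is.null(truth))
        p <- p + ggplot2::annotate("point", x = truth[params[1L]],
                                   y = truth[params[2L]], shape = 4,
                                   colour = "red", size = 4, stroke = 1.5)
    p
}
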