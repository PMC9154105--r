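#' Demography constructors
#'
#' Epochs are measured backward from sampling: `demographyConstant(N)` is a
#' single open-ended epoch; `demographyTwoEpoch(Nanc, Ncur, tau)` switches
#' instantaneously from `Nanc` to `Ncur` `tau` generations before sampling;
#' `demographyBottleneck` inserts a reduced epoch of `duration` generations
#' beginning `start` generations ago.
#'
#' @param N,Nanc,Ncur,Nbot diploid sizes.
#' @param tau time of the size change, generations before sampling.
#' @param start backward start of the bottleneck (oldest edge).
#' @param duration bottleneck length in generations.
#' @return a [Demography].
#' @export
demographyConstant <- function(N) {
    new("Demography", epochs = data.frame(size = N, time = 0))
}

#' @rdname demographyConstant
#' @export
demographyTwoEpoch <- function(Nanc, Ncur, tau) {
    new("Demography",
        epochs = data.frame(size = c(Ncur, Nanc), time = c(0, tau)))
}

#' @rdname demographyConstant
#' @export
demographyBottleneck <- function(Nanc, Ncur, Nbot, start, duration) {
    if (duration <= 0 || duration >= start)
        stop("need 0 < duration < start")
    new("Demography",
        epochs = data.frame(size = c(Ncur, Nbot, Nanc),
                            time = c(0, start - duration, start)))
}

#' DFE constructors
#'
#' `neutralDFE()` disables selection entirely; `dfeConfig()` assembles the
#' 4-class deleterious DFE and/or the exponential beneficial tail.  Scaled
#' effects are population-scaled heterozygous coefficients (see
#' [DFEConfig-class]); the strongly deleterious class is uniform on
#' `[-delMax, -100]` with `delMax` defaulting to the scaled lethal bound
#' `N_anc` (homozygote effect -1).
#'
#' @param deleterious activate the 4-class deleterious DFE.
#' @param gamma population-scaled mean beneficial effect (2 N_anc s_het).
#' @param fpos beneficial fraction of new exonic mutations.
#' @param delWeights class weights, summing to 1.
#' @param delMax magnitude of the scaled lower bound of the strongest class.
#' @param h dominance coefficient on the homozygous effect (semidominance).
#' @param Nanc ancestral diploid size used for the lethal bound default.
#' @return a [DFEConfig].
#' @export
dfeConfig <- function(deleterious = FALSE, gamma = 0, fpos = 0,
                      delWeights = rep(0.25, 4), delMax = NULL,
                      h = 0.5, Nanc = 5000) {
    if (is.null(delMax)) delMax <- Nanc  # scaled het effect of a lethal homozygote
    bounds <- matrix(c(-1, 0, -10, -1, -100, -10, -delMax, -100),
                     nrow = 4, byrow = TRUE,
                     dimnames = list(c("neutral-ish", "weak", "moderate",
                                       "strong"), c("lower", "upper")))
    new("DFEConfig", deleterious = deleterious, delWeights = delWeights,
        delBounds = bounds, gamma = gamma, fpos = fpos, h = h)
}

#' @rdname dfeConfig
#' @export
neutralDFE <- function() dfeConfig()

#' Named scenario presets
#'
#' Returns a fully parameterized [ScenarioConfig] for the study's "true
#' scenario" battery, in rescaled units (N_anc = 5,000 diploids, mu = 9e-7,
#' r = 2e-6 per bp per generation; rescale factor 200 applied to the
#' Drosophila-like base).  Components:
#' \describe{
#'   \item{eqm_neutral}{constant size, strict neutrality.}
#'   \item{eqm_pos}{constant size, neutral + beneficial exonic mutations
#'     (gamma = 125, fpos = 2.2e-3) -- the recurrent-sweep scenario.}
#'   \item{eqm_bgs}{constant size + 4-class deleterious DFE.}
#'   \item{eqm_bgs_pos}{BGS and recurrent sweeps combined.}
#'   \item{bottleneck_bgs_pos}{as eqm_bgs_pos with a bottleneck to 1% of
#'     5,000 (50 diploids) for 100 generations starting 2,000 generations
#'     ago.}
#'   \item{growth_bgs_pos}{instantaneous expansion 5,000 -> 10,000,
#'     100 generations ago.}
#'   \item{growth_bgs_pos_ascert}{as growth_bgs_pos plus removal of a third
#'     of sample singletons.}
#'   \item{decline_bgs_pos}{instantaneous decline 5,000 -> 100,
#'     100 generations ago.}
#'   \item{eqm_psi05, eqm_psi10}{strict neutrality, constant size, progeny
#'     skew psi = 0.05 / 0.1.}
#' }
#' Appending `"_varrates"` to any name replaces the constant rate map with a
#' per-10-kb heterogeneous map (Gaussian, CV 0.5, truncated at 0; drawn with
#' R's RNG).
#'
#' @param name preset name, see Details.
#' @param sampleSize haploid sample size (default 100).
#' @return a [ScenarioConfig].
#' @export
scenarioPreset <- function(name, sampleSize = 100L) {
    varrates <- grepl("_varrates$", name)
    base <- sub("_varrates$", "", name)
    known <- c("eqm_neutral", "eqm_pos", "eqm_bgs", "eqm_bgs_pos",
               "bottleneck_bgs_pos", "growth_bgs_pos",
               "growth_bgs_pos_ascert", "decline_bgs_pos",
               "eqm_psi05", "eqm_psi10")
    if (!base %in% known)
        stop("unknown preset '", name, "'; choices: ",
             paste(known, collapse = ", "), " (optionally + '_varrates')")

    layout <- buildLayout()
    Nanc <- 5000
    dem <- switch(base,
        bottleneck_bgs_pos = demographyBottleneck(Nanc, Nanc, 0.01 * Nanc,
                                                  start = 2000, duration = 100),
        growth_bgs_pos = ,
        growth_bgs_pos_ascert = demographyTwoEpoch(Nanc, 10000, tau = 100),
        decline_bgs_pos = demographyTwoEpoch(Nanc, 100, tau = 100),
        demographyConstant(Nanc))
    dfe <- switch(base,
        eqm_neutral = , eqm_psi05 = , eqm_psi10 = neutralDFE(),
        eqm_pos = dfeConfig(deleterious = FALSE, gamma = 125, fpos = 2.2e-3,
                            Nanc = Nanc),
        eqm_bgs = dfeConfig(deleterious = TRUE, Nanc = Nanc),
        dfeConfig(deleterious = TRUE, gamma = 125, fpos = 2.2e-3, Nanc = Nanc))
    psi <- switch(base, eqm_psi05 = 0.05, eqm_psi10 = 0.1, 0)
    drop <- if (base == "growth_bgs_pos_ascert") 1 / 3 else 0
    rates <- drawRateMap(layout, meanMu = 9e-7, meanRec = 2e-6,
                         cv = if (varrates) 0.5 else 0)
    cfg <- new("ScenarioConfig", name = name, layout = layout, rates = rates,
               demography = dem, dfe = dfe, psi = psi, singletonDrop = drop,
               sampleSize = as.integer(sampleSize), seed = NA_integer_)
    validObject(cfg)
    cfg
}

#' Apply an additional rescaling to a scenario
#'
#' Divides all diploid sizes and epoch times by `Q` and multiplies the rate
#' map by `Q`, preserving theta, rho and the (already population-scaled) DFE.
#' Used to shrink presets to desk scale.  The haploid sample size is capped
#' at 2 x the rescaled current size when necessary (with a warning).
#'
#' @param config a [ScenarioConfig].
#' @param Q additional rescale factor (>= 1).
#' @return the rescaled [ScenarioConfig].
#' @export
rescaleScenario <- function(config, Q) {
    if (Q < 1) stop("Q must be >= 1")
    if (Q == 1) return(config)
    ep <- config@demography@epochs
    ep$size <- pmax(2, round(ep$size / Q))
    tt <- round(ep$time / Q)
    tt[1L] <- 0
    if (nrow(ep) > 1L)  # keep epochs strictly ordered after rounding
        for (i in 2:nrow(ep)) tt[i] <- max(tt[i], tt[i - 1L] + 1)
    ep$time <- tt
    rm0 <- config@rates
    rates <- new("RateMap", blockLength = rm0@blockLength, mu = rm0@mu * Q,
                 rec = rm0@rec * Q, meanMu = rm0@meanMu * Q,
                 meanRec = rm0@meanRec * Q, cv = rm0@cv,
                 segmentLength = rm0@segmentLength)
    n <- config@sampleSize
    if (n > 2 * ep$size[1L]) {
        n <- as.integer(2 * ep$size[1L])
        warning("sample size capped at 2 x rescaled current size (", n, ")")
    }
    new("ScenarioConfig", name = config@name, layout = config@layout,
        rates = rates, demography = new("Demography", epochs = ep),
        dfe = config@dfe, psi = config@psi,
        singletonDrop = config@singletonDrop, sampleSize = n,
        seed = config@seed)
}

#' Default run length of a forward simulation
#'
#' `20 N_anc` burn-in generations plus the span of the timed demographic
#' events, with a minimum 100-generation tail: constant-size selection
#' scenarios run for `20 N + 100` generations (100,100 at N = 5,000).
#'
#' @param config a [ScenarioConfig].
#' @return number of generations.
#' @export
totalGenerations <- function(config) {
    ep <- config@demography@epochs
    Nanc <- ep$size[nrow(ep)]
    20 * Nanc + max(100, max(ep$time))
}

#' Serialize / restore a scenario as YAML
#'
#' Round-trip-safe serialization of a [ScenarioConfig] (schema version 1).
#'
#' @param config a [ScenarioConfig].
#' @param file optional path; when given the YAML is written there.
#' @return `scenarioToYaml`: YAML string (invisibly when `file` is given);
#'   `scenarioFromYaml`: the restored [ScenarioConfig].
#' @export
scenarioToYaml <- function(config, file = NULL) {
    lay <- config@layout
    obj <- list(
        schema = 1L,
        name = config@name,
        layout = list(geneCount = lay@geneCount,
                      exonLength = unname(lay@elementLengths["exon"]),
                      intronLength = unname(lay@elementLengths["intron"]),
                      intergenicLength = unname(lay@elementLengths["intergenic"]),
                      exonsPerGene = unname(lay@elementLengths["exonsPerGene"]),
                      intronsPerGene = unname(lay@elementLengths["intronsPerGene"])),
        rates = list(blockLength = config@rates@blockLength,
                     mu = as.numeric(config@rates@mu),
                     rec = as.numeric(config@rates@rec),
                     meanMu = config@rates@meanMu,
                     meanRec = config@rates@meanRec, cv = config@rates@cv),
        demography = list(size = config@demography@epochs$size,
                          time = config@demography@epochs$time),
        dfe = list(deleterious = config@dfe@deleterious,
                   delWeights = config@dfe@delWeights,
                   delBounds = as.numeric(config@dfe@delBounds),
                   gamma = config@dfe@gamma, fpos = config@dfe@fpos,
                   h = config@dfe@h),
        psi = config@psi, singletonDrop = config@singletonDrop,
        sampleSize = config@sampleSize,
        seed = if (is.na(config@seed)) NULL else config@seed)
    txt <- yaml::as.yaml(obj, precision = 15L)
    if (!is.null(file)) {
        writeLines(txt, file)
        return(invisible(txt))
    }
    txt
}

#' @rdname scenarioToYaml
#' @param yamlText YAML string (alternative to `file`).
#' @export
scenarioFromYaml <- function(file = NULL, yamlText = NULL) {
    obj <- if (!is.null(file)) yaml::read_yaml(file) else yaml::yaml.load(yamlText)
    if (is.null(obj$schema) || obj$schema != 1L)
        stop("unsupported scenario schema")
    layout <- buildLayout(geneCount = obj$layout$geneCount,
                          exonLength = obj$layout$exonLength,
                          intronLength = obj$layout$intronLength,
                          intergenicLength = obj$layout$intergenicLength,
                          exonsPerGene = obj$layout$exonsPerGene,
                          intronsPerGene = obj$layout$intronsPerGene)
    rates <- new("RateMap", blockLength = as.integer(obj$rates$blockLength),
                 mu = as.numeric(obj$rates$mu), rec = as.numeric(obj$rates$rec),
                 meanMu = obj$rates$meanMu, meanRec = obj$rates$meanRec,
                 cv = obj$rates$cv, segmentLength = layout@segmentLength)
    dem <- new("Demography",
               epochs = data.frame(size = as.numeric(obj$demography$size),
                                   time = as.numeric(obj$demography$time)))
    dfe <- new("DFEConfig", deleterious = obj$dfe$deleterious,
               delWeights = as.numeric(obj$dfe$delWeights),
               delBounds = matrix(as.numeric(obj$dfe$delBounds), nrow = 4,
                                  dimnames = list(c("neutral-ish", "weak",
                                                    "moderate", "strong"),
                                                  c("lower", "upper"))),
               gamma = obj$dfe$gamma, fpos = obj$dfe$fpos, h = obj$dfe$h)
    cfg <- new("ScenarioConfig", name = obj$name, layout = layout,
               rates = rates, demography = dem, dfe = dfe, psi = obj$psi,
               singletonDrop = obj$singletonDrop,
               sampleSize = as.integer(obj$sampleSize),
               seed = if (is.null(obj$seed)) NA_integer_ else as.integer(obj$seed))
    validObject(cfg)
    cfg
}
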