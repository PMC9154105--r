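test_that("presets encode the stated demographies and DFEs", {
    dec <- scenarioPreset("decline_bgs_pos")
    expect_equal(dec@demography@epochs$size, c(100, 5000))
    expect_equal(dec@demography@epochs$time, c(0, 100))
    expect_true(dec@dfe@deleterious)
    expect_equal(dec@dfe@gamma, 125)
    expect_equal(dec@dfe@fpos, 2.2e-3)

    psi <- scenarioPreset("eqm_psi10")
    expect_equal(psi@psi, 0.1)
    expect_false(psi@dfe@deleterious)
    expect_equal(psi@dfe@fpos, 0)
    expect_equal(psi@demography@epochs$size, 5000)

    bp <- scenarioPreset("eqm_bgs_pos")
    expect_equal(bp@dfe@gamma, 125)
    expect_equal(bp@dfe@delWeights, rep(0.25, 4))

    bot <- scenarioPreset("bottleneck_bgs_pos")
    expect_equal(bot@demography@epochs$size, c(5000, 50, 5000))
    expect_equal(bot@demography@epochs$time, c(0, 1900, 2000))

    gro <- scenarioPreset("growth_bgs_pos")
    expect_equal(gro@demography@epochs$size[1L], 10000)

    asc <- scenarioPreset("growth_bgs_pos_ascert")
    expect_equal(asc@singletonDrop, 1 / 3)

    expect_error(scenarioPreset("nope"), "choices")
})

test_that("varrates presets draw a heterogeneous CV-0.5 map", {
    set.seed(2)
    v <- scenarioPreset("eqm_bgs_pos_varrates")
    expect_equal(v@rates@cv, 0.5)
    expect_gt(var(v@rates@mu), 0)
})

test_that("default run length is 20N + 100 at the standard scale", {
    expect_equal(totalGenerations(scenarioPreset("eqm_bgs_pos")), 100100)
    expect_equal(totalGenerations(scenarioPreset("decline_bgs_pos")), 100100)
    expect_equal(totalGenerations(scenarioPreset("bottleneck_bgs_pos")),
                 102000)
})

test_that("extra rescaling preserves theta, rho and the scaled DFE", {
    cfg <- scenarioPreset("eqm_bgs_pos")
    r <- rescaleScenario(cfg, 10)
    expect_equal(r@demography@epochs$size, 500)
    expect_equal(4 * 500 * r@rates@meanMu, 4 * 5000 * cfg@rates@meanMu)
    expect_equal(4 * 500 * r@rates@meanRec, 4 * 5000 * cfg@rates@meanRec)
    expect_identical(r@dfe@gamma, cfg@dfe@gamma)  # population-scaled: unchanged
    d <- suppressWarnings(rescaleScenario(scenarioPreset("decline_bgs_pos"),
                                          10))  # capping tested separately
    expect_equal(d@demography@epochs$size, c(10, 500))
    expect_equal(d@demography@epochs$time, c(0, 10))
})

test_that("rescaling caps the sample size at 2 N_cur with a warning", {
    cfg <- scenarioPreset("decline_bgs_pos")
    expect_warning(r <- rescaleScenario(cfg, 20), "capped")
    expect_identical(r@sampleSize, 10L)
})

test_that("all presets round-trip through YAML unchanged", {
    set.seed(4)
    for (nm in c("eqm_neutral", "eqm_pos", "eqm_bgs", "eqm_bgs_pos",
                 "bottleneck_bgs_pos", "growth_bgs_pos",
                 "growth_bgs_pos_ascert", "decline_bgs_pos", "eqm_psi05",
                 "eqm_psi10", "eqm_bgs_pos_varrates")) {
        cfg <- scenarioPreset(nm)
        back <- scenarioFromYaml(yamlText = scenarioToYaml(cfg))
        expect_identical(back@name, cfg@name)
        expect_equal(back@rates@mu, cfg@rates@mu)
        expect_equal(back@rates@rec, cfg@rates@rec)
        expect_equal(back@demography@epochs, cfg@demography@epochs)
        expect_equal(back@dfe@delBounds, cfg@dfe@delBounds)
        expect_equal(back@dfe@gamma, cfg@dfe@gamma)
        expect_equal(back@psi, cfg@psi)
        expect_equal(back@singletonDrop, cfg@singletonDrop)
        expect_identical(back@sampleSize, cfg@sampleSize)
        expect_identical(segmentLength(back@layout),
                         segmentLength(cfg@layout))
    }
})

test_that("scenario validity catches inconsistent settings", {
    cfg <- scenarioPreset("eqm_neutral")
    expect_error(new("ScenarioConfig", name = "bad", layout = cfg@layout,
                     rates = cfg@rates, demography = cfg@demography,
                     dfe = cfg@dfe, psi = 1.2, singletonDrop = 0,
                     sampleSize = 100L, seed = NA_integer_), "psi")
    expect_error(new("ScenarioConfig", name = "bad", layout = cfg@layout,
                     rates = cfg@rates, demography = demographyConstant(10),
                     dfe = cfg@dfe, psi = 0, singletonDrop = 0,
                     sampleSize = 100L, seed = NA_integer_), "sampleSize")
})
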