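test_that("the reduced network carries the expected reactions exactly once", {
    net <- refNet()
    rx <- reactions(net)
    expected <- c("Diet_EX_etoh[d]", "EX_etoh_[br]", "EX_etoh[u]",
                  "EX_etoh[sw]", "Excretion_EX_etoh[fe]", "Liver_ALCD2if",
                  "Colon_CAT2p", "Colon_ALCD2if", "Adipocytes_ALCD2if",
                  "Adipocytes_ALCD2yf")
    for (id in expected) expect_equal(sum(rx$id == id), 1)
    ## aldehyde-dehydrogenase closures for both acetaldehyde species
    expect_true(all(c("Liver_ALDH2x", "Colon_ALDH2x") %in% rx$id))
    ## diet input is the sole ethanol source
    S <- stoichiometry(net)
    producers <- colnames(S)[S["etoh[bc]", ] > 0]
    expect_identical(producers, "Diet_EX_etoh[d]")
    ## structurally-present-but-silent routes are pinned at zero
    pinned <- rx$id[rx$role %in% c("colon_ADH", "adipose_ADH", "feces_ex")]
    expect_true(all(rx$ub[rx$id %in% pinned] == 0))
})

test_that("stoichiometric consistency: internal rows cancel for steady flux", {
    net <- refNet()
    S <- stoichiometry(net)
    ## any steady flux lies in the null space; verify with a basis of it
    ns <- MASS::Null(t(S))
    expect_gt(ncol(ns), 0)
    expect_lt(max(abs(S %*% ns)), 1e-10)
    ## and every metabolite participates in at least one reaction
    expect_true(all(rowSums(abs(S)) > 0))
})

test_that("closed network admits only the zero flux", {
    net <- refNet()
    net@reactions$ub[] <- 0
    sol <- solveFBA(net)
    expect_equal(sol@status, "optimal")
    expect_true(all(fluxes(sol) == 0))
})

test_that("state-dependent bounds follow the kinetics and scenario scales", {
    net <- refNet(); kin <- refKin(); phys <- refPhys()
    V <- organVolumes(phys)

    m0 <- setBounds(net, 0, 0, kin, phys, ScenarioConfig(), availability = 0)
    expect_equal(m0@reactions$ub[m0@reactions$id == "Liver_ALCD2if"], 0)

    mSat <- setBounds(net, 1000 * kin@kmADH, 0.001, kin, phys,
                      ScenarioConfig(), bloodCEthanol = 8,
                      colonCEthanol = 7, availability = 500)
    ubADH <- mSat@reactions$ub[mSat@reactions$id == "Liver_ALCD2if"]
    expect_lt(abs(ubADH - kin@vmaxADH * V[["liver"]]) /
              (kin@vmaxADH * V[["liver"]]), 0.002)

    ## ALDH2.2 scales the aldehyde capacity to 1.5% of wild type
    mWT <- setBounds(net, 5, 0.004, kin, phys, ScenarioConfig(),
                     availability = 500)
    mMu <- setBounds(net, 5, 0.004, kin, phys,
                     ScenarioConfig(isoform = "ALDH2.2"), availability = 500)
    ubWT <- mWT@reactions$ub[mWT@reactions$id == "Liver_ALDH2x"]
    ubMu <- mMu@reactions$ub[mMu@reactions$id == "Liver_ALDH2x"]
    expect_equal(ubMu / ubWT, 0.015, tolerance = 1e-10)

    ## negative scales are rejected at scenario construction
    expect_error(ScenarioConfig(expressionScale = -1), "expressionScale")
    expect_error(setBounds(net, -1, 0, kin, phys, ScenarioConfig()),
                 ">= 0")
})

test_that("the LP solve matches independent oracles", {
    ## 3-reaction toy chain: input -> A -> B -> sink, input capped at 2
    S <- matrix(c(1, -1, 0,
                  0, 1, -1), 2, 3, byrow = TRUE,
                dimnames = list(c("A", "B"), NULL))
    rx <- data.frame(id = c("in", "conv", "out"),
                     role = c("diet_input", "liver_ADH", "urine_ex"),
                     lb = 0, ub = c(2, 10, 10))
    toy <- stoichiometricModel(S, rx, objective = "conv")
    sol <- solveFBA(toy)
    expect_equal(sol@objectiveValue, 2)
    expect_equal(unname(fluxes(sol)), c(2, 2, 2))
    oracle <- vertexOptimum(toy)
    expect_equal(sol@objectiveValue, oracle$objective, tolerance = 1e-9)

    ## full ethanol network at a saturated state: simplex == enumeration
    m <- setBounds(refNet(), 6, 0.004, refKin(), refPhys(),
                   ScenarioConfig(), bloodCEthanol = 7, colonCEthanol = 6,
                   availability = 400)
    sol <- solveFBA(m)
    oracle <- vertexOptimum(m)
    expect_equal(sol@objectiveValue, oracle$objective, tolerance = 1e-7)

    ## cross-check against a second implementation on a benign instance
    if (requireNamespace("boot", quietly = TRUE)) {
        res <- boot::simplex(a = c(1, 0, 0),
                             A1 = rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 1)),
                             b1 = c(2, 5, 6), maxi = TRUE)
        own <- ethanolWBM:::.lpSolve(c(1, 0, 0),
                                     A1 = rbind(c(1, 0, 0), c(0, 1, 0),
                                                c(1, 1, 1)),
                                     b1 = c(2, 5, 6), maximize = TRUE)
        expect_equal(own$value, unname(res$value), tolerance = 1e-10)
    }
})

test_that("optimal solutions satisfy steady state, bounds and monotonicity", {
    net <- refNet(); kin <- refKin(); phys <- refPhys()
    states <- list(c(eth = 0.5, blood = 0.6), c(eth = 2, blood = 2.2),
                   c(eth = 6, blood = 6.8), c(eth = 12, blood = 13))
    lastObj <- -1
    for (st in states) {
        m <- setBounds(net, st[["eth"]], 0.004, kin, phys, ScenarioConfig(),
                       bloodCEthanol = st[["blood"]],
                       colonCEthanol = st[["eth"]], availability = 400)
        sol <- solveFBA(m)
        v <- fluxes(sol)
        expect_lt(max(abs(stoichiometry(m) %*% v)), 1e-8)
        expect_true(all(v >= m@reactions$lb - 1e-9))
        expect_true(all(v <= m@reactions$ub + 1e-9))
        ## raising the liver bound (higher concentration) never lowers the
        ## objective
        expect_gte(sol@objectiveValue, lastObj - 1e-9)
        lastObj <- sol@objectiveValue
        ## deterministic tie-break: identical repeat solves
        expect_identical(fluxes(solveFBA(m)), v)
    }
})

test_that("flux fractions partition total elimination", {
    net <- refNet()
    ## single active route
    m <- net
    m@reactions$ub[] <- 0
    m@reactions$ub[m@reactions$id %in%
                   c("Diet_EX_etoh[d]", "Liver_ALCD2if", "Liver_ALDH2x")] <- 5
    m@couplings <- m@couplings[0, ]
    fr <- fluxFractions(solveFBA(m), m)
    expect_equal(unname(fr[["liver_ADH"]]), 1)
    expect_equal(sum(fr, na.rm = TRUE), 1)

    ## zero elimination: explicit undefined flag
    z <- net; z@reactions$ub[] <- 0
    frz <- fluxFractions(solveFBA(z), z)
    expect_true(all(is.na(frz)))
    expect_false(attr(frz, "defined"))

    ## fractions equal an independent per-role accumulation
    mb <- setBounds(net, 6, 0.004, refKin(), refPhys(), ScenarioConfig(),
                    bloodCEthanol = 7, colonCEthanol = 6, availability = 400)
    sol <- solveFBA(mb)
    fr <- fluxFractions(sol, mb)
    v <- fluxes(sol)
    roles <- setNames(mb@reactions$role, mb@reactions$id)
    manual <- tapply(v, roles[names(v)], sum)
    manual <- manual[!(names(manual) %in% c("diet_input", "liver_ALDH2",
                                            "colon_ALDH2"))]
    expect_equal(sum(fr), 1, tolerance = 1e-9)
    for (r in names(manual))
        expect_equal(unname(fr[[r]]), unname(manual[[r]] / sum(manual)),
                     tolerance = 1e-9)
})

test_that("network serialisation round-trips S-matrix, bounds and couplings", {
    net <- refNet()
    m <- setBounds(net, 4, 0.003, refKin(), refPhys(), ScenarioConfig(),
                   bloodCEthanol = 5, colonCEthanol = 4, availability = 300)

    tf <- tempfile(fileext = ".tsv")
    exportNetworkTable(m, tf)
    back <- readNetworkTable(tf)
    expect_equal(stoichiometry(back), stoichiometry(m))
    expect_equal(reactions(back)$lb, reactions(m)$lb, tolerance = 1e-9)
    expect_equal(reactions(back)$ub, reactions(m)$ub, tolerance = 1e-9)
    expect_equal(back@couplings$cmin, m@couplings$cmin, tolerance = 1e-9)
    expect_equal(back@objective, m@objective)

    xf <- tempfile(fileext = ".xml")
    exportNetworkSBML(m, xf)
    sb <- readNetworkSBML(xf)
    expect_equal(stoichiometry(sb), stoichiometry(m))
    expect_equal(reactions(sb)$ub, reactions(m)$ub, tolerance = 1e-9)
    expect_equal(reactions(sb)$role, reactions(m)$role)
})
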