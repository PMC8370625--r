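test_that("derived physiology conserves flow at both mixing points", {
    set.seed(41)
    for (i in 1:8) {
        ind <- Individual(age = runif(1, 20, 70), sex = "male",
                          height = runif(1, 155, 200),
                          weight = runif(1, 50, 120),
                          bodyFat = runif(1, 0.08, 0.45))
        phys <- buildPhysiology(ind)
        org <- phys@organs
        tissue <- org[org$is_lumen == 0, ]
        systemic <- tissue[!(tissue$organ %in% c("lung", "blood")), ]
        ## lung mixing point: systemic flows sum to cardiac output
        expect_equal(sum(systemic$flow), cardiacOutput(phys),
                     tolerance = 1e-10)
        ## liver mixing point: inflow = hepatic artery + portal flows
        portal <- org$flow[org$portal == 1]
        livIn <- org$flow[org$organ == "liver"] + sum(portal)
        expect_gt(livIn, org$flow[org$organ == "liver"])
        expect_equal(livIn,
                     org$flow[org$organ == "liver"] +
                     sum(org$flow[org$organ %in%
                         c("stomach", "small_intestine", "large_intestine",
                           "pancreas", "spleen")]), tolerance = 1e-12)
        ## organ volumes fit inside the body
        expect_lt(sum(tissue$volume), ind@weight / 0.9)
        expect_true(all(tissue$volume > 0))
    }
})

test_that("physiology construction is deterministic and fat-sensitive", {
    a <- buildPhysiology(referenceMale())
    b <- buildPhysiology(referenceMale())
    expect_identical(a@organs, b@organs)

    lean <- buildPhysiology(Individual(30, "male", 180, 80, 0.15))
    fat <- buildPhysiology(Individual(30, "male", 180, 80, 0.30))
    vl <- organVolumes(lean); vf <- organVolumes(fat)
    expect_gt(vf[["adipose"]], vl[["adipose"]])
    nonAdipose <- setdiff(names(vl), c("adipose", "stomach_lumen",
                                       "si_lumen", "li_lumen"))
    expect_true(all(vf[nonAdipose] <= vl[nonAdipose] + 1e-12))
})

test_that("out-of-range anthropometrics raise errors naming the field", {
    expect_error(buildPhysiology(Individual(99, "male", 180, 75, 0.2)),
                 "'age'")
    expect_error(buildPhysiology(Individual(30, "male", 180, 300, 0.2)),
                 "weight")
    expect_error(Individual(30, "male", 180, 75, 1.2), "bodyFat")
    expect_error(Individual(30, "other", 180, 75, 0.2), "sex")
})

test_that("partition coefficient has its closed-form and limiting behaviour", {
    eth <- defaultMetabolites()$ethanol
    plasma <- c(water = 0.945, nlipid = 0.0035, plipid = 0.00225)

    ## identity: tissue composed exactly like plasma, fully unbound
    ident <- Metabolite("x", 50, -0.3, 1)
    expect_equal(partitionCoefficient(ident, plasma, plasma = plasma), 1)

    ## hydrophilic ethanol in a high-water tissue ~ water ratio
    muscle <- c(water = 0.760, nlipid = 0.022, plipid = 0.0072)
    k <- partitionCoefficient(eth, muscle, plasma = plasma)
    expect_lt(abs(k - 0.760 / 0.945), 0.06)

    ## symbol-by-symbol re-evaluation of the documented formula
    for (m in defaultMetabolites()) {
        phys <- refPhys()
        for (i in which(phys@organs$is_lumen == 0)) {
            o <- phys@organs[i, ]
            if (o$organ == "blood") next
            P <- 10^m@lipophilicity
            expected <- m@fractionUnbound *
                (P * (o$nlipid + 0.3 * o$plipid) +
                 (o$water + 0.7 * o$plipid)) /
                (P * (plasma[["nlipid"]] + 0.3 * plasma[["plipid"]]) +
                 (plasma[["water"]] + 0.7 * plasma[["plipid"]]))
            got <- partitionCoefficient(
                m, c(water = o$water, nlipid = o$nlipid, plipid = o$plipid),
                plasma = plasma)
            expect_equal(got, expected, tolerance = 1e-12)
        }
    }

    ## monotone increasing in lipophilicity for lipid-richer-than-plasma
    ## tissue
    ks <- vapply(seq(-2, 2, by = 0.25), function(lp)
        partitionCoefficient(Metabolite("x", 50, lp, 0.99), muscle,
                             plasma = plasma), numeric(1))
    expect_true(all(diff(ks) > 0))

    ## zero unbound fraction violates the division contract
    expect_error(Metabolite("x", 50, 0, 0), "fractionUnbound")
})

test_that("partitions cover all compartments with blood as reference", {
    parts <- refParts()
    expect_named(parts, c("ethanol", "acetaldehyde"))
    for (k in parts) {
        expect_length(k, 17)
        expect_true(all(k > 0))
        expect_equal(unname(k[["blood"]]), 1)
    }
})
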