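test_that("carcinogen restriction intersects transactions and drops emptied WS", {
    db <- toyDB()
    cdb <- restrictToCarcinogens(db, toyCatalog())
    # wood dust (unflagged) WS disappears; ethanol dropped from its WS
    expect_equal(nTransactions(cdb), 3)
    sets <- unname(vapply(agentSets(cdb), paste, character(1),
                          collapse = ","))
    expect_setequal(sets, c("asbestos,lead", "benzene,lead",
                            "asbestos,chromium,lead"))
    expect_equal(nMultiAgent(cdb), 3)
    # misconfigured catalog
    noc <- toyCatalog(carcinogens = character(0))
    expect_error(restrictToCarcinogens(db, noc), "no carcinogens")
})

test_that("restriction commutes with counting", {
    corpus <- generateCorpus(synthConfig(nWS = 600, seed = 23))
    det <- corpus$records[flagDetected(corpus$records), ]
    db <- buildTransactions(det)
    cdb <- restrictToCarcinogens(db, corpus$catalog)
    carc <- intersect(agentUniverse(db),
                      corpus$catalog$agent_id[corpus$catalog$carcinogen])
    for (rep in 1:10) {
        items <- sample(carc, sample(1:2, 1))
        expect_equal(itemsetSupport(cdb, items, "all")$nWS,
                     itemsetSupport(db, items, "all")$nWS)
    }
    # >=2-carcinogen WS count equals a brute-force recount
    sets <- agentSets(db)
    expect_equal(nMultiAgent(cdb),
                 sum(vapply(sets, function(s)
                     sum(s %in% carc) >= 2, logical(1))))
})

test_that("strata below 100 multi-agent WS are skipped, at 100 analysed", {
    mkStratum <- function(sector, nMulti, nSingle = 5) {
        rbind(
            data.frame(agent_id = rep(c("a", "b"), nMulti),
                       sector = sector,
                       occupation = sprintf("%s_m%04d", sector,
                                            rep(seq_len(nMulti), each = 2)),
                       task = "T", year = 2015L, source = "X"),
            data.frame(agent_id = "a", sector = sector,
                       occupation = sprintf("%s_s%04d", sector,
                                            seq_len(nSingle)),
                       task = "T", year = 2015L, source = "X"))
    }
    db <- buildTransactions(rbind(mkStratum("S99", 99),
                                  mkStratum("S100", 100)))
    res <- stratifiedMining(db, "sector", minStratumWS = 100,
                            minSupport = 0.001, minWS = 10)
    expect_setequal(names(res), "S100")
    skipped <- attr(res, "skipped")
    expect_equal(skipped$code, "S99")
    expect_equal(skipped$n_multi, 99)
})

test_that("the stratified support floor is max(ceil(0.1% of n), 10)", {
    mk <- function(n) data.frame(
        agent_id = rep(c("a", "b"), n), sector = "S",
        occupation = sprintf("O%05d", rep(seq_len(n), each = 2)),
        task = "T", year = 2015L, source = "X")
    res <- stratifiedMining(buildTransactions(mk(500)), "sector",
                            minStratumWS = 100, minSupport = 0.001,
                            minWS = 10)
    expect_equal(res$S$threshold, 10)   # max(ceil(0.5), 10)
    res2 <- stratifiedMining(buildTransactions(mk(20000)), "sector",
                             minStratumWS = 100, minSupport = 0.001,
                             minWS = 10)
    expect_equal(res2$S$threshold, 20)  # max(ceil(20), 10)
})

test_that("a sector-specific planted pair ranks first in its stratum", {
    corpus <- generateCorpus(synthConfig(seed = 29))
    det <- corpus$records[flagDetected(corpus$records), ]
    db <- buildTransactions(det)
    res <- stratifiedMining(db, "sector", minStratumWS = 100,
                            minSupport = 0.001, minWS = 10,
                            denominator = "multi")
    # S06 hosts only the two-agent silica-like profile: its planted
    # pair is the stratum's sole and therefore top itemset
    expect_true("S06" %in% names(res))
    expect_equal(res$S06$itemsets$items[1], "A11|A12")
    # S04 hosts only the welding/metals profile: every frequent
    # itemset there is a subset of the planted emission set
    expect_true("S04" %in% names(res))
    mined <- strsplit(res$S04$itemsets$items, "|", fixed = TRUE)
    expect_true(all(vapply(mined, function(x)
        all(x %in% paste0("A", sprintf("%02d", 6:10))), logical(1))))
})

test_that("co-occurrence counts equal pairwise itemset supports and mask below floor", {
    db <- toyDB()
    cm <- cooccurrenceMatrix(db, floor = 0)
    m <- cooccurrenceCounts(cm, masked = FALSE)
    expect_equal(m["asbestos", "lead"], 2L)
    expect_equal(m["asbestos", "chromium"], 1L)
    expect_equal(m["lead", "lead"], 3L)
    expect_true(isSymmetric(m))
    # floor 10 masks every off-diagonal entry of the toy set
    cm10 <- cooccurrenceMatrix(db, floor = 10)
    mm <- cooccurrenceCounts(cm10, masked = TRUE)
    off <- mm; diag(off) <- NA
    expect_true(all(is.na(off)))
    expect_false(any(is.na(diag(mm))))
    # raw counts survive masking
    expect_equal(cooccurrenceCounts(cm10, masked = FALSE), m)

    # cross-module consistency with the miner on richer data
    corpus <- generateCorpus(synthConfig(nWS = 500, seed = 31))
    det <- corpus$records[flagDetected(corpus$records), ]
    db2 <- buildTransactions(det)
    cm2 <- cooccurrenceCounts(cooccurrenceMatrix(db2, floor = 0),
                              masked = FALSE)
    fi <- mineItemsets(db2, minSupport = 1e-9, minWS = 1, maxLen = 2,
                       denominator = "all")
    pairs <- itemList(fi)[lengths(itemList(fi)) == 2]
    ns <- wsCount(fi)[lengths(itemList(fi)) == 2]
    for (i in seq_along(pairs))
        expect_equal(cm2[pairs[[i]][1], pairs[[i]][2]], ns[i],
                     ignore_attr = TRUE)
})

test_that("exclusion lists drop agents before counting", {
    db <- toyDB()
    cm <- cooccurrenceMatrix(db, floor = 0,
                             exclude = c("lead", "wood dust"))
    expect_false("lead" %in% rownames(cooccurrenceCounts(cm)))
    expect_error(cooccurrenceMatrix(db, exclude = agentUniverse(db)),
                 "no agents left")
})
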