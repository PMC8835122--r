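test_that("supports on the textbook database are exact", {
    db <- toyDB()
    s <- itemsetSupport(db, c("asbestos", "lead"), "all")
    expect_equal(s$nWS, 2)
    expect_equal(s$support, 0.5)
    s <- itemsetSupport(db, "wood dust", "all")
    expect_equal(s$nWS, 1)
    expect_equal(s$support, 0.25)
    # items outside the universe count zero by contract
    expect_equal(itemsetSupport(db, c("lead", "radon"), "all")$nWS, 0)
    # empty itemset support is undefined
    expect_error(itemsetSupport(db, character(0)), "empty itemset")
    # multi-agent denominator
    expect_equal(itemsetSupport(db, c("asbestos", "lead"), "multi")$support,
                 2 / 3)
})

test_that("mining at 50% support keeps (asbestos, lead) and drops (asbestos, chromium)", {
    fi <- mineItemsets(toyDB(), minSupport = 0.5, denominator = "all")
    keys <- itemsetKeys(fi)
    expect_true(.itemKey(c("asbestos", "lead")) %in% keys)
    expect_true(.itemKey("lead") %in% keys)
    expect_false(.itemKey(c("asbestos", "chromium")) %in% keys)
    expect_false(.itemKey(c("benzene", "ethanol")) %in% keys)
})

test_that("support of small subsets equals an exhaustive scan on random data", {
    set.seed(202)
    db <- randomDB(10, 50)
    sets <- agentSets(db)
    universe <- agentUniverse(db)
    for (k in 1:3) {
        for (rep in 1:20) {
            items <- sample(universe, k)
            expect_equal(itemsetSupport(db, items, "all")$nWS,
                         bruteCount(sets, items))
        }
    }
})

test_that("the miner is complete and sound against powerset enumeration", {
    set.seed(303)
    for (rep in 1:10) {
        db <- randomDB(sample(5:8, 1), sample(20:60, 1),
                       density = runif(1, 0.2, 0.5))
        thr <- sample(1:6, 1)
        fi <- mineItemsets(db, minSupport = 1e-9, minWS = thr,
                           denominator = "all")
        want <- bruteItemsets(db, thr)
        got <- stats::setNames(wsCount(fi), itemsetKeys(fi))
        expect_equal(sort(names(got)), sort(names(want)))
        expect_equal(unname(got[names(want)]), unname(unlist(want)))
    }
})

test_that("anti-monotonicity holds over the mined lattice", {
    set.seed(404)
    db <- randomDB(9, 80)
    fi <- mineItemsets(db, minSupport = 1e-9, minWS = 2,
                       denominator = "all")
    lk <- new.env()
    its <- itemList(fi); ns <- wsCount(fi)
    for (i in seq_along(its)) assign(.itemKey(its[[i]]), ns[i], envir = lk)
    for (i in seq_along(its)) {
        I <- its[[i]]
        if (length(I) < 2) next
        for (drop in seq_along(I)) {
            sub <- .itemKey(I[-drop])
            expect_true(exists(sub, envir = lk))  # subsets are frequent too
            expect_gte(get(sub, envir = lk), ns[i])
        }
    }
})

test_that("raising the support threshold only shrinks the result", {
    set.seed(505)
    db <- randomDB(8, 60)
    prev <- NULL
    for (thr in c(1, 2, 4, 8, 16)) {
        fi <- mineItemsets(db, minSupport = 1e-9, minWS = thr,
                           denominator = "all")
        keys <- itemsetKeys(fi)
        if (!is.null(prev)) expect_true(all(keys %in% prev))
        prev <- keys
    }
})

test_that("the effective threshold ceils the fractional support then applies the floor", {
    # 1000 transactions at 0.1% -> ceil(1) = 1; floor 10 wins
    rec <- data.frame(agent_id = rep(c("a", "b"), 500),
                      sector = "S", occupation = sprintf("O%04d",
                          rep(1:500, each = 2)),
                      task = "T", year = 2015L, source = "X")
    db <- buildTransactions(rec)
    fi <- mineItemsets(db, minSupport = 0.001, minWS = 10,
                       denominator = "all")
    expect_equal(fi@params$threshold, 10)
    # large denominator: fractional part wins, with exact ceiling
    fi2 <- mineItemsets(db, minSupport = 0.02, minWS = 1,
                        denominator = "all")
    expect_equal(fi2@params$threshold, 10)  # ceil(0.02*500)=10
    fi3 <- mineItemsets(db, minSupport = 0.0201, minWS = 1,
                        denominator = "all")
    expect_equal(fi3@params$threshold, 11)  # ceil(10.05)=11
})

test_that("output ordering is deterministic and sorted by count, length, items", {
    set.seed(606)
    db <- randomDB(7, 40)
    fi <- mineItemsets(db, minSupport = 1e-9, minWS = 2,
                       denominator = "all")
    n <- wsCount(fi); len <- lengths(itemList(fi)); key <- itemsetKeys(fi)
    ord <- order(-n, len, key)
    expect_equal(ord, seq_along(ord))
    fi2 <- mineItemsets(db, minSupport = 1e-9, minWS = 2,
                        denominator = "all")
    expect_identical(as.data.frame(fi), as.data.frame(fi2))
})

test_that("top-k annotation finds the modal sector or falls back to n/a", {
    # sectors present: modal sector equals a brute-force group count
    set.seed(707)
    corpus <- generateCorpus(synthConfig(nWS = 600, seed = 19))
    det <- corpus$records[flagDetected(corpus$records), ]
    db <- buildTransactions(det)
    fi <- mineItemsets(db, minSupport = 0.01, denominator = "all")
    top <- topItemsets(fi, db, k = 5, minLen = 2)
    sets <- agentSets(db)
    secs <- wsInfo(db)$sector
    for (i in seq_len(nrow(top))) {
        items <- strsplit(top$items[i], "|", fixed = TRUE)[[1]]
        inWS <- vapply(sets, function(s) all(items %in% s), logical(1))
        tab <- table(secs[inWS])
        expect_equal(top$modal_stratum_n[i], max(tab))
        expect_true(top$modal_stratum[i] %in%
                    names(tab)[tab == max(tab)])
    }
    # k larger than the result: all rows, no padding
    expect_lte(nrow(topItemsets(fi, db, k = 10000)), length(fi))
    # absent sector codes fall back to n/a
    rec <- toyRecords(); rec$sector <- ""
    db2 <- buildTransactions(rec)
    fi2 <- mineItemsets(db2, minSupport = 0.5, denominator = "all")
    expect_true(all(topItemsets(fi2, db2, k = 3)$modal_stratum == "n/a"))
})
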