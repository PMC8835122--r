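test_that("well-formed files round-trip and malformed rows are rejected with reasons", {
    f <- tempfile(fileext = ".csv")
    df <- data.frame(agent_id = c("a", "b", "a", "c"),
                     sector = "S1", occupation = "O1",
                     task = "T1", year = 2015,
                     concentration = c(2, 0.4, 1.5, 3), loq = 1,
                     source = "X")
    write.csv(df, f, row.names = FALSE)
    rr <- readRecords(f)
    expect_equal(nrow(rr$records), 4)
    expect_equal(nrow(rr$rejects), 0)

    df$concentration[2] <- "abc"
    df$sector[3] <- ""
    write.csv(df, f, row.names = FALSE)
    rr <- readRecords(f)
    expect_equal(nrow(rr$records), 2)
    expect_setequal(rr$rejects$reason, c("bad_numeric", "missing_descriptor"))
    expect_setequal(rr$rejects$row, c(2, 3))

    # missing mandatory column is a hard error
    df2 <- df[, setdiff(names(df), "task")]
    write.csv(df2, f, row.names = FALSE)
    expect_error(readRecords(f), "missing mandatory column")
})

test_that("a generated corpus round-trips write -> read unchanged", {
    corpus <- generateCorpus(synthConfig(nWS = 300, seed = 11))
    d <- tempfile()
    writeCorpus(corpus, d)
    rr <- readRecords(file.path(d, "records.csv"))
    expect_equal(nrow(rr$rejects), 0)
    expect_equal(nrow(rr$records), nrow(corpus$records))
    expect_equal(rr$records$agent_id, corpus$records$agent_id)
    expect_equal(rr$records$concentration, corpus$records$concentration)
    expect_equal(rr$records$year, corpus$records$year)
    cat2 <- readCatalog(file.path(d, "catalog.csv"))
    expect_equal(cat2$carcinogen, corpus$catalog$carcinogen)
})

test_that("detection is strict at the LOQ boundary and configurable", {
    rec <- data.frame(concentration = c(5, 1, 0.5), loq = 1)
    expect_equal(flagDetected(rec), c(TRUE, FALSE, FALSE))
    expect_equal(flagDetected(rec, boundary = "inclusive"),
                 c(TRUE, TRUE, FALSE))
    expect_error(flagDetected(data.frame(x = 1)), "neither")
    # flag dialect takes precedence and is used as-is
    expect_equal(flagDetected(data.frame(detected = c(TRUE, FALSE))),
                 c(TRUE, FALSE))
})

test_that("per-record detected fraction matches the planted censoring rate", {
    corpus <- generateCorpus(synthConfig(nWS = 2000, seed = 3))
    det <- flagDetected(corpus$records)
    p <- 1 - corpus$config$censorProb
    se <- sqrt(p * (1 - p) / length(det))
    expect_lt(abs(mean(det) - p), 3 * se)
})

test_that("the minimum-count filter keeps 100 and drops 99 detected records", {
    mk <- function(agent, n) data.frame(
        agent_id = agent, sector = "S", occupation = "O",
        task = paste0("T", seq_len(n)), year = 2015L,
        concentration = 2, loq = 1, source = "X")
    rec <- rbind(mk("X99", 99), mk("Y100", 100))
    catalog <- data.frame(agent_id = c("X99", "Y100"), name = c("x", "y"),
                          carcinogen = FALSE, excluded = FALSE,
                          exclusion_reason = "")
    fl <- applyInclusionFilters(rec, catalog, filterConfig())
    expect_setequal(unique(fl$records$agent_id), "Y100")
    expect_equal(fl$audit$n_removed[fl$audit$stage == "min_count_per_agent"],
                 99)
})

test_that("catalog and per-source exclusions remove the flagged records", {
    rec <- data.frame(
        agent_id = c("inhalable dust", "lead", "asbestos", "asbestos"),
        sector = "S", occupation = "O", task = "T", year = 2015L,
        concentration = 2, loq = 1,
        source = c("A", "A", "A", "B"))
    catalog <- data.frame(
        agent_id = c("inhalable dust", "lead", "asbestos"),
        name = c("dust", "lead", "asbestos"),
        carcinogen = c(FALSE, TRUE, TRUE),
        excluded = c(TRUE, FALSE, FALSE),
        exclusion_reason = c("generic_dust", "", ""))
    fl <- applyInclusionFilters(rec, catalog, filterConfig(
        minAgentRecords = 1,
        sourceExclusions = data.frame(agent_id = "asbestos", source = "B")))
    expect_setequal(paste(fl$records$agent_id, fl$records$source),
                    c("lead A", "asbestos A"))
    expect_equal(
        fl$audit$n_removed[fl$audit$stage == "agent_source_exclusions"], 2)
})

test_that("filters audit sums, are idempotent, and retain only detected records", {
    corpus <- generateCorpus(synthConfig(nWS = 500, seed = 5))
    fl <- applyInclusionFilters(corpus$records, corpus$catalog,
                                filterConfig(minAgentRecords = 20))
    # audit consistency at every stage
    expect_true(all(fl$audit$n_in - fl$audit$n_removed == fl$audit$n_out))
    expect_equal(fl$audit$n_in[1], nrow(corpus$records))
    expect_equal(fl$audit$n_out[nrow(fl$audit)], nrow(fl$records))
    # all retained records are detected
    expect_true(all(flagDetected(fl$records)))
    # idempotence
    fl2 <- applyInclusionFilters(fl$records, corpus$catalog,
                                 filterConfig(minAgentRecords = 20))
    expect_equal(fl2$records, fl$records, ignore_attr = TRUE)
    # retained agent set equals an independent recount
    det <- corpus$records[flagDetected(corpus$records), ]
    cnt <- table(det$agent_id)
    expect_setequal(unique(fl$records$agent_id), names(cnt)[cnt >= 20])
    # unknown agents are a hard error
    bad <- rbind(fl$records[1, ], within(fl$records[1, ],
                                         agent_id <- "ghost"))
    expect_error(applyInclusionFilters(bad, corpus$catalog), "catalog")
})

test_that("records outside the study window are removed first", {
    rec <- data.frame(agent_id = "a", sector = "S", occupation = "O",
                      task = "T", year = c(2009L, 2010L, 2019L, 2020L),
                      concentration = 2, loq = 1, source = "X")
    catalog <- data.frame(agent_id = "a", name = "a", carcinogen = FALSE,
                          excluded = FALSE, exclusion_reason = "")
    fl <- applyInclusionFilters(rec, catalog,
                                filterConfig(minAgentRecords = 1))
    expect_setequal(fl$records$year, c(2010L, 2019L))
    expect_equal(fl$audit$stage[1], "year_window")
    expect_equal(fl$audit$n_removed[1], 2)
})
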