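#' Rounding conventions for report tables
#'
#' Report tables round half-up: percentages to one decimal, lift to one
#' decimal at 10 or above and two decimals below. Machine-readable
#' outputs always keep full precision; these helpers are applied only
#' in the formatted report layer.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 0) {
    s <- 10^digits
    sign(x) * floor(abs(x) * s + 0.5) / s
}

#' @rdname roundHalfUp
#' @export
formatPercent <- function(x) sprintf("%.1f%%", roundHalfUp(100 * x, 1))

#' @rdname roundHalfUp
#' @export
formatLift <- function(x) {
    ifelse(x >= 10, sprintf("%.1f", roundHalfUp(x, 1)),
           sprintf("%.2f", roundHalfUp(x, 2)))
}

#' Lift under the rounded-intermediate pedagogical convention
#'
#' Worked examples conventionally present lift as the already-rounded
#' confidence divided by the consequent's support (e.g. 0.67 / 0.5 =
#' 1.34 where the exact ratio 4/3 would print 1.33). This helper
#' reproduces that display convention; [ruleLift()] is always exact.
#'
#' @param confidence exact confidence of the rule.
#' @param supportC support of the consequent.
#' @return lift rounded to two decimals via the rounded confidence.
#' @export
liftRoundedConvention <- function(confidence, supportC) {
    roundHalfUp(roundHalfUp(confidence, 2) / supportC, 2)
}

#' Assemble the run configuration
#'
#' One serializable list holding every parameter of a pipeline run. A
#' completed run writes the resolved configuration next to its outputs
#' for provenance.
#'
#' @param recordsFile,catalogFile input paths.
#' @param outDir output directory.
#' @param schema record column mapping, see [recordSchema()].
#' @param filters filter parameters, see [filterConfig()].
#' @param minSupport,minWS,minConfidence,denominator mining defaults
#'   (0.1% support, 10% confidence, multi-agent denominator).
#' @param k rows per report table.
#' @param confidenceReportSupport,liftReportSupport report-level
#'   support floors of the confidence- and lift-ranked rule tables.
#' @param strataMinWS stratified-analysis qualification threshold
#'   (multi-agent WS per stratum).
#' @param strataMinSupportWS absolute support floor within strata.
#' @param cooccurFloor,cooccurExclude co-occurrence display floor and
#'   exclusion list.
#' @param seed forwarded to the synthetic generator when used.
#' @return a `RunConfig` list.
#' @export
runConfig <- function(recordsFile = NULL, catalogFile = NULL,
                      outDir = "coexminer-out",
                      schema = recordSchema(), filters = filterConfig(),
                      minSupport = 0.001, minWS = 1L, minConfidence = 0.1,
                      denominator = "multi", k = 10L,
                      confidenceReportSupport = 0.05,
                      liftReportSupport = 0.01,
                      strataMinWS = 100L, strataMinSupportWS = 10L,
                      cooccurFloor = 10L, cooccurExclude = character(),
                      seed = 1L) {
    list(recordsFile = recordsFile, catalogFile = catalogFile,
         outDir = outDir, schema = schema, filters = filters,
         minSupport = minSupport, minWS = as.integer(minWS),
         minConfidence = minConfidence, denominator = denominator,
         k = as.integer(k),
         confidenceReportSupport = confidenceReportSupport,
         liftReportSupport = liftReportSupport,
         strataMinWS = as.integer(strataMinWS),
         strataMinSupportWS = as.integer(strataMinSupportWS),
         cooccurFloor = as.integer(cooccurFloor),
         cooccurExclude = cooccurExclude, seed = as.integer(seed))
}

#' Read a YAML run configuration
#'
#' Keys absent from the file keep their [runConfig()] defaults; nested
#' blocks (`schema`, `filters`) are merged key-wise.
#'
#' @param path YAML file.
#' @return a `RunConfig` list.
#' @export
readRunConfig <- function(path) {
    raw <- yaml::read_yaml(path)
    base <- runConfig()
    if (!is.null(raw$schema))
        raw$schema <- modifyList(base$schema, raw$schema)
    if (!is.null(raw$filters)) {
        if (!is.null(raw$filters$sourceExclusions))
            raw$filters$sourceExclusions <-
                do.call(rbind, lapply(raw$filters$sourceExclusions,
                                      as.data.frame))
        raw$filters <- modifyList(base$filters, raw$filters)
    }
    modifyList(base, raw)
}

.writeTable <- function(df, path) {
    write.csv(df, path, row.names = FALSE)
    path
}

#' Run the full coexposure-mining pipeline
#'
#' Executes records -> filters -> transactions -> itemset mining ->
#' rule mining -> subanalyses in order and writes the report bundle to
#' `config$outDir`: reject and filter-audit tables, the per-agent
#' coexposure summary, top itemset tables (overall and by length),
#' rule tables ranked by confidence and by lift, carcinogen-restricted
#' counterparts, the co-occurrence matrix, per-stratum bundles, a JSON
#' run manifest with the headline counts, and the resolved
#' configuration. All outputs are deterministic given identical inputs
#' and configuration.
#'
#' @param config a [runConfig()] (or path to a YAML file).
#' @return invisibly, a list with the in-memory objects (`db`, `fi`,
#'   `rules`, `carcDb`, `cooccur`, `strata`, `manifest`).
#' @export
runPipeline <- function(config) {
    if (is.character(config))
        config <- readRunConfig(config)
    out <- config$outDir
    dir.create(out, recursive = TRUE, showWarnings = FALSE)

    rr <- readRecords(config$recordsFile, config$schema)
    catalog <- readCatalog(config$catalogFile)
    .writeTable(rr$rejects, file.path(out, "rejects.csv"))

    fl <- applyInclusionFilters(rr$records, catalog, config$filters)
    .writeTable(fl$audit, file.path(out, "filter_audit.csv"))

    db <- buildTransactions(fl$records)
    if (nTransactions(db) == 0)
        stop("pipeline aborted at transactions: no retained records")
    exportTransactions(db, file.path(out, "transactions_long.csv"), "long")

    coex <- summarizeCoexposure(db, catalog)
    .writeTable(coex, file.path(out, "agent_coexposure.csv"))

    fi <- mineItemsets(db, minSupport = config$minSupport,
                       minWS = config$minWS,
                       denominator = config$denominator)
    .writeTable(as.data.frame(fi), file.path(out, "itemsets.csv"))
    .writeTable(topItemsets(fi, db, k = config$k, minLen = 2L),
                file.path(out, "top_itemsets.csv"))
    byLen <- do.call(rbind, lapply(2:5, function(L) {
        sel <- fi[which(lengths(itemList(fi)) == L)]
        if (length(sel) == 0) return(NULL)
        topItemsets(sel, db, k = 5L, minLen = L)
    }))
    if (!is.null(byLen))
        .writeTable(byLen, file.path(out, "top_itemsets_by_length.csv"))

    rules <- mineRules(db, minSupport = config$minSupport,
                       minWS = config$minWS,
                       minConfidence = config$minConfidence,
                       denominator = config$denominator)
    .writeTable(as.data.frame(rules), file.path(out, "rules.csv"))
    .writeTable(as.data.frame(rankRules(rules, "confidence",
                                        config$confidenceReportSupport,
                                        config$k)),
                file.path(out, "top_rules_confidence.csv"))
    .writeTable(as.data.frame(rankRules(rules, "lift",
                                        config$liftReportSupport,
                                        config$k)),
                file.path(out, "top_rules_lift.csv"))

    carcDb <- NULL
    if (any(catalog$carcinogen &
            catalog$agent_id %in% agentUniverse(db))) {
        carcDb <- restrictToCarcinogens(db, catalog)
        cfi <- mineItemsets(carcDb, minSupport = config$minSupport,
                            minWS = config$minWS,
                            denominator = config$denominator)
        .writeTable(topItemsets(cfi, carcDb, k = config$k, minLen = 2L),
                    file.path(out, "top_carcinogen_itemsets.csv"))
        cooc <- cooccurrenceMatrix(carcDb, floor = config$cooccurFloor,
                                   exclude = config$cooccurExclude)
        cm <- cooccurrenceCounts(cooc, masked = TRUE)
        write.csv(cm, file.path(out, "carcinogen_cooccurrence.csv"))
    } else {
        cooc <- NULL
    }

    strata <- list()
    for (by in c("sector", "task")) {
        strata[[by]] <- stratifiedMining(
            db, stratBy = by, minStratumWS = config$strataMinWS,
            minSupport = config$minSupport,
            minWS = config$strataMinSupportWS,
            minConfidence = config$minConfidence,
            denominator = config$denominator, k = config$k,
            catalog = catalog)
        for (st in strata[[by]]) {
            d <- file.path(out, "strata", by, st$code)
            dir.create(d, recursive = TRUE, showWarnings = FALSE)
            .writeTable(st$prevalence, file.path(d, "prevalence.csv"))
            .writeTable(st$itemsets, file.path(d, "itemsets.csv"))
            .writeTable(as.data.frame(st$rulesByConfidence),
                        file.path(d, "rules_confidence.csv"))
            .writeTable(as.data.frame(st$rulesByLift),
                        file.path(d, "rules_lift.csv"))
        }
    }

    perWS <- Matrix::rowSums(incidence(db))
    multi <- perWS >= 2
    manifest <- list(
        n_input_rows = nrow(rr$records) + nrow(rr$rejects),
        n_rejected_rows = nrow(rr$rejects),
        n_records_retained = nrow(fl$records),
        n_agents_retained = length(agentUniverse(db)),
        n_ws = nTransactions(db),
        n_multi_ws = nMultiAgent(db),
        median_agents_per_multi_ws =
            if (any(multi)) as.numeric(median(perWS[multi])) else NA,
        max_agents_per_ws = as.numeric(max(perWS)),
        n_unique_mixtures =
            length(unique(.joinItems(agentSets(db)[multi]))),
        n_frequent_itemsets = length(fi),
        n_rules = length(rules),
        n_carcinogen_multi_ws =
            if (!is.null(carcDb)) nMultiAgent(carcDb) else 0L)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    cfg <- config
    cfg$filters$sourceExclusions <- NULL
    jsonlite::write_json(cfg, file.path(out, "config_resolved.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    invisible(list(db = db, fi = fi, rules = rules, carcDb = carcDb,
                   cooccur = cooc, strata = strata, manifest = manifest))
}
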