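#' Restrict a transaction database to carcinogenic agents
#'
#' Intersects every transaction with the set of catalog-flagged
#' carcinogens (IARC group 1, 2A or 2B, as supplied in the catalog) and
#' drops work situations left with no agent. Multi-agent counts are
#' recomputed on the restricted database, so downstream supports use
#' the WS-exposed-to-at-least-two-carcinogens universe.
#'
#' @param db a [TransactionDB-class].
#' @param catalog agent catalog with a logical `carcinogen` column.
#' @return a [TransactionDB-class] over carcinogens only.
#' @export
restrictToCarcinogens <- function(db, catalog) {
    carc <- catalog$agent_id[catalog$carcinogen]
    if (length(carc) == 0)
        stop("no carcinogens flagged in the catalog")
    keep <- intersect(agentUniverse(db), carc)
    if (length(keep) == 0)
        stop("no carcinogenic agent present in the database")
    db[, keep]
}

#' Sector- or task-stratified mining
#'
#' Splits the database by industrial sector or task, analyses each
#' stratum holding at least `minStratumWS` multi-agent work situations,
#' and emits per stratum the four report tables: agent prevalence,
#' frequent itemsets, top rules by confidence and top rules by lift.
#' Within a stratum the effective support floor is
#' `max(ceiling(minSupport * n), minWS)` with `n` the stratum's
#' denominator count — the 0.1%-or-10-WS-whichever-is-greater rule.
#'
#' @param db a [TransactionDB-class].
#' @param stratBy `"sector"` or `"task"`.
#' @param minStratumWS minimum number of multi-agent WS for a stratum
#'   to be analysed (default 100); smaller strata are skipped and
#'   listed in the `skipped` attribute.
#' @param minSupport,minWS,minConfidence,denominator mining parameters
#'   applied within each stratum (defaults: 0.001, floor of 10 WS,
#'   confidence 0.10, multi-agent denominator).
#' @param k rows per report table.
#' @param catalog optional catalog passed to [summarizeCoexposure()].
#' @return named list (one element per analysed stratum) of lists with
#'   `code`, `n_ws`, `n_multi`, `threshold`, `prevalence`, `itemsets`,
#'   `rulesByConfidence`, `rulesByLift`; skipped strata (code and WS
#'   count) in `attr(, "skipped")`.
#' @export
stratifiedMining <- function(db, stratBy = c("sector", "task"),
                             minStratumWS = 100L, minSupport = 0.001,
                             minWS = 10L, minConfidence = 0.1,
                             denominator = c("multi", "all"), k = 10L,
                             catalog = NULL) {
    stratBy <- match.arg(stratBy)
    denominator <- match.arg(denominator)
    codes <- wsInfo(db)[[stratBy]]
    out <- list()
    skipped <- data.frame(code = character(0), n_multi = integer(0),
                          stringsAsFactors = FALSE)
    for (code in sort(unique(codes))) {
        sub <- db[codes == code, ]
        if (nMultiAgent(sub) < minStratumWS) {
            skipped <- rbind(skipped,
                             data.frame(code = code,
                                        n_multi = nMultiAgent(sub)))
            next
        }
        fi <- mineItemsets(sub, minSupport = minSupport, minWS = minWS,
                           denominator = denominator)
        rules <- mineRules(sub, minSupport = minSupport, minWS = minWS,
                           minConfidence = minConfidence,
                           denominator = denominator)
        out[[code]] <- list(
            code = code,
            n_ws = nTransactions(sub),
            n_multi = nMultiAgent(sub),
            threshold = fi@params$threshold,
            prevalence = summarizeCoexposure(sub, catalog),
            itemsets = topItemsets(fi, sub, k = k, minLen = 2L),
            rulesByConfidence = rankRules(rules, "confidence", k = k),
            rulesByLift = rankRules(rules, "lift", k = k))
    }
    attr(out, "skipped") <- skipped
    out
}

#' Pairwise agent co-occurrence matrix
#'
#' Counts, for every agent pair, the number of work situations in which
#' both were detected (the diagonal carries per-agent WS counts). A
#' display floor masks infrequent pairs in exports — they are reported
#' as missing, not as zero — and a configurable exclusion list removes
#' agents whose dominant pairing would mask all other relationships
#' from a plot.
#'
#' @param db a [TransactionDB-class].
#' @param agents agent subset to tabulate (default: whole universe).
#' @param floor minimum WS count for an off-diagonal entry to be shown
#'   (default 10).
#' @param exclude agents removed before counting.
#' @return a [CooccurrenceMatrix-class].
#' @export
cooccurrenceMatrix <- function(db, agents = NULL, floor = 10L,
                               exclude = character()) {
    if (is.null(agents))
        agents <- agentUniverse(db)
    agents <- sort(setdiff(agents, exclude))
    if (length(agents) == 0)
        stop("no agents left after exclusions")
    inc <- incidence(db)[, agents, drop = FALSE]
    m <- as.matrix(Matrix::crossprod(inc * 1))
    storage.mode(m) <- "integer"
    new("CooccurrenceMatrix", counts = m, floor = as.integer(floor),
        excluded = as.character(exclude))
}

#' Heatmap of a co-occurrence matrix
#'
#' Renders the masked co-occurrence counts with darker shades for more
#' frequent coexposures. Requires the `pheatmap` package.
#'
#' @param x a [CooccurrenceMatrix-class].
#' @param filename optional output file (PNG/PDF, by extension).
#' @param ... passed to [pheatmap::pheatmap()].
#' @return the pheatmap object, invisibly.
#' @export
plotCooccurrence <- function(x, filename = NA, ...) {
    if (!requireNamespace("pheatmap", quietly = TRUE))
        stop("plotCooccurrence requires the 'pheatmap' package")
    m <- cooccurrenceCounts(x, masked = TRUE)
    diag(m) <- NA_integer_
    m[is.na(m)] <- 0L
    p <- pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                            filename = filename, ...)
    invisible(p)
}
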