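#' Group retained records into work-situation transactions
#'
#' A work situation (WS) is the unique combination of industrial sector,
#' occupation, task and calendar year. Each WS becomes one transaction
#' whose items are the distinct agents detected among its records —
#' detection status only, regardless of concentration magnitude.
#' Records from different database sources fall into the same WS when
#' their descriptors agree.
#'
#' @param records retained (detected-only) records, e.g. the `records`
#'   element of [applyInclusionFilters()].
#' @return a [TransactionDB-class], rows ordered by
#'   (sector, occupation, task, year) so outputs are byte-stable.
#' @examples
#' rec <- data.frame(
#'     agent_id = c("asbestos", "lead", "wood dust"),
#'     sector = "S1", occupation = "O1", task = c("T1", "T1", "T2"),
#'     year = 2015L, source = "A")
#' buildTransactions(rec)
#' @export
buildTransactions <- function(records) {
    if (nrow(records) == 0) {
        m <- methods::as(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                              x = numeric(0), dims = c(0, 0)),
                         "dgCMatrix")
        return(new("TransactionDB", counts = m,
                   wsInfo = data.frame(sector = character(0),
                                       occupation = character(0),
                                       task = character(0),
                                       year = integer(0),
                                       n_records = integer(0),
                                       sources = character(0))))
    }
    key <- paste(records$sector, records$occupation, records$task,
                 records$year, sep = "\x1f")
    wsKeys <- sort(unique(key))
    agents <- sort(unique(records$agent_id))
    i <- match(key, wsKeys)
    j <- match(records$agent_id, agents)
    m <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                              dims = c(length(wsKeys), length(agents)))
    m <- methods::as(m, "dgCMatrix")
    parts <- do.call(rbind, strsplit(wsKeys, "\x1f", fixed = TRUE))
    rownames(m) <- sprintf("WS%0*d", nchar(length(wsKeys)),
                           seq_along(wsKeys))
    colnames(m) <- agents
    srcs <- vapply(split(records$source, i), function(s)
        paste(sort(unique(s)), collapse = ","), character(1))
    info <- data.frame(sector = parts[, 1], occupation = parts[, 2],
                       task = parts[, 3], year = as.integer(parts[, 4]),
                       n_records = as.integer(tabulate(i, length(wsKeys))),
                       sources = srcs[as.character(seq_along(wsKeys))],
                       row.names = rownames(m), stringsAsFactors = FALSE)
    new("TransactionDB", counts = m, wsInfo = info)
}

#' Per-agent coexposure summary
#'
#' For each agent: the number of detected records, the number of WS in
#' which it was detected, and the proportion of those WS that were also
#' exposed to at least one other agent (the coexposure proportion). The
#' distribution of agents per WS (median, quartiles, maximum) is
#' attached both for all WS and for multi-agent WS.
#'
#' @param db a [TransactionDB-class].
#' @param catalog optional catalog; adds display names and carcinogen
#'   flags to the table.
#' @return `data.frame` with one row per agent plus an
#'   `"agentsPerWS"` attribute holding the distribution summaries.
#' @export
summarizeCoexposure <- function(db, catalog = NULL) {
    stopifnot(nTransactions(db) > 0)
    inc <- incidence(db)
    perWS <- Matrix::rowSums(inc)
    nRec <- Matrix::colSums(recordCounts(db))
    nWS <- Matrix::colSums(inc)
    coex <- Matrix::colSums(inc * (perWS >= 2))
    out <- data.frame(agent_id = colnames(inc),
                      n_records = as.integer(nRec),
                      n_ws = as.integer(nWS),
                      n_ws_coexposed = as.integer(coex),
                      prop_coexposed = as.numeric(coex / nWS),
                      stringsAsFactors = FALSE)
    if (!is.null(catalog)) {
        idx <- match(out$agent_id, catalog$agent_id)
        out$name <- catalog$name[idx]
        out$carcinogen <- catalog$carcinogen[idx]
    }
    out <- out[order(-out$n_ws, out$agent_id), , drop = FALSE]
    rownames(out) <- NULL
    summ <- function(x) c(median = as.numeric(median(x)),
                          q1 = as.numeric(quantile(x, 0.25)),
                          q3 = as.numeric(quantile(x, 0.75)),
                          max = as.numeric(max(x)))
    attr(out, "agentsPerWS") <- list(
        all = summ(perWS),
        multi = if (any(perWS >= 2)) summ(perWS[perWS >= 2]) else NULL)
    out
}

#' Export a transaction database
#'
#' Two interoperable dialects: `"long"` writes one (ws_id, agent_id) row
#' per detected agent; `"basket"` writes one WS per line with its agents
#' joined by `sep`, the common input format of basket-analysis tools.
#'
#' @param db a [TransactionDB-class].
#' @param path output file.
#' @param format `"long"` or `"basket"`.
#' @param sep agent separator for the basket format.
#' @return `path`, invisibly.
#' @export
exportTransactions <- function(db, path, format = c("long", "basket"),
                               sep = "|") {
    format <- match.arg(format)
    sets <- agentSets(db)
    if (format == "long") {
        df <- data.frame(ws_id = rep(names(sets), lengths(sets)),
                         agent_id = unlist(sets, use.names = FALSE),
                         stringsAsFactors = FALSE)
        write.csv(df, path, row.names = FALSE)
    } else {
        writeLines(vapply(sets, paste, character(1), collapse = sep), path)
    }
    invisible(path)
}
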