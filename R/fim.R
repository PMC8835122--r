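.denomCount <- function(db, denominator) {
    switch(denominator, all = nTransactions(db), multi = nMultiAgent(db))
}

## Effective absolute WS-count threshold: the fractional minimum support
## is ceiled (0.1% of 10,547 -> 11 WS) and the absolute floor then
## applies, whichever is the greater. The small epsilon guards against
## decimal fractions that are not binary-representable (0.001 * 5000
## must give 5, not 6).
.effectiveThreshold <- function(minSupport, denom, minWS) {
    max(as.integer(ceiling(minSupport * denom - 1e-9)), as.integer(minWS), 1L)
}

## tid-lists (sorted transaction row indices) per agent
.tidLists <- function(db) {
    m <- Matrix::drop0(recordCounts(db))
    p <- m@p
    lapply(seq_len(ncol(m)), function(j)
        m@i[seq.int(p[j] + 1L, length.out = p[j + 1L] - p[j])] + 1L)
}

#' Support of an agent itemset
#'
#' Exact number of work situations containing every agent of the
#' itemset, and the support relative to the chosen denominator
#' universe: all WS, or only the WS exposed to at least two agents
#' (the convention used for headline coexposure prevalences).
#'
#' @param db a [TransactionDB-class].
#' @param items non-empty character vector of agent ids. Agents absent
#'   from the database yield a count of 0 by contract.
#' @param denominator `"all"` or `"multi"`.
#' @return list with `nWS` (integer count) and `support` (numeric).
#' @examples
#' rec <- data.frame(agent_id = c("a", "b", "a"), sector = "S",
#'     occupation = "O", task = c("T1", "T1", "T2"),
#'     year = 2015L, source = "X")
#' itemsetSupport(buildTransactions(rec), c("a", "b"), "all")
#' @export
itemsetSupport <- function(db, items, denominator = c("all", "multi")) {
    denominator <- match.arg(denominator)
    if (length(items) == 0)
        stop("support of the empty itemset is undefined")
    items <- unique(items)
    n <- if (!all(items %in% agentUniverse(db))) 0L else {
        sub <- incidence(db)[, items, drop = FALSE]
        as.integer(sum(Matrix::rowSums(sub) == length(items)))
    }
    denom <- .denomCount(db, denominator)
    list(nWS = n, support = if (denom > 0) n / denom else NA_real_)
}

#' Mine all frequent agent itemsets (depth-first Eclat)
#'
#' Enumerates every itemset whose WS count reaches the effective
#' absolute threshold `max(ceiling(minSupport * denominator size),
#' minWS)`, by depth-first search over the item lattice with
#' per-item transaction-id lists and set intersection (Eclat). The
#' output is complete (no frequent itemset missed), duplicate-free,
#' carries exact WS counts, and is sorted by descending count, then
#' ascending length, then lexicographic items.
#'
#' Singleton itemsets are included: they are needed for rule metrics
#' and per-agent prevalence even though coexposure reports start at
#' two agents.
#'
#' @param db a [TransactionDB-class].
#' @param minSupport fractional minimum support in (0, 1]; the
#'   analysis default is 0.001 (0.1%).
#' @param minWS absolute floor on the WS count (e.g. 10 for stratified
#'   analyses); the effective threshold is whichever is greater.
#' @param maxLen maximum itemset length (`Inf` for unlimited).
#' @param denominator support denominator universe, see
#'   [itemsetSupport()]. `"multi"` (WS with >= 2 agents) is the
#'   headline-report convention.
#' @return a [FrequentItemsets-class].
#' @export
mineItemsets <- function(db, minSupport = 0.001, minWS = 1L, maxLen = Inf,
                         denominator = c("multi", "all")) {
    denominator <- match.arg(denominator)
    stopifnot(minSupport > 0, minSupport <= 1, minWS >= 1)
    denom <- .denomCount(db, denominator)
    threshold <- .effectiveThreshold(minSupport, denom, minWS)
    params <- list(minSupport = minSupport, minWS = as.integer(minWS),
                   maxLen = maxLen, threshold = threshold)

    empty <- new("FrequentItemsets", items = list(), nWS = integer(0),
                 support = numeric(0), denominator = denominator,
                 denomCount = as.integer(denom), params = params)
    if (nTransactions(db) == 0 || maxLen < 1)
        return(empty)

    tids <- .tidLists(db)
    names(tids) <- agentUniverse(db)
    tids <- tids[lengths(tids) >= threshold]
    if (length(tids) == 0)
        return(empty)
    ## ascending frequency keeps DFS branches short
    tids <- tids[order(lengths(tids), names(tids))]

    acc <- new.env(parent = emptyenv())
    acc$items <- vector("list", 256L)
    acc$n <- integer(256L)
    acc$k <- 0L
    push <- function(set, count) {
        k <- acc$k + 1L
        if (k > length(acc$items)) {
            length(acc$items) <- 2L * length(acc$items)
            length(acc$n) <- 2L * length(acc$n)
        }
        acc$items[[k]] <- set
        acc$n[k] <- count
        acc$k <- k
    }

    dfs <- function(prefix, names_, tids_) {
        for (k in seq_along(tids_)) {
            newTids <- tids_[[k]]
            set <- c(prefix, names_[k])
            push(set, length(newTids))
            if (length(set) < maxLen && k < length(tids_)) {
                restN <- names_[(k + 1L):length(tids_)]
                rest <- lapply(tids_[(k + 1L):length(tids_)],
                               function(t) t[t %in% newTids])
                keep <- lengths(rest) >= threshold
                if (any(keep))
                    dfs(set, restN[keep], rest[keep])
            }
        }
    }
    dfs(character(0), names(tids), unname(tids))

    items <- lapply(acc$items[seq_len(acc$k)], sort)
    nWS <- acc$n[seq_len(acc$k)]
    key <- vapply(items, paste, character(1), collapse = "\x1f")
    ord <- order(-nWS, lengths(items), key)
    new("FrequentItemsets", items = items[ord], nWS = nWS[ord],
        support = if (denom > 0) nWS[ord] / denom else
            rep(NA_real_, length(ord)),
        denominator = denominator, denomCount = as.integer(denom),
        params = params)
}

#' Top-k itemset report with modal sector annotation
#'
#' The k itemsets with the largest WS counts (ties broken by length,
#' then lexicographically), each annotated with the industrial sector
#' having the largest number of exposed WS and that count. When sector
#' codes are absent the annotation falls back to `"n/a"`.
#'
#' @param itemsets a [FrequentItemsets-class].
#' @param db the [TransactionDB-class] the itemsets were mined from.
#' @param k number of rows (fewer are returned if fewer exist).
#' @param minLen keep only itemsets of at least this many agents
#'   (coexposure tables use 2).
#' @param by `"sector"` or `"task"`: the stratification variable used
#'   for the annotation.
#' @return `data.frame` with columns `items`, `n_items`, `n_ws`,
#'   `support`, `modal_stratum`, `modal_stratum_n`.
#' @export
topItemsets <- function(itemsets, db, k = 10L, minLen = 1L,
                        by = c("sector", "task")) {
    by <- match.arg(by)
    keep <- lengths(itemList(itemsets)) >= minLen
    sel <- itemsets[which(keep)]
    idx <- seq_len(min(k, length(sel)))
    sel <- sel[idx]
    inc <- incidence(db)
    strat <- wsInfo(db)[[by]]
    ann <- vapply(itemList(sel), function(items) {
        rows <- Matrix::rowSums(inc[, items, drop = FALSE]) == length(items)
        s <- strat[rows]
        s <- s[!is.na(s) & nzchar(s)]
        if (length(s) == 0)
            return(c("n/a", NA_character_))
        tab <- table(s)
        best <- sort(names(tab)[tab == max(tab)])[1]
        c(best, as.character(tab[[best]]))
    }, character(2))
    out <- as.data.frame(sel)
    out$modal_stratum <- if (length(sel)) ann[1, ] else character(0)
    out$modal_stratum_n <- if (length(sel)) as.integer(ann[2, ]) else integer(0)
    out
}
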