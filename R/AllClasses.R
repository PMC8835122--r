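#' @include AllGenerics.R
NULL

## Internal canonical key for an itemset. "\x1f" (unit separator) cannot
## occur in validated agent tokens, so keys are collision-free.
.itemKey <- function(items) paste(sort(items), collapse = "\x1f")

.keyItems <- function(key) strsplit(key, "\x1f", fixed = TRUE)

.joinItems <- function(items, sep = "|") {
    vapply(items, function(x) paste(sort(x), collapse = sep), character(1))
}

#' TransactionDB: work situations as transactions over detected agents
#'
#' A `TransactionDB` holds the transaction database built from filtered
#' measurement records: one row per work situation (WS), one column per
#' agent. The `counts` slot stores, for each (WS, agent) cell, the number
#' of detected measurement records; an agent belongs to a WS's transaction
#' whenever its count is positive. Per-WS descriptors (sector, occupation,
#' task, year, contributing sources) live in `wsInfo`.
#'
#' @slot counts a [Matrix::dgCMatrix] of detected-record counts,
#'   WS x agents, with WS ids as rownames and agent ids as colnames.
#' @slot wsInfo `data.frame` aligned with the rows of `counts`, with
#'   columns `sector`, `occupation`, `task`, `year`, `n_records`,
#'   `sources`.
#'
#' @seealso [buildTransactions()], [mineItemsets()]
#' @export
setClass("TransactionDB",
    representation(counts = "dgCMatrix", wsInfo = "data.frame"))

setValidity("TransactionDB", function(object) {
    m <- object@counts
    info <- object@wsInfo
    msg <- character(0)
    if (nrow(info) != nrow(m))
        msg <- c(msg, "wsInfo rows must match transaction rows")
    need <- c("sector", "occupation", "task", "year", "n_records", "sources")
    if (!all(need %in% names(info)))
        msg <- c(msg, paste("wsInfo must have columns:",
                            paste(need, collapse = ", ")))
    if (nrow(m) > 0) {
        if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
            msg <- c(msg, "transactions need unique WS ids as rownames")
        if (is.null(colnames(m)) || anyDuplicated(colnames(m)) ||
            any(!nzchar(colnames(m))))
            msg <- c(msg, "agents need unique non-empty ids as colnames")
        if (any(m@x < 0))
            msg <- c(msg, "record counts must be non-negative")
        if (any(Matrix::rowSums(m > 0) < 1))
            msg <- c(msg, "every transaction must contain at least one agent")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn TransactionDB number of work situations (transactions)
#' @param x a `TransactionDB`
#' @export
setMethod("nTransactions", "TransactionDB", function(x) nrow(x@counts))

#' @describeIn TransactionDB number of WS with two or more detected agents
#' @export
setMethod("nMultiAgent", "TransactionDB",
    function(x) sum(Matrix::rowSums(x@counts > 0) >= 2L))

#' @describeIn TransactionDB agent ids present in the database
#' @export
setMethod("agentUniverse", "TransactionDB", function(x) colnames(x@counts))

#' @describeIn TransactionDB per-WS descriptor table
#' @export
setMethod("wsInfo", "TransactionDB", function(x) x@wsInfo)

#' @describeIn TransactionDB detected-record counts (WS x agents)
#' @export
setMethod("recordCounts", "TransactionDB", function(x) x@counts)

#' @describeIn TransactionDB logical incidence matrix (WS x agents)
#' @export
setMethod("incidence", "TransactionDB", function(x) x@counts > 0)

#' @describeIn TransactionDB transactions as a list of agent-id vectors
#' @export
setMethod("agentSets", "TransactionDB", function(x) {
    inc <- x@counts > 0
    ag <- colnames(inc)
    sets <- apply(inc, 1L, function(r) sort(ag[r]), simplify = FALSE)
    names(sets) <- rownames(inc)
    sets
})

setMethod("show", "TransactionDB", function(object) {
    n <- nTransactions(object)
    cat("TransactionDB:", n, "work situations,",
        length(agentUniverse(object)), "agents\n")
    if (n > 0)
        cat("  multi-agent WS:", nMultiAgent(object),
            sprintf("(%.1f%%)\n", 100 * nMultiAgent(object) / n))
})

#' Subset a TransactionDB
#'
#' Row subsetting keeps the selected work situations. Column subsetting
#' restricts the agent universe; WS emptied by the restriction are
#' dropped (their remaining transaction would be empty).
#'
#' @param x a `TransactionDB`
#' @param i,j row (WS) and column (agent) indices
#' @param ... ignored
#' @param drop ignored (always `FALSE`)
#' @export
setMethod("[", "TransactionDB", function(x, i, j, ..., drop = FALSE) {
    m <- x@counts
    info <- x@wsInfo
    if (!missing(j)) m <- m[, j, drop = FALSE]
    if (!missing(i)) {
        m <- m[i, , drop = FALSE]
        info <- info[i, , drop = FALSE]
    }
    keep <- Matrix::rowSums(m > 0) >= 1L
    new("TransactionDB", counts = m[keep, , drop = FALSE],
        wsInfo = info[keep, , drop = FALSE])
})

#' FrequentItemsets: mined agent itemsets with exact WS counts
#'
#' Result container of [mineItemsets()]. Each element is an agent set
#' together with the exact number of work situations containing all of
#' its agents and the support relative to the chosen denominator
#' universe (`"all"` WS or `"multi"`, the WS exposed to at least two
#' agents).
#'
#' @slot items list of sorted character vectors of agent ids.
#' @slot nWS integer WS count per itemset.
#' @slot support numeric support per itemset (`nWS / denomCount`).
#' @slot denominator `"all"` or `"multi"`.
#' @slot denomCount integer size of the denominator universe.
#' @slot params mining parameters used.
#' @export
setClass("FrequentItemsets",
    representation(items = "list", nWS = "integer", support = "numeric",
                   denominator = "character", denomCount = "integer",
                   params = "list"))

setValidity("FrequentItemsets", function(object) {
    n <- length(object@items)
    msg <- character(0)
    if (length(object@nWS) != n || length(object@support) != n)
        msg <- c(msg, "items, nWS and support must have equal length")
    if (!object@denominator %in% c("all", "multi"))
        msg <- c(msg, "denominator must be 'all' or 'multi'")
    if (n > 0 && any(object@nWS < 0))
        msg <- c(msg, "nWS must be non-negative")
    if (n > 0 && object@denomCount > 0 &&
        any(abs(object@support * object@denomCount - object@nWS) > 1e-8))
        msg <- c(msg, "support * denomCount must equal nWS")
    if (length(msg)) msg else TRUE
})

#' @describeIn FrequentItemsets number of itemsets
#' @param x a `FrequentItemsets`
#' @export
setMethod("length", "FrequentItemsets", function(x) length(x@items))

#' @describeIn FrequentItemsets the itemsets as a list of agent vectors
#' @export
setMethod("itemList", "FrequentItemsets", function(x) x@items)

#' @describeIn FrequentItemsets WS count per itemset
#' @export
setMethod("wsCount", "FrequentItemsets", function(x) x@nWS)

#' @describeIn FrequentItemsets support per itemset
#' @export
setMethod("supportValues", "FrequentItemsets", function(x) x@support)

#' @describeIn FrequentItemsets denominator kind (`"all"`/`"multi"`)
#' @export
setMethod("denominatorKind", "FrequentItemsets", function(x) x@denominator)

#' @describeIn FrequentItemsets denominator universe size
#' @export
setMethod("denominatorCount", "FrequentItemsets", function(x) x@denomCount)

#' @param i index
#' @describeIn FrequentItemsets subset, keeping metadata
#' @export
setMethod("[", "FrequentItemsets", function(x, i, j, ..., drop = FALSE) {
    initialize(x, items = x@items[i], nWS = x@nWS[i], support = x@support[i])
})

setMethod("show", "FrequentItemsets", function(object) {
    cat("FrequentItemsets:", length(object), "itemsets",
        sprintf("(denominator: %s WS, n = %d)\n",
                object@denominator, object@denomCount))
    if (length(object) > 0) {
        k <- min(5L, length(object))
        df <- as.data.frame(object)[seq_len(k), , drop = FALSE]
        print(df, row.names = FALSE)
        if (length(object) > k) cat("  ...", length(object) - k, "more\n")
    }
})

#' @describeIn FrequentItemsets as a data.frame (items "|"-joined)
#' @param row.names,optional,... passed on conventions, ignored
#' @export
setMethod("as.data.frame", "FrequentItemsets",
    function(x, row.names = NULL, optional = FALSE, ...) {
        data.frame(items = .joinItems(x@items),
                   n_items = lengths(x@items),
                   n_ws = x@nWS,
                   support = x@support,
                   stringsAsFactors = FALSE)
    })

#' AssociationRules: scored antecedent/consequent rules
#'
#' Result container of [mineRules()]. Each rule A -> C has disjoint
#' non-empty antecedent and consequent itemsets and carries support
#' (of A union C), confidence, lift and the confidence of the
#' complementary rule C -> A.
#'
#' @slot lhs,rhs lists of sorted agent-id vectors (antecedent,
#'   consequent).
#' @slot nWS integer WS count of A union C.
#' @slot support,confidence,lift,confidenceComplement numeric metrics.
#' @slot denominator,denomCount,params as in [FrequentItemsets-class].
#' @export
setClass("AssociationRules",
    representation(lhs = "list", rhs = "list", nWS = "integer",
                   support = "numeric", confidence = "numeric",
                   lift = "numeric", confidenceComplement = "numeric",
                   denominator = "character", denomCount = "integer",
                   params = "list"))

setValidity("AssociationRules", function(object) {
    n <- length(object@lhs)
    msg <- character(0)
    lens <- c(length(object@rhs), length(object@nWS), length(object@support),
              length(object@confidence), length(object@lift),
              length(object@confidenceComplement))
    if (any(lens != n))
        msg <- c(msg, "all rule slots must have equal length")
    if (n > 0) {
        disjoint <- mapply(function(a, c) length(intersect(a, c)) == 0,
                           object@lhs, object@rhs)
        if (!all(disjoint))
            msg <- c(msg, "antecedent and consequent must be disjoint")
        if (any(lengths(object@lhs) == 0) || any(lengths(object@rhs) == 0))
            msg <- c(msg, "antecedent and consequent must be non-empty")
        if (any(object@confidence < -1e-12 | object@confidence > 1 + 1e-12))
            msg <- c(msg, "confidence must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn AssociationRules number of rules
#' @param x an `AssociationRules`
#' @export
setMethod("length", "AssociationRules", function(x) length(x@lhs))

#' @describeIn AssociationRules antecedent itemsets
#' @export
setMethod("antecedents", "AssociationRules", function(x) x@lhs)

#' @describeIn AssociationRules consequent itemsets
#' @export
setMethod("consequents", "AssociationRules", function(x) x@rhs)

#' @describeIn AssociationRules WS count of the joint itemset
#' @export
setMethod("wsCount", "AssociationRules", function(x) x@nWS)

#' @describeIn AssociationRules support values
#' @export
setMethod("supportValues", "AssociationRules", function(x) x@support)

#' @describeIn AssociationRules denominator kind
#' @export
setMethod("denominatorKind", "AssociationRules", function(x) x@denominator)

#' @describeIn AssociationRules denominator universe size
#' @export
setMethod("denominatorCount", "AssociationRules", function(x) x@denomCount)

#' @param i index
#' @describeIn AssociationRules subset, keeping metadata
#' @export
setMethod("[", "AssociationRules", function(x, i, j, ..., drop = FALSE) {
    initialize(x, lhs = x@lhs[i], rhs = x@rhs[i], nWS = x@nWS[i],
               support = x@support[i], confidence = x@confidence[i],
               lift = x@lift[i],
               confidenceComplement = x@confidenceComplement[i])
})

setMethod("show", "AssociationRules", function(object) {
    cat("AssociationRules:", length(object), "rules",
        sprintf("(denominator: %s WS, n = %d)\n",
                object@denominator, object@denomCount))
    if (length(object) > 0) {
        k <- min(5L, length(object))
        print(as.data.frame(object)[seq_len(k), , drop = FALSE],
              row.names = FALSE)
        if (length(object) > k) cat("  ...", length(object) - k, "more\n")
    }
})

#' @describeIn AssociationRules as a data.frame
#' @param row.names,optional,... passed on conventions, ignored
#' @export
setMethod("as.data.frame", "AssociationRules",
    function(x, row.names = NULL, optional = FALSE, ...) {
        data.frame(antecedent = .joinItems(x@lhs),
                   consequent = .joinItems(x@rhs),
                   n_ws = x@nWS,
                   support = x@support,
                   confidence = x@confidence,
                   lift = x@lift,
                   confidence_complement = x@confidenceComplement,
                   stringsAsFactors = FALSE)
    })

#' CooccurrenceMatrix: pairwise agent co-occurrence over work situations
#'
#' Symmetric matrix of WS counts: off-diagonal entry (i, j) is the number
#' of WS in which both agents were detected; the diagonal holds per-agent
#' WS counts. A display floor masks (as `NA`, never zero) off-diagonal
#' entries below the floor in exports; raw counts are retained.
#'
#' @slot counts symmetric integer matrix with agent ids as dimnames.
#' @slot floor integer display floor for off-diagonal entries.
#' @slot excluded agents excluded before counting.
#' @export
setClass("CooccurrenceMatrix",
    representation(counts = "matrix", floor = "integer",
                   excluded = "character"))

setValidity("CooccurrenceMatrix", function(object) {
    m <- object@counts
    msg <- character(0)
    if (nrow(m) != ncol(m) || !isTRUE(all.equal(m, t(m))))
        msg <- c(msg, "counts must be a symmetric square matrix")
    if (is.null(rownames(m)))
        msg <- c(msg, "counts needs agent ids as dimnames")
    d <- diag(m)
    off <- m; diag(off) <- 0
    if (nrow(m) > 1 && any(off > outer(d, d, pmin)))
        msg <- c(msg, "pair counts cannot exceed either marginal count")
    if (length(msg)) msg else TRUE
})

#' @describeIn CooccurrenceMatrix co-occurrence counts; with
#'   `masked = TRUE` (the default, used for exports) off-diagonal
#'   entries below the floor are `NA`.
#' @param x a `CooccurrenceMatrix`
#' @param masked mask sub-floor off-diagonal entries as `NA`?
#' @export
setMethod("cooccurrenceCounts", "CooccurrenceMatrix",
    function(x, masked = TRUE) {
        m <- x@counts
        if (masked && x@floor > 0L) {
            mask <- m < x@floor
            diag(mask) <- FALSE
            m[mask] <- NA_integer_
        }
        m
    })

setMethod("show", "CooccurrenceMatrix", function(object) {
    cat("CooccurrenceMatrix:", nrow(object@counts), "agents, floor",
        object@floor, "WS")
    if (length(object@excluded))
        cat(", excluded:", paste(object@excluded, collapse = ", "))
    cat("\n")
})
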