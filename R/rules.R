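#' Confidence of an association rule
#'
#' Proportion of work situations containing the antecedent that also
#' contain the consequent: `nWS(A u C) / nWS(A)`. Being a ratio of
#' counts, confidence does not depend on the denominator universe.
#'
#' @param db a [TransactionDB-class].
#' @param lhs,rhs non-empty, disjoint agent-id vectors (antecedent and
#'   consequent).
#' @return numeric confidence in `[0, 1]`.
#' @export
ruleConfidence <- function(db, lhs, rhs) {
    stopifnot(length(lhs) > 0, length(rhs) > 0,
              length(intersect(lhs, rhs)) == 0)
    nA <- itemsetSupport(db, lhs, "all")$nWS
    if (nA == 0)
        stop("confidence undefined: antecedent occurs in no transaction")
    itemsetSupport(db, c(lhs, rhs), "all")$nWS / nA
}

#' Lift of an association rule
#'
#' Ratio of the observed rule support to its expected support were
#' antecedent and consequent independent:
#' `support(A u C) / (support(A) * support(C))`, equivalently
#' `confidence(A -> C) / support(C)`. Lift 1 indicates independence;
#' values above 1 indicate positive dependence. Lift is symmetric in
#' antecedent and consequent.
#'
#' @inheritParams ruleConfidence
#' @param denominator support denominator universe (`"all"` or
#'   `"multi"`); lift depends on it through the marginal supports.
#' @return non-negative numeric lift.
#' @export
ruleLift <- function(db, lhs, rhs, denominator = c("all", "multi")) {
    denominator <- match.arg(denominator)
    stopifnot(length(lhs) > 0, length(rhs) > 0,
              length(intersect(lhs, rhs)) == 0)
    denom <- .denomCount(db, denominator)
    nA <- itemsetSupport(db, lhs, denominator)$nWS
    nC <- itemsetSupport(db, rhs, denominator)$nWS
    if (nA == 0 || nC == 0)
        stop("lift undefined: zero marginal support")
    nAC <- itemsetSupport(db, c(lhs, rhs), denominator)$nWS
    (nAC * denom) / (nA * nC)
}

#' Mine association rules from frequent itemsets
#'
#' Every frequent itemset of two or more agents is split into all
#' ordered pairs of non-empty disjoint antecedent/consequent itemsets
#' covering it. A rule is emitted when its support (the joint
#' itemset's) clears the support threshold — guaranteed by frequency —
#' and its confidence reaches `minConfidence`. Each rule carries the
#' confidence of its complementary rule (consequent -> antecedent)
#' whether or not the complement itself passes the confidence floor.
#' Rules with a zero marginal support cannot arise (both sides of an
#' emitted rule are frequent), so lift is always defined.
#'
#' @inheritParams mineItemsets
#' @param minConfidence minimum confidence in `[0, 1]` applied to the
#'   rule's own confidence only (analysis default 0.10).
#' @param maxConsequent maximum consequent size (`Inf` enumerates all
#'   bipartitions; published tables conventionally show single-agent
#'   consequents).
#' @return an [AssociationRules-class], sorted by descending support
#'   then antecedent/consequent lexicographically.
#' @export
mineRules <- function(db, minSupport = 0.001, minWS = 1L,
                      minConfidence = 0.1,
                      denominator = c("multi", "all"),
                      maxConsequent = Inf) {
    denominator <- match.arg(denominator)
    stopifnot(minConfidence >= 0, minConfidence <= 1)
    fi <- mineItemsets(db, minSupport = minSupport, minWS = minWS,
                       maxLen = Inf, denominator = denominator)
    denom <- denominatorCount(fi)
    params <- c(fi@params, list(minConfidence = minConfidence,
                                maxConsequent = maxConsequent))

    lookup <- new.env(parent = emptyenv(), size = max(16L, length(fi)))
    its <- itemList(fi)
    ns <- wsCount(fi)
    for (k in seq_along(its))
        assign(.itemKey(its[[k]]), ns[k], envir = lookup)
    getN <- function(items) get(.itemKey(items), envir = lookup)

    lhs <- list(); rhs <- list()
    nWS <- integer(0); conf <- numeric(0); lft <- numeric(0)
    confC <- numeric(0)
    for (k in seq_along(its)) {
        I <- its[[k]]
        m <- length(I)
        if (m < 2) next
        nI <- ns[k]
        for (mask in seq_len(2L^m - 2L)) {
            inA <- as.logical(bitwAnd(mask, 2L^(seq_len(m) - 1L)))
            A <- I[inA]; C <- I[!inA]
            if (length(C) > maxConsequent) next
            nA <- getN(A); nC <- getN(C)
            cf <- nI / nA
            if (cf < minConfidence - 1e-12) next
            lhs[[length(lhs) + 1L]] <- A
            rhs[[length(rhs) + 1L]] <- C
            nWS <- c(nWS, nI)
            conf <- c(conf, cf)
            lft <- c(lft, (nI * denom) / (nA * nC))
            confC <- c(confC, nI / nC)
        }
    }
    supp <- if (denom > 0) nWS / denom else rep(NA_real_, length(nWS))
    ord <- order(-nWS, .joinItems(lhs, "\x1f"), .joinItems(rhs, "\x1f"))
    new("AssociationRules", lhs = lhs[ord], rhs = rhs[ord],
        nWS = as.integer(nWS[ord]), support = supp[ord],
        confidence = conf[ord], lift = lft[ord],
        confidenceComplement = confC[ord],
        denominator = denominator, denomCount = as.integer(denom),
        params = params)
}

#' Rank rules for reporting
#'
#' Applies a report-level support floor, sorts by the chosen metric
#' (descending; ties broken by descending support, then antecedent and
#' consequent lexicographically) and truncates to the top k. Lift
#' tables conventionally carry both the rule's confidence and its
#' complement's, as returned by [as.data.frame()] on the result.
#'
#' @param rules an [AssociationRules-class].
#' @param by ranking metric, `"confidence"` or `"lift"`.
#' @param minSupportReport report-level support floor (e.g. 0.05 for
#'   confidence tables, 0.01 for lift tables).
#' @param k number of rules to keep.
#' @return an [AssociationRules-class] with at most `k` rules.
#' @export
rankRules <- function(rules, by = c("confidence", "lift"),
                      minSupportReport = 0, k = 10L) {
    by <- match.arg(by)
    keep <- which(rules@support >= minSupportReport - 1e-12)
    sel <- rules[keep]
    metric <- slot(sel, by)
    ord <- order(-metric, -sel@support, .joinItems(sel@lhs, "\x1f"),
                 .joinItems(sel@rhs, "\x1f"))
    sel[ord[seq_len(min(k, length(ord)))]]
}
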