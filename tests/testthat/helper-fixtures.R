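## Shared fixtures: the four-WS textbook transaction set, random record
## generators, and brute-force oracles kept deliberately independent of
## the package's Matrix-based counting (they scan plain list-of-sets).

toyRecords <- function() {
    ws <- list(
        list(task = "T1", agents = c("asbestos", "lead")),
        list(task = "T2", agents = "wood dust"),
        list(task = "T3", agents = c("benzene", "ethanol", "lead")),
        list(task = "T4", agents = c("asbestos", "chromium", "lead")))
    do.call(rbind, lapply(ws, function(w)
        data.frame(agent_id = w$agents, sector = "S1", occupation = "O1",
                   task = w$task, year = 2015L, source = "SRC_A",
                   stringsAsFactors = FALSE)))
}

toyDB <- function() buildTransactions(toyRecords())

toyCatalog <- function(carcinogens = c("asbestos", "benzene", "lead",
                                       "chromium")) {
    ag <- c("asbestos", "benzene", "chromium", "ethanol", "lead",
            "wood dust")
    data.frame(agent_id = ag, name = ag, carcinogen = ag %in% carcinogens,
               excluded = FALSE, exclusion_reason = "",
               stringsAsFactors = FALSE)
}

## random transaction database: each WS draws a non-empty agent subset
randomRecords <- function(nAgents, nTrans, density = 0.35) {
    agents <- sprintf("ag%02d", seq_len(nAgents))
    rows <- lapply(seq_len(nTrans), function(i) {
        picked <- agents[runif(nAgents) < density]
        if (length(picked) == 0) picked <- sample(agents, 1)
        data.frame(agent_id = picked, sector = sample(c("SA", "SB"), 1),
                   occupation = sprintf("O%04d", i), task = "T1",
                   year = 2015L, source = "X", stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

randomDB <- function(nAgents, nTrans, density = 0.35)
    buildTransactions(randomRecords(nAgents, nTrans, density))

## --- independent oracles -------------------------------------------------

## containment count by direct scan over list-of-sets
bruteCount <- function(sets, items)
    sum(vapply(sets, function(s) all(items %in% s), logical(1)))

## all itemsets with count >= threshold, by exhaustive subset enumeration
bruteItemsets <- function(db, threshold, maxLen = Inf) {
    sets <- agentSets(db)
    universe <- sort(unique(unlist(sets)))
    out <- list()
    for (k in seq_len(min(length(universe), maxLen))) {
        combos <- combn(universe, k, simplify = FALSE)
        for (cm in combos) {
            n <- bruteCount(sets, cm)
            if (n >= threshold)
                out[[paste(cm, collapse = "\x1f")]] <- n
        }
    }
    out
}

## all rules from exhaustive bipartition enumeration of frequent itemsets
bruteRules <- function(db, threshold, minConfidence) {
    freq <- bruteItemsets(db, threshold)
    sets <- agentSets(db)
    keys <- character(0); conf <- numeric(0)
    for (key in names(freq)) {
        items <- strsplit(key, "\x1f", fixed = TRUE)[[1]]
        m <- length(items)
        if (m < 2) next
        for (mask in seq_len(2^m - 2)) {
            inA <- as.logical(bitwAnd(mask, 2^(seq_len(m) - 1)))
            A <- items[inA]; C <- items[!inA]
            cf <- freq[[key]] / bruteCount(sets, A)
            if (cf >= minConfidence - 1e-12) {
                keys <- c(keys, paste(paste(sort(A), collapse = "\x1f"),
                                      paste(sort(C), collapse = "\x1f"),
                                      sep = " => "))
                conf <- c(conf, cf)
            }
        }
    }
    stats::setNames(conf, keys)
}

itemsetKeys <- function(fi)
    vapply(itemList(fi), paste, character(1), collapse = "\x1f")

ruleKeys <- function(rules)
    paste(vapply(antecedents(rules), function(x)
              paste(sort(x), collapse = "\x1f"), character(1)),
          vapply(consequents(rules), function(x)
              paste(sort(x), collapse = "\x1f"), character(1)),
          sep = " => ")
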