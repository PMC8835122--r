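#' Define a process profile for the synthetic generator
#'
#' A process profile emulates a work process (e.g. solvent-based
#' coating, arc welding) that exposes workers to a characteristic set
#' of agents: each WS drawn from the profile emits each of its agents
#' independently with the given probability, and occurs in sectors and
#' tasks drawn from the profile's code pools.
#'
#' @param id profile identifier.
#' @param agents agent ids the profile can emit.
#' @param probs per-agent emission probabilities in (0, 1].
#' @param weight relative frequency of the profile among WS.
#' @param sectors,tasks code pools the profile's WS are assigned to.
#' @return a `list` describing the profile.
#' @export
synthProfile <- function(id, agents, probs, weight, sectors, tasks) {
    stopifnot(length(agents) == length(probs), length(agents) > 0,
              all(probs > 0), all(probs <= 1), weight > 0,
              length(sectors) > 0, length(tasks) > 0)
    list(id = id, agents = agents, probs = probs, weight = weight,
         sectors = sectors, tasks = tasks)
}

.defaultProfiles <- function() {
    list(
        synthProfile("coating_solvents", paste0("A", sprintf("%02d", 1:4)),
                     c(0.90, 0.85, 0.80, 0.60), 0.200,
                     c("S01", "S02"), c("T01", "T02")),
        synthProfile("degreasing", paste0("A", sprintf("%02d", 3:5)),
                     c(0.70, 0.75, 0.80), 0.150,
                     c("S02", "S03"), c("T03", "T04")),
        synthProfile("welding_metals", paste0("A", sprintf("%02d", 6:10)),
                     c(0.90, 0.85, 0.80, 0.70, 0.50), 0.150,
                     c("S04", "S05"), c("T05", "T06")),
        synthProfile("silica_pair", paste0("A", sprintf("%02d", 11:12)),
                     c(0.95, 0.90), 0.120,
                     c("S06"), c("T07")),
        synthProfile("printing", paste0("A", sprintf("%02d", 13:15)),
                     c(0.60, 0.60, 0.60), 0.120,
                     c("S07", "S08"), c("T08", "T09")),
        synthProfile("plastics", paste0("A", sprintf("%02d", 16:19)),
                     c(0.80, 0.50, 0.50, 0.40), 0.100,
                     c("S09"), c("T10")),
        synthProfile("maintenance_misc", paste0("A", sprintf("%02d", 20:24)),
                     rep(0.35, 5), 0.155,
                     c("S10", "S11"), c("T11", "T12")),
        synthProfile("rare_specialty", paste0("A", sprintf("%02d", 25:28)),
                     rep(0.50, 4), 0.005,
                     c("S12"), c("T13")))
}

#' Configuration of the synthetic corpus generator
#'
#' The defaults define the reference validation corpus: 5,000 work
#' situations drawn from 8 process profiles over 28 agents, a
#' per-record censoring (below-LOQ) probability of 0.48, records per
#' emitted (WS, agent) distributed as 1 + Poisson(2) (mean 3), study
#' years 2010-2019, and two source tags mixed 72/28. Everything is
#' deterministic given `seed`.
#'
#' @param nWS number of work situations to plant.
#' @param profiles list of [synthProfile()] definitions; weights are
#'   normalized to sum to 1.
#' @param censorProb probability that any single measurement falls
#'   below its LOQ; scalar, or named per-agent vector.
#' @param recordsLambda Poisson rate of extra records per emitted
#'   (WS, agent); the count is `1 + Poisson(recordsLambda)`.
#' @param years calendar years sampled uniformly per WS.
#' @param sources,sourceWeights source tags and their mixing weights.
#' @param carcinogens agent ids flagged as carcinogens in the
#'   generated catalog.
#' @param seed integer seed; identical configs and seeds reproduce
#'   byte-identical output.
#' @return a `SynthConfig` list.
#' @export
synthConfig <- function(nWS = 5000L, profiles = .defaultProfiles(),
                        censorProb = 0.48, recordsLambda = 2,
                        years = 2010:2019,
                        sources = c("SRC_A", "SRC_B"),
                        sourceWeights = c(0.72, 0.28),
                        carcinogens = c("A03", paste0("A", sprintf("%02d", 6:12)),
                                        paste0("A", sprintf("%02d", 25:28)),
                                        "A13"),
                        seed = 1L) {
    stopifnot(nWS >= 1, length(profiles) >= 1,
              all(censorProb >= 0), all(censorProb <= 1),
              recordsLambda >= 0, length(sources) == length(sourceWeights))
    w <- vapply(profiles, `[[`, numeric(1), "weight")
    for (k in seq_along(profiles))
        profiles[[k]]$weight <- w[k] / sum(w)
    list(nWS = as.integer(nWS), profiles = profiles,
         censorProb = censorProb, recordsLambda = recordsLambda,
         years = as.integer(years), sources = sources,
         sourceWeights = sourceWeights / sum(sourceWeights),
         carcinogens = carcinogens, seed = as.integer(seed))
}

.censorOf <- function(config, agent) {
    cp <- config$censorProb
    if (length(cp) == 1 && is.null(names(cp))) rep(cp, length(agent))
    else ifelse(agent %in% names(cp), cp[agent], NA_real_)
}

#' WS-level detection probability of an agent under the generator
#'
#' An agent is detected in a WS when at least one of its records clears
#' the LOQ. With per-record censoring probability c and a record count
#' of `1 + Poisson(lambda)`, the WS-level detection probability is
#' `1 - c * exp(-lambda * (1 - c))`.
#'
#' @param config a [synthConfig()].
#' @param agent agent id(s).
#' @return numeric detection probabilities.
#' @export
expectedDetection <- function(config, agent) {
    cc <- .censorOf(config, agent)
    1 - cc * exp(-config$recordsLambda * (1 - cc))
}

#' Closed-form expected support of an itemset under the generator
#'
#' Mixture expectation over profiles: within a profile, agents are
#' emitted and detected independently, so the probability that a WS
#' drawn from profile p contains the whole itemset is the product of
#' the members' emission-times-detection probabilities (zero when the
#' profile does not emit some member). Summed over profiles with their
#' weights, this gives the expected WS-level support relative to all
#' planted WS, used as the recovery target for the miner.
#'
#' @param items agent-id vector.
#' @param config a [synthConfig()].
#' @return expected support in `[0, 1]`.
#' @export
expectedSupport <- function(items, config) {
    items <- unique(items)
    d <- expectedDetection(config, items)
    total <- 0
    for (p in config$profiles) {
        idx <- match(items, p$agents)
        if (anyNA(idx)) next
        total <- total + p$weight * prod(p$probs[idx] * d)
    }
    total
}

#' Generate a synthetic measurement corpus with known ground truth
#'
#' Draws `nWS` work situations from the configured process-profile
#' mixture; each WS gets a sector and task from its profile's pools, a
#' uniform study year, and a unique occupation token (occupation codes
#' index the workplace, guaranteeing a one-to-one mapping between
#' planted WS and transaction keys). Each emitted (WS, agent) produces
#' `1 + Poisson(lambda)` measurement records; each record falls below
#' its LOQ with probability `censorProb`, implemented by drawing the
#' concentration on the appropriate side of a unit LOQ so that
#' [flagDetected()] remains the single censoring decision point.
#'
#' @param config a [synthConfig()].
#' @return list with `records` (data.frame in the [readRecords()]
#'   default dialect), `assignment` (planted WS-to-profile table),
#'   `catalog` (agent catalog with the configured carcinogen flags)
#'   and `config`.
#' @export
generateCorpus <- function(config = synthConfig()) {
    set.seed(config$seed, kind = "Mersenne-Twister")
    np <- length(config$profiles)
    pw <- vapply(config$profiles, `[[`, numeric(1), "weight")
    prof <- sample.int(np, config$nWS, replace = TRUE, prob = pw)

    sector <- character(config$nWS)
    task <- character(config$nWS)
    for (k in seq_len(np)) {
        idx <- which(prof == k)
        p <- config$profiles[[k]]
        sector[idx] <- sample(p$sectors, length(idx), replace = TRUE)
        task[idx] <- sample(p$tasks, length(idx), replace = TRUE)
    }
    occupation <- sprintf("O%05d", seq_len(config$nWS))
    year <- sample(config$years, config$nWS, replace = TRUE)

    wsI <- integer(0); agentI <- character(0)
    for (k in seq_len(np)) {
        idx <- which(prof == k)
        p <- config$profiles[[k]]
        for (a in seq_along(p$agents)) {
            hit <- idx[runif(length(idx)) < p$probs[a]]
            wsI <- c(wsI, hit)
            agentI <- c(agentI, rep(p$agents[a], length(hit)))
        }
    }
    ord <- order(wsI, agentI)
    wsI <- wsI[ord]; agentI <- agentI[ord]

    nrec <- 1L + rpois(length(wsI), config$recordsLambda)
    rw <- rep(wsI, nrec)
    ra <- rep(agentI, nrec)
    n <- length(rw)
    cens <- runif(n) < .censorOf(config, ra)
    loq <- rep(1, n)
    conc <- ifelse(cens, runif(n, 0, 1), 1 + runif(n, 0, 9))
    src <- sample(config$sources, n, replace = TRUE,
                  prob = config$sourceWeights)

    records <- data.frame(agent_id = ra,
                          sector = sector[rw],
                          occupation = occupation[rw],
                          task = task[rw],
                          year = year[rw],
                          concentration = conc,
                          loq = loq,
                          source = src,
                          stringsAsFactors = FALSE)

    allAgents <- sort(unique(unlist(lapply(config$profiles, `[[`, "agents"))))
    catalog <- data.frame(agent_id = allAgents,
                          name = allAgents,
                          carcinogen = allAgents %in% config$carcinogens,
                          excluded = FALSE,
                          exclusion_reason = "",
                          stringsAsFactors = FALSE)
    assignment <- data.frame(ws = seq_len(config$nWS),
                             profile = vapply(config$profiles, `[[`,
                                              character(1), "id")[prof],
                             sector = sector, occupation = occupation,
                             task = task, year = year,
                             stringsAsFactors = FALSE)
    list(records = records, assignment = assignment, catalog = catalog,
         config = config)
}

#' Write a synthetic corpus to delimited files
#'
#' Writes `records.csv` (the measurement-record dialect read by
#' [readRecords()]), `catalog.csv`, and the ground-truth tables
#' `truth_assignment.csv` and `truth_profiles.csv`.
#'
#' @param corpus result of [generateCorpus()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCorpus <- function(corpus, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(corpus$records, file.path(dir, "records.csv"),
              row.names = FALSE)
    write.csv(corpus$catalog, file.path(dir, "catalog.csv"),
              row.names = FALSE)
    write.csv(corpus$assignment, file.path(dir, "truth_assignment.csv"),
              row.names = FALSE)
    profs <- do.call(rbind, lapply(corpus$config$profiles, function(p)
        data.frame(profile = p$id, agent_id = p$agents,
                   emission_prob = p$probs, weight = p$weight,
                   stringsAsFactors = FALSE)))
    write.csv(profs, file.path(dir, "truth_profiles.csv"),
              row.names = FALSE)
    invisible(dir)
}
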