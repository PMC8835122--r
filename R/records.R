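#' Declare the column layout of a measurement-record file
#'
#' Measurement files come as delimited text with one row per personal air
#' sample. Column names vary between extracts, so the mapping from the
#' canonical fields to the file's column names is declared here. Exactly
#' one of two detection dialects is used per file: `mode = "loq"` carries
#' a measured concentration and a limit of quantification (LOQ), while
#' `mode = "flag"` carries a pre-computed detected/censored flag.
#'
#' @param agent,sector,occupation,task,year,source column names of the
#'   descriptor fields.
#' @param concentration,loq column names used when `mode = "loq"`.
#' @param detected column name used when `mode = "flag"`.
#' @param mode detection dialect of the file.
#' @return a list usable as the `schema` argument of [readRecords()].
#' @export
recordSchema <- function(agent = "agent_id", sector = "sector",
                         occupation = "occupation", task = "task",
                         year = "year", concentration = "concentration",
                         loq = "loq", detected = "detected",
                         source = "source", mode = c("loq", "flag")) {
    mode <- match.arg(mode)
    list(agent = agent, sector = sector, occupation = occupation,
         task = task, year = year, concentration = concentration,
         loq = loq, detected = detected, source = source, mode = mode)
}

.readDelim <- function(path) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    read.csv(path, sep = sep, colClasses = "character",
             check.names = FALSE, stringsAsFactors = FALSE)
}

.parseLogical <- function(x) {
    lx <- tolower(trimws(x))
    out <- rep(NA, length(x))
    out[lx %in% c("true", "t", "1", "yes")] <- TRUE
    out[lx %in% c("false", "f", "0", "no")] <- FALSE
    out
}

#' Read and validate measurement records
#'
#' Reads a delimited file (comma for `.csv`, tab otherwise) of personal
#' air-measurement records and validates every row. Malformed rows are
#' never silently dropped: they are returned in a reject table with the
#' offending row number and a reason code (`missing_descriptor`,
#' `bad_numeric`, `bad_value`, `missing_detection`).
#'
#' @param path file to read.
#' @param schema column mapping from [recordSchema()].
#' @return a list with elements `records` (validated `data.frame` with
#'   canonical columns `agent_id`, `sector`, `occupation`, `task`,
#'   `year`, `source` and, depending on the dialect, `concentration` +
#'   `loq` or `detected`) and `rejects` (`data.frame` of `row`,
#'   `reason`).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(agent_id = "lead", sector = "S1",
#'     occupation = "O1", task = "T1", year = 2015,
#'     concentration = 2.5, loq = 0.5, source = "A"), f, row.names = FALSE)
#' readRecords(f)$records
#' @export
readRecords <- function(path, schema = recordSchema()) {
    stopifnot(file.exists(path))
    raw <- .readDelim(path)
    need <- c(schema$agent, schema$sector, schema$occupation, schema$task,
              schema$year, schema$source,
              if (schema$mode == "loq") c(schema$concentration, schema$loq)
              else schema$detected)
    missing <- setdiff(need, names(raw))
    if (length(missing))
        stop("missing mandatory column(s): ", paste(missing, collapse = ", "))

    n <- nrow(raw)
    reason <- rep(NA_character_, n)
    grab <- function(col) trimws(raw[[col]])

    rec <- data.frame(agent_id = grab(schema$agent),
                      sector = grab(schema$sector),
                      occupation = grab(schema$occupation),
                      task = grab(schema$task),
                      year = suppressWarnings(as.integer(grab(schema$year))),
                      source = grab(schema$source),
                      stringsAsFactors = FALSE)

    descOK <- nzchar(rec$agent_id) & nzchar(rec$sector) &
        nzchar(rec$occupation) & nzchar(rec$task) & nzchar(rec$source)
    reason[!descOK] <- "missing_descriptor"
    reason[is.na(reason) & is.na(rec$year)] <- "bad_numeric"

    if (schema$mode == "loq") {
        conc <- suppressWarnings(as.numeric(grab(schema$concentration)))
        loq <- suppressWarnings(as.numeric(grab(schema$loq)))
        reason[is.na(reason) & (is.na(conc) | is.na(loq))] <- "bad_numeric"
        reason[is.na(reason) & (conc < 0 | loq <= 0)] <- "bad_value"
        rec$concentration <- conc
        rec$loq <- loq
    } else {
        det <- .parseLogical(raw[[schema$detected]])
        reason[is.na(reason) & is.na(det)] <- "missing_detection"
        rec$detected <- det
    }

    keep <- is.na(reason)
    rejects <- data.frame(row = which(!keep), reason = reason[!keep],
                          stringsAsFactors = FALSE)
    list(records = rec[keep, , drop = FALSE], rejects = rejects)
}

#' Read an agent catalog
#'
#' The catalog carries one row per agent id: a display name, the
#' carcinogen flag (IARC group 1, 2A or 2B status supplied by the user),
#' and an exclusion flag with a reason drawn from a closed vocabulary
#' (`generic_dust`, `duplicate_indicator`, `source_specific`, `other`).
#'
#' @param path delimited file with columns `agent_id`, `name`,
#'   `carcinogen`, `excluded`, `exclusion_reason`.
#' @return validated `data.frame`.
#' @export
readCatalog <- function(path) {
    stopifnot(file.exists(path))
    raw <- .readDelim(path)
    need <- c("agent_id", "name", "carcinogen", "excluded", "exclusion_reason")
    missing <- setdiff(need, names(raw))
    if (length(missing))
        stop("catalog is missing column(s): ", paste(missing, collapse = ", "))
    cat <- data.frame(agent_id = trimws(raw$agent_id),
                      name = trimws(raw$name),
                      carcinogen = .parseLogical(raw$carcinogen),
                      excluded = .parseLogical(raw$excluded),
                      exclusion_reason = trimws(raw$exclusion_reason),
                      stringsAsFactors = FALSE)
    if (anyDuplicated(cat$agent_id))
        stop("duplicated agent_id in catalog")
    if (any(is.na(cat$carcinogen)) || any(is.na(cat$excluded)))
        stop("carcinogen/excluded flags must be TRUE/FALSE")
    vocab <- c("generic_dust", "duplicate_indicator", "source_specific",
               "other", "")
    if (any(!cat$exclusion_reason %in% vocab))
        stop("exclusion_reason outside the closed vocabulary")
    if (any(cat$excluded & !nzchar(cat$exclusion_reason)))
        stop("excluded agents need an exclusion_reason")
    cat
}

#' Detection status of measurement records
#'
#' The single place where censoring is decided: a record counts as
#' detected when its concentration lies strictly above the limit of
#' quantification (a concentration exactly equal to the LOQ is NOT
#' detected), or when the file's pre-computed flag says so. The boundary
#' is configurable for sensitivity analyses.
#'
#' @param records `data.frame` from [readRecords()].
#' @param boundary `"exclusive"` (default, strict `>`) or `"inclusive"`
#'   (`>=`).
#' @return logical vector, one element per record.
#' @export
flagDetected <- function(records, boundary = c("exclusive", "inclusive")) {
    boundary <- match.arg(boundary)
    if (!is.null(records$detected))
        return(as.logical(records$detected))
    if (is.null(records$concentration) || is.null(records$loq))
        stop("records carry neither a detected flag nor concentration + loq")
    if (boundary == "exclusive") records$concentration > records$loq
    else records$concentration >= records$loq
}

#' Inclusion/exclusion filter parameters
#'
#' @param yearMin,yearMax study window (calendar years, inclusive).
#' @param minAgentRecords minimum number of detected records an agent
#'   must have, pooled over sources, to be retained (default 100:
#'   agents with fewer than 100 quantified samples are dropped).
#' @param sourceExclusions optional `data.frame` with columns
#'   `agent_id`, `source`: agent/source pairs removed regardless of the
#'   catalog (e.g. one source's records of a single agent lacking task
#'   information).
#' @param detectionBoundary passed to [flagDetected()].
#' @return parameter list for [applyInclusionFilters()].
#' @export
filterConfig <- function(yearMin = 2010L, yearMax = 2019L,
                         minAgentRecords = 100L, sourceExclusions = NULL,
                         detectionBoundary = "exclusive") {
    list(yearMin = as.integer(yearMin), yearMax = as.integer(yearMax),
         minAgentRecords = as.integer(minAgentRecords),
         sourceExclusions = sourceExclusions,
         detectionBoundary = detectionBoundary)
}

#' Apply the inclusion/exclusion filters to validated records
#'
#' Filters are applied in a fixed, audited order:
#' \enumerate{
#'   \item study-window restriction on calendar year;
#'   \item catalog exclusions (e.g. generic dust classes, duplicate
#'     exposure indicators) and per-(agent, source) exclusions;
#'   \item detected-only restriction via [flagDetected()];
#'   \item removal of agents with fewer than `minAgentRecords` detected
#'     records, counted on the pooled corpus.
#' }
#' The audit table reports, per stage, how many records entered, were
#' removed, and survived, plus the number of agents removed, so that
#' `n_in - n_removed == n_out` at every stage.
#'
#' @param records validated records from [readRecords()].
#' @param catalog agent catalog from [readCatalog()]; every agent id
#'   occurring in `records` must have a catalog entry.
#' @param filters parameters from [filterConfig()].
#' @return list with `records` (retained, all detected) and `audit`
#'   (`data.frame` of `stage`, `n_in`, `n_removed`, `n_out`,
#'   `agents_removed`).
#' @export
applyInclusionFilters <- function(records, catalog,
                                  filters = filterConfig()) {
    unknown <- setdiff(unique(records$agent_id), catalog$agent_id)
    if (length(unknown))
        stop("agents missing from the catalog: ",
             paste(head(unknown, 5), collapse = ", "))

    audit <- list()
    note <- function(stage, before, after) {
        data.frame(stage = stage, n_in = nrow(before),
                   n_removed = nrow(before) - nrow(after),
                   n_out = nrow(after),
                   agents_removed = length(setdiff(unique(before$agent_id),
                                                   unique(after$agent_id))),
                   stringsAsFactors = FALSE)
    }

    step0 <- records
    step1 <- records[records$year >= filters$yearMin &
                     records$year <= filters$yearMax, , drop = FALSE]
    audit$year <- note("year_window", step0, step1)

    excl <- catalog$agent_id[catalog$excluded]
    drop2 <- step1$agent_id %in% excl
    se <- filters$sourceExclusions
    if (!is.null(se) && nrow(se) > 0)
        drop2 <- drop2 | (paste(step1$agent_id, step1$source, sep = "\x1f")
                          %in% paste(se$agent_id, se$source, sep = "\x1f"))
    step2 <- step1[!drop2, , drop = FALSE]
    audit$excl <- note("agent_source_exclusions", step1, step2)

    det <- flagDetected(step2, boundary = filters$detectionBoundary)
    step3 <- step2[det, , drop = FALSE]
    audit$det <- note("detected_only", step2, step3)

    counts <- table(step3$agent_id)
    keepAgents <- names(counts)[counts >= filters$minAgentRecords]
    step4 <- step3[step3$agent_id %in% keepAgents, , drop = FALSE]
    audit$minc <- note("min_count_per_agent", step3, step4)

    list(records = step4, audit = do.call(rbind, unname(audit)))
}
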