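#' Assign reference and target roles to two spike trains
#'
#' The jitter method jitters only one of the two trains; by convention the
#' slower-firing (fewer-spike) train is the reference, which also conserves
#' computational effort. Ties go to the first argument. `override = TRUE`
#' forces `a` to be the reference regardless of spike counts.
#'
#' @param a,b [SpikeTrain-class] objects sharing identical epoch bounds.
#' @param override logical; force `a` as reference.
#' @return A [PairedRecording-class].
#' @examples
#' a <- SpikeTrain(c(10, 20, 30), epochEnd = 100)
#' b <- SpikeTrain(c(15, 35), epochEnd = 100)
#' nSpikes(referenceTrain(assignRoles(a, b)))  # 2: b has fewer spikes
#' @export
assignRoles <- function(a, b, override = FALSE) {
    stopifnot(is(a, "SpikeTrain"), is(b, "SpikeTrain"))
    if (a@epochStart != b@epochStart || a@epochEnd != b@epochEnd)
        stop("trains must share identical epoch bounds")
    if (override || nSpikes(a) <= nSpikes(b))
        PairedRecording(reference = a, target = b)
    else
        PairedRecording(reference = b, target = a)
}

## Parse one plain-text column of spike times; '#' starts a comment.
## Errors name the offending line for non-numeric rows.
.parseTimesFile <- function(path) {
    lines <- readLines(path)
    stripped <- sub("#.*$", "", lines)
    keep <- which(nzchar(trimws(stripped)))
    vals <- suppressWarnings(as.numeric(trimws(stripped[keep])))
    bad <- which(is.na(vals) | !is.finite(vals))
    if (length(bad))
        stop(sprintf("non-numeric spike time in '%s' at line %d: '%s'",
                     path, keep[bad[1L]], trimws(lines[keep[bad[1L]]])))
    vals
}

## Parse a two-column (train_id, time_ms) CSV; returns list of time vectors
## named by train id, ids in ascending order.
.parsePairFile <- function(path) {
    lines <- readLines(path)
    stripped <- sub("#.*$", "", lines)
    keep <- which(nzchar(trimws(stripped)))
    parts <- strsplit(trimws(stripped[keep]), "[,;[:space:]]+")
    nf <- lengths(parts)
    badn <- which(nf != 2L)
    if (length(badn))
        stop(sprintf("expected two columns (train_id, time_ms) in '%s' at line %d",
                     path, keep[badn[1L]]))
    m <- matrix(unlist(parts), ncol = 2L, byrow = TRUE)
    ## tolerate a header row
    if (suppressWarnings(is.na(as.numeric(m[1L, 2L]))) && nrow(m) > 1L) {
        keep <- keep[-1L]; m <- m[-1L, , drop = FALSE]
    }
    tm <- suppressWarnings(as.numeric(m[, 2L]))
    bad <- which(is.na(tm) | !is.finite(tm))
    if (length(bad))
        stop(sprintf("non-numeric spike time in '%s' at line %d: '%s'",
                     path, keep[bad[1L]], trimws(lines[keep[bad[1L]]])))
    ids <- m[, 1L]
    uid <- sort(unique(ids))
    if (length(uid) != 2L)
        stop(sprintf("'%s' must contain exactly two train ids, found %d",
                     path, length(uid)))
    lapply(stats::setNames(uid, uid), function(id) tm[ids == id])
}

#' Read a pair of spike trains from plain-text files
#'
#' Two formats are supported: a single two-column CSV of (train_id,
#' time_ms), or one file per train with one spike time (ms) per line. `#`
#' starts a comment in both. Times are sorted (with a warning if they were
#' out of order) and duplicates collapsed. Unless `epoch` is given, the
#' epoch is \[0, ceiling(max time)\]. Roles are assigned with the
#' fewer-spikes-is-reference rule; for the two-column format ties go to the
#' lower train id, for the two-file format to the first file.
#'
#' @param path path to the two-column CSV, or to the first train's file.
#' @param path2 optional path to the second train's file (one-column
#'   format).
#' @param epoch optional numeric(2) epoch bounds (ms).
#' @return A [PairedRecording-class].
#' @export
readSpikeTrains <- function(path, path2 = NULL, epoch = NULL) {
    if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
    if (is.null(path2)) {
        tl <- .parsePairFile(path)
    } else {
        if (!file.exists(path2)) stop(sprintf("file not found: '%s'", path2))
        tl <- list(.parseTimesFile(path), .parseTimesFile(path2))
    }
    allt <- unlist(tl)
    if (is.null(epoch))
        epoch <- c(0, if (length(allt)) ceiling(max(allt)) else 1)
    a <- SpikeTrain(tl[[1L]], epochStart = epoch[1L], epochEnd = epoch[2L])
    b <- SpikeTrain(tl[[2L]], epochStart = epoch[1L], epochEnd = epoch[2L])
    assignRoles(a, b)
}

#' Write a pair of spike trains as a two-column CSV
#'
#' Emits (train_id, time_ms) rows, reference train as id 1 and target as
#' id 2, times rounded to `digits` decimals (default 1, i.e. 0.1 ms).
#'
#' @param pair a [PairedRecording-class].
#' @param path output file path.
#' @param digits decimal places for spike times.
#' @return `path`, invisibly.
#' @export
writeSpikeTrains <- function(pair, path, digits = 1) {
    stopifnot(is(pair, "PairedRecording"))
    t1 <- round(spikeTimes(pair@reference), digits)
    t2 <- round(spikeTimes(pair@target), digits)
    df <- data.frame(train = c(rep(1L, length(t1)), rep(2L, length(t2))),
                     time_ms = c(t1, t2))
    utils::write.table(df, path, sep = ",", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
    invisible(path)
}
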