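# Tab-delimited dialect: occupancy-table input, compatibility-matrix and
# mechanism-key outputs.  UTF-8, Unix newlines, ASCII "-1".

#' Read a tab-delimited occupancy table
#'
#' The header holds one token per factor: a one-letter code followed by its
#' association rank (e.g. `T1<TAB>B2`); the association order is the rank
#' sort, irrespective of column order.  Each data line holds the percent
#' occupancies in header-column order followed by the cluster name
#' (a leading-name layout is auto-detected as a fallback).  Malformed input
#' is rejected with line-numbered errors.
#'
#' @param file path or connection.
#' @return list with `assoc` (a [FactorOrder-class]) and `table`
#'   (an [OccupancyTable-class]).
#' @export
readOccupancyTable <- function(file) {
    lines <- readLines(file)
    lines <- lines[cumsum(nzchar(lines)) > 0]   # leading blanks only
    if (length(lines) < 1L) stop("empty file")
    hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1]]
    hdr <- trimws(hdr)
    hdr <- hdr[nzchar(hdr)]
    m <- regmatches(hdr, regexec("^(\\S)([0-9]+)$", hdr))
    bad <- vapply(m, length, 1L) != 3L
    if (any(bad))
        stop("line 1: malformed header token(s): ",
             paste(hdr[bad], collapse = ", "))
    codes <- vapply(m, `[`, "", 2L)
    ranks <- as.integer(vapply(m, `[`, "", 3L))
    if (anyDuplicated(codes)) stop("line 1: duplicate factor codes")
    if (!identical(sort(ranks), seq_along(ranks)))
        stop("line 1: association ranks must be the permutation 1..n")
    n <- length(codes)
    body <- lines[-1L]
    body <- body[nzchar(trimws(body))]
    if (length(body) == 0L) stop("no data lines after the header")
    parseRow <- function(ln, i, nameLast = TRUE) {
        fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
        if (length(fields) != n + 1L)
            stop(sprintf("line %d: expected %d fields, found %d",
                         i + 1L, n + 1L, length(fields)))
        occIdx <- if (nameLast) seq_len(n) else seq_len(n) + 1L
        vals <- suppressWarnings(as.numeric(fields[occIdx]))
        if (anyNA(vals))
            stop(sprintf("line %d: non-numeric occupancy value", i + 1L))
        if (any(vals < 0 | vals > 100))
            stop(sprintf("line %d: occupancy outside [0, 100]", i + 1L))
        list(vals = vals, name = fields[if (nameLast) n + 1L else 1L])
    }
    rows <- tryCatch(
        lapply(seq_along(body), function(i) parseRow(body[i], i, TRUE)),
        error = function(e) {
            # leading-name fallback: retry with the name in the first field
            ok <- tryCatch(
                lapply(seq_along(body), function(i) parseRow(body[i], i, FALSE)),
                error = function(e2) NULL)
            if (is.null(ok)) stop(e) else ok
        })
    vals <- do.call(rbind, lapply(rows, `[[`, "vals"))
    colnames(vals) <- codes
    assoc <- FactorOrder(codes[order(ranks)])
    list(assoc = assoc,
         table = OccupancyTable(vals, assoc,
                                rowNames = vapply(rows, `[[`, "", "name")))
}

#' Write an occupancy table in the tab-delimited input dialect
#'
#' Header tokens are `<code><rank>` in association order; each row holds the
#' occupancies then the group name.
#'
#' @param table an [OccupancyTable-class].
#' @param file path or connection.
#' @param digits maximum decimal places written (default 6).
#' @export
writeOccupancyTable <- function(table, file, digits = 6) {
    stopifnot(is(table, "OccupancyTable"))
    codes <- factorCodes(table)
    v <- occupancies(table)
    hdr <- paste0(codes, seq_along(codes))
    rows <- vapply(seq_len(nrow(v)), function(i)
        paste(c(formatC(v[i, ], format = "fg", digits = digits),
                rownames(v)[i]), collapse = "\t"), "")
    writeLines(c(paste(hdr, collapse = "\t"), rows), file)
}

#' Write a compatibility matrix as a tab-delimited grid
#'
#' First row: a corner field then the mechanism ids; each following row: the
#' cluster name then the -1/0 cells (ASCII hyphen-minus).  Loadable by
#' Cluster/Treeview-class tools.
#'
#' @param matrix a [CompatibilityMatrix-class].
#' @param file path or connection.
#' @export
writeCompatibilityMatrix <- function(matrix, file) {
    stopifnot(is(matrix, "CompatibilityMatrix"))
    m <- compatibilityCalls(matrix)
    lines <- c(paste(c("", colnames(m)), collapse = "\t"),
               vapply(seq_len(nrow(m)), function(i)
                   paste(c(rownames(m)[i], m[i, ]), collapse = "\t"), ""))
    writeLines(lines, file)
}

#' Read back a compatibility matrix written by [writeCompatibilityMatrix()]
#'
#' @param file path or connection.
#' @param assoc the [FactorOrder-class] the columns refer to.
#' @return a [CompatibilityMatrix-class].
#' @export
readCompatibilityMatrix <- function(file, assoc) {
    if (!is(assoc, "FactorOrder")) assoc <- FactorOrder(assoc)
    lines <- readLines(file)
    lines <- lines[nzchar(lines)]
    hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1]]
    ids <- hdr[-1L]
    cells <- lapply(lines[-1L], function(ln)
        strsplit(ln, "\t", fixed = TRUE)[[1]])
    m <- do.call(rbind, lapply(cells, function(x) as.integer(x[-1L])))
    rownames(m) <- vapply(cells, `[`, "", 1L)
    colnames(m) <- ids
    new("CompatibilityMatrix", calls = m, association = assoc)
}

#' Write the mechanism key file
#'
#' Two tab-separated columns: mechanism id and dissociation sequence
#' (concatenated codes, first to leave first), ids ascending.
#'
#' @param key data.frame from [mechanismKey()].
#' @param file path or connection.
#' @export
writeMechanismKey <- function(key, file) {
    stopifnot(is.data.frame(key), all(c("id", "dissociation") %in% names(key)))
    key <- key[order(key$id), ]
    writeLines(paste(key$id, key$dissociation, sep = "\t"), file)
}
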