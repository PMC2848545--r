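# Enumeration of dissociation mechanisms and their DNA-state cycles.

# All permutations of 1..n in lexicographic order (rows of a matrix).
.permutationsLex <- function(n) {
    if (n == 1L) return(matrix(1L, 1L, 1L))
    sub <- .permutationsLex(n - 1L)
    out <- matrix(0L, nrow = factorial(n), ncol = n)
    row <- 1L
    for (first in seq_len(n)) {
        rest <- setdiff(seq_len(n), first)
        blk <- matrix(rest[sub], nrow(sub), n - 1L)
        idx <- row:(row + nrow(sub) - 1L)
        out[idx, 1L] <- first
        out[idx, -1L] <- blk
        row <- row + nrow(sub)
    }
    out
}

#' Enumerate all dissociation mechanisms for a fixed association order
#'
#' For `n` factors there are `n!` orders in which the assembled complex can
#' shed its components.  Each is paired with the fixed association order to
#' form a [Mechanism-class].  Numbering is canonical: dissociation
#' permutations are written in association-rank indices and sorted
#' lexicographically; mechanism 1 therefore dissociates in association order
#' and mechanism `n!` in reverse (last in, first out).
#'
#' @param assoc a [FactorOrder-class] (or anything [FactorOrder()] accepts).
#' @return list of [Mechanism-class] objects, element `i` having id `i`.
#' @examples
#' length(enumerateDissociations("TBP"))  # 6
#' @export
enumerateDissociations <- function(assoc) {
    if (!is(assoc, "FactorOrder")) assoc <- FactorOrder(assoc)
    n <- length(assoc@codes)
    perms <- .permutationsLex(n)
    lapply(seq_len(nrow(perms)), function(i)
        new("Mechanism", association = assoc,
            dissociation = assoc@codes[perms[i, ]], id = i))
}

#' Look up one mechanism by id
#'
#' @inheritParams enumerateDissociations
#' @param dissociation character vector or string giving the dissociation
#'   order; mutually exclusive with `id`.
#' @param id integer mechanism id in the canonical enumeration.
#' @return a [Mechanism-class].
#' @examples
#' mechanism("TB", dissociation = "BT")  # id 2
#' @export
mechanism <- function(assoc, dissociation = NULL, id = NULL) {
    if (!is(assoc, "FactorOrder")) assoc <- FactorOrder(assoc)
    if (is.null(dissociation) == is.null(id))
        stop("supply exactly one of 'dissociation' or 'id'")
    if (!is.null(dissociation)) {
        if (length(dissociation) == 1L && nchar(dissociation) > 1L)
            dissociation <- strsplit(dissociation, "")[[1]]
        ranks <- match(dissociation, assoc@codes)
        if (anyNA(ranks) || length(ranks) != length(assoc@codes) ||
            anyDuplicated(ranks))
            stop("dissociation must be a permutation of the association codes")
        perms <- .permutationsLex(length(ranks))
        id <- which(apply(perms, 1L, identical, y = as.integer(ranks)))
        return(new("Mechanism", association = assoc,
                   dissociation = as.character(dissociation),
                   id = as.integer(id)))
    }
    n <- length(assoc@codes)
    if (id < 1L || id > factorial(n)) stop("mechanism id out of range")
    perms <- .permutationsLex(n)
    new("Mechanism", association = assoc,
        dissociation = assoc@codes[perms[id, ]], id = as.integer(id))
}

.stateKey <- function(state, codes) paste(codes[codes %in% state], collapse = "")

#' Build the DNA-state cycle of a mechanism
#'
#' Assembly intermediates follow the association order (first k factors,
#' k = 1..n); disassembly intermediates remove factors in dissociation order;
#' the cycle closes at the empty state.  The assembly and disassembly legs may
#' share subsets, so `occupiedStates` holds the distinct non-empty states.
#'
#' @param mech a [Mechanism-class].
#' @return a [StateCycle-class].
#' @examples
#' buildStateCycle(mechanism("TB", dissociation = "TB"))
#' @export
buildStateCycle <- function(mech) {
    stopifnot(is(mech, "Mechanism"))
    codes <- mech@association@codes
    n <- length(codes)
    assembly <- lapply(seq_len(n), function(k) codes[seq_len(k)])
    disassembly <- lapply(seq_len(n - 1L), function(k) {
        s <- setdiff(codes, mech@dissociation[seq_len(k)])
        codes[codes %in% s]   # canonical order within a subset
    })
    states <- c(assembly, disassembly, list(character(0)))
    nonEmpty <- states[lengths(states) > 0L]
    keys <- vapply(nonEmpty, .stateKey, "", codes = codes)
    new("StateCycle", states = states,
        occupiedStates = nonEmpty[!duplicated(keys)],
        mechanism = mech)
}

#' Tabulate the mechanism key (id to dissociation sequence)
#'
#' Reproduces the key file the compatibility chart's column numbers refer to.
#' Changing the association order permutes which sequence carries which id but
#' never the set of sequences.
#'
#' @inheritParams enumerateDissociations
#' @return data.frame with integer `id` and character `dissociation` (codes
#'   concatenated, first to leave first).
#' @examples
#' mechanismKey("TBP")
#' @export
mechanismKey <- function(assoc) {
    mechs <- enumerateDissociations(assoc)
    data.frame(id = vapply(mechs, mechanismId, 1L),
               dissociation = vapply(mechs, function(m)
                   paste(m@dissociation, collapse = ""), ""),
               stringsAsFactors = FALSE)
}
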