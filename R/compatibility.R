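# The two occupancy-compatibility rules and the groups x mechanisms chart.
#
# Comparisons use a fixed tolerance on the percent scale so that
# preprocessing round-off cannot flip a decision.
.OCC_EPS <- 1e-9

.checkOcc <- function(mech, occ) {
    codes <- mech@association@codes
    if (is.null(names(occ)) || !setequal(names(occ), codes))
        stop("occupancy vector must be named by the mechanism's factor codes")
    occ <- occ[codes]
    if (any(!is.finite(occ)) || any(occ < 0 | occ > 100))
        stop("occupancies must be finite and in [0, 100]")
    occ
}

#' Rule 1: unconditional pairwise occupancy ordering
#'
#' A mechanism in which factor `j` associates before factor `i` *and*
#' dissociates after it makes every DNA state that contains `i` also contain
#' `j`, so the mechanism unconditionally forces `occ(i) <= occ(j)`.  The rule
#' rejects the mechanism iff some such pair has strictly `occ(i) > occ(j)`;
#' equality is allowed.
#'
#' @param mech a [Mechanism-class].
#' @param occ named numeric: percent occupancy per factor code.
#' @return logical: `TRUE` if the mechanism survives the rule.
#' @examples
#' rule1Allows(mechanism("TB", dissociation = "BT"), c(T = 30, B = 60)) # FALSE
#' @export
rule1Allows <- function(mech, occ) {
    occ <- .checkOcc(mech, occ)
    codes <- mech@association@codes
    arank <- seq_along(codes)                      # association position
    drank <- match(codes, mech@dissociation)       # dissociation position
    for (i in seq_along(codes)) {
        for (j in seq_along(codes)) {
            if (i == j) next
            # j strictly contains i's occupancy interval
            if (arank[j] < arank[i] && drank[j] > drank[i] &&
                occ[i] > occ[j] + .OCC_EPS)
                return(FALSE)
        }
    }
    TRUE
}

#' Rule 2: a middle factor exceeding its neighbours' summed occupancy
#'
#' If a factor `m` that associates after `a` and before `b` has occupancy
#' strictly greater than `occ(a) + occ(b)`, then at some point `m` must
#' occupy DNA without either of them, which is only possible if `m`
#' dissociates after both.  The rule rejects the mechanism iff such a triple
#' exists and `m` does not outlast both `a` and `b` in the dissociation
#' order.  Vacuously true for fewer than three factors.
#'
#' @inheritParams rule1Allows
#' @return logical: `TRUE` if the mechanism survives the rule.
#' @examples
#' # B = 70 > 20 + 30 forces B to dissociate last:
#' rule2Allows(mechanism("TBP", dissociation = "TPB"), c(T = 20, B = 70, P = 30))
#' @export
rule2Allows <- function(mech, occ) {
    occ <- .checkOcc(mech, occ)
    codes <- mech@association@codes
    n <- length(codes)
    if (n < 3L) return(TRUE)
    drank <- match(codes, mech@dissociation)
    for (m in 2:(n - 1L)) {
        for (a in seq_len(m - 1L)) {
            for (b in (m + 1L):n) {
                if (occ[m] > occ[a] + occ[b] + .OCC_EPS &&
                    !(drank[m] > drank[a] && drank[m] > drank[b]))
                    return(FALSE)
            }
        }
    }
    TRUE
}

#' Joint compatibility decision (Rules 1 and 2)
#'
#' @inheritParams rule1Allows
#' @return logical.
#' @examples
#' isCompatible(mechanism("TB", dissociation = "TB"), c(T = 30, B = 60)) # TRUE
#' @export
isCompatible <- function(mech, occ) {
    rule1Allows(mech, occ) && rule2Allows(mech, occ)
}

#' Rule-based compatibility chart for all mechanisms and all groups
#'
#' Runs [isCompatible()] for every group (row of `table`) against every
#' dissociation mechanism under the fixed association order; cells are
#' encoded -1 (compatible) / 0 (incompatible).
#'
#' @inheritParams enumerateDissociations
#' @param table an [OccupancyTable-class] sharing `assoc`'s factor codes.
#' @return a [CompatibilityMatrix-class] of dimension groups x n!.
#' @examples
#' tab <- OccupancyTable(rbind(`(L,H)` = c(5, 40), `(H,H)` = c(40, 60)), "TB")
#' compatibilityMatrix("TB", tab)
#' @export
compatibilityMatrix <- function(assoc, table) {
    if (!is(assoc, "FactorOrder")) assoc <- FactorOrder(assoc)
    stopifnot(is(table, "OccupancyTable"))
    if (!identical(factorCodes(table), assoc@codes))
        table <- OccupancyTable(occupancies(table), assoc)
    mechs <- enumerateDissociations(assoc)
    vals <- occupancies(table)
    calls <- matrix(0L, nrow(vals), length(mechs),
                    dimnames = list(rownames(vals),
                                    vapply(mechs, mechanismId, 1L)))
    for (g in seq_len(nrow(vals))) {
        occ <- vals[g, ]
        for (m in seq_along(mechs))
            if (isCompatible(mechs[[m]], occ)) calls[g, m] <- -1L
    }
    new("CompatibilityMatrix", calls = calls, association = assoc)
}
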