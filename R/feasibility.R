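# Exact linear-feasibility oracle over state dwell fractions.
#
# A mechanism is compatible with observed occupancies iff nonnegative dwell
# fractions f(S) over its occupied DNA states reproduce them:
#   sum_{S containing i} f(S) = occ(i)  for every factor i,  f >= 0
# (optionally sum_S f(S) <= 100, the DNA-total bound).  Decided by a phase-1
# LP (minimize the sum of artificial slacks) via boot::simplex.

.LP_TOL <- 1e-7

.membershipMatrix <- function(codes, states) {
    m <- matrix(0, length(codes), length(states),
                dimnames = list(codes, vapply(states, paste, "", collapse = "")))
    for (s in seq_along(states)) m[codes %in% states[[s]], s] <- 1
    m
}

#' Dwell-fraction linear feasibility of a state cycle
#'
#' Phase-1 linear program: minimize the total slack `sum(s)` over
#' `f >= 0, s >= 0` subject to `A f + s = occ`, where `A` is the factor x
#' occupied-state membership matrix.  Slacks only relax each constraint
#' downward, so the optimum is 0 iff some nonnegative `f` meets every
#' occupancy exactly.  On infeasibility a Farkas certificate `y` (with
#' `y'A <= 0` and `y . occ > 0`) is recovered by a second LP.
#'
#' @param cycle a [StateCycle-class].
#' @param occ named numeric percent occupancies over the cycle's factor codes.
#' @param capTotal logical: additionally require `sum(f) <= 100` (DNA cannot
#'   be more than fully occupied).  Off by default; the compatibility rules
#'   make no use of the bound and the 0-100% scaling keeps it non-binding in
#'   the archetype cases, but the constraint is physically real.
#' @return a [FeasibilityResult-class].
#' @examples
#' cyc <- buildStateCycle(mechanism("TB", dissociation = "BT"))
#' lpFeasible(cyc, c(T = 30, B = 60))  # infeasible: forces occ(B) <= occ(T)
#' lpFeasible(cyc, c(T = 60, B = 30))  # feasible
#' @export
lpFeasible <- function(cycle, occ, capTotal = FALSE) {
    stopifnot(is(cycle, "StateCycle"))
    codes <- cycle@mechanism@association@codes
    occ <- .checkOcc(cycle@mechanism, occ)
    states <- cycle@occupiedStates
    nS <- length(states)
    nF <- length(codes)
    if (nS == 0L) {   # degenerate: nothing can be occupied
        feas <- all(occ <= .LP_TOL)
        return(new("FeasibilityResult", feasible = feas,
                   residual = sum(occ^2),
                   certificate = if (feas) NULL else
                       setNames(rep(1, nF), codes),
                   dwell = if (feas) numeric(0) else NULL))
    }
    A <- .membershipMatrix(codes, states)
    # variables: f (nS), s (nF)
    a3 <- cbind(A, diag(nF))
    obj <- c(rep(0, nS), rep(1, nF))
    A1 <- NULL; b1 <- NULL
    if (capTotal) { A1 <- matrix(c(rep(1, nS), rep(0, nF)), 1L); b1 <- 100 }
    sol <- boot::simplex(a = obj, A1 = A1, b1 = b1, A3 = a3, b3 = unname(occ),
                         maxi = FALSE, eps = 1e-10)
    f <- sol$soln[seq_len(nS)]
    viol <- pmax(unname(occ) - as.vector(A %*% f), 0)
    feas <- sol$solved == 1L && sol$value <= .LP_TOL
    cert <- NULL
    if (!feas && !capTotal) cert <- .farkasCertificate(A, unname(occ), codes)
    new("FeasibilityResult", feasible = feas, residual = sum(viol^2),
        certificate = cert,
        dwell = if (feas) setNames(f, colnames(A)) else NULL)
}

# max y.occ s.t. y'A <= 0, -1 <= y <= 1; optimum > 0 witnesses infeasibility.
.farkasCertificate <- function(A, occ, codes) {
    nF <- nrow(A); nS <- ncol(A)
    # y = u - w with u, w in [0, 1]
    A1 <- rbind(cbind(t(A), -t(A)),           # (u - w)'A <= 0
                cbind(diag(nF), matrix(0, nF, nF)),   # u <= 1
                cbind(matrix(0, nF, nF), diag(nF)))   # w <= 1
    b1 <- c(rep(0, nS), rep(1, 2 * nF))
    sol <- boot::simplex(a = c(occ, -occ), A1 = A1, b1 = b1, maxi = TRUE,
                         eps = 1e-10)
    if (sol$solved != 1L || sol$value <= .LP_TOL) return(NULL)
    y <- sol$soln[seq_len(nF)] - sol$soln[nF + seq_len(nF)]
    setNames(y, codes)
}

#' Feasibility-oracle compatibility chart
#'
#' Mirror of [compatibilityMatrix()] with every cell decided by
#' [lpFeasible()] instead of the two rules; used to validate the rules.
#'
#' @inheritParams compatibilityMatrix
#' @param capTotal passed to [lpFeasible()].
#' @return a [CompatibilityMatrix-class].
#' @export
oracleMatrix <- function(assoc, table, capTotal = FALSE) {
    if (!is(assoc, "FactorOrder")) assoc <- FactorOrder(assoc)
    stopifnot(is(table, "OccupancyTable"))
    if (!identical(factorCodes(table), assoc@codes))
        table <- OccupancyTable(occupancies(table), assoc)
    mechs <- enumerateDissociations(assoc)
    cycles <- lapply(mechs, buildStateCycle)
    vals <- occupancies(table)
    calls <- matrix(0L, nrow(vals), length(mechs),
                    dimnames = list(rownames(vals),
                                    vapply(mechs, mechanismId, 1L)))
    for (g in seq_len(nrow(vals))) {
        occ <- vals[g, ]
        for (m in seq_along(mechs))
            if (lpFeasible(cycles[[m]], occ, capTotal)@feasible)
                calls[g, m] <- -1L
    }
    new("CompatibilityMatrix", calls = calls, association = assoc)
}

#' Compare the rule-based decisions against the feasibility oracle
#'
#' Evaluates both deciders on every (occupancy vector, mechanism) cell
#' supplied and returns the divergent cells.  Any divergence is also raised
#' as a warning so it surfaces in logs rather than being silently accepted.
#'
#' @inheritParams compatibilityMatrix
#' @param vectors numeric matrix of occupancy vectors (columns = factor
#'   codes), one row per vector to test.
#' @param mechIds optional integer vector: per-row mechanism id to test; if
#'   `NULL`, all `n!` mechanisms are tested for every row.
#' @return data.frame of divergences (possibly 0 rows) with columns `row`,
#'   `mechanism`, `rules`, `oracle`, plus attribute `nTested`.
#' @export
compareRulesToOracle <- function(assoc, vectors, mechIds = NULL) {
    if (!is(assoc, "FactorOrder")) assoc <- FactorOrder(assoc)
    codes <- assoc@codes
    vectors <- as.matrix(vectors)
    colnames(vectors) <- codes
    mechs <- enumerateDissociations(assoc)
    cycles <- lapply(mechs, buildStateCycle)
    out <- list(); nTested <- 0L
    for (r in seq_len(nrow(vectors))) {
        occ <- vectors[r, ]
        ids <- if (is.null(mechIds)) seq_along(mechs) else mechIds[r]
        for (m in ids) {
            rules <- isCompatible(mechs[[m]], occ)
            orac <- lpFeasible(cycles[[m]], occ)@feasible
            nTested <- nTested + 1L
            if (rules != orac)
                out[[length(out) + 1L]] <- data.frame(
                    row = r, mechanism = m, rules = rules, oracle = orac)
        }
    }
    div <- if (length(out)) do.call(rbind, out) else
        data.frame(row = integer(), mechanism = integer(),
                   rules = logical(), oracle = logical())
    if (nrow(div))
        warning(sprintf("rules and feasibility oracle diverge on %d of %d cells",
                        nrow(div), nTested))
    attr(div, "nTested") <- nTested
    div
}
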