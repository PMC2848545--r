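# Irreversible mass-action kinetics: model construction, steady-state
# solution, least-squares E objective and multi-start rate estimation.
#
# The steady state is found by damped Newton iteration on the reduced
# system (conservation laws substituted), warm-startable across objective
# evaluations; stiff integration (deSolve::lsoda) with horizon doubling is
# the fallback and cross-check.

#' Build the irreversible mass-action model of a mechanism
#'
#' Species are the free factors plus the distinct DNA states of the
#' mechanism's cycle (including empty DNA).  The 2n reactions are the cycle
#' steps: `state + free factor -> next state` (association) and
#' `state -> next state + free factor` (dissociation), all irreversible.
#' DNA and every free protein start at equal concentrations (default 10,
#' arbitrary units); mass is conserved per factor and for DNA.
#'
#' @param mech a [Mechanism-class].
#' @param dnaTotal,proteinTotal initial totals; `dnaTotal = 1` reproduces the
#'   reduced-DNA variant used as a regression check.
#' @return a [KineticModel-class].
#' @examples
#' buildKineticModel(mechanism("TB", dissociation = "BT"))
#' @export
buildKineticModel <- function(mech, dnaTotal = 10, proteinTotal = 10) {
    stopifnot(is(mech, "Mechanism"))
    codes <- mech@association@codes
    n <- length(codes)
    cyc <- buildStateCycle(mech)
    # distinct states, empty first; map cycle positions onto them
    keys <- vapply(cyc@states, .stateKey, "", codes = codes)
    distinctKeys <- c("", setdiff(unique(keys), ""))
    states <- lapply(distinctKeys, function(k)
        if (nzchar(k)) strsplit(k, "")[[1]] else character(0))
    # cycle order: empty -> assembly -> disassembly -> empty
    walk <- c(1L, match(keys, distinctKeys))   # 2n + 1 positions
    fac <- c(mech@association@codes, mech@dissociation)
    reactions <- data.frame(
        substrate = walk[seq_len(2L * n)],
        product = walk[seq_len(2L * n) + 1L],
        factor = fac,
        type = rep(c("association", "dissociation"), each = n),
        stringsAsFactors = FALSE)
    new("KineticModel", mechanism = mech, states = states,
        reactions = reactions, dnaTotal = dnaTotal,
        proteinTotal = proteinTotal)
}

# Precompute the index matrices used by the RHS/Jacobian evaluations.
.modelWork <- function(model) {
    codes <- model@mechanism@association@codes
    n <- length(codes)
    occStates <- model@states[-1L]           # occupied (distinct, non-empty)
    m <- length(occStates)
    memb <- .membershipMatrix(codes, occStates)   # n x m
    rx <- model@reactions
    nR <- nrow(rx)
    isAssoc <- rx$type == "association"
    aIdx <- match(rx$factor, codes)
    subIdx <- rx$substrate                   # 1 = empty
    # incidence N (m x nR): +1 product, -1 substrate (occupied states only)
    N <- matrix(0, m, nR)
    for (j in seq_len(nR)) {
        if (rx$product[j] > 1L) N[rx$product[j] - 1L, j] <- N[rx$product[j] - 1L, j] + 1
        if (rx$substrate[j] > 1L) N[rx$substrate[j] - 1L, j] <- N[rx$substrate[j] - 1L, j] - 1
    }
    # d c_substrate / d x  (nR x m), constant
    Dsub <- matrix(0, nR, m)
    for (j in seq_len(nR)) {
        if (subIdx[j] == 1L) Dsub[j, ] <- -1 else Dsub[j, subIdx[j] - 1L] <- 1
    }
    # d fTerm / d x (nR x m): -memb[a_j, ] for association steps
    dF <- matrix(0, nR, m)
    for (j in seq_len(nR)) if (isAssoc[j]) dF[j, ] <- -memb[aIdx[j], ]
    list(codes = codes, n = n, m = m, memb = memb, N = N, Dsub = Dsub,
         dF = dF, isAssoc = isAssoc, aIdx = aIdx, subIdx = subIdx,
         D = model@dnaTotal, P = model@proteinTotal)
}

# rates and RHS at occupied-state concentrations x
.rhs <- function(x, k, w) {
    cEmpty <- w$D - sum(x)
    f <- w$P - as.vector(w$memb %*% x)
    cAll <- c(cEmpty, x)
    fTerm <- ifelse(w$isAssoc, f[w$aIdx], 1)
    rates <- k * cAll[w$subIdx] * fTerm
    list(g = as.vector(w$N %*% rates), rates = rates, f = f,
         cEmpty = cEmpty, fTerm = fTerm)
}

.jacobian <- function(x, k, w, ev) {
    cAll <- c(ev$cEmpty, x)
    dr <- k * (w$Dsub * ev$fTerm + w$dF * cAll[w$subIdx])
    w$N %*% dr
}

.newtonSteady <- function(x0, k, w, tol = 1e-11, maxIter = 60L) {
    x <- x0
    ev <- .rhs(x, k, w)
    normG <- max(abs(ev$g))
    for (it in seq_len(maxIter)) {
        if (normG <= tol * (1 + max(k) * w$D * w$P)) break
        J <- .jacobian(x, k, w, ev)
        step <- tryCatch(solve(J, -ev$g), error = function(e) NULL)
        if (is.null(step)) return(NULL)
        alpha <- 1
        repeat {
            xNew <- x + alpha * step
            evNew <- .rhs(xNew, k, w)
            if (max(abs(evNew$g)) < normG || alpha < 1e-6) break
            alpha <- alpha / 2
        }
        if (max(abs(evNew$g)) >= normG && alpha < 1e-6) return(NULL)
        x <- xNew; ev <- evNew; normG <- max(abs(ev$g))
    }
    if (normG > tol * (1 + max(k) * w$D * w$P)) return(NULL)
    if (any(x < -1e-8) || ev$cEmpty < -1e-8 || any(ev$f < -1e-8)) return(NULL)
    pmax(x, 0)
}

# run an expression with the integrator's console chatter silenced
.quietly <- function(expr) {
    tf <- file(tempfile(), open = "wt")
    sink(tf); sink(tf, type = "message")
    on.exit({ sink(type = "message"); sink(); close(tf) })
    suppressWarnings(expr)
}

.integrateSteady <- function(x0, k, w, tol = 1e-9, tMax = 1e10,
                             maxsteps = 50000L) {
    func <- function(t, y, parms) list(.rhs(y, k, w)$g)
    tEnd <- 10
    x <- x0
    repeat {
        sol <- .quietly(tryCatch(
            deSolve::lsoda(y = x, times = c(0, tEnd), func = func,
                           rtol = 1e-9, atol = 1e-11, maxsteps = maxsteps),
            error = function(e) NULL))
        if (!is.null(sol) && nrow(sol) == 2L)
            x <- pmax(as.numeric(sol[2L, -1L]), 0)
        ev <- .rhs(x, k, w)
        if (max(abs(ev$g)) / (1 + max(abs(x))) < tol) return(x)
        tEnd <- tEnd * 4
        if (tEnd > tMax) return(NULL)
    }
}

.steadyState <- function(w, k, warm = NULL, fast = FALSE) {
    # warm start, then cheap interior cold starts, then integration
    if (!is.null(warm)) {
        x <- .newtonSteady(warm, k, w)
        if (!is.null(x)) return(x)
    }
    for (x0 in list(rep(w$D / (4 * (w$m + 1)), w$m),
                    rep(w$D / (w$m + 1), w$m),
                    rep(1e-3 * w$D, w$m))) {
        x <- .newtonSteady(x0, k, w)
        if (!is.null(x)) return(x)
    }
    xi <- .integrateSteady(rep(0, w$m), k, w,
                           tMax = if (fast) 1e6 else 1e10,
                           maxsteps = if (fast) 10000L else 50000L)
    if (is.null(xi)) return(NULL)
    x <- .newtonSteady(xi, k, w)
    if (is.null(x)) xi else x
}

#' Simulate a kinetic model to steady state
#'
#' Starting from empty DNA and all proteins free, finds the steady state of
#' the irreversible mass-action system (long-horizon stiff integration with
#' horizon doubling, polished by Newton iteration on the reduced system).
#' Fails explicitly if the integrator has not converged by the horizon limit.
#'
#' @param model a [KineticModel-class].
#' @param rates positive numeric vector of length 2n: rate constants in
#'   reaction order (associations first, then dissociations).
#' @param tol relative time-derivative norm required for convergence.
#' @return list with `free` (named free-factor concentrations), `states`
#'   (named DNA-state concentrations, `"0"` = empty DNA), `occupancy`
#'   (percent of DNA bound per factor), `derivNorm`.
#' @examples
#' mod <- buildKineticModel(mechanism("TB", dissociation = "TB"))
#' ss <- simulateSteadyState(mod, rates = rep(1, 4))
#' sum(ss$states)  # DNA total, 10
#' @export
simulateSteadyState <- function(model, rates, tol = 1e-9) {
    stopifnot(is(model, "KineticModel"))
    w <- .modelWork(model)
    if (length(rates) != nrow(model@reactions) || any(rates <= 0))
        stop("need ", nrow(model@reactions), " positive rate constants")
    x <- .integrateSteady(rep(0, w$m), rates, w, tol = tol)
    if (is.null(x))
        stop("steady state not reached within the integration horizon limit")
    xp <- .newtonSteady(x, rates, w)
    if (!is.null(xp)) x <- xp
    ev <- .rhs(x, rates, w)
    bound <- as.vector(w$memb %*% x)
    stateNames <- c("0", vapply(model@states[-1L], paste, "", collapse = ""))
    # mass conservation check (construction guarantees it; verify anyway)
    if (abs(sum(c(ev$cEmpty, x)) - w$D) > 1e-6 * w$D)
        stop("DNA mass conservation violated")
    list(free = setNames(ev$f, w$codes),
         states = setNames(c(ev$cEmpty, x), stateNames),
         occupancy = setNames(100 * bound / w$D, w$codes),
         derivNorm = max(abs(ev$g)) / (1 + max(abs(x))))
}

#' Least-squares objective between measured and simulated occupancies
#'
#' `E = sum_i w_i (x_i - y_i)^2`, compared on the free-protein-concentration
#' scale: the target for factor `i` is `proteinTotal - dnaTotal * Occ_i/100`
#' with the measured occupancy floored at 0.1% (the practical lower limit);
#' with both totals at 10 this is `(1 - Occ/100) * 10`.
#'
#' @param observed,simulated named numeric percent occupancies over the same
#'   factor codes.
#' @param weights positive numeric (recycled); default uniform 1.
#' @param dnaTotal,proteinTotal concentration totals (defaults 10, 10).
#' @return nonnegative numeric.
#' @examples
#' evalue(c(T = 30, B = 60), c(T = 30, B = 60))  # 0
#' @export
evalue <- function(observed, simulated, weights = 1, dnaTotal = 10,
                   proteinTotal = 10) {
    if (is.null(names(observed)) || !setequal(names(observed), names(simulated)))
        stop("observed and simulated must be named by the same factor codes")
    simulated <- simulated[names(observed)]
    if (any(weights <= 0)) stop("weights must be positive")
    x <- proteinTotal - dnaTotal * pmax(observed, 0.1) / 100
    y <- proteinTotal - dnaTotal * simulated / 100
    sum(weights * (x - y)^2)
}

#' Fit rate constants to observed occupancies by multi-start least squares
#'
#' Emulates a random-search parameter estimation: `nRestarts` seeded random
#' initializations of the log10 rate constants (bounds `logRateBounds`), each
#' refined by Nelder-Mead minimization of [evalue()] between target and
#' steady-state free-protein concentrations.  Runs with the same seed are
#' identical; compatible mechanisms reach E near 0, incompatible mechanisms
#' stay bounded away from 0 across restarts.
#'
#' @param mech a [Mechanism-class].
#' @param occ named numeric percent occupancies.
#' @param nRestarts number of random initializations (default 20).
#' @param seed integer RNG seed.
#' @param weights `"uniform"` (w = 1, default) or `"meansquare"`
#'   (w = 1/target^2), or a numeric vector per factor.
#' @param dnaTotal,proteinTotal concentration totals.
#' @param logRateBounds log10 bounds of the rate-constant search box.
#' @param maxit Nelder-Mead iteration cap per restart; default scales with
#'   the number of rate constants (300 per dimension).  Each restart is
#'   polished by a second run from its optimum (a fresh simplex), which
#'   rescues stalled high-dimensional searches.
#' @return a [FitResult-class] for the best restart.
#' @examples
#' \donttest{
#' fit <- estimateParameters(mechanism("TB", dissociation = "TB"),
#'                           c(T = 30, B = 60), nRestarts = 5, seed = 1)
#' fit@log10E  # well below 0: the mechanism can reproduce the data
#' }
#' @export
estimateParameters <- function(mech, occ, nRestarts = 20L, seed = 1L,
                               weights = "uniform", dnaTotal = 10,
                               proteinTotal = 10,
                               logRateBounds = c(-4, 4), maxit = NULL) {
    stopifnot(is(mech, "Mechanism"), nRestarts >= 1L)
    occ <- .checkOcc(mech, occ)
    model <- buildKineticModel(mech, dnaTotal, proteinTotal)
    w <- .modelWork(model)
    nR <- nrow(model@reactions)
    if (is.null(maxit)) maxit <- 300L * nR
    target <- proteinTotal - dnaTotal * pmax(occ, 0.1) / 100
    wts <- if (identical(weights, "uniform")) rep(1, w$n)
           else if (identical(weights, "meansquare")) 1 / pmax(target, 0.1)^2
           else rep_len(weights, w$n)
    lo <- logRateBounds[1]; hi <- logRateBounds[2]
    warmEnv <- new.env(parent = emptyenv())
    objective <- function(u) {
        uc <- pmin(pmax(u, lo), hi)
        penalty <- 1e3 * sum((u - uc)^2)
        k <- 10^uc
        x <- .steadyState(w, k, warm = warmEnv$x, fast = TRUE)
        if (is.null(x)) return(1e8)
        warmEnv$x <- x
        f <- w$P - as.vector(w$memb %*% x)
        sum(wts * (target - f)^2) + penalty
    }
    set.seed(seed)
    inits <- matrix(runif(nRestarts * nR, lo, hi), nRestarts, nR)
    best <- NULL
    for (r in seq_len(nRestarts)) {
        warmEnv$x <- NULL
        fit <- tryCatch(
            optim(inits[r, ], objective, method = "Nelder-Mead",
                  control = list(maxit = maxit, reltol = 1e-12)),
            error = function(e) NULL)
        if (is.null(fit)) next
        # polish: restart the simplex at the incumbent until no real gain
        for (p in 1:3) {
            if (fit$value < 1e-10) break
            fit2 <- tryCatch(
                optim(fit$par, objective, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-12)),
                error = function(e) NULL)
            if (is.null(fit2) || fit2$value > fit$value * 0.5) break
            fit <- fit2
        }
        if (is.null(best) || fit$value < best$value) best <- fit
        if (best$value < 1e-10) break
    }
    if (is.null(best))
        stop("parameter estimation failed on every restart")
    kBest <- 10^pmin(pmax(best$par, lo), hi)
    warmEnv$x <- NULL
    xs <- .steadyState(w, kBest)
    simOcc <- if (is.null(xs)) rep(NA_real_, w$n)
              else 100 * as.vector(w$memb %*% xs) / w$D
    E <- max(best$value, 0)
    new("FitResult", E = E, log10E = log10(max(E, 1e-12)),
        rates = setNames(kBest, paste0(model@reactions$type, "_",
                                       model@reactions$factor)),
        simulatedOcc = setNames(simOcc, w$codes),
        nRestarts = as.integer(nRestarts), seed = as.integer(seed))
}

# Default classification threshold on log10 E, frozen from the bimodal gap of
# the three-factor archetype suite (all 8 H/L patterns at L = 5%, H = 40%
# against all 6 mechanisms, 20 restarts): 2-means midpoint of the gap
# (compatible cells reached log10E <= -4.7, incompatible >= +0.48).
.DEFAULT_LOG10E_THRESHOLD <- -2.1

#' Default log10 E threshold separating compatible from incompatible fits
#'
#' The log10 E values of fitted cells are strongly bimodal: compatible cells
#' reach essentially zero error while incompatible cells are pinned at the
#' feasibility gap.  The default cut sits at the midpoint of the empirical
#' gap of the three-factor archetype suite; [gapThreshold()] recomputes it
#' for any fit set.
#'
#' @return numeric scalar.
#' @export
defaultLog10EThreshold <- function() .DEFAULT_LOG10E_THRESHOLD

#' Midpoint of the bimodal gap of a set of log10 E values
#'
#' 2-means split of the values; returns the midpoint between the largest
#' member of the low cluster and the smallest member of the high cluster.
#'
#' @param log10E numeric vector (needs both modes present).
#' @return numeric scalar.
#' @export
gapThreshold <- function(log10E) {
    stopifnot(length(log10E) >= 2L)
    km <- kmeans(log10E, centers = 2L, nstart = 5L)
    lowCl <- which.min(km$centers)
    (max(log10E[km$cluster == lowCl]) + min(log10E[km$cluster != lowCl])) / 2
}

#' Classify fits as compatible/incompatible by log10 E
#'
#' @param fits list of [FitResult-class] objects, or a numeric vector of
#'   log10 E values.
#' @param thresholdLog10E cut below which a fit counts as compatible;
#'   defaults to [defaultLog10EThreshold()].
#' @return logical vector.
#' @export
classifyByEvalue <- function(fits, thresholdLog10E = defaultLog10EThreshold()) {
    l10 <- if (is.numeric(fits)) fits
           else vapply(fits, function(f) f@log10E, 0)
    if (length(l10) < 1L) stop("need at least one fit")
    l10 < thresholdLog10E
}

#' Kinetics-based compatibility classification of chart cells
#'
#' Fits the mass-action model of each requested (group, mechanism) cell of an
#' occupancy table and classifies it by log10 E, alongside the rule-based
#' call, mirroring the kinetic spot-validation of the compatibility chart.
#'
#' @inheritParams compatibilityMatrix
#' @param cells data.frame/matrix with columns `group` (row index of
#'   `table`) and `mechanism` (mechanism id), or `NULL` for all cells.
#' @param nRestarts,seed,weights,dnaTotal,proteinTotal,maxit passed to
#'   [estimateParameters()]; each cell uses a seed derived from `seed`.
#' @param thresholdLog10E classification cut.
#' @return data.frame with one row per cell: `group`, `mechanism`, `log10E`,
#'   `kinetics` and `rules` (logical calls); attribute `agreement` = percent
#'   of cells where the two calls agree.
#' @export
kineticsClassification <- function(assoc, table, cells = NULL, nRestarts = 20L,
                                   seed = 1L, weights = "uniform",
                                   dnaTotal = 10, proteinTotal = 10,
                                   maxit = NULL,
                                   thresholdLog10E = defaultLog10EThreshold()) {
    if (!is(assoc, "FactorOrder")) assoc <- FactorOrder(assoc)
    stopifnot(is(table, "OccupancyTable"))
    mechs <- enumerateDissociations(assoc)
    vals <- occupancies(table)
    if (is.null(cells))
        cells <- expand.grid(group = seq_len(nrow(vals)),
                             mechanism = seq_along(mechs))
    cells <- as.data.frame(cells)
    res <- vector("list", nrow(cells))
    for (i in seq_len(nrow(cells))) {
        g <- cells$group[i]; m <- cells$mechanism[i]
        occ <- vals[g, ]
        fit <- estimateParameters(mechs[[m]], occ, nRestarts = nRestarts,
                                  seed = (seed * 1000L + i) %% .Machine$integer.max,
                                  weights = weights, dnaTotal = dnaTotal,
                                  proteinTotal = proteinTotal, maxit = maxit)
        res[[i]] <- data.frame(group = rownames(vals)[g], mechanism = m,
                               log10E = fit@log10E,
                               kinetics = fit@log10E < thresholdLog10E,
                               rules = isCompatible(mechs[[m]], occ))
    }
    out <- do.call(rbind, res)
    attr(out, "agreement") <- 100 * mean(out$kinetics == out$rules)
    out
}
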