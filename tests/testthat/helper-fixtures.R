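# Shared fixtures: all built in code at test time.

# archetype occupancy table (2^n H/L rows) for a code string like "TBP"
archTable <- function(codes, L = 5, H = 40) {
    generateGroupMedians(codes = codes, L = L, H = H)
}

# random valid occupancy vectors (rows), percent scale
randomOccVectors <- function(nVec, codes, seed) {
    set.seed(seed)
    m <- matrix(runif(nVec * nchar(codes), 0, 100), nVec)
    colnames(m) <- strsplit(codes, "")[[1]]
    m
}

# small synthetic probe config sized for tests; the top tier must stay above
# the 99th-percentile anchor rank (> 1% of probes)
testProbeConfig <- function(codes = "TBP", sigma = 0.1, seed = 1L, ...) {
    syntheticConfig(codes = codes, nGenes = 1600L, nTopGenes = 120L,
                    nProbesTotal = 6000L, nTTProbes = 600L,
                    sigma = sigma, seed = seed, ...)
}

plantedPatterns <- function(pd) {
    rd <- SummarizedExperiment::rowData(pd)
    rd$pattern[rd$probeClass == "TSS"]
}

trueOccMatrix <- function(pd, codes) {
    rd <- SummarizedExperiment::rowData(pd)
    as.matrix(rd[rd$probeClass == "TSS",
                 paste0("trueOcc.", strsplit(codes, "")[[1]])])
}

# independent full-species mass-action integrator (free factors + all DNA
# states as explicit ODEs), used as an oracle for the package's steady-state
# solver; deliberately shares no code with it.
referenceSteadyState <- function(model, rates, tEnd = 1e6) {
    codes <- factorCodes(model@mechanism)
    states <- model@states
    rx <- model@reactions
    nS <- length(states)
    y0 <- c(rep(model@proteinTotal, length(codes)),      # free factors
            model@dnaTotal, rep(0, nS - 1L))             # empty DNA first
    names(y0) <- c(codes, paste0("s", seq_len(nS)))
    rhs <- function(t, y, p) {
        f <- y[seq_along(codes)]
        cs <- y[length(codes) + seq_len(nS)]
        dy <- numeric(length(y))
        for (j in seq_len(nrow(rx))) {
            fi <- match(rx$factor[j], codes)
            v <- if (rx$type[j] == "association")
                rates[j] * cs[rx$substrate[j]] * f[fi]
            else rates[j] * cs[rx$substrate[j]]
            dy[length(codes) + rx$substrate[j]] <-
                dy[length(codes) + rx$substrate[j]] - v
            dy[length(codes) + rx$product[j]] <-
                dy[length(codes) + rx$product[j]] + v
            dy[fi] <- dy[fi] + if (rx$type[j] == "association") -v else v
        }
        list(dy)
    }
    sol <- deSolve::lsoda(y0, times = c(0, tEnd), rhs, rtol = 1e-10,
                          atol = 1e-12)
    y <- sol[nrow(sol), -1L]
    list(free = y[seq_along(codes)],
         states = y[length(codes) + seq_len(nS)])
}
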