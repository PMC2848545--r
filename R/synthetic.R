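# Synthetic probe-level datasets with planted H/L structure.
#
# The generator emulates the low-density tiling design the preprocessing
# chain expects: one TSS probe per gene, T-T intergenic control probes, a
# filler set of unbound probes, replicated factor IPs and background-strain
# hybridizations, multiplicative lognormal noise, and a per-factor
# crosslinking scale that the 0-100% scaling must cancel.

.archetypePatterns <- function(codes, L = 5, H = 40) {
    n <- length(codes)
    grid <- as.matrix(expand.grid(rep(list(c("L", "H")), n),
                                  stringsAsFactors = FALSE))[, n:1, drop = FALSE]
    vals <- matrix(ifelse(grid == "H", H, L), ncol = n,
                   dimnames = list(paste0("(", apply(grid, 1L, paste,
                                                     collapse = ","), ")"),
                                   codes))
    vals
}

#' Construct a SyntheticConfig
#'
#' Defaults reproduce the study-scale design: 5,743 genes with TSS probes
#' split over all 2^n H/L archetype patterns (L = 5%, H = 40%) plus a
#' 250-gene fully-occupied top tier (the highly loaded promoters that anchor
#' the 99th-percentile scaling), 2,000 T-T intergenic probes, filler probes
#' up to ~20,000 total, 2 IP replicates per factor, 3 background replicates,
#' lognormal noise sigma = 0.1 and a 9-fold signal at 100% occupancy.
#'
#' @param codes factor codes in association order (default `T`, `B`, `P`).
#' @param L,H archetype percent occupancies for low/high patterns.
#' @param nGenes total TSS genes (archetype tiers; the top tier is extra).
#' @param nTopGenes genes in the ~100% top tier.
#' @param topOcc top-tier percent occupancy.
#' @param nProbesTotal total probes; filler `other` probes make up the
#'   difference after TSS and T-T probes.
#' @param nTTProbes tail-to-tail intergenic control probes.
#' @param ipReplicates,bgReplicates replicate counts.
#' @param kappa per-factor crosslinking scale (recycled over codes).
#' @param foldAt100 fold over background at 100% occupancy for kappa = 1.
#' @param backgroundLevel expected raw background signal.
#' @param sigma lognormal noise sd (log scale).
#' @param occJitterSD sd of per-gene jitter around the archetype occupancy.
#' @param seed integer RNG seed.
#' @return a [SyntheticConfig-class].
#' @export
syntheticConfig <- function(codes = c("T", "B", "P"), L = 5, H = 40,
                            nGenes = 5743L, nTopGenes = 250L, topOcc = 100,
                            nProbesTotal = 20000L, nTTProbes = 2000L,
                            ipReplicates = 2L, bgReplicates = 3L,
                            kappa = 1, foldAt100 = 9,
                            backgroundLevel = 100, sigma = 0.1,
                            occJitterSD = 1.0, seed = 1L) {
    if (length(codes) == 1L && nchar(codes) > 1L)
        codes <- strsplit(codes, "")[[1]]
    arch <- .archetypePatterns(codes, L, H)
    per <- rep(nGenes %/% nrow(arch), nrow(arch))
    per[seq_len(nGenes %% nrow(arch))] <- per[seq_len(nGenes %% nrow(arch))] + 1L
    if (nTopGenes > 0L) {
        arch <- rbind(arch, top = rep(topOcc, length(codes)))
        rownames(arch)[nrow(arch)] <- "(top)"
        per <- c(per, nTopGenes)
    }
    nTSS <- sum(per)
    nOther <- max(nProbesTotal - nTSS - nTTProbes, 0L)
    new("SyntheticConfig", codes = as.character(codes), archetypes = arch,
        genesPerPattern = as.integer(per), nTTProbes = as.integer(nTTProbes),
        nOtherProbes = as.integer(nOther),
        ipReplicates = as.integer(ipReplicates),
        bgReplicates = as.integer(bgReplicates),
        kappa = setNames(rep_len(kappa, length(codes)), codes),
        foldAt100 = foldAt100, backgroundLevel = backgroundLevel,
        sigma = sigma, occJitterSD = occJitterSD, seed = as.integer(seed))
}

#' Generate a probe-level dataset with planted occupancy structure
#'
#' Each gene draws a true occupancy vector near its pattern's archetype
#' (truncated-normal jitter); its TSS probe signal for factor `f` is
#' `backgroundLevel * (1 + kappa_f * occ/100 * (foldAt100 - 1))` times
#' lognormal noise.  T-T and filler probes sit at zero occupancy; background
#' replicates are noisy copies of the background level.  Byte-identical
#' under a fixed config and seed.
#'
#' @param config a [SyntheticConfig-class].
#' @return a [ProbeDataset-class]; the planted truth is attached in
#'   `rowData` columns `pattern` and `trueOcc.<code>`.
#' @export
generateProbeDataset <- function(config) {
    stopifnot(is(config, "SyntheticConfig"))
    set.seed(config@seed)
    codes <- config@codes
    n <- length(codes)
    nTSS <- sum(config@genesPerPattern)
    pattern <- rep(rownames(config@archetypes), config@genesPerPattern)
    trueOcc <- config@archetypes[pattern, , drop = FALSE] +
        matrix(rnorm(nTSS * n, 0, config@occJitterSD), nTSS, n)
    trueOcc <- pmin(pmax(trueOcc, 0), 100)
    nProbes <- nTSS + config@nTTProbes + config@nOtherProbes
    probeOcc <- rbind(trueOcc,
                      matrix(0, config@nTTProbes + config@nOtherProbes, n))
    colnames(probeOcc) <- codes
    probeClass <- c(rep("TSS", nTSS),
                    rep("TT_intergenic", config@nTTProbes),
                    rep("other", config@nOtherProbes))
    geneId <- c(sprintf("gene%05d", seq_len(nTSS)), rep(NA, nProbes - nTSS))
    ipNames <- as.vector(outer(codes, seq_len(config@ipReplicates),
                               function(f, r) paste0(f, "_rep", r)))
    bgNames <- paste0("BG_rep", seq_len(config@bgReplicates))
    sig <- matrix(NA_real_, nProbes, length(ipNames) + length(bgNames),
                  dimnames = list(
                      c(geneId[seq_len(nTSS)],
                        sprintf("tt%05d", seq_len(config@nTTProbes)),
                        sprintf("x%05d", seq_len(config@nOtherProbes))),
                      c(ipNames, bgNames)))
    col <- 0L
    for (r in seq_len(config@ipReplicates)) {
        for (f in seq_len(n)) {
            fold <- 1 + config@kappa[f] * probeOcc[, f] / 100 *
                (config@foldAt100 - 1)
            sig[, paste0(codes[f], "_rep", r)] <-
                config@backgroundLevel * fold *
                exp(rnorm(nProbes, 0, config@sigma))
        }
        col <- col + n
    }
    for (r in seq_len(config@bgReplicates))
        sig[, paste0("BG_rep", r)] <- config@backgroundLevel *
            exp(rnorm(nProbes, 0, config@sigma))
    pd <- ProbeDataset(signal = sig,
                       probeClass = probeClass,
                       geneId = geneId,
                       sampleType = c(rep("IP", length(ipNames)),
                                      rep("background", length(bgNames))),
                       factorCode = c(rep(codes, times = config@ipReplicates),
                                      rep(NA, length(bgNames))),
                       replicate = c(rep(seq_len(config@ipReplicates),
                                         each = n),
                                     seq_len(config@bgReplicates)))
    rd <- SummarizedExperiment::rowData(pd)
    rd$pattern <- c(pattern, rep(NA, nProbes - nTSS))
    for (f in seq_len(n))
        rd[[paste0("trueOcc.", codes[f])]] <- probeOcc[, f]
    SummarizedExperiment::rowData(pd) <- rd
    pd
}

#' Archetype group-median occupancy table
#'
#' One row per planted H/L pattern with its archetype occupancies: the
#' canonical direct input for the compatibility chart (2^n rows for n
#' factors, plus the top tier if configured with `includeTop = TRUE`).
#'
#' @param config a [SyntheticConfig-class], or `NULL` to build from `codes`,
#'   `L`, `H` directly.
#' @param codes,L,H used when `config` is `NULL` (defaults `T`,`B`,`P`,
#'   L = 5, H = 40).
#' @param includeTop keep the fully-occupied top tier row (default FALSE).
#' @return an [OccupancyTable-class].
#' @examples
#' generateGroupMedians(codes = "TB")  # 4 rows
#' @export
generateGroupMedians <- function(config = NULL, codes = c("T", "B", "P"),
                                 L = 5, H = 40, includeTop = FALSE) {
    if (!is.null(config)) {
        stopifnot(is(config, "SyntheticConfig"))
        arch <- config@archetypes
        if (!includeTop) arch <- arch[rownames(arch) != "(top)", , drop = FALSE]
        return(OccupancyTable(arch, FactorOrder(config@codes)))
    }
    if (length(codes) == 1L && nchar(codes) > 1L)
        codes <- strsplit(codes, "")[[1]]
    OccupancyTable(.archetypePatterns(codes, L, H), FactorOrder(codes))
}
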