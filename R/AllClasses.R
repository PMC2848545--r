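#' @import methods
#' @importFrom stats median quantile optim runif setNames kmeans rnorm
#' @importFrom utils head read.table write.table
#' @importFrom boot simplex
#' @importFrom deSolve lsoda
#' @importFrom S4Vectors DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData "rowData<-"
NULL

#' FactorOrder: a fixed association order of DNA-binding factors
#'
#' Represents the order in which `n` factors (each named by a single-character
#' code, e.g. `T` for TBP, `B` for TFIIB, `P` for RNA polymerase II) associate
#' onto DNA.  Association rank is the position in `codes`: the first code
#' associates first.
#'
#' @slot codes character vector of distinct single-character factor codes, in
#'   association order.
#' @export
setClass("FactorOrder", representation(codes = "character"))

setValidity("FactorOrder", function(object) {
    codes <- object@codes
    if (length(codes) < 1L)
        return("empty factor order: at least one factor code is required")
    if (length(codes) > 8L)
        return("at most 8 factors are supported (n! mechanisms are enumerated)")
    if (any(nchar(codes) != 1L) || any(grepl("[[:space:]]", codes)))
        return("factor codes must be single printable non-whitespace characters")
    if (anyDuplicated(codes))
        return("factor codes must be unique")
    TRUE
})

#' Mechanism: one association order paired with one dissociation order
#'
#' @slot association a [FactorOrder-class].
#' @slot dissociation character vector: permutation of the association codes,
#'   in dissociation order (first element leaves DNA first).
#' @slot id integer mechanism identifier: the 1-based position of the
#'   dissociation permutation in the canonical (lexicographic over
#'   association-rank indices) enumeration.
#' @export
setClass("Mechanism", representation(association = "FactorOrder",
                                     dissociation = "character",
                                     id = "integer"))

setValidity("Mechanism", function(object) {
    a <- object@association@codes
    d <- object@dissociation
    if (!setequal(a, d) || length(a) != length(d))
        return("dissociation must be a permutation of the association codes")
    if (length(object@id) != 1L || is.na(object@id) || object@id < 1L)
        return("mechanism id must be a positive integer")
    TRUE
})

#' StateCycle: the chain of DNA-bound states a mechanism traverses
#'
#' The DNA passes from the empty state through the assembly intermediates
#' (first k associating factors, k = 1..n), then sheds factors in dissociation
#' order back to the empty state: 2n states in all, of which the 2n - 1
#' non-empty ones may contain duplicates (assembly and disassembly legs can
#' visit the same subset).
#'
#' @slot states list of character vectors: the 2n states in cycle order,
#'   ending with the empty state (`character(0)`).
#' @slot occupiedStates list of character vectors: the distinct non-empty
#'   states.
#' @slot mechanism the generating [Mechanism-class].
#' @export
setClass("StateCycle", representation(states = "list",
                                      occupiedStates = "list",
                                      mechanism = "Mechanism"))

#' OccupancyTable: percent occupancy per gene or group (rows) and factor
#'
#' Columns follow the association order of `factorOrder`; values are percent
#' occupancies in [0, 100].
#'
#' @slot values numeric matrix, rows = genes/groups, columns = factor codes.
#' @slot factorOrder a [FactorOrder-class]; column order matches its codes.
#' @export
setClass("OccupancyTable", representation(values = "matrix",
                                          factorOrder = "FactorOrder"))

setValidity("OccupancyTable", function(object) {
    v <- object@values
    codes <- object@factorOrder@codes
    if (!is.numeric(v)) return("occupancies must be numeric")
    if (is.null(colnames(v)) || !identical(colnames(v), codes))
        return("column names must equal the factor codes in association order")
    if (nrow(v) < 1L) return("occupancy table has no rows")
    if (any(!is.finite(v))) return("occupancies must be finite")
    if (any(v < 0 | v > 100)) return("occupancies must lie in [0, 100]")
    TRUE
})

#' CompatibilityMatrix: groups x mechanisms chart of -1/0 calls
#'
#' Cells are -1 where the group's occupancies are compatible with the
#' mechanism and 0 where they are not (the tool's historical file encoding).
#'
#' @slot calls integer matrix in \{-1, 0\}; rownames = group names, colnames =
#'   mechanism ids.
#' @slot association the fixed [FactorOrder-class] the columns refer to.
#' @export
setClass("CompatibilityMatrix", representation(calls = "matrix",
                                               association = "FactorOrder"))

setValidity("CompatibilityMatrix", function(object) {
    m <- object@calls
    if (!all(m %in% c(-1L, 0L))) return("cells must be -1 or 0")
    if (is.null(rownames(m)) || is.null(colnames(m)))
        return("calls must carry group rownames and mechanism-id colnames")
    TRUE
})

#' FeasibilityResult: outcome of the dwell-fraction linear feasibility test
#'
#' @slot feasible logical.
#' @slot residual numeric: sum of squared equality violations (percent^2
#'   scale) at the phase-1 optimum; ~0 when feasible.
#' @slot certificate numeric or NULL: when infeasible, a Farkas vector y per
#'   factor with y'A <= 0 over occupied states and y . occ > 0, i.e. a linear
#'   combination of occupancies no dwell-fraction assignment can reach.
#' @slot dwell numeric or NULL: a witnessing dwell-fraction assignment over
#'   occupied states when feasible.
#' @export
setClass("FeasibilityResult", representation(feasible = "logical",
                                             residual = "numeric",
                                             certificate = "ANY",
                                             dwell = "ANY"))

#' KineticModel: irreversible mass-action model of a mechanism
#'
#' Species are the n free factors plus the DNA states of the mechanism's
#' [StateCycle-class] (distinct subsets, plus empty DNA).  Reactions are the
#' 2n cycle steps: association steps consume one free factor, dissociation
#' steps release one; all irreversible.
#'
#' @slot mechanism the [Mechanism-class] modeled.
#' @slot states list: distinct DNA states; element 1 is the empty state.
#' @slot reactions data.frame with columns `substrate`, `product` (state
#'   indices), `factor` (code), `type` ("association"/"dissociation").
#' @slot dnaTotal,proteinTotal numeric initial totals (default 10 and 10,
#'   arbitrary concentration units).
#' @export
setClass("KineticModel", representation(mechanism = "Mechanism",
                                        states = "list",
                                        reactions = "data.frame",
                                        dnaTotal = "numeric",
                                        proteinTotal = "numeric"))

#' FitResult: best multi-start least-squares fit of a kinetic model
#'
#' @slot E numeric: weighted sum of squared differences between target and
#'   simulated free-protein concentrations at steady state.
#' @slot log10E numeric: log10(max(E, 1e-12)).
#' @slot rates named numeric: fitted rate constants of the best restart.
#' @slot simulatedOcc named numeric: percent occupancies implied by the best
#'   fit's steady state.
#' @slot nRestarts,seed integers recording the search settings.
#' @export
setClass("FitResult", representation(E = "numeric",
                                     log10E = "numeric",
                                     rates = "numeric",
                                     simulatedOcc = "numeric",
                                     nRestarts = "integer",
                                     seed = "integer"))

#' ProbeDataset: probe-level microarray signals with probe annotations
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one `signal` assay
#' (probes x samples).  `rowData` must carry `probeClass` (one of `TSS`,
#' `TT_intergenic`, `other`) and `geneId` (NA except for TSS probes);
#' `colData` must carry `sampleType` (`IP` or `background`), `factorCode`
#' (single-character code for IP samples, NA for background) and `replicate`.
#'
#' @export
setClass("ProbeDataset", contains = "SummarizedExperiment")

setValidity("ProbeDataset", function(object) {
    rd <- SummarizedExperiment::rowData(object)
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("probeClass", "geneId") %in% colnames(rd)))
        return("rowData must contain probeClass and geneId")
    if (!all(rd$probeClass %in% c("TSS", "TT_intergenic", "other")))
        return("probeClass must be TSS, TT_intergenic or other")
    if (!all(c("sampleType", "factorCode", "replicate") %in% colnames(cd)))
        return("colData must contain sampleType, factorCode and replicate")
    if (!all(cd$sampleType %in% c("IP", "background")))
        return("sampleType must be IP or background")
    if (!"signal" %in% SummarizedExperiment::assayNames(object))
        return("a 'signal' assay is required")
    sig <- SummarizedExperiment::assay(object, "signal")
    if (any(!is.finite(sig)) || any(sig <= 0))
        return("signals must be finite and positive")
    tss <- rd$probeClass == "TSS"
    if (any(is.na(rd$geneId[tss])))
        return("TSS probes must carry a geneId")
    if (any(!is.na(rd$geneId[rd$probeClass == "TT_intergenic"])))
        return("T-T intergenic probes must not carry a geneId")
    TRUE
})

#' SyntheticConfig: design of a simulated probe-level experiment
#'
#' Defaults emulate the study design the package targets: ~20,000 probes of a
#' low-density tiling array with one TSS probe for each of 5,743 genes, 2,000
#' tail-to-tail intergenic control probes, archetype H/L occupancy patterns at
#' L = 5% / H = 40%, plus a small top tier of fully occupied genes anchoring
#' the 99th-percentile scaling.
#'
#' @slot codes character: factor codes in association order.
#' @slot archetypes numeric matrix: one row per planted pattern (rownames =
#'   pattern labels), columns = codes, percent occupancy.
#' @slot genesPerPattern integer vector parallel to archetype rows.
#' @slot nTTProbes,nOtherProbes integers: control and filler probe counts.
#' @slot ipReplicates,bgReplicates integers: replicates per factor IP and for
#'   the untagged background strain.
#' @slot kappa named numeric: per-factor crosslinking scale (fold units per
#'   100% occupancy, relative to the fold anchor).
#' @slot foldAt100 numeric: fold over background produced by 100% occupancy at
#'   kappa = 1.
#' @slot backgroundLevel numeric: expected raw background signal.
#' @slot sigma numeric: lognormal noise sd (log scale) applied to each signal.
#' @slot occJitterSD numeric: sd of the per-gene jitter around its pattern's
#'   archetype occupancy.
#' @slot seed integer RNG seed.
#' @export
setClass("SyntheticConfig", representation(codes = "character",
                                           archetypes = "matrix",
                                           genesPerPattern = "integer",
                                           nTTProbes = "integer",
                                           nOtherProbes = "integer",
                                           ipReplicates = "integer",
                                           bgReplicates = "integer",
                                           kappa = "numeric",
                                           foldAt100 = "numeric",
                                           backgroundLevel = "numeric",
                                           sigma = "numeric",
                                           occJitterSD = "numeric",
                                           seed = "integer"))

setValidity("SyntheticConfig", function(object) {
    if (ncol(object@archetypes) != length(object@codes))
        return("archetype columns must match the factor codes")
    if (length(object@genesPerPattern) != nrow(object@archetypes))
        return("genesPerPattern must parallel the archetype rows")
    if (any(object@genesPerPattern < 0L)) return("gene counts must be >= 0")
    if (any(object@archetypes < 0 | object@archetypes > 100))
        return("archetype occupancies must lie in [0, 100]")
    if (any(object@kappa <= 0)) return("kappa must be positive")
    if (object@foldAt100 <= 1) return("foldAt100 must exceed 1")
    if (object@sigma < 0) return("sigma must be >= 0")
    TRUE
})
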