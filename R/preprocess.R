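# Probe-level signal -> percent occupancy -> H/L groups -> group medians.
#
# The chain follows the low-density tiling ChIP-chip design: background-strain
# normalization, per-probe fold over background centered on tail-to-tail
# (T-T) intergenic probes, 0-100% scaling anchored at the 99th percentile,
# binarization at a 10% cutoff and (beyond three factors) consolidation of
# under-populated groups.

#' Construct a ProbeDataset
#'
#' @param signal numeric matrix, probes x samples, positive raw signals.
#' @param probeClass character per probe: `TSS`, `TT_intergenic` or `other`.
#' @param geneId character per probe (NA except TSS probes).
#' @param sampleType character per sample: `IP` or `background`.
#' @param factorCode character per sample: factor code for IP samples, NA for
#'   background.
#' @param replicate integer per sample.
#' @return a [ProbeDataset-class].
#' @export
ProbeDataset <- function(signal, probeClass, geneId, sampleType, factorCode,
                         replicate) {
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(signal = as.matrix(signal)),
        rowData = S4Vectors::DataFrame(probeClass = probeClass,
                                       geneId = geneId),
        colData = S4Vectors::DataFrame(sampleType = sampleType,
                                       factorCode = factorCode,
                                       replicate = replicate))
    new("ProbeDataset", se)
}

#' Combine background-strain replicates into one per-probe background
#'
#' Each replicate is first normalized to its own grand median, then the
#' replicates are combined by taking the per-probe median.
#'
#' @param replicates numeric matrix, probes x replicates, positive.
#' @return numeric vector, one background value per probe.
#' @examples
#' combineBackground(cbind(c(1, 2, 4), c(2, 4, 8)))
#' @export
combineBackground <- function(replicates) {
    replicates <- as.matrix(replicates)
    if (ncol(replicates) < 1L) stop("need at least one background replicate")
    if (any(!is.finite(replicates)) || any(replicates <= 0))
        stop("background signals must be finite and positive")
    normed <- sweep(replicates, 2L, apply(replicates, 2L, median), "/")
    apply(normed, 1L, median)
}

#' Per-probe fold over background, centered on T-T intergenic probes
#'
#' Divides the factor signal by the background probe-by-probe, then by the
#' median of the resulting ratios over the T-T probes, so the fold in
#' factor-free regions centers at exactly 1.
#'
#' @param signal numeric vector: one (replicate-combined) factor-IP value per
#'   probe.
#' @param background numeric vector from [combineBackground()].
#' @param ttProbes logical/integer index of the T-T intergenic probes.
#' @return numeric vector of fold-over-background values.
#' @export
foldOverBackground <- function(signal, background, ttProbes) {
    if (length(signal) != length(background))
        stop("signal and background must cover the same probes")
    ratio <- signal / background
    tt <- ratio[ttProbes]
    if (length(tt) == 0L) stop("no T-T intergenic probes available")
    ttMedian <- median(tt)
    if (!is.finite(ttMedian) || ttMedian <= 0)
        stop("T-T median must be positive")
    ratio / ttMedian
}

#' Scale fold-over-background to percent occupancy
#'
#' Folds at or below 1 are background and become 0%; folds at or above the
#' `upperPercentile`-th percentile (rank `ceiling(q * N)` of the sorted
#' folds) become 100%; in between, background (1) is subtracted and the
#' result divided by `p - 1` where `p` is the percentile anchor, so that the
#' anchor itself maps to exactly 100%.
#'
#' @param folds positive numeric vector over all probes of one factor.
#' @param upperPercentile percentile anchoring 100% (default 99; 98
#'   reproduces the alternative-anchor variant).
#' @return numeric vector of percent occupancies in [0, 100].
#' @examples
#' scalePercent(c(1, 3, 5), upperPercentile = 99)  # anchor 5 -> 0, 50, 100
#' @export
scalePercent <- function(folds, upperPercentile = 99) {
    if (any(!is.finite(folds)) || any(folds <= 0))
        stop("folds must be finite and positive")
    n <- length(folds)
    p <- sort(folds)[ceiling(upperPercentile / 100 * n)]
    if (p <= 1) stop("degenerate dataset: percentile anchor <= background")
    pmin(pmax(100 * (folds - 1) / (p - 1), 0), 100)
}

#' Probe-level signals to a per-gene occupancy table
#'
#' Runs the full chain for each factor: combine background replicates,
#' combine factor-IP replicates (per-probe median), fold over background
#' centered on T-T probes, scale to percent with the percentile anchor, then
#' keep the TSS probe of each gene.  Genes lacking a usable TSS value for
#' any modeled factor are dropped with a message.
#'
#' @param probes a [ProbeDataset-class].
#' @param assoc the modeled [FactorOrder-class] (codes must appear among the
#'   dataset's IP factor codes).
#' @param upperPercentile passed to [scalePercent()].
#' @return an [OccupancyTable-class] with one row per gene.
#' @export
occupancyFromProbes <- function(probes, assoc, upperPercentile = 99) {
    stopifnot(is(probes, "ProbeDataset"))
    if (!is(assoc, "FactorOrder")) assoc <- FactorOrder(assoc)
    codes <- assoc@codes
    sig <- SummarizedExperiment::assay(probes, "signal")
    cd <- SummarizedExperiment::colData(probes)
    rd <- SummarizedExperiment::rowData(probes)
    bgCols <- which(cd$sampleType == "background")
    if (length(bgCols) == 0L) stop("no background samples in the dataset")
    background <- combineBackground(sig[, bgCols, drop = FALSE])
    tt <- rd$probeClass == "TT_intergenic"
    pct <- sapply(codes, function(fc) {
        cols <- which(cd$sampleType == "IP" & cd$factorCode == fc)
        if (length(cols) == 0L) stop("no IP samples for factor ", fc)
        combined <- apply(sig[, cols, drop = FALSE], 1L, median)
        scalePercent(foldOverBackground(combined, background, tt),
                     upperPercentile)
    })
    tss <- which(rd$probeClass == "TSS")
    genes <- rd$geneId[tss]
    keep <- !duplicated(genes) & !is.na(genes)
    dropped <- sum(!keep)
    if (dropped > 0L)
        message(dropped, " TSS probe(s) dropped (duplicate or missing gene)")
    OccupancyTable(pct[tss[keep], , drop = FALSE], assoc,
                   rowNames = genes[keep])
}

#' Binarize occupancies into H/L pattern labels
#'
#' Per gene and factor: occupancy below `cutoff` is low (L), all others high
#' (H) -- an exact-cutoff value is H.  The pattern concatenates the letters
#' in association order, e.g. `"(L,H,H)"`.
#'
#' @param table an [OccupancyTable-class].
#' @param cutoff percent cutoff (default 10; 15 and the three-tier variants
#'   are robustness settings).
#' @return character vector of pattern labels, one per row of `table`.
#' @examples
#' tab <- OccupancyTable(rbind(c(9.99, 10), c(40, 5)), "TB")
#' assignGroups(tab)  # "(L,H)" "(H,L)"
#' @export
assignGroups <- function(table, cutoff = 10) {
    stopifnot(is(table, "OccupancyTable"))
    v <- occupancies(table)
    letters <- ifelse(v < cutoff, "L", "H")
    paste0("(", apply(letters, 1L, paste, collapse = ","), ")")
}

#' Consolidate under-populated child groups after adding a factor
#'
#' When a new factor splits each parent group into two children, a split is
#' kept only if it is well supported: both children are kept if each has
#' more than 100 genes (exempt from consolidation), or if the split is no
#' worse than 4:1 with both children at 10 or more genes.  Otherwise the two
#' children are merged back into one group carrying the larger child's
#' label.  Total membership is conserved.
#'
#' @param parentLabels character per gene: group labels before the factor
#'   was added.
#' @param childLabels character per gene: labels after adding the factor
#'   (must refine `parentLabels`).
#' @return character per gene: consolidated labels.
#' @export
consolidateGroups <- function(parentLabels, childLabels) {
    if (length(parentLabels) != length(childLabels))
        stop("parent and child labels must cover the same genes")
    if (anyNA(parentLabels) || anyNA(childLabels)) stop("labels must not be NA")
    crossTab <- table(parentLabels, childLabels)
    if (any(colSums(crossTab > 0) > 1L))
        stop("child labels do not refine the parent labels")
    out <- childLabels
    for (p in rownames(crossTab)) {
        kids <- colnames(crossTab)[crossTab[p, ] > 0L]
        if (length(kids) != 2L) next
        sizes <- crossTab[p, kids]
        merge <- if (any(sizes < 10L)) TRUE
                 else if (all(sizes > 100L)) FALSE
                 else max(sizes) / min(sizes) > 4
        if (merge)
            out[childLabels %in% kids] <- kids[which.max(sizes)]
    }
    out
}

#' Per-group, per-factor median occupancies
#'
#' @param table an [OccupancyTable-class] of gene-level occupancies.
#' @param labels character group label per gene (e.g. from [assignGroups()]
#'   or [groupOccupancies()]).
#' @return an [OccupancyTable-class] with one row per group (valid direct
#'   input for [compatibilityMatrix()]); attribute `membership` carries the
#'   gene counts.
#' @export
groupMedians <- function(table, labels) {
    stopifnot(is(table, "OccupancyTable"))
    v <- occupancies(table)
    if (length(labels) != nrow(v))
        stop("need one label per gene")
    groups <- sort(unique(labels))
    med <- t(vapply(groups, function(g)
        apply(v[labels == g, , drop = FALSE], 2L, median),
        numeric(ncol(v))))
    out <- OccupancyTable(med, table@factorOrder, rowNames = groups)
    attr(out@values, "membership") <- as.integer(table(labels)[groups])
    out
}

#' Gene grouping with incremental consolidation
#'
#' Labels genes by H/L pattern, adding one factor at a time in association
#' order and applying [consolidateGroups()] at each step once more than
#' three factors are in play (consolidation is skipped for two- and
#' three-factor models).
#'
#' @inheritParams assignGroups
#' @param consolidate logical (default TRUE): apply the consolidation rules
#'   for models of four or more factors.
#' @return character vector of final group labels per gene.
#' @export
groupOccupancies <- function(table, cutoff = 10, consolidate = TRUE) {
    stopifnot(is(table, "OccupancyTable"))
    v <- occupancies(table)
    letters <- ifelse(v < cutoff, "L", "H")
    n <- ncol(v)
    patt <- function(k) paste0("(", apply(letters[, seq_len(k), drop = FALSE],
                                          1L, paste, collapse = ","), ")")
    labels <- patt(min(n, 2L))
    if (n <= 3L || !consolidate) return(patt(n))
    labels <- patt(3L)
    for (k in 4:n) {
        child <- paste0(substr(labels, 1L, nchar(labels) - 1L), ",",
                        letters[, k], ")")
        labels <- consolidateGroups(labels, child)
    }
    labels
}
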