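#' Construct a FactorOrder
#'
#' @param codes either a character vector of single-character codes in
#'   association order, or a single string such as `"TBP"` (split into
#'   characters).
#' @return a [FactorOrder-class].
#' @examples
#' FactorOrder("TBP")
#' FactorOrder(c("T", "B"))
#' @export
FactorOrder <- function(codes) {
    if (length(codes) == 1L && nchar(codes) > 1L)
        codes <- strsplit(codes, "")[[1]]
    new("FactorOrder", codes = as.character(codes))
}

#' Construct an OccupancyTable
#'
#' @param values numeric matrix (or data.frame) of percent occupancies; rows
#'   are genes or groups, columns are factors.  Columns are reordered to
#'   association order by name when column names are present.
#' @param factorOrder a [FactorOrder-class] or anything accepted by
#'   [FactorOrder()].
#' @param rowNames optional row (group) names.
#' @return an [OccupancyTable-class].
#' @examples
#' OccupancyTable(rbind(`(L,H)` = c(5, 40), `(H,H)` = c(40, 60)), "TB")
#' @export
OccupancyTable <- function(values, factorOrder, rowNames = NULL) {
    if (!is(factorOrder, "FactorOrder")) factorOrder <- FactorOrder(factorOrder)
    values <- as.matrix(values)
    codes <- factorOrder@codes
    if (!is.null(colnames(values))) {
        if (!setequal(colnames(values), codes))
            stop("column names do not match the factor codes: ",
                 paste(colnames(values), collapse = ","))
        values <- values[, codes, drop = FALSE]
    } else {
        if (ncol(values) != length(codes))
            stop("need one column per factor code")
        colnames(values) <- codes
    }
    if (!is.null(rowNames)) rownames(values) <- rowNames
    if (is.null(rownames(values)))
        rownames(values) <- paste0("group", seq_len(nrow(values)))
    new("OccupancyTable", values = values, factorOrder = factorOrder)
}

#' @describeIn FactorOrder-class the factor codes in association order.
#' @param x,object an object.
#' @export
setGeneric("factorCodes", function(x) standardGeneric("factorCodes"))

#' @rdname FactorOrder-class
#' @export
setMethod("factorCodes", "FactorOrder", function(x) x@codes)

#' @rdname Mechanism-class
#' @export
setMethod("factorCodes", "Mechanism", function(x) x@association@codes)

#' @rdname OccupancyTable-class
#' @export
setMethod("factorCodes", "OccupancyTable", function(x) x@factorOrder@codes)

#' @describeIn Mechanism-class the dissociation order (first code leaves
#'   first).
#' @export
setGeneric("dissociationOrder", function(x) standardGeneric("dissociationOrder"))

#' @rdname Mechanism-class
#' @export
setMethod("dissociationOrder", "Mechanism", function(x) x@dissociation)

#' @describeIn Mechanism-class the canonical mechanism id.
#' @export
setGeneric("mechanismId", function(x) standardGeneric("mechanismId"))

#' @rdname Mechanism-class
#' @export
setMethod("mechanismId", "Mechanism", function(x) x@id)

#' @describeIn OccupancyTable-class the numeric matrix of percent
#'   occupancies.
#' @export
setGeneric("occupancies", function(x) standardGeneric("occupancies"))

#' @rdname OccupancyTable-class
#' @export
setMethod("occupancies", "OccupancyTable", function(x) x@values)

#' @describeIn CompatibilityMatrix-class the integer -1/0 call matrix.
#' @export
setGeneric("compatibilityCalls", function(x) standardGeneric("compatibilityCalls"))

#' @rdname CompatibilityMatrix-class
#' @export
setMethod("compatibilityCalls", "CompatibilityMatrix", function(x) x@calls)

#' @describeIn StateCycle-class the distinct non-empty DNA states.
#' @export
setGeneric("occupiedStates", function(x) standardGeneric("occupiedStates"))

#' @rdname StateCycle-class
#' @export
setMethod("occupiedStates", "StateCycle", function(x) x@occupiedStates)

setMethod("length", "FactorOrder", function(x) length(x@codes))

setMethod("show", "FactorOrder", function(object) {
    cat("FactorOrder:", paste(object@codes, collapse = " -> "), "\n")
})

setMethod("show", "Mechanism", function(object) {
    cat(sprintf("Mechanism #%d: assoc %s | dissoc %s\n", object@id,
                paste(object@association@codes, collapse = "->"),
                paste(object@dissociation, collapse = "->")))
})

setMethod("show", "StateCycle", function(object) {
    lab <- vapply(object@states, function(s)
        if (length(s)) paste(s, collapse = "") else "0", "")
    cat("StateCycle:", paste(lab, collapse = " -> "), "\n")
    cat(sprintf("%d distinct occupied states\n", length(object@occupiedStates)))
})

setMethod("show", "OccupancyTable", function(object) {
    cat(sprintf("OccupancyTable: %d group(s) x %d factor(s) [%s]\n",
                nrow(object@values), ncol(object@values),
                paste(factorCodes(object), collapse = "->")))
    print(head(object@values, 8))
    if (nrow(object@values) > 8) cat("...\n")
})

setMethod("show", "CompatibilityMatrix", function(object) {
    cat(sprintf("CompatibilityMatrix: %d group(s) x %d mechanism(s), assoc %s\n",
                nrow(object@calls), ncol(object@calls),
                paste(object@association@codes, collapse = "->")))
    print(object@calls)
})

setMethod("show", "FeasibilityResult", function(object) {
    cat(sprintf("FeasibilityResult: %s (residual %.3g)\n",
                if (object@feasible) "feasible" else "infeasible",
                object@residual))
    if (!is.null(object@certificate)) {
        cat("Farkas certificate (y . occ > 0, y'A <= 0):\n")
        print(object@certificate)
    }
})

setMethod("show", "FitResult", function(object) {
    cat(sprintf("FitResult: E = %.4g (log10E = %.2f), %d restart(s), seed %d\n",
                object@E, object@log10E, object@nRestarts, object@seed))
})

setMethod("show", "KineticModel", function(object) {
    cat(sprintf("KineticModel: %d factors, %d DNA states, %d irreversible reactions\n",
                length(object@mechanism@association@codes),
                length(object@states), nrow(object@reactions)))
})
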