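#' Accessors for pipeline objects
#'
#' Small accessor generics in the Bioconductor style so slots are never
#' reached into directly: \code{driverAnnot} returns the patient x driver
#' binary matrix, \code{sampleId} the (pseudo-)sample identifier,
#' \code{netNodes}/\code{netEdges} the node and edge tables of a network or
#' pattern, \code{occurrence} the binary matrix of an
#' \linkS4class{OccurrenceMatrix}, \code{supportSet} and
#' \code{canonicalCode} the support and canonical DFS code of a
#' \linkS4class{FrequentSubnetwork}.
#'
#' @param x an object of the documented class.
#' @return The slot content described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("driverAnnot", function(x) standardGeneric("driverAnnot"))

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("netNodes", function(x) standardGeneric("netNodes"))

#' @rdname accessors
#' @export
setGeneric("netEdges", function(x) standardGeneric("netEdges"))

#' @rdname accessors
#' @export
setGeneric("occurrence", function(x) standardGeneric("occurrence"))

#' @rdname accessors
#' @export
setGeneric("supportSet", function(x) standardGeneric("supportSet"))

#' @rdname accessors
#' @export
setGeneric("canonicalCode", function(x) standardGeneric("canonicalCode"))

#' @rdname accessors
#' @export
setMethod("driverAnnot", "AnnotatedCohort", function(x) x@driverAnnot)

#' @rdname accessors
#' @export
setMethod("sampleId", "MCTCNetwork", function(x) x@sampleId)

#' @rdname accessors
#' @export
setMethod("sampleId", "PseudoSample", function(x) x@sampleId)

#' @rdname accessors
#' @export
setMethod("netNodes", "MCTCNetwork", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("netEdges", "MCTCNetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("netNodes", "FrequentSubnetwork", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("netEdges", "FrequentSubnetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("occurrence", "OccurrenceMatrix", function(x) x@mat)

#' @rdname accessors
#' @export
setMethod("supportSet", "FrequentSubnetwork", function(x) x@supportSet)

#' @rdname accessors
#' @export
setMethod("canonicalCode", "FrequentSubnetwork", function(x) x@canonicalCode)

#' @describeIn accessors cell types declared in the cohort vocabulary.
#' @export
cohortCellTypes <- function(x) {
    stopifnot(is(x, "AnnotatedCohort"))
    levels(colData(x)$cell_type)
}

#' @describeIn accessors patient identifiers of the cohort.
#' @export
patientIds <- function(x) {
    stopifnot(is(x, "AnnotatedCohort"))
    rownames(x@driverAnnot)
}

#' @describeIn accessors per-cell metadata (cell_id, patient_id, cell_type).
#' @export
cellMeta <- function(x) {
    stopifnot(is(x, "AnnotatedCohort"))
    data.frame(cell_id = colnames(x),
               patient_id = as.character(colData(x)$patient_id),
               cell_type = as.character(colData(x)$cell_type),
               stringsAsFactors = FALSE)
}

#' @describeIn accessors log-normalized expression matrix (genes x cells).
#' @export
exprMatrix <- function(x) {
    stopifnot(is(x, "AnnotatedCohort"))
    as.matrix(assay(x, "logcounts"))
}

#' @describeIn accessors per-(gene, cell type) retention mask recorded by
#'   [filterLowExpressed()], or NULL if filtering has not been run.
#' @export
retentionMask <- function(x) {
    stopifnot(is(x, "AnnotatedCohort"))
    metadata(x)$retention
}

setMethod("show", "AnnotatedCohort", function(object) {
    callNextMethod()
    cat("driverAnnot:", nrow(object@driverAnnot), "patients x",
        ncol(object@driverAnnot), "drivers\n")
    cat("cell types:", paste(cohortCellTypes(object), collapse = ", "), "\n")
})

setMethod("show", "PseudoSample", function(object) {
    n <- vapply(object@cellsByType, length, integer(1))
    cat("PseudoSample", object@sampleId, "from patient",
        object@sourcePatient, "(replicate", object@replicateIndex, ")\n")
    cat("  cells:", paste(sprintf("%s=%d", names(n), n), collapse = ", "),
        "\n")
})

setMethod("show", "MCTCNetwork", function(object) {
    cat("MCTCNetwork", object@sampleId, "with", nrow(object@nodes),
        "nodes and", nrow(object@edges), "edges (",
        sum(object@edges$kind == "intercellular"), "intercellular )\n")
})

setMethod("show", "FrequentSubnetwork", function(object) {
    cat("FrequentSubnetwork", object@patternId, ":",
        signatureNotation(object), "\n  support:",
        length(object@supportSet), "samples\n")
})

setMethod("show", "OccurrenceMatrix", function(object) {
    cat("OccurrenceMatrix:", nrow(object@mat), "samples x",
        ncol(object@mat), "frequent subnetworks\n")
})

setMethod("show", "BulkCohort", function(object) {
    cat("BulkCohort:", nrow(object@expr), "genes x", ncol(object@expr),
        "samples;", sum(object@clinical$event), "events in",
        nrow(object@clinical), "annotated samples\n")
})

setMethod("show", "IEPath", function(object) {
    if (length(object@nodes))
        cat("IEPath (", object@length, "edges):",
            paste(object@nodes, collapse = " -> "), "\n")
    else
        cat("IEPath:", object@driverNode, "->", object@targetNode,
            "(unreachable)\n")
})
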