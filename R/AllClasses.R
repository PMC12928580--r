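#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment assay assayNames colData
#' @importFrom SingleCellExperiment SingleCellExperiment
NULL

#' Annotated single-cell cohort
#'
#' An \code{AnnotatedCohort} is a \linkS4class{SingleCellExperiment} whose
#' \code{colData} carries per-cell \code{patient_id} and \code{cell_type}
#' labels, extended with a patient-by-driver binary annotation matrix
#' encoding which driver-gene events are present in each patient. It is the
#' entry point of the pipeline: expression is stored log-normalized in the
#' \code{"logcounts"} assay (raw counts, when supplied, are kept in
#' \code{"counts"}).
#'
#' Cell types form a declared finite vocabulary (the levels of the
#' \code{cell_type} factor); every cell's patient must appear in the driver
#' annotation, gene and cell identifiers are unique, and expression is
#' non-negative.
#'
#' @slot driverAnnot numeric matrix, patients x driver genes, values in
#'   \{0, 1\}; 1 means the driver event is present in that patient.
#'
#' @seealso [AnnotatedCohort()], [readCohort()], [filterLowExpressed()]
#' @export
setClass("AnnotatedCohort",
    contains = "SingleCellExperiment",
    slots = c(driverAnnot = "matrix"))

setValidity("AnnotatedCohort", function(object) {
    msg <- character()
    cd <- colData(object)
    if (!all(c("patient_id", "cell_type") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'patient_id' and 'cell_type'")
    else {
        if (!is.factor(cd$cell_type))
            msg <- c(msg, "'cell_type' must be a factor (declared vocabulary)")
        da <- object@driverAnnot
        if (is.null(rownames(da)))
            msg <- c(msg, "driverAnnot must have patient rownames")
        else if (!all(as.character(cd$patient_id) %in% rownames(da)))
            msg <- c(msg, "every cell's patient_id must appear in driverAnnot")
        if (length(da) && !all(da %in% c(0, 1)))
            msg <- c(msg, "driverAnnot values must be 0 or 1")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "gene identifiers must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "cell identifiers must be unique")
    if (length(assayNames(object))) {
        a <- assay(object, 1L)
        if (min(a) < 0)
            msg <- c(msg, "expression must be non-negative")
    }
    if (length(msg)) msg else TRUE
})

#' One bootstrap pseudo-sample of a patient
#'
#' Holds the cell draw of a single pseudo-sample: for each focal cell type, a
#' multiset of cell identifiers sampled (with replacement) from one source
#' patient, together with that patient's driver annotation row. Undersized
#' patients included directly carry \code{replicateIndex} 0 and all their
#' cells.
#'
#' @slot sampleId character, unique pseudo-sample identifier.
#' @slot sourcePatient character, the patient the cells were drawn from.
#' @slot replicateIndex integer >= 0; 0 is reserved for directly included
#'   undersized patients.
#' @slot cellsByType named list, one character vector (with possible
#'   repetitions) of cell ids per focal cell type.
#' @slot driverVector named numeric 0/1 vector, the source patient's row of
#'   the cohort driver annotation.
#'
#' @seealso [generatePseudosamples()]
#' @export
setClass("PseudoSample",
    slots = c(sampleId = "character", sourcePatient = "character",
              replicateIndex = "integer", cellsByType = "list",
              driverVector = "numeric"))

setValidity("PseudoSample", function(object) {
    msg <- character()
    if (length(object@sampleId) != 1L || !nzchar(object@sampleId))
        msg <- c(msg, "sampleId must be a single non-empty string")
    if (object@replicateIndex < 0L)
        msg <- c(msg, "replicateIndex must be >= 0")
    if (is.null(names(object@cellsByType)))
        msg <- c(msg, "cellsByType must be named by cell type")
    if (length(msg)) msg else TRUE
})

#' Multi-cell-type communication network
#'
#' An undirected labeled graph for one (pseudo-)sample. Nodes are
#' (gene, cell type) pairs; edges are typed \code{"intracellular"} (both
#' endpoints in the same cell type) or \code{"intercellular"} (endpoints in
#' different cell types). No edge weights or node prizes are stored: the
#' object is the unweighted union of pairwise signal-transduction networks
#' and is what the frequent-subnetwork miner consumes.
#'
#' @slot sampleId character identifier of the (pseudo-)sample.
#' @slot nodes data.frame with columns \code{gene}, \code{cell_type}.
#' @slot edges data.frame with columns \code{gene_a}, \code{type_a},
#'   \code{gene_b}, \code{type_b}, \code{kind}.
#' @slot info list of optional metadata (e.g. expansion bookkeeping).
#'
#' @seealso [readNetwork()], [litePairwiseNetwork()], [unionNetworks()]
#' @export
setClass("MCTCNetwork",
    slots = c(sampleId = "character", nodes = "data.frame",
              edges = "data.frame", info = "list"))

setValidity("MCTCNetwork", function(object) {
    msg <- character()
    nd <- object@nodes
    ed <- object@edges
    if (!all(c("gene", "cell_type") %in% colnames(nd)))
        msg <- c(msg, "nodes need columns 'gene' and 'cell_type'")
    if (!all(c("gene_a", "type_a", "gene_b", "type_b", "kind") %in%
             colnames(ed)))
        msg <- c(msg, "edges need gene_a/type_a/gene_b/type_b/kind")
    if (length(msg)) return(msg)
    if (anyDuplicated(paste(nd$gene, nd$cell_type, sep = "@")))
        msg <- c(msg, "duplicate nodes")
    if (nrow(ed)) {
        same <- ed$type_a == ed$type_b
        if (any(same & ed$gene_a == ed$gene_b))
            msg <- c(msg, "self-loop edges are not allowed")
        bad <- (same & ed$kind != "intracellular") |
               (!same & ed$kind != "intercellular")
        if (any(bad))
            msg <- c(msg, "edge kind inconsistent with endpoint cell types")
        key <- edgeKey(ed)
        if (anyDuplicated(key))
            msg <- c(msg, "parallel edges are not allowed")
        lab <- c(paste(ed$gene_a, ed$type_a, sep = "@"),
                 paste(ed$gene_b, ed$type_b, sep = "@"))
        if (!all(lab %in% paste(nd$gene, nd$cell_type, sep = "@")))
            msg <- c(msg, "edge endpoints must be listed as nodes")
    }
    if (length(msg)) msg else TRUE
})

#' Frequent connected subnetwork
#'
#' A connected labeled subgraph mined from a collection of MCTC networks,
#' identified by its canonical (minimum) DFS code, together with the exact
#' set of samples whose network contains it.
#'
#' @slot patternId integer identifier assigned by the miner.
#' @slot canonicalCode character, the minimum DFS code serialized as an
#'   edge-tuple sequence; equal codes mean isomorphic patterns.
#' @slot nodes data.frame with columns \code{gene}, \code{cell_type}.
#' @slot edges data.frame as in \linkS4class{MCTCNetwork}.
#' @slot supportSet character vector of supporting sample ids.
#'
#' @seealso [gspanMine()], [encodeOccurrence()]
#' @export
setClass("FrequentSubnetwork",
    slots = c(patternId = "integer", canonicalCode = "character",
              nodes = "data.frame", edges = "data.frame",
              supportSet = "character"))

#' Binary pseudo-sample x subnetwork occurrence matrix
#'
#' The one-hot encoding of mined frequent subnetworks: entry (i, j) is 1
#' exactly when sample i's network contains a subgraph isomorphic
#' (label-preservingly) to pattern j. Columns are the extrinsic feature
#' vectors fed to the association test.
#'
#' @slot mat integer 0/1 matrix; rownames are sample ids, colnames pattern
#'   ids.
#'
#' @seealso [encodeOccurrence()], [associateAll()]
#' @export
setClass("OccurrenceMatrix", slots = c(mat = "matrix"))

setValidity("OccurrenceMatrix", function(object) {
    m <- object@mat
    msg <- character()
    if (length(m) && !all(m %in% c(0L, 1L)))
        msg <- c(msg, "occurrence matrix must be binary")
    if (is.null(rownames(m)))
        msg <- c(msg, "occurrence matrix needs sample rownames")
    if (length(msg)) msg else TRUE
})

#' Bulk expression cohort with clinical follow-up
#'
#' Holds a gene x sample bulk expression matrix plus per-sample survival
#' annotations used by the signature stratification and log-rank analyses.
#'
#' @slot expr numeric matrix, genes x samples.
#' @slot clinical data.frame with columns \code{sample}, \code{time}
#'   (follow-up, > 0, in the cohort's native unit) and \code{event}
#'   (1 = event observed, 0 = censored).
#'
#' @seealso [readBulkCohort()], [stratifyBulk()], [logrankGroups()]
#' @export
setClass("BulkCohort", slots = c(expr = "matrix", clinical = "data.frame"))

setValidity("BulkCohort", function(object) {
    msg <- character()
    cl <- object@clinical
    if (!all(c("sample", "time", "event") %in% colnames(cl)))
        msg <- c(msg, "clinical needs columns sample/time/event")
    else {
        if (!all(cl$sample %in% colnames(object@expr)))
            msg <- c(msg, "clinical samples must be expression columns")
        if (any(cl$time <= 0))
            msg <- c(msg, "follow-up times must be positive")
        if (!all(cl$event %in% c(0, 1)))
            msg <- c(msg, "event must be 0/1")
    }
    if (length(msg)) msg else TRUE
})

#' Intrinsic-extrinsic signaling path
#'
#' An ordered node sequence in a driver-expanded MCTC network, from the
#' driver-gene node in the cancer cell type to one node of an associated
#' communication signature, of minimal edge count.
#'
#' @slot driverNode character "gene@celltype" label of the driver node.
#' @slot targetNode character label of the reached signature node.
#' @slot nodes character vector of node labels along the path (first is the
#'   driver node, last the target; empty when the target is unreachable).
#' @slot length integer edge count (\code{NA} when unreachable).
#'
#' @seealso [iePaths()]
#' @export
setClass("IEPath",
    slots = c(driverNode = "character", targetNode = "character",
              nodes = "character", length = "integer"))
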