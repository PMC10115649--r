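#' @import methods
NULL

#' Germline-rooted clone phylogeny
#'
#' A rooted tree over tumour clones. Node 0 is the normal diploid germline
#' ancestor; its single child is the most recent common ancestor (MRCA) of
#' all sequenced tumour cells, and the germline-to-MRCA edge is the trunk.
#' All other nodes are ancestral or extant tumour clones.
#'
#' @slot parent Named integer vector mapping each non-root node (name) to its
#'   parent node id. The germline root does not appear as a name.
#' @slot germlineRoot Integer id of the germline root (always \code{0L}).
#' @slot mrca Integer id of the MRCA clone.
#'
#' @examples
#' ph <- simulateTopology(4)
#' nClones(ph)
#' cloneParents(ph)
#' @export
setClass("ClonePhylogeny",
    representation(
        parent = "integer",
        germlineRoot = "integer",
        mrca = "integer"
    )
)

setValidity("ClonePhylogeny", function(object) {
    p <- object@parent
    msgs <- character()
    nodes <- sort(unique(c(as.integer(names(p)), p)))
    if (!(object@germlineRoot %in% p))
        msgs <- c(msgs, "germline root must be a parent of at least one node")
    if (object@germlineRoot %in% as.integer(names(p)))
        msgs <- c(msgs, "germline root must not have a parent")
    if (sum(p == object@germlineRoot) != 1L)
        msgs <- c(msgs, "germline root must have exactly one child (the MRCA)")
    if (!identical(as.integer(names(p))[p == object@germlineRoot][1], object@mrca) &&
        sum(p == object@germlineRoot) == 1L)
        msgs <- c(msgs, "mrca slot must be the single child of the germline root")
    ## connectivity / acyclicity: walking up from every node must reach the root
    for (v in as.integer(names(p))) {
        seen <- integer(0)
        cur <- v
        ok <- FALSE
        while (TRUE) {
            if (cur == object@germlineRoot) { ok <- TRUE; break }
            if (cur %in% seen) break
            seen <- c(seen, cur)
            nxt <- p[as.character(cur)]
            if (is.na(nxt)) break
            cur <- as.integer(nxt)
        }
        if (!ok) {
            msgs <- c(msgs, sprintf("node %d does not reach the germline root", v))
            break
        }
    }
    if (length(msgs)) msgs else TRUE
})

#' @describeIn ClonePhylogeny-class number of tumour clones (nodes minus the
#'   germline root)
#' @param object,x a \code{ClonePhylogeny}
#' @export
setGeneric("nClones", function(object) standardGeneric("nClones"))

#' @rdname ClonePhylogeny-class
#' @export
setMethod("nClones", "ClonePhylogeny", function(object) length(object@parent))

#' @describeIn ClonePhylogeny-class named integer vector child -> parent
#' @export
setGeneric("cloneParents", function(object) standardGeneric("cloneParents"))

#' @rdname ClonePhylogeny-class
#' @export
setMethod("cloneParents", "ClonePhylogeny", function(object) object@parent)

#' @describeIn ClonePhylogeny-class id of the MRCA clone
#' @export
setGeneric("mrcaClone", function(object) standardGeneric("mrcaClone"))

#' @rdname ClonePhylogeny-class
#' @export
setMethod("mrcaClone", "ClonePhylogeny", function(object) object@mrca)

setMethod("show", "ClonePhylogeny", function(object) {
    cat("ClonePhylogeny with", nClones(object), "tumour clone(s)\n")
    cat("  germline root:", object@germlineRoot, " MRCA:", object@mrca, "\n")
    ne <- length(object@parent)
    ed <- paste0(object@parent, "->", names(object@parent))
    cat("  edges:", paste(utils::head(ed, 8), collapse = " "),
        if (ne > 8) "..." else "", "\n")
})

#' Simulated multi-region tumour
#'
#' Container for one simulated tumour: the clone phylogeny, the evolutionary
#' events on its edges, per-clone genotypes, bulk-sample composition, read
#' counts and allele-specific copy-number segments, plus a ground-truth
#' record used for benchmarking.
#'
#' @slot phylogeny a [ClonePhylogeny-class]
#' @slot events data.frame of evolutionary events (kind, parent, child,
#'   locus, arm, allele, magnitude, order_index)
#' @slot genotypes list with matrices `x`, `y` (arms x clones), `z`
#'   (loci x clones) and the integer vector `locusArm`
#' @slot samples data.frame with one row per bulk sample (sample_id, purity,
#'   coverage, rho)
#' @slot proportions clone-by-sample matrix of clone proportions (columns sum
#'   to one over the clones present in the sample)
#' @slot readCounts data.frame of per-locus, per-sample read counts
#' @slot segments data.frame of per-sample arm-level allele-specific copy
#'   numbers as a copy-number caller would report them
#' @slot truth list of ground-truth records (clone CCFs, mutation cluster
#'   identities, WGD events with per-region CCFs)
#' @export
setClass("SimulatedTumour",
    representation(
        phylogeny = "ClonePhylogeny",
        events = "data.frame",
        genotypes = "list",
        samples = "data.frame",
        proportions = "matrix",
        readCounts = "data.frame",
        segments = "data.frame",
        truth = "list"
    )
)

setValidity("SimulatedTumour", function(object) {
    msgs <- character()
    if (nrow(object@samples) &&
        ncol(object@proportions) != nrow(object@samples))
        msgs <- c(msgs, "proportions must have one column per sample")
    cs <- colSums(object@proportions)
    if (length(cs) && any(abs(cs - 1) > 1e-8))
        msgs <- c(msgs, "clone proportions must sum to 1 in every sample")
    if (nrow(object@readCounts) &&
        any(object@readCounts$var_count > object@readCounts$total_count))
        msgs <- c(msgs, "variant reads must not exceed total reads")
    if (length(msgs)) msgs else TRUE
})

setMethod("show", "SimulatedTumour", function(object) {
    cat("SimulatedTumour:", nClones(object@phylogeny), "clones,",
        nrow(object@samples), "samples,",
        sum(object@events$kind == "SNV"), "SNVs,",
        sum(object@events$kind == "WGD"), "WGD event(s)\n")
})

#' Reconstructed clone tree over mutation clusters
#'
#' @slot ccf numeric matrix of per-region mean PhyloCCF, rows = clusters
#'   (rownames are cluster ids), columns = regions
#' @slot parent named character vector mapping each non-trunk cluster to its
#'   parent cluster; the trunk does not appear as a name
#' @slot trunk id of the trunk (truncal) cluster
#' @slot alternatives list of alternative parent maps (each like `parent`);
#'   the default tree is always also a member
#' @slot truncated TRUE if enumeration stopped at the cap
#' @export
setClass("CloneTree",
    representation(
        ccf = "matrix",
        parent = "character",
        trunk = "character",
        alternatives = "list",
        truncated = "logical"
    )
)

setValidity("CloneTree", function(object) {
    msgs <- character()
    if (object@trunk %in% names(object@parent))
        msgs <- c(msgs, "trunk must not have a parent")
    bad <- setdiff(names(object@parent), rownames(object@ccf))
    if (length(bad)) msgs <- c(msgs, "parent map references unknown clusters")
    if (length(msgs)) msgs else TRUE
})

#' @describeIn CloneTree-class parent map of the default tree
#' @param object a \code{CloneTree}
#' @export
setGeneric("treeParents", function(object) standardGeneric("treeParents"))

#' @rdname CloneTree-class
#' @export
setMethod("treeParents", "CloneTree", function(object) object@parent)

#' @describeIn CloneTree-class list of all enumerated valid parent maps
#' @export
setGeneric("treeAlternatives", function(object) standardGeneric("treeAlternatives"))

#' @rdname CloneTree-class
#' @export
setMethod("treeAlternatives", "CloneTree", function(object) object@alternatives)

#' @describeIn CloneTree-class cluster-by-region PhyloCCF matrix
#' @export
setGeneric("clusterCCF", function(object) standardGeneric("clusterCCF"))

#' @rdname CloneTree-class
#' @export
setMethod("clusterCCF", "CloneTree", function(object) object@ccf)

setMethod("show", "CloneTree", function(object) {
    cat("CloneTree:", nrow(object@ccf), "clusters,",
        ncol(object@ccf), "regions; trunk =", object@trunk, ";",
        length(object@alternatives), "valid tree(s)",
        if (object@truncated) "(enumeration truncated)" else "", "\n")
})

#' Set of whole-genome-doubling events called in a tumour
#'
#' @slot events data.frame with one row per WGD event: `event_id`,
#'   `clonality` ("truncal"/"subclonal"), `regions` (comma-separated region
#'   ids), `source` ("doubled-cluster"/"parsimony"), `clusters`
#'   (comma-separated contributing cluster ids, or NA)
#' @slot regionCounts named integer vector of per-region WGD counts given as
#'   input (the detector never assigns more events to a region than this)
#' @slot status tumour-level status: "no_wgd", "truncal_only" or "subclonal"
#' @slot reviewFlag TRUE when more than 2 subclonal events were initially
#'   inferred and merged down to the cap (manual-review situation)
#' @export
setClass("WGDEventSet",
    representation(
        events = "data.frame",
        regionCounts = "integer",
        status = "character",
        reviewFlag = "logical"
    )
)

setValidity("WGDEventSet", function(object) {
    msgs <- character()
    ev <- object@events
    if (nrow(ev)) {
        used <- table(unlist(strsplit(ev$regions, ",")))
        over <- names(used)[used > object@regionCounts[names(used)]]
        if (length(over))
            msgs <- c(msgs, sprintf(
                "region(s) %s assigned more WGD events than their input count",
                paste(over, collapse = ",")))
        if (sum(ev$clonality == "subclonal") > 2L)
            msgs <- c(msgs, "more than 2 subclonal WGD events")
    }
    if (length(msgs)) msgs else TRUE
})

#' @describeIn WGDEventSet-class event table
#' @param object a \code{WGDEventSet}
#' @export
setGeneric("wgdEvents", function(object) standardGeneric("wgdEvents"))

#' @rdname WGDEventSet-class
#' @export
setMethod("wgdEvents", "WGDEventSet", function(object) object@events)

setMethod("show", "WGDEventSet", function(object) {
    cat("WGDEventSet:", nrow(object@events), "event(s); status =",
        object@status, "\n")
    if (nrow(object@events)) {
        print(object@events, row.names = FALSE)
    }
})
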