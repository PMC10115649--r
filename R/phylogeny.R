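#' Simulate a random clone-tree topology
#'
#' Draws a random rooted clone tree with `nClones` tumour clones by first
#' generating a full rooted binary tree with `nClones` leaves (uniform random
#' leaf splitting) and then iteratively removing uniformly chosen leaves
#' until only `nClones` nodes remain. A germline diploid root (node 0) is
#' then attached above the tumour root, so the MRCA is the single child of
#' the germline root and the germline-to-MRCA edge is the trunk. Every tree
#' shape reachable by the leaf-removal process has positive probability.
#'
#' Consumes the R random number stream.
#'
#' @param nClones positive integer, number of tumour clones.
#' @return a [ClonePhylogeny-class]
#' @examples
#' set.seed(1)
#' simulateTopology(6)
#' @export
simulateTopology <- function(nClones) {
    if (!is.numeric(nClones) || length(nClones) != 1L || is.na(nClones) ||
        nClones < 1 || nClones != round(nClones))
        stop("'nClones' must be a single positive integer")
    nClones <- as.integer(nClones)
    ## full rooted binary tree with nClones leaves: split random leaves
    parent <- c(NA_integer_)           # node 1 = tumour root
    isLeaf <- c(TRUE)
    while (sum(isLeaf) < nClones) {
        leaves <- which(isLeaf)
        v <- if (length(leaves) == 1L) leaves else sample(leaves, 1L)
        isLeaf[v] <- FALSE
        parent <- c(parent, v, v)
        isLeaf <- c(isLeaf, TRUE, TRUE)
    }
    alive <- rep(TRUE, length(parent))
    ## remove random leaves until nClones nodes remain (root never a leaf
    ## while it has children; it can only be removed last, which the stop
    ## condition prevents for nClones >= 1)
    while (sum(alive) > nClones) {
        hasChild <- seq_along(parent) %in% parent[alive]
        leaves <- which(alive & !hasChild)
        v <- if (length(leaves) == 1L) leaves else sample(leaves, 1L)
        alive[v] <- FALSE
    }
    keep <- which(alive)
    newId <- integer(length(parent))
    newId[keep] <- seq_along(keep)     # tumour clones relabelled 1..nClones
    p <- integer(0)
    nm <- character(0)
    for (v in keep) {
        pa <- parent[v]
        p <- c(p, if (is.na(pa)) 0L else newId[pa])
        nm <- c(nm, as.character(newId[v]))
    }
    names(p) <- nm
    new("ClonePhylogeny", parent = p, germlineRoot = 0L,
        mrca = as.integer(names(p)[p == 0L]))
}

#' Draw a clone count for a sample-size group
#'
#' Clone numbers are drawn uniformly at random from the range observed for
#' each sample-size group: 8-16 clones for "low" (2-3 samples), 12-24 for
#' "medium" (4-7 samples) and 22-30 for "high" (>7 samples).
#'
#' @param group one of "low", "medium", "high"
#' @return integer clone count
#' @export
drawCloneCount <- function(group = c("low", "medium", "high")) {
    group <- match.arg(group)
    rng <- switch(group, low = 8:16, medium = 12:24, high = 22:30)
    sample(rng, 1L)
}

## ---- internal tree helpers ----

#' @noRd
treeEdges <- function(phylo) {
    p <- cloneParents(phylo)
    cbind(parent = unname(p), child = as.integer(names(p)))
}

## children of a node
#' @noRd
childrenOf <- function(phylo, node) {
    p <- cloneParents(phylo)
    as.integer(names(p)[p == node])
}

## all descendants of `node` including itself (tumour clones only)
#' @noRd
descendantsOf <- function(phylo, node) {
    out <- node
    queue <- node
    while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        ch <- childrenOf(phylo, v)
        out <- c(out, ch)
        queue <- c(queue, ch)
    }
    setdiff(out, phylo@germlineRoot)
}

## ancestor chain of a clone up to (excluding) the germline root
#' @noRd
ancestorsOf <- function(phylo, node) {
    p <- cloneParents(phylo)
    out <- integer(0)
    cur <- node
    while (TRUE) {
        pa <- p[as.character(cur)]
        if (is.na(pa) || pa == phylo@germlineRoot) break
        out <- c(out, as.integer(pa))
        cur <- as.integer(pa)
    }
    out
}

## edges below the trunk, as child ids
#' @noRd
subclonalEdgeChildren <- function(phylo) {
    setdiff(as.integer(names(cloneParents(phylo))), phylo@mrca)
}
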