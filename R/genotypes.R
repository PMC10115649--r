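#' Propagate genotypes down a clone phylogeny
#'
#' Determines the genotype triplet (x, y, z) of every clone at every locus by
#' a recursive top-down pass: the germline root is (1, 1, 0) everywhere and
#' each child's genotype is its parent's genotype with the child edge's
#' events applied in their `order_index` order. `x` and `y` are the
#' allele-specific copy numbers of the A and B alleles (tracked per
#' chromosome arm, since SCNAs are arm-scale), and `z` is the mutation
#' multiplicity of each SNV locus; by convention SNVs reside on allele A.
#'
#' Event semantics:
#' \itemize{
#'   \item SNV: z <- z + 1 at the locus (skipped and logged when allele A is
#'     already lost there).
#'   \item GAIN of magnitude m: the chosen allele gains m copies; when allele
#'     A already carries a mutation at a locus the duplicated copies are
#'     mutant copies, so z also gains m (constant-multiplicity convention).
#'   \item LOSS: the chosen allele loses one copy; a mutant copy is lost only
#'     when every A copy is mutant (z = x before the loss). Losses on an
#'     allele already at 0 copies are skipped and logged: LOH is irreversible.
#'   \item WGD: doubles x, y and z (every allele present at one or more
#'     copies is doubled).
#' }
#'
#' @param phylo a [ClonePhylogeny-class]
#' @param events event table from [assignEvents()]
#' @param nArms number of chromosome arms
#' @return list with `x`, `y` (arm-by-clone integer matrices), `z`
#'   (locus-by-clone integer matrix), `locusArm` (arm of each SNV locus) and
#'   `skipped` (data.frame of skipped events)
#' @examples
#' set.seed(1)
#' ph <- simulateTopology(3)
#' ev <- assignEvents(ph, nSnvs = 20, truncalFraction = 0.5)
#' g <- propagateGenotypes(ph, ev)
#' dim(g$z)
#' @export
propagateGenotypes <- function(phylo, events, nArms = 44L) {
    stopifnot(is(phylo, "ClonePhylogeny"))
    snv <- events[events$kind == "SNV", , drop = FALSE]
    nLoci <- nrow(snv)
    locusArm <- integer(nLoci)
    if (nLoci) {
        locusArm[snv$locus] <- snv$arm
        if (anyDuplicated(snv$locus))
            stop("infinite-sites violation: an SNV locus occurs on two edges")
    }
    clones <- sort(as.integer(names(cloneParents(phylo))))
    n <- length(clones)
    x <- matrix(1L, nArms, n, dimnames = list(NULL, clones))
    y <- matrix(1L, nArms, n, dimnames = list(NULL, clones))
    z <- matrix(0L, max(nLoci, 0L), n, dimnames = list(NULL, clones))
    skipped <- list()
    ## DFS from the germline root; parent's state applied at entry
    applyEdge <- function(ch, xs, ys, zs) {
        ev <- events[events$child == ch, , drop = FALSE]
        ev <- ev[order(ev$order_index), , drop = FALSE]
        for (i in seq_len(nrow(ev))) {
            e <- ev[i, ]
            if (e$kind == "SNV") {
                if (xs[e$arm] == 0L) {
                    skipped[[length(skipped) + 1L]] <<- e
                } else {
                    zs[e$locus] <- zs[e$locus] + 1L
                }
            } else if (e$kind == "GAIN") {
                if (e$allele == "A") {
                    if (xs[e$arm] == 0L) {
                        skipped[[length(skipped) + 1L]] <<- e
                    } else {
                        xs[e$arm] <- xs[e$arm] + e$magnitude
                        onArm <- which(locusArm == e$arm)
                        mut <- onArm[zs[onArm] > 0L]
                        zs[mut] <- zs[mut] + e$magnitude
                    }
                } else {
                    if (ys[e$arm] == 0L) {
                        skipped[[length(skipped) + 1L]] <<- e
                    } else {
                        ys[e$arm] <- ys[e$arm] + e$magnitude
                    }
                }
            } else if (e$kind == "LOSS") {
                if (e$allele == "A") {
                    if (xs[e$arm] == 0L) {
                        skipped[[length(skipped) + 1L]] <<- e
                    } else {
                        xOld <- xs[e$arm]
                        xs[e$arm] <- xOld - 1L
                        onArm <- which(locusArm == e$arm)
                        full <- onArm[zs[onArm] == xOld]
                        zs[full] <- zs[full] - 1L
                    }
                } else {
                    if (ys[e$arm] == 0L) {
                        skipped[[length(skipped) + 1L]] <<- e
                    } else {
                        ys[e$arm] <- ys[e$arm] - 1L
                    }
                }
            } else if (e$kind == "WGD") {
                xs <- 2L * xs
                ys <- 2L * ys
                zs <- 2L * zs
            }
        }
        list(x = xs, y = ys, z = zs)
    }
    recurse <- function(node, xs, ys, zs) {
        for (ch in childrenOf(phylo, node)) {
            st <- applyEdge(ch, xs, ys, zs)
            j <- as.character(ch)
            x[, j] <<- st$x
            y[, j] <<- st$y
            if (nLoci) z[, j] <<- st$z
            recurse(ch, st$x, st$y, st$z)
        }
    }
    recurse(phylo@germlineRoot,
            rep(1L, nArms), rep(1L, nArms), integer(nLoci))
    skipped <- if (length(skipped)) do.call(rbind, skipped) else
        events[0, , drop = FALSE]
    list(x = x, y = y, z = z, locusArm = locusArm, skipped = skipped)
}
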