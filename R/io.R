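#' Read a mutation count table
#'
#' Tab-separated with header columns tumour_id, sample_id, mutation_id,
#' chrom, pos, ref_count, var_count (1-based positions). Duplicate
#' (tumour, sample, mutation) keys and negative counts are rejected with
#' the offending row number.
#'
#' @param path file path
#' @return validated data.frame
#' @export
readMutationTable <- function(path) {
    need <- c("tumour_id", "sample_id", "mutation_id", "chrom", "pos",
              "ref_count", "var_count")
    tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
    miss <- setdiff(need, names(tab))
    if (length(miss))
        stop("parse error: missing column(s) ", paste(miss, collapse = ", "))
    bad <- which(tab$ref_count < 0 | tab$var_count < 0)
    if (length(bad))
        stop("parse error: negative count at row ", bad[1])
    key <- paste(tab$tumour_id, tab$sample_id, tab$mutation_id)
    if (anyDuplicated(key))
        stop("parse error: duplicate (tumour, sample, mutation) key at row ",
             which(duplicated(key))[1])
    tab
}

#' Read an allele-specific copy-number segment table
#'
#' Tab-separated SEG-like file with header columns tumour_id, sample_id,
#' chrom, start, end, major_cn, minor_cn; 1-based inclusive coordinates.
#' Overlapping segments within a sample, major < minor and negative copy
#' numbers are rejected.
#'
#' @param path file path
#' @return validated data.frame
#' @export
readSegments <- function(path) {
    need <- c("tumour_id", "sample_id", "chrom", "start", "end",
              "major_cn", "minor_cn")
    tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
    miss <- setdiff(need, names(tab))
    if (length(miss))
        stop("parse error: missing column(s) ", paste(miss, collapse = ", "))
    if (any(tab$minor_cn < 0) || any(tab$major_cn < tab$minor_cn))
        stop("validation error: require major_cn >= minor_cn >= 0")
    for (grp in split(tab, paste(tab$tumour_id, tab$sample_id, tab$chrom))) {
        grp <- grp[order(grp$start), , drop = FALSE]
        if (nrow(grp) > 1 && any(grp$start[-1] <= grp$end[-nrow(grp)])) {
            i <- which(grp$start[-1] <= grp$end[-nrow(grp)])[1]
            stop("validation error: overlapping segments ",
                 sprintf("%s:%d-%d and %s:%d-%d in sample %s",
                         grp$chrom[i], grp$start[i], grp$end[i],
                         grp$chrom[i + 1], grp$start[i + 1], grp$end[i + 1],
                         grp$sample_id[1]))
        }
    }
    tab
}

#' Serialize a clone tree
#'
#' JSON serialization is lossless (round-trip safe via [readTreeJSON()]):
#' trunk id, edge list, per-cluster per-region PhyloCCF and all alternative
#' parent maps. Newick keeps topology and node labels, writing each cluster
#' as a labelled (possibly unary) internal node.
#'
#' @param tree a [CloneTree-class]
#' @param path output file
#' @param format "json" or "newick"
#' @return `path`, invisibly
#' @export
writeTree <- function(tree, path, format = c("json", "newick")) {
    format <- match.arg(format)
    if (format == "json") {
        obj <- list(
            trunk = tree@trunk,
            parent = as.list(treeParents(tree)),
            ccf = apply(clusterCCF(tree), 1, as.list, simplify = FALSE),
            regions = colnames(clusterCCF(tree)),
            alternatives = lapply(treeAlternatives(tree), as.list),
            truncated = tree@truncated)
        jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    } else {
        writeLines(paste0(.newickOf(treeParents(tree), tree@trunk), ";"), path)
    }
    invisible(path)
}

#' @noRd
.newickOf <- function(parent, node) {
    ch <- sort(names(parent)[parent == node])
    if (!length(ch)) return(node)
    paste0("(", paste(vapply(ch, function(c) .newickOf(parent, c), ""),
                      collapse = ","), ")", node)
}

#' Read a clone tree from its JSON serialization
#'
#' @param path file written by [writeTree()] with `format = "json"`
#' @return a [CloneTree-class]
#' @export
readTreeJSON <- function(path) {
    obj <- jsonlite::read_json(path)
    ccf <- do.call(rbind, lapply(obj$ccf, function(r) unlist(r)))
    rownames(ccf) <- names(obj$ccf)
    colnames(ccf) <- unlist(obj$regions)
    new("CloneTree", ccf = ccf,
        parent = unlist(lapply(obj$parent, as.character)),
        trunk = obj$trunk,
        alternatives = lapply(obj$alternatives, function(a)
            unlist(lapply(a, as.character))),
        truncated = isTRUE(obj$truncated))
}

#' Write the standard outputs of a simulated tumour
#'
#' Writes the read-count TSV (tumour_id, sample_id, locus_id, chrom, pos,
#' ref_count, var_count), the SEG-like segment TSV and a ground-truth JSON
#' (topology edge list, events, clone proportions, WGD truth with per-region
#' CCFs) into a directory.
#'
#' @param tumour a [SimulatedTumour-class]
#' @param dir output directory (created if needed)
#' @return invisible character vector of the three file paths
#' @export
writeSimOutputs <- function(tumour, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    id <- tumour@readCounts$tumour_id[1]
    geno <- tumour@genotypes
    rc <- tumour@readCounts
    arm <- geno$locusArm[rc$locus]
    armLength <- tumour@segments$end[1]
    reads <- data.frame(
        tumour_id = rc$tumour_id, sample_id = rc$sample_id,
        locus_id = rc$locus,
        chrom = ifelse(is.na(arm), NA_integer_, ceiling(arm / 2)),
        pos = ifelse(is.na(arm), NA_integer_,
                     (arm - 1) %% 2 * armLength + rc$locus %% armLength + 1),
        ref_count = rc$total_count - rc$var_count,
        var_count = rc$var_count)
    fReads <- file.path(dir, paste0(id, "_reads.tsv"))
    fSegs <- file.path(dir, paste0(id, "_segments.tsv"))
    fTruth <- file.path(dir, paste0(id, "_truth.json"))
    utils::write.table(reads, fReads, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    segs <- tumour@segments[, c("tumour_id", "sample_id", "chrom", "start",
                                "end", "major_cn", "minor_cn")]
    utils::write.table(segs, fSegs, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p <- cloneParents(tumour@phylogeny)
    truth <- list(
        edges = data.frame(parent = unname(p),
                           child = as.integer(names(p))),
        events = tumour@events,
        samples = tumour@samples,
        proportions = as.data.frame(tumour@proportions),
        clone_ccf = as.data.frame(tumour@truth$cloneCCF),
        wgd = tumour@truth$wgd)
    jsonlite::write_json(truth, fTruth, dataframe = "rows", digits = NA)
    invisible(c(fReads, fSegs, fTruth))
}
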