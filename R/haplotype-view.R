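# Locus-level haplotype analyses: select signal SNVs around a focal SV,
# hierarchically cluster haplotypes, and build a TCS-like minimum-spanning
# haplotype network.

#' Select flanking SNVs with selection signals around a focal SV
#'
#' SNVs within \code{flank} bp of the SV position whose statistic exceeds
#' \code{threshold}; optionally restricted to SNVs in LD with the SV above
#' an r2 cutoff.  Ordered by position; empty results are allowed (with a
#' warning).
#'
#' @param scan data.frame with columns position and the statistic named by
#'   \code{statistic} (e.g. the per-site output of [xpehhScan()])
#' @param svPos focal SV position in bp
#' @param flank flank size in bp on each side
#' @param statistic column name of the signal statistic
#' @param threshold inclusion threshold (strictly greater)
#' @param svAlleles optional per-haplotype SV alleles for LD filtering
#' @param haps optional \linkS4class{HaplotypeMatrix} (required with
#'   \code{svAlleles})
#' @param r2Cutoff LD cutoff used when \code{svAlleles} is given
#' @return data.frame of selected scan rows, ordered by position
#' @export
selectSignalSNVs <- function(scan, svPos, flank = 5e5,
                             statistic = "xpehh", threshold = 2,
                             svAlleles = NULL, haps = NULL,
                             r2Cutoff = 0.8) {
  stat <- scan[[statistic]]
  keep <- !is.na(stat) & stat > threshold &
    abs(scan$position - svPos) <= flank
  out <- scan[keep, , drop = FALSE]
  if (!is.null(svAlleles)) {
    if (is.null(haps)) stop("haps required for LD filtering")
    m <- hapMatrix(haps)
    siteOf <- match(out$position, positions(haps))
    r2 <- vapply(siteOf, function(s)
      ldR2(svAlleles, m[, s]), numeric(1))
    out <- out[!is.na(r2) & r2 > r2Cutoff, , drop = FALSE]
  }
  out <- out[order(out$position), , drop = FALSE]
  if (!nrow(out)) warning("no SNVs passed the signal criteria")
  rownames(out) <- NULL
  out
}

#' Hierarchically cluster haplotypes over selected SNVs
#'
#' Pairwise Hamming distances, agglomerative clustering (average linkage by
#' default).  Leaf order is deterministic for a given input order.
#'
#' @param haps a \linkS4class{HaplotypeMatrix} or a 0/1 matrix (haplotypes
#'   in rows)
#' @param linkage linkage method passed to [stats::hclust()]
#' @return list(hclust, order, labels, dist)
#' @export
clusterHaplotypes <- function(haps, linkage = "average") {
  m <- if (is(haps, "HaplotypeMatrix")) hapMatrix(haps) else haps
  if (nrow(m) < 2) stop("need >= 2 haplotypes")
  if (ncol(m) < 1) stop("need >= 1 SNV")
  d <- stats::dist(m, method = "manhattan")   # = Hamming on 0/1 data
  hc <- stats::hclust(d, method = linkage)
  list(hclust = hc, order = hc$order,
       labels = rownames(m) %||% as.character(seq_len(nrow(m))),
       dist = d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' TCS-like minimum-spanning haplotype network
#'
#' Distinct haplotypes become nodes (carrier counts per population
#' retained); edges are added in increasing Hamming distance, keeping every
#' tying edge that joins two components still separate at the start of its
#' distance tier (reticulation), until the network is connected.  Edges
#' above \code{connectionLimit} steps are omitted, which may leave the
#' network disconnected.
#'
#' @param haps a \linkS4class{HaplotypeMatrix} or 0/1 matrix
#' @param populations optional per-haplotype labels (default: from
#'   \code{haps})
#' @param carrierFlag optional logical per haplotype (e.g. carries the
#'   focal SV); summarized per node
#' @param connectionLimit maximum mutation steps per edge (default Inf)
#' @return list(nodes = data.frame(node, haplotype, count, per-population
#'   counts, carriers), edges = data.frame(from, to, steps),
#'   graph = igraph object)
#' @export
haplotypeNetwork <- function(haps, populations = NULL, carrierFlag = NULL,
                             connectionLimit = Inf) {
  m <- if (is(haps, "HaplotypeMatrix")) hapMatrix(haps) else haps
  if (is.null(populations))
    populations <- if (is(haps, "HaplotypeMatrix")) popLabels(haps)
      else rep("pop1", nrow(m))
  key <- apply(m, 1, paste, collapse = "")
  uniq <- !duplicated(key)
  nodeKey <- key[uniq]
  if (length(nodeKey) < 2) stop("need >= 2 distinct haplotypes")
  nodeOf <- match(key, nodeKey)
  um <- m[uniq, , drop = FALSE]
  nNode <- nrow(um)
  nodes <- data.frame(node = seq_len(nNode), haplotype = nodeKey,
                      count = as.integer(table(factor(nodeOf,
                                                      seq_len(nNode)))))
  for (pop in sort(unique(populations)))
    nodes[[paste0("n_", pop)]] <- as.integer(
      table(factor(nodeOf[populations == pop], seq_len(nNode))))
  if (!is.null(carrierFlag))
    nodes$carriers <- as.integer(
      table(factor(nodeOf[carrierFlag], seq_len(nNode))))
  # candidate edges ordered by Hamming distance
  pairs <- utils::combn(nNode, 2)
  steps <- apply(pairs, 2, function(ij)
    sum(um[ij[1], ] != um[ij[2], ]))
  o <- order(steps, pairs[1, ], pairs[2, ])
  parent <- seq_len(nNode)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  edges <- data.frame(from = integer(), to = integer(), steps = integer())
  for (d in sort(unique(steps))) {
    if (d > connectionLimit) break
    tier <- o[steps[o] == d]
    # components are frozen at the start of the tier: all tying edges
    # between then-separate components are retained (reticulation)
    compBefore <- vapply(seq_len(nNode), find, integer(1))
    added <- list()
    for (e in tier) {
      i <- pairs[1, e]; j <- pairs[2, e]
      if (compBefore[i] != compBefore[j])
        added[[length(added) + 1L]] <- c(i, j)
    }
    for (ij in added) {
      edges <- rbind(edges, data.frame(from = ij[1], to = ij[2],
                                       steps = d))
      ri <- find(ij[1]); rj <- find(ij[2])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
    if (length(unique(vapply(seq_len(nNode), find, integer(1)))) == 1)
      break
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  list(nodes = nodes, edges = edges, graph = g)
}
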