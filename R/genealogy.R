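#' Build a genealogy index
#'
#' Indexes the cell registry as a rooted genealogy and counts, for every cell
#' ever born, how many cells of an observation set descend from it (a cell
#' counts itself when observed). The observation set defaults to all cells
#' alive at observation time — the set over which "fraction of the primary"
#' is defined for tree-based detectability — but may be any subset (e.g. the
#' union of sampled regions).
#'
#' @param tumor a [Tumor-class].
#' @param observed integer vector of observed cell ids; default
#'   `aliveIds(tumor)`.
#' @return a [Genealogy-class].
#' @export
genealogyIndex <- function(tumor, observed = aliveIds(tumor)) {
  if (!length(observed)) stop("empty observation set")
  cc <- cells(tumor)
  obs <- matrix(FALSE, nrow = nrow(cc), ncol = 1)
  obs[observed, 1] <- TRUE
  counts <- cpp_descendant_counts(as.integer(cc$parent_id), obs)[, 1]
  new("Genealogy", parent = as.integer(cc$parent_id),
      descCounts = as.integer(counts), nObserved = length(observed),
      variantOrigin = as.integer(variants(tumor)$origin_cell))
}

#' @rdname genealogyIndex
#' @param gen a [Genealogy-class].
#' @return `descendantFraction`: per-cell observed-descendant fraction.
#' @export
descendantFraction <- function(gen) gen@descCounts / gen@nObserved

#' Detectable ancestors at a cancer-cell-fraction threshold
#'
#' Cells whose observed-descendant fraction reaches `thresholdCcf` — the
#' progenitors whose variants are carried by a detectable fraction of the
#' final tumor. For a sequencing detectability threshold `alpha` on VAFs of
#' heterozygous variants, the corresponding CCF threshold is `2 * alpha`.
#' Ancestors of a detectable ancestor are detectable by construction.
#'
#' @param gen a [Genealogy-class].
#' @param thresholdCcf fraction in (0, 1].
#' @return integer vector of cell ids.
#' @export
detectableAncestors <- function(gen, thresholdCcf) {
  stopifnot(thresholdCcf > 0, thresholdCcf <= 1)
  which(gen@descCounts / gen@nObserved >= thresholdCcf)
}

#' Most recent detectable ancestor of a cell
#'
#' The deepest cell on the path from the founder to `cellId` whose
#' observed-descendant fraction reaches the threshold. Always exists: the
#' founder has fraction 1.
#'
#' @inheritParams detectableAncestors
#' @param cellId the focal (e.g. seeding) cell.
#' @return a cell id.
#' @export
mrda <- function(gen, cellId, thresholdCcf) {
  frac <- gen@descCounts / gen@nObserved
  i <- as.integer(cellId)
  while (i > 0) {
    if (frac[i] >= thresholdCcf) return(i)
    i <- gen@parent[i]
  }
  stop("no detectable ancestor found (founder should always qualify)")
}

.pathToRoot <- function(parent, cellId) {
  path <- integer(0)
  i <- as.integer(cellId)
  while (i > 0) {
    path <- c(path, i)
    i <- parent[i]
  }
  rev(path)
}

#' Tree-based divergence elements of a seeding cell
#'
#' Computes, on the single-cell genealogy, the elements of
#' metastatic--primary divergence for one seeding cell:
#' \itemize{
#' \item `k`: total variants carried by the seeding cell;
#' \item `bmd_variants`: `k` minus the variants of the most recent
#'   detectable ancestor at CCF `2*alpha` — the pre-dissemination,
#'   undetectable-in-primary part of the metastasis-specific branch;
#' \item `bmd_generations`: the number of edges from the seeding cell up to
#'   that ancestor;
#' \item `bp_tree`: the variant-weighted total branch length of the
#'   genealogy of detectable ancestors at CCF `2*gamma`, minus the branch
#'   from the founder to the seeding cell's most recent detectable ancestor
#'   at that threshold — the tree counterpart of the primary-specific
#'   branch;
#' \item `bp_tree_edges`: the same quantity counted in edges (cell
#'   generations).
#' }
#'
#' @param gen a [Genealogy-class].
#' @param cellId the seeding cell id.
#' @param alpha sequencing detectability VAF threshold (CCF cut `2*alpha`).
#' @param gamma substantial-presence VAF threshold (CCF cut `2*gamma`),
#'   `gamma > alpha`.
#' @return one-row data.frame with columns `k`, `bmd_variants`,
#'   `bmd_generations`, `bp_tree`, `bp_tree_edges`, `mrda_alpha`,
#'   `mrda_gamma`.
#' @export
divergenceElements <- function(gen, cellId, alpha = 0.01, gamma = 0.2) {
  stopifnot(alpha > 0, gamma > alpha, gamma < 1)
  if (cellId > length(gen@parent)) stop("seeding cell not in the registry")
  frac <- gen@descCounts / gen@nObserved
  path <- .pathToRoot(gen@parent, cellId)
  nVarAt <- function(ids) sum(gen@variantOrigin %in% ids)
  k <- nVarAt(path)
  ma <- mrda(gen, cellId, 2 * alpha)
  mg <- mrda(gen, cellId, 2 * gamma)
  ia <- match(ma, path)
  bmdVariants <- k - nVarAt(path[seq_len(ia)])
  bmdGenerations <- length(path) - ia
  daGamma <- which(frac >= 2 * gamma)
  ig <- match(mg, path)
  bpTree <- sum(gen@variantOrigin %in% daGamma) - nVarAt(path[seq_len(ig)])
  # edge count: the DA-gamma genealogy is the union of root paths; every
  # non-root DA cell contributes its incoming edge
  bpTreeEdges <- sum(gen@parent[daGamma] != 0) - (ig - 1L)
  data.frame(k = k, bmd_variants = bmdVariants,
             bmd_generations = bmdGenerations,
             bp_tree = bpTree, bp_tree_edges = bpTreeEdges,
             mrda_alpha = ma, mrda_gamma = mg)
}

#' Tree-based divergence elements for every seeding event
#'
#' @param tumor a primary [Tumor-class] grown with [runWithSeeding()].
#' @inheritParams divergenceElements
#' @param observed observation set; default alive cells.
#' @return data.frame with one row per seeding event (`seed_index`,
#'   `seeding_cell`, `primary_size_at_seed`, plus the
#'   [divergenceElements()] columns).
#' @export
divergenceTree <- function(tumor, alpha = 0.01, gamma = 0.2,
                           observed = aliveIds(tumor)) {
  ev <- seedingEvents(tumor)
  if (!nrow(ev)) stop("tumor has no seeding events")
  gen <- genealogyIndex(tumor, observed)
  out <- do.call(rbind, lapply(ev$seeding_cell, function(sc)
    divergenceElements(gen, sc, alpha, gamma)))
  cbind(ev[c("seed_index", "seeding_cell", "primary_size_at_seed")], out)
}

#' Export an induced genealogy as Newick
#'
#' Builds the subtree of the genealogy induced by a set of tip cells, with
#' branch lengths equal to the number of variants gained along each edge
#' (unbranched internal cells are suppressed, their variants summed onto the
#' collapsed edge), and serializes via \pkg{ape}. Tip labels are
#' `cell_<id>`. A tip that is an ancestor of another tip is represented as a
#' zero-length pendant leaf of the corresponding internal node, so the leaf
#' set always equals the requested tip set.
#'
#' @param tumor a [Tumor-class].
#' @param tips integer vector of tip cell ids.
#' @return a Newick string (terminated by ";").
#' @export
exportNewick <- function(tumor, tips) {
  if (!length(tips)) stop("tip set is empty")
  cc <- cells(tumor)
  tips <- sort(unique(as.integer(tips)))
  if (any(tips > nrow(cc)) || any(tips < 1)) stop("some tips are not in the registry")
  parent <- cc$parent_id
  nVarAtCell <- tabulate(variants(tumor)$origin_cell, nbins = nrow(cc))
  if (length(tips) == 1L)
    return(paste0("(cell_", tips, ":",
                  sum(nVarAtCell[.pathToRoot(parent, tips)]), ");"))
  inUnion <- logical(nrow(cc))
  for (tp in tips) {
    i <- tp
    while (i > 0 && !inUnion[i]) { inUnion[i] <- TRUE; i <- parent[i] }
  }
  ids <- which(inUnion)
  hasChild <- logical(nrow(cc))
  hasChild[parent[ids][parent[ids] > 0]] <- TRUE
  isTip <- logical(nrow(cc)); isTip[tips] <- TRUE
  # node numbering: leaves 1..Ntip (one per requested tip), internals after
  nTip <- length(tips)
  internals <- ids[hasChild[ids]]
  intIdx <- integer(nrow(cc))
  intIdx[internals] <- nTip + seq_along(internals)
  leafIdx <- integer(nrow(cc))
  leafIdx[tips] <- seq_len(nTip)
  nodeIdx <- function(i) if (hasChild[i]) intIdx[i] else leafIdx[i]
  root <- ids[parent[ids] == 0]
  edges <- matrix(0L, nrow = 0, ncol = 2)
  lens <- numeric(0)
  for (i in ids) {
    if (i != root) {
      edges <- rbind(edges, c(intIdx[parent[i]], nodeIdx(i)))
      lens <- c(lens, nVarAtCell[i])
    }
    if (isTip[i] && hasChild[i]) { # sampled-ancestor tip: pendant leaf
      edges <- rbind(edges, c(intIdx[i], leafIdx[i]))
      lens <- c(lens, 0)
    }
  }
  tr <- structure(list(edge = edges, edge.length = lens,
                       tip.label = paste0("cell_", tips),
                       Nnode = length(internals)),
                  class = "phylo", order = "cladewise")
  tr <- ape::collapse.singles(tr)
  ape::write.tree(tr)
}
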