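#' Per-seeding-event divergence series for a simulated tumor pair sequence
#'
#' The full measurement pipeline: grows (or takes) a primary with seeding
#' events, samples and virtually sequences it, computes the tree-based
#' divergence elements of every seeding cell, then — for each seeding event
#' — grows the corresponding metastasis, sequences it, and measures `B_m`
#' and `B_p` from pooled frequencies of the pair. Metastases are grown one
#' at a time and discarded after measurement; each uses an RNG seed derived
#' from (`seed`, seed index) so that adding one metastasis does not perturb
#' the others.
#'
#' @param primary a [Tumor-class] from [runWithSeeding()].
#' @param metTarget metastasis size (default `Nfinal` of the primary's
#'   params).
#' @param nRegions,radius multi-region sampling parameters.
#' @param meanDepth,dispersion virtual sequencing parameters.
#' @param alpha,gamma detectability and substantial-presence VAF thresholds.
#' @param seed base RNG seed for sampling/sequencing and per-metastasis
#'   streams.
#' @param growMets set `FALSE` to skip metastasis growth; measured columns
#'   `B_m`/`B_p` are then `NA` and only primary-side quantities are
#'   returned.
#' @param treeObserved observation set for the tree-based detectability
#'   thresholds: `"sampled"` (default) evaluates descendant fractions over
#'   the union of the sampled regions — the same cells the virtual
#'   sequencing sees, so tree and measured quantities share one detection
#'   frame — or `"alive"` for the whole final population.
#' @param verbose print progress.
#' @return data.frame with one row per seeding event: `seed_index`,
#'   `size_fraction` (primary size at dissemination over final size), tree
#'   quantities from [divergenceTree()], measured `B_m`, `B_p`, and
#'   `frac_detectable` (fraction of the seeding cell's variants whose
#'   pooled primary VAF is at least `alpha`).
#' @export
divergenceSeries <- function(primary, metTarget = simParamsOf(primary)@Nfinal,
                             nRegions = 10, radius = 6.3,
                             meanDepth = 100, dispersion = 10,
                             alpha = 0.01, gamma = 0.2,
                             seed = 1L, growMets = TRUE,
                             treeObserved = c("sampled", "alive"),
                             verbose = FALSE) {
  treeObserved <- match.arg(treeObserved)
  ev <- seedingEvents(primary)
  if (!nrow(ev)) stop("primary has no seeding events")
  finalN <- length(aliveIds(primary))

  set.seed(seed %% 2147483647L)
  rs <- sampleRegions(primary, nRegions, radius)
  ci <- regionCarrierMatrix(primary, rs)
  seqP <- virtualSequence(ci, meanDepth, dispersion)
  poolP <- pooledVAF(seqP)
  fpByKey <- setNames(poolP$pooled_vaf, poolP$variant_key)

  obsSet <- if (treeObserved == "sampled")
    sort(unique(unlist(rs@members))) else aliveIds(primary)
  tree <- divergenceTree(primary, alpha, gamma, observed = obsSet)

  Bm <- Bp <- rep(NA_real_, nrow(ev))
  fracDet <- rep(NA_real_, nrow(ev))
  for (i in seq_len(nrow(ev))) {
    sc <- ev$seeding_cell[i]
    lineageVars <- cellVariants(primary, sc)
    if (length(lineageVars)) {
      fpLin <- fpByKey[as.character(lineageVars)]
      fpLin[is.na(fpLin)] <- 0
      fracDet[i] <- mean(fpLin >= alpha)
    } else fracDet[i] <- NA_real_
    if (growMets) {
      metSeed <- (as.integer(seed) * 1009L + ev$seed_index[i] * 7919L) %% 2147483647L
      set.seed(metSeed)
      met <- growMetastasis(primary, ev$seed_index[i], target = metTarget)
      rsM <- sampleRegions(met, nRegions, radius)
      ciM <- regionCarrierMatrix(met, rsM)
      seqM <- virtualSequence(ciM, meanDepth, dispersion)
      poolM <- pooledVAF(seqM)
      d <- measureDivergence(poolP, poolM, gamma, alpha)
      Bm[i] <- d$B_m
      Bp[i] <- d$B_p
      if (verbose)
        message(sprintf("event %d/%d: B_m=%d B_p=%d (met retries %d)",
                        i, nrow(ev), d$B_m, d$B_p,
                        met@metaData$extinction_retries))
    }
  }
  data.frame(seed_index = ev$seed_index,
             size_fraction = ev$primary_size_at_seed / finalN,
             k = tree$k, bmd_variants = tree$bmd_variants,
             bmd_generations = tree$bmd_generations,
             bp_tree = tree$bp_tree, bp_tree_edges = tree$bp_tree_edges,
             B_m = Bm, B_p = Bp, frac_detectable = fracDet)
}

#' Simulate a primary with seeding, reproducibly
#'
#' Seeds the RNG and runs [runWithSeeding()], conditioning on long-term
#' survival: a lineage that dies out (probability ~`rho` for the founder) is
#' restarted on the same RNG stream, so the result is deterministic given
#' `seed`.
#'
#' @param params a [SimParams-class].
#' @param seed integer RNG seed.
#' @param maxRetries attempts before giving up.
#' @return a [Tumor-class].
#' @export
simulatePrimary <- function(params, seed = 1L, maxRetries = 1000) {
  set.seed(as.integer(seed) %% 2147483647L)
  for (i in seq_len(maxRetries)) {
    tum <- suppressWarnings(runWithSeeding(params))
    if (!isExtinct(tum)) {
      tum@metaData$extinction_retries <- i - 1L
      tum@metaData$rng_seed <- as.integer(seed)
      return(tum)
    }
  }
  stop("primary extinct in all ", maxRetries, " attempts")
}
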