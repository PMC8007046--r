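#' Sample spherical regions from a tumor
#'
#' Draws `nRegions` spheres of the given radius (lattice units) centered on
#' occupied sites chosen uniformly at random among alive cells; members are
#' the alive cells within Euclidean distance `radius` of the center. At the
#' default radius 6.3 a dense tumor yields roughly one thousand cells per
#' region; spheres centered near the surface contain fewer, and overlap
#' between regions is permitted (a `disjoint` flag resamples centers whose
#' spheres would intersect an earlier region, for sensitivity checks).
#'
#' @param tumor a [Tumor-class].
#' @param nRegions number of regions (default 10).
#' @param radius sphere radius in lattice units (default 6.3).
#' @param disjoint forbid overlapping spheres.
#' @return a [RegionSample-class].
#' @export
sampleRegions <- function(tumor, nRegions = 10, radius = 6.3,
                          disjoint = FALSE) {
  cc <- cells(tumor)
  idx <- aliveIds(tumor)
  if (length(idx) < 2) stop("tumor too small to sample")
  px <- cc$x[idx]; py <- cc$y[idx]; pz <- cc$z[idx]
  centers <- matrix(NA_real_, nRegions, 3)
  members <- vector("list", nRegions)
  r2 <- radius^2
  tries <- 0
  i <- 1
  while (i <= nRegions) {
    ci <- sample.int(length(idx), 1)
    ctr <- c(px[ci], py[ci], pz[ci])
    if (disjoint && i > 1) {
      d2c <- colSums((t(centers[seq_len(i - 1), , drop = FALSE]) - ctr)^2)
      if (any(d2c < (2 * radius)^2)) {
        tries <- tries + 1
        if (tries > 1000) stop("cannot place disjoint regions")
        next
      }
    }
    d2 <- (px - ctr[1])^2 + (py - ctr[2])^2 + (pz - ctr[3])^2
    centers[i, ] <- ctr
    members[[i]] <- idx[d2 <= r2]
    i <- i + 1
  }
  regions <- data.frame(region_id = seq_len(nRegions),
                        cx = centers[, 1], cy = centers[, 2], cz = centers[, 3],
                        radius = radius,
                        n_cells = vapply(members, length, 1L))
  new("RegionSample", regions = regions, members = members)
}

#' Per-region variant carrier counts
#'
#' For every variant of the tumor (plus, for a metastasis, the variants
#' inherited clonally from its seeding cell), counts the member cells of
#' each region that carry it. A cell carries a variant iff the variant's
#' originating cell is among its ancestors (or itself), so carrier counts
#' are observed-descendant counts of the origin cells restricted to each
#' region.
#'
#' @param tumor a [Tumor-class].
#' @param regionSample a [RegionSample-class] from the same tumor.
#' @return list with `carriers` (variant x region integer matrix, rownames =
#'   variant keys), `regionSizes`, and `variantId` / `inherited` vectors.
#'   Inherited variants (clonal) have carrier count equal to the region
#'   size; their keys are prefixed `"inh_"` to keep them distinct from the
#'   metastasis's own variant ids.
#' @export
regionCarrierMatrix <- function(tumor, regionSample) {
  cc <- cells(tumor)
  members <- regionSample@members
  m <- length(members)
  obs <- matrix(FALSE, nrow = nrow(cc), ncol = m)
  for (j in seq_len(m)) obs[members[[j]], j] <- TRUE
  counts <- cpp_descendant_counts(as.integer(cc$parent_id), obs)
  vv <- variants(tumor)
  carriers <- counts[vv$origin_cell, , drop = FALSE]
  sizes <- vapply(members, length, 1L)
  keys <- as.character(vv$variant_id)
  inherited <- rep(FALSE, nrow(vv))
  if (length(tumor@inheritedVariants)) {
    inhC <- matrix(rep(sizes, each = length(tumor@inheritedVariants)),
                   nrow = length(tumor@inheritedVariants))
    carriers <- rbind(carriers, inhC)
    keys <- c(keys, paste0("inh_", tumor@inheritedVariants))
    inherited <- c(inherited, rep(TRUE, length(tumor@inheritedVariants)))
  }
  rownames(carriers) <- keys
  list(carriers = carriers, regionSizes = sizes,
       variantKey = keys, inherited = inherited)
}

#' Virtual sequencing of sampled regions
#'
#' For each (variant, region) pair the sequencing depth is drawn as
#' `D ~ NegBinom(mean = meanDepth, size = dispersion)` (so
#' `Var(D) = meanDepth + meanDepth^2/dispersion`), and the variant read
#' count as `M ~ Binom(D, F)` where the true allele frequency
#' `F = carriers / (2 * region size)` assumes heterozygous variants. A zero
#' depth yields an observed frequency of 0 (variant not seen).
#'
#' @param carrierInfo output of [regionCarrierMatrix()].
#' @param meanDepth mean sequencing depth (default 100).
#' @param dispersion negative binomial size parameter (default 10).
#' @return data.frame with one row per (variant, region): `variant_key`,
#'   `region_id`, `depth`, `alt_reads`, `true_vaf`, `obs_vaf`, `inherited`.
#' @export
virtualSequence <- function(carrierInfo, meanDepth = 100, dispersion = 10) {
  carriers <- carrierInfo$carriers
  sizes <- carrierInfo$regionSizes
  nv <- nrow(carriers); m <- ncol(carriers)
  FF <- sweep(carriers, 2, 2 * pmax(sizes, 1L), "/")
  FF[, sizes == 0] <- 0
  D <- matrix(rnbinom(nv * m, mu = meanDepth, size = dispersion), nv, m)
  M <- matrix(rbinom(nv * m, as.vector(D), as.vector(FF)), nv, m)
  data.frame(variant_key = rep(rownames(carriers), m),
             region_id = rep(seq_len(m), each = nv),
             depth = as.vector(D), alt_reads = as.vector(M),
             true_vaf = as.vector(FF),
             obs_vaf = ifelse(as.vector(D) > 0, as.vector(M) / as.vector(D), 0),
             inherited = rep(carrierInfo$inherited, m))
}

#' Pooled variant allele frequencies
#'
#' Pools reads across regions: `f = sum(M) / sum(D)` per variant.
#'
#' @param seqTable a [virtualSequence()] table.
#' @return data.frame(variant_key, pooled_vaf, inherited).
#' @export
pooledVAF <- function(seqTable) {
  Msum <- rowsum(seqTable$alt_reads, seqTable$variant_key, reorder = FALSE)
  Dsum <- rowsum(seqTable$depth, seqTable$variant_key, reorder = FALSE)
  inh <- seqTable$inherited[!duplicated(seqTable$variant_key)]
  data.frame(variant_key = rownames(Msum),
             pooled_vaf = ifelse(Dsum[, 1] > 0, Msum[, 1] / Dsum[, 1], 0),
             inherited = inh, row.names = NULL)
}

#' Measured metastatic-primary divergence from pooled frequencies
#'
#' Counts metastasis-specific variants
#' `B_m = #\{v: f_m > gamma, f_p < alpha\}` and primary-specific variants
#' `B_p = #\{v: f_p > gamma, f_m < alpha\}` over the union of the two
#' variant universes; a variant absent from one tumor has pooled frequency 0
#' there. Inequalities are strict on both sides.
#'
#' @param pooledPrimary,pooledMet [pooledVAF()] tables; `variant_key` values
#'   shared between the tumors (the inherited `"inh_"` keys of the
#'   metastasis against the primary's own ids) are matched via
#'   `metKeyMap`.
#' @param metKeyMap named character vector translating metastasis keys to
#'   primary keys (default: strip the `"inh_"` prefix, and namespace the
#'   metastasis's own post-dissemination variants as `"met_<id>"` so they
#'   never collide with primary ids — under infinite alleles they are
#'   distinct variants).
#' @param gamma substantial-presence threshold (default 0.2).
#' @param alpha detectability threshold (default 0.01).
#' @return data.frame(B_m, B_p).
#' @export
measureDivergence <- function(pooledPrimary, pooledMet,
                              gamma = 0.2, alpha = 0.01,
                              metKeyMap = NULL) {
  pk <- pooledPrimary$variant_key
  mk <- pooledMet$variant_key
  mkShared <- if (is.null(metKeyMap))
    ifelse(grepl("^inh_", mk), sub("^inh_", "", mk), paste0("met_", mk))
  else ifelse(mk %in% names(metKeyMap), metKeyMap[mk], mk)
  universe <- union(pk, mkShared)
  fp <- setNames(rep(0, length(universe)), universe)
  fm <- fp
  fp[pk] <- pooledPrimary$pooled_vaf
  fm[mkShared] <- pooledMet$pooled_vaf
  data.frame(B_m = sum(fm > gamma & fp < alpha),
             B_p = sum(fp > gamma & fm < alpha))
}

#' Hudson-style Fst between two sampled regions
#'
#' For each variant with frequencies `f_r`, `f_r'` at depths `D_r`, `D_r'`,
#' the numerator `(f_r - f_r')^2 - f_r(1-f_r)/(D_r - 1) - f_r'(1-f_r')/(D_r'-1)`
#' and denominator `f_r(1-f_r') + f_r'(1-f_r)` are each summed over variants
#' before taking the ratio (the genetic variance components are averaged
#' separately). Variants with depth < 2 in either region are dropped; a zero
#' denominator yields `NA`.
#'
#' @param seqTable a [virtualSequence()] table.
#' @param r,rprime region ids.
#' @return Fst estimate (can be slightly negative under no differentiation).
#' @export
fstPair <- function(seqTable, r, rprime) {
  a <- seqTable[seqTable$region_id == r, ]
  b <- seqTable[seqTable$region_id == rprime, ]
  b <- b[match(a$variant_key, b$variant_key), ]
  keep <- a$depth >= 2 & b$depth >= 2
  fa <- a$obs_vaf[keep]; fb <- b$obs_vaf[keep]
  Da <- a$depth[keep]; Db <- b$depth[keep]
  num <- sum((fa - fb)^2 - fa * (1 - fa) / (Da - 1) - fb * (1 - fb) / (Db - 1))
  den <- sum(fa * (1 - fb) + fb * (1 - fa))
  if (den == 0) return(NA_real_)
  num / den
}

#' @rdname fstPair
#' @return `fstMean`: average pairwise Fst over all region pairs (missing
#'   pairs dropped).
#' @export
fstMean <- function(seqTable) {
  ids <- sort(unique(seqTable$region_id))
  prs <- utils::combn(ids, 2)
  vals <- apply(prs, 2, function(p) fstPair(seqTable, p[1], p[2]))
  mean(vals, na.rm = TRUE)
}
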