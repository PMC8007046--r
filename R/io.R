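#' Write a simulated run to a directory
#'
#' Writes the standard tab-separated artifacts: `cells.tsv` (with
#' comma-joined `new_variant_ids` per cell), `variants.tsv`,
#' `seeding_events.tsv` and `run_meta.json` (full parameter echo, software
#' version, seeds).
#'
#' @param tumor a [Tumor-class].
#' @param dir output directory (created if missing).
#' @param seed the RNG seed used for the run, echoed into the manifest.
#' @return invisibly, the paths written.
#' @export
writeRun <- function(tumor, dir, seed = NA_integer_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cc <- cells(tumor)
  vv <- variants(tumor)
  byCell <- split(vv$variant_id, vv$origin_cell)
  nv <- character(nrow(cc))
  nv[as.integer(names(byCell))] <- vapply(byCell, paste, "", collapse = ",")
  cc$new_variant_ids <- nv
  p <- simParamsOf(tumor)
  paths <- c(cells = file.path(dir, "cells.tsv"),
             variants = file.path(dir, "variants.tsv"),
             seeding = file.path(dir, "seeding_events.tsv"),
             meta = file.path(dir, "run_meta.json"))
  data.table::fwrite(cc, paths["cells"], sep = "\t")
  data.table::fwrite(vv, paths["variants"], sep = "\t")
  data.table::fwrite(seedingEvents(tumor), paths["seeding"], sep = "\t")
  meta <- list(
    params = list(lambda0 = p@lambda0, mu = p@mu, rho = p@mu / p@lambda0,
                  u = p@u, ub = p@ub, s_mean = p@sMean, s_sd = p@sSd,
                  Ns = p@Ns, Nfinal = p@Nfinal, rho_met = p@rhoMet,
                  m_intra = p@mIntra,
                  genome_len_passenger = p@glenPassenger,
                  genome_len_driver = p@glenDriver,
                  poisson_mutations = p@poissonMutations,
                  density_dependent_death = p@densityDependentDeath),
    role = tumor@role, extinct = isExtinct(tumor),
    n_alive = length(aliveIds(tumor)),
    inherited_variants = tumor@inheritedVariants,
    rng_seed = seed,
    software = paste0("mpdiverge ", as.character(packageVersion("mpdiverge"))),
    run_meta = tumor@metaData)
  jsonlite::write_json(meta, paths["meta"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' Read a run directory back into a Tumor
#'
#' Inverse of [writeRun()]; field recovery is lossless for the registry
#' tables and parameters.
#'
#' @param dir a directory written by [writeRun()].
#' @return a [Tumor-class].
#' @export
readRun <- function(dir) {
  cc <- as.data.frame(data.table::fread(file.path(dir, "cells.tsv")))
  vv <- as.data.frame(data.table::fread(file.path(dir, "variants.tsv")))
  ev <- as.data.frame(data.table::fread(file.path(dir, "seeding_events.tsv")))
  meta <- jsonlite::read_json(file.path(dir, "run_meta.json"),
                              simplifyVector = TRUE)
  mp <- meta$params
  params <- simParams(lambda0 = mp$lambda0, mu = mp$mu, u = mp$u, ub = mp$ub,
                      sMean = mp$s_mean, sSd = mp$s_sd, Ns = mp$Ns,
                      Nfinal = mp$Nfinal, rhoMet = mp$rho_met,
                      glenPassenger = mp$genome_len_passenger,
                      glenDriver = mp$genome_len_driver,
                      poissonMutations = mp$poisson_mutations,
                      densityDependentDeath = mp$density_dependent_death)
  cc$new_variant_ids <- NULL
  cc$t_death[is.nan(cc$t_death)] <- NA_real_
  alive <- cc$cell_id[is.na(cc$t_death) & cc$disseminated == 0]
  if (!nrow(ev))
    ev <- data.frame(seed_index = integer(), seeding_cell = integer(),
                     primary_size_at_seed = numeric(), t_seed = numeric())
  new("Tumor", cells = cc, variants = vv, seeding = ev,
      sizeHistory = data.frame(time = numeric(), population = numeric()),
      params = params, aliveIds = as.integer(alive),
      extinct = isTRUE(meta$extinct), role = meta$role,
      inheritedVariants = as.integer(unlist(meta$inherited_variants)),
      metaData = as.list(meta$run_meta))
}

#' Minimal VCF export of a sequenced region
#'
#' Writes one VCF per region with virtual coordinates (`CHROM` is `"pass"`
#' or `"driver"` by variant kind, `POS` the virtual coordinate) and the
#' observed depth/alt counts; `INFO` carries the true cancer-cell fraction.
#' Intended for interoperability checks, not for real-data pipelines.
#'
#' @param tumor the sequenced [Tumor-class].
#' @param seqTable a [virtualSequence()] table for it.
#' @param regionId which region to export.
#' @param file output path.
#' @return invisibly, `file`.
#' @export
writeRegionVcf <- function(tumor, seqTable, regionId, file) {
  vv <- variants(tumor)
  tab <- seqTable[seqTable$region_id == regionId & !seqTable$inherited, ]
  idx <- match(as.integer(tab$variant_key), vv$variant_id)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=mpdiverge virtual sequencing",
           '##INFO=<ID=CCF,Number=1,Type=Float,Description="True cancer cell fraction in the region">',
           '##INFO=<ID=DP,Number=1,Type=Integer,Description="Simulated depth">',
           '##INFO=<ID=AC,Number=1,Type=Integer,Description="Simulated alt read count">',
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- sprintf("%s\t%d\tv%s\tN\tA\t.\tPASS\tCCF=%.6g;DP=%d;AC=%d",
                  ifelse(vv$kind[idx] == 1, "driver", "pass"),
                  as.integer(vv$coordinate[idx]), tab$variant_key,
                  2 * tab$true_vaf, tab$depth, tab$alt_reads)
  writeLines(c(hdr, rows), file)
  invisible(file)
}
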