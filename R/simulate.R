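#' Construct simulation parameters
#'
#' Defaults reflect the reference growth conditions: a four-day cell cycle
#' (`lambda0 = 0.25`/day), death rate set through the death-to-birth ratio
#' `rho`, passenger probability `u = 0.15` per daughter birth, driver
#' probability `ub` with selection coefficients from a Gaussian of mean
#' `sMean` and sd `sMean/2` truncated at zero, one metastatic seeding per
#' `Ns = 25000` cells of primary growth up to `Nfinal = 1e7` cells, and
#' metastases grown at `rhoMet = 0.72`. Variant coordinates are uniform
#' labels over a 5e7-position passenger space and a 2e5-position driver pool.
#'
#' @param lambda0 birth rate per day.
#' @param rho death-to-birth ratio `mu/lambda0`; ignored when `mu` is given.
#' @param mu death rate per day (overrides `rho`).
#' @param u passenger variant probability per daughter-cell birth.
#' @param ub driver variant probability per daughter-cell birth.
#' @param sMean mean selection coefficient.
#' @param sSd sd of the selection coefficient; defaults to `sMean/2`.
#' @param Ns primary-size increment triggering one seeding event.
#' @param Nfinal target size of the primary and of each metastasis.
#' @param rhoMet death-to-birth ratio for metastatic growth.
#' @param glenPassenger,glenDriver coordinate label space sizes.
#' @param poissonMutations draw Poisson(u) passengers per birth instead of
#'   Bernoulli(u).
#' @param densityDependentDeath modulate death by local density too (the
#'   default); see [SimParams-class].
#' @return a [SimParams-class] object.
#' @examples
#' p <- simParams(rho = 0.72, Nfinal = 1e4, Ns = 2500)
#' @export
simParams <- function(lambda0 = 0.25, rho = 0.99, mu = NULL,
                      u = 0.15, ub = 1e-5, sMean = 0, sSd = NULL,
                      Ns = 25000, Nfinal = 1e7, rhoMet = 0.72,
                      glenPassenger = 5e7, glenDriver = 2e5,
                      poissonMutations = FALSE, densityDependentDeath = TRUE) {
  if (is.null(mu)) mu <- rho * lambda0
  if (is.null(sSd)) sSd <- sMean / 2
  obj <- new("SimParams", lambda0 = lambda0, mu = mu, u = u, ub = ub,
             sMean = sMean, sSd = sSd, Ns = Ns, Nfinal = Nfinal,
             rhoMet = rhoMet, mIntra = 0,
             glenPassenger = glenPassenger, glenDriver = glenDriver,
             poissonMutations = poissonMutations,
             densityDependentDeath = densityDependentDeath)
  if (mu / lambda0 >= 1 && ub == 0)
    warning("rho >= 1 with no drivers: the tumor cannot reach the target size")
  obj
}

#' @rdname SimParams-class
#' @param x a `SimParams`
#' @export
rho <- function(x) x@mu / x@lambda0

.newTumor <- function(res, params, role, inherited = integer(),
                      meta = list()) {
  new("Tumor",
      cells = res$cells, variants = res$variants, seeding = res$seeding,
      sizeHistory = res$size_history, params = params,
      aliveIds = sort(as.integer(res$alive_ids)), extinct = res$extinct,
      role = role, inheritedVariants = as.integer(inherited),
      metaData = c(meta, list(final_time = res$final_time,
                              n_birth_events = res$n_birth_events,
                              n_death_events = res$n_death_events)))
}

#' Initialize a tumor with a single founder cell
#'
#' Returns a tumor of size one: the founder sits at the lattice center at
#' time zero with an empty variant set (its clonal variants are implicit;
#' time zero is the founder's birth).
#'
#' @param params a [SimParams-class].
#' @return a [Tumor-class] of one alive cell.
#' @export
initTumor <- function(params) {
  res <- cpp_grow_tumor(params@lambda0, params@mu, params@u, params@ub,
                        params@sMean, params@sSd, params@poissonMutations,
                        1, 0, params@glenPassenger, params@glenDriver,
                        1.0, 200L, 2.0, params@densityDependentDeath)
  .newTumor(res, params, "primary")
}

.grow <- function(params, target, ns, founderMult = 1.0, mu = NULL) {
  if (is.null(mu)) mu <- params@mu
  # near-critical fronts (rho close to 1) are strongly ramified and need a
  # much wider lattice than the dense-ball radius suggests
  rhoEff <- mu / params@lambda0
  lf <- if (rhoEff > 0.9) 8.0 else 2.0
  cpp_grow_tumor(params@lambda0, mu, params@u, params@ub,
                 params@sMean, params@sSd, params@poissonMutations,
                 target, ns, params@glenPassenger, params@glenDriver,
                 founderMult, 200L, lf, params@densityDependentDeath)
}

#' Grow a tumor to a target size (no seeding)
#'
#' Runs the exact stochastic event loop: cell `i` divides at rate
#' `lambda0 * multiplier_i * psi_i` and (by default) dies at rate
#' `mu * psi_i`, where `psi_i` is its fraction of empty Moore neighbors;
#' with `densityDependentDeath = FALSE` every alive cell instead dies at
#' rate `mu`. On division one daughter keeps the mother's site and the
#' other fills a uniformly chosen empty Moore neighbor; on death the site
#' is vacated.
#'
#' @param params a [SimParams-class].
#' @param target target population; defaults to `Nfinal`.
#' @return a [Tumor-class]. If the population dies out first, a condition of
#'   class `"mpdExtinct"` is raised carrying the partial tumor in its
#'   `tumor` field.
#' @export
runToSize <- function(params, target = params@Nfinal) {
  res <- .grow(params, target, 0)
  tum <- .newTumor(res, params, "primary")
  if (res$extinct)
    stop(structure(class = c("mpdExtinct", "error", "condition"),
                   list(message = "tumor went extinct before reaching the target size",
                        call = sys.call(-1), tumor = tum)))
  tum
}

#' Grow a primary tumor with periodic metastatic seeding
#'
#' Whenever the primary first reaches `I * Ns` cells (`I = 1, 2, ...`), the
#' next cell that is born disseminates: it is recorded in the registry
#' (flagged `disseminated`) and in the seeding table, but never occupies a
#' lattice site of the primary. The primary continues to `Nfinal`, yielding
#' `floor(Nfinal/Ns)` seeding events.
#'
#' @inheritParams runToSize
#' @return a [Tumor-class] whose `seedingEvents()` table has one row per
#'   dissemination. On extinction the partial tumor is returned with
#'   `isExtinct(x) == TRUE` and a warning.
#' @export
runWithSeeding <- function(params, target = params@Nfinal) {
  res <- .grow(params, target, params@Ns)
  tum <- .newTumor(res, params, "primary")
  if (res$extinct)
    warning("primary went extinct before reaching the target size; partial results returned")
  tum
}

#' Lineage (root path) of a cell
#'
#' @param tumor a [Tumor-class].
#' @param cellId a cell id.
#' @return integer vector of cell ids from the founder down to `cellId`.
#' @export
lineagePath <- function(tumor, cellId) {
  parent <- cells(tumor)$parent_id
  path <- integer(0)
  i <- as.integer(cellId)
  while (i > 0) {
    path <- c(path, i)
    i <- parent[i]
  }
  rev(path)
}

#' Variant ids carried by a cell
#'
#' All variants gained along the root path of the cell, in order of
#' acquisition (infinite-allele model: variants are never lost within a
#' lineage).
#'
#' @inheritParams lineagePath
#' @return integer vector of variant ids.
#' @export
cellVariants <- function(tumor, cellId) {
  path <- lineagePath(tumor, cellId)
  v <- variants(tumor)
  v$variant_id[v$origin_cell %in% path]
}

#' Grow a metastasis from a seeding event
#'
#' The disseminating cell refounds a tumor on a fresh lattice at
#' `rhoMet` (default 0.72) with all other parameters inherited from the
#' primary's configuration. The founder carries the seeding cell's full
#' variant set (clonal in the metastasis, recorded in
#' `x@inheritedVariants` as primary variant ids) and its driver-derived
#' birth-rate multiplier. Because a single lineage at `rhoMet = 0.72` dies
#' out with probability ~0.72, extinct attempts are refounded from the same
#' genotype with a fresh RNG stream, up to `maxRetries` times; the retry
#' count is kept in `metaData`.
#'
#' @param primary the primary [Tumor-class].
#' @param seedIndex which seeding event to grow.
#' @param target metastasis size; defaults to `Nfinal`.
#' @param maxRetries attempts before giving up.
#' @return a [Tumor-class] with `role == "metastasis"`.
#' @export
growMetastasis <- function(primary, seedIndex, target = simParamsOf(primary)@Nfinal,
                           maxRetries = 100) {
  ev <- seedingEvents(primary)
  row <- ev[ev$seed_index == seedIndex, , drop = FALSE]
  if (nrow(row) != 1) stop("no seeding event with index ", seedIndex)
  seedCell <- row$seeding_cell
  params <- simParamsOf(primary)
  inherited <- cellVariants(primary, seedCell)
  founderMult <- cells(primary)$multiplier[seedCell]
  muMet <- params@rhoMet * params@lambda0
  for (attempt in seq_len(maxRetries)) {
    res <- .grow(params, target, 0, founderMult = founderMult, mu = muMet)
    if (!res$extinct)
      return(.newTumor(res, params, "metastasis", inherited = inherited,
                       meta = list(seed_index = seedIndex,
                                   seeding_cell = seedCell,
                                   extinction_retries = attempt - 1L)))
  }
  stop("metastasis extinct in all ", maxRetries, " attempts")
}

#' Draw selection coefficients
#'
#' Gaussian(`sMean`, `sSd`) truncated below at zero by resampling; a zero
#' mean returns exact zeros. This is the distribution used for every driver
#' gained during simulation.
#'
#' @param n number of draws.
#' @param sMean,sSd mean and sd of the untruncated Gaussian.
#' @return numeric vector of non-negative coefficients.
#' @export
drawSelection <- function(n, sMean, sSd = sMean / 2) {
  cpp_draw_selection(as.integer(n), sMean, sSd)
}

#' Variant gains at one daughter birth
#'
#' Applies the per-birth mutation rule to a newborn daughter: one new
#' passenger with probability `u` (or Poisson(`u`) passengers behind the
#' flag), and independently one new driver with probability `ub`, whose
#' selection coefficient multiplies the inherited birth-rate multiplier by
#' `1 + s`.
#'
#' @param multiplier the mother's birth-rate multiplier.
#' @param params a [SimParams-class].
#' @return list with `kind` (0 passenger / 1 driver), `coordinate`,
#'   `s_value` per new variant, and the daughter's `multiplier`.
#' @export
applyBirthMutations <- function(multiplier, params) {
  res <- cpp_birth_mutations(params@u, params@ub, params@sMean, params@sSd,
                             params@poissonMutations,
                             params@glenPassenger, params@glenDriver)
  list(kind = res$kind, coordinate = res$coordinate, s_value = res$s_value,
       multiplier = multiplier * res$mult_factor)
}

#' Population size at given times
#'
#' Reconstructs the population trajectory from the registry: births minus
#' deaths minus disseminations up to each time.
#'
#' @param tumor a [Tumor-class].
#' @param times numeric vector of times (days).
#' @return integer population sizes.
#' @export
populationAt <- function(tumor, times) {
  cc <- cells(tumor)
  tb <- sort(cc$t_birth[cc$disseminated == 0])
  td <- sort(cc$t_death[!is.na(cc$t_death)])
  findInterval(times, tb) - findInterval(times, td)
}
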