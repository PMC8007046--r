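#' @useDynLib mpdiverge, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats lm coef confint rbinom rnbinom rnorm runif sd var
#'   pnorm dnorm complete.cases quantile setNames
#' @importFrom utils head tail write.table read.delim packageVersion
NULL

#' Simulation parameters for spatial tumor growth
#'
#' Holds the birth--death, mutation and seeding parameters of the
#' single-cell lattice model. Construct with [simParams()], which applies the
#' defaults used throughout: a four-day mean cell cycle (`lambda0 = 0.25`
#' per day), death-to-birth ratio `rho = mu/lambda0`, a passenger variant
#' probability `u` per daughter-cell birth, a driver probability `ub` with
#' Gaussian-distributed selection coefficients truncated at zero, seeding of
#' one metastasis every `Ns` cells of primary growth until the primary
#' reaches `Nfinal`, and a fast-growing metastasis (`rhoMet = 0.72`).
#'
#' @slot lambda0 numeric(1), initial birth rate per day.
#' @slot mu numeric(1), death rate per day.
#' @slot u numeric(1), passenger variant probability per daughter birth.
#' @slot ub numeric(1), driver variant probability per daughter birth.
#' @slot sMean numeric(1), mean selection coefficient.
#' @slot sSd numeric(1), sd of the selection coefficient (default `sMean/2`).
#' @slot Ns numeric(1), primary-size increment that triggers one seeding.
#' @slot Nfinal numeric(1), target cell count for the primary and each
#'   metastasis.
#' @slot rhoMet numeric(1), death-to-birth ratio applied to metastases.
#' @slot mIntra numeric(1), intra-tumoral migration rate (fixed at 0).
#' @slot glenPassenger numeric(1), passenger coordinate label space size.
#' @slot glenDriver numeric(1), driver coordinate label space size.
#' @slot poissonMutations logical(1), Poisson(u) passenger counts per birth
#'   instead of the default Bernoulli(u).
#' @slot densityDependentDeath logical(1), modulate the death rate by the
#'   empty-neighbor fraction `psi` as well (default `TRUE`), making each
#'   active-cell lineage an exact `lambda:mu` branching process; `FALSE`
#'   applies the death rate uniformly to all alive cells.
#' @exportClass SimParams
setClass("SimParams",
  representation(
    lambda0 = "numeric", mu = "numeric", u = "numeric", ub = "numeric",
    sMean = "numeric", sSd = "numeric", Ns = "numeric", Nfinal = "numeric",
    rhoMet = "numeric", mIntra = "numeric",
    glenPassenger = "numeric", glenDriver = "numeric",
    poissonMutations = "logical", densityDependentDeath = "logical"))

setValidity("SimParams", function(object) {
  msg <- character()
  if (object@lambda0 <= 0) msg <- c(msg, "lambda0 must be > 0")
  if (object@mu < 0) msg <- c(msg, "mu must be >= 0")
  if (object@u < 0 || object@u > 1) msg <- c(msg, "u must be in [0, 1]")
  if (object@ub < 0 || object@ub > 1) msg <- c(msg, "ub must be in [0, 1]")
  if (object@sMean < 0) msg <- c(msg, "sMean must be >= 0")
  if (object@sSd < 0) msg <- c(msg, "sSd must be >= 0")
  if (object@Ns > object@Nfinal) msg <- c(msg, "Ns must be <= Nfinal")
  if (object@Nfinal < 1) msg <- c(msg, "Nfinal must be >= 1")
  if (object@mIntra != 0) msg <- c(msg, "intra-tumoral migration is not modeled; mIntra must be 0")
  if (object@rhoMet < 0 || object@rhoMet >= 1) msg <- c(msg, "rhoMet must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' A simulated tumor: cell registry, variants and seeding events
#'
#' Returned by [runToSize()], [runWithSeeding()] and [growMetastasis()].
#' The cell registry has one row per cell ever born (identity, parentage,
#' lattice position, birth/death times, driver-derived birth-rate
#' multiplier); the variant table one row per somatic variant (virtual
#' coordinate, passenger/driver kind, selection coefficient, originating
#' cell). For a metastasis, `inheritedVariants` lists the primary variant ids
#' carried clonally by the seeding cell.
#'
#' @slot cells data.frame cell registry.
#' @slot variants data.frame variant registry.
#' @slot seeding data.frame of seeding events (primary only).
#' @slot sizeHistory data.frame of (time, population) checkpoints.
#' @slot params the [SimParams-class] used.
#' @slot aliveIds integer vector of cells alive at observation.
#' @slot extinct logical(1), whether the population died out before target.
#' @slot role "primary" or "metastasis".
#' @slot inheritedVariants integer, primary variant ids clonal in a
#'   metastasis (empty for a primary).
#' @slot metaData list of run metadata (seeds, retries, event counts).
#' @exportClass Tumor
setClass("Tumor",
  representation(
    cells = "data.frame", variants = "data.frame", seeding = "data.frame",
    sizeHistory = "data.frame", params = "SimParams",
    aliveIds = "integer", extinct = "logical", role = "character",
    inheritedVariants = "integer", metaData = "list"))

setValidity("Tumor", function(object) {
  msg <- character()
  cells <- object@cells
  if (nrow(cells)) {
    if (cells$parent_id[1] != 0) msg <- c(msg, "founder must have parent_id 0")
    if (cells$t_birth[1] != 0) msg <- c(msg, "founder must be born at time 0")
    bad <- !is.na(cells$t_death) & cells$t_death < cells$t_birth
    if (any(bad)) msg <- c(msg, "t_death must be >= t_birth")
    if (any(cells$multiplier < 1 - 1e-12)) msg <- c(msg, "birth-rate multipliers must be >= 1")
  }
  if (!object@role %in% c("primary", "metastasis"))
    msg <- c(msg, "role must be 'primary' or 'metastasis'")
  if (length(msg)) msg else TRUE
})

#' Genealogy index of a simulated tumor
#'
#' Parent map plus per-cell counts of observed (e.g. alive or sampled)
#' descendants, the structure on which detectable ancestors and the most
#' recent detectable ancestor are defined. Build with [genealogyIndex()].
#'
#' @slot parent integer parent id per cell (0 for the founder).
#' @slot descCounts integer observed-descendant count per cell (a cell counts
#'   itself when observed).
#' @slot nObserved integer(1), size of the observation set.
#' @slot variantOrigin integer, originating cell of each variant.
#' @exportClass Genealogy
setClass("Genealogy",
  representation(parent = "integer", descCounts = "integer",
                 nObserved = "integer", variantOrigin = "integer"))

setValidity("Genealogy", function(object) {
  if (length(object@descCounts) != length(object@parent))
    return("descCounts and parent must have equal length")
  if (object@nObserved > 0 && object@descCounts[1] != object@nObserved)
    return("root descendant count must equal the observation set size")
  TRUE
})

#' Spherical multi-region sample of a tumor
#'
#' Regions are spheres of fixed radius centered on randomly chosen occupied
#' lattice sites; overlap is permitted. Build with [sampleRegions()].
#'
#' @slot regions data.frame(region_id, cx, cy, cz, radius, n_cells).
#' @slot members list of integer cell-id vectors, one per region.
#' @exportClass RegionSample
setClass("RegionSample",
  representation(regions = "data.frame", members = "list"))

setValidity("RegionSample", function(object) {
  if (nrow(object@regions) != length(object@members))
    return("one member set per region required")
  if (!identical(object@regions$n_cells, vapply(object@members, length, 1L)))
    return("n_cells must match member set sizes")
  TRUE
})

#' Cell-type structure for the multi-type analytic model
#'
#' Describes a chain of nested advantageous types: type 0 is the founder's
#' type; each later type arises inside its predecessor at clock index `Tk[i]`
#' (measured on the seeding-cell variant-count clock), has death-to-birth
#' ratio `rho[i]` and its beneficial variant reaches final population
#' fraction `f[i]`. `scenario` selects how the seeding origin is weighted
#' across extant types. Build with [typeStructure()].
#'
#' @slot rho numeric death-to-birth ratios, strictly decreasing along the
#'   chain (type 0 first).
#' @slot Tk numeric appearance clock indices, `Tk[1] = 0`, strictly
#'   increasing.
#' @slot f numeric final population fractions of the beneficial variants
#'   (`f[1] = 1` for type 0; nested, so strictly decreasing).
#' @slot lambda numeric per-type birth rates (default proportional to
#'   `1/rho`, i.e. a shared death rate).
#' @slot scenario one of "most_advanced", "fitness_proportional", "uniform".
#' @exportClass TypeStructure
setClass("TypeStructure",
  representation(rho = "numeric", Tk = "numeric", f = "numeric",
                 lambda = "numeric", scenario = "character"))

setValidity("TypeStructure", function(object) {
  msg <- character()
  n <- length(object@rho)
  if (length(object@Tk) != n || length(object@f) != n || length(object@lambda) != n)
    msg <- c(msg, "rho, Tk, f and lambda must have equal length")
  if (n >= 1) {
    if (object@Tk[1] != 0) msg <- c(msg, "type 0 must appear at clock 0")
    if (object@f[1] != 1) msg <- c(msg, "type 0 fraction must be 1")
  }
  if (n >= 2) {
    if (any(diff(object@rho) >= 0)) msg <- c(msg, "rho must strictly decrease along the chain")
    if (any(diff(object@Tk) <= 0)) msg <- c(msg, "Tk must strictly increase")
    if (any(diff(object@f) >= 0)) msg <- c(msg, "f must strictly decrease (nested subtypes)")
    if (any(object@f[-1] <= 0 | object@f[-1] >= 1))
      msg <- c(msg, "type fractions must lie in (0, 1)")
  }
  if (!object@scenario %in% c("most_advanced", "fitness_proportional", "uniform"))
    msg <- c(msg, "unknown seeding scenario")
  if (any(object@rho < 0 | object@rho >= 1)) msg <- c(msg, "rho values must be in [0, 1)")
  if (length(msg)) msg else TRUE
})
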