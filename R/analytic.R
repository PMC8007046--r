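#' Expected population size of a supercritical birth-death process
#'
#' Expected cell count at time `t`, conditioned on long-term survival, for a
#' process with birth rate `lambda` and death-to-birth ratio `rho`:
#' `N(t) = (1/rho) exp(lambda t) - (1/rho - 1) exp(-lambda t)`.
#'
#' @param t time (same units as `1/lambda`).
#' @param rho death-to-birth ratio in (0, 1).
#' @param lambda birth rate (default 1; only the product `lambda*t` matters).
#' @return expected number of cells.
#' @export
populationSize <- function(t, rho, lambda = 1) {
  stopifnot(all(t >= 0))
  if (rho <= 0 || rho >= 1) stop("rho must be in (0, 1)")
  (1 / rho) * exp(lambda * t) - (1 / rho - 1) * exp(-lambda * t)
}

#' Order map of seeding-lineage variants
#'
#' Maps the `j`-th variant particular to the seeding cell's lineage to its
#' expected absolute order of appearance in the whole tumor,
#' `g(c_j) = u * N(t_j)` with `t_j = j/(u*lambda)` (inter-variant waiting
#' times along a lineage are exponential with rate `u*lambda`, and a
#' population of `N` cells carries about `N*u` surviving variants). The
#' birth rate cancels, so `g` depends only on `j`, `u` and `rho`;
#' algebraically `g(c_j) = u * (exp(-j/u) + 2*sinh(j/u)/rho)`.
#'
#' @param j variant index along the lineage (0 = founder variant).
#' @param u passenger variant probability per division.
#' @param rho death-to-birth ratio in (0, 1).
#' @return expected absolute variant order (numeric, may be `Inf` for large
#'   `j`).
#' @export
orderMap <- function(j, u, rho) {
  stopifnot(all(j >= 0), u > 0, u <= 1)
  if (rho <= 0 || rho >= 1) stop("rho must be in (0, 1)")
  u * populationSize(j / u, rho, lambda = 1)
}

#' Detectability of seeding-lineage variants
#'
#' Probability that the `j`-th variant along the seeding cell's lineage ends
#' up present in at least a fraction `f` of the final primary tumor:
#' `d_j = (u / (u - log(1 + (rho - 1) f)))^g(c_j)` for `j >= 1`, with
#' `d_0 = 1` exactly (the founder variant is clonal). The sequence is
#' strictly decreasing in `j` and tends to 0; it is the decay whose shape
#' controls the expected pre-dissemination divergence.
#'
#' @param j integer vector of lineage indices (>= 0).
#' @param u passenger probability per division.
#' @param rho death-to-birth ratio in (0, 1).
#' @param f detectability frequency threshold (e.g. `2*alpha`), must satisfy
#'   `f < 1/(1 - rho)`.
#' @return probabilities in [0, 1].
#' @export
detectability <- function(j, u, rho, f) {
  stopifnot(all(j >= 0), f > 0)
  arg <- 1 + (rho - 1) * f
  if (arg <= 0) stop("threshold too large: requires f < 1/(1 - rho)")
  base <- u / (u - log(arg))
  if (base <= 0 || base > 1) stop("invalid detectability base; check u, rho, f")
  g <- orderMap(j, u, rho)
  d <- exp(g * log(base))       # handles g = Inf -> 0
  d[j == 0] <- 1
  d
}

#' Distribution of the pre-dissemination divergence at a given seeding time
#'
#' For a seeding cell carrying `k` variants, the number of its variants that
#' end up undetectable in the primary has pmf
#' `Pr[B = k - j] = d_j - d_{j+1}` for `j < k` and `Pr[B = 0] = d_k`, where
#' `d_j` is the detectability of the `j`-th lineage variant. The pmf
#' telescopes to 1 because `d_0 = 1`.
#'
#' @param k seeding time on the variant-count clock (>= 0).
#' @param u,rho,f as in [detectability()].
#' @return list with `value` (0..k), `pmf`, `mean`, `sd`.
#' @export
bmdPmf <- function(k, u, rho, f) {
  d <- detectability(0:(k + 1), u, rho, f)
  bmdPmfFromDetectability(d[seq_len(k + 1)])
}

#' @rdname bmdPmf
#' @param d vector `d_0..d_k` of detectability probabilities (decreasing,
#'   `d[1] = 1`).
#' @export
bmdPmfFromDetectability <- function(d) {
  k <- length(d) - 1L
  if (k < 0) stop("need at least d_0")
  value <- 0:k
  if (k == 0) pmf <- 1
  else pmf <- c(d[k + 1], rev(d[-length(d)] - d[-1]))  # Pr[B=0], then k-j
  mu <- sum(value * pmf)
  list(value = value, pmf = pmf, mean = mu,
       sd = sqrt(max(0, sum(value^2 * pmf) - mu^2)))
}

#' Expected pre-dissemination divergence under neutral growth
#'
#' Closed-form expectation
#' `E = sum_{j=1}^{K} j * (d_{K-j} - d_{K-j+1})`, the mean of the
#' [bmdPmf()] distribution computed by the direct sum. Monotonically
#' non-decreasing in `K`, with an initial near-flat phase whose length grows
#' with `rho` followed by a steady linear increase.
#'
#' @param K seeding time on the variant-count clock.
#' @param f detectability frequency threshold.
#' @param rho death-to-birth ratio.
#' @param u passenger probability per division.
#' @return expected number of undetectable seeding-cell variants.
#' @export
expectedBmdNeutral <- function(K, f, rho, u) {
  if (K == 0) return(0)
  d <- detectability(0:K, u, rho, f)
  j <- seq_len(K)
  sum(j * (d[K - j + 1] - d[K - j + 2]))
}

#' Construct a multi-type structure
#'
#' @param rho death-to-birth ratios, type 0 first, strictly decreasing.
#' @param Tk appearance indices on the variant-count clock (`Tk[1] = 0`).
#' @param f final population fractions of the beneficial variants
#'   (`f[1] = 1`; nested subtypes, strictly decreasing).
#' @param scenario seeding-origin weighting: `"most_advanced"`,
#'   `"fitness_proportional"` or `"uniform"`.
#' @param lambda per-type birth rates; default `rho[1]/rho` (shared death
#'   rate across types, birth rate raised by the beneficial variant).
#' @return a [TypeStructure-class].
#' @export
typeStructure <- function(rho, Tk, f, scenario = c("most_advanced",
                                                   "fitness_proportional",
                                                   "uniform"),
                          lambda = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(lambda)) lambda <- rho[1] / rho
  new("TypeStructure", rho = as.numeric(rho), Tk = as.numeric(Tk),
      f = as.numeric(f), lambda = as.numeric(lambda), scenario = scenario)
}

#' Seeding-origin weights at a given seeding time
#'
#' Probability that the seeding cell originates from each type, at clock
#' index `k`, under the structure's scenario: (a) `most_advanced` puts all
#' mass on the newest extant type; (b) `fitness_proportional` weights extant
#' types by birth rate; (c) `uniform` weights them by expected population
#' size, whose ratios are governed by the net growth rates
#' `lambda_i - mu` over the elapsed clock `(k - T_i)/u` (shared death rate,
#' so a fitter late type overtakes gradually). A type has weight 0 before
#' its appearance index; weights sum to 1.
#'
#' @param k seeding time on the variant-count clock.
#' @param structure a [TypeStructure-class].
#' @return numeric vector of weights, one per type.
#' @export
seedingWeights <- function(k, structure) {
  n <- length(structure@rho)
  extant <- structure@Tk <= k
  w <- numeric(n)
  if (structure@scenario == "most_advanced") {
    w[max(which(extant))] <- 1
  } else if (structure@scenario == "fitness_proportional") {
    w[extant] <- structure@lambda[extant]
    w <- w / sum(w)
  } else {
    # expected type sizes: ratios are governed by the net growth rates
    # lambda_i - mu (shared death rate mu = lambda_0 * rho_0), on the
    # lineage clock t = k/(u*lambda_0); computed in log space
    u <- 0.15
    mu <- structure@lambda[1] * structure@rho[1]
    logN <- rep(-Inf, n)
    for (i in which(extant))
      logN[i] <- (structure@lambda[i] - mu) * (k - structure@Tk[i]) /
        (u * structure@lambda[1])
    w[extant] <- exp(pmin(logN[extant] - max(logN[extant]), 0))
    w <- w / sum(w)
  }
  w
}

#' Expected divergence under the multi-type mixture
#'
#' Scenario-weighted mixture of neutral expectations: the branch for type
#' `i` uses the clock `k - T_i` and the rescaled detectability threshold
#' `2*alpha/f_i` (the variant must reach a fraction `2*alpha` of the whole
#' tumor from inside a subpopulation of final fraction `f_i`); the type-0
#' branch uses `2*alpha/(1 - f_1)`. For two types this is
#' `phi_1 * E[B; k - T_1, 2a/f_1, rho_1] + (1 - phi_1) * E[B; k, 2a/(1-f_1), rho_0]`,
#' and it extends recursively along nested subtype chains. The reported sd
#' is the between-origin component, `sqrt(sum_i phi_i E_i^2 - E^2)`: the
#' variability induced by the uncertainty in seeding origination, which is
#' exactly 0 under the deterministic `most_advanced` scenario.
#'
#' @param k seeding time on the variant-count clock.
#' @param structure a [TypeStructure-class].
#' @param alpha sequencing detectability VAF threshold (`f = 2*alpha`).
#' @param u passenger probability per division.
#' @return list with `mean`, `sd`, `weights`, `perType`.
#' @export
expectedBmdMultitype <- function(k, structure, alpha = 0.01, u = 0.15) {
  n <- length(structure@rho)
  fFull <- structure@f
  # effective subpopulation fraction per branch: full f_i for advantaged
  # types, remainder 1 - f_1 for type 0
  fracs <- c(if (n >= 2) 1 - fFull[2] else 1, fFull[-1])
  w <- seedingWeights(k, structure)
  Ei <- vapply(seq_len(n), function(i) {
    if (w[i] == 0) return(0)
    expectedBmdNeutral(max(k - structure@Tk[i], 0),
                       2 * alpha / fracs[i], structure@rho[i], u)
  }, 1)
  E <- sum(w * Ei)
  list(mean = E, sd = sqrt(max(0, sum(w * Ei^2) - E^2)),
       weights = w, perType = Ei)
}

#' Expected primary-specific branch length
#'
#' `B_p(k) = |M| - k + B_md(k; gamma)`: the detectable primary variants
#' minus those carried by the seeding cell. Decays linearly with seeding
#' time where `B_md` is flat, stays flat where `B_md` grows one-per-variant,
#' and tracks its drops. Negative values (the approximation pushed beyond
#' its regime) are clamped to 0 with a warning.
#'
#' @param k seeding time on the variant-count clock.
#' @param Mcount number of variants with frequency above `gamma` in the
#'   primary (known, e.g. from multi-region sampling).
#' @param bmdAtGamma expected `B_md` evaluated at the `gamma` threshold.
#' @return expected number of primary-specific variants.
#' @export
expectedBp <- function(k, Mcount, bmdAtGamma) {
  v <- Mcount - k + bmdAtGamma
  if (any(v < 0)) {
    warning("negative expected B_p clamped to 0 (approximation regime exceeded)")
    v <- pmax(v, 0)
  }
  v
}

#' Analytic divergence curves over seeding time
#'
#' Tabulates expected `B_md`, its between-origin sd, and expected `B_p` for
#' `k = 0..kMax`, either for a neutral model (pass `rho` and no
#' `structure`) or for a multi-type structure under one or more seeding
#' scenarios.
#'
#' @param kMax largest seeding index.
#' @param u passenger probability per division.
#' @param alpha detectability VAF threshold (`f = 2*alpha`).
#' @param gamma substantial-presence VAF threshold (for the `B_p` column).
#' @param Mcount detectable-variant count used for `B_p`.
#' @param rho neutral death-to-birth ratio (ignored if `structure` given).
#' @param structure optional [TypeStructure-class]; `scenario` is taken from
#'   it.
#' @return data.frame(k, scenario, E_bmd, Sd_bmd, E_bp).
#' @export
analyticCurves <- function(kMax, u = 0.15, alpha = 0.01, gamma = 0.2,
                           Mcount = 50, rho = 0.95, structure = NULL) {
  ks <- 0:kMax
  if (is.null(structure)) {
    E <- vapply(ks, function(k) expectedBmdNeutral(k, 2 * alpha, rho, u), 1)
    S <- vapply(ks, function(k) bmdPmf(k, u, rho, 2 * alpha)$sd, 1)
    Eg <- vapply(ks, function(k) expectedBmdNeutral(k, 2 * gamma, rho, u), 1)
    scen <- "neutral"
  } else {
    res <- lapply(ks, function(k) expectedBmdMultitype(k, structure, alpha, u))
    E <- vapply(res, `[[`, 1, "mean")
    S <- vapply(res, `[[`, 1, "sd")
    Eg <- vapply(ks, function(k)
      expectedBmdMultitype(k, structure, alpha = gamma, u = u)$mean, 1)
    scen <- structure@scenario
  }
  Ebp <- suppressWarnings(expectedBp(ks, Mcount, Eg))
  data.frame(k = ks, scenario = scen, E_bmd = E, Sd_bmd = S, E_bp = Ebp)
}
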