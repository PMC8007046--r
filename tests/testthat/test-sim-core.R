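test_that("initialization produces a single founder at the origin", {
  p <- simParams(lambda0 = 0.25, mu = 0.2475, Nfinal = 10, Ns = 10)
  tum <- initTumor(p)
  cc <- cells(tum)
  expect_equal(nrow(cc), 1)
  expect_equal(cc$parent_id, 0)
  expect_equal(unlist(cc[1, c("x", "y", "z")]), c(x = 0, y = 0, z = 0))
  expect_equal(cc$t_birth, 0)
  expect_equal(length(aliveIds(tum)), 1)
  expect_equal(nrow(variants(tum)), 0)
})

test_that("identical seeds give identical runs", {
  p <- simParams(rho = 0.72, sMean = 0.1, ub = 1e-3, Nfinal = 500, Ns = 100)
  a <- simulatePrimary(p, seed = 11)
  b <- simulatePrimary(p, seed = 11)
  expect_identical(cells(a), cells(b))
  expect_identical(variants(a), variants(b))
  expect_identical(seedingEvents(a), seedingEvents(b))
})

test_that("registry conserves births, deaths and disseminations", {
  p <- simParams(rho = 0.72, Nfinal = 2000, Ns = 500)
  tum <- simulatePrimary(p, seed = 2)
  cc <- cells(tum)
  births <- nrow(cc)
  deaths <- sum(!is.na(cc$t_death))
  diss <- sum(cc$disseminated)
  expect_equal(births - deaths - diss, length(aliveIds(tum)))
  # lineage closure: parents born before children
  nonRoot <- cc$parent_id > 0
  expect_true(all(cc$t_birth[cc$parent_id[nonRoot]] < cc$t_birth[nonRoot]))
  # alive cells occupy distinct lattice sites
  al <- aliveIds(tum)
  expect_equal(anyDuplicated(cc[al, c("x", "y", "z")]), 0)
})

test_that("neutral total births match the branching-process expectation", {
  # with both rates density-modulated the embedded per-cell process is an
  # exact lambda:mu branching process: E[births to reach N] ~ N/(1-rho)
  p <- simParams(rho = 0.72, u = 0, ub = 0, Nfinal = 1000, Ns = 1000)
  births <- c()
  set.seed(42)
  nRep <- 0
  while (length(births) < 50) {
    tum <- tryCatch(runToSize(p), mpdExtinct = function(e) NULL)
    nRep <- nRep + 1
    if (!is.null(tum)) births <- c(births, tum@metaData$n_birth_events)
  }
  expected <- 1000 / (1 - 0.72)
  # conditioning on survival and the +N-1 net-growth constraint keep the
  # mean within a few percent of the unconditioned branching value
  expect_lt(abs(mean(births) - expected) / expected, 0.10)
  # extinction frequency ~ rho
  extRate <- 1 - 50 / nRep
  expect_lt(abs(extRate - 0.72), 0.15)
})

test_that("a fully surrounded cell cannot divide and the interior stays dense", {
  p <- simParams(rho = 0.72, Nfinal = 5000, Ns = 5000)
  tum <- growConditioned(p, 7)
  cc <- cells(tum)
  al <- aliveIds(tum)
  d <- sqrt(cc$x[al]^2 + cc$y[al]^2 + cc$z[al]^2)
  # interior density near 1: psi ~ 0 there, so neither birth nor death occurs
  innerSites <- 4 / 3 * pi * 6^3
  expect_gt(sum(d <= 6) / innerSites, 0.9)
})

test_that("passenger accrual is Binomial(births, u)", {
  p <- simParams(rho = 0.72, u = 0.15, ub = 0, Nfinal = 5000, Ns = 5000)
  tum <- growConditioned(p, 3)
  nb <- nrow(cells(tum)) - 1 # daughters born
  np <- sum(variants(tum)$kind == 0)
  sigma <- sqrt(nb * 0.15 * 0.85)
  expect_lt(abs(np - nb * 0.15), 3 * sigma)
})

test_that("per-birth mutation rule updates the multiplier by 1+s", {
  p <- simParams(sMean = 0.1, ub = 1, u = 0, Nfinal = 10, Ns = 10)
  set.seed(1)
  res <- applyBirthMutations(1.5, p)
  expect_equal(length(res$s_value), 1)
  expect_equal(res$multiplier, 1.5 * (1 + res$s_value))
  p0 <- simParams(sMean = 0, ub = 0, u = 0, Nfinal = 10, Ns = 10)
  res0 <- applyBirthMutations(1, p0)
  expect_equal(length(res0$kind), 0)
  expect_equal(res0$multiplier, 1)
})

test_that("selection draws follow the truncated Gaussian", {
  expect_equal(drawSelection(100, 0), rep(0, 100))
  set.seed(9)
  x <- drawSelection(1e4, 0.2, 0.1)
  expect_true(all(x >= 0))
  # truncated-normal mean: m + sd * phi(a) / (1 - Phi(a)), a = -m/sd
  a <- -0.2 / 0.1
  mTrunc <- 0.2 + 0.1 * dnorm(a) / (1 - pnorm(a))
  vTrunc <- 0.1^2 * (1 + a * dnorm(a) / (1 - pnorm(a)) -
                       (dnorm(a) / (1 - pnorm(a)))^2)
  expect_lt(abs(mean(x) - mTrunc), 3 * sqrt(vTrunc / 1e4))
})

test_that("seeding fires once per Ns increment and removes the emigrant", {
  p <- simParams(rho = 0.72, Nfinal = 1e4, Ns = 250)
  prim <- simulatePrimary(p, seed = 4)
  ev <- seedingEvents(prim)
  expect_equal(nrow(ev), 40) # floor(Nfinal/Ns)
  expect_true(all(diff(ev$primary_size_at_seed) > 0))
  expect_false(any(ev$seeding_cell %in% aliveIds(prim)))
  cc <- cells(prim)
  expect_true(all(cc$disseminated[ev$seeding_cell] == 1))
  expect_true(all(is.na(cc$t_death[ev$seeding_cell])))
})

test_that("metastases inherit genotype but grow at rho_met", {
  p <- simParams(rho = 0.99, sMean = 0.2, ub = 1e-3, Nfinal = 2000, Ns = 500,
                 rhoMet = 0.72)
  prim <- simulatePrimary(p, seed = 6)
  ev <- seedingEvents(prim)
  set.seed(6)
  met <- growMetastasis(prim, ev$seed_index[2], target = 1000)
  expect_s4_class(met, "Tumor")
  expect_equal(met@role, "metastasis")
  # founder variants are clonal: carrier fraction 1 among all met cells
  expect_setequal(met@inheritedVariants,
                  cellVariants(prim, ev$seeding_cell[2]))
  # founder multiplier carried over
  expect_equal(cells(met)$multiplier[1],
               cells(prim)$multiplier[ev$seeding_cell[2]])
  # with u = 0 the met has exactly the inherited variants
  p0 <- simParams(rho = 0.72, u = 0, ub = 0, Nfinal = 2000, Ns = 500)
  prim0 <- simulatePrimary(p0, seed = 8)
  set.seed(8)
  met0 <- growMetastasis(prim0, 1, target = 500)
  expect_equal(nrow(variants(met0)), 0)
  expect_setequal(met0@inheritedVariants,
                  cellVariants(prim0, seedingEvents(prim0)$seeding_cell[1]))
})

test_that("neutral site-frequency tail is monotone", {
  p <- simParams(rho = 0.72, Nfinal = 5000, Ns = 5000)
  tum <- growConditioned(p, 12)
  gen <- genealogyIndex(tum)
  frac <- descendantFraction(gen)[variants(tum)$origin_cell]
  tail <- vapply(c(0.01, 0.02, 0.05, 0.1, 0.2, 0.4), function(f)
    sum(frac >= f), 1)
  expect_true(all(diff(tail) <= 0))
})

test_that("peripheral growth: division depth increases with distance to center", {
  p <- simParams(rho = 0.72, sMean = 0, ub = 0, Nfinal = 1e4, Ns = 1e4)
  tum <- growConditioned(p, 5)
  cc <- cells(tum)
  al <- aliveIds(tum)
  vv <- variants(tum)
  nVar <- tabulate(vv$origin_cell, nbins = nrow(cc))
  gen <- numeric(nrow(cc)); burden <- numeric(nrow(cc))
  for (i in seq_len(nrow(cc))) {
    pid <- cc$parent_id[i]
    gen[i] <- if (pid > 0) gen[pid] + 1 else 0
    burden[i] <- nVar[i] + if (pid > 0) burden[pid] else 0
  }
  d <- sqrt(cc$x[al]^2 + cc$y[al]^2 + cc$z[al]^2)
  expect_gt(cor(d, gen[al]), 0.5)
  # the variant count inherits the signal through Binomial(g, u) thinning;
  # at this size the correlation is positive but attenuated
  expect_gt(cor(d, burden[al]), 0.1)
})

test_that("invalid configurations are rejected, subcritical ones warned", {
  expect_error(simParams(lambda0 = -1, Nfinal = 10, Ns = 10), "lambda0")
  expect_error(simParams(u = 2, Nfinal = 10, Ns = 10), "u must")
  expect_error(simParams(Nfinal = 10, Ns = 100), "Ns")
  expect_warning(simParams(rho = 1.2, ub = 0, Nfinal = 10, Ns = 10),
                 "cannot reach")
  p <- simParams(rho = 0.9999, mu = 0.25, ub = 0, Nfinal = 1e5, Ns = 1e5) |>
    suppressWarnings()
  expect_s4_class(p, "SimParams")
})
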