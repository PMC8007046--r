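test_that("conditioned population size evaluates the closed form", {
  expect_equal(populationSize(0, 0.5), 1)
  expect_equal(populationSize(1, 0.5), 2 * exp(1) - exp(-1))
  # dominant term for large t
  expect_equal(populationSize(30, 0.8) / (exp(30) / 0.8), 1, tolerance = 1e-10)
  expect_error(populationSize(1, 0), "rho")
  expect_error(populationSize(1, 1), "rho")
})

test_that("the order map follows from the lineage clock", {
  expect_equal(orderMap(0, 0.15, 0.8), 0.15)
  u <- 0.15
  for (rho in c(0.72, 0.95, 0.99)) {
    g <- orderMap(1:10, u, rho)
    expect_true(all(diff(g) > 0))
    # direct substitution of t_j = j/(u*lambda) into the population size
    j <- 1:10
    expect_equal(g, u * ((1 / rho) * exp(j / u) - (1 / rho - 1) * exp(-j / u)))
    # sinh rearrangement of the same expression
    expect_equal(g, u * (exp(-j / u) + 2 * sinh(j / u) / rho))
  }
})

test_that("detectability decays from 1 to 0 along the lineage", {
  d <- detectability(0:25, u = 0.15, rho = 0.72, f = 0.02)
  expect_equal(d[1], 1)
  expect_true(all(diff(d) < 0 | d[-1] == 0))
  expect_lt(d[26], 1e-10)
  # near-critical limit: base -> 1 so detectability stays near 1 at fixed j
  dCrit <- detectability(1, 0.15, 0.999999, 0.02)
  expect_gt(dCrit, 0.999)
  # domain error when the threshold exceeds 1/(1-rho)
  expect_error(detectability(1, 0.15, 0.5, 2.5), "f <")
})

test_that("high-precision re-evaluation matches the closed form", {
  u <- 0.15; rho <- 0.72; f <- 0.02
  j <- 1:6
  base <- u / (u - log1p((rho - 1) * f))
  g <- u * (exp(-j / u) + 2 * sinh(j / u) / rho)
  expect_equal(detectability(j, u, rho, f), base^g, tolerance = 1e-12)
})

test_that("the divergence pmf telescopes to 1 and matches hand differencing", {
  hand <- bmdPmfFromDetectability(c(1, 0.9, 0.5, 0.1))
  expect_equal(hand$value, 0:3)
  expect_equal(hand$pmf, c(0.1, 0.4, 0.4, 0.1))
  expect_equal(sum(hand$pmf), 1)
  # point mass at zero seeding time
  expect_equal(bmdPmf(0, 0.15, 0.9, 0.02)$pmf, 1)
  for (k in c(1, 7, 40, 200, 1000)) {
    pm <- bmdPmf(k, 0.15, 0.95, 0.02)
    expect_equal(sum(pm$pmf), 1, tolerance = 1e-12)
    expect_true(all(pm$pmf >= 0))
    expect_equal(length(pm$pmf), k + 1)
  }
})

test_that("the closed-form expectation equals the pmf mean on a parameter grid", {
  for (u in c(0.05, 0.15, 0.5))
    for (rho in c(0.72, 0.95, 0.99))
      for (f in c(0.002, 0.02, 0.2))
        for (K in c(1, 3, 10, 50)) {
          expect_equal(expectedBmdNeutral(K, f, rho, u),
                       bmdPmf(K, u, rho, f)$mean, tolerance = 1e-9)
        }
})

test_that("neutral expectation is monotone with a rho-controlled flat phase", {
  for (rho in c(0.72, 0.9, 0.99)) {
    E <- vapply(0:60, function(K) expectedBmdNeutral(K, 0.02, rho, 0.15), 1)
    expect_true(all(diff(E) >= -1e-12))
    # late phase: unit slope (new variants are almost surely undetectable)
    expect_equal(diff(E)[50:59], rep(1, 10), tolerance = 1e-6)
  }
  # the asymptotic offset K - E (total expected detectability mass) grows
  # with rho: slower growth keeps early variants detectable longer
  offset <- vapply(c(0.72, 0.9, 0.95, 0.99), function(rho)
    60 - expectedBmdNeutral(60, 0.02, rho, 0.15), 1)
  expect_true(all(diff(offset) > 0))
})

test_that("seeding weights implement the three origination scenarios", {
  tsA <- typeStructure(c(0.95, 0.93), c(0, 6), c(1, 0.873), "most_advanced")
  expect_equal(seedingWeights(3, tsA), c(1, 0))   # before T1
  expect_equal(seedingWeights(6, tsA), c(0, 1))   # newest extant wins
  tsB <- typeStructure(c(0.95, 0.93), c(0, 6), c(1, 0.873),
                       "fitness_proportional")
  wB <- seedingWeights(10, tsB)
  expect_equal(wB, tsB@lambda / sum(tsB@lambda))
  expect_equal(sum(wB), 1)
  tsC <- typeStructure(c(0.95, 0.93), c(0, 6), c(1, 0.873), "uniform")
  expect_equal(seedingWeights(2, tsC), c(1, 0))
  wC <- seedingWeights(20, tsC)
  expect_equal(sum(wC), 1)
  expect_true(all(wC >= 0))
  # equal expected sizes -> weight 1/2 (identical types, same birth epoch)
  tsEq <- new("TypeStructure", rho = c(0.95, 0.95 - 1e-9), Tk = c(0, 1e-9),
              f = c(1, 0.5), lambda = c(1, 1), scenario = "uniform")
  expect_equal(seedingWeights(10, tsEq), c(0.5, 0.5), tolerance = 1e-6)
})

test_that("type structure validity enforces the nested-chain ordering", {
  expect_error(typeStructure(c(0.95, 0.96), c(0, 5), c(1, 0.8)), "decrease")
  expect_error(typeStructure(c(0.95, 0.9), c(0, 0), c(1, 0.8)), "increase")
  expect_error(typeStructure(c(0.95, 0.9), c(0, 5), c(1, 1.2)), "decrease|\\(0, 1\\)")
})

test_that("mixture expectation collapses to neutral and drops at introductions", {
  # collapse: f1 -> 1 under most_advanced reduces to neutral with shifted clock
  ts1 <- typeStructure(c(0.95, 0.93), c(0, 6), c(1, 1 - 1e-9), "most_advanced")
  m <- expectedBmdMultitype(20, ts1, alpha = 0.01, u = 0.15)
  expect_equal(m$mean, expectedBmdNeutral(14, 0.02, 0.93, 0.15),
               tolerance = 1e-6)
  expect_equal(m$sd, 0) # deterministic origination
  # the reference two-type structure: drops at each introduction for (a), (b)
  for (scen in c("most_advanced", "fitness_proportional")) {
    ts <- typeStructure(c(0.95, 0.93, 0.83), c(0, 6, 13), c(1, 0.873, 0.771),
                        scen)
    E <- vapply(0:21, function(k) expectedBmdMultitype(k, ts)$mean, 1)
    dE <- diff(E)
    expect_lt(dE[6], 0)   # k = 5 -> 6 crosses T1
    expect_lt(dE[13], 0)  # k = 12 -> 13 crosses T2
  }
  # scenario (c): a negative finite difference appears after T1
  tsU <- typeStructure(c(0.95, 0.93, 0.83), c(0, 6, 13), c(1, 0.873, 0.771),
                       "uniform")
  EU <- vapply(0:21, function(k) expectedBmdMultitype(k, tsU)$mean, 1)
  expect_lt(min(diff(EU)[7:21]), 0)
  # origination variability appears only after a second type can seed
  tsB <- typeStructure(c(0.95, 0.93), c(0, 6), c(1, 0.873),
                       "fitness_proportional")
  sdB <- vapply(0:15, function(k) expectedBmdMultitype(k, tsB)$sd, 1)
  expect_true(all(sdB[1:6] == 0))
  expect_gt(max(sdB[8:16]), 0)
})

test_that("expected primary-specific branch follows the linear-decay identity", {
  expect_equal(expectedBp(20, 50, 5), 35)
  expect_warning(v <- expectedBp(100, 50, 5), "clamped")
  expect_equal(v, 0)
  # where B_md grows with unit slope, B_p is flat
  rho <- 0.95; u <- 0.15
  ks <- 30:40
  bmdG <- vapply(ks, function(k) expectedBmdNeutral(k, 0.4, rho, u), 1)
  bp <- expectedBp(ks, 60, bmdG)
  expect_lt(diff(range(bp)), 0.05)
})

test_that("analytic curve tables cover neutral and multitype modes", {
  cn <- analyticCurves(15, rho = 0.95)
  expect_equal(nrow(cn), 16)
  expect_true(all(diff(cn$E_bmd) >= 0))
  ts <- typeStructure(c(0.95, 0.93, 0.83), c(0, 6, 13), c(1, 0.873, 0.771),
                      "most_advanced")
  cm <- analyticCurves(21, structure = ts)
  expect_equal(unique(cm$scenario), "most_advanced")
  expect_lt(min(diff(cm$E_bmd)), 0)          # the drops
  expect_true(all(cm$Sd_bmd == 0))           # deterministic origination
  c1 <- analyticCurves(0, rho = 0.9)
  expect_equal(nrow(c1), 1)
})

test_that("non-spatial birth-death simulation reproduces the detectability decay", {
  # small exponential tumors: empirical per-rank detectability of lineage
  # variants is decreasing, and the empirical mean divergence at fixed k
  # tracks the closed form computed from the EMPIRICAL detectability curve
  # (the analytic g() is an asymptotic approximation, so it is checked in
  # shape, not held to the small-N simulation)
  simTree <- function(N, rho, u) {
    parent <- c(0L); nvar <- c(0L); alive <- c(1L)
    while (length(alive) < N) {
      i <- alive[sample.int(length(alive), 1)]
      if (runif(1) < 1 / (1 + rho)) {
        parent <- c(parent, i)
        nvar <- c(nvar, rbinom(1, 1, u))
        alive <- c(alive, length(parent))
      } else {
        alive <- alive[alive != i]
        if (!length(alive)) return(NULL)
      }
    }
    list(parent = parent, nvar = nvar, alive = alive)
  }
  set.seed(77)
  f <- 0.1
  num <- matrix(0, 2, 12)  # detected / total per rank
  bmdByK <- list()
  reps <- 0
  while (reps < 60) {
    tr <- simTree(300, 0.5, 0.3)
    if (is.null(tr)) next
    reps <- reps + 1
    n <- length(tr$parent)
    obs <- matrix(FALSE, n, 1); obs[tr$alive, 1] <- TRUE
    counts <- mpdiverge:::cpp_descendant_counts(tr$parent, obs)[, 1]
    frac <- counts / length(tr$alive)
    sc <- tr$alive[sample.int(length(tr$alive), 1)]
    path <- integer(0); i <- sc
    while (i > 0) { path <- c(i, path); i <- tr$parent[i] }
    varCells <- path[tr$nvar[path] == 1]
    k <- length(varCells)
    if (k == 0 || k > 12) next
    det <- frac[varCells] >= f
    for (j in seq_len(k)) {
      num[1, j] <- num[1, j] + det[j]
      num[2, j] <- num[2, j] + 1
    }
    bmd <- k - max(c(0, which(det)))
    bmdByK[[length(bmdByK) + 1]] <- c(k, bmd)
  }
  dEmp <- num[1, ] / pmax(num[2, ], 1)
  ranks <- which(num[2, ] >= 15)
  # decay with rank (allowing sampling noise via a fitted slope)
  expect_lt(coef(lm(dEmp[ranks] ~ ranks))[2], 0)
  # structural identity: mean B_md equals k - E[deepest detectable rank],
  # the quantity the telescoping pmf encodes
  bk <- do.call(rbind, bmdByK)
  kk <- bk[bk[, 1] == as.integer(names(which.max(table(bk[, 1])))), ]
  dHat <- c(1, dEmp[seq_len(kk[1, 1])])
  expect_equal(mean(kk[, 2]),
               bmdPmfFromDetectability(pmin(cummin(dHat), 1))$mean,
               tolerance = 0.6)
})
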