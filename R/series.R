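#' Running mean and standard deviation of a divergence series
#'
#' Centered moving statistics over seeding-event order; windows are
#' truncated at the edges.
#'
#' @param y numeric series (ordered by seeding index).
#' @param window window width in events (default 20).
#' @return data.frame(index, mean, sd); sd is `NA` for singleton windows.
#' @export
runningStats <- function(y, window = 20) {
  n <- length(y)
  if (n < 2) stop("series must have at least 2 points")
  if (window < 2) stop("window must be >= 2")
  h <- window %/% 2
  lo <- pmax(1, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + (window - 1 - h))
  m <- vapply(seq_len(n), function(i) mean(y[lo[i]:hi[i]]), 1)
  s <- vapply(seq_len(n), function(i) sd(y[lo[i]:hi[i]]), 1)
  data.frame(index = seq_len(n), mean = m, sd = s)
}

#' Variance explained by a predictor
#'
#' Ordinary least squares of `y` on `x`: coefficient of determination,
#' slope, and its 95% confidence interval. Used to quantify how much of the
#' measured metastasis-specific divergence is captured by the tree-based
#' branch length versus, e.g., tumor size at dissemination.
#'
#' @param x predictor, `y` response.
#' @return list with `r_squared`, `slope`, `slope_ci` (length-2),
#'   `intercept`, `n`.
#' @export
varianceExplained <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 10) stop("need at least 10 complete points")
  if (var(x) == 0) stop("zero-variance predictor")
  fit <- lm(y ~ x)
  ci <- confint(fit)["x", ]
  list(r_squared = summary(fit)$r.squared,
       slope = unname(coef(fit)["x"]),
       slope_ci = unname(ci),
       intercept = unname(coef(fit)["(Intercept)"]),
       n = length(x))
}

#' White's test for heteroscedasticity of a divergence series
#'
#' Regresses the series on seeding order and applies White's test (the
#' auxiliary regression of squared residuals on the regressor and its
#' square, via the studentized Breusch-Pagan statistic). Small p-values
#' indicate that the series' variability changes over seeding time, the
#' signature of selective growth modes.
#'
#' @param y numeric series ordered by seeding index.
#' @param x optional predictor (default seeding order `seq_along(y)`).
#' @return p-value.
#' @export
heteroscedasticityTest <- function(y, x = seq_along(y)) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(y) < 20) stop("need at least 20 points")
  if (var(x) == 0) stop("degenerate design")
  fit <- lm(y ~ x)
  unname(lmtest::bptest(fit, ~ x + I(x^2))$p.value)
}

#' Detect subclonal expansions
#'
#' Finds every cell whose descendants make up at least `threshold` of the
#' final sampled population (each qualifying cell is an event, including
#' nested ancestors), and reports the primary tumor size — as a fraction of
#' its final size — when that cell was born.
#'
#' @param tumor a primary [Tumor-class].
#' @param sampledCells integer cell ids defining the final sampled
#'   population (e.g. the union of sampled regions); defaults to all alive
#'   cells.
#' @param threshold minimum sampled-descendant fraction (default 0.05).
#' @return data.frame(cell_id, t_birth, size_at_birth, size_fraction,
#'   sampled_fraction).
#' @export
detectExpansions <- function(tumor, sampledCells = aliveIds(tumor),
                             threshold = 0.05) {
  if (!length(sampledCells)) stop("empty sampled population")
  gen <- genealogyIndex(tumor, sampledCells)
  frac <- gen@descCounts / gen@nObserved
  ids <- which(frac >= threshold)
  cc <- cells(tumor)
  sz <- populationAt(tumor, cc$t_birth[ids])
  finalN <- length(aliveIds(tumor))
  data.frame(cell_id = ids, t_birth = cc$t_birth[ids],
             size_at_birth = sz, size_fraction = sz / finalN,
             sampled_fraction = frac[ids])
}

#' Zigzag partition of a series into increasing and decreasing phases
#'
#' Peak/trough segmentation that retains only reversals exceeding
#' `changePct` percent of the preceding extremum (a zig-zag filter applied
#' to running means). When an extremum is 0 the threshold falls back to
#' `changePct` percent of the series mean, so count-valued series with
#' zeros remain segmentable.
#'
#' @param y numeric series (typically a running mean).
#' @param changePct minimum reversal size, percent (default 10).
#' @return data.frame(start, end, direction) of alternating phases covering
#'   the series; a flat series yields a single phase of direction 0.
#' @export
zigzagPartition <- function(y, changePct = 10) {
  n <- length(y)
  if (n < 2) stop("series too short")
  thr <- function(ref) {
    base <- if (abs(ref) > 0) abs(ref) else mean(abs(y))
    base * changePct / 100
  }
  pivots <- 1L
  lastExt <- y[1]; lastIdx <- 1L
  dir <- 0L  # unresolved
  candExt <- y[1]; candIdx <- 1L
  for (i in 2:n) {
    if (dir == 0L) {
      if (y[i] >= lastExt + thr(lastExt)) { dir <- 1L; candExt <- y[i]; candIdx <- i }
      else if (y[i] <= lastExt - thr(lastExt)) { dir <- -1L; candExt <- y[i]; candIdx <- i }
    } else if (dir == 1L) {
      if (y[i] > candExt) { candExt <- y[i]; candIdx <- i }
      else if (y[i] <= candExt - thr(candExt)) {
        pivots <- c(pivots, candIdx); lastExt <- candExt
        dir <- -1L; candExt <- y[i]; candIdx <- i
      }
    } else {
      if (y[i] < candExt) { candExt <- y[i]; candIdx <- i }
      else if (y[i] >= candExt + thr(candExt)) {
        pivots <- c(pivots, candIdx); lastExt <- candExt
        dir <- 1L; candExt <- y[i]; candIdx <- i
      }
    }
  }
  if (dir == 0L) return(data.frame(start = 1L, end = n, direction = 0L))
  pivots <- c(pivots, n)
  starts <- pivots[-length(pivots)]
  ends <- pivots[-1]
  dirs <- as.integer(sign(y[ends] - y[starts]))
  data.frame(start = starts, end = ends, direction = dirs)
}

#' Valley detection against a randomization envelope
#'
#' Flags the intervals where the running mean of the observed series falls
#' below the pointwise `quantile` (default 5%) of running means computed on
#' `nRandomizations` random shuffles of the series. A `literalFraction`
#' flag switches to the alternative reading — below `quantile` times the
#' mean of the randomized running means.
#'
#' @param y numeric series.
#' @param window running-mean window (default 20).
#' @param nRandomizations number of shuffles (default 1000).
#' @param quantile envelope level (default 0.05).
#' @param literalFraction use the fraction-of-mean rule instead of the
#'   percentile envelope.
#' @return list with `intervals` (data.frame start/end, possibly empty),
#'   `running` (observed running mean) and `envelope`.
#' @export
valleyDetection <- function(y, window = 20, nRandomizations = 1000,
                            quantile = 0.05, literalFraction = FALSE) {
  n <- length(y)
  if (n < 20) stop("series must have at least 20 points")
  obs <- runningStats(y, window)$mean
  rnd <- vapply(seq_len(nRandomizations), function(i)
    runningStats(sample(y), window)$mean, numeric(n))
  env <- if (literalFraction) quantile * rowMeans(rnd)
         else apply(rnd, 1, stats::quantile, probs = quantile)
  below <- obs < env
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- data.frame(start = starts[r$values], end = ends[r$values])
  list(intervals = iv, running = obs, envelope = env)
}

#' Permutation test for co-occurrence of expansions with divergence drops
#'
#' Tests whether subclonal-expansion birth times fall inside drop/valley
#' intervals of the divergence series more often than chance, restricted to
#' the part of growth after `domainStart` (fraction of final size). The
#' null relocates the intervals by a circular shift within the restricted
#' domain (preserving their number and lengths); the one-sided p-value is
#' `(1 + #{shifts with overlap >= observed}) / (nPerm + 1)`.
#'
#' @param eventPositions expansion birth positions in size-fraction
#'   coordinates.
#' @param intervals data.frame(start, end) in the same coordinates.
#' @param domainStart lower bound of the analysed domain (default 0.2).
#' @param nPerm number of random shifts (default 1000).
#' @return list with `p_value`, `observed` overlap count and `n_events`.
#' @export
cooccurrenceTest <- function(eventPositions, intervals, domainStart = 0.2,
                             nPerm = 1000) {
  dEnd <- 1
  if (domainStart >= dEnd) stop("empty domain")
  ev <- eventPositions[eventPositions > domainStart & eventPositions <= dEnd]
  iv <- intervals
  iv$start <- pmax(iv$start, domainStart)
  iv <- iv[iv$end > domainStart, , drop = FALSE]
  width <- dEnd - domainStart
  countIn <- function(shift) {
    s <- (iv$start - domainStart + shift) %% width
    e <- s + (iv$end - iv$start)
    sum(vapply(ev, function(p) {
      q <- (p - domainStart) %% width
      any((q >= s & q <= e) | (q + width >= s & q + width <= e))
    }, TRUE))
  }
  if (!nrow(iv) || !length(ev))
    return(list(p_value = 1, observed = 0L, n_events = length(ev)))
  obs <- countIn(0)
  perm <- vapply(runif(nPerm, 0, width), countIn, 1L)
  list(p_value = (1 + sum(perm >= obs)) / (nPerm + 1),
       observed = obs, n_events = length(ev))
}
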