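# shared fixtures: conditioned growth and a hand-built genealogy

growConditioned <- function(params, seed, target = params@Nfinal) {
  set.seed(seed)
  repeat {
    tum <- tryCatch(runToSize(params, target), mpdExtinct = function(e) NULL)
    if (!is.null(tum)) return(tum)
  }
}

# Small deterministic tumor built by hand: a comb-like genealogy with known
# descendant structure. Cells 1..n; `parents` maps child -> parent;
# `alive` marks the observation set; `varOrigin` places one variant per
# listed cell.
handTumor <- function(parents, alive, varOrigin = integer(),
                      params = simParams(Nfinal = length(parents) + 1,
                                         Ns = length(parents) + 1)) {
  n <- length(parents) + 1L
  cellIds <- seq_len(n)
  tb <- seq(0, by = 0.5, length.out = n)
  td <- rep(NA_real_, n)
  td[setdiff(cellIds, alive)] <- max(tb) + 1
  cells <- data.frame(cell_id = cellIds,
                      parent_id = c(0L, as.integer(parents)),
                      x = 0L, y = 0L, z = cellIds, t_birth = tb, t_death = td,
                      disseminated = 0L, multiplier = 1)
  variants <- data.frame(variant_id = seq_along(varOrigin),
                         coordinate = seq_along(varOrigin),
                         kind = 0L, s_value = 0,
                         origin_cell = as.integer(varOrigin),
                         t_origin = tb[varOrigin])
  new("Tumor", cells = cells, variants = variants,
      seeding = data.frame(seed_index = integer(), seeding_cell = integer(),
                           primary_size_at_seed = numeric(), t_seed = numeric()),
      sizeHistory = data.frame(time = 0, population = 1),
      params = params, aliveIds = as.integer(alive), extinct = FALSE,
      role = "primary", inheritedVariants = integer(), metaData = list())
}

# random genealogy via a pure-birth chain: every new cell picks a uniform
# existing parent; all cells observed unless dropFrac given
randomGenealogy <- function(n, seed, dropFrac = 0) {
  set.seed(seed)
  parents <- integer(n - 1)
  for (i in seq_len(n - 1)) parents[i] <- sample.int(i, 1)
  alive <- seq_len(n)
  if (dropFrac > 0)
    alive <- sort(sample(alive, ceiling(n * (1 - dropFrac))))
  varOrigin <- seq_len(n) # one variant per cell birth
  handTumor(parents, alive, varOrigin)
}

# brute-force observed-descendant sets by transitive closure
bruteDescendants <- function(tumor) {
  cc <- cells(tumor)
  n <- nrow(cc)
  kids <- split(cc$cell_id[cc$parent_id > 0], cc$parent_id[cc$parent_id > 0])
  desc <- vector("list", n)
  for (i in n:1) {
    ks <- kids[[as.character(i)]]
    desc[[i]] <- c(i, unlist(desc[ks]))
  }
  desc
}
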