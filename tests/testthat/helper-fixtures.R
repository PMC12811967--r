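# Small fixtures shared across tests; everything is built in code.

# the flagged toy series used throughout the variant-derivation examples:
# marks 1..5, mark 3 XPL-only, marks 4-5 one multiplet group
toy_flagged_series <- function(id = "TOY") {
  growth_series(id, "tibia", data.frame(
    cgmc = 1:5,
    circumference = c(100, 120, 130, 135, 150),
    xpl_only = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    multiplet_group = c(NA, NA, NA, "g1", "g1")))
}

linear_series <- function(id, start, slope, n, element = "tibia") {
  growth_series(id, element,
                data.frame(cgmc = seq_len(n),
                           circumference = start + slope * (seq_len(n) - 1)))
}

# three specimens on one noise-free logistic with known erased-mark offsets
noise_free_logistic <- function(offsets = c(0, 3, 7),
                                params = c(a = 500, b = 15, c = 4),
                                n_marks = 14) {
  f <- function(t) params[["a"]] * stats::plogis((t - params[["b"]]) / params[["c"]])
  lapply(seq_along(offsets), function(j) {
    yrs <- offsets[j] + seq_len(n_marks)
    growth_series(sprintf("NF-%d", j), "tibia",
                  data.frame(cgmc = seq_len(n_marks), circumference = f(yrs)))
  })
}

# brute-force grid-search oracle for pairwise start offsets (<= 3 series):
# scans every combination of free starts on a grid and returns the minimizer
# of the symmetric projection objective used by cluster_starts
grid_search_starts <- function(series, lo = -10, hi = 10, by = 0.01) {
  ds <- pool_dataset(series, "A")
  keys <- sapply(ds$series, function(s) paste(s$specimen_id, s$element, sep = ":"))
  mins <- sapply(ds$series, function(s) min(s$records$circumference, na.rm = TRUE))
  ref <- which.min(mins)
  free <- setdiff(seq_along(series), ref)
  age_at <- function(s, circ) {
    r <- s$records[s$records$measured, ]
    stats::approx(r$circumference, r$cgmc, xout = circ, ties = mean, rule = 1)$y
  }
  # per ordered pair, the projection differences d_i = cgmc_u,i - age_v,i
  # are fixed; the pair contributes sum((d_i + s_u - s_v)^2), so the grid
  # scan only needs (count, sum d, sum d^2) per pair
  pairs <- list()
  for (u in seq_along(series)) for (v in seq_along(series)) {
    if (u == v) next
    ru <- ds$series[[u]]$records
    av <- age_at(ds$series[[v]], ru$circumference)
    ok <- !is.na(av)
    if (!any(ok)) next
    d <- ru$cgmc[ok] - av[ok]
    pairs[[length(pairs) + 1]] <-
      list(u = u, v = v, n = sum(ok), s1 = sum(d), s2 = sum(d^2))
  }
  # obj accepts one vector-valued start (recycled), so a whole grid row is
  # evaluated at once
  obj <- function(starts) {
    tot <- 0
    for (p in pairs) {
      dd <- starts[[p$u]] - starts[[p$v]]
      tot <- tot + p$n * dd^2 + 2 * dd * p$s1 + p$s2
    }
    tot
  }
  grid <- seq(lo, hi, by = by)
  starts <- numeric(length(series))
  base <- as.list(starts)
  if (length(free) == 1) {
    s <- base; s[[free]] <- grid
    starts[free] <- grid[which.min(obj(s))]
  } else if (length(free) == 2) {
    best <- Inf
    for (g1 in grid) {
      s <- base; s[[free[1]]] <- g1; s[[free[2]]] <- grid
      vals <- obj(s)
      i <- which.min(vals)
      if (vals[i] < best) { best <- vals[i]; starts[free] <- c(g1, grid[i]) }
    }
  } else stop("oracle supports <= 3 series")
  stats::setNames(starts, keys)
}
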