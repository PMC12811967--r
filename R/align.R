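#' Circumference-overlap graph of a dataset
#'
#' Two series overlap when their measured circumference ranges intersect.
#' Start-age clustering is defined only when this graph is connected.
#'
#' @param dataset a `variant_dataset`.
#' @return an [igraph][igraph::make_graph] undirected graph whose vertices
#'   are series keys (`specimen:element`).
#' @export
overlap_graph <- function(dataset) {
  series <- dataset$series
  keys <- vapply(series, series_key, character(1))
  ranges <- lapply(series, function(s)
    range(s$records$circumference[s$records$measured]))
  n <- length(series)
  edges <- character(0)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (ranges[[i]][1] <= ranges[[j]][2] &&
          ranges[[j]][1] <= ranges[[i]][2])
        edges <- c(edges, keys[i], keys[j])
    }
  }
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(keys)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  g
}

# age at a given circumference on a series, by piecewise-linear
# interpolation of (circumference -> cgmc); NA outside the measured range
age_at_circumference <- function(series, circ) {
  r <- series$records[series$records$measured, ]
  if (length(unique(r$circumference)) < 2)
    return(rep(NA_real_, length(circ)))
  stats::approx(x = r$circumference, y = r$cgmc, xout = circ,
                ties = mean, rule = 1)$y
}

#' Least-squares clustering of start ages
#'
#' Initializes the per-series relative start ages by projecting every
#' measured point of each series onto every overlapping series (piecewise
#' linear interpolation on the circumference axis) and minimizing the total
#' squared age residual. Because start ages shift series horizontally, the
#' residuals are linear in the starts and the minimizer is obtained in
#' closed form as a linear least-squares solution. Both directions of each
#' overlapping pair contribute, making the objective symmetric in series
#' order. The reference series - the one containing the smallest measured
#' circumference - is pinned at start 0.
#'
#' @param dataset a `variant_dataset` whose overlap graph is connected.
#' @return object of class `start_assignment`: list with `starts` (named
#'   numeric, years), `reference_series` and `objective` (the minimized sum
#'   of squared age residuals).
#' @export
cluster_starts <- function(dataset) {
  series <- dataset$series
  keys <- vapply(series, series_key, character(1))
  g <- overlap_graph(dataset)
  comp <- igraph::components(g)
  if (comp$no > 1) {
    iso <- names(comp$membership)[comp$membership != comp$membership[1]]
    stop("overlap graph is disconnected; clustering only works if each ",
         "growth series is overlapped by one or more other series ",
         "(isolated: ", paste(iso, collapse = ", "), ")")
  }
  min_circ <- vapply(series, function(s)
    min(s$records$circumference[s$records$measured]), numeric(1))
  ref <- which.min(min_circ)

  # residual rows: (cgmc_u + s_u) - (age_v + s_v)  =>  s_u - s_v = age_v - cgmc_u
  rows_u <- integer(0); rows_v <- integer(0); rhs <- numeric(0)
  n <- length(series)
  for (u in seq_len(n)) for (v in seq_len(n)) {
    if (u == v) next
    ru <- series[[u]]$records[series[[u]]$records$measured, ]
    av <- age_at_circumference(series[[v]], ru$circumference)
    ok <- !is.na(av)
    if (!any(ok)) next
    rows_u <- c(rows_u, rep(u, sum(ok)))
    rows_v <- c(rows_v, rep(v, sum(ok)))
    rhs <- c(rhs, av[ok] - ru$cgmc[ok])
  }
  free <- setdiff(seq_len(n), ref)
  X <- matrix(0, nrow = length(rhs), ncol = length(free),
              dimnames = list(NULL, keys[free]))
  for (m in seq_along(free)) {
    X[rows_u == free[m], m] <- X[rows_u == free[m], m] + 1
    X[rows_v == free[m], m] <- X[rows_v == free[m], m] - 1
  }
  fit <- stats::lm.fit(X, rhs)
  starts <- stats::setNames(numeric(n), keys)
  starts[free] <- fit$coefficients
  starts[is.na(starts)] <- 0
  structure(
    list(starts = starts, reference_series = keys[ref],
         objective = sum(fit$residuals^2)),
    class = "start_assignment")
}

#' @export
print.start_assignment <- function(x, ...) {
  cat("<start_assignment> reference:", x$reference_series, "\n")
  print(round(x$starts, 3))
  invisible(x)
}

#' Write a start-age table
#'
#' @param assignment a `start_assignment`.
#' @param path CSV output path.
#' @export
write_starts_table <- function(assignment, path) {
  utils::write.csv(
    data.frame(series = names(assignment$starts),
               start = unname(assignment$starts),
               reference = names(assignment$starts) ==
                 assignment$reference_series),
    path, row.names = FALSE)
  invisible(path)
}
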