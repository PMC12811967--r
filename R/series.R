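#' Construct a CGM growth series
#'
#' A growth series is the ordered record of cortical growth marks (CGM) read
#' from one skeletal element (femur or tibia) of one specimen. Each mark
#' carries its count index `cgmc` (years since the first preserved mark,
#' starting at 1 or higher when inner marks were erased by medullary
#' expansion), its circumference in millimetres when measurable, and
#' annotation flags: `measured` (FALSE for marks whose presence was counted
#' but whose circumference could not be traced), `xpl_only` (annuli visible
#' only under cross-polarized light), `multiplet_group` (label shared by the
#' tightly-spaced members of one multiplet) and `double_lag` (informational;
#' a double LAG is a single CGM).
#'
#' @param specimen_id specimen identifier, e.g. a museum number.
#' @param element `"femur"` or `"tibia"`.
#' @param records data.frame with columns `cgmc`, `circumference`, and
#'   optionally `uid`, `measured`, `xpl_only`, `multiplet_group`,
#'   `double_lag`.
#' @param taxon_label free-text taxon annotation.
#' @return object of class `growth_series`.
#' @export
growth_series <- function(specimen_id, element, records, taxon_label = "") {
  stopifnot(is.character(specimen_id), length(specimen_id) == 1)
  element <- match.arg(element, c("femur", "tibia"))
  records <- as.data.frame(records)
  if (!all(c("cgmc", "circumference") %in% names(records)))
    stop("records must have columns cgmc and circumference")
  n <- nrow(records)
  if (is.null(records$measured)) records$measured <- !is.na(records$circumference)
  if (is.null(records$xpl_only)) records$xpl_only <- FALSE
  if (is.null(records$multiplet_group)) records$multiplet_group <- NA_character_
  if (is.null(records$double_lag)) records$double_lag <- FALSE
  if (is.null(records$uid))
    records$uid <- sprintf("%s|%s|%03d", specimen_id, element,
                           as.integer(records$cgmc))
  records <- records[order(records$cgmc),
                     c("uid", "cgmc", "circumference", "measured",
                       "xpl_only", "multiplet_group", "double_lag")]
  records$cgmc <- as.integer(records$cgmc)
  records$circumference <- as.numeric(records$circumference)
  records$multiplet_group <- as.character(records$multiplet_group)
  rownames(records) <- NULL
  out <- structure(
    list(specimen_id = specimen_id, element = element,
         records = records, taxon_label = taxon_label),
    class = "growth_series")
  validate_growth_series(out)
  out
}

validate_growth_series <- function(series) {
  r <- series$records
  id <- paste(series$specimen_id, series$element)
  if (any(diff(r$cgmc) < 1))
    stop("cgmc must be strictly increasing in series ", id)
  if (anyDuplicated(r$uid))
    stop("duplicate uid in series ", id)
  if (any(r$cgmc < 1))
    stop("cgmc must be >= 1 in series ", id)
  if (any(r$measured & (is.na(r$circumference) | r$circumference <= 0)))
    stop("measured records need a positive circumference in series ", id)
  if (any(!r$measured & !is.na(r$circumference)))
    stop("unmeasured records must have absent circumference in series ", id)
  circ <- r$circumference[r$measured]
  if (length(circ) > 1 && any(diff(circ) < 0))
    stop("circumference decreases in series ", id,
         " (bone perimeter cannot shrink)")
  invisible(series)
}

#' @export
print.growth_series <- function(x, ...) {
  cat(sprintf("<growth_series> %s %s: %d marks (%d measured)\n",
              x$specimen_id, x$element, nrow(x$records),
              sum(x$records$measured)))
  invisible(x)
}

#' Read growth series from a delimited table
#'
#' Expects a header with columns `specimen_id`, `element`, `cgmc`,
#' `circumference_mm`, `measured`, `xpl_only`, `multiplet_group` (and
#' optionally `uid`, `double_lag`, `taxon_label`). Booleans are 0/1. One
#' series is built per (specimen_id, element) pair; records are sorted by
#' `cgmc` and the series invariants validated.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return list of [growth_series].
#' @export
read_series_table <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""),
                           fileEncoding = "UTF-8")
  need <- c("specimen_id", "element", "cgmc", "circumference_mm")
  if (!all(need %in% names(tab)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  if (!is.numeric(tab$circumference_mm))
    stop("non-numeric circumference at row ",
         which(!is.na(tab$circumference_mm) &
                 is.na(suppressWarnings(as.numeric(tab$circumference_mm))))[1])
  if (any(tab$circumference_mm <= 0, na.rm = TRUE))
    stop("non-positive circumference at row ",
         which(tab$circumference_mm <= 0)[1])
  if (is.null(tab$measured)) tab$measured <- !is.na(tab$circumference_mm)
  if (is.null(tab$xpl_only)) tab$xpl_only <- 0
  if (is.null(tab$multiplet_group)) tab$multiplet_group <- NA_character_
  if (is.null(tab$double_lag)) tab$double_lag <- 0
  if (is.null(tab$taxon_label)) tab$taxon_label <- ""
  key <- paste(tab$specimen_id, tab$element, sep = "\r")
  lapply(split(tab, factor(key, levels = unique(key))), function(d) {
    rec <- data.frame(cgmc = d$cgmc,
                      circumference = d$circumference_mm,
                      measured = as.logical(d$measured),
                      xpl_only = as.logical(d$xpl_only),
                      multiplet_group = as.character(d$multiplet_group),
                      double_lag = as.logical(d$double_lag),
                      stringsAsFactors = FALSE)
    if (!is.null(d$uid)) rec$uid <- d$uid
    growth_series(d$specimen_id[1], d$element[1], rec,
                  taxon_label = d$taxon_label[1])
  }) |> unname()
}

#' Write growth series to a delimited table
#'
#' Inverse of [read_series_table()]; round-trips valid tables.
#'
#' @param series list of [growth_series].
#' @param path file path.
#' @param dialect `"csv"` or `"tsv"`.
#' @export
write_series_table <- function(series, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  rows <- do.call(rbind, lapply(series, function(s) {
    r <- s$records
    data.frame(specimen_id = s$specimen_id, element = s$element,
               cgmc = r$cgmc, circumference_mm = r$circumference,
               measured = as.integer(r$measured),
               xpl_only = as.integer(r$xpl_only),
               multiplet_group = r$multiplet_group,
               double_lag = as.integer(r$double_lag),
               uid = r$uid, taxon_label = s$taxon_label,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

variant_labels <- c("A", "NoM", "NoX", "NoXM")

#' Derive a dataset variant from a growth series
#'
#' The four variants encode alternative histological readings of the marks:
#' `A` counts every mark as one annual hiatus; `NoM` collapses each multiplet
#' group to its single outermost member (one hiatus event per group); `NoX`
#' drops annuli visible only in cross-polarized light; `NoXM` applies both.
#' Dropped marks do not count as years: every retained mark's `cgmc` is
#' decremented by the number of dropped marks below it, so counted-unmeasured
#' gaps are preserved while variant-dropped marks vanish from the age axis.
#' Record uids are preserved.
#'
#' @param series a [growth_series].
#' @param variant one of `"A"`, `"NoM"`, `"NoX"`, `"NoXM"`.
#' @return a derived [growth_series].
#' @export
derive_variant <- function(series, variant) {
  if (!variant %in% variant_labels)
    stop("unknown variant label: ", variant)
  r <- series$records
  drop <- rep(FALSE, nrow(r))
  if (variant %in% c("NoX", "NoXM")) drop <- drop | r$xpl_only
  if (variant %in% c("NoM", "NoXM")) {
    keep_of_group <- function(idx) {
      # outermost member: largest circumference, i.e. the last by cgmc
      idx[length(idx)]
    }
    grp <- r$multiplet_group
    # XPL-flagged members are governed by the X rule alone: excluding them
    # here keeps the dropped-by-M and dropped-by-X sets disjoint, so the
    # variant set identities (A = NoM U NoX, NoXM = NoM n NoX) hold exactly
    grp[drop | r$xpl_only] <- NA
    for (g in unique(stats::na.omit(grp))) {
      idx <- which(!is.na(grp) & grp == g)
      if (length(idx) > 1) drop[setdiff(idx, keep_of_group(idx))] <- TRUE
    }
  }
  kept <- r[!drop, , drop = FALSE]
  shift <- vapply(kept$cgmc,
                  function(ci) sum(r$cgmc[drop] < ci), integer(1))
  kept$cgmc <- kept$cgmc - shift
  out <- series
  out$records <- kept
  rownames(out$records) <- NULL
  validate_growth_series(out)
  out
}

#' Pool growth series into a variant dataset
#'
#' Applies [derive_variant()] to every series and pools them. `n_points`
#' counts measured records only (counted-unmeasured marks contribute to the
#' age numbering, never to fitting objectives).
#'
#' @param series list of at least two [growth_series].
#' @param variant variant label.
#' @return object of class `variant_dataset`.
#' @export
pool_dataset <- function(series, variant = "A") {
  if (length(series) < 2)
    stop("composite fitting needs at least 2 series")
  derived <- lapply(series, derive_variant, variant = variant)
  structure(
    list(variant = variant, series = derived,
         n_points = sum(vapply(derived, function(s) sum(s$records$measured),
                               integer(1)))),
    class = "variant_dataset")
}

#' @export
print.variant_dataset <- function(x, ...) {
  cat(sprintf("<variant_dataset> %s: %d series, %d measured points\n",
              x$variant, length(x$series), x$n_points))
  invisible(x)
}

series_key <- function(s) paste(s$specimen_id, s$element, sep = ":")

dataset_uids <- function(dataset) {
  sort(unlist(lapply(dataset$series, function(s) s$records$uid)))
}

#' Build all four dataset variants and verify their set identities
#'
#' Derives A, NoM, NoX and NoXM from one source and checks, on record uids,
#' that A = NoM U NoX and NoXM = NoM n NoX. A violation indicates corrupt
#' flag annotations.
#'
#' @param series list of [growth_series].
#' @return named list of four `variant_dataset`s.
#' @export
variant_family <- function(series) {
  fam <- lapply(stats::setNames(variant_labels, variant_labels),
                function(v) pool_dataset(series, v))
  u <- lapply(fam, dataset_uids)
  if (!setequal(u$A, union(u$NoM, u$NoX)))
    stop("variant set identity violated: A != NoM U NoX")
  if (!setequal(u$NoXM, intersect(u$NoM, u$NoX)))
    stop("variant set identity violated: NoXM != NoM n NoX")
  fam
}
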