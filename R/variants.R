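#' Points shared between two dataset variants
#'
#' Intersection by record uid (uids are preserved under variant
#' derivation, so a mark keeps its identity even though its renumbered
#' `cgmc` differs between variants).
#'
#' @param variant_x,variant_y `variant_dataset`s derived from the same
#'   source series.
#' @return character vector of shared measured-point uids.
#' @export
shared_points <- function(variant_x, variant_y) {
  ux <- unlist(lapply(variant_x$series, function(s)
    s$records$uid[s$records$measured]))
  uy <- unlist(lapply(variant_y$series, function(s)
    s$records$uid[s$records$measured]))
  out <- intersect(ux, uy)
  if (!length(out))
    stop("variants share no points; are they derived from the same source?")
  sort(out)
}

#' AICc of a fitted model restricted to a point set
#'
#' Recomputes the residual sum of squares of an existing fit over a subset
#' of its points only - using the fit's own model, parameters and start
#' ages without refitting, each point's age being its renumbered count under
#' that fit's variant plus the fitted start - and scores it with `n` equal
#' to the subset size and the fit's own `k`. This is the "same-points AICc"
#' used to compare models fitted to nested dataset variants on an equal
#' footing.
#'
#' @param fit a `cgm_fit`.
#' @param uids uids of the points to keep; all must be fitted points.
#' @return AICc score.
#' @export
same_points_aicc <- function(fit, uids) {
  res <- fit$residuals
  missing <- setdiff(uids, res$uid)
  if (length(missing))
    stop("uid(s) not in fit: ", paste(utils::head(missing, 5), collapse = ", "))
  sub <- res[res$uid %in% uids, ]
  aicc(sum(sub$raw^2), nrow(sub), fit$k)
}

#' Same-points AICc dominance check across variants
#'
#' Evaluates, on same-points AICc values, the dominance conditions under
#' which the all-marks variant A is preferred: on the NoXM-shared points A
#' must score strictly best and the remaining variants must order
#' NoM < NoX < NoXM; on the NoM-shared points A must beat NoM; on the
#' NoX-shared points A must beat NoX.
#'
#' @param fits named list of `cgm_fit`s for variants `A`, `NoM`, `NoX`,
#'   `NoXM` derived from one source.
#' @return object of class `dominance_report`: per-scope same-points AICc
#'   tables, per-clause booleans and `all_met`.
#' @export
dominance_check <- function(fits) {
  stopifnot(all(variant_labels %in% names(fits)))
  ds <- lapply(fits, function(f) f$dataset)
  sp_noxm <- shared_points(ds$A, ds$NoXM)
  sp_nom <- shared_points(ds$A, ds$NoM)
  sp_nox <- shared_points(ds$A, ds$NoX)

  scope_noxm <- vapply(fits, same_points_aicc, numeric(1),
                       uids = sp_noxm)[variant_labels]
  scope_nom <- c(A = same_points_aicc(fits$A, sp_nom),
                 NoM = same_points_aicc(fits$NoM, sp_nom))
  scope_nox <- c(A = same_points_aicc(fits$A, sp_nox),
                 NoX = same_points_aicc(fits$NoX, sp_nox))

  conditions <- c(
    A_best_on_noxm_points = unname(
      scope_noxm["A"] < min(scope_noxm[c("NoM", "NoX", "NoXM")])),
    nom_beats_nox_on_noxm_points = unname(
      scope_noxm["NoM"] < scope_noxm["NoX"]),
    nox_beats_noxm_on_noxm_points = unname(
      scope_noxm["NoX"] < scope_noxm["NoXM"]),
    A_best_on_nom_points = unname(scope_nom["A"] < scope_nom["NoM"]),
    A_best_on_nox_points = unname(scope_nox["A"] < scope_nox["NoX"]))

  structure(
    list(scope_noxm = scope_noxm,
         delta_noxm = scope_noxm - min(scope_noxm),
         scope_nom = scope_nom, scope_nox = scope_nox,
         conditions_met = conditions,
         all_met = all(conditions)),
    class = "dominance_report")
}

#' @export
print.dominance_report <- function(x, ...) {
  cat("<dominance_report> same-points AICc (NoXM scope):\n")
  print(round(x$scope_noxm, 2))
  cat("conditions met:\n"); print(x$conditions_met)
  cat("all met:", x$all_met, "\n")
  invisible(x)
}

# Insert fictitious marks into one (flag-free) series. Each mark is placed
# in a uniformly chosen inter-mark interval of the measured records, with a
# circumference drawn uniformly between the bounding circumferences; all
# subsequent counts shift by one year per inserted mark. A fictitious
# multiplet member shares a group with the real mark bounding its interval
# on the outside, so the NoM collapse retains the real mark.
insert_fictitious_marks <- function(series, n_x, n_m) {
  total <- n_x + n_m
  if (total == 0) return(series)
  r0 <- series$records
  meas <- which(r0$measured)
  if (length(meas) < 2)
    stop("series ", series_key(series), " has fewer than 2 measured marks")
  flags <- sample(rep(c("x", "m"), c(n_x, n_m)))
  gap <- sample(length(meas) - 1, total, replace = TRUE)
  lo <- r0$circumference[meas[gap]]
  hi <- r0$circumference[meas[gap + 1]]
  circ <- stats::runif(total, lo, hi)

  key <- series_key(series)
  partner_uid <- r0$uid[meas[gap + 1]]
  grp <- ifelse(flags == "m", paste0("mcg<", partner_uid, ">"), NA)
  new <- data.frame(
    uid = sprintf("mc|%s|%s%03d", key, flags, seq_len(total)),
    cgmc = NA_integer_, circumference = circ, measured = TRUE,
    xpl_only = flags == "x", multiplet_group = grp, double_lag = FALSE,
    # sort position: between the bounding measured rows, ordered by size
    pos = meas[gap] + (circ - lo) / (hi - lo + 1e-12),
    stringsAsFactors = FALSE)
  # real partners join the group of their fictitious multiplet members
  for (i in which(flags == "m"))
    r0$multiplet_group[r0$uid == partner_uid[i]] <- grp[i]
  old <- cbind(r0, pos = seq_len(nrow(r0)))
  all <- rbind(old, new[, names(old)])
  all <- all[order(all$pos), ]
  fict <- is.na(all$cgmc)
  final <- integer(nrow(all))
  seen <- 0L
  for (i in seq_len(nrow(all))) {
    if (fict[i]) {
      final[i] <- final[i - 1] + 1L
      seen <- seen + 1L
    } else {
      final[i] <- all$cgmc[i] + seen
    }
  }
  all$cgmc <- final
  all$pos <- NULL
  rownames(all) <- NULL
  series$records <- all
  validate_growth_series(series)
  series
}

#' Monte Carlo null test for extraneous marks
#'
#' Tests the null hypothesis that the XPL-only and multiplet marks are
#' extraneous (non-annual) features. Each trial inserts fictitious marks
#' into the NoXM series - allocated across series proportionally to the
#' observed per-series flagged-mark counts, each placed in a uniformly
#' random inter-mark interval with circumference drawn uniformly between
#' the bounding measured circumferences, shifting subsequent counts by one
#' year - rebuilds all four variants, refits each, and runs
#' [dominance_check()]. The p-value is the fraction of trials meeting every
#' dominance condition.
#'
#' @param noxm_series list of [growth_series] representing the NoXM reading
#'   (no flags).
#' @param x_counts,m_counts named integer vectors (by series key) of
#'   fictitious XPL and multiplet marks per series; totals must be positive.
#' @param trials number of Monte Carlo trials (>= 100 for the headline
#'   analysis; smaller values are accepted for smoke use).
#' @param seed integer seed.
#' @param registry model registry used per trial (defaults to a single
#'   family; pass the full registry for selection per trial).
#' @param ... passed to [joint_fit()].
#' @return list with `count_met`, `trials`, `p_value` and the per-trial
#'   `all_met` logical vector.
#' @export
mc_null_test <- function(noxm_series, x_counts, m_counts, trials = 100L,
                         seed = 1L,
                         registry = model_registry("extreme_value3"), ...) {
  keys <- vapply(noxm_series, series_key, character(1))
  x_counts <- x_counts[keys]; m_counts <- m_counts[keys]
  x_counts[is.na(x_counts)] <- 0L; m_counts[is.na(m_counts)] <- 0L
  if (sum(x_counts) + sum(m_counts) == 0)
    stop("no fictitious marks requested (n_x + n_m = 0)")
  set.seed(seed)
  met <- logical(trials)
  for (tr in seq_len(trials)) {
    aug <- lapply(seq_along(noxm_series), function(i)
      insert_fictitious_marks(noxm_series[[i]], x_counts[i], m_counts[i]))
    ok <- tryCatch({
      fam <- variant_family(aug)
      fits <- lapply(fam, function(ds)
        select_model(ds, registry = registry, seed = seed, ...))
      dominance_check(fits)$all_met
    }, error = function(e) NA)
    met[tr] <- isTRUE(ok)
  }
  list(count_met = sum(met), trials = trials,
       p_value = sum(met) / trials, all_met = met)
}
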