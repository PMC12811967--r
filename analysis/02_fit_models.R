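#!/usr/bin/env Rscript
# Stage 2: derive the four dataset variants, cluster start ages, and select
# the best sigmoid per variant by AICc (joint fit of curve parameters and
# start ages). The outlier stays in for now; stage 4 screens it out.

suppressMessages(library(cgmgrowth))

series <- read_series_table(file.path("results", "data", "series.csv"))
dir.create(file.path("results", "fits"), recursive = TRUE,
           showWarnings = FALSE)

fam <- variant_family(series)
cat("variant point counts:",
    paste(sprintf("%s=%d", names(fam),
                  vapply(fam, function(d) d$n_points, integer(1))),
          collapse = " "), "\n")

registry <- model_registry(include_diagnostics = FALSE)
rankings <- list()
for (v in names(fam)) {
  cl <- cluster_starts(fam[[v]])
  fit <- select_model(fam[[v]], registry = registry, init = cl, seed = 1)
  rankings[[v]] <- cbind(variant = v, fit$ranking)
  utils::write.csv(fit$ranking,
                   file.path("results", "fits",
                             sprintf("ranking_%s.csv", v)),
                   row.names = FALSE)
  jsonlite::write_json(
    list(variant = v, model = fit$model, params = as.list(fit$params),
         starts = as.list(fit$starts), rss = fit$rss, n = fit$n,
         k = fit$k, aicc = fit$aicc),
    file.path("results", "fits", sprintf("best_%s.json", v)),
    auto_unbox = TRUE, digits = NA)
  q <- residual_quantiles(fit)
  cat(sprintf(
    "%s: best %s, AICc %.2f (n=%d, k=%d); 95%% residual band %.1f%%..%.1f%%\n",
    v, fit$model, fit$aicc, fit$n, fit$k,
    q$percent_residual[1], q$percent_residual[3]))
}
utils::write.csv(do.call(rbind, rankings),
                 file.path("results", "fits", "rankings_all.csv"),
                 row.names = FALSE)
cat("wrote per-variant rankings and best-fit summaries under results/fits\n")
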