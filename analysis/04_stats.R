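#!/usr/bin/env Rscript
# Compare conditions on the per-microtubule metrics with the gated
# nonparametric battery (normality gate -> Kruskal-Wallis -> Conover post
# hoc with Holm correction) and write the stats report.

suppressPackageStartupMessages(library(kymotility))

mt_all <- read.csv("results/metrics/per_mt_metrics_all.csv")
man_all <- do.call(rbind, lapply(c("ddh", "hk", "ddhk", "fhf"), function(p) {
  man <- read.csv(file.path("results/data", p, "manifest.csv"),
                  colClasses = "character")
  man$context_id <- paste(p, man$context_id, sep = ".")
  man
}))
cond <- man_all$condition[match(mt_all$context_id, man_all$context_id)]

report <- list()
for (metric in c("landing_rate_um_min", "event_freq_um_s",
                 "mean_run_length_nm", "mean_speed_nm_s")) {
  ok <- !is.na(mt_all[[metric]])
  groups <- split(mt_all[[metric]][ok], cond[ok])
  groups <- groups[vapply(groups, length, 1L) > 1]
  if (length(groups) < 2) next
  r <- compare_groups(groups, posthoc = "conover", adjust = "holm")
  report[[metric]] <- list(
    path = r$path,
    omnibus = if (is.null(r$omnibus)) NULL else
      list(H = r$omnibus$statistic, df = r$omnibus$df,
           p = r$omnibus$p_value),
    pairwise = r$pairwise)
  cat(sprintf("%s [%s]%s\n", metric, r$path,
              if (!is.null(r$omnibus))
                sprintf(" H=%.2f p=%.3g", r$omnibus$statistic,
                        r$omnibus$p_value) else ""))
  sig <- r$pairwise[r$pairwise$p_adjusted < 0.05, ]
  if (nrow(sig) > 0)
    cat(paste(sprintf("  %s vs %s: p_adj=%.3g", sig$group1, sig$group2,
                      sig$p_adjusted), collapse = "\n"), "\n")
}
dir.create("results/stats", recursive = TRUE, showWarnings = FALSE)
jsonlite::write_json(report, "results/stats/stats_report.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("stats report at results/stats/stats_report.json\n")
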