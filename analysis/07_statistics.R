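#!/usr/bin/env Rscript
# The statistical layer over the per-cell tables: Welch tests for the
# confinement contrasts, one-way ANOVA with Games-Howell post hoc
# comparisons across the immunostain conditions, and notched-boxplot
# summaries with 1.5 x IQR outlier flagging.

suppressMessages(library(confinemetry))

dir.create("results", showWarnings = FALSE)
wm <- read_table_tsv("results/fura_window_means.tsv")
rec <- read_table_tsv("results/immuno_records.tsv")
rec <- rec[!is.na(rec$cell), ]

perk <- split(rec$perk_mean, rec$condition)
gh <- anova_games_howell(perk)
cat(sprintf("pErk ANOVA: F = %.1f, p = %.2g\n", gh$anova$F, gh$anova$p))
for (i in seq_len(nrow(gh$pairwise)))
  cat(sprintf("  %-26s q = %6.2f  p = %.3g%s\n",
              gh$pairwise$comparison[i], gh$pairwise$statistic[i],
              gh$pairwise$p[i],
              if (gh$pairwise$significant[i]) " *" else ""))

welch <- rbind(
  welch_ttest(wm$area_post, wm$area_pre, "sectional area post vs pre"),
  welch_ttest(wm$ratio_post, wm$ratio_pre, "Ca2+ ratio post vs pre"),
  welch_ttest(perk$act_unconf, perk$rest_unconf,
              "pErk act vs rest (unconfined)"))
write_table_tsv(rbind(welch, gh$pairwise), "results/stats_tests.tsv")
write_table_tsv(gh$anova, "results/stats_anova.tsv")

summaries <- do.call(rbind, lapply(names(perk), function(cond) {
  s <- box_summary(perk[[cond]])
  data.frame(metric = "perk_mean", group = cond, n = s$n, mean = s$mean,
             sd = s$sd, median = s$median, q1 = s$q1, q3 = s$q3,
             notch_half_width = s$notch_half_width,
             n_outliers = length(s$outliers))
}))
write_table_tsv(summaries, "results/stats_box_summaries.tsv")
cat("wrote results/stats_tests.tsv, stats_anova.tsv, stats_box_summaries.tsv\n")
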