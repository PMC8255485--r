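#!/usr/bin/env Rscript
# The statistical battery over the scored cohort: subtype prevalence
# filter, log-CVS repeated-measures ANOVAs (condition x reward zone per
# task), between-subtype Kruskal-Wallis on dSVS, within-subtype
# Wilcoxon/Friedman tests, behavioral preference ANOVA with Bonferroni
# post hocs and indifference t tests. Reads the score tables written by
# 02_score.R; its outputs land beside them.

library(usvscore)

vocal <- reanalyze_scores("results/run", threshold = 2)

cat("Subtype filter at 2% of call frames:\n")
cat("  included:", paste(vocal$filter$included, collapse = ", "), "\n")
cat("  excluded:", paste(vocal$filter$excluded, collapse = ", "), "\n\n")

cat("log-CVS repeated-measures ANOVAs:\n")
print(as.data.frame(vocal$anova), digits = 3)

if (!is.null(vocal$between_subtype)) {
  cat("\nBetween-subtype Kruskal-Wallis on dSVS (per condition):\n")
  print(as.data.frame(vocal$between_subtype), digits = 3)
}
if (!is.null(vocal$within_subtype)) {
  cat("\nWithin-subtype tests across conditions:\n")
  print(as.data.frame(vocal$within_subtype), digits = 3)
}

# behavioral battery straight from the saved zone scores
zs <- read_scores_table("results/run/zone_scores.csv")
sv <- read_scores_table("results/run/svs.csv")
pooled <- tapply(sv$frames, sv$subtype, sum)
scored <- list(zone_scores = zs, svs = sv,
               pooled_counts = stats::setNames(as.numeric(pooled),
                                               names(pooled)))
behav <- run_behavior_stats(scored)
cat("\nSSPT juvenile preference ANOVA:\n")
print(as.data.frame(behav$anova), digits = 3)
cat("\nPreference vs indifference (50%):\n")
print(as.data.frame(behav$vs_indifference), digits = 3)

for (nm in c("anova", "between_subtype", "within_subtype")) {
  if (!is.null(vocal[[nm]]))
    write_scores_table(vocal[[nm]],
                       file.path("results", paste0("stats_", nm,
                                                   ".csv")))
}
cat("\nStats tables written under results/\n")
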