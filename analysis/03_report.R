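#!/usr/bin/env Rscript
# Step 3: summarize the group statistics.
#
# Reads results/analysis/stats.tsv, prints the significant findings and
# trends per feature family, checks that the planted effects were recovered,
# and writes a compact results/summary.tsv.

stats_path <- "results/analysis/stats.tsv"
if (!file.exists(stats_path))
  stop("run analysis/02_analyze.R first (missing ", stats_path, ")")
res <- read.delim(stats_path)

fmt <- function(df) {
  if (nrow(df) == 0) return("  (none)")
  paste0(sprintf("  %-10s %-28s %-12s Z = %7.4f  p = %.4f  |r| = %.4f",
                 df$feature_kind, df$region_or_pair, df$band,
                 df$Z, df$p, df$abs_r), collapse = "\n")
}

sig <- res[res$significant %in% TRUE, ]
tr <- res[res$trend %in% TRUE, ]
cat("== significant pre/post differences (p < 0.05) ==\n")
for (k in c("power", "coherence", "entropy")) {
  cat(fmt(sig[sig$feature_kind == k, ]), "\n")
}
ncfc <- sum(sig$feature_kind == "cfc")
cat(sprintf("  cfc: %d significant comodulogram cells across %d region pairs\n",
            ncfc, length(unique(sig$region_or_pair[sig$feature_kind == "cfc"]))))
cat("\n== trends (0.05 <= p < 0.10) ==\n")
cat(sprintf("  %d features, %d of them cfc cells\n",
            nrow(tr), sum(tr$feature_kind == "cfc")))

planted <- rbind(
  res[res$feature_kind == "power" & res$region_or_pair == "occipital" &
        res$band == "beta_gamma", ],
  res[res$feature_kind == "coherence" & res$region_or_pair == "temporal" &
        res$band == "alpha", ],
  res[res$feature_kind == "cfc" & res$region_or_pair == "fronto_polar" &
        res$band == "6:60", ])
cat("\n== planted effects ==\n")
cat(fmt(planted), "\n")
cat(sprintf("recovered %d of %d planted effects as significant\n",
            sum(planted$significant), nrow(planted)))

out <- res[res$significant %in% TRUE | res$trend %in% TRUE,
           c("feature_kind", "region_or_pair", "band", "n", "W", "Z", "p",
             "abs_r", "significant", "trend")]
write.table(out[order(out$p), ], "results/summary.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("summary written: results/summary.tsv\n")
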