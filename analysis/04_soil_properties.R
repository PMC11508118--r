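#!/usr/bin/env Rscript
# Soil-horizon analyses: texture vs chemistry correlation matrix over the
# complete-chemistry horizons, and a recomputation check of the base
# saturation (BS) and effective base saturation (EBS) columns from the
# exchangeable cations.

suppressPackageStartupMessages(library(inundr))
dir.create("results", showWarnings = FALSE)

h <- load_soil_horizons()
pearson <- texture_correlations(h, method = "pearson")
rank_based <- texture_correlations(h, method = "spearman")
write.csv(round(pearson, 3), "results/texture_correlations_pearson.csv")
write.csv(round(rank_based, 3), "results/texture_correlations_spearman.csv")

rep <- run_full_analysis()
write.csv(rep$saturation_check, "results/saturation_check.csv",
          row.names = FALSE)

cat("Texture correlations on the", attr(pearson, "n"),
    "complete-chemistry horizons (product-moment):\n")
print(round(pearson[c("sand", "silt", "clay", "cec", "exch_ca", "bray2_p"), ], 2))
cat("\nNote: the published matrix is reproduced by the product-moment\nmethod; rank correlation gives e.g. sand-clay",
    round(rank_based["clay", "sand"], 2), "instead of",
    paste0(round(pearson["clay", "sand"], 2), ".\n"))
dev <- abs(rep$saturation_check$ebs_recomputed - rep$saturation_check$ebs_published)
cat(sprintf("EBS recomputation: max |deviation| %.1f%% over %d horizons (printed-input rounding).\n",
            max(dev), nrow(rep$saturation_check)))
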