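#!/usr/bin/env Rscript

# Step 2 -- classical tissue detection baseline.
#
# Segments every evaluation slide with the uniform Otsu + morphology preset
# and measures pixel-wise sensitivity and precision against ground truth.
# The expected picture: high sensitivity on clearly stained slides,
# detection failures on the luminance-matched pale slides, and precision
# penalties on pen-marked slides.

library(tissuedetect)

dir.create("results", showWarnings = FALSE)
man <- read_cohort_manifest("results/cohort_manifest.csv")

metrics <- evaluate_segmenter(man, threshold_segmenter(), role = "eval")
write.csv(metrics, "results/threshold_metrics.csv", row.names = FALSE)

plain <- metrics$color_profile == "normal" & metrics$artifacts == ""
pale <- metrics$color_profile == "pale"
cat(sprintf("Evaluation slides: %d\n", nrow(metrics)))
cat(sprintf("  mean sensitivity (normal, artifact-free): %.4f over %d slides\n",
            mean(metrics$sensitivity[plain]), sum(plain)))
cat(sprintf("  mean precision (where defined): %.4f\n",
            mean(metrics$precision, na.rm = TRUE)))
cat(sprintf("  detection failures: %d (all pale: %s)\n",
            sum(metrics$failure),
            all(metrics$failure == pale)))

by_group <- aggregate(cbind(sensitivity, precision) ~ color_profile + artifacts,
                      metrics, mean, na.action = na.omit)
print(by_group)
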