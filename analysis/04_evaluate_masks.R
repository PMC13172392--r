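#!/usr/bin/env Rscript

# Step 4 -- head-to-head mask quality.
#
# Evaluates the trained network and the thresholding baseline on the same
# evaluation slides, tabulates pixel metrics side by side, and applies the
# sensitivity-under-a-precision-floor model selection rule to the
# candidate segmenters.

library(tissuedetect)

dir.create("results", showWarnings = FALSE)
man <- read_cohort_manifest("results/cohort_manifest.csv")
ck <- load_checkpoint("scratch/segmenter_checkpoint.rds")

learned <- evaluate_segmenter(man, learned_segmenter(ck, overlap = 32L))
thr <- evaluate_segmenter(man, threshold_segmenter())

both <- rbind(cbind(method = "learned", learned),
              cbind(method = "threshold", thr))
write.csv(both, "results/segmentation_metrics.csv", row.names = FALSE)

summarize <- function(m) c(sensitivity = mean(m$sensitivity),
                           precision = mean(m$precision, na.rm = TRUE),
                           failures = sum(m$failure))
cat("learned:   "); print(round(summarize(learned), 4))
cat("threshold: "); print(round(summarize(thr), 4))

# model selection over the two candidates: best sensitivity subject to
# precision >= 0.90
cands <- list(c(mean(learned$sensitivity), mean(learned$precision, na.rm = TRUE)),
              c(mean(thr$sensitivity), mean(thr$precision, na.rm = TRUE)))
sel <- tryCatch(select_best_model(cands),
                no_qualifying_model = function(e) NA_integer_)
cat(sprintf("Selected segmenter: %s\n",
            if (is.na(sel)) "none qualifies" else c("learned", "threshold")[sel]))
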