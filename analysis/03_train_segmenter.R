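#!/usr/bin/env Rscript

# Step 3 -- train the desk-scale segmentation network.
#
# Trains the encoder-decoder on the cohort's training block (weighted
# binary cross entropy, AdamW, cosine-annealed learning rate) with early
# stopping on validation F1, then stores the checkpoint and the per-epoch
# training log.

library(tissuedetect)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)
man <- read_cohort_manifest("results/cohort_manifest.csv")

t0 <- Sys.time()
ck <- train_standard_segmenter(man, seed = seed)
cat(sprintf("Trained in %.0f s; best validation F1 %.4f at epoch %d\n",
            as.numeric(difftime(Sys.time(), t0, units = "secs")),
            ck$val_f1, ck$epoch))

save_checkpoint(ck, "scratch/segmenter_checkpoint.rds")
write.csv(ck$log, "results/training_log.csv", row.names = FALSE)
write_provenance("results/03_provenance.json",
                 config = unclass(ck$config), seed = seed)
cat("Checkpoint in scratch/segmenter_checkpoint.rds; log in results/training_log.csv\n")
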