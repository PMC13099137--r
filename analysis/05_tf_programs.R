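#!/usr/bin/env Rscript
# Evaluate the TF activity classification: which planted activators and
# repressors were selected and classed correctly from the full pipeline
# run, and a metacell-level benchmark of classification accuracy and null
# behavior.

suppressPackageStartupMessages(library(comap))

out <- "results/05_tf_programs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
res <- readRDS("scratch/pipeline_cache.rds")
truth <- simulate_dataset(res$config$sim)$truth

if (!is.null(res$tf)) {
  m <- merge(res$tf, truth$tf_classes, by = "tf_id")
  write.table(m, file.path(out, "tf_classification_vs_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sel <- m[m$selected & m$activity != "null", ]
  cat(sprintf("Pipeline TF stage: %d/%d TFs selected at padj < 0.01;\n",
              sum(m$selected), nrow(m)))
  if (nrow(sel))
    cat(sprintf(" activity class correct for %.0f%% of selected planted TFs.\n",
                100 * mean(sel$activity_class == sel$activity)))
  cat(sprintf(" %d null TFs selected; %d TFs at test R2 > 0.6.\n",
              sum(m$selected[m$activity == "null"]),
              sum(m$high_accuracy, na.rm = TRUE)))
}

## metacell-level benchmark (independent of the pipeline run)
d <- simulate_tf_metacells(n_metacells = 120, n_act = 8, n_rep = 8,
                           n_null = 4, seed = 21)
bench <- tf_program_analysis(d$shared, d$responses, d$tf_features,
                             n_perm = 200, seed = 21, padj_max = 0.01)
mb <- merge(bench, d$truth, by = "tf_id")
write.table(mb, file.path(out, "tf_benchmark.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
selb <- mb[mb$selected & mb$activity != "null", ]
cat(sprintf(
  "Benchmark: %d selected, activity accuracy %.0f%%, %d nulls selected.\n",
  sum(mb$selected),
  if (nrow(selb)) 100 * mean(selb$activity_class == selb$activity) else 0,
  sum(mb$selected[mb$activity == "null"])))
regb <- mb[mb$selected & !is.na(mb$regulation) &
             mb$regulation == "regulated", ]
if (nrow(regb))
  cat(sprintf(
    "Chromatin-regulated TFs recovered as regulated: %.0f%% of %d.\n",
    100 * mean(regb$regulation_class == "regulated"), nrow(regb)))
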