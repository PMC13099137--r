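#!/usr/bin/env Rscript
# Characterize the domain calls from the pooled pseudo-bulk tracks: class
# composition (promoter / genic / gene-covering / intergenic), the
# partition of regions between the two marks, and the caller's
# recall/precision on an independent planted track.

suppressPackageStartupMessages(library(comap))

out <- "results/04_domains"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
res <- readRDS("scratch/pipeline_cache.rds")

for (mk in c("k27", "k4")) {
  dom <- res[[paste0("domains_", mk)]]
  tab <- as.data.frame(table(class = dom$class, source = dom$source))
  write.table(tab, file.path(out, paste0("domain_classes_", mk, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
part <- as.data.frame(table(res$mark_partition$partition))
names(part) <- c("partition", "n")
write.table(part, file.path(out, "mark_partition.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("H3K27me3: %d calls (%d subpeaks); H3K4me1: %d calls.\n",
            nrow(res$domains_k27),
            sum(res$domains_k27$source == "subpeak"),
            nrow(res$domains_k4)))
cat("Mark partition:\n")
print(part, row.names = FALSE)

## planted-track benchmark
tr <- simulate_domain_track(n_bins = 50000, background = 2,
                            n_plants = 100, plant_bins = 20, fold = 10,
                            seed = 11)
d <- call_domains(tr$counts, domain_params(bin_size = 750))
called <- rep(FALSE, 50000); planted <- rep(FALSE, 50000)
for (i in seq_len(nrow(d))) called[d$first_bin[i]:d$last_bin[i]] <- TRUE
for (i in seq_len(nrow(tr$plants)))
  planted[tr$plants$first_bin[i]:tr$plants$last_bin[i]] <- TRUE
recall <- mean(vapply(seq_len(nrow(tr$plants)), function(i)
  mean(called[tr$plants$first_bin[i]:tr$plants$last_bin[i]]) >= 0.5,
  logical(1)))
precision <- mean(vapply(seq_len(nrow(d)), function(i)
  mean(planted[d$first_bin[i]:d$last_bin[i]]) >= 0.5, logical(1)))
bench <- data.frame(n_plants = 100, fold = 10, recall = recall,
                    precision = precision, n_calls = nrow(d))
write.table(bench, file.path(out, "caller_benchmark.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf(
  "Planted-track benchmark: recall %.2f, precision %.2f over 100 plants.\n",
  recall, precision))
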