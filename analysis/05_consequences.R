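#!/usr/bin/env Rscript
# Stage 5: protein-level consequences of multi-exon skip events.
#
# For every observed skip of two or more exons: coding nucleotides removed,
# reading-frame status, premature termination codon in the mutant frame, and
# per-domain none/partial/total loss mapped back onto the annotated protein.

suppressMessages({library(ejcsplice); library(data.table)})

chains <- reference_chains("results/dataset/annotation.gtf")
files <- list.files("results/dataset/junctions", full.names = TRUE)
jn <- rbindlist(lapply(files, function(f) {
  sid <- sub("\\.junctions\\.tsv$", "", basename(f))
  load_junctions(f, "bed", sample_id = sid,
                 condition = if (startsWith(sid, "kd")) "kd" else "control",
                 chains = chains)
}))
events <- unique(tabulate_skip_events(jn, chains)[
  k_skipped >= 2L, .(gene_id, upstream_exon, downstream_exon)])

cds <- Biostrings::readDNAStringSet("results/dataset/cds.fa")
cds <- setNames(as.character(cds), sub("\\s.*$", "", names(cds)))
domains <- fread("results/dataset/domains.tsv")

cons <- classify_consequences(events, chains, cds, domains)
fwrite(cons, "results/consequences.tsv", sep = "\t")

per_event <- unique(cons[, .(gene_id, skipped, frame, ptc = !is.na(ptc_codon))])
cat(sprintf("classified %d multi-exon skip events\n", nrow(per_event)))
print(per_event[, .N, by = .(frame, ptc)])
dom <- cons[!is.na(effect), .N, by = effect]
cat("domain impact calls:\n"); print(dom)
altered <- unique(cons[frame != "none" | (!is.na(effect) & effect != "none"),
                       .(gene_id, skipped)])
cat(sprintf("%.0f%% of events alter the protein (frameshift, PTC or domain loss)\n",
            100 * nrow(altered) / max(1, nrow(per_event))))
cat("table written to results/consequences.tsv\n")
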