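#!/usr/bin/env Rscript
# Stage 2: skipped-exon (SE) event calling.
#
# Reads the simulated per-sample junction files back from disk (exercising
# the same loaders a real STAR SJ.out.tab analysis would use), classifies
# every junction against the reference exon chains, computes per-condition
# PSI for each internal exon, and applies the |dPSI| > 0.2 / FDR < 0.01
# significance gates.

suppressMessages({library(ejcsplice); library(data.table)})

chains <- reference_chains("results/dataset/annotation.gtf")
files <- list.files("results/dataset/junctions", full.names = TRUE)
jn <- rbindlist(lapply(files, function(f) {
  sid <- sub("\\.junctions\\.tsv$", "", basename(f))
  load_junctions(f, "bed", sample_id = sid,
                 condition = if (startsWith(sid, "kd")) "kd" else "control",
                 chains = chains)
}))

calls <- call_se_events(jn, chains, dpsi_min = 0.2, fdr_max = 0.01)
fwrite(calls, "results/se_calls.tsv", sep = "\t")

cat(sprintf("tested %d internal exons in %d genes\n",
            nrow(calls), uniqueN(calls$gene_id)))
cat(sprintf("significant SE events (|dPSI| > 0.2, FDR < 0.01): %d\n",
            sum(calls$significant)))
if (sum(calls$significant) == 0) {
  cat("note: under the modest knockdown multipliers of this dataset the true\n")
  cat("dPSI stays below the 0.2 gate, so zero calls is the expected outcome\n")
} else {
  cat(sprintf("median dPSI among significant events: %.3f\n",
              median(calls[significant == TRUE, delta_psi])))
}
cat("table written to results/se_calls.tsv\n")

# high-contrast companion run: exons engineered to PSI 0.9 (control) vs 0.3
# (knockdown) at depth 200/condition demonstrate both gates firing
cfg_hi <- sim_config(seed = 102, n_genes = 80, exon_count_range = c(3L, 3L),
                     depth_per_gene = 200, replicates_per_condition = 1L,
                     base_skip_rate = 1 / 18, kd_multiplier = 21,
                     fraction_affected_genes = 0.5)
sim_hi <- simulate_gene_models(cfg_hi)
jn_hi <- simulate_junction_reads(sim_hi$chains, sim_hi$truth, cfg_hi)
calls_hi <- call_se_events(jn_hi, sim_hi$chains)
fwrite(calls_hi, "results/se_calls_highcontrast.tsv", sep = "\t")
cat(sprintf("high-contrast run: %d/%d exons significant (true dPSI -0.6), %d unaffected exons called\n",
            sum(calls_hi$significant), sum(sim_hi$truth$affected),
            nrow(calls_hi[significant == TRUE][
              !gene_id %in% sim_hi$truth[affected == TRUE, gene_id]])))
cat("table written to results/se_calls_highcontrast.tsv\n")
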