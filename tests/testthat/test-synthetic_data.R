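test_that("every simulated artifact is a pure function of the configuration", {
  cfg <- sim_config(seed = 7, n_genes = 10, exon_count_range = c(4L, 8L))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_dataset(cfg, d1)
  s2 <- simulate_dataset(cfg, d2)
  expect_identical(readLines(s1$paths$gtf), readLines(s2$paths$gtf))
  expect_identical(readLines(s1$paths$occupancy), readLines(s2$paths$occupancy))
  expect_identical(readLines(s1$paths$cds), readLines(s2$paths$cds))
  for (p in seq_along(s1$paths$junctions)) {
    expect_identical(readLines(s1$paths$junctions[p]), readLines(s2$paths$junctions[p]))
  }
  expect_identical(s1$truth, s2$truth)
})

test_that("generated GTF re-parses into the chains returned directly", {
  cfg <- sim_config(seed = 3, n_genes = 12)
  sim <- simulate_gene_models(cfg)
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(sim$models, gtf)
  reparsed <- reference_chains(gtf, eligible_only = FALSE)
  expect_setequal(names(reparsed), names(sim$chains))
  for (g in names(sim$chains)) {
    expect_equal(as.data.frame(reparsed[[g]]$exons), as.data.frame(sim$chains[[g]]$exons),
                 info = g)
    expect_equal(reparsed[[g]]$cds_start, sim$chains[[g]]$cds_start)
    expect_equal(reparsed[[g]]$cds_end, sim$chains[[g]]$cds_end)
    expect_equal(reparsed[[g]]$strand, sim$chains[[g]]$strand)
  }
})

test_that("structural knobs behave: minimum exon counts and degenerate ranges", {
  sim <- simulate_gene_models(sim_config(seed = 1, n_genes = 8,
                                         exon_count_range = c(3L, 3L)))
  expect_true(all(vapply(sim$chains, `[[`, FALSE, "eligible")))
  expect_error(sim_config(exon_count_range = c(8L, 4L)), "degenerate")
  expect_error(sim_config(exon_count_range = c(2L, 2L)), ">= 3")
  expect_error(sim_config(base_skip_rate = c(0.1, 2)), "base_skip_rate")
})

test_that("ground truth is recoverable from the emitted junction files", {
  cfg <- sim_config(seed = 19, n_genes = 10, fraction_affected_genes = 1,
                    depth_per_gene = 5000)
  sim <- simulate_gene_models(cfg)
  jn <- simulate_junction_reads(sim$chains, sim$truth, cfg)
  dir <- withr::local_tempdir()
  write_junction_files(jn, dir, "bed")
  reread <- data.table::rbindlist(lapply(unique(jn$sample_id), function(sid) {
    load_junctions(file.path(dir, paste0(sid, ".junctions.tsv")), "bed",
                   sample_id = sid,
                   condition = unique(jn[sample_id == sid, condition]),
                   chains = sim$chains)
  }))
  ev <- tabulate_skip_events(reread, sim$chains)
  # every affected gene's designated event is observed at the right junction
  tr <- sim$truth[affected == TRUE]
  found <- merge(tr, unique(ev[, .(gene_id, upstream_exon, downstream_exon)]),
                 by = c("gene_id", "upstream_exon", "downstream_exon"))
  expect_equal(nrow(found), nrow(tr))
  # counts recover the configured rates within Poisson error (pooled reps)
  pooled <- ev[, .(n = sum(read_count)), by = .(gene_id, k_skipped, condition)]
  chk <- merge(pooled, tr[, .(gene_id, k = k)], by = "gene_id")
  chk[, expected := cfg$depth_per_gene * cfg$replicates_per_condition *
        cfg$base_skip_rate[k] * ifelse(condition == "kd", cfg$kd_multiplier[k], 1)]
  expect_true(all(abs(chk$n - chk$expected) < 5 * sqrt(chk$expected) + 5))
})

test_that("null skip simulation recovers unit ratios and kd multipliers recover theirs", {
  # kd multiplier 1 for all k: per-k median ratio ~ 1 at high depth
  cfg1 <- sim_config(seed = 23, n_genes = 30, depth_per_gene = 1e4,
                     fraction_affected_genes = 1,
                     base_skip_rate = c(0.01, 0.01), kd_multiplier = c(1, 1))
  sim <- simulate_gene_models(cfg1)
  jn <- simulate_junction_reads(sim$chains, sim$truth, cfg1)
  ev <- tabulate_skip_events(jn, sim$chains)
  totals <- jn[, .(t = sum(read_count)), by = sample_id]
  prof <- skip_read_ratio_profile(ev, stats::setNames(totals$t, totals$sample_id))
  expect_true(all(abs(prof$median_ratio - 1) <= 0.1))
})

test_that("occupancy simulation enriches exactly the designated upstream exons", {
  cfg <- sim_config(seed = 29, n_genes = 400, fraction_affected_genes = 0.5,
                    enrichment_gamma = 4, silent_gene_fraction = 0,
                    occ_dispersion = 5)
  sim <- simulate_gene_models(cfg)
  occ <- simulate_occupancy(sim$chains, sim$truth, cfg)
  occ[, crosslink := crosslink_1 + crosslink_2]
  tr <- sim$truth
  enriched <- merge(occ, tr[affected == TRUE, .(gene_id, exon_index = enriched_exon)],
                    by = c("gene_id", "exon_index"))
  baseline <- occ[!paste(gene_id, exon_index) %in%
                    paste(enriched$gene_id, enriched$exon_index)]
  expect_gt(mean(enriched$crosslink) / mean(baseline$crosslink), 2.5)
  expect_lt(abs(mean(baseline$crosslink) - cfg$occ_mean), 2)
})

test_that("silent genes are exactly the ones dropped by the occupancy loader", {
  cfg <- sim_config(seed = 31, n_genes = 40, silent_gene_fraction = 0.3)
  sim <- simulate_gene_models(cfg)
  occ <- simulate_occupancy(sim$chains, sim$truth, cfg)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_occupancy_tsv(occ, f)
  loaded <- load_occupancy(f, sim$chains)
  silent <- occ[, .(silent = all(rnaseq_1 + rnaseq_2 == 0)), by = gene_id]
  expect_setequal(unique(loaded$gene_id), silent[silent == FALSE, gene_id])
  expect_gt(sum(silent$silent), 0)
})

test_that("constructed CDS/domain fixtures match their emitted expectations end-to-end", {
  for (seed in c(41, 42)) {
    cfg <- sim_config(seed = seed, n_genes = 30, fraction_affected_genes = 1)
    sim <- simulate_gene_models(cfg)
    cd <- simulate_cds_and_domains(sim$chains, sim$truth, cfg)
    expect_gt(nrow(cd$expected), 0)
    ev <- unique(cd$expected[, .(gene_id, upstream_exon, downstream_exon)])
    calls <- classify_consequences(ev, sim$chains, cd$cds, cd$domains)
    got <- merge(cd$expected,
                 calls[, .(gene_id, domain_name, got_frame = frame,
                           got_ptc = ptc_codon, got_effect = effect,
                           got_nt = skipped_cds_nt)],
                 by = c("gene_id", "domain_name"))
    expect_equal(nrow(got), nrow(cd$expected))
    expect_equal(got$got_frame, got$frame)
    expect_equal(got$got_nt, got$skipped_cds_nt)
    expect_equal(got$got_effect, got$effect)
    expect_equal(got$got_ptc, got$ptc_codon)
    # both frame classes are exercised
    expect_setequal(unique(cd$expected$frame), c("in_frame", "frameshift"))
  }
})

test_that("the synthetic paralog pair has the documented divergence structure", {
  p <- simulate_paralog_pair()
  expect_identical(p, simulate_paralog_pair())
  aa_a <- strsplit(p$protein_a, "")[[1]]
  aa_b <- strsplit(p$protein_b, "")[[1]]
  expect_length(aa_a, 146L)
  expect_equal(which(aa_a != aa_b), c(1L, 2L))
  # CDSs translate to their proteins
  expect_equal(sub("\\*$", "", as.character(Biostrings::translate(Biostrings::DNAString(p$cds_a)))),
               p$protein_a)
  expect_equal(sub("\\*$", "", as.character(Biostrings::translate(Biostrings::DNAString(p$cds_b)))),
               p$protein_b)
  # shipped fixtures are exactly the generator output
  pf <- system.file("extdata", "synthetic_magoh_paralogs_protein.fa", package = "ejcsplice")
  cf <- system.file("extdata", "synthetic_magoh_paralogs_cds.fa", package = "ejcsplice")
  prot <- Biostrings::readAAStringSet(pf)
  cds <- Biostrings::readDNAStringSet(cf)
  expect_equal(as.character(prot[[1]]), p$protein_a)
  expect_equal(as.character(prot[[2]]), p$protein_b)
  expect_equal(as.character(cds[[1]]), p$cds_a)
  expect_equal(as.character(cds[[2]]), p$cds_b)
})

test_that("the pipeline wrapper writes a complete, digest-stamped report", {
  dir <- withr::local_tempdir()
  res <- run_pipeline(sim_config(seed = 2, n_genes = 15), out_dir = dir,
                      B = 500, seed = 1)
  rep <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_true(all(vapply(rep$outputs, function(o) file.exists(o$path), FALSE)))
  expect_true(all(vapply(rep$outputs, function(o) nchar(o$md5) == 32, FALSE)))
  expect_equal(rep$stage_counts$ejc_offsets, 2L)
  # re-running with the same config reproduces identical outputs
  dir2 <- withr::local_tempdir()
  res2 <- run_pipeline(sim_config(seed = 2, n_genes = 15), out_dir = dir2,
                       B = 500, seed = 1)
  for (nm in names(rep$outputs)) {
    expect_equal(unname(tools::md5sum(file.path(dir2, basename(rep$outputs[[nm]]$path)))),
                 rep$outputs[[nm]]$md5)
  }
})
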