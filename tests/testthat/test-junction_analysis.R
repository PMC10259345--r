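# chain used throughout: 6 exons, plus strand
chain6 <- make_chain("G6", "+", seq(0, 2500, by = 500), seq(100, 2600, by = 500))

test_that("SJ-style and 4-column junction dialects load equivalently", {
  # junction joining exon 2 (end 600) to exon 3 (start 1000), 0-based half-open
  sj <- withr::local_tempfile(fileext = ".tab")
  writeLines(c("chr1\t601\t1000\t1\t1\t0\t12\t3\t20",
               "chr1\t1101\t1500\t1\t1\t0\t7\t0\t20",
               "chr1\t601\t2000\t1\t1\t0\t5\t0\t20"), sj)
  bed <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t600\t1000\t12", "chr1\t1100\t1500\t7", "chr1\t600\t2000\t5"), bed)
  a <- load_junctions(sj, "sj_tab", sample_id = "s1", condition = "control")
  b <- load_junctions(bed, "bed", sample_id = "s1", condition = "control")
  expect_equal(nrow(a), 3L)
  expect_equal(a$read_count, c(12L, 7L, 5L))
  expect_equal(a[, .(chrom, donor_end, acceptor_start, read_count)],
               b[, .(chrom, donor_end, acceptor_start, read_count)])
})

test_that("zero-read records are dropped and invalid junctions rejected", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t600\t1000\t4", "chr1\t1100\t1500\t0"), f)
  expect_equal(nrow(load_junctions(f, "bed", sample_id = "s", condition = "kd")), 1L)
  bad <- withr::local_tempfile()
  writeLines("chr1\t1000\t600\t4", bad)
  expect_error(load_junctions(bad, "bed", sample_id = "s", condition = "kd"),
               "acceptor <= donor")
})

test_that("strand is inferred from the annotation when unknown", {
  f <- withr::local_tempfile()
  writeLines("chr1\t100\t500\t4", f)  # exon1 end -> exon2 start of chain6
  j <- load_junctions(f, "bed", sample_id = "s", condition = "control",
                      chains = list(chain6))
  expect_equal(j$strand, "+")
  g <- withr::local_tempfile()
  writeLines("chrZ\t100\t500\t4", g)
  expect_warning(load_junctions(g, "bed", sample_id = "s", condition = "control",
                                chains = list(chain6)), "chrZ")
})

test_that("junction classification handles adjacency, skips and mismatches", {
  # canonical: exon 2 end (600) -> exon 3 start (1000)
  j <- list(chrom = "chr1", donor_end = 600, acceptor_start = 1000, strand = "+")
  expect_equal(classify_junction(j, chain6),
               list(kind = "canonical", k_skipped = 0L,
                    upstream_exon = 2L, downstream_exon = 3L))
  # skip of exons 3,4: exon 2 end -> exon 5 start (2000)
  j$acceptor_start <- 2000
  cl <- classify_junction(j, chain6)
  expect_equal(cl$kind, "skip")
  expect_equal(cl$k_skipped, 2L)
  expect_equal(skipped_exons(cl$upstream_exon, cl$downstream_exon), c(3L, 4L))
  # boundary inside an exon body -> unannotated
  j$donor_end <- 580
  expect_equal(classify_junction(j, chain6)$kind, "unannotated")
  expect_error(classify_junction(list(chrom = "chr2", donor_end = 600,
                                      acceptor_start = 1000), chain6),
               "chromosome mismatch")
  expect_error(classify_junction(list(chrom = "chr1", donor_end = 600,
                                      acceptor_start = 1000, strand = "-"), chain6),
               "strand mismatch")
})

test_that("minus-strand junctions resolve donor/acceptor in transcript orientation", {
  # 6 exons on minus strand: transcript exon 1 is genomically last
  chm <- make_chain("GM", "-", seq(0, 2500, by = 500), seq(100, 2600, by = 500))
  # junction joining transcript exons 2 and 5 (skip of exons 3,4)
  co <- junction_pair_coords(chm, 2, 5)
  cl <- classify_junction(list(chrom = "chr1", donor_end = co[["donor_end"]],
                               acceptor_start = co[["acceptor_start"]],
                               strand = "-"), chm)
  expect_equal(cl[c("kind", "k_skipped", "upstream_exon", "downstream_exon")],
               list(kind = "skip", k_skipped = 2L, upstream_exon = 2L,
                    downstream_exon = 5L))
})

test_that("classification agrees with the brute-force boundary matcher", {
  set.seed(11)
  for (i in 1:300) {
    ch <- random_chain()
    n <- ch$n_exons
    kind <- sample(c("pair", "perturbed"), 1)
    u <- sample(n - 1, 1); d <- sample((u + 1):n, 1)
    co <- junction_pair_coords(ch, u, d)
    if (kind == "perturbed") co <- co + sample(c(-3:-1, 1:3), 2, replace = TRUE)
    if (co[["donor_end"]] >= co[["acceptor_start"]]) next
    j <- list(chrom = ch$chrom, donor_end = co[["donor_end"]],
              acceptor_start = co[["acceptor_start"]], strand = ch$strand)
    expect_equal(classify_junction(j, ch), bf_classify(j, ch))
  }
})

test_that("skip events are tabulated with zero-filled samples", {
  co35 <- junction_pair_coords(chain6, 3, 5)
  co14 <- junction_pair_coords(chain6, 1, 4)
  jn <- make_junctions(chain6, list(
    s1 = list(condition = "control",
              tab = data.frame(donor_end = co35[["donor_end"]],
                               acceptor_start = co35[["acceptor_start"]], n = 5)),
    s2 = list(condition = "kd",
              tab = data.frame(donor_end = c(co35[["donor_end"]], co14[["donor_end"]]),
                               acceptor_start = c(co35[["acceptor_start"]],
                                                  co14[["acceptor_start"]]),
                               n = c(5, 9)))))
  ev <- tabulate_skip_events(jn, list(G6 = chain6))
  expect_equal(nrow(ev), 4L)  # 2 events x 2 samples
  e35 <- ev[upstream_exon == 3 & downstream_exon == 5]
  expect_equal(e35[order(sample_id), read_count], c(5L, 5L))
  e14 <- ev[upstream_exon == 1 & downstream_exon == 4]
  expect_equal(e14[sample_id == "s1", read_count], 0L)  # kd-only junction
  expect_equal(unique(ev$k_skipped[ev$upstream_exon == 1]), 2L)
})

test_that("read conservation: canonical + skip + unannotated = gene total", {
  set.seed(21)
  sim <- simulate_gene_models(sim_config(seed = 21, n_genes = 8))
  jn <- simulate_junction_reads(sim$chains, sim$truth, sim_config(seed = 21, n_genes = 8))
  cl <- classify_junctions(jn, sim$chains)
  expect_true(all(!is.na(cl$gene_id)))
  per_gene <- cl[, .(tot = sum(read_count)), by = .(gene_id, sample_id)]
  by_kind <- cl[, .(tot = sum(read_count)),
                by = .(gene_id, sample_id, kind)][, .(tot = sum(tot)),
                                                  by = .(gene_id, sample_id)]
  expect_equal(per_gene[order(gene_id, sample_id)], by_kind[order(gene_id, sample_id)])
})

test_that("skip-read ratio profile reproduces hand-computed ratios", {
  co <- junction_pair_coords(chain6, 2, 5)  # k = 2
  mk <- function(n_ctrl, n_kd) make_junctions(chain6, list(
    c1 = list(condition = "control",
              tab = data.frame(donor_end = co[["donor_end"]],
                               acceptor_start = co[["acceptor_start"]], n = n_ctrl)),
    k1 = list(condition = "kd",
              tab = data.frame(donor_end = co[["donor_end"]],
                               acceptor_start = co[["acceptor_start"]], n = n_kd))))
  # totals of 1e6 make CPM equal raw counts; c = 0 -> plain ratio 4/2 = 2
  ev <- tabulate_skip_events(mk(2, 4), list(G6 = chain6))
  prof <- skip_read_ratio_profile(ev, c(c1 = 1e6, k1 = 1e6), pseudocount = 0)
  expect_equal(prof[k == "2", median_ratio], 2.0)
  expect_equal(prof[k == "ge2", median_ratio], 2.0)
  expect_equal(prof[k == "2", n_events], 1L)
  # pseudocount formula: control 0, kd 3 -> (3 + .5)/(0 + .5) = 7
  ev0 <- tabulate_skip_events(mk(1, 3), list(G6 = chain6))
  ev0[condition == "control", read_count := 0L]
  prof0 <- skip_read_ratio_profile(ev0, c(c1 = 1e6, k1 = 1e6), pseudocount = 0.5)
  expect_equal(prof0[k == "2", median_ratio], 7.0)
  # identical tables are symmetric -> ratio exactly 1
  prof1 <- skip_read_ratio_profile(ev <- tabulate_skip_events(mk(6, 6), list(G6 = chain6)),
                                   c(c1 = 1e6, k1 = 1e6))
  expect_equal(prof1[k == "2", median_ratio], 1.0)
  expect_error(skip_read_ratio_profile(ev[0], c(c1 = 1)), "no skip events")
})

test_that("junction-count PSI follows its defining formula", {
  expect_equal(compute_psi(30, 30, 10), 0.75)
  expect_equal(compute_psi(12, 20, 0), 1.0)
  expect_equal(compute_psi(0, 0, 7), 0.0)
  expect_true(is.na(compute_psi(0, 0, 0)))
  psis <- compute_psi(sample(0:50, 100, TRUE), sample(0:50, 100, TRUE),
                      sample(0:50, 100, TRUE))
  expect_true(all(is.na(psis) | (psis >= 0 & psis <= 1)))
})

se_fixture <- function(inc_c, exc_c, inc_k, exc_k) {
  # inclusion junctions flank exon 3; exclusion junction skips it (2 -> 4)
  up <- junction_pair_coords(chain6, 2, 3)
  dn <- junction_pair_coords(chain6, 3, 4)
  ex <- junction_pair_coords(chain6, 2, 4)
  tab <- function(inc, exc) data.frame(
    donor_end = c(up[["donor_end"]], dn[["donor_end"]], ex[["donor_end"]]),
    acceptor_start = c(up[["acceptor_start"]], dn[["acceptor_start"]],
                       ex[["acceptor_start"]]),
    n = c(inc, inc, exc))
  make_junctions(chain6, list(
    c1 = list(condition = "control", tab = tab(inc_c, exc_c)),
    k1 = list(condition = "kd", tab = tab(inc_k, exc_k))))
}

test_that("SE calling gates on both delta-PSI and FDR", {
  # control PSI 0.9 vs kd PSI 0.3 at depth ~200/condition: significant
  calls <- call_se_events(se_fixture(90, 10, 30, 70), list(G6 = chain6))
  x <- calls[exon_index == 3]
  expect_equal(x$psi_control, 0.9)
  expect_equal(x$psi_kd, 0.3)
  expect_true(x$significant)
  # identical conditions: p = 1 everywhere, nothing called
  calls0 <- call_se_events(se_fixture(90, 10, 90, 10), list(G6 = chain6))
  expect_equal(sum(calls0$significant), 0L)
  # |dPSI| = 0.15 with enormous depth: tiny p but the dPSI gate fails
  calls15 <- call_se_events(se_fixture(9500, 500, 8000, 2000), list(G6 = chain6))
  x15 <- calls15[exon_index == 3]
  expect_equal(x15$delta_psi, -0.15, tolerance = 1e-9)
  expect_lt(x15$p_value, 1e-10)
  expect_false(x15$significant)
  # junctions that hit no exon boundary leave nothing testable
  stray <- data.table::data.table(
    chrom = "chr1", donor_end = c(77, 77), acceptor_start = c(333, 333),
    strand = "+", sample_id = c("c1", "k1"), condition = c("control", "kd"),
    read_count = 5L)
  expect_warning(empty <- call_se_events(stray, list(G6 = chain6)), "no testable")
  expect_equal(nrow(empty), 0L)
  expect_error(call_se_events(se_fixture(1, 1, 1, 1)[condition == "control"],
                              list(G6 = chain6)), "both 'control' and 'kd'")
})

test_that("BH-adjusted FDR is monotone in ranked p order", {
  set.seed(31)
  sim <- simulate_gene_models(sim_config(seed = 31, n_genes = 15))
  jn <- simulate_junction_reads(sim$chains, sim$truth, sim_config(seed = 31, n_genes = 15))
  calls <- call_se_events(jn, sim$chains)
  expect_gt(nrow(calls), 0)
  o <- order(calls$p_value)
  expect_true(all(diff(calls$fdr[o]) >= -1e-12))
  expect_true(all(calls$delta_psi >= -1 & calls$delta_psi <= 1))
})
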