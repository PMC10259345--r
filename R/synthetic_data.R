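# Synthetic data with known ground truth: gene models, junction-read tables,
# exon-level occupancy, CDS/domain fixtures and a divergent paralog pair.
# Every artifact is a pure function of the configuration (including its seed).

#' Simulation configuration
#'
#' Defaults describe the study conditions the pipeline targets: a few hundred
#' multi-exon genes, Poisson junction-read noise at a set per-gene depth,
#' condition-dependent skip rates rising with knockdown (multipliers grow
#' with skip class k, reaching 3x for k = 5), negative-binomially
#' overdispersed CLIP-like crosslink counts, and occupancy enrichment on the
#' exon immediately upstream of each designated skipped exon.
#'
#' @param seed Integer seed; fixes every downstream artifact.
#' @param n_genes Number of genes (one transcript each).
#' @param exon_count_range,exon_len_range,intron_len_range Uniform ranges for
#'   gene structure (counts; nucleotides).
#' @param replicates_per_condition Replicates per condition.
#' @param depth_per_gene Expected junction reads per gene and sample.
#' @param base_skip_rate Per-class skip rate (fraction of depth) for
#'   k = 1..K in the control condition.
#' @param kd_multiplier Knockdown fold change on the skip rate, per k.
#' @param occ_mean,occ_dispersion Negative-binomial mean / size for per-exon
#'   crosslink counts.
#' @param enrichment_gamma Multiplier on the crosslink mean of exons
#'   immediately upstream of designated skipped exons (affected genes).
#' @param fraction_affected_genes Probability that a gene carries a
#'   designated skip event.
#' @param silent_gene_fraction Fraction of genes emitted with all-zero
#'   RNA-seq support (dropped by the occupancy loader).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 60L,
                       exon_count_range = c(4L, 12L),
                       exon_len_range = c(80L, 300L),
                       intron_len_range = c(200L, 2000L),
                       replicates_per_condition = 3L,
                       depth_per_gene = 2000,
                       base_skip_rate = c(0.02, 0.01, 0.006, 0.004, 0.003),
                       kd_multiplier = c(1.5, 2, 2.33, 2.66, 3),
                       occ_mean = 50, occ_dispersion = 0.5,
                       enrichment_gamma = 3,
                       fraction_affected_genes = 0.3,
                       silent_gene_fraction = 0.1) {
  chk_range <- function(r, name) {
    if (length(r) != 2L || r[1L] > r[2L] || r[1L] < 1L) {
      stop("degenerate range for ", name)
    }
  }
  chk_range(exon_count_range, "exon_count_range")
  chk_range(exon_len_range, "exon_len_range")
  chk_range(intron_len_range, "intron_len_range")
  if (exon_count_range[1L] < 3L) stop("exon_count_range must allow >= 3 exons")
  stopifnot(length(base_skip_rate) == length(kd_multiplier),
            all(base_skip_rate >= 0 & base_skip_rate <= 1),
            all(kd_multiplier > 0),
            fraction_affected_genes >= 0, fraction_affected_genes <= 1,
            silent_gene_fraction >= 0, silent_gene_fraction <= 1,
            occ_mean > 0, occ_dispersion > 0, depth_per_gene > 0,
            replicates_per_condition >= 1L, n_genes >= 1L)
  structure(as.list(environment())[c(
    "seed", "n_genes", "exon_count_range", "exon_len_range", "intron_len_range",
    "replicates_per_condition", "depth_per_gene", "base_skip_rate",
    "kd_multiplier", "occ_mean", "occ_dispersion", "enrichment_gamma",
    "fraction_affected_genes", "silent_gene_fraction")],
    class = "sim_config")
}

runif_int <- function(n, range) {
  if (range[1L] == range[2L]) rep(range[1L], n)
  else sample(seq.int(range[1L], range[2L]), n, replace = TRUE)
}

#' Simulate gene models
#'
#' Generates `n_genes` single-transcript genes on alternating strands with
#' exon counts/lengths/intron lengths drawn uniformly from the configured
#' ranges. The CDS covers all internal exons plus parts of the flanking
#' exons (leaving 5'/3' UTRs), padded so its length is a multiple of 3.
#'
#' @param cfg A [sim_config()].
#' @return List with `models` (list of `transcript_model`s), `chains` (named
#'   list of `exon_chain`s) and `truth` (`data.table` of designated skip
#'   events: gene_id, affected, k, upstream_exon, downstream_exon,
#'   enriched_exon).
#' @export
simulate_gene_models <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  K <- length(cfg$base_skip_rate)
  pos <- 10000L
  models <- vector("list", cfg$n_genes)
  truth <- vector("list", cfg$n_genes)
  for (g in seq_len(cfg$n_genes)) {
    gid <- sprintf("G%04d", g)
    n_ex <- runif_int(1L, cfg$exon_count_range)
    lens <- runif_int(n_ex, cfg$exon_len_range)
    introns <- runif_int(max(0L, n_ex - 1L), cfg$intron_len_range)
    starts <- pos + cumsum(c(0L, lens[-n_ex] + introns))
    ends <- starts + lens
    pos <- ends[n_ex] + 10000L
    strand <- if (g %% 2L == 0L) "-" else "+"
    # CDS: internal exons fully coding, flanks partially (UTRs), length % 3 == 0
    ex_tx <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
    utr5 <- lens[ex_tx[1L]] %/% 3L
    utr3 <- lens[ex_tx[n_ex]] %/% 3L
    cds_len <- sum(lens) - utr5 - utr3
    utr3 <- utr3 + cds_len %% 3L  # pad so CDS is a codon multiple
    if (strand == "+") {
      cds_start <- starts[1L] + utr5
      cds_end <- ends[n_ex] - utr3
    } else {
      cds_start <- starts[1L] + utr3
      cds_end <- ends[n_ex] - utr5
    }
    models[[g]] <- transcript_model(
      gene_id = gid, transcript_id = paste0("T", substring(gid, 2L)),
      chrom = "chrS", strand = strand,
      exons = data.frame(start = starts, end = ends),
      cds_start = cds_start, cds_end = cds_end, is_mane = TRUE)
    affected <- stats::runif(1L) < cfg$fraction_affected_genes
    k <- sample(seq_len(min(K, n_ex - 2L)), 1L)
    u_lo <- if (n_ex - 1L - k >= 2L) 2L else 1L
    u <- runif_int(1L, c(u_lo, n_ex - 1L - k))
    truth[[g]] <- data.table::data.table(
      gene_id = gid, affected = affected, k = k,
      upstream_exon = u, downstream_exon = u + k + 1L,
      enriched_exon = u)
  }
  chains <- lapply(models, build_exon_chain)
  names(chains) <- vapply(chains, `[[`, "", "gene_id")
  list(models = models, chains = chains, truth = data.table::rbindlist(truth))
}

#' Write transcript models as GTF
#'
#' Emits gene/transcript/exon/CDS records (1-based inclusive coordinates,
#' Ensembl attribute dialect, `tag "MANE_Select"` on transcripts).
#'
#' @param models List of `transcript_model`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  lines <- unlist(lapply(models, function(t) {
    attr_g <- sprintf('gene_id "%s";', t$gene_id)
    attr_t <- sprintf('gene_id "%s"; transcript_id "%s"; tag "MANE_Select";',
                      t$gene_id, t$transcript_id)
    span <- c(min(t$exons$start), max(t$exons$end))
    rec <- function(type, s0, e0, at) {
      sprintf("chrS\tsim\t%s\t%d\t%d\t.\t%s\t.\t%s", type, s0 + 1L, e0, t$strand, at)
    }
    cds <- if (!is.na(t$cds_start)) {
      ov <- t$exons[pmax(start, t$cds_start) < pmin(end, t$cds_end)]
      vapply(seq_len(nrow(ov)), function(i) {
        rec("CDS", max(ov$start[i], t$cds_start), min(ov$end[i], t$cds_end), attr_t)
      }, "")
    } else character()
    c(rec("gene", span[1L], span[2L], attr_g),
      rec("transcript", span[1L], span[2L], attr_t),
      vapply(seq_len(nrow(t$exons)), function(i) {
        rec("exon", t$exons$start[i], t$exons$end[i], attr_t)
      }, ""),
      cds)
  }))
  writeLines(lines, path)
  invisible(path)
}

junction_coords <- function(chain, u, d) {
  ex <- chain$exons
  if (chain$strand == "+") {
    c(donor_end = ex[exon_index == u, end], acceptor_start = ex[exon_index == d, start])
  } else {
    c(donor_end = ex[exon_index == d, end], acceptor_start = ex[exon_index == u, start])
  }
}

#' Simulate per-sample junction reads
#'
#' Canonical junction counts are Poisson with the per-gene depth shared
#' equally over the gene's n-1 canonical junctions. Each affected gene's
#' designated skip event of class k receives Poisson(depth x rate) reads with
#' `rate = base_skip_rate[k]` in control and `base_skip_rate[k] *
#' kd_multiplier[k]` in knockdown.
#'
#' @param chains Named list of `exon_chain`s.
#' @param truth Ground-truth table from [simulate_gene_models()].
#' @param cfg A [sim_config()].
#' @return Long junction `data.table` (chrom, donor_end, acceptor_start,
#'   strand, sample_id, condition, read_count).
#' @export
simulate_junction_reads <- function(chains, truth, cfg) {
  set.seed(cfg$seed + 1L)
  samples <- data.table::data.table(
    sample_id = c(paste0("ctrl_", seq_len(cfg$replicates_per_condition)),
                  paste0("kd_", seq_len(cfg$replicates_per_condition))),
    condition = rep(c("control", "kd"), each = cfg$replicates_per_condition))
  rows <- list()
  for (gid in names(chains)) {
    ch <- chains[[gid]]
    tr <- truth[gene_id == gid]
    n_ex <- ch$n_exons
    canon_mu <- cfg$depth_per_gene / (n_ex - 1L)
    for (si in seq_len(nrow(samples))) {
      cond <- samples$condition[si]
      for (i in seq_len(n_ex - 1L)) {
        co <- junction_coords(ch, i, i + 1L)
        rows[[length(rows) + 1L]] <- data.table::data.table(
          chrom = ch$chrom, donor_end = co[["donor_end"]],
          acceptor_start = co[["acceptor_start"]], strand = ch$strand,
          sample_id = samples$sample_id[si], condition = cond,
          read_count = stats::rpois(1L, canon_mu))
      }
      if (nrow(tr) && tr$affected[1L]) {
        k <- tr$k[1L]
        rate <- cfg$base_skip_rate[k] *
          if (cond == "kd") cfg$kd_multiplier[k] else 1
        co <- junction_coords(ch, tr$upstream_exon[1L], tr$downstream_exon[1L])
        rows[[length(rows) + 1L]] <- data.table::data.table(
          chrom = ch$chrom, donor_end = co[["donor_end"]],
          acceptor_start = co[["acceptor_start"]], strand = ch$strand,
          sample_id = samples$sample_id[si], condition = cond,
          read_count = stats::rpois(1L, cfg$depth_per_gene * rate))
      }
    }
  }
  out <- data.table::rbindlist(rows)[read_count > 0L]
  out[]
}

#' Simulate exon-level occupancy
#'
#' Two crosslink columns (summed downstream) are drawn negative-binomially
#' with total mean `occ_mean`, multiplied by `enrichment_gamma` on the exon
#' immediately upstream of each affected gene's designated skipped exon(s).
#' Two RNA-seq support columns are Poisson-positive for expressed genes and
#' all-zero for a `silent_gene_fraction` of genes.
#'
#' @inheritParams simulate_junction_reads
#' @return `data.table`: gene_id, exon_index, crosslink_1, crosslink_2,
#'   rnaseq_1, rnaseq_2.
#' @export
simulate_occupancy <- function(chains, truth, cfg) {
  set.seed(cfg$seed + 2L)
  gids <- names(chains)
  silent <- gids[stats::runif(length(gids)) < cfg$silent_gene_fraction]
  rows <- lapply(gids, function(gid) {
    ch <- chains[[gid]]
    tr <- truth[gene_id == gid]
    mu <- rep(cfg$occ_mean, ch$n_exons)
    if (nrow(tr) && tr$affected[1L]) {
      mu[tr$enriched_exon[1L]] <- mu[tr$enriched_exon[1L]] * cfg$enrichment_gamma
    }
    is_silent <- gid %in% silent
    data.table::data.table(
      gene_id = gid, exon_index = seq_len(ch$n_exons),
      crosslink_1 = stats::rnbinom(ch$n_exons, mu = mu / 2, size = cfg$occ_dispersion / 2),
      crosslink_2 = stats::rnbinom(ch$n_exons, mu = mu / 2, size = cfg$occ_dispersion / 2),
      rnaseq_1 = if (is_silent) 0L else stats::rpois(ch$n_exons, 20),
      rnaseq_2 = if (is_silent) 0L else stats::rpois(ch$n_exons, 20))
  })
  data.table::rbindlist(rows)
}

SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                        names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == "*"])

random_sense_cds <- function(n_codons) {
  paste0(paste(sample(SENSE_CODONS, n_codons - 1L, replace = TRUE), collapse = ""), "TAA")
}

#' Simulate CDS sequences and domain annotations with expected consequences
#'
#' For each coding gene: a random internal-stop-free CDS of the chain's CDS
#' length. For affected genes, domains are placed relative to the amino-acid
#' span removed by the designated skip event so the expected
#' none/partial/total outcome is known by construction (a domain strictly
#' before the lost span, one inside it, one straddling its start, and one
#' after it). In-frame events are adjusted never to create a stop at the new
#' exon junction; frameshift expectations are derived by translating the
#' constructed mutant.
#'
#' @inheritParams simulate_junction_reads
#' @return List: `cds` (named character by transcript id), `domains`
#'   (`data.table`: protein_id, domain_name, aa_start, aa_end), `expected`
#'   (`data.table`: gene_id, upstream_exon, downstream_exon, skipped_cds_nt,
#'   frame, has_ptc, ptc_codon, domain_name, effect).
#' @export
simulate_cds_and_domains <- function(chains, truth, cfg) {
  set.seed(cfg$seed + 3L)
  cds_out <- list()
  dom_rows <- list()
  exp_rows <- list()
  for (gid in names(chains)) {
    ch <- chains[[gid]]
    if (is.na(ch$cds_start)) next
    ex <- ch$exons
    clen <- pmax(0L, pmin(ex$end, ch$cds_end) - pmax(ex$start, ch$cds_start))
    off <- cumsum(c(0L, clen[-length(clen)]))
    total <- sum(clen)
    if (total %% 3L != 0L || total < 30L) next
    s <- random_sense_cds(total %/% 3L)
    tr <- truth[gene_id == gid]
    if (nrow(tr) && tr$affected[1L]) {
      sk <- seq.int(tr$upstream_exon[1L] + 1L, tr$downstream_exon[1L] - 1L)
      d0 <- off[sk[1L]]                       # 0-based start of deleted CDS span
      d1 <- off[sk[length(sk)]] + clen[sk[length(sk)]]
      del_nt <- sum(clen[sk])
      stopifnot(d1 - d0 == del_nt)            # designated skips are contiguous
      frame <- if (del_nt %% 3L == 0L) "in_frame" else "frameshift"
      if (frame == "in_frame" && d0 %% 3L != 0L) {
        # hybrid junction codon must not be a stop: a C can never create one
        substr(s, d1 + 1L, d1 + 1L) <- "C"
      }
      mutant <- paste0(substr(s, 1L, d0), substr(s, d1 + 1L, total))
      maa <- translate_codons(mutant)
      first_stop <- which(maa == "*")[1L]
      prot_len <- total %/% 3L - 1L
      if (frame == "in_frame") {
        has_ptc <- !is.na(first_stop) && first_stop < nchar(mutant) / 3
        ptc_codon <- if (has_ptc) first_stop else NA_integer_
      } else {
        has_ptc <- !is.na(first_stop)
        ptc_codon <- first_stop
      }
      aa_lost_start <- d0 %/% 3L + 1L
      aa_lost_end <- min(prot_len, (d1 - 1L) %/% 3L + 1L)
      truncating <- frame == "frameshift" || isTRUE(has_ptc)
      doms <- list()
      if (aa_lost_start >= 12L) {
        doms$before <- c(aa_lost_start - 11L, aa_lost_start - 2L)
      }
      if (aa_lost_end - aa_lost_start >= 4L) {
        doms$inside <- c(aa_lost_start + 1L, aa_lost_end - 1L)
      }
      if (aa_lost_start >= 5L && aa_lost_end >= aa_lost_start + 2L) {
        doms$straddle <- c(aa_lost_start - 4L, aa_lost_start + 2L)
      }
      if (aa_lost_end + 12L <= prot_len) {
        doms$after <- c(aa_lost_end + 3L, aa_lost_end + 12L)
      }
      expect_effect <- c(before = "none",
                         inside = "total",
                         straddle = "partial",
                         after = if (truncating) "total" else "none")
      for (nm in names(doms)) {
        dom_rows[[length(dom_rows) + 1L]] <- data.table::data.table(
          protein_id = ch$transcript_id, domain_name = paste0(nm, "_", gid),
          aa_start = doms[[nm]][1L], aa_end = doms[[nm]][2L])
        exp_rows[[length(exp_rows) + 1L]] <- data.table::data.table(
          gene_id = gid, upstream_exon = tr$upstream_exon[1L],
          downstream_exon = tr$downstream_exon[1L],
          skipped_cds_nt = del_nt, frame = frame,
          has_ptc = isTRUE(has_ptc), ptc_codon = ptc_codon,
          domain_name = paste0(nm, "_", gid), effect = expect_effect[[nm]])
      }
    }
    cds_out[[ch$transcript_id]] <- s
  }
  list(cds = unlist(cds_out),
       domains = data.table::rbindlist(dom_rows),
       expected = data.table::rbindlist(exp_rows))
}

#' Synthetic paralog pair with a fixed divergence structure
#'
#' Builds a pair of coding sequences patterned on the mago-nashi-like EJC
#' core proteins: two proteins of equal length identical except their first
#' two residues, and CDSs whose nucleotide identity is driven down to a
#' target by single-nucleotide synonymous substitutions. The result is a
#' synthetic stand-in with the published divergence structure of the human
#' MAGOH/MAGOHB pair (98.63% protein identity; 86% CDS identity), not the
#' real sequences.
#'
#' @param protein Template protein (character, no stop). Default: a
#'   146-residue mago-nashi-like template.
#' @param nt_identity_target Target CDS identity (fraction).
#' @param seed Integer seed.
#' @return List: protein_a, protein_b, cds_a, cds_b (CDSs include the stop
#'   codon).
#' @export
simulate_paralog_pair <- function(protein = mago_template_protein,
                                  nt_identity_target = 0.86, seed = 42L) {
  protein <- toupper(protein)
  aa <- strsplit(protein, "")[[1L]]
  stopifnot(length(aa) >= 10L, !"*" %in% aa)
  codon_for <- function(a) sample(SENSE_CODONS[Biostrings::GENETIC_CODE[SENSE_CODONS] == a], 1L)
  # synonymous single-nucleotide neighbours of a codon
  syn1 <- function(codon) {
    out <- character()
    for (pos in 1:3) for (nt in setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- nt
      if (identical(as.character(Biostrings::GENETIC_CODE[mut]),
                    as.character(Biostrings::GENETIC_CODE[codon]))) out <- c(out, mut)
    }
    out
  }
  L <- 3L * (length(aa) + 1L)  # incl. stop codon
  target <- round((1 - nt_identity_target) * L)
  # The constructed substitutions must survive re-alignment: clustered
  # substitutions can let the affine-gap aligner realign a region through
  # indels and report a different identity, so placements are retried until
  # the aligned identity rounds to the target.
  for (attempt in seq_len(50L)) {
    set.seed(seed + attempt - 1L)
    codons_a <- vapply(aa, codon_for, "", USE.NAMES = FALSE)
    aa_b <- aa
    aa_b[1L] <- if (aa[1L] == "A") "V" else "A"
    aa_b[2L] <- if (aa[2L] == "T") "S" else "T"
    codons_b <- codons_a
    codons_b[1L] <- codon_for(aa_b[1L])
    codons_b[2L] <- codon_for(aa_b[2L])
    n_diff <- function() sum(strsplit(paste(codons_a, collapse = ""), "")[[1L]] !=
                               strsplit(paste(codons_b, collapse = ""), "")[[1L]])
    for (i in sample(seq.int(3L, length(aa)))) {
      if (n_diff() >= target) break
      alts <- syn1(codons_b[i])
      if (length(alts)) codons_b[i] <- sample(alts, 1L)
    }
    out <- list(protein_a = protein, protein_b = paste(aa_b, collapse = ""),
                cds_a = paste0(paste(codons_a, collapse = ""), "TAA"),
                cds_b = paste0(paste(codons_b, collapse = ""), "TAA"))
    aln <- global_align(out$cds_a, out$cds_b, mode = "nucleotide")
    if (round(percent_identity(aln)) == round(100 * nt_identity_target)) return(out)
  }
  stop("could not construct a paralog pair at the requested identity")
}

#' A 146-residue mago-nashi-like template protein
#'
#' Template for [simulate_paralog_pair()]; a synthetic stand-in patterned on
#' the human MAGOH protein family (146 residues, no internal stop).
#' @format Character scalar.
#' @export
mago_template_protein <- paste0(
  "MESDFYLRYYVGHKGKFGHEFLEFEFRPDGKLRYANNSNYKNDVMIRKEAYVHKSVMEEL",
  "KRIIDDSEITKEDDALWPPPDRVGRQELEIVIGDEHISFTTSKIGSLIDVNQSKDPEGLR",
  "VFYYLVQDLKCLVFSLIGLHFKIKPI")

#' Writers for the simulated artifacts
#'
#' Emit the exact dialects the pipeline consumes: per-sample junction files
#' (SJ-style or 4-column TSV), the occupancy TSV, a CDS FASTA and the domain
#' TSV.
#'
#' @param junctions,occ,cds,domains Simulated objects.
#' @param dir,path Output locations.
#' @param dialect Junction dialect to emit.
#' @return Written path(s), invisibly.
#' @name sim_writers
NULL

#' @rdname sim_writers
#' @export
write_junction_files <- function(junctions, dir, dialect = c("bed", "sj_tab")) {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(unique(junctions$sample_id), function(sid) {
    j <- junctions[sample_id == sid][order(chrom, donor_end, acceptor_start)]
    p <- file.path(dir, paste0(sid, if (dialect == "bed") ".junctions.tsv" else ".SJ.out.tab"))
    if (dialect == "bed") {
      data.table::fwrite(j[, .(chrom, donor_end, acceptor_start, read_count)], p,
                         sep = "\t", col.names = FALSE)
    } else {
      sj <- j[, .(chrom, intron_start = donor_end + 1L, intron_end = acceptor_start,
                  strand_code = ifelse(strand == "+", 1L, ifelse(strand == "-", 2L, 0L)),
                  motif = 0L, annotated = 0L, unique_reads = read_count,
                  multi_reads = 0L, overhang = 20L)]
      data.table::fwrite(sj, p, sep = "\t", col.names = FALSE)
    }
    p
  }, "")
  invisible(paths)
}

#' @rdname sim_writers
#' @export
write_occupancy_tsv <- function(occ, path) {
  data.table::fwrite(occ, path, sep = "\t")
  invisible(path)
}

#' @rdname sim_writers
#' @export
write_cds_fasta <- function(cds, path) {
  writeLines(unlist(lapply(names(cds), function(n) c(paste0(">", n), cds[[n]]))), path)
  invisible(path)
}

#' @rdname sim_writers
#' @export
write_domain_tsv <- function(domains, path) {
  data.table::fwrite(domains, path, sep = "\t")
  invisible(path)
}

#' Simulate a complete dataset on disk
#'
#' Runs every generator and writes the GTF, per-sample junction files (both
#' dialects), occupancy TSV, CDS FASTA, domain TSV and a ground-truth JSON
#' into `dir`.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if missing).
#' @return Invisible list of the in-memory objects and file paths.
#' @export
simulate_dataset <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gm <- simulate_gene_models(cfg)
  jn <- simulate_junction_reads(gm$chains, gm$truth, cfg)
  occ <- simulate_occupancy(gm$chains, gm$truth, cfg)
  cd <- simulate_cds_and_domains(gm$chains, gm$truth, cfg)
  paths <- list(
    gtf = file.path(dir, "annotation.gtf"),
    occupancy = file.path(dir, "occupancy.tsv"),
    cds = file.path(dir, "cds.fa"),
    domains = file.path(dir, "domains.tsv"),
    truth = file.path(dir, "truth.json"))
  write_gtf(gm$models, paths$gtf)
  paths$junctions <- write_junction_files(jn, file.path(dir, "junctions"), "bed")
  paths$sj <- write_junction_files(jn, file.path(dir, "junctions_sj"), "sj_tab")
  write_occupancy_tsv(occ, paths$occupancy)
  write_cds_fasta(as.list(cd$cds), paths$cds)
  write_domain_tsv(cd$domains, paths$domains)
  jsonlite::write_json(
    list(config = unclass(cfg), truth = gm$truth, expected_consequences = cd$expected),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(config = cfg, models = gm$models, chains = gm$chains,
                 truth = gm$truth, junctions = jn, occupancy = occ,
                 cds = cd$cds, domains = cd$domains,
                 expected_consequences = cd$expected, paths = paths))
}
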