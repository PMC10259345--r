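# Independent oracles and fixture builders used across the suite.

# --- fixture builders --------------------------------------------------------

# chain directly from genomic exon coordinates (0-based half-open, ascending)
make_chain <- function(gene_id, strand, starts, ends, cds_start = NA, cds_end = NA,
                       chrom = "chr1") {
  build_exon_chain(transcript_model(
    gene_id = gene_id, transcript_id = paste0("T_", gene_id), chrom = chrom,
    strand = strand, exons = data.frame(start = starts, end = ends),
    cds_start = cds_start, cds_end = cds_end))
}

random_chain <- function(gene_id = "G", n_exons = sample(3:10, 1),
                         strand = sample(c("+", "-"), 1)) {
  lens <- sample(50:200, n_exons, replace = TRUE)
  gaps <- sample(100:500, n_exons, replace = TRUE)
  starts <- cumsum(gaps + c(0, lens[-n_exons]))
  make_chain(gene_id, strand, starts, starts + lens)
}

# occupancy table straight from per-gene crosslink vectors
make_occ <- function(...) {
  genes <- list(...)
  data.table::rbindlist(lapply(names(genes), function(g) {
    data.table::data.table(gene_id = g, exon_index = seq_along(genes[[g]]),
                           crosslink = as.numeric(genes[[g]]),
                           rnaseq = 1, n_exons = length(genes[[g]]))
  }))
}

# long junction table from explicit per-sample counts:
# counts = list(sample_id = list(condition, data.frame(donor_end, acceptor_start, n)))
make_junctions <- function(chain, per_sample) {
  data.table::rbindlist(lapply(names(per_sample), function(sid) {
    x <- per_sample[[sid]]
    data.table::data.table(chrom = chain$chrom, donor_end = x$tab$donor_end,
                           acceptor_start = x$tab$acceptor_start,
                           strand = chain$strand, sample_id = sid,
                           condition = x$condition, read_count = x$tab$n)
  }))
}

# genomic (donor_end, acceptor_start) of the junction joining transcript
# exons u and d of a chain
junction_pair_coords <- function(chain, u, d) {
  ex <- chain$exons
  left <- if (chain$strand == "+") u else d   # genomically left exon
  right <- if (chain$strand == "+") d else u
  c(donor_end = ex$end[ex$exon_index == left],
    acceptor_start = ex$start[ex$exon_index == right])
}

# --- naive line-by-line GTF parser (gene_model oracle) -----------------------

naive_gtf_exons <- function(path) {
  out <- list()
  for (line in readLines(path)) {
    if (grepl("^#", line) || !nzchar(trimws(line))) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (f[3] != "exon") next
    tid <- sub('.*transcript_id "([^"]+)".*', "\\1", f[9])
    out[[tid]] <- rbind(out[[tid]],
                        data.frame(chrom = f[1], start = as.integer(f[4]) - 1L,
                                   end = as.integer(f[5]), strand = f[7]))
  }
  lapply(out, function(d) d[order(d$start), , drop = FALSE])
}

# --- brute-force junction matcher (junction_analysis oracle) -----------------

bf_classify <- function(j, chain) {
  n <- chain$n_exons
  for (u in seq_len(n)) {
    for (d in seq_len(n)) {
      if (d <= u) next
      co <- junction_pair_coords(chain, u, d)
      if (j$donor_end == co[["donor_end"]] &&
          j$acceptor_start == co[["acceptor_start"]]) {
        return(list(kind = if (d == u + 1L) "canonical" else "skip",
                    k_skipped = if (d == u + 1L) 0L else d - u - 1L,
                    upstream_exon = u, downstream_exon = d))
      }
    }
  }
  list(kind = "unannotated", k_skipped = NA_integer_,
       upstream_exon = NA_integer_, downstream_exon = NA_integer_)
}

# --- brute-force NG86 pathway enumerator (divergence oracle) -----------------

GC_TABLE <- Biostrings::GENETIC_CODE
CODON_BASES <- c("A", "C", "G", "T")
SENSE <- names(GC_TABLE)[GC_TABLE != "*"]

bf_path_orders <- list(
  `1` = list(1L),
  `2` = list(c(1L, 2L), c(2L, 1L)),
  `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
             c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

bf_ng86_differences <- function(a, b) {
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (!length(pos)) return(c(syn = 0, nonsyn = 0))
  orders <- lapply(bf_path_orders[[as.character(length(pos))]], function(o) pos[o])
  tally <- lapply(orders, function(ord) {
    cur <- a; sd <- nd <- 0; hit_stop <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (unname(GC_TABLE[nxt]) == "*" && nxt != b) hit_stop <- TRUE
      if (unname(GC_TABLE[cur]) == unname(GC_TABLE[nxt])) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    list(sd = sd, nd = nd, ok = !hit_stop)
  })
  ok <- Filter(function(t) t$ok, tally)
  use <- if (length(ok)) ok else tally
  c(syn = mean(vapply(use, `[[`, 0, "sd")),
    nonsyn = mean(vapply(use, `[[`, 0, "nd")))
}

# --- exact enumeration of the bootstrap resampling distribution --------------

# all pool^m equally likely draws; returns exact mean and variance of the
# replicate mean
enumerate_bootstrap_moments <- function(pool, m) {
  grids <- do.call(expand.grid, rep(list(pool), m))
  means <- rowMeans(as.matrix(grids))
  c(mean = mean(means), var = mean((means - mean(means))^2))
}
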