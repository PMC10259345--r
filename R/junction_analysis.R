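# Junction classification against exon chains, skip-read quantification and
# skipped-exon (SE) event calling.
#
# A junction record stores the genomic boundaries of the spliced-out segment:
# donor_end = 0-based exclusive end of the upstream exonic segment,
# acceptor_start = 0-based start of the downstream exonic segment, so
# donor_end < acceptor_start genomically regardless of strand.

#' Load splice-junction records
#'
#' Reads per-sample junction counts in one of two dialects:
#' * `"sj_tab"` — STAR SJ.out.tab: chrom, intron start (1-based), intron end
#'   (1-based inclusive), strand code (0 = unknown, 1 = `+`, 2 = `-`), motif,
#'   annotated, unique reads, multimapping reads, overhang. Unique reads are
#'   used.
#' * `"bed"` — minimal 4-column TSV: chrom, donor_end, acceptor_start, count
#'   (0-based half-open).
#'
#' Records with zero reads are dropped. When the file leaves the strand
#' unknown, it is inferred from `chains` (by matching either junction boundary
#' to an annotated exon boundary of the chromosome).
#'
#' @param path Input file.
#' @param dialect `"sj_tab"` or `"bed"`.
#' @param sample_id,condition Labels attached to every record; `condition`
#'   must be `"control"` or `"kd"`.
#' @param chains Optional named list of [build_exon_chain()] chains used for
#'   strand inference and unknown-chromosome warnings.
#' @return A `data.table` with columns chrom, donor_end, acceptor_start,
#'   strand, sample_id, condition, read_count.
#' @export
load_junctions <- function(path, dialect = c("sj_tab", "bed"), sample_id,
                           condition = c("control", "kd"), chains = NULL) {
  dialect <- match.arg(dialect)
  condition <- match.arg(condition)
  if (!file.exists(path)) stop("junction file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  if (nrow(dt) == 0L) {
    return(data.table::data.table(chrom = character(), donor_end = integer(),
                                  acceptor_start = integer(), strand = character(),
                                  sample_id = character(), condition = character(),
                                  read_count = integer()))
  }
  if (dialect == "sj_tab") {
    if (ncol(dt) < 7L) stop("SJ.out.tab dialect needs >= 7 columns: ", path)
    out <- data.table::data.table(
      chrom = as.character(dt[[1L]]),
      donor_end = as.integer(dt[[2L]]) - 1L,   # last exonic base before intron
      acceptor_start = as.integer(dt[[3L]]),   # 1-based intron end == 0-based next exon start
      strand = c("?", "+", "-")[as.integer(dt[[4L]]) + 1L],
      read_count = as.integer(dt[[7L]]))
  } else {
    if (ncol(dt) < 4L) stop("bed dialect needs 4 columns: ", path)
    out <- data.table::data.table(
      chrom = as.character(dt[[1L]]),
      donor_end = as.integer(dt[[2L]]),
      acceptor_start = as.integer(dt[[3L]]),
      strand = "?",
      read_count = as.integer(dt[[4L]]))
  }
  bad <- out$acceptor_start <= out$donor_end
  if (any(bad)) {
    stop("invalid junction (acceptor <= donor) at row ", which(bad)[1L], " of ", path)
  }
  out <- out[read_count > 0L]
  if (!is.null(chains)) {
    ann <- data.table::rbindlist(lapply(chains, function(ch) {
      data.table::data.table(chrom = ch$chrom, strand = ch$strand,
                             bnd = c(ch$exons$start, ch$exons$end))
    }))
    unk <- out$strand == "?"
    if (any(unk)) {
      inferred <- vapply(which(unk), function(i) {
        hit <- ann[chrom == out$chrom[i] &
                     (bnd == out$donor_end[i] | bnd == out$acceptor_start[i])]
        if (nrow(hit) && length(unique(hit$strand)) == 1L) hit$strand[1L] else "?"
      }, "")
      out$strand[unk] <- inferred
    }
    known_chr <- unique(vapply(chains, `[[`, "", "chrom"))
    if (!all(out$chrom %in% known_chr)) {
      warning("junctions on chromosomes absent from the annotation retained: ",
              paste(setdiff(unique(out$chrom), known_chr), collapse = ", "))
    }
  }
  out[, `:=`(sample_id = sample_id, condition = condition)]
  data.table::setcolorder(out, c("chrom", "donor_end", "acceptor_start", "strand",
                                 "sample_id", "condition", "read_count"))
  out[]
}

#' Classify one junction against an exon chain
#'
#' A junction is `canonical` when it joins the 3' boundary of exon i to the 5'
#' boundary of exon i+1 (transcript orientation), a `skip` of k exons when it
#' joins exon i to exon j = i+k+1, and `unannotated` otherwise (including any
#' boundary falling inside an exon body). On the minus strand the
#' transcript-upstream (donor) exon is the genomically right flanking exon, so
#' the record's `acceptor_start` must equal that exon's genomic start and
#' `donor_end` the downstream exon's genomic end. Boundary matching is exact.
#'
#' @param j A list or one-row data.frame with chrom, donor_end,
#'   acceptor_start, and optionally strand (`"?"` to skip the strand check).
#' @param chain An eligible `exon_chain` on the same chromosome and strand.
#' @return A list with `kind` (`canonical`/`skip`/`unannotated`), `k_skipped`,
#'   `upstream_exon`, `downstream_exon` (indices in transcript orientation;
#'   `NA` for unannotated).
#' @export
classify_junction <- function(j, chain) {
  stopifnot(inherits(chain, "exon_chain"))
  if (!identical(as.character(j$chrom), chain$chrom)) {
    stop("chromosome mismatch: junction on ", j$chrom, ", chain on ", chain$chrom)
  }
  js <- if (!is.null(j$strand)) as.character(j$strand) else "?"
  if (js != "?" && js != chain$strand) {
    stop("strand mismatch: junction ", js, ", chain ", chain$strand)
  }
  ex <- chain$exons
  if (chain$strand == "+") {
    u <- match(j$donor_end, ex$end)        # donor = genomic end of upstream exon
    d <- match(j$acceptor_start, ex$start)
  } else {
    u <- match(j$acceptor_start, ex$start) # minus-strand donor site = genomic start
    d <- match(j$donor_end, ex$end)
  }
  unann <- list(kind = "unannotated", k_skipped = NA_integer_,
                upstream_exon = NA_integer_, downstream_exon = NA_integer_)
  if (is.na(u) || is.na(d)) return(unann)
  ui <- ex$exon_index[u]; di <- ex$exon_index[d]
  if (di == ui + 1L) {
    list(kind = "canonical", k_skipped = 0L, upstream_exon = ui, downstream_exon = di)
  } else if (di > ui + 1L) {
    list(kind = "skip", k_skipped = di - ui - 1L, upstream_exon = ui, downstream_exon = di)
  } else unann
}

#' Classify a junction table against all chains
#'
#' Vectorised companion to [classify_junction()]: each record is matched to
#' the gene whose exon boundaries it joins; records matching no boundary pair
#' are assigned by genomic containment in a gene span (kind `unannotated`) or
#' left without a gene.
#'
#' @param junctions `data.table` as returned by [load_junctions()].
#' @param chains Named list of `exon_chain`s.
#' @return The input with gene_id, kind, upstream_exon, downstream_exon and
#'   k_skipped columns added.
#' @export
classify_junctions <- function(junctions, chains) {
  jn <- data.table::copy(junctions)
  jn[, `:=`(gene_id = NA_character_, kind = "unannotated",
            upstream_exon = NA_integer_, downstream_exon = NA_integer_,
            k_skipped = NA_integer_)]
  for (ch in chains) {
    idx <- which(jn$chrom == ch$chrom & is.na(jn$gene_id) &
                   (jn$strand == "?" | jn$strand == ch$strand))
    if (!length(idx)) next
    ex <- ch$exons
    if (ch$strand == "+") {
      u <- ex$exon_index[match(jn$donor_end[idx], ex$end)]
      d <- ex$exon_index[match(jn$acceptor_start[idx], ex$start)]
    } else {
      u <- ex$exon_index[match(jn$acceptor_start[idx], ex$start)]
      d <- ex$exon_index[match(jn$donor_end[idx], ex$end)]
    }
    hit <- !is.na(u) & !is.na(d) & d > u
    if (any(hit)) {
      h <- idx[hit]
      jn$gene_id[h] <- ch$gene_id
      jn$upstream_exon[h] <- u[hit]
      jn$downstream_exon[h] <- d[hit]
      jn$k_skipped[h] <- d[hit] - u[hit] - 1L
      jn$kind[h] <- ifelse(jn$k_skipped[h] == 0L, "canonical", "skip")
    }
    # containment fallback: inside the gene span but not boundary-matched
    span <- range(ex$start, ex$end)
    inside <- idx[!hit][jn$donor_end[idx[!hit]] >= span[1L] &
                          jn$acceptor_start[idx[!hit]] <= span[2L]]
    jn$gene_id[inside] <- ch$gene_id
  }
  jn[]
}

#' Tabulate skip events with per-sample read counts
#'
#' One event per distinct (gene, upstream exon, downstream exon) junction with
#' kind `skip`; samples without reads for an event are recorded as 0 so that
#' conditions are always comparable.
#'
#' @param junctions Classified junction table ([classify_junctions()]), or a
#'   raw table plus `chains` to classify here.
#' @param chains Optional; required when `junctions` is unclassified.
#' @return Long `data.table`: gene_id, upstream_exon, downstream_exon,
#'   k_skipped, sample_id, condition, read_count — one row per event x sample.
#' @export
tabulate_skip_events <- function(junctions, chains = NULL) {
  jn <- if (!"kind" %in% names(junctions)) {
    if (is.null(chains)) stop("chains required to classify junctions")
    classify_junctions(junctions, chains)
  } else junctions
  sk <- jn[kind == "skip"]
  samples <- unique(jn[, .(sample_id, condition)])
  if (nrow(sk) == 0L) {
    return(data.table::data.table(gene_id = character(), upstream_exon = integer(),
                                  downstream_exon = integer(), k_skipped = integer(),
                                  sample_id = character(), condition = character(),
                                  read_count = integer()))
  }
  agg <- sk[, .(read_count = sum(read_count)),
            by = .(gene_id, upstream_exon, downstream_exon, k_skipped, sample_id)]
  events <- unique(agg[, .(gene_id, upstream_exon, downstream_exon, k_skipped)])
  full <- events[, cbind(.SD, samples[, .(sample_id, condition)]),
                 by = seq_len(nrow(events))][, seq_len := NULL]
  out <- merge(full, agg,
               by = c("gene_id", "upstream_exon", "downstream_exon", "k_skipped", "sample_id"),
               all.x = TRUE)
  out[is.na(read_count), read_count := 0L]
  data.table::setorder(out, gene_id, upstream_exon, downstream_exon, sample_id)
  out[]
}

#' Skipped exon indices of an event
#' @param upstream_exon,downstream_exon Flanking exon indices.
#' @return Integer vector of the skipped (intervening) exon indices.
#' @export
skipped_exons <- function(upstream_exon, downstream_exon) {
  if (downstream_exon - upstream_exon < 2L) return(integer())
  seq.int(upstream_exon + 1L, downstream_exon - 1L)
}

#' Per-k knockdown/control skip-read ratio profile
#'
#' For each skip event, per-sample counts are scaled to counts per million
#' junction reads (CPM), averaged within condition, and summarised as
#' `(mean kd CPM + c) / (mean control CPM + c)` with pseudocount `c`. The
#' profile reports, per skip class k and for the pooled class k >= 2, the
#' median ratio and event count — the summary behind the observation that
#' knockdown cells carry relatively more reads supporting multi-exon skips.
#'
#' @param events Long event table from [tabulate_skip_events()].
#' @param per_sample_totals Named numeric: total junction reads per sample.
#' @param pseudocount Added to both condition means (default 0.5).
#' @param per_event Compute the ratio per event before taking the per-k median
#'   (default) rather than per k-class on summed counts.
#' @return `data.table` with k (character, including `"ge2"`), n_events,
#'   median_ratio.
#' @export
skip_read_ratio_profile <- function(events, per_sample_totals, pseudocount = 0.5,
                                    per_event = TRUE) {
  if (nrow(events) == 0L) stop("no skip events to profile")
  ev <- data.table::copy(events)
  if (!all(unique(ev$sample_id) %in% names(per_sample_totals))) {
    stop("per_sample_totals missing samples: ",
         paste(setdiff(unique(ev$sample_id), names(per_sample_totals)), collapse = ", "))
  }
  ev[, cpm := read_count / per_sample_totals[sample_id] * 1e6]
  n_by_k <- unique(ev[, .(gene_id, upstream_exon, downstream_exon, k_skipped)])[
    , .(n_events = .N), by = .(k_skipped)]
  if (per_event) {
    cond_means <- ev[, .(m = mean(cpm)),
                     by = .(gene_id, upstream_exon, downstream_exon, k_skipped, condition)]
    wide <- data.table::dcast(cond_means,
                              gene_id + upstream_exon + downstream_exon + k_skipped ~ condition,
                              value.var = "m", fill = 0)
  } else {
    cond_means <- ev[, .(cpm = sum(cpm)), by = .(k_skipped, sample_id, condition)][
      , .(m = mean(cpm)), by = .(k_skipped, condition)]
    wide <- data.table::dcast(cond_means, k_skipped ~ condition, value.var = "m", fill = 0)
  }
  for (cc in c("control", "kd")) if (!cc %in% names(wide)) wide[[cc]] <- 0
  wide[, ratio := (kd + pseudocount) / (control + pseudocount)]
  per_k <- wide[, .(median_ratio = stats::median(ratio)), by = .(k_skipped)]
  pooled_med <- if (any(wide$k_skipped >= 2L)) {
    stats::median(wide[k_skipped >= 2L, ratio])
  } else NULL
  out <- merge(per_k, n_by_k, by = "k_skipped")[
    , .(k = as.character(k_skipped), n_events, median_ratio)]
  if (!is.null(pooled_med)) {
    out <- rbind(out, data.table::data.table(
      k = "ge2", n_events = sum(n_by_k[k_skipped >= 2L, n_events]),
      median_ratio = pooled_med))
  }
  data.table::setorder(out, k)
  out[]
}

#' Junction-count PSI
#'
#' Percent spliced in from junction counts only: the two inclusion junctions
#' are averaged and weighed against exclusion reads,
#' `PSI = ((inc_up + inc_down)/2) / ((inc_up + inc_down)/2 + exc)`.
#' `NA` when no junction covers the exon.
#'
#' @param inc_up,inc_down Reads on the upstream/downstream inclusion
#'   junctions.
#' @param exc Reads on junctions excluding (skipping over) the exon.
#' @return PSI in `[0, 1]`, or `NA` when all three counts are zero.
#' @export
compute_psi <- function(inc_up, inc_down, exc) {
  stopifnot(all(inc_up >= 0), all(inc_down >= 0), all(exc >= 0))
  inc <- (inc_up + inc_down) / 2
  ifelse(inc + exc == 0, NA_real_, inc / (inc + exc))
}

#' Call skipped-exon events with delta-PSI and FDR gates
#'
#' For every internal exon of every eligible chain with junction evidence:
#' pools inclusion/exclusion junction reads per condition across replicates,
#' computes PSI per condition and delta-PSI (kd - control), tests the pooled
#' 2x2 (inclusion, exclusion) x (control, kd) table with Fisher's exact test,
#' adjusts p-values by Benjamini-Hochberg across all tested exons, and flags
#' events passing both gates `|dPSI| > dpsi_min` and `FDR < fdr_max`.
#'
#' @param junctions Junction `data.table` covering both conditions (classified
#'   or raw).
#' @param chains Named list of eligible `exon_chain`s.
#' @param dpsi_min,fdr_max Significance gates (defaults 0.2 and 0.01).
#' @return `data.table`: gene_id, exon_index, inc/exc counts per condition,
#'   psi_control, psi_kd, delta_psi, p_value, fdr, significant.
#' @export
call_se_events <- function(junctions, chains, dpsi_min = 0.2, fdr_max = 0.01) {
  jn <- if (!"kind" %in% names(junctions)) classify_junctions(junctions, chains) else junctions
  if (!all(c("control", "kd") %in% unique(jn$condition))) {
    stop("junction table must contain both 'control' and 'kd' conditions")
  }
  jn <- jn[kind %in% c("canonical", "skip")]
  pooled <- jn[, .(read_count = sum(read_count)),
               by = .(gene_id, upstream_exon, downstream_exon, kind, condition)]
  rows <- list()
  for (ch in chains) {
    if (!ch$eligible) next
    g <- pooled[gene_id == ch$gene_id]
    if (nrow(g) == 0L) next
    for (e in seq.int(2L, ch$n_exons - 1L)) {
      counts <- vapply(c("control", "kd"), function(cc) {
        gc <- g[condition == cc]
        c(inc_up = sum(gc[kind == "canonical" & downstream_exon == e, read_count]),
          inc_down = sum(gc[kind == "canonical" & upstream_exon == e, read_count]),
          exc = sum(gc[kind == "skip" & upstream_exon < e & downstream_exon > e, read_count]))
      }, numeric(3L))
      if (sum(counts) == 0) next
      psi_c <- compute_psi(counts["inc_up", "control"], counts["inc_down", "control"],
                           counts["exc", "control"])
      psi_k <- compute_psi(counts["inc_up", "kd"], counts["inc_down", "kd"],
                           counts["exc", "kd"])
      if (is.na(psi_c) || is.na(psi_k)) next
      tab <- rbind(
        control = c(inc = round((counts["inc_up", "control"] + counts["inc_down", "control"]) / 2),
                    exc = counts["exc", "control"]),
        kd = c(inc = round((counts["inc_up", "kd"] + counts["inc_down", "kd"]) / 2),
               exc = counts["exc", "kd"]))
      p <- if (all(rowSums(tab) > 0)) stats::fisher.test(tab)$p.value else 1
      rows[[length(rows) + 1L]] <- data.table::data.table(
        gene_id = ch$gene_id, exon_index = e,
        inc_control = tab["control", "inc"], exc_control = tab["control", "exc"],
        inc_kd = tab["kd", "inc"], exc_kd = tab["kd", "exc"],
        psi_control = psi_c, psi_kd = psi_k, delta_psi = psi_k - psi_c,
        p_value = p)
    }
  }
  if (!length(rows)) {
    warning("no testable exons")
    return(data.table::data.table(gene_id = character(), exon_index = integer(),
                                  inc_control = numeric(), exc_control = numeric(),
                                  inc_kd = numeric(), exc_kd = numeric(),
                                  psi_control = numeric(), psi_kd = numeric(),
                                  delta_psi = numeric(), p_value = numeric(),
                                  fdr = numeric(), significant = logical()))
  }
  calls <- data.table::rbindlist(rows)
  calls[, fdr := stats::p.adjust(p_value, method = "BH")]
  calls[, significant := abs(delta_psi) > dpsi_min & fdr < fdr_max]
  calls[]
}
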