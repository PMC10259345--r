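# EJC occupancy ratio statistic and its bootstrap null.
#
# The statistic: for an exon-skipping event, the crosslink count of the exon
# upstream of the skipped exon(s), divided by the gene's internal-exon mean
# crosslink count (exons 2..n-1; first and last exons are excluded because
# their apparent skipping is usually driven by other events). The observed
# mean ratio over events is compared with B resampled means of randomly
# selected pool exons, giving a two-tailed empirical p-value.

#' Load exon-level EJC occupancy
#'
#' Reads a TSV with columns `gene_id`, `exon_index`, one or more crosslink
#' count columns and one or more RNA-seq count columns. Crosslink columns are
#' aggregated (summed) per exon — the convention for combining replicate
#' chemical-crosslink experiments — as are RNA-seq columns. Genes whose
#' RNA-seq counts are zero on every exon are dropped (no expression support),
#' as are genes with fewer than three exons (the ratio is undefined) and genes
#' absent from `chains` (with a warning).
#'
#' @param path Occupancy TSV.
#' @param chains Named list of `exon_chain`s keyed by gene id.
#' @param crosslink_cols,rnaseq_cols Column names; by default every column
#'   starting with `crosslink` / `rnaseq`.
#' @return `data.table` with gene_id, exon_index, crosslink, rnaseq, n_exons.
#' @export
load_occupancy <- function(path, chains, crosslink_cols = NULL, rnaseq_cols = NULL) {
  dt <- data.table::fread(path, sep = "\t")
  if (is.null(crosslink_cols)) crosslink_cols <- grep("^crosslink", names(dt), value = TRUE)
  if (is.null(rnaseq_cols)) rnaseq_cols <- grep("^rnaseq", names(dt), value = TRUE)
  if (!length(crosslink_cols) || !length(rnaseq_cols)) {
    stop("could not identify crosslink/rnaseq columns in ", path)
  }
  if (anyDuplicated(dt[, .(gene_id, exon_index)])) {
    stop("duplicate (gene, exon) rows in ", path)
  }
  dt[, crosslink := rowSums(.SD), .SDcols = crosslink_cols]
  dt[, rnaseq := rowSums(.SD), .SDcols = rnaseq_cols]
  out <- dt[, .(gene_id, exon_index = as.integer(exon_index), crosslink, rnaseq)]
  missing_genes <- setdiff(unique(out$gene_id), names(chains))
  if (length(missing_genes)) {
    warning("genes absent from chains skipped: ", paste(missing_genes, collapse = ", "))
    out <- out[!gene_id %in% missing_genes]
  }
  n_by_gene <- vapply(chains, `[[`, 0L, "n_exons")
  out[, n_exons := n_by_gene[gene_id]]
  if (any(out$exon_index < 1L | out$exon_index > out$n_exons)) {
    bad <- out[exon_index < 1L | exon_index > n_exons][1L]
    stop("exon_index ", bad$exon_index, " outside chain of gene ", bad$gene_id)
  }
  expressed <- out[, .(any_read = any(rnaseq > 0)), by = gene_id][any_read == TRUE, gene_id]
  out <- out[gene_id %in% expressed & n_exons >= 3L]
  data.table::setkey(out, gene_id, exon_index)
  out[]
}

#' Internal-exon mean
#'
#' Mean count over a gene's exons excluding the first and the last — the
#' denominator of the occupancy ratio.
#'
#' @param counts Numeric vector over exons 1..n in transcript orientation.
#' @return The mean of `counts[2..n-1]`, or `NA` when n < 3.
#' @export
internal_mean <- function(counts) {
  n <- length(counts)
  if (n < 3L) return(NA_real_)
  mean(counts[seq.int(2L, n - 1L)])
}

gene_internal_means <- function(occ) {
  occ[, .(internal_mean_v = internal_mean(crosslink[order(exon_index)]),
          n_exons = n_exons[1L]), by = gene_id]
}

#' Occupancy ratio of the exon upstream of a skip event
#'
#' For `offset = 1` the referenced exon is the event's upstream flanking exon;
#' for `offset = 2` the next exon 5'-ward. The ratio is that exon's crosslink
#' count over the gene's internal-exon mean. `NA` (the exclusion signal) when
#' the referenced exon would be exon 1 or further 5', or when the internal
#' mean is zero or undefined.
#'
#' @param event List/row with `gene_id` and `upstream_exon`.
#' @param occ Occupancy table from [load_occupancy()].
#' @param offset 1 (immediately upstream) or 2 (further upstream).
#' @return A single ratio, or `NA`.
#' @export
upstream_ratio <- function(event, occ, offset = 1L) {
  stopifnot(offset >= 1L)
  g <- occ[gene_id == event$gene_id]
  if (nrow(g) == 0L) return(NA_real_)
  ref <- event$upstream_exon - (offset - 1L)
  if (ref < 2L) return(NA_real_)
  im <- internal_mean(g[order(exon_index), crosslink])
  if (is.na(im) || im == 0) return(NA_real_)
  x <- g[exon_index == ref, crosslink]
  if (!length(x)) return(NA_real_)
  x / im
}

#' Upstream ratios for a table of events (vectorised)
#' @param events `data.table` with gene_id and upstream_exon (deduplicated or
#'   not).
#' @inheritParams upstream_ratio
#' @return Numeric vector of ratios aligned with `events` rows (`NA` where
#'   excluded).
#' @export
upstream_ratios <- function(events, occ, offset = 1L) {
  ims <- gene_internal_means(occ)
  ev <- data.table::as.data.table(events)[, .(gene_id, upstream_exon)]
  ev[, exon_index := upstream_exon - (offset - 1L)]
  ev <- merge(ev, ims, by = "gene_id", all.x = TRUE, sort = FALSE)
  ev <- merge(ev, occ[, .(gene_id, exon_index, crosslink)],
              by = c("gene_id", "exon_index"), all.x = TRUE, sort = FALSE)
  ifelse(ev$exon_index < 2L | is.na(ev$internal_mean_v) | ev$internal_mean_v == 0 |
           is.na(ev$crosslink),
         NA_real_, ev$crosslink / ev$internal_mean_v)
}

#' Observed mean upstream-occupancy ratio
#' @inheritParams upstream_ratios
#' @return List with `mean` (over non-`NA` ratios) and `m` (contributing
#'   events). Errors when no event contributes.
#' @export
observed_mean_ratio <- function(events, occ, offset = 1L) {
  r <- upstream_ratios(events, occ, offset)
  r <- r[!is.na(r)]
  if (!length(r)) stop("no events contribute a defined occupancy ratio at offset ", offset)
  list(mean = mean(r), m = length(r))
}

#' Resampling pool of exon occupancy ratios
#'
#' Each pool member is one exon's crosslink count divided by its own gene's
#' internal-exon mean; genes with internal mean 0 contribute nothing. The pool
#' defaults to internal exons (2..n-1), matching the domain of the statistic;
#' `"all_but_last"` and `"all"` are alternative compositions.
#'
#' @inheritParams upstream_ratio
#' @param pool Pool composition.
#' @return Numeric vector of ratios (the enumeration of possible draws).
#' @export
occupancy_pool <- function(occ, pool = c("internal", "all_but_last", "all")) {
  pool <- match.arg(pool)
  ims <- gene_internal_means(occ)
  x <- merge(occ, ims[, .(gene_id, internal_mean_v)], by = "gene_id", sort = FALSE)
  x <- x[!is.na(internal_mean_v) & internal_mean_v > 0]
  x <- switch(pool,
              internal = x[exon_index >= 2L & exon_index <= n_exons - 1L],
              all_but_last = x[exon_index <= n_exons - 1L],
              all = x)
  x[, crosslink / internal_mean_v]
}

#' Bootstrap null distribution of the mean occupancy ratio
#'
#' Each of the B replicates draws `m` exons uniformly with replacement from
#' the pool and records the mean of their within-gene occupancy ratios.
#'
#' @inheritParams occupancy_pool
#' @param m Exons per replicate (matched to the number of observed events so
#'   observed and null means are exchangeable under the null).
#' @param B Number of resamplings (default 100,000).
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used (callers that need one generator instance per run seed once
#'   themselves).
#' @return Numeric vector of B null mean ratios.
#' @export
bootstrap_null <- function(occ, m, B = 100000L, seed = NULL,
                           pool = c("internal", "all_but_last", "all")) {
  ratios <- if (is.numeric(occ)) occ else occupancy_pool(occ, match.arg(pool))
  if (!length(ratios)) stop("empty resampling pool")
  stopifnot(m >= 1L, B >= 1L)
  if (!is.null(seed)) set.seed(seed)
  out <- numeric(B)
  chunk <- max(1L, min(B, as.integer(ceiling(2e7 / m))))
  done <- 0L
  while (done < B) {
    nb <- min(chunk, B - done)
    draws <- matrix(sample(ratios, m * nb, replace = TRUE), nrow = m)
    out[(done + 1L):(done + nb)] <- colMeans(draws)
    done <- done + nb
  }
  out
}

#' Two-tailed empirical p-value
#'
#' Add-one-corrected empirical p:
#' `p = min(1, 2 * min((1 + #\{null >= obs\})/(B+1), (1 + #\{null <= obs\})/(B+1)))`,
#' so p is never exactly zero and is floored at `2/(B+1)`.
#'
#' @param observed Observed statistic.
#' @param null_vector Null replicate values.
#' @return p-value in `(0, 1]`.
#' @export
empirical_two_tailed_p <- function(observed, null_vector) {
  B <- length(null_vector)
  stopifnot(B >= 1L)
  up <- (1 + sum(null_vector >= observed)) / (B + 1)
  lo <- (1 + sum(null_vector <= observed)) / (B + 1)
  min(1, 2 * min(up, lo))
}

#' Run the EJC occupancy enrichment test
#'
#' For each offset (1 = exon immediately upstream of the skipped exon(s),
#' 2 = the next exon 5'-ward): deduplicates events on (gene, upstream exon) so
#' the same junction cannot contribute twice, computes the observed mean
#' ratio, draws a bootstrap null of means of randomly selected pool exons
#' (m matched to the observed event count), and reports the two-tailed
#' empirical p-value. A single RNG stream seeded once serves both offsets.
#'
#' @param events Event table with `gene_id` and `upstream_exon` columns
#'   (e.g. [tabulate_skip_events()] output).
#' @param occ Occupancy table from [load_occupancy()].
#' @param B Resamplings per offset (default 100,000).
#' @param seed Integer seed for the run.
#' @param offsets Offsets to test (default `c(1, 2)`).
#' @inheritParams occupancy_pool
#' @param keep_null Attach the null vectors (as attribute `"null"`, a list by
#'   offset) for plotting.
#' @return `data.table` with one row per offset: offset, m_events,
#'   observed_mean_ratio, null_mean, null_sd, B, p_two_tailed, seed.
#' @export
run_ejc_test <- function(events, occ, B = 100000L, seed = 1L, offsets = c(1L, 2L),
                         pool = c("internal", "all_but_last", "all"),
                         keep_null = FALSE) {
  pool <- match.arg(pool)
  ev <- unique(data.table::as.data.table(events)[, .(gene_id, upstream_exon)])
  if (nrow(ev) == 0L) stop("no events supplied")
  ratios <- occupancy_pool(occ, pool)
  if (!length(ratios)) stop("empty resampling pool")
  set.seed(seed)
  nulls <- list()
  rows <- lapply(offsets, function(off) {
    obs <- observed_mean_ratio(ev, occ, off)
    nv <- bootstrap_null(ratios, m = obs$m, B = B, seed = NULL)
    if (keep_null) nulls[[as.character(off)]] <<- nv
    data.table::data.table(
      offset = off, m_events = obs$m, observed_mean_ratio = obs$mean,
      null_mean = mean(nv), null_sd = stats::sd(nv), B = B,
      p_two_tailed = empirical_two_tailed_p(obs$mean, nv), seed = seed)
  })
  res <- data.table::rbindlist(rows)
  if (keep_null) data.table::setattr(res, "null", nulls)
  res[]
}
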