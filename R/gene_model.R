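# Gene models: GTF parsing, reference-transcript selection, exon chains.
#
# Coordinates are 0-based half-open internally; GTF's 1-based inclusive
# convention is converted at the parser boundary.

#' Construct a transcript model
#'
#' A transcript model is a gene's transcript as an ordered set of exons on one
#' strand, with optional CDS boundaries. Exons are stored genomically
#' ascending; transcript orientation is resolved later by
#' [build_exon_chain()].
#'
#' @param gene_id,transcript_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons A data.frame with columns `start`, `end` (0-based half-open).
#'   Overlapping exons are merged with a warning.
#' @param cds_start,cds_end Optional genomic CDS span (0-based half-open), or
#'   `NA` for non-coding transcripts.
#' @param is_mane Logical; whether the annotation tags this transcript as the
#'   MANE Select reference.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(gene_id, transcript_id, chrom, strand, exons,
                             cds_start = NA_integer_, cds_end = NA_integer_,
                             is_mane = FALSE) {
  stopifnot(strand %in% c("+", "-"), nrow(exons) >= 1)
  ex <- data.table::as.data.table(exons)[, .(start = as.integer(start), end = as.integer(end))]
  if (any(ex$start >= ex$end)) stop("exon with start >= end in transcript ", transcript_id)
  data.table::setorder(ex, start)
  ex <- unique(ex)
  # merge overlapping / bookended-overlapping exons (messy annotations)
  if (nrow(ex) > 1L && any(ex$start[-1L] < cummax(ex$end)[-nrow(ex)])) {
    warning("overlapping exons merged in transcript ", transcript_id)
    grp <- cumsum(c(TRUE, ex$start[-1L] >= cummax(ex$end)[-nrow(ex)]))
    ex <- ex[, .(start = min(start), end = max(end)), by = .(grp)][, grp := NULL][]
  }
  if (!is.na(cds_start) && !is.na(cds_end)) {
    covered <- any(ex$start <= cds_start & cds_start < ex$end) &&
      any(ex$start < cds_end & cds_end <= ex$end)
    if (!covered) stop("CDS boundaries outside exon union in transcript ", transcript_id)
  }
  structure(
    list(gene_id = gene_id, transcript_id = transcript_id, chrom = chrom,
         strand = strand, exons = ex,
         cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
         is_mane = isTRUE(is_mane)),
    class = "transcript_model")
}

#' Load transcript models from a GTF annotation
#'
#' Parses an Ensembl/GENCODE-dialect GTF into one [transcript_model()] per
#' transcript. Exons are deduplicated and sorted; the CDS span is the union of
#' CDS records; MANE status is read from `tag "MANE_Select"` attributes.
#'
#' @param path Path to a GTF file.
#' @param dialect Annotation dialect; only `"gtf"` is supported.
#' @return A list of `transcript_model` objects (empty for an empty file).
#' @export
load_annotation <- function(path, dialect = "gtf") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  body <- which(!grepl("^#", raw) & nzchar(trimws(raw)))
  if (length(body) == 0L) return(list())
  nf <- lengths(strsplit(raw[body], "\t", fixed = TRUE))
  if (any(nf < 9L)) {
    stop("malformed GTF record at line ", body[which(nf < 9L)[1L]],
         " of ", path, " (expected 9 tab-separated fields)")
  }
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop("failed to parse GTF ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  md <- as.data.frame(gr)
  needed <- c("type", "gene_id", "transcript_id")
  if (!all(needed %in% names(md))) {
    stop("GTF ", path, " lacks required attributes: ",
         paste(setdiff(needed, names(md)), collapse = ", "))
  }
  if (!"tag" %in% names(md)) md$tag <- NA_character_
  md <- md[md$type %in% c("transcript", "exon", "CDS") & !is.na(md$transcript_id), , drop = FALSE]
  # to 0-based half-open
  md$start0 <- md$start - 1L
  md$end0 <- md$end
  out <- list()
  for (tid in unique(md$transcript_id)) {
    rec <- md[md$transcript_id == tid, , drop = FALSE]
    ex <- rec[rec$type == "exon", , drop = FALSE]
    if (nrow(ex) == 0L) next
    tr <- rec[rec$type == "transcript", , drop = FALSE]
    if (nrow(tr) == 1L &&
        (min(ex$start0) < tr$start0 || max(ex$end0) > tr$end0)) {
      stop("exon outside declared transcript span for transcript ", tid)
    }
    cds <- rec[rec$type == "CDS", , drop = FALSE]
    is_mane <- any(grepl("MANE_Select", rec$tag, fixed = TRUE), na.rm = TRUE)
    out[[tid]] <- transcript_model(
      gene_id = ex$gene_id[1L], transcript_id = tid,
      chrom = as.character(ex$seqnames[1L]), strand = as.character(ex$strand[1L]),
      exons = data.frame(start = ex$start0, end = ex$end0),
      cds_start = if (nrow(cds)) min(cds$start0) else NA_integer_,
      cds_end = if (nrow(cds)) max(cds$end0) else NA_integer_,
      is_mane = is_mane)
  }
  unname(out)
}

cds_length <- function(t) {
  if (is.na(t$cds_start) || is.na(t$cds_end)) return(0L)
  sum(pmax(0L, pmin(t$exons$end, t$cds_end) - pmax(t$exons$start, t$cds_start)))
}

#' Select the reference transcript of a gene
#'
#' Follows the MANE-reference convention: if exactly one transcript is MANE
#' (tagged in the annotation, or listed in `mane_ids`), it is the reference.
#' Otherwise the transcript with the longest CDS wins (longest exonic span if
#' no transcript has a CDS), ties broken by the lexicographically smallest
#' transcript id.
#'
#' @param transcripts Non-empty list of `transcript_model`s of one gene.
#' @param mane_ids Optional character vector of MANE transcript ids (version
#'   suffixes ignored).
#' @return A single `transcript_model`.
#' @export
select_reference <- function(transcripts, mane_ids = NULL) {
  if (length(transcripts) == 0L) stop("no transcripts supplied")
  strip_ver <- function(x) sub("\\.\\d+$", "", x)
  ids <- vapply(transcripts, `[[`, "", "transcript_id")
  mane <- vapply(transcripts, `[[`, FALSE, "is_mane")
  if (!is.null(mane_ids)) mane <- mane | strip_ver(ids) %in% strip_ver(mane_ids)
  if (sum(mane) > 1L) {
    stop("ambiguous reference: ", sum(mane), " MANE transcripts for gene ",
         transcripts[[1L]]$gene_id)
  }
  if (sum(mane) == 1L) return(transcripts[[which(mane)]])
  key_cds <- vapply(transcripts, cds_length, 0L)
  key <- if (all(key_cds == 0L)) {
    vapply(transcripts, function(t) sum(t$exons$end - t$exons$start), 0L)
  } else key_cds
  best <- which(key == max(key))
  transcripts[[best[order(ids[best])][1L]]]
}

#' Build a strand-oriented exon chain
#'
#' Reindexes a transcript's exons in transcript (5' to 3') orientation: exon 1
#' is the 5'-most exon, which on the minus strand is the genomically last
#' interval. The chain is the coordinate frame for junction classification,
#' occupancy ratios and consequence calling. A gene is `eligible` for skipping
#' analyses when it has at least three exons.
#'
#' @param t A `transcript_model`.
#' @return An object of class `exon_chain` with an `exons` table carrying
#'   `exon_index`, genomic `start`/`end` and `len` per exon.
#' @export
build_exon_chain <- function(t) {
  stopifnot(inherits(t, "transcript_model"))
  ex <- data.table::copy(t$exons)
  if (t$strand == "-") ex <- ex[rev(seq_len(nrow(ex)))]
  ex[, `:=`(exon_index = seq_len(.N), len = end - start)]
  data.table::setcolorder(ex, c("exon_index", "start", "end", "len"))
  structure(
    list(gene_id = t$gene_id, transcript_id = t$transcript_id,
         chrom = t$chrom, strand = t$strand, n_exons = nrow(ex),
         exons = ex[], cds_start = t$cds_start, cds_end = t$cds_end,
         eligible = nrow(ex) >= 3L),
    class = "exon_chain")
}

#' @export
print.exon_chain <- function(x, ...) {
  cat(sprintf("<exon_chain> %s/%s %s(%s) %d exons%s%s\n",
              x$gene_id, x$transcript_id, x$chrom, x$strand, x$n_exons,
              if (x$eligible) ", eligible" else "",
              if (!is.na(x$cds_start)) sprintf(", CDS [%d,%d)", x$cds_start, x$cds_end) else ""))
  invisible(x)
}

#' Keep genes with at least `min_exons` exons
#'
#' @param chains List of `exon_chain`s.
#' @param min_exons Minimum exon count (default 3, the standard eligibility
#'   gate for skipped-exon analyses: a skip needs an internal exon).
#' @return The eligible chains, input order preserved.
#' @export
filter_eligible_genes <- function(chains, min_exons = 3L) {
  if (min_exons < 1L) stop("min_exons must be >= 1")
  chains[vapply(chains, function(ch) ch$n_exons >= min_exons, FALSE)]
}

#' Write / read exon chains as TSV
#'
#' One row per exon: gene_id, transcript_id, chrom, strand, exon_index, start,
#' end, plus the genomic CDS span repeated per row (`NA` when non-coding).
#' `read_exon_chains()` inverts `write_exon_chains()` field-by-field.
#'
#' @param chains List of `exon_chain`s.
#' @param path Output TSV path.
#' @return `write_exon_chains()` returns `path` invisibly;
#'   `read_exon_chains()` returns a list of `exon_chain`s.
#' @export
write_exon_chains <- function(chains, path) {
  rows <- data.table::rbindlist(lapply(chains, function(ch) {
    data.table::data.table(
      gene_id = ch$gene_id, transcript_id = ch$transcript_id,
      chrom = ch$chrom, strand = ch$strand,
      exon_index = ch$exons$exon_index, start = ch$exons$start, end = ch$exons$end,
      cds_start = ch$cds_start, cds_end = ch$cds_end)
  }))
  data.table::fwrite(rows, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_exon_chains
#' @export
read_exon_chains <- function(path) {
  dt <- data.table::fread(path, sep = "\t", na.strings = "NA")
  lapply(split(dt, by = "transcript_id", sorted = FALSE), function(d) {
    data.table::setorder(d, exon_index)
    ex <- d[, .(exon_index, start = as.integer(start), end = as.integer(end))]
    ex[, len := end - start]
    data.table::setcolorder(ex, c("exon_index", "start", "end", "len"))
    structure(
      list(gene_id = d$gene_id[1L], transcript_id = d$transcript_id[1L],
           chrom = as.character(d$chrom[1L]), strand = d$strand[1L],
           n_exons = nrow(ex), exons = ex[],
           cds_start = as.integer(d$cds_start[1L]), cds_end = as.integer(d$cds_end[1L]),
           eligible = nrow(ex) >= 3L),
      class = "exon_chain")
  })
}

#' Reference exon chains for every gene in an annotation
#'
#' Convenience wrapper: load the GTF, pick one reference transcript per gene,
#' build chains, and (optionally) drop genes with fewer than `min_exons`
#' exons.
#'
#' @inheritParams load_annotation
#' @inheritParams select_reference
#' @inheritParams filter_eligible_genes
#' @param eligible_only Drop ineligible genes (default `TRUE`).
#' @return Named list of `exon_chain`s, keyed by gene id.
#' @export
reference_chains <- function(path, mane_ids = NULL, min_exons = 3L,
                             eligible_only = TRUE) {
  models <- load_annotation(path)
  by_gene <- split(models, vapply(models, `[[`, "", "gene_id"))
  chains <- lapply(by_gene, function(ts) build_exon_chain(select_reference(ts, mane_ids)))
  if (eligible_only) chains <- filter_eligible_genes(chains, min_exons)
  chains
}
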