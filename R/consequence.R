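# Protein-level consequences of multi-exon skipping: reading-frame status,
# premature termination codons (PTC), and per-domain partial/total loss.
#
# Domain coordinates always refer to the ORIGINAL annotated protein; losses
# are mapped back onto it, never forward onto the mutant.

#' CDS coverage of each exon, in transcript orientation
#'
#' For a coding chain, returns per exon the number of coding nucleotides and
#' the exon's offset within the CDS (0-based, transcript orientation).
#'
#' @param chain A coding `exon_chain` (non-`NA` `cds_start`/`cds_end`).
#' @return `data.table`: exon_index, cds_len, cds_off.
#' @export
cds_segments <- function(chain) {
  if (is.na(chain$cds_start) || is.na(chain$cds_end)) {
    stop("chain ", chain$gene_id, " has no CDS")
  }
  ex <- chain$exons
  clen <- pmax(0L, pmin(ex$end, chain$cds_end) - pmax(ex$start, chain$cds_start))
  data.table::data.table(exon_index = ex$exon_index, cds_len = clen,
                         cds_off = cumsum(c(0L, clen[-length(clen)])))
}

#' Coding nucleotides removed by skipping a set of exons
#'
#' Total length of the intersection between the skipped exons and the CDS
#' interval, in transcript orientation. Zero for UTR-only skips.
#'
#' @param chain A coding `exon_chain`.
#' @param skipped Integer exon indices (transcript orientation).
#' @return Non-negative integer nucleotide count.
#' @export
skipped_cds_span <- function(chain, skipped) {
  if (any(skipped < 1L | skipped > chain$n_exons)) {
    stop("skipped exon index outside chain (n_exons = ", chain$n_exons, ")")
  }
  seg <- cds_segments(chain)
  sum(seg[exon_index %in% skipped, cds_len])
}

#' Reading-frame effect of a skipped coding span
#' @param skipped_cds_nt Coding nucleotides removed.
#' @return `"none"` (0 nt), `"in_frame"` (multiple of 3) or `"frameshift"`.
#' @export
frame_effect <- function(skipped_cds_nt) {
  stopifnot(skipped_cds_nt >= 0)
  if (skipped_cds_nt == 0) "none"
  else if (skipped_cds_nt %% 3 == 0) "in_frame"
  else "frameshift"
}

mutant_cds <- function(cds_sequence, chain, skipped) {
  s <- toupper(as.character(cds_sequence))
  seg <- cds_segments(chain)
  if (nchar(s) != sum(seg$cds_len)) {
    stop("CDS sequence length (", nchar(s), ") does not match chain CDS length (",
         sum(seg$cds_len), ")")
  }
  if (nchar(s) %% 3 != 0) stop("CDS length not a multiple of 3")
  del <- seg[exon_index %in% skipped & cds_len > 0L]
  keep <- rep(TRUE, nchar(s))
  for (i in seq_len(nrow(del))) {
    keep[(del$cds_off[i] + 1L):(del$cds_off[i] + del$cds_len[i])] <- FALSE
  }
  list(mutant = paste(strsplit(s, "")[[1L]][keep], collapse = ""),
       first_deleted = if (nrow(del)) min(del$cds_off) + 1L else NA_integer_,
       deleted_nt = sum(del$cds_len),
       stop_deleted = any(!keep[(nchar(s) - 2L):nchar(s)]))
}

translate_codons <- function(s) {
  n <- nchar(s) %/% 3
  if (n == 0L) return(character())
  ss <- substr(s, 1L, 3L * n)
  if (grepl("[^ACGT]", ss)) stop("invalid base in CDS sequence")
  strsplit(as.character(Biostrings::translate(Biostrings::DNAString(ss))), "")[[1L]]
}

#' Detect a premature termination codon after exon skipping
#'
#' Splices the CDS by deleting the coding span of the skipped exons,
#' translates from the original start codon, and reports the first in-frame
#' stop in the mutant reading frame. The stop is premature iff it appears
#' strictly before the position homologous to the annotated stop codon (for
#' frameshifts, or when the annotated stop itself is deleted, any stop
#' encountered is premature).
#'
#' @param cds_sequence Character or `DNAString`: the full annotated CDS
#'   including the stop codon; length must be a multiple of 3, end in a stop,
#'   and match the chain's CDS length.
#' @param chain A coding `exon_chain`.
#' @param skipped Skipped exon indices.
#' @return List: `has_ptc`, `ptc_codon` (position in the mutant frame, `NA`
#'   when none), `mutant_aa` (translated mutant up to and excluding the first
#'   stop).
#' @export
detect_ptc <- function(cds_sequence, chain, skipped) {
  mc <- mutant_cds(cds_sequence, chain, skipped)
  orig_aa <- translate_codons(toupper(as.character(cds_sequence)))
  if (orig_aa[length(orig_aa)] != "*") stop("CDS does not end in a stop codon")
  if (any(orig_aa[-length(orig_aa)] == "*")) stop("internal stop codon in annotated CDS")
  if (mc$deleted_nt == 0L) {
    return(list(has_ptc = FALSE, ptc_codon = NA_integer_,
                mutant_aa = paste(orig_aa[-length(orig_aa)], collapse = "")))
  }
  aa <- translate_codons(mc$mutant)
  stop_at <- which(aa == "*")
  first_stop <- if (length(stop_at)) stop_at[1L] else NA_integer_
  in_frame <- mc$deleted_nt %% 3 == 0
  L <- nchar(as.character(cds_sequence))
  homolog <- if (in_frame && !mc$stop_deleted) (L - mc$deleted_nt) / 3 else Inf
  has_ptc <- !is.na(first_stop) && first_stop < homolog
  list(has_ptc = has_ptc,
       ptc_codon = if (has_ptc) first_stop else NA_integer_,
       mutant_aa = paste(aa[seq_len(if (length(stop_at)) stop_at[1L] - 1L else length(aa))],
                         collapse = ""))
}

#' Per-domain impact of lost protein regions
#'
#' A domain is `total`ly lost when its span is fully covered by the union of
#' lost intervals and (when a truncation applies) the suffix
#' `[truncation_from, Inf)`; `partial` when properly overlapped; `none`
#' otherwise. All coordinates are 1-based inclusive positions of the original
#' protein.
#'
#' @param domains `data.frame` with `domain_name`, `aa_start`, `aa_end`.
#' @param lost_aa_intervals `data.frame`/`data.table` with `aa_start`,
#'   `aa_end` of regions deleted from the original protein (may be empty).
#' @param truncation_from Optional first original-protein position from which
#'   everything downstream is lost (frameshift or PTC).
#' @return `data.table`: domain_name, effect (`none`/`partial`/`total`).
#' @export
domain_impact <- function(domains, lost_aa_intervals, truncation_from = NA_integer_) {
  dm <- data.table::as.data.table(domains)
  li <- data.table::as.data.table(lost_aa_intervals)
  if (nrow(dm) == 0L) {
    return(data.table::data.table(domain_name = character(), effect = character()))
  }
  eff <- vapply(seq_len(nrow(dm)), function(i) {
    pos <- seq.int(dm$aa_start[i], dm$aa_end[i])
    lost <- rep(FALSE, length(pos))
    for (j in seq_len(nrow(li))) {
      lost <- lost | (pos >= li$aa_start[j] & pos <= li$aa_end[j])
    }
    if (!is.na(truncation_from)) lost <- lost | pos >= truncation_from
    if (all(lost)) "total" else if (any(lost)) "partial" else "none"
  }, "")
  data.table::data.table(domain_name = dm$domain_name, effect = eff)
}

# aa intervals (original protein) covered by the deleted CDS span(s)
lost_aa_from_deletion <- function(chain, skipped, protein_len) {
  seg <- cds_segments(chain)
  del <- seg[exon_index %in% skipped & cds_len > 0L]
  if (nrow(del) == 0L) {
    return(data.table::data.table(aa_start = integer(), aa_end = integer()))
  }
  iv <- del[, .(aa_start = pmin(protein_len, cds_off %/% 3L + 1L),
                aa_end = pmin(protein_len, (cds_off + cds_len - 1L) %/% 3L + 1L))]
  iv[aa_start <= aa_end][order(aa_start)]
}

#' Classify the consequence of a skip event
#'
#' Composes [skipped_cds_span()], [frame_effect()], [detect_ptc()] and
#' [domain_impact()] into one call. The lost amino-acid intervals are the
#' original-protein positions whose codons intersect the deleted coding span;
#' when the event truncates the protein (frameshift, or an in-frame PTC at
#' the new exon junction), every position from the first affected codon
#' onward is treated as lost.
#'
#' @param event List/row with `upstream_exon` and `downstream_exon` (and
#'   optionally `gene_id`).
#' @param chain A coding `exon_chain`.
#' @param cds_sequence Annotated CDS (with stop codon).
#' @param domains Domain table (`domain_name`, `aa_start`, `aa_end`) of the
#'   original protein; may be empty.
#' @return An object of class `consequence_call`: gene_id, skipped exon
#'   indices, skipped_cds_nt, frame, ptc_codon, domain_effects.
#' @export
classify_consequence <- function(event, chain, cds_sequence, domains) {
  skipped <- skipped_exons(event$upstream_exon, event$downstream_exon)
  if (!length(skipped)) stop("event skips no exons")
  nt <- skipped_cds_span(chain, skipped)
  frame <- frame_effect(nt)
  protein_len <- nchar(as.character(cds_sequence)) / 3 - 1L
  if (frame == "none") {
    ptc <- list(has_ptc = FALSE, ptc_codon = NA_integer_)
    lost <- data.table::data.table(aa_start = integer(), aa_end = integer())
    trunc_from <- NA_integer_
  } else {
    ptc <- detect_ptc(cds_sequence, chain, skipped)
    lost <- lost_aa_from_deletion(chain, skipped, protein_len)
    trunc_from <- if (frame == "frameshift" || ptc$has_ptc) min(lost$aa_start)
    else NA_integer_
  }
  structure(
    list(gene_id = chain$gene_id,
         upstream_exon = event$upstream_exon, downstream_exon = event$downstream_exon,
         skipped = skipped, k_skipped = length(skipped), skipped_cds_nt = nt,
         frame = frame, ptc_codon = ptc$ptc_codon,
         domain_effects = domain_impact(domains, lost, trunc_from)),
    class = "consequence_call")
}

#' @export
print.consequence_call <- function(x, ...) {
  cat(sprintf("<consequence_call> %s skip exons %s: %d coding nt, %s%s\n",
              x$gene_id, paste(x$skipped, collapse = ","), x$skipped_cds_nt, x$frame,
              if (!is.na(x$ptc_codon)) sprintf(", PTC at mutant codon %d", x$ptc_codon) else ""))
  if (nrow(x$domain_effects)) print(x$domain_effects)
  invisible(x)
}

#' Consequence calls for a table of events
#'
#' @param events Skip-event table (`gene_id`, `upstream_exon`,
#'   `downstream_exon`; deduplicated here).
#' @param chains Named list of coding `exon_chain`s.
#' @param cds_seqs Named character vector / `DNAStringSet` of CDS sequences
#'   keyed by transcript id (or gene id).
#' @param domains Domain table with a `protein_id` column matching transcript
#'   (or gene) ids.
#' @return `data.table`, one row per event x domain (plus one row with
#'   domain `NA` for events in genes without domains): gene_id, skipped,
#'   k_skipped, skipped_cds_nt, frame, ptc_codon, domain_name, effect.
#' @export
classify_consequences <- function(events, chains, cds_seqs, domains) {
  ev <- unique(data.table::as.data.table(events)[, .(gene_id, upstream_exon, downstream_exon)])
  dm <- data.table::as.data.table(domains)
  seq_names <- names(cds_seqs)
  rows <- lapply(seq_len(nrow(ev)), function(i) {
    ch <- chains[[ev$gene_id[i]]]
    if (is.null(ch)) return(NULL)
    key <- if (ch$transcript_id %in% seq_names) ch$transcript_id else ch$gene_id
    if (!key %in% seq_names) return(NULL)
    gd <- dm[dm$protein_id %in% c(ch$transcript_id, ch$gene_id),
             .(domain_name, aa_start, aa_end)]
    call <- classify_consequence(ev[i], ch, as.character(cds_seqs[[key]]), gd)
    base <- data.table::data.table(
      gene_id = call$gene_id,
      skipped = paste(call$skipped, collapse = ","), k_skipped = call$k_skipped,
      skipped_cds_nt = call$skipped_cds_nt, frame = call$frame,
      ptc_codon = call$ptc_codon)
    if (nrow(call$domain_effects)) {
      cbind(base, call$domain_effects)
    } else {
      cbind(base, data.table::data.table(domain_name = NA_character_,
                                         effect = NA_character_))
    }
  })
  data.table::rbindlist(rows)
}
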