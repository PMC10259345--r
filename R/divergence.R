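# Paralog divergence: global pairwise identity (protein and CDS) and
# Nei-Gojobori (1986) dN/dS with Jukes-Cantor correction.

#' Global pairwise alignment
#'
#' Needleman-Wunsch global alignment with affine gaps, via
#' `Biostrings::pairwiseAlignment`. Defaults: BLOSUM62 for protein; +5/-4
#' match/mismatch for nucleotide; gap opening 10, gap extension 0.5 (penalty
#' magnitudes).
#'
#' @param a,b Sequences (character or XString).
#' @param mode `"protein"` or `"nucleotide"`.
#' @param gap_open,gap_extend Affine gap penalties (positive magnitudes).
#' @param matrix Optional substitution matrix overriding the mode default.
#' @return An object of class `pairwise_alignment`: `aligned_a`, `aligned_b`
#'   (equal-length gapped strings), `mode`, `score`.
#' @export
global_align <- function(a, b, mode = c("protein", "nucleotide"),
                         gap_open = 10, gap_extend = 0.5, matrix = NULL) {
  mode <- match.arg(mode)
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  alphabet <- if (mode == "protein") "ACDEFGHIKLMNPQRSTVWY*" else "ACGT"
  bad <- grepl(sprintf("[^%s]", gsub("\\*", "\\\\*", alphabet)), c(a, b))
  if (any(bad)) stop("invalid characters for ", mode, " sequence")
  if (is.null(matrix)) {
    matrix <- if (mode == "protein") {
      get(utils::data("BLOSUM62", package = "Biostrings", envir = environment()))
    } else {
      Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4, baseOnly = TRUE)
    }
  }
  xa <- if (mode == "protein") Biostrings::AAString(a) else Biostrings::DNAString(a)
  xb <- if (mode == "protein") Biostrings::AAString(b) else Biostrings::DNAString(b)
  pa <- Biostrings::pairwiseAlignment(xa, xb, type = "global",
                                      substitutionMatrix = matrix,
                                      gapOpening = gap_open, gapExtension = gap_extend)
  out <- structure(
    list(aligned_a = as.character(Biostrings::alignedPattern(pa)),
         aligned_b = as.character(Biostrings::alignedSubject(pa)),
         mode = mode, score = Biostrings::score(pa)),
    class = "pairwise_alignment")
  stopifnot(gsub("-", "", out$aligned_a) == a, gsub("-", "", out$aligned_b) == b)
  out
}

#' Percent identity of a pairwise alignment
#'
#' `100 * matches / denominator`, where a match is a column with identical
#' non-gap residues. The default denominator counts only columns where
#' neither sequence is gapped; `"alignment_length"` divides by the full
#' alignment length instead.
#'
#' @param aln A `pairwise_alignment`.
#' @param denominator Denominator convention.
#' @return Percentage in `[0, 100]`.
#' @export
percent_identity <- function(aln,
                             denominator = c("aligned_columns_excluding_gaps",
                                             "alignment_length")) {
  denominator <- match.arg(denominator)
  ca <- strsplit(aln$aligned_a, "")[[1L]]
  cb <- strsplit(aln$aligned_b, "")[[1L]]
  nongap <- ca != "-" & cb != "-"
  matches <- sum(nongap & ca == cb)
  den <- if (denominator == "alignment_length") length(ca) else sum(nongap)
  if (den == 0L) stop("zero denominator: alignment has no aligned columns")
  100 * matches / den
}

split_codons <- function(cds) {
  n <- nchar(cds)
  substring(cds, 3L * seq_len(n %/% 3L) - 2L, 3L * seq_len(n %/% 3L))
}

translate1 <- function(codon) {
  as.character(Biostrings::GENETIC_CODE[codon])
}

#' Back-translate a protein alignment into a codon alignment
#'
#' Maps each aligned residue column to its source codon (residue gaps become
#' `---` codon gaps). Terminal stop codons on the CDSs are trimmed; every
#' codon must translate to its aligned residue.
#'
#' @param protein_aln A `pairwise_alignment` with `mode == "protein"`.
#' @param cds_a,cds_b CDS sequences (character or DNAString), with or without
#'   the terminal stop codon.
#' @return An object of class `codon_alignment`: `codons_a`, `codons_b`
#'   (character vectors, one codon or `"---"` per column).
#' @export
back_translate_alignment <- function(protein_aln, cds_a, cds_b) {
  stopifnot(inherits(protein_aln, "pairwise_alignment"), protein_aln$mode == "protein")
  prep <- function(cds, aligned, label) {
    cds <- toupper(as.character(cds))
    if (nchar(cds) %% 3 != 0) stop("CDS ", label, " length not a multiple of 3")
    codons <- split_codons(cds)
    aa <- translate1(codons)
    if (any(is.na(aa))) stop("invalid codon in CDS ", label)
    if (aa[length(aa)] == "*") { codons <- codons[-length(codons)]; aa <- aa[-length(aa)] }
    if (any(aa == "*")) stop("internal stop codon in CDS ", label)
    prot <- gsub("-", "", aligned)
    if (length(codons) != nchar(prot)) {
      stop("CDS ", label, " encodes ", length(codons), " residues but protein has ",
           nchar(prot))
    }
    if (!identical(paste(aa, collapse = ""), prot)) {
      i <- which(aa != strsplit(prot, "")[[1L]])[1L]
      stop("CDS ", label, " translation mismatch at codon ", i)
    }
    codons
  }
  codons_a <- prep(cds_a, protein_aln$aligned_a, "a")
  codons_b <- prep(cds_b, protein_aln$aligned_b, "b")
  ca <- strsplit(protein_aln$aligned_a, "")[[1L]]
  cb <- strsplit(protein_aln$aligned_b, "")[[1L]]
  ia <- ib <- 0L
  out_a <- out_b <- character(length(ca))
  for (i in seq_along(ca)) {
    out_a[i] <- if (ca[i] == "-") "---" else { ia <- ia + 1L; codons_a[ia] }
    out_b[i] <- if (cb[i] == "-") "---" else { ib <- ib + 1L; codons_b[ib] }
  }
  structure(list(codons_a = out_a, codons_b = out_b), class = "codon_alignment")
}

# Synonymous site fraction of one codon: per position, the fraction of the 3
# single-nucleotide changes that preserve the amino acid (changes to stop
# codons count as nonsynonymous).
ng86_sites <- function(codon) {
  aa <- translate1(codon)
  if (is.na(aa) || aa == "*") stop("cannot count sites of codon ", codon)
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    for (nt in setdiff(bases, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- nt
      if (identical(translate1(mut), aa)) s <- s + 1 / 3
    }
  }
  c(syn = s, nonsyn = 3 - s)
}

# Synonymous/nonsynonymous differences between two codons, averaged over all
# shortest mutational pathways; pathways through stop codons are excluded
# (all pathways are used if every one is blocked).
ng86_differences <- function(codon_a, codon_b) {
  diff_pos <- which(strsplit(codon_a, "")[[1L]] != strsplit(codon_b, "")[[1L]])
  if (!length(diff_pos)) return(c(syn = 0, nonsyn = 0))
  paths <- if (length(diff_pos) == 1L) list(diff_pos) else {
    perms <- function(v) {
      if (length(v) == 1L) return(list(v))
      do.call(c, lapply(seq_along(v), function(i) {
        lapply(perms(v[-i]), function(p) c(v[i], p))
      }))
    }
    perms(diff_pos)
  }
  walk <- function(order) {
    cur <- codon_a
    sd <- nd <- 0
    blocked <- FALSE
    for (pos in order) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(codon_b, pos, pos)
      aa_cur <- translate1(cur); aa_nxt <- translate1(nxt)
      if (identical(aa_nxt, "*") && nxt != codon_b) blocked <- TRUE
      if (identical(aa_cur, aa_nxt)) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    list(sd = sd, nd = nd, blocked = blocked)
  }
  res <- lapply(paths, walk)
  ok <- !vapply(res, `[[`, FALSE, "blocked")
  use <- if (any(ok)) res[ok] else res
  c(syn = mean(vapply(use, `[[`, 0, "sd")),
    nonsyn = mean(vapply(use, `[[`, 0, "nd")))
}

#' Nei-Gojobori (1986) dN/dS
#'
#' Counting method with Jukes-Cantor correction over the gapless codon
#' columns of a codon alignment: synonymous/nonsynonymous sites are averaged
#' between the two sequences; differences between unequal codons are averaged
#' over all shortest mutational pathways (pathways through stop codons
#' excluded); `pN = Nd/N`, `pS = Sd/S`;
#' `d = -3/4 * log(1 - 4p/3)`; `omega = dN/dS` (`NA` when `dS = 0`).
#'
#' @param codon_aln A `codon_alignment` (or list with `codons_a`/`codons_b`).
#' @return List: dN, dS, omega, plus the raw counts S, N, Sd, Nd.
#' @export
ng86_dnds <- function(codon_aln) {
  keep <- codon_aln$codons_a != "---" & codon_aln$codons_b != "---"
  ca <- codon_aln$codons_a[keep]
  cb <- codon_aln$codons_b[keep]
  if (!length(ca)) stop("no countable (gapless) codon columns")
  sites_a <- vapply(ca, ng86_sites, numeric(2L))
  sites_b <- vapply(cb, ng86_sites, numeric(2L))
  S <- (sum(sites_a["syn", ]) + sum(sites_b["syn", ])) / 2
  N <- (sum(sites_a["nonsyn", ]) + sum(sites_b["nonsyn", ])) / 2
  diffs <- vapply(seq_along(ca), function(i) ng86_differences(ca[i], cb[i]), numeric(2L))
  Sd <- sum(diffs["syn", ]); Nd <- sum(diffs["nonsyn", ])
  jc <- function(p) {
    if (p >= 0.75) stop("proportion of differences ", signif(p, 3),
                        " >= 0.75: Jukes-Cantor correction undefined")
    -0.75 * log(1 - 4 * p / 3)
  }
  dS <- if (S > 0) jc(Sd / S) else NA_real_
  dN <- if (N > 0) jc(Nd / N) else NA_real_
  omega <- if (!is.na(dS) && dS > 0) dN / dS else NA_real_
  list(dN = dN, dS = dS, omega = omega, S = S, N = N, Sd = Sd, Nd = Nd)
}

#' Paralog divergence summary
#'
#' Aligns the two proteins and the two CDSs globally, reports percent
#' identity (both denominator conventions), back-translates the protein
#' alignment and computes NG86 dN/dS.
#'
#' @param protein_a,protein_b Protein sequences.
#' @param cds_a,cds_b Matching CDS sequences (terminal stop codon allowed).
#' @return List: pct_identity_protein, pct_identity_nt (excluding-gap
#'   denominator), the `_full_length` variants, dN, dS, omega, method,
#'   params.
#' @export
paralog_divergence <- function(protein_a, protein_b, cds_a, cds_b) {
  pa <- global_align(protein_a, protein_b, mode = "protein")
  na <- global_align(cds_a, cds_b, mode = "nucleotide")
  codon <- back_translate_alignment(pa, cds_a, cds_b)
  dnds <- ng86_dnds(codon)
  list(pct_identity_protein = percent_identity(pa),
       pct_identity_protein_full_length = percent_identity(pa, "alignment_length"),
       pct_identity_nt = percent_identity(na),
       pct_identity_nt_full_length = percent_identity(na, "alignment_length"),
       dN = dnds$dN, dS = dnds$dS, omega = dnds$omega,
       method = "NG86 counting + Jukes-Cantor correction",
       params = list(protein_matrix = "BLOSUM62", nt_match = 5, nt_mismatch = -4,
                     gap_open = 10, gap_extend = 0.5))
}
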