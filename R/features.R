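#' Read sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] returning a named
#' character vector (first word of each header as the name), the form the
#' feature functions take.
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase DNA sequences.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Extract the upstream region of a gene (-100 to +1)
#'
#' Returns the 101-nt window from 100 bp upstream of the start codon through
#' its first base, in transcript orientation (reverse-complemented for minus
#' strand genes). Coordinates are 1-based on the given sequence; `start` is
#' the genomic coordinate of the first base of the start codon.
#'
#' @param genome A single DNA sequence (character).
#' @param start Genomic coordinate(s) of the translational start.
#' @param strand `"+"` or `"-"`, recycled against `start`.
#' @param width Upstream window length in nt (default 100, giving 101-nt
#'   windows including the start base).
#' @return Character vector of upstream sequences; windows that would run
#'   past the sequence ends are truncated with a warning.
#' @examples
#' extract_upstream(strrep("ACGT", 60), start = 101, strand = "+")
#' @export
extract_upstream <- function(genome, start, strand = "+", width = 100) {
  stopifnot(length(genome) == 1, all(strand %in% c("+", "-")))
  genome <- toupper(genome)
  n <- nchar(genome)
  if (any(start < 1 | start > n)) {
    stop("start coordinate outside the sequence")
  }
  strand <- rep_len(strand, length(start))
  out <- character(length(start))
  truncated <- FALSE
  for (i in seq_along(start)) {
    if (strand[i] == "+") {
      from <- start[i] - width
      to <- start[i]
      if (from < 1) {
        truncated <- TRUE
        from <- 1
      }
      out[i] <- substr(genome, from, to)
    } else {
      from <- start[i]
      to <- start[i] + width
      if (to > n) {
        truncated <- TRUE
        to <- n
      }
      out[i] <- revcomp(substr(genome, from, to))
    }
  }
  if (truncated) warning("upstream window truncated at sequence boundary")
  out
}

revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

split_codons <- function(cds) {
  cds <- toupper(chartr("U", "T", cds))
  if (nchar(cds) %% 3 != 0) {
    stop("CDS length not divisible by 3")
  }
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}

genetic_code_tbl <- function() {
  gc <- Biostrings::GENETIC_CODE
  tibble::tibble(codon = names(gc), aa = unname(gc))
}

#' Codon adaptation weights from a highly expressed reference set
#'
#' Counts codon usage across a reference gene set (canonically the ribosomal
#' protein CDS) and assigns each codon a relative adaptiveness weight
#' `w = freq(codon) / max freq among its synonymous codons`. Codons never
#' observed in the reference set receive a pseudo-count of 0.5 before
#' normalization. Stop codons carry no weight.
#'
#' @param reference_cds Character vector of reference CDS (each a multiple of
#'   3 nt long).
#' @return A tibble: `codon`, `aa`, `weight`.
#' @export
cai_weights <- function(reference_cds) {
  codons <- unlist(lapply(reference_cds, split_codons))
  tab <- table(factor(codons, levels = names(Biostrings::GENETIC_CODE)))
  genetic_code_tbl() |>
    dplyr::filter(.data$aa != "*") |>
    dplyr::mutate(count = as.numeric(tab[.data$codon]),
                  count = ifelse(.data$count == 0, 0.5, .data$count)) |>
    dplyr::group_by(.data$aa) |>
    dplyr::mutate(weight = .data$count / max(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::select("codon", "aa", "weight")
}

#' Codon adaptation index of coding sequences
#'
#' The CAI of a gene is the geometric mean of the relative adaptiveness
#' weights of its codons. Stop codons and the single-codon families (Met,
#' Trp), whose weight is 1 by construction, are excluded from the product.
#'
#' @param cds Character vector of CDS.
#' @param weights Weight table from [cai_weights()].
#' @return Numeric vector of CAI values in (0, 1].
#' @examples
#' ref <- c("AAAAAAGGT", "AAAGGTGGT")
#' compute_cai("AAAGGT", cai_weights(ref))
#' @export
compute_cai <- function(cds, weights) {
  single <- c("M", "W")
  w <- setNames(weights$weight, weights$codon)
  aa <- setNames(weights$aa, weights$codon)
  vapply(cds, function(s) {
    codons <- split_codons(s)
    code <- Biostrings::GENETIC_CODE[codons]
    if (any(code[-length(code)] == "*")) {
      warning("internal stop codon in CDS")
    }
    keep <- codons[!is.na(aa[codons]) & !(aa[codons] %in% single)]
    if (length(keep) == 0) {
      return(NA_real_)
    }
    exp(mean(log(w[keep])))
  }, numeric(1), USE.NAMES = FALSE)
}

# Selective constraints for non-Watson-Crick codon:anticodon pairings at the
# wobble position (anticodon base 34), in the standard order used for tRNA
# adaptation weights.
default_wobble_penalties <- function() {
  c(gu = 0.41, ic = 0.28, ia = 0.9999, ug = 0.68)
}

#' tRNA adaptation weights from genomic tRNA copy numbers
#'
#' Each codon's absolute adaptiveness is the copy-number-weighted sum over
#' the tRNAs able to read it: the Watson-Crick decoder at full efficiency
#' plus one wobble decoder discounted by a selective constraint `s`
#' (efficiency `1 - s`): G34 reads U-ending codons (s_gu), inosine (from
#' A34) reads C- and A-ending codons (s_ic, s_ia) and U34 reads G-ending
#' codons (s_ug). Weights are normalized to their maximum.
#'
#' @param trna_copies Named numeric vector of tRNA gene copy numbers, named
#'   by anticodon (DNA alphabet, 5'->3', e.g. `"TGC"` for the Ala tRNA
#'   reading GCA). Absent anticodons count 0.
#' @param wobble_penalties Named vector with elements `gu`, `ic`, `ia`, `ug`;
#'   defaults to the published selective constraints.
#' @return A tibble: `codon`, `aa`, `weight` (NA for codons no supplied tRNA
#'   can read).
#' @export
tai_weights <- function(trna_copies,
                        wobble_penalties = default_wobble_penalties()) {
  s <- wobble_penalties
  stopifnot(all(c("gu", "ic", "ia", "ug") %in% names(s)))
  code <- genetic_code_tbl() |> dplyr::filter(.data$aa != "*")
  copies <- function(anticodon) {
    out <- trna_copies[anticodon]
    ifelse(is.na(out), 0, out)
  }
  wc <- function(codon) revcomp(codon)
  third <- substr(code$codon, 3, 3)
  stem <- substr(code$codon, 1, 2)
  W <- numeric(nrow(code))
  for (i in seq_len(nrow(code))) {
    self <- copies(wc(code$codon[i]))
    W[i] <- switch(
      third[i],
      "T" = self + (1 - s[["gu"]]) * copies(wc(paste0(stem[i], "C"))),
      "C" = self + (1 - s[["ic"]]) * copies(wc(paste0(stem[i], "T"))),
      "A" = self + (1 - s[["ia"]]) * copies(wc(paste0(stem[i], "T"))),
      "G" = self + (1 - s[["ug"]]) * copies(wc(paste0(stem[i], "A")))
    )
  }
  code$weight <- ifelse(W > 0, W / max(W), NA_real_)
  code
}

#' tRNA adaptation index of coding sequences
#'
#' Geometric mean of the tRNA adaptation weights over a gene's codons,
#' excluding stop codons and single-codon families. Codons without a
#' recognizing tRNA in the supplied table are excluded from the product with
#' a warning.
#'
#' @param cds Character vector of CDS.
#' @param weights Weight table from [tai_weights()].
#' @return Numeric vector of tAI values in (0, 1].
#' @export
compute_tai <- function(cds, weights) {
  single <- c("M", "W")
  w <- setNames(weights$weight, weights$codon)
  aa <- setNames(weights$aa, weights$codon)
  vapply(cds, function(s) {
    codons <- split_codons(s)
    keep <- codons[!is.na(aa[codons]) & !(aa[codons] %in% single)]
    ws <- w[keep]
    if (anyNA(ws)) {
      warning("codon(s) without a recognizing tRNA excluded from tAI")
      ws <- ws[!is.na(ws)]
    }
    if (length(ws) == 0) {
      return(NA_real_)
    }
    exp(mean(log(ws)))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Count (possibly overlapping) motif occurrences
#'
#' Counts occurrences of a motif on the given strand only, allowing
#' overlaps — e.g. `"AGGAGGAG"` contains the ribosome-binding-site-like
#' pentamer AGGAG twice.
#'
#' @param sequence Character vector of DNA/RNA sequences.
#' @param motif Motif to count (default `"AGGAG"`).
#' @return Integer vector of counts.
#' @examples
#' count_motif("AGGAGGAG") # 2
#' @export
count_motif <- function(sequence, motif = "AGGAG") {
  motif <- toupper(chartr("U", "T", motif))
  vapply(sequence, function(s) {
    s <- toupper(chartr("U", "T", s))
    hits <- gregexpr(paste0("(?=", motif, ")"), s, perl = TRUE)[[1]]
    if (hits[1] == -1) 0L else length(hits)
  }, integer(1), USE.NAMES = FALSE)
}

#' GC content of sequences
#'
#' Fraction (G + C) / (A + C + G + T/U); ambiguity codes are excluded from
#' both numerator and denominator.
#'
#' @param sequence Character vector of non-empty sequences.
#' @return Numeric vector of fractions in [0, 1].
#' @export
gc_content <- function(sequence) {
  stopifnot(all(nchar(sequence) > 0))
  vapply(sequence, function(s) {
    s <- toupper(chartr("U", "T", s))
    chars <- strsplit(s, "")[[1]]
    unamb <- chars[chars %in% c("A", "C", "G", "T")]
    if (length(unamb) == 0) {
      return(NA_real_)
    }
    sum(unamb %in% c("G", "C")) / length(unamb)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Assemble a per-gene feature table
#'
#' Joins computed sequence features (length, codon count, CAI, tAI, GC
#' content, upstream motif count) with externally supplied quantities
#' (folding free energies of the upstream regions as produced by a standard
#' folding tool, pre-arrest mRNA levels, functional categories) into the
#' table the covariance model consumes. The motif count is binned into the
#' qualitative classes 0 / 1 / 2+.
#'
#' @param cds Named character vector of coding sequences.
#' @param upstream Named character vector of -100..+1 regions (same names).
#' @param dg Optional tibble `gene`, `dg` (kcal/mol, typically negative);
#'   stored as `abs_dg`.
#' @param mrna Optional tibble `gene`, `mrna` (pre-arrest level).
#' @param category Optional tibble `gene`, `category`.
#' @param cai_ref Reference CDS for [cai_weights()]; defaults to `cds`
#'   itself when no dedicated highly expressed set is given.
#' @param trna_copies Optional anticodon copy-number vector for tAI.
#' @return A tibble with one row per gene.
#' @export
gene_features <- function(cds, upstream = NULL, dg = NULL, mrna = NULL,
                          category = NULL, cai_ref = cds,
                          trna_copies = NULL) {
  stopifnot(!is.null(names(cds)))
  feats <- tibble::tibble(
    gene = names(cds),
    length = unname(nchar(cds)),
    n_codons = unname(nchar(cds) %/% 3L),
    gc = gc_content(cds),
    cai = compute_cai(cds, cai_weights(cai_ref))
  )
  if (!is.null(trna_copies)) {
    feats$tai <- compute_tai(cds, tai_weights(trna_copies))
  }
  if (!is.null(upstream)) {
    up <- tibble::tibble(
      gene = names(upstream),
      motif_count = count_motif(upstream),
      motif_class = factor(
        ifelse(count_motif(upstream) >= 2, "2+",
               as.character(count_motif(upstream))),
        levels = c("0", "1", "2+")
      )
    )
    feats <- dplyr::left_join(feats, up, by = "gene")
  }
  if (!is.null(dg)) {
    feats <- dplyr::left_join(
      feats, dplyr::transmute(dg, gene = .data$gene, abs_dg = abs(.data$dg)),
      by = "gene"
    )
  }
  if (!is.null(mrna)) {
    feats <- dplyr::left_join(feats, mrna, by = "gene")
  }
  if (!is.null(category)) {
    feats <- dplyr::left_join(feats, category, by = "gene")
  }
  feats
}
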