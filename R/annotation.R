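# Variant site classification against gene models (GFF3 subset) and a
# reference sequence, and gene nomination for association records.

SITE_CLASSES <- c("NonSynonymous", "Synonymous", "Intron", "UTR",
                  "Upstream", "Downstream", "Intergenic")

#' Read an annotation set (GFF3 gene models + FASTA reference)
#'
#' Supports the gene/mRNA/exon/CDS subset of GFF3 with `ID`/`Parent`
#' attributes and 1-based inclusive coordinates.
#'
#' @param gff_path Path to a GFF3 file.
#' @param fasta_path Path to the reference FASTA (optional; required for
#'   coding-site classification).
#' @return An `annotation_set`: list of per-transcript models and the
#'   reference `Biostrings::DNAStringSet`.
#' @export
read_annotation <- function(gff_path, fasta_path = NULL) {
  gff <- as.data.frame(rtracklayer::readGFF(gff_path))
  gff$Parent <- vapply(gff$Parent, function(p)
    if (length(p)) as.character(p[1]) else NA_character_, "")
  tx_rows <- gff[gff$type %in% c("mRNA", "transcript"), , drop = FALSE]
  transcripts <- lapply(seq_len(nrow(tx_rows)), function(i) {
    tid <- tx_rows$ID[i]
    ex <- gff[gff$type == "exon" & gff$Parent == tid, , drop = FALSE]
    cds <- gff[gff$type == "CDS" & gff$Parent == tid, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    cds <- cds[order(cds$start), , drop = FALSE]
    list(id = tid, gene = tx_rows$Parent[i],
         chrom = as.character(tx_rows$seqid[i]),
         strand = as.character(tx_rows$strand[i]),
         start = min(tx_rows$start[i], if (nrow(ex)) min(ex$start) else Inf),
         end = max(tx_rows$end[i], if (nrow(ex)) max(ex$end) else -Inf),
         exons = ex[, c("start", "end")],
         cds = cds[, c("start", "end")])
  })
  seqs <- if (!is.null(fasta_path)) Biostrings::readDNAStringSet(fasta_path)
          else NULL
  if (!is.null(seqs)) names(seqs) <- sub("\\s.*$", "", names(seqs))
  structure(list(transcripts = transcripts, seq = seqs),
            class = "annotation_set")
}

cds_sequence <- function(tx, seqs) {
  segs <- tx$cds
  chrom_seq <- seqs[[tx$chrom]]
  pieces <- lapply(seq_len(nrow(segs)), function(i)
    Biostrings::subseq(chrom_seq, segs$start[i], segs$end[i]))
  cds <- do.call(Biostrings::xscat, pieces)
  if (tx$strand == "-") cds <- Biostrings::reverseComplement(cds)
  cds
}

cds_offset <- function(tx, pos) {
  # 1-based offset of genomic pos within the spliced CDS, strand-aware
  segs <- tx$cds
  if (tx$strand == "+") {
    off <- 0L
    for (i in seq_len(nrow(segs))) {
      if (pos >= segs$start[i] && pos <= segs$end[i]) {
        return(off + (pos - segs$start[i] + 1L))
      }
      off <- off + (segs$end[i] - segs$start[i] + 1L)
    }
  } else {
    off <- 0L
    for (i in rev(seq_len(nrow(segs)))) {
      if (pos >= segs$start[i] && pos <= segs$end[i]) {
        return(off + (segs$end[i] - pos + 1L))
      }
      off <- off + (segs$end[i] - segs$start[i] + 1L)
    }
  }
  NA_integer_
}

classify_one <- function(chrom, pos, ref, minor, type, annotation,
                         max_flank = 1000L) {
  txs <- Filter(function(t) t$chrom == chrom, annotation$transcripts)
  best_class <- "Intergenic"
  best_gene <- NA_character_
  flank_genes <- character(0)
  flank_dist <- numeric(0)
  flank_side <- character(0)
  rank <- function(cl) match(cl, c("NonSynonymous", "Synonymous", "UTR",
                                   "Intron", "Upstream", "Downstream",
                                   "Intergenic"))
  for (tx in txs) {
    if (pos >= tx$start && pos <= tx$end) {
      in_cds <- nrow(tx$cds) > 0 &&
        any(pos >= tx$cds$start & pos <= tx$cds$end)
      in_exon <- nrow(tx$exons) > 0 &&
        any(pos >= tx$exons$start & pos <= tx$exons$end)
      cl <- if (in_cds) {
        if (type != "SNP") "NonSynonymous"
        else classify_coding_snp(tx, pos, ref, minor, annotation$seq)
      } else if (in_exon) "UTR" else "Intron"
      if (rank(cl) < rank(best_class)) {
        best_class <- cl
        best_gene <- tx$gene
      }
    } else {
      d <- if (pos < tx$start) tx$start - pos else pos - tx$end
      if (d <= max_flank) {
        before <- pos < tx$start
        side <- if (tx$strand == "+") {
          if (before) "Upstream" else "Downstream"
        } else {
          if (before) "Downstream" else "Upstream"
        }
        flank_genes <- c(flank_genes, tx$gene)
        flank_dist <- c(flank_dist, d)
        flank_side <- c(flank_side, side)
      }
    }
  }
  if (best_class == "Intergenic" && length(flank_genes)) {
    dmin <- min(flank_dist)
    nearest <- flank_dist == dmin
    genes <- sort(unique(flank_genes[nearest]))
    side <- sort(unique(flank_side[nearest]))[1]
    best_class <- side
    best_gene <- paste(genes, collapse = ";")
  }
  if (best_class == "Intergenic") best_gene <- "n/a"
  list(site_class = best_class, gene = best_gene)
}

classify_coding_snp <- function(tx, pos, ref, minor, seqs) {
  if (is.null(seqs)) stop("reference sequence required for coding sites")
  chrom_seq <- seqs[[tx$chrom]]
  genome_base <- as.character(Biostrings::subseq(chrom_seq, pos, pos))
  if (!is.na(ref) && nzchar(ref) && genome_base != ref) {
    stop(sprintf("variant at %s:%d has ref '%s' but reference base is '%s'",
                 tx$chrom, pos, ref, genome_base))
  }
  off <- cds_offset(tx, pos)
  cds <- cds_sequence(tx, seqs)
  alt_base <- if (tx$strand == "+") minor else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(minor)))
  codon_idx <- (off - 1L) %/% 3L
  within <- (off - 1L) %% 3L
  codon_start <- codon_idx * 3L + 1L
  if (codon_start + 2L > length(cds)) return("NonSynonymous")
  codon <- as.character(Biostrings::subseq(cds, codon_start, codon_start + 2L))
  alt_codon <- codon
  substr(alt_codon, within + 1L, within + 1L) <- alt_base
  aa_ref <- Biostrings::GENETIC_CODE[[codon]]
  aa_alt <- Biostrings::GENETIC_CODE[[alt_codon]]
  if (identical(aa_ref, aa_alt)) "Synonymous" else "NonSynonymous"
}

#' Classify variant sites against gene models
#'
#' Assigns each variant one site class with precedence
#' CDS > UTR > Intron > Upstream/Downstream (within 1 kb of the transcript
#' span, strand-aware) > Intergenic. For SNPs inside a CDS the minor allele
#' is substituted into the codon (standard genetic code, strand-aware) and
#' compared with the reference amino acid; indels in CDS are called
#' NonSynonymous.
#'
#' @param variants Data frame with `chrom`, `pos`, `ref`, `minor`, `type`
#'   columns (as in `line_panel$variants`).
#' @param annotation An `annotation_set` from [read_annotation()].
#' @param max_flank Flank distance in bp for Upstream/Downstream
#'   (default 1000).
#' @return Character vector of site classes.
#' @export
classify_site <- function(variants, annotation, max_flank = 1000L) {
  vapply(seq_len(nrow(variants)), function(i)
    classify_one(variants$chrom[i], variants$pos[i], variants$ref[i],
                 variants$minor[i], variants$type[i], annotation,
                 max_flank)$site_class, "")
}

#' Nominate genes for classified variants
#'
#' The gene owning the exon/intron for genic classes; the nearest gene
#' within 1 kb for Upstream/Downstream (equidistant ties all reported,
#' joined by `";"` in ascending id order); `"n/a"` for Intergenic.
#'
#' @inheritParams classify_site
#' @return Character vector of nominated genes.
#' @export
nominate_genes <- function(variants, annotation, max_flank = 1000L) {
  vapply(seq_len(nrow(variants)), function(i)
    classify_one(variants$chrom[i], variants$pos[i], variants$ref[i],
                 variants$minor[i], variants$type[i], annotation,
                 max_flank)$gene, "")
}

#' Grouped site-class distribution
#'
#' Fractions (percent, rounded to 0.1) of records falling in the three
#' groups used for reporting: intronic; intergenic or within 1 kb
#' up/downstream; coding (synonymous + non-synonymous).
#'
#' @param site_class Character vector of site classes (see
#'   [classify_site()]), or a data frame with a `site_class` column.
#' @return Named numeric vector `c(intronic, intergenic_1kb, coding)` in
#'   percent.
#' @export
summarize_site_distribution <- function(site_class) {
  if (is.data.frame(site_class)) site_class <- site_class$site_class
  site_class <- site_class[!is.na(site_class)]
  site_class <- gsub("-", "", site_class)  # accept "Non-Synonymous" spelling
  n <- length(site_class)
  if (n == 0L) return(c(intronic = NA_real_, intergenic_1kb = NA_real_,
                        coding = NA_real_))
  groups <- c(
    intronic = sum(site_class == "Intron"),
    intergenic_1kb = sum(site_class %in% c("Intergenic", "Upstream",
                                           "Downstream")),
    coding = sum(site_class %in% c("Synonymous", "NonSynonymous")))
  round(100 * groups / n, 1)
}
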