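# Shared fixture builders: toy monitors, window-sum tables, intron
# clusters, and a toy annotation (GFF3 + FASTA) with known gene models.

make_monitor <- function(counts, start = "2020-01-01 18:00:00",
                         cadence_min = 30, monitor_id = "M1") {
  counts <- as.matrix(counts)
  if (ncol(counts) < 32) {
    counts <- cbind(counts, matrix(0L, nrow(counts), 32 - ncol(counts)))
  }
  times <- as.POSIXct(start, tz = "UTC") +
    (seq_len(nrow(counts)) - 1) * cadence_min * 60
  monitor_file(monitor_id, seq_len(nrow(counts)), times,
               rep(1L, nrow(counts)), counts)
}

simple_layout <- function(n_channels, monitor_id = "M1",
                          strain_id = "s1", condition = "starvation") {
  data.frame(monitor_id = monitor_id, channel = seq_len(n_channels),
             fly_id = sprintf("f%02d", seq_len(n_channels)),
             strain_id = strain_id, condition = condition,
             stringsAsFactors = FALSE)
}

make_ws <- function(fly_id, strain_id, condition, totals) {
  out <- data.frame(fly_id = fly_id, strain_id = strain_id,
                    condition = condition, stringsAsFactors = FALSE)
  m <- matrix(totals, ncol = 5, byrow = TRUE,
              dimnames = list(NULL, c("N1", "D1", "N2", "D2", "N3")))
  cbind(out, as.data.frame(m))
}

make_cluster <- function(counts, ids = NULL, chrom = "2L", strand = "+") {
  counts <- as.matrix(counts)
  if (is.null(ids)) ids <- paste0("j", seq_len(nrow(counts)))
  rownames(counts) <- ids
  structure(list(cluster_id = "clu_test",
                 junctions = data.frame(id = ids, chrom = chrom,
                                        start = 0L,
                                        end = 100L * seq_along(ids),
                                        strand = strand,
                                        stringsAsFactors = FALSE),
                 counts = counts),
            class = "intron_cluster")
}

# union-find oracle for junction clustering
uf_components <- function(junctions) {
  n <- nrow(junctions)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && junctions$chrom[i] == junctions$chrom[j] &&
        junctions$strand[i] == junctions$strand[j] &&
        (junctions$start[i] == junctions$start[j] ||
         junctions$end[i] == junctions$end[j])) union(i, j)
  }
  vapply(seq_len(n), find, 0L)
}

# toy annotation: two-exon plus-strand gene with CTT-repeat CDS, a
# minus-strand gene, and an equidistant pair of flanking genes
write_toy_annotation <- function(dir = tempfile("anno_")) {
  dir.create(dir, showWarnings = FALSE)
  len <- 10000L
  seq <- rep("A", len)
  # g1 (+): exons 1001-1100, 1201-1400; CDS 1051-1100 (50) + 1201-1330 (130)
  cds_coords <- c(1051:1100, 1201:1330)
  codons <- rep(c("C", "T", "T"), length.out = length(cds_coords))
  seq[cds_coords] <- codons
  fa <- file.path(dir, "toy.fa")
  writeLines(c(">chrA", paste(seq, collapse = "")), fa)
  gff <- file.path(dir, "toy.gff3")
  lines <- c(
    "##gff-version 3",
    "chrA\ttoy\tgene\t1001\t1400\t.\t+\t.\tID=g1",
    "chrA\ttoy\tmRNA\t1001\t1400\t.\t+\t.\tID=t1;Parent=g1",
    "chrA\ttoy\texon\t1001\t1100\t.\t+\t.\tID=t1e1;Parent=t1",
    "chrA\ttoy\texon\t1201\t1400\t.\t+\t.\tID=t1e2;Parent=t1",
    "chrA\ttoy\tCDS\t1051\t1100\t.\t+\t0\tID=t1c1;Parent=t1",
    "chrA\ttoy\tCDS\t1201\t1330\t.\t+\t1\tID=t1c2;Parent=t1",
    "chrA\ttoy\tgene\t5001\t5600\t.\t-\t.\tID=g2",
    "chrA\ttoy\tmRNA\t5001\t5600\t.\t-\t.\tID=t2;Parent=g2",
    "chrA\ttoy\texon\t5001\t5600\t.\t-\t.\tID=t2e1;Parent=t2",
    "chrA\ttoy\tCDS\t5101\t5502\t.\t-\t0\tID=t2c1;Parent=t2",
    "chrA\ttoy\tgene\t8001\t8200\t.\t+\t.\tID=g3",
    "chrA\ttoy\tmRNA\t8001\t8200\t.\t+\t.\tID=t3;Parent=g3",
    "chrA\ttoy\texon\t8001\t8200\t.\t+\t.\tID=t3e1;Parent=t3",
    "chrA\ttoy\tgene\t8800\t9000\t.\t+\t.\tID=g4",
    "chrA\ttoy\tmRNA\t8800\t9000\t.\t+\t.\tID=t4;Parent=g4",
    "chrA\ttoy\texon\t8800\t9000\t.\t+\t.\tID=t4e1;Parent=t4")
  writeLines(lines, gff)
  list(gff = gff, fasta = fa)
}

toy_variant <- function(chrom, pos, ref = "A", minor = "T", type = "SNP") {
  data.frame(id = sprintf("%s_%d_%s", chrom, pos, type), chrom = chrom,
             pos = pos, ref = ref, minor = minor, major = ref, type = type,
             stringsAsFactors = FALSE)
}
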