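# in-code fixtures: small repeat/gene tables and annotation files

make_repeats <- function(start, end, strand,
                         chrom = "chr1",
                         name = "AluSx") {
  n <- length(start)
  chrom <- rep_len(chrom, n)
  name <- rep_len(name, n)
  df <- data.frame(
    id = sprintf("r%03d", seq_len(n)),
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    strand = strand, name = name,
    family = parse_family(name),
    length = as.integer(end - start),
    stringsAsFactors = FALSE
  )
  df
}

# mark every element genic without a real gene (segment relation then
# falls back to "unknown"); gene strand "+" so site strands are simple
as_genic <- function(repeats, gene_id = "geneX", gene_strand = "+") {
  repeats$gene_id <- gene_id
  repeats$gene_strand <- gene_strand
  repeats$expressed_strand_class <-
    ifelse(repeats$strand == gene_strand, "polyA", "polyU")
  repeats
}

dummy_genes <- function(chrom = "chrZ") {
  data.frame(
    gene_id = "dummy", chrom = chrom, strand = "+",
    tx_start = 0L, tx_end = 1000L,
    exons = I(list(cbind(start = 0L, end = 1000L))),
    stringsAsFactors = FALSE
  )
}

make_gene <- function(gene_id, chrom, strand, tx_start, tx_end, exons) {
  data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
             tx_start = as.integer(tx_start), tx_end = as.integer(tx_end),
             exons = I(list(exons)), stringsAsFactors = FALSE)
}

make_sites <- function(pos, a, g, chrom = "chr1", strand = "+") {
  data.frame(chrom = rep_len(chrom, length(pos)), pos = as.integer(pos),
             strand = rep_len(strand, length(pos)),
             a_reads = as.integer(a), g_reads = as.integer(g),
             stringsAsFactors = FALSE)
}

write_ucsc_rmsk <- function(rows, path = tempfile(fileext = ".tsv")) {
  # rows: data.frame(chrom, start, end, strand, name)
  writeLines(c(
    paste(c("bin", "genoName", "genoStart", "genoEnd", "strand", "repName",
            "repClass"), collapse = "\t"),
    apply(rows, 1, function(r) {
      paste(c("0", r[["chrom"]], r[["start"]], r[["end"]], r[["strand"]],
              r[["name"]], "SINE"), collapse = "\t")
    })
  ), path)
  path
}

write_rmsk_out <- function(rows, path = tempfile(fileext = ".out")) {
  # native .out: 1-based inclusive, strand C for minus
  hdr <- c("   SW   perc perc perc  query    position in query",
           "score   div. del. ins.  sequence  begin  end",
           "")
  body <- apply(rows, 1, function(r) {
    strand <- if (r[["strand"]] == "-") "C" else "+"
    sprintf("  463   11.3  0.3  0.3  %s  %d  %d  (1000)  %s  %s  SINE/Alu  1  300  (12)  1",
            r[["chrom"]], as.integer(r[["start"]]) + 1L,
            as.integer(r[["end"]]), strand, r[["name"]])
  })
  writeLines(c(hdr, body), path)
  path
}

write_bed6 <- function(rows, path = tempfile(fileext = ".bed")) {
  writeLines(apply(rows, 1, function(r) {
    paste(c(r[["chrom"]], r[["start"]], r[["end"]], r[["name"]], "0",
            r[["strand"]]), collapse = "\t")
  }), path)
  path
}

write_refflat <- function(genes, path = tempfile(fileext = ".txt")) {
  writeLines(vapply(seq_len(nrow(genes)), function(i) {
    ex <- genes$exons[[i]]
    paste(c(genes$gene_id[i], genes$gene_id[i], genes$chrom[i],
            genes$strand[i], genes$tx_start[i], genes$tx_end[i],
            genes$tx_start[i], genes$tx_start[i], nrow(ex),
            paste0(paste(ex[, "start"], collapse = ","), ","),
            paste0(paste(ex[, "end"], collapse = ","), ",")),
          collapse = "\t")
  }, ""), path)
  path
}

write_site_tsv <- function(sites, path = tempfile(fileext = ".tsv")) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# random repeat layout for oracle comparisons; may contain overlapping and
# nested elements on several chromosomes
random_layout <- function(n, n_chrom = 2, span = 60000) {
  chrom <- sample(paste0("chr", seq_len(n_chrom)), n, replace = TRUE)
  start <- sample.int(span, n, replace = TRUE)
  len <- sample(50:600, n, replace = TRUE)
  make_repeats(start, start + len, sample(c("+", "-"), n, replace = TRUE),
               chrom = chrom,
               name = sample(c("AluSx", "AluY", "AluJb", "FLAM_C"), n,
                             replace = TRUE))
}
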