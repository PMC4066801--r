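#' Read repeat annotations
#'
#' Parses a repeat annotation file into the canonical repeat-element table
#' used throughout the package, keeping only Alu-lineage elements
#' (repeat names beginning with `"Alu"` or `"FLAM"`). Internal coordinates
#' are always 0-based half-open; conversion from 1-based dialects happens
#' here and only here.
#'
#' @param path Path to the annotation file.
#' @param dialect One of `"rmsk_out"` (native RepeatMasker `.out`,
#'   whitespace-delimited with a three-line header, 1-based inclusive
#'   coordinates, strand `C` meaning complement), `"ucsc_rmsk"` (UCSC rmsk
#'   table dump with a header line naming at least
#'   `genoName`/`genoStart`/`genoEnd`/`strand`/`repName`, 0-based half-open)
#'   or `"bed6"` (headerless BED, 0-based half-open, name in column 4,
#'   strand in column 6). The dialect is declared, never sniffed.
#'
#' @return A `data.frame` with columns `id`, `chrom`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`), `name`, `family`
#'   (`AluJ`/`AluS`/`AluY`/`FLAM`/`other`) and `length` (`end - start`).
#'   Ids are unique (`<chrom>:<start>-<end>:<strand>:<n>`).
#' @seealso [parse_family()], [select_genic_alus()], [write_repeat_bed()]
#' @export
read_repeat_annotations <- function(path, dialect = c("rmsk_out", "ucsc_rmsk", "bed6")) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  parsed <- switch(dialect,
    rmsk_out  = .parse_rmsk_out(lines),
    ucsc_rmsk = .parse_ucsc_rmsk(lines),
    bed6      = .parse_bed6(lines)
  )
  keep <- startsWith(parsed$name, "Alu") | startsWith(parsed$name, "FLAM")
  parsed <- parsed[keep, , drop = FALSE]
  .finish_repeat_table(parsed)
}

# shared postprocessing: validation, family assignment, unique ids
.finish_repeat_table <- function(df) {
  rownames(df) <- NULL
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad)) {
    stop("invalid interval at input line ", df$line[bad[1]],
         ": start=", df$start[bad[1]], " end=", df$end[bad[1]])
  }
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad)) {
    stop("invalid strand at input line ", df$line[bad[1]], ": '", df$strand[bad[1]], "'")
  }
  key <- paste0(df$chrom, ":", df$start, "-", df$end, ":", df$strand)
  id <- paste0(key, ":", stats::ave(seq_along(key), key, FUN = seq_along))
  out <- data.frame(
    id = id, chrom = df$chrom,
    start = as.integer(df$start), end = as.integer(df$end),
    strand = df$strand, name = df$name,
    family = parse_family(df$name),
    length = as.integer(df$end - df$start),
    stringsAsFactors = FALSE
  )
  out
}

.parse_rmsk_out <- function(lines) {
  body <- if (length(lines) > 3) lines[-(1:3)] else character(0)
  lineno <- seq_along(lines)[-seq_len(min(3L, length(lines)))]
  keep <- nzchar(trimws(body))
  body <- body[keep]; lineno <- lineno[keep]
  fields <- strsplit(trimws(body), "[ \t]+")
  n <- vapply(fields, length, 1L)
  bad <- which(n < 10)
  if (length(bad)) stop("unparseable RepeatMasker line ", lineno[bad[1]])
  chrom  <- vapply(fields, `[`, "", 5L)
  begin  <- suppressWarnings(as.integer(vapply(fields, `[`, "", 6L)))
  end    <- suppressWarnings(as.integer(vapply(fields, `[`, "", 7L)))
  strand <- vapply(fields, `[`, "", 9L)
  name   <- vapply(fields, `[`, "", 10L)
  bad <- which(is.na(begin) | is.na(end))
  if (length(bad)) stop("unparseable RepeatMasker line ", lineno[bad[1]])
  strand[strand == "C"] <- "-"
  # RepeatMasker is 1-based inclusive
  data.frame(chrom = chrom, start = begin - 1L, end = end, strand = strand,
             name = name, line = lineno, stringsAsFactors = FALSE)
}

.parse_ucsc_rmsk <- function(lines) {
  if (!length(lines)) stop("empty ucsc_rmsk file")
  header <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
  need <- c("genoName", "genoStart", "genoEnd", "strand", "repName")
  miss <- setdiff(need, header)
  if (length(miss)) stop("ucsc_rmsk header missing column(s): ", paste(miss, collapse = ", "))
  body <- lines[-1]
  lineno <- seq_along(lines)[-1]
  keep <- nzchar(body)
  body <- body[keep]; lineno <- lineno[keep]
  fields <- strsplit(body, "\t")
  idx <- match(need, header)
  n <- vapply(fields, length, 1L)
  bad <- which(n < max(idx))
  if (length(bad)) stop("unparseable ucsc_rmsk line ", lineno[bad[1]])
  get <- function(i) vapply(fields, `[`, "", i)
  start <- suppressWarnings(as.integer(get(idx[2])))
  end <- suppressWarnings(as.integer(get(idx[3])))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop("unparseable ucsc_rmsk line ", lineno[bad[1]])
  data.frame(chrom = get(idx[1]), start = start, end = end,
             strand = get(idx[4]), name = get(idx[5]),
             line = lineno, stringsAsFactors = FALSE)
}

.parse_bed6 <- function(lines) {
  lineno <- seq_along(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")
  body <- lines[keep]; lineno <- lineno[keep]
  fields <- strsplit(body, "\t")
  n <- vapply(fields, length, 1L)
  bad <- which(n < 6)
  if (length(bad)) stop("unparseable BED6 line ", lineno[bad[1]], ": fewer than 6 columns")
  get <- function(i) vapply(fields, `[`, "", i)
  start <- suppressWarnings(as.integer(get(2)))
  end <- suppressWarnings(as.integer(get(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop("unparseable BED6 line ", lineno[bad[1]])
  data.frame(chrom = get(1), start = start, end = end, strand = get(6),
             name = get(4), line = lineno, stringsAsFactors = FALSE)
}

#' Classify a repeat name into an Alu family
#'
#' Longest matching prefix among `AluJ`, `AluS`, `AluY`, `FLAM`; anything
#' else (including bare `"Alu"`) is `"other"`. FLAM, the short single-armed
#' relative of Alu, is carried as a family of its own in all group
#' summaries.
#'
#' @param name Character vector of RepeatMasker repeat names.
#' @return Character vector of family labels.
#' @examples
#' parse_family(c("AluSx1", "AluYb8", "FLAM_C", "L1PA3"))
#' @export
parse_family <- function(name) {
  stopifnot(is.character(name), all(nzchar(name)))
  fam <- rep("other", length(name))
  for (p in c("AluJ", "AluS", "AluY", "FLAM")) {
    fam[startsWith(name, p)] <- p
  }
  fam
}

#' Read gene models
#'
#' @param path Path to the gene model file.
#' @param dialect `"refflat"` (geneName, name, chrom, strand, txStart,
#'   txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds) or
#'   `"bed12"`. Both are 0-based half-open.
#' @return A `data.frame` with columns `gene_id`, `chrom`, `strand`,
#'   `tx_start`, `tx_end` and a list-column `exons` holding one two-column
#'   integer matrix (`start`, `end`) per gene, sorted and merged if
#'   overlapping, all within the transcript span.
#' @export
read_gene_models <- function(path, dialect = c("refflat", "bed12")) {
  if (!file.exists(path)) stop("gene model file not found: ", path)
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  body <- lines[keep]
  lineno <- seq_along(lines)[keep]
  fields <- strsplit(body, "\t")
  parse_row <- function(f, ln) {
    if (dialect == "refflat") {
      if (length(f) < 11) stop("unparseable refFlat line ", ln)
      gene_id <- f[2]; chrom <- f[3]; strand <- f[4]
      tx_start <- as.integer(f[5]); tx_end <- as.integer(f[6])
      ex_s <- as.integer(strsplit(f[10], ",")[[1]])
      ex_e <- as.integer(strsplit(f[11], ",")[[1]])
    } else {
      if (length(f) < 12) stop("unparseable BED12 line ", ln)
      gene_id <- f[4]; chrom <- f[1]; strand <- f[6]
      tx_start <- as.integer(f[2]); tx_end <- as.integer(f[3])
      sizes  <- as.integer(strsplit(f[11], ",")[[1]])
      starts <- as.integer(strsplit(f[12], ",")[[1]])
      if (length(sizes) != length(starts)) stop("unparseable BED12 line ", ln, ": block count mismatch")
      ex_s <- tx_start + starts
      ex_e <- ex_s + sizes
    }
    if (any(is.na(c(tx_start, tx_end, ex_s, ex_e)))) stop("unparseable line ", ln)
    if (!strand %in% c("+", "-")) stop("invalid strand at line ", ln)
    if (any(ex_s < tx_start) || any(ex_e > tx_end) || any(ex_s >= ex_e)) {
      stop("exon outside transcript bounds at line ", ln)
    }
    exons <- .merge_intervals(ex_s, ex_e)
    list(gene_id = gene_id, chrom = chrom, strand = strand,
         tx_start = tx_start, tx_end = tx_end, exons = exons)
  }
  rows <- mapply(parse_row, fields, lineno, SIMPLIFY = FALSE)
  data.frame(
    gene_id = vapply(rows, `[[`, "", "gene_id"),
    chrom = vapply(rows, `[[`, "", "chrom"),
    strand = vapply(rows, `[[`, "", "strand"),
    tx_start = vapply(rows, function(r) r$tx_start, 1L),
    tx_end = vapply(rows, function(r) r$tx_end, 1L),
    exons = I(lapply(rows, `[[`, "exons")),
    stringsAsFactors = FALSE
  )
}

# sort and merge overlapping/touching half-open intervals
.merge_intervals <- function(s, e) {
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  ms <- s[1]; me <- e[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(s)[-1]) {
    if (s[i] <= me) {
      me <- max(me, e[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- s[i]; me <- e[i]
    }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

#' Restrict repeats to genic context and assign the expressed strand
#'
#' An element is genic when its full interval lies inside at least one
#' gene's transcript span. When several genes contain it, the gene with the
#' smallest transcript span wins (ties broken by lexicographically smallest
#' `gene_id`). The expressed-strand class records whether the transcribed
#' copy carries the Alu consensus strand (`"polyA"`, repeat strand equal to
#' gene strand) or its reverse complement (`"polyU"`): reads are attributed
#' to the annotated gene strand, never inferred from data.
#'
#' @param repeats Repeat table from [read_repeat_annotations()].
#' @param genes Gene table from [read_gene_models()].
#' @return The rows of `repeats` that are genic, with added columns
#'   `gene_id`, `gene_strand` and `expressed_strand_class`
#'   (`"polyA"`/`"polyU"`).
#' @export
select_genic_alus <- function(repeats, genes) {
  stopifnot(nrow(repeats) > 0, nrow(genes) > 0)
  rg <- GenomicRanges::GRanges(repeats$chrom,
                               IRanges::IRanges(repeats$start + 1L, repeats$end))
  gg <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$tx_start + 1L, genes$tx_end))
  hits <- GenomicRanges::findOverlaps(rg, gg, type = "within")
  if (!length(hits)) {
    return(cbind(repeats[0, , drop = FALSE],
                 gene_id = character(0), gene_strand = character(0),
                 expressed_strand_class = character(0)))
  }
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  span <- genes$tx_end[sh] - genes$tx_start[sh]
  o <- order(qh, span, genes$gene_id[sh])
  qh <- qh[o]; sh <- sh[o]
  first <- !duplicated(qh)
  qh <- qh[first]; sh <- sh[first]
  out <- repeats[qh, , drop = FALSE]
  out$gene_id <- genes$gene_id[sh]
  out$gene_strand <- genes$strand[sh]
  out$expressed_strand_class <- ifelse(out$strand == out$gene_strand, "polyA", "polyU")
  rownames(out) <- NULL
  out
}

#' Write a repeat table as BED6 (+family, +gene_id when present)
#'
#' @param repeats Repeat table ([read_repeat_annotations()] or
#'   [select_genic_alus()] output).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeat_bed <- function(repeats, path) {
  df <- data.frame(repeats$chrom, repeats$start, repeats$end,
                   repeats$name, 0L, repeats$strand, repeats$family,
                   stringsAsFactors = FALSE)
  if (!is.null(repeats$gene_id)) df$gene_id <- repeats$gene_id
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
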