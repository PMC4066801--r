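#' Read a site-level editing count table
#'
#' Expects a header line and columns `chrom`, `pos` (0-based adenosine
#' position on the expressed strand), `strand`, `a_reads`, `g_reads` —
#' the per-site output shape of upstream editing-detection tools, where
#' inosine is sequenced as G. A `.gz` path is read transparently. Sites
#' with zero total depth are rejected at parse time.
#'
#' @param path Path to the (optionally gzip-compressed) TSV.
#' @return A `data.frame` with the five columns above.
#' @export
read_site_counts <- function(path) {
  if (!file.exists(path)) stop("site count file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  df <- utils::read.delim(con, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "strand", "a_reads", "g_reads")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("site count table missing column(s): ", paste(miss, collapse = ", "))
  df <- df[need]
  if (!nrow(df)) stop("site count table is empty")
  if (any(!df$strand %in% c("+", "-"))) stop("invalid strand in site count table")
  if (any(df$a_reads < 0 | df$g_reads < 0)) stop("negative read count in site count table")
  zero <- df$a_reads + df$g_reads < 1
  if (any(zero)) {
    stop("site with zero read depth at row ", which(zero)[1],
         " (", df$chrom[which(zero)[1]], ":", df$pos[which(zero)[1]], ")")
  }
  df
}

# Match sites to containing genic Alus; strand must equal the Alu's gene
# strand (reads are attributed to the expressed strand upstream).
# Returns data.frame(site = row in sites, alu = row in alus).
.match_sites_to_alus <- function(sites, alus) {
  sg <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos + 1L, width = 1L))
  ag <- GenomicRanges::GRanges(alus$chrom, IRanges::IRanges(alus$start + 1L, alus$end))
  hits <- GenomicRanges::findOverlaps(sg, ag)
  si <- S4Vectors::queryHits(hits); ai <- S4Vectors::subjectHits(hits)
  bad <- which(sites$strand[si] != alus$gene_strand[ai])
  if (length(bad)) {
    b <- bad[1]
    stop("site ", sites$chrom[si[b]], ":", sites$pos[si[b]],
         " has strand '", sites$strand[si[b]], "' but containing Alu ",
         alus$id[ai[b]], " is expressed on '", alus$gene_strand[ai[b]],
         "': inconsistent upstream strand handling")
  }
  data.frame(site = si, alu = ai)
}

.editability_from_matches <- function(sites, alus, m, g_eff) {
  depth <- sites$a_reads + sites$g_reads
  tot_depth <- rowsum(depth[m$site], m$alu)
  tot_g <- rowsum(g_eff[m$site], m$alu)
  n_sites <- rowsum(rep(1L, nrow(m)), m$alu)
  ai <- as.integer(rownames(tot_depth))
  out <- data.frame(
    alu_id = alus$id[ai],
    chrom = alus$chrom[ai], start = alus$start[ai], end = alus$end[ai],
    strand = alus$strand[ai], gene_id = alus$gene_id[ai],
    expressed_strand_class = alus$expressed_strand_class[ai],
    n_sites_covered = as.integer(n_sites[, 1]),
    total_a = as.numeric(tot_depth[, 1] - tot_g[, 1]),
    total_g = as.numeric(tot_g[, 1]),
    editability_pct = 100 * tot_g[, 1] / tot_depth[, 1],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Aggregate site-level counts into per-Alu editability
#'
#' Editability of an element is the percentage of sequenced adenosine read
#' bases observed as G (inosine), pooled over every covered adenosine
#' position inside the element: `100 * sum(g) / sum(a + g)`. Sites outside
#' any Alu are ignored; a site inside an Alu whose strand contradicts the
#' Alu's gene strand is an error. Alus with no covered site are absent
#' from the output (no coverage filter is applied here; see
#' [apply_coverage_filters()]).
#'
#' @param sites Site count table ([read_site_counts()] shape).
#' @param alus Genic Alu table ([select_genic_alus()] output).
#' @return A `data.frame` with one row per covered Alu: `alu_id`, `chrom`,
#'   `start`, `end`, `strand`, `gene_id`, `expressed_strand_class`,
#'   `n_sites_covered`, `total_a`, `total_g`, `editability_pct`.
#' @export
aggregate_site_counts <- function(sites, alus) {
  m <- .match_sites_to_alus(sites, alus)
  .editability_from_matches(sites, alus, m, as.numeric(sites$g_reads))
}

#' Per-Alu editability restricted to strong editing sites
#'
#' Variant of [aggregate_site_counts()] that credits only strong sites:
#' a site whose own editing level `100*g/(a+g)` is at or below
#' `threshold_pct` keeps its full depth in the denominator but contributes
#' zero edited reads, so the statistic remains a per-adenosine fraction
#' over the same read mass and is directly comparable to the aggregate
#' value (which it can never exceed).
#'
#' @inheritParams aggregate_site_counts
#' @param threshold_pct Site-level editing threshold in percent,
#'   strictly between 0 and 100. Default 25.
#' @return Same shape as [aggregate_site_counts()].
#' @export
strong_site_editability <- function(sites, alus, threshold_pct = 25) {
  stopifnot(threshold_pct > 0, threshold_pct < 100)
  level <- 100 * sites$g_reads / (sites$a_reads + sites$g_reads)
  g_eff <- ifelse(level > threshold_pct, as.numeric(sites$g_reads), 0)
  m <- .match_sites_to_alus(sites, alus)
  .editability_from_matches(sites, alus, m, g_eff)
}

#' Coverage filters for per-Alu editability
#'
#' Keeps elements measured deeply enough for a stable per-element average:
#' at least `min_sites` distinct covered adenosine positions along the
#' element and at least `min_depth` sequenced adenosine/inosine read bases
#' in total. Both thresholds are inclusive.
#'
#' @param records Per-Alu editability table ([aggregate_site_counts()]).
#' @param min_sites Minimum covered adenosine positions (default 30).
#' @param min_depth Minimum total `a + g` read bases (default 1000).
#' @return The surviving rows of `records`.
#' @export
apply_coverage_filters <- function(records, min_sites = 30, min_depth = 1000) {
  stopifnot(min_sites >= 0, min_depth >= 0)
  keep <- records$n_sites_covered >= min_sites &
    (records$total_a + records$total_g) >= min_depth
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the per-Alu editability table
#' @param records Output of [aggregate_site_counts()] /
#'   [apply_coverage_filters()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_editability_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
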