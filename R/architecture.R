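#' Gap distance between two repeat elements
#'
#' Distance between nearest edges of two intervals on the same chromosome,
#' in bp: `0` for touching, overlapping, or nested elements (a nested
#' inverted pair is "at zero distance" even though pairing is geometrically
#' constrained there).
#'
#' @param a,b One-row repeat records (anything with `chrom`, `start`,
#'   `end` fields, 0-based half-open).
#' @return Non-negative integer gap in bp.
#' @export
pair_gap_distance <- function(a, b) {
  if (a$chrom != b$chrom) stop("pair_gap_distance: elements on different chromosomes")
  max(0L, max(a$start, b$start) - min(a$end, b$end))
}

#' Nearest reversely oriented neighbor of one element
#'
#' Among all repeats on the same chromosome with the opposite annotation
#' strand, the one minimizing the gap distance to `target`; ties broken by
#' smaller `start`, then `id`. The neighbor pool should contain all
#' annotated Alus on the chromosome (genic and intergenic), not only the
#' genic cohort.
#'
#' @param target One-row repeat record.
#' @param all_repeats Repeat table including `target`'s chromosome.
#' @return `list(neighbor_id =, d =)` or `NULL` when no opposite-strand
#'   repeat exists on the chromosome.
#' @export
nearest_reverse_neighbor <- function(target, all_repeats) {
  cand <- all_repeats[all_repeats$chrom == target$chrom &
                        all_repeats$strand != target$strand, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  gap <- pmax(0L, pmax(target$start, cand$start) - pmin(target$end, cand$end))
  o <- order(gap, cand$start, cand$id)
  list(neighbor_id = cand$id[o[1]], d = as.integer(gap[o[1]]))
}

#' Windowed neighbor counts around one element
#'
#' Counts repeats on the same chromosome (excluding the target itself, by
#' id) whose gap distance to the target is at most `window` bp, split into
#' same-strand and reverse-strand counts. Membership is measured edge to
#' edge and the boundary is inclusive.
#'
#' @param target One-row repeat record.
#' @param all_repeats Repeat table.
#' @param window Window half-width in bp on each side, positive.
#' @return `c(nss =, nrs =)` integer vector.
#' @export
neighbor_counts <- function(target, all_repeats, window) {
  stopifnot(window > 0)
  cand <- all_repeats[all_repeats$chrom == target$chrom &
                        all_repeats$id != target$id, , drop = FALSE]
  gap <- pmax(0L, pmax(target$start, cand$start) - pmin(target$end, cand$end))
  inw <- gap <= window
  c(nss = sum(inw & cand$strand == target$strand),
    nrs = sum(inw & cand$strand != target$strand))
}

# segment index of a 0-based position within a gene:
# > 0  : exon number k
# < 0  : -k for the intron following exon k (0 = intron before first exon)
# NA   : outside [tx_start, tx_end)
.segment_index <- function(pos, gene) {
  ex <- gene$exons[[1]]
  k <- findInterval(pos, ex[, "start"])
  in_exon <- k >= 1 & pos < ex[pmax(k, 1L), "end"]
  seg <- ifelse(in_exon, k, -k)
  seg[pos < gene$tx_start | pos >= gene$tx_end] <- NA_integer_
  seg
}

#' Intron/exon co-residence of an inverted Alu pair
#'
#' Each element is assigned to the exon or intron containing its midpoint.
#' Two paired elements in the same intron (or exon) form one uninterrupted
#' pre-mRNA duplex; a pair split across segments, or with the neighbor
#' outside the gene span, does not.
#'
#' @param alu One-row genic Alu record (with `gene_id`).
#' @param neighbor One-row repeat record (its nearest reverse neighbor).
#' @param gene The one-row gene record the Alu is assigned to.
#' @return One of `"same_exon"`, `"same_intron"`, `"different_segment"`,
#'   `"neighbor_outside_gene"`, `"unknown"`.
#' @export
classify_segment_relation <- function(alu, neighbor, gene) {
  if (is.null(neighbor) || is.null(gene)) return("unknown")
  if (neighbor$chrom != gene$chrom) return("neighbor_outside_gene")
  mid_a <- (alu$start + alu$end) %/% 2
  mid_n <- (neighbor$start + neighbor$end) %/% 2
  seg_a <- .segment_index(mid_a, gene)
  seg_n <- .segment_index(mid_n, gene)
  if (is.na(seg_n)) return("neighbor_outside_gene")
  if (is.na(seg_a)) return("unknown")
  if (seg_a == seg_n) {
    if (seg_a > 0) "same_exon" else "same_intron"
  } else {
    "different_segment"
  }
}

# nearest reversely oriented repeat for every query element, with the
# documented deterministic tie-break (minimal gap, then smaller start,
# then smaller id). Sorted-vector search: for a disjoint candidate the
# gap is minimized by the largest end to the left / smallest start to
# the right; overlapping or touching candidates (gap 0) are enumerated
# with findOverlaps(maxgap = 0). A left candidate always has a smaller
# start than a right candidate at the same gap.
.nearest_reverse_all <- function(genic_alus, all_repeats) {
  n <- nrow(genic_alus)
  nb_idx <- rep(NA_integer_, n)
  nb_d <- rep(NA_integer_, n)
  for (ch in unique(genic_alus$chrom)) {
    for (s in c("+", "-")) {
      q <- which(genic_alus$chrom == ch & genic_alus$strand == s)
      if (!length(q)) next
      sj <- which(all_repeats$chrom == ch & all_repeats$strand != s)
      if (!length(sj)) next
      s_start <- all_repeats$start[sj]
      s_end <- all_repeats$end[sj]
      s_id <- all_repeats$id[sj]
      qs <- genic_alus$start[q]
      qe <- genic_alus$end[q]

      # best left candidate per distinct end value
      oL <- order(s_end, s_start, s_id)
      firstL <- !duplicated(s_end[oL])
      ends_u <- s_end[oL][firstL]
      winL <- oL[firstL]
      kL <- findInterval(qs, ends_u)
      left_gap <- ifelse(kL >= 1, qs - ends_u[pmax(kL, 1L)], Inf)

      # best right candidate per distinct start value
      oR <- order(s_start, s_id)
      firstR <- !duplicated(s_start[oR])
      starts_u <- s_start[oR][firstR]
      winR <- oR[firstR]
      kR <- findInterval(qe - 1L, starts_u) + 1L
      right_gap <- ifelse(kR <= length(starts_u),
                          starts_u[pmin(kR, length(starts_u))] - qe, Inf)

      d <- pmin(left_gap, right_gap)
      use_left <- left_gap <= right_gap
      loc <- ifelse(use_left, winL[pmax(kL, 1L)],
                    winR[pmin(kR, length(starts_u))])

      # overlapping/touching candidates: gap 0, min (start, id) wins
      hits <- GenomicRanges::findOverlaps(
        GenomicRanges::GRanges(ch, IRanges::IRanges(qs + 1L, qe)),
        GenomicRanges::GRanges(ch, IRanges::IRanges(s_start + 1L, s_end)),
        maxgap = 0L)
      if (length(hits)) {
        qh <- S4Vectors::queryHits(hits)
        sh <- S4Vectors::subjectHits(hits)
        o <- order(qh, s_start[sh], s_id[sh])
        first <- !duplicated(qh[o])
        d[qh[o][first]] <- 0
        loc[qh[o][first]] <- sh[o][first]
      }
      ok <- is.finite(d)
      nb_idx[q[ok]] <- sj[loc[ok]]
      nb_d[q[ok]] <- as.integer(d[ok])
    }
  }
  list(idx = nb_idx, d = nb_d)
}

# vectorized segment indices: one call for all (position, gene_row) pairs,
# flattening every gene's exon list into one sorted table keyed by
# gene_row * 2^31 + position (exact in doubles for coordinates < 2^31)
.segment_index_vec <- function(pos, gene_row, genes) {
  nex <- vapply(genes$exons, nrow, 1L)
  grow_ex <- rep(seq_len(nrow(genes)), nex)
  ex_start <- unlist(lapply(genes$exons, function(m) m[, "start"]), use.names = FALSE)
  ex_end <- unlist(lapply(genes$exons, function(m) m[, "end"]), use.names = FALSE)
  off <- cumsum(nex) - nex
  KM <- 2^31
  j <- findInterval(gene_row * KM + pos, grow_ex * KM + ex_start)
  k_local <- pmax(j - off[gene_row], 0L)
  in_gene_block <- k_local >= 1 & k_local <= nex[gene_row]
  in_exon <- in_gene_block & pos < ex_end[pmax(j, 1L)]
  seg <- ifelse(in_exon, k_local, -k_local)
  seg[pos < genes$tx_start[gene_row] | pos >= genes$tx_end[gene_row]] <- NA_integer_
  seg
}

.segment_relation_vec <- function(genic_alus, all_repeats, nb_idx, genes,
                                  gene_row) {
  n <- nrow(genic_alus)
  segrel <- rep("unknown", n)
  ok <- which(!is.na(nb_idx) & !is.na(gene_row))
  if (!length(ok)) return(segrel)
  mid_a <- (genic_alus$start[ok] + genic_alus$end[ok]) %/% 2
  mid_n <- (all_repeats$start[nb_idx[ok]] + all_repeats$end[nb_idx[ok]]) %/% 2
  gr <- gene_row[ok]
  off_chrom <- all_repeats$chrom[nb_idx[ok]] != genes$chrom[gr]
  seg_a <- .segment_index_vec(mid_a, gr, genes)
  seg_n <- .segment_index_vec(mid_n, gr, genes)
  rel <- ifelse(off_chrom | is.na(seg_n), "neighbor_outside_gene",
         ifelse(is.na(seg_a), "unknown",
         ifelse(seg_a == seg_n & seg_a > 0, "same_exon",
         ifelse(seg_a == seg_n, "same_intron", "different_segment"))))
  segrel[ok] <- rel
  segrel
}

#' Percent identity of an inverted repeat pair by local alignment
#'
#' Smith–Waterman local alignment with BLASTN-like scoring (match +2,
#' mismatch -3, gap open -5, gap extend -2), used as a fast proxy for the
#' pairing potential of the duplex the two elements can form. The second
#' sequence is reverse-complemented first (the pair is on opposite
#' strands), so two elements copied from the same consensus align directly.
#' Identity is `100 * matches / alignment_columns` of the best local
#' alignment (gap columns count in the denominator; `N` never counts as a
#' match).
#'
#' @param seq_a,seq_b Nucleotide strings (ACGTN alphabet).
#' @param revcomp_b Reverse-complement `seq_b` before aligning
#'   (default `TRUE`).
#' @return Percent identity in `[0, 100]`; `0` for an empty best local
#'   alignment.
#' @export
pair_identity <- function(seq_a, seq_b, revcomp_b = TRUE) {
  stopifnot(is.character(seq_a), is.character(seq_b),
            nzchar(seq_a), nzchar(seq_b))
  if (grepl("[^ACGTNacgtn]", seq_a) || grepl("[^ACGTNacgtn]", seq_b)) {
    stop("pair_identity: sequences must contain only A, C, G, T, N")
  }
  a <- toupper(seq_a)
  b <- toupper(seq_b)
  if (revcomp_b) {
    b <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(b)))
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "local",
    substitutionMatrix = .aluedit_submat(),
    gapOpening = 5, gapExtension = 2
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ncol_aln <- length(pa)
  if (ncol_aln == 0) return(0)
  matches <- sum(pa == sb & pa %in% c("A", "C", "G", "T"))
  100 * matches / ncol_aln
}

# match +2 / mismatch -3 over ACGT; N is always a mismatch
.aluedit_submat <- function() {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(-3, 5, 5, dimnames = list(letters, letters))
  diag(m) <- 2
  m["N", "N"] <- -3
  m
}

#' Architecture covariates for a genic Alu cohort
#'
#' One row per genic Alu: distance `d` to the nearest reversely oriented
#' repeat on the chromosome (NA when none exists), that neighbor's id and
#' length, same-strand/reverse-strand counts within two windows, the
#' intron/exon relation of the pair, optional pair percent identity, and
#' family/subfamily agreement with the neighbor. The neighbor pool is
#' `all_repeats` — every annotated Alu, genic or not.
#'
#' @param genic_alus Output of [select_genic_alus()].
#' @param all_repeats Full repeat table (must contain `genic_alus` rows,
#'   matched by `id`).
#' @param genes Gene table from [read_gene_models()].
#' @param sequences Optional named character vector (or
#'   [Biostrings::DNAStringSet]) of element sequences keyed by repeat id;
#'   when supplied, `pair_identity_pct` is computed for each pair.
#' @param window_large,window_small Window half-widths in bp
#'   (defaults 10000 and 2000).
#' @return A `data.frame` with columns `alu_id`, `d`, `neighbor_id`,
#'   `neighbor_length`, `nss_10k`, `nrs_10k`, `nss_2k`, `nrs_2k`,
#'   `segment_relation`, `pair_identity_pct`, `same_family`,
#'   `same_subfamily`, plus `expressed_strand_class`, `family` and
#'   `length` carried over for modelling.
#' @export
build_feature_table <- function(genic_alus, all_repeats, genes,
                                sequences = NULL,
                                window_large = 10000, window_small = 2000) {
  stopifnot(nrow(genic_alus) > 0, nrow(all_repeats) > 0)
  idx_in_all <- match(genic_alus$id, all_repeats$id)
  if (anyNA(idx_in_all)) stop("genic alus must be present in all_repeats (id mismatch)")

  gr_all <- GenomicRanges::GRanges(all_repeats$chrom,
                                   IRanges::IRanges(all_repeats$start + 1L, all_repeats$end))
  gr_q <- gr_all[idx_in_all]
  n <- nrow(genic_alus)

  ## nearest reversely oriented neighbor, deterministic tie-break
  nearest <- .nearest_reverse_all(genic_alus, all_repeats)
  nb_idx <- nearest$idx
  nb_d <- nearest$d

  ## windowed strand-split counts (gap <= window, inclusive; self excluded)
  count_window <- function(window) {
    hits <- GenomicRanges::findOverlaps(gr_q, gr_all, maxgap = window)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    keep <- idx_in_all[qh] != sh
    qh <- qh[keep]; sh <- sh[keep]
    same <- genic_alus$strand[qh] == all_repeats$strand[sh]
    nss <- tabulate(qh[same], nbins = n)
    nrs <- tabulate(qh[!same], nbins = n)
    list(nss = nss, nrs = nrs)
  }
  w10 <- count_window(window_large)
  w2 <- count_window(window_small)

  ## segment relation of the pair within the assigned gene (vectorized)
  gene_row <- match(genic_alus$gene_id, genes$gene_id)
  has_nb <- !is.na(nb_idx)
  segrel <- .segment_relation_vec(genic_alus, all_repeats, nb_idx, genes,
                                  gene_row)

  ## pair identity (optional) and family relations
  ident <- rep(NA_real_, n)
  if (!is.null(sequences)) {
    seqs <- if (methods::is(sequences, "DNAStringSet")) {
      stats::setNames(as.character(sequences), names(sequences))
    } else sequences
    for (i in which(has_nb)) {
      sa <- seqs[[genic_alus$id[i]]]
      sb <- seqs[[all_repeats$id[nb_idx[i]]]]
      if (!is.null(sa) && !is.null(sb)) ident[i] <- pair_identity(sa, sb)
    }
  }
  nb_name <- ifelse(has_nb, all_repeats$name[nb_idx], NA_character_)
  nb_family <- ifelse(has_nb, all_repeats$family[nb_idx], NA_character_)

  data.frame(
    alu_id = genic_alus$id,
    d = nb_d,
    neighbor_id = ifelse(has_nb, all_repeats$id[nb_idx], NA_character_),
    neighbor_length = ifelse(has_nb, all_repeats$length[nb_idx], NA_integer_),
    nss_10k = w10$nss, nrs_10k = w10$nrs,
    nss_2k = w2$nss, nrs_2k = w2$nrs,
    segment_relation = segrel,
    pair_identity_pct = ident,
    same_family = ifelse(has_nb, genic_alus$family == nb_family, NA),
    same_subfamily = ifelse(has_nb, genic_alus$name == nb_name, NA),
    expressed_strand_class = genic_alus$expressed_strand_class,
    family = genic_alus$family,
    length = genic_alus$length,
    stringsAsFactors = FALSE
  )
}

#' Write the per-Alu feature table
#' @param features Output of [build_feature_table()].
#' @param path Output TSV path; absent values are written as `NA`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
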