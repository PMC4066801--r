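# independent brute-force oracles, kept deliberately naive

bf_gap <- function(s1, e1, s2, e2) max(0L, max(s1, s2) - min(e1, e2))

# O(n^2) nearest reversely oriented neighbor for every row: all pairwise
# gaps computed, minimum selected with (gap, start, id) ordering
bf_nearest_reverse <- function(df) {
  n <- nrow(df)
  out_id <- rep(NA_character_, n)
  out_d <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    cand <- which(df$chrom == df$chrom[i] & df$strand != df$strand[i])
    cand <- setdiff(cand, i)
    if (!length(cand)) next
    g <- pmax(0L, pmax(df$start[i], df$start[cand]) -
                pmin(df$end[i], df$end[cand]))
    o <- order(g, df$start[cand], df$id[cand])
    out_id[i] <- df$id[cand[o[1]]]
    out_d[i] <- g[o[1]]
  }
  data.frame(neighbor_id = out_id, d = out_d, stringsAsFactors = FALSE)
}

# O(n^2) windowed strand-split neighbor counts
bf_neighbor_counts <- function(df, window) {
  n <- nrow(df)
  nss <- integer(n); nrs <- integer(n)
  for (i in seq_len(n)) {
    j <- setdiff(which(df$chrom == df$chrom[i]), i)
    if (!length(j)) next
    g <- pmax(0L, pmax(df$start[i], df$start[j]) - pmin(df$end[i], df$end[j]))
    inw <- g <= window
    nss[i] <- sum(inw & df$strand[j] == df$strand[i])
    nrs[i] <- sum(inw & df$strand[j] != df$strand[i])
  }
  data.frame(nss = nss, nrs = nrs)
}

# full affine-gap Smith-Waterman DP oracle: best local score plus the set
# of percent identities achievable by optimal alignments (all-paths
# traceback, capped)
sw_oracle <- function(a, b, match = 2, mismatch = -3, open = 5, ext = 2,
                      max_paths = 2000) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes A)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes B)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (A[i] == B[j] && A[i] != "N") match else mismatch
      M[i + 1, j + 1] <- s + max(0, M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
    }
  }
  best <- max(M)
  if (best <= 0) return(list(score = 0, identities = 0, paths = 0L))
  idents <- new.env()
  n_paths <- 0L
  eps <- 1e-9
  # walk back through every optimal predecessor chain, counting
  # matches and alignment columns; record identity at each valid start
  walk <- function(i, j, state, matches, cols) {
    if (n_paths >= max_paths) return()
    if (state == "M") {
      s <- if (A[i - 1] == B[j - 1] && A[i - 1] != "N") match else mismatch
      matches <- matches + (s == match)
      cols <- cols + 1L
      prev <- M[i, j] - s
      if (abs(prev) < eps) {            # fresh local start is optimal here
        assign(sprintf("%.6f", 100 * matches / cols), TRUE, envir = idents)
        n_paths <<- n_paths + 1L
      }
      for (st in c("M", "X", "Y")) {
        v <- switch(st, M = M[i - 1, j - 1], X = X[i - 1, j - 1],
                    Y = Y[i - 1, j - 1])
        if (v > -1e8 && abs(v - prev) < eps) walk(i - 1, j - 1, st, matches, cols)
      }
    } else if (state == "X") {
      cols <- cols + 1L
      if (abs(X[i, j] - (M[i - 1, j] - open - ext)) < eps) {
        walk(i - 1, j, "M", matches, cols)
      }
      if (abs(X[i, j] - (X[i - 1, j] - ext)) < eps) {
        walk(i - 1, j, "X", matches, cols)
      }
    } else {
      cols <- cols + 1L
      if (abs(Y[i, j] - (M[i, j - 1] - open - ext)) < eps) {
        walk(i, j - 1, "M", matches, cols)
      }
      if (abs(Y[i, j] - (Y[i, j - 1] - ext)) < eps) {
        walk(i, j - 1, "Y", matches, cols)
      }
    }
  }
  ends <- which(M == best, arr.ind = TRUE)
  for (r in seq_len(nrow(ends))) {
    walk(ends[r, 1], ends[r, 2], "M", 0L, 0L)
  }
  list(score = best,
       identities = sort(as.numeric(ls(idents))),
       paths = n_paths)
}

# direct re-scan of sites against one element, for sum conservation
bf_alu_depth <- function(sites, alu) {
  sel <- sites$chrom == alu$chrom & sites$pos >= alu$start &
    sites$pos < alu$end & sites$strand == alu$gene_strand
  sum(sites$a_reads[sel] + sites$g_reads[sel])
}
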