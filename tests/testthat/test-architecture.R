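test_that("gap distance: edge gap, nesting, adjacency, symmetry, chrom error", {
  r <- make_repeats(c(100, 1000, 300, 400), c(400, 1300, 400, 700),
                    c("+", "-", "-", "-"))
  expect_equal(pair_gap_distance(r[1, ], r[2, ]), 600)
  big <- make_repeats(100, 700, "+")
  expect_equal(pair_gap_distance(big[1, ], r[3, ]), 0)   # nested
  expect_equal(pair_gap_distance(r[1, ], r[4, ]), 0)     # touching
  # symmetry on random pairs
  set.seed(5)
  for (i in 1:50) {
    ab <- random_layout(2, n_chrom = 1)
    expect_equal(pair_gap_distance(ab[1, ], ab[2, ]),
                 pair_gap_distance(ab[2, ], ab[1, ]))
  }
  other <- make_repeats(100, 400, "+", chrom = "chr9")
  expect_error(pair_gap_distance(r[1, ], other[1, ]), "different chromosomes")
})

test_that("nearest reverse neighbor picks the minimal gap with stated tie-breaks", {
  df <- make_repeats(c(5000, 1000, 6000), c(5300, 1300, 6300),
                     c("+", "-", "-"))
  nb <- nearest_reverse_neighbor(df[1, ], df)
  expect_equal(nb$neighbor_id, "r003")
  expect_equal(nb$d, 700L)
  # only same-strand elements -> absent
  same <- make_repeats(c(100, 900), c(400, 1200), c("+", "+"))
  expect_null(nearest_reverse_neighbor(same[1, ], same))
  # equal gaps on both sides -> smaller start wins
  tie <- make_repeats(c(2000, 1000, 2900), c(2300, 1400, 3300),
                      c("+", "-", "-"))
  expect_equal(nearest_reverse_neighbor(tie[1, ], tie)$neighbor_id, "r002")
})

test_that("window counts split by strand with an inclusive gap boundary", {
  # 3 same-strand and 2 reverse within 10 kb, 1 reverse beyond
  df <- make_repeats(
    c(50000, 41000, 55000, 58000, 45000, 52000, 75000),
    c(50300, 41300, 55300, 58300, 45300, 52300, 75300),
    c("+",   "+",   "+",   "+",   "-",   "-",   "-"))
  expect_equal(neighbor_counts(df[1, ], df, 10000), c(nss = 3L, nrs = 2L))
  lone <- make_repeats(100, 400, "+")
  expect_equal(neighbor_counts(lone[1, ], lone, 10000), c(nss = 0L, nrs = 0L))
  # element exactly at gap == window is counted
  edge <- make_repeats(c(1000, 3300), c(1300, 3600), c("+", "-"))
  expect_equal(neighbor_counts(edge[1, ], edge, 2000)[["nrs"]], 1L)
  expect_equal(neighbor_counts(edge[1, ], edge, 1999)[["nrs"]], 0L)
})

test_that("feature table agrees with scalar operations on a constructed cohort", {
  set.seed(21)
  df <- random_layout(60, n_chrom = 2)
  genic <- as_genic(df)
  feats <- build_feature_table(genic, df, dummy_genes())
  expect_equal(nrow(feats), nrow(df))
  for (i in seq_len(nrow(df))) {
    nb <- nearest_reverse_neighbor(df[i, ], df)
    if (is.null(nb)) {
      expect_true(is.na(feats$d[i]))
    } else {
      expect_equal(feats$d[i], nb$d)
      expect_equal(feats$neighbor_id[i], nb$neighbor_id)
    }
    expect_equal(c(nss = feats$nss_10k[i], nrs = feats$nrs_10k[i]),
                 neighbor_counts(df[i, ], df, 10000))
    expect_equal(c(nss = feats$nss_2k[i], nrs = feats$nrs_2k[i]),
                 neighbor_counts(df[i, ], df, 2000))
  }
  # window nesting and close-pair consistency invariants
  expect_true(all(feats$nss_2k <= feats$nss_10k))
  expect_true(all(feats$nrs_2k <= feats$nrs_10k))
  close_d <- which(!is.na(feats$d) & feats$d <= 2000)
  expect_true(all(feats$nrs_2k[close_d] >= 1))
})

test_that("features are invariant under coordinate translation", {
  set.seed(33)
  df <- random_layout(40, n_chrom = 1)
  genic <- as_genic(df)
  f1 <- build_feature_table(genic, df, dummy_genes())
  shift <- 13571L
  df2 <- df; df2$start <- df2$start + shift; df2$end <- df2$end + shift
  genic2 <- as_genic(df2)
  f2 <- build_feature_table(genic2, df2, dummy_genes())
  expect_equal(f1$d, f2$d)
  expect_equal(f1$nss_10k, f2$nss_10k)
  expect_equal(f1$nrs_10k, f2$nrs_10k)
})

test_that("segment relation classifies midpoint co-residence", {
  gene <- make_gene("g1", "chr1", "+", 0, 20000,
                    cbind(start = c(0L, 5000L, 12000L),
                          end = c(1000L, 6000L, 13000L)))
  alu_in_i2 <- as_genic(make_repeats(7000, 7300, "+"), "g1")
  nb_in_i2 <- make_repeats(9000, 9300, "-")
  expect_equal(classify_segment_relation(alu_in_i2[1, ], nb_in_i2[1, ], gene[1, ]),
               "same_intron")
  alu_in_e2 <- as_genic(make_repeats(5100, 5400, "+"), "g1")
  nb_in_e2 <- make_repeats(5500, 5800, "-")
  expect_equal(classify_segment_relation(alu_in_e2[1, ], nb_in_e2[1, ], gene[1, ]),
               "same_exon")
  expect_equal(classify_segment_relation(alu_in_e2[1, ], nb_in_i2[1, ], gene[1, ]),
               "different_segment")
  nb_beyond <- make_repeats(25000, 25300, "-")
  expect_equal(classify_segment_relation(alu_in_i2[1, ], nb_beyond[1, ], gene[1, ]),
               "neighbor_outside_gene")
})

test_that("vectorized segment relations in the feature table match the scalar rule", {
  set.seed(44)
  gene <- make_gene("g1", "chr1", "+", 0, 50000,
                    cbind(start = c(0L, 10000L, 30000L),
                          end = c(2000L, 15000L, 32000L)))
  start <- sample(0:49000, 30)
  df <- make_repeats(start, start + 300, sample(c("+", "-"), 30, replace = TRUE))
  genic <- as_genic(df, "g1")
  feats <- build_feature_table(genic, df, gene)
  for (i in seq_len(nrow(df))) {
    if (is.na(feats$neighbor_id[i])) next
    nb <- df[df$id == feats$neighbor_id[i], ]
    expect_equal(feats$segment_relation[i],
                 classify_segment_relation(genic[i, ], nb, gene[1, ]),
                 info = paste("element", i))
  }
})

test_that("pair identity handles self, point substitution, and rejects bad input", {
  set.seed(9)
  s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_equal(pair_identity(s, rc), 100)
  s100 <- substr(s, 1, 100)
  mut <- s100
  pos <- 50
  substr(mut, pos, pos) <- setdiff(c("A", "C", "G", "T"), substr(s100, pos, pos))[1]
  rc_mut <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(mut)))
  expect_equal(pair_identity(s100, rc_mut), 99)
  expect_error(pair_identity("ACGTX", "ACGT"), "A, C, G, T, N")
})

test_that("local-alignment identity matches the exhaustive DP oracle on 30-mers", {
  set.seed(17)
  for (rep in 1:25) {
    a <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = "")
    oracle <- sw_oracle(a, b)
    got <- pair_identity(a, b, revcomp_b = FALSE)
    expect_true(any(abs(oracle$identities - got) < 1e-6),
                info = sprintf("rep %d: got %.4f, oracle {%s}", rep, got,
                               paste(round(oracle$identities, 4), collapse = ", ")))
  }
})

test_that("identity fields appear only when sequences are supplied", {
  df <- make_repeats(c(100, 1000), c(400, 1300), c("+", "-"))
  genic <- as_genic(df)
  f0 <- build_feature_table(genic, df, dummy_genes())
  expect_true(all(is.na(f0$pair_identity_pct)))
  set.seed(3)
  s1 <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  seqs <- c(r001 = s1,
            r002 = as.character(Biostrings::reverseComplement(Biostrings::DNAString(s1))))
  f1 <- build_feature_table(genic, df, dummy_genes(), sequences = seqs)
  expect_equal(f1$pair_identity_pct, c(100, 100))
  # family/subfamily relations come from names
  expect_true(all(f1$same_family))
  expect_true(all(f1$same_subfamily))
})
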