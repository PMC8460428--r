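test_that("extract_fragments slides a step-1 window and excludes N windows", {
  g <- as_genome(S = "ACGTACGT")
  fs <- extract_fragments(g, region_spec("S", 0, 8), k = 8)
  expect_identical(nrow(fs$fragments), 1L)
  expect_identical(fs$fragments$seq_, "ACGTACGT")

  fs4 <- extract_fragments(g, region_spec("S", 0, 8), k = 4)
  expect_identical(nrow(fs4$fragments), 5L)  # L - k + 1
  expect_identical(fs4$fragments$offset, as.numeric(0:4))

  # windows overlapping the N are excluded; verify against brute force
  gn <- as_genome(S = "ACGNACGT")
  fsn <- extract_fragments(gn, region_spec("S", 0, 8), k = 4)
  brute <- sapply(1:5, function(i) substr("ACGNACGT", i, i + 3))
  keep <- !grepl("N", brute)
  expect_identical(fsn$fragments$seq_, brute[keep])
  expect_identical(fsn$n_excluded_N, sum(!keep))

  expect_error(extract_fragments(g, region_spec("S", 0, 20), k = 4),
               "past chromosome end")
  expect_error(extract_fragments(g, region_spec("S", 0, 3), k = 4),
               "shorter than fragment length")
})

test_that("locate_matches reports all overlapping occurrences", {
  g <- as_genome(src = "AAAA", tgt = "AAAAAA")
  fs <- extract_fragments(g, region_spec("src", 0, 4), k = 4)
  hits <- locate_matches(fs, g, "tgt")
  fwd <- hits[hits$strand == "+", ]
  expect_identical(fwd$pos, c(0, 1, 2))
  # reverse complement TTTT matches nowhere
  expect_identical(nrow(hits[hits$strand == "-", ]), 0L)
})

test_that("palindromic fragments are counted once per position", {
  g <- as_genome(src = "GAATTC", tgt = "CCCCGAATTCCCCC")
  fs <- extract_fragments(g, region_spec("src", 0, 6), k = 6)
  hits <- locate_matches(fs, g, "tgt", strand_mode = "both")
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$pos, 4)
  expect_identical(hits$strand, "+")
})

test_that("exclude region removes hits starting inside it", {
  g <- as_genome(src = "ACGT", tgt = "ACGTACGT")
  fs <- extract_fragments(g, region_spec("src", 0, 4), k = 4)
  all_hits <- locate_matches(fs, g, "tgt")
  expect_gt(nrow(all_hits), 0)
  none <- locate_matches(fs, g, "tgt", exclude = region_spec("tgt", 0, 8))
  expect_identical(nrow(none), 0L)
  # half-open: a hit starting exactly at exclude$end survives
  part <- locate_matches(fs, g, "tgt", exclude = region_spec("tgt", 0, 4))
  expect_identical(part$pos, 4)
})

test_that("locate_matches errors on unknown chromosome", {
  g <- as_genome(src = "ACGTACGT")
  fs <- extract_fragments(g, region_spec("src", 0, 8), k = 4)
  expect_error(locate_matches(fs, g, "nope"), "not in genome")
})

test_that("locate_matches agrees with the naive character-scan oracle", {
  set.seed(101)
  for (i in 1:40) {
    len <- sample(60:400, 1)
    k <- sample(4:12, 1)
    tgt <- random_genome_seq(len, at = 0.7)  # AT-rich boosts repeat matches
    src_start <- sample(0:(len - k - 5), 1)
    src <- region_spec("T", src_start, src_start + k + sample(0:5, 1))
    g <- as_genome(T = tgt)
    fs <- extract_fragments(g, src, k)
    for (sm in c("both", "forward_only")) {
      hits <- locate_matches(fs, g, "T", strand_mode = sm)
      oracle <- naive_locate(fs$fragments$seq_, tgt, strand_mode = sm)
      got <- hits[order(hits$pos, hits$strand, hits$fragment),
                  c("pos", "strand", "fragment")]
      want <- oracle[order(oracle$pos, oracle$strand, oracle$fragment), ]
      expect_identical(unname(as.list(got)), unname(as.list(want)))
    }
  }
})

test_that("hit lists are deterministic and sorted by (chrom, pos, strand)", {
  set.seed(5)
  tgt <- random_genome_seq(2000, at = 0.7)
  g <- as_genome(T = tgt)
  fs <- extract_fragments(g, region_spec("T", 100, 160), k = 6)
  h1 <- locate_matches(fs, g, "T")
  h2 <- locate_matches(fs, g, "T")
  expect_identical(h1, h2)
  expect_true(!is.unsorted(h1$pos))
})

test_that("build_lff assigns hits by half-open band intervals", {
  bands <- band_map(rep("T", 2), c(0, 1000), c(1000, 2000), c("b1", "b2"))
  hits <- data.table::data.table(
    chrom = "T", pos = seq(0, 900, by = 100), strand = "+",
    fragment = "AAAA", weight = 1L)
  prof <- build_lff(hits, bands)
  expect_identical(prof$raw, c(10, 0))
  expect_identical(prof$per_kb, c(10, 0))

  # a hit at pos == band1.end belongs to band2
  hb <- data.table::data.table(chrom = "T", pos = 1000, strand = "+",
                               fragment = "AAAA", weight = 1L)
  pb <- build_lff(hb, bands)
  expect_identical(pb$raw, c(0, 1))
})

test_that("LFF conserves totals and matches brute-force interval counts", {
  set.seed(42)
  for (i in 1:20) {
    n_bands <- sample(2:6, 1)
    starts <- cumsum(c(0, sample(100:500, n_bands)))
    bands <- band_map(rep("T", n_bands), head(starts, -1), starts[-1],
                      paste0("b", seq_len(n_bands)))
    n_hits <- sample(5:50, 1)
    hits <- data.table::data.table(
      chrom = "T", pos = sample(0:(max(starts) + 200), n_hits, replace = TRUE),
      strand = "+", fragment = "AAAA", weight = sample(1:3, n_hits, TRUE))
    prof <- build_lff(hits, bands)
    expect_equal(sum(prof$raw) + attr(prof, "outside_band"),
                 attr(prof, "total_hits"))
    # brute-force membership count per band
    for (b in seq_len(n_bands)) {
      inside <- hits$pos >= bands$start[b] & hits$pos < bands$end[b]
      expect_equal(prof$raw[b], sum(hits$weight[inside]))
    }
  }
})

test_that("adding a hit inside a band never decreases its raw LFF", {
  set.seed(9)
  bands <- band_map("T", 0, 1000, "b1")
  hits <- data.table::data.table(chrom = "T", pos = sample(0:999, 20, TRUE),
                                 strand = "+", fragment = "ACGT", weight = 1L)
  base <- build_lff(hits, bands)$raw
  more <- rbind(hits, data.table::data.table(chrom = "T", pos = 500,
                                             strand = "+", fragment = "ACGT",
                                             weight = 1L))
  expect_gte(build_lff(more, bands)$raw, base)
})

test_that("proportional weighting multiplies by source multiplicity", {
  # source contains the same 4-mer twice; one target site
  g <- as_genome(src = "ACGTACGT", tgt = "GGGGACGTGGGG")
  fs <- extract_fragments(g, region_spec("src", 0, 8), k = 4)
  hits <- locate_matches(fs, g, "tgt", strand_mode = "forward_only")
  bands <- band_map("tgt", 0, 12, "b1")
  expect_identical(build_lff(hits, bands, weighting = "proportional")$raw[1], 2)
  expect_identical(build_lff(hits, bands, weighting = "unique")$raw[1], 1)
})

test_that("scan_region excludes self-hits by default", {
  sim <- make_genome(small_spec())
  src <- sim$truth$source_region
  sc <- scan_region(sim$genome, src, sim$bands, k = 30)
  src_band <- sprintf("B%02d", sim$truth$spec$source_band)
  expect_identical(sc$profile$raw[sc$profile$band == src_band], 0)
  sc2 <- scan_region(sim$genome, src, sim$bands, k = 30, exclude_self = FALSE)
  expect_gt(sc2$profile$raw[sc2$profile$band == src_band], 0)
})
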