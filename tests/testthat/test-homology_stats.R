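test_that("spearman_rs handles perfect monotone association", {
  expect_equal(spearman_rs(1:3, c(10, 20, 30))$rS, 1)
  expect_equal(spearman_rs(1:3, c(3, 2, 1))$rS, -1)
})

test_that("spearman_rs equals the rank-then-Pearson oracle, with ties", {
  set.seed(21)
  for (i in 1:100) {
    n <- sample(5:30, 1)
    x <- sample.int(8, n, replace = TRUE)   # heavy ties
    y <- sample.int(8, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    r <- spearman_rs(x, y, p_method = "asymptotic")
    expect_equal(r$rS, rank_pearson(x, y), tolerance = 1e-12)
  }
})

test_that("spearman_rs matches the closed form on tie-free data", {
  set.seed(22)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(spearman_rs(x, y, p_method = "asymptotic")$rS,
                 spearman_closed_form(x, y), tolerance = 1e-12)
  }
})

test_that("spearman_rs drops NA pairs and needs three complete pairs", {
  r <- spearman_rs(c(1, 2, NA, 4, 5), c(2, 4, 6, NA, 10))
  expect_identical(r$n, 3L)
  expect_equal(r$rS, 1)
  expect_error(spearman_rs(c(1, NA, 3), c(2, 5, NA)), "3 complete pairs")
})

test_that("constant vectors give an undefined correlation, never significance", {
  r <- spearman_rs(c(1, 1, 1, 1), c(1, 2, 3, 4))
  expect_true(is.na(r$rS))
  expect_identical(r$p_value, 1)
  expect_false(r$significant)
})

test_that("asymptotic p agrees with cor.test and flags p < 0.01 only", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(12:40, 1)
    x <- rnorm(n); y <- x + rnorm(n, 0, 2)
    r <- spearman_rs(x, y, p_method = "asymptotic")
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    expect_equal(r$rS, unname(ct$estimate), tolerance = 1e-12)
    expect_identical(r$significant, r$p_value < 0.01)
  }
})

test_that("permutation p is reproducible and consistent with asymptotic", {
  set.seed(24)
  x <- rnorm(8); y <- x + rnorm(8, 0, 0.3)
  p1 <- spearman_rs(x, y, p_method = "permutation", seed = 5)$p_value
  p2 <- spearman_rs(x, y, p_method = "permutation", seed = 5)$p_value
  expect_identical(p1, p2)
  pa <- spearman_rs(x, y, p_method = "asymptotic")$p_value
  expect_lt(abs(p1 - pa), 0.05)
})

test_that("rS is invariant under strictly monotone transforms", {
  set.seed(25)
  x <- rnorm(15); y <- rnorm(15)
  base <- spearman_rs(x, y, p_method = "asymptotic")$rS
  expect_equal(spearman_rs(exp(x), y, p_method = "asymptotic")$rS, base)
  expect_equal(spearman_rs(x, y^3 + 5 * y, p_method = "asymptotic")$rS, base)
})

test_that("correlate_lff_fec pairs bands, drops the NA self-band", {
  bands <- band_map(rep("T", 11), seq(0, 10000, 1000), seq(1000, 11000, 1000),
                    paste0("b", 1:11))
  prof <- build_lff(data.table::data.table(
    chrom = "T", pos = rep(seq(500, 9500, 1000), times = 1:10),
    strand = "+", fragment = "A", weight = 1L), bands)
  # FEC = 2 * LFF + 1 on 10 bands, NA on the 11th (self) band
  fec <- data.table::data.table(band = paste0("b", 1:11),
                                S = c(2 * (1:10) + 1, NA_real_))
  data.table::setattr(fec, "class", c("fec_table", class(fec)))
  cr <- correlate_lff_fec(prof, fec, "S")
  expect_equal(cr$rS, 1)
  expect_identical(cr$n, 10L)
  expect_false("b11" %in% attr(cr, "coverage")$bands_used)
  expect_error(correlate_lff_fec(prof, fec, "missing"), "not in FEC table")
})

test_that("correlate_lff_fec is invariant to band row order", {
  sim <- make_genome(small_spec())
  sc <- scan_region(sim$genome, sim$truth$source_region, sim$bands, k = 30)
  fec <- make_fec(sim$truth, noise = 2, seed = 3)
  r1 <- correlate_lff_fec(sc$profile, fec, "strainA")
  fec_shuf <- fec[sample(nrow(fec)), ]
  data.table::setattr(fec_shuf, "class", class(fec))
  r2 <- correlate_lff_fec(sc$profile, fec_shuf, "strainA")
  expect_equal(r1$rS, r2$rS)
})

test_that("all-equal FEC yields no significance", {
  sim <- make_genome(small_spec())
  sc <- scan_region(sim$genome, sim$truth$source_region, sim$bands, k = 30)
  fec <- make_fec(sim$truth, noise = 0, densities = rep(1, 10))
  cr <- correlate_lff_fec(sc$profile, fec, "strainA")
  expect_true(is.na(cr$rS))
  expect_false(cr$significant)
})

test_that("length_sweep emits one row per (region, k, strain)", {
  sim <- make_genome(small_spec())
  fec <- make_fec(sim$truth, strains = c("s1", "s2"), noise = 0)
  tab <- length_sweep(sim$genome, list(source = sim$truth$source_region),
                      sim$bands, fec, k_values = 25L)
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$strain, c("s1", "s2"))
  expect_error(
    length_sweep(sim$genome, list(source = sim$truth$source_region),
                 sim$bands, fec, k_values = 1e6L),
    "exceeds region")
  expect_error(
    length_sweep(sim$genome, list(sim$truth$source_region), sim$bands, fec),
    "named list")
})

test_that("rank_fragments orders by NO with lexicographic ties", {
  set.seed(30)
  # plant one 20-mer 50 times in a random background
  unit <- random_genome_seq(20)
  bg <- random_genome_seq(30000)
  positions <- seq(1000, by = 550, length.out = 50)
  for (p in positions) substr(bg, p, p + 19) <- unit
  src <- paste0(unit, random_genome_seq(40))
  g <- as_genome(S = paste0(src, bg))
  fs <- extract_fragments(g, region_spec("S", 0, 60), k = 20)
  rep_ <- rank_fragments(fs, g, "S", exclude = region_spec("S", 0, 60),
                         top_n = 5)
  expect_identical(rep_$fragment[1], unit)
  expect_gte(rep_$NO[1], 50L)
  expect_true(all(diff(rep_$NO) <= 0))

  # top_n larger than the number of distinct fragments returns all
  all_rep <- rank_fragments(fs, g, "S", top_n = 10000)
  expect_identical(nrow(all_rep), length(unique(fs$fragments$seq_)))

  # excluding the whole chromosome zeroes NO
  none <- rank_fragments(fs, g, "S",
                         exclude = region_spec("S", 0, nchar(g[["S"]])),
                         top_n = 3)
  expect_true(all(none$NO == 0L))
})

test_that("self_complementarity scores palindromes and homopolymers", {
  expect_equal(self_complementarity("GAATTC"), 1)
  expect_equal(self_complementarity("AAAAAA"), 0)
  expect_error(self_complementarity("ACGTN"), "\\{A,C,G,T\\}")
})

test_that("self_complementarity matches brute-force common-substring search", {
  set.seed(31)
  for (i in 1:20) {
    s <- random_genome_seq(50)
    expect_equal(self_complementarity(s),
                 lcs_brute(s, oracle_revcomp(s)) / 50)
  }
})

test_that("detect_simple_repeat finds dinucleotide and longer units", {
  r <- detect_simple_repeat(strrep("AT", 15))
  expect_identical(r$unit, "AT")
  expect_identical(r$copies, 15L)

  r2 <- detect_simple_repeat("ACGTACGTACGT")
  expect_identical(r2$unit, "ACGT")
  expect_identical(r2$copies, 3L)

  r3 <- detect_simple_repeat(strrep("A", 12))
  expect_identical(r3$unit, "A")

  # shortest qualifying unit wins: (ATAT)n is reported as (AT)n
  expect_identical(detect_simple_repeat(strrep("ATAT", 6))$unit, "AT")
})

test_that("detect_simple_repeat rejects non-repetitive sequence", {
  set.seed(32)
  # exhaustive check: no unit of length <= 6 covers >= 90 % in tandem
  covers <- function(s) {
    L <- nchar(s)
    for (ul in 1:6) for (p in 1:(L - 2 * ul + 1)) {
      u <- substr(s, p, p + ul - 1)
      cp <- 1; q <- p + ul
      while (q + ul - 1 <= L && substr(s, q, q + ul - 1) == u) {
        cp <- cp + 1; q <- q + ul
      }
      if (cp * ul >= 0.9 * L) return(TRUE)
    }
    FALSE
  }
  for (i in 1:15) {
    s <- random_genome_seq(30)
    expect_identical(!is.null(detect_simple_repeat(s)), covers(s))
  }
})
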