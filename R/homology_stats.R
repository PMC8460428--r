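# run code under a temporary RNG state so seeded internals do not
# perturb the caller's random stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Spearman rank-order correlation with significance call
#'
#' Tie-corrected Spearman rS (Pearson correlation of mid-ranks; equals the
#' closed form \eqn{1 - 6\sum d^2 / (n(n^2-1))} when tie-free) with a
#' two-sided p-value. Pairs with a missing value in either vector are
#' dropped. The p-value uses the large-sample t approximation for
#' `n >= 10` and a seeded label-permutation estimate for smaller samples
#' (`p_method = "auto"`); both methods can be forced.
#'
#' @param x,y numeric vectors of equal length.
#' @param p_method `"auto"` (default), `"asymptotic"` or `"permutation"`.
#' @param n_perm permutations for the permutation p-value (default 10000).
#' @param seed seed for the permutation p-value.
#' @param alpha significance threshold (default 0.01; correlations with
#'   `p >= alpha` are flagged non-significant).
#' @return a `correlation_result`: list with `rS`, `n`, `p_value`,
#'   `significant`. `rS` is `NA` (with `p_value = 1`) when either vector is
#'   constant after NA removal, since ranks then carry no order information.
#' @export
spearman_rs <- function(x, y, p_method = c("auto", "asymptotic", "permutation"),
                        n_perm = 10000L, seed = 0L, alpha = 0.01) {
  p_method <- match.arg(p_method)
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- as.numeric(x[keep]); y <- as.numeric(y[keep])
  n <- length(x)
  if (n < 3L)
    stop_fmt("need >= 3 complete pairs for Spearman correlation, got %d", n)
  if (sd(x) == 0 || sd(y) == 0) {
    res <- list(rS = NA_real_, n = n, p_value = 1, significant = FALSE)
    class(res) <- "correlation_result"
    return(res)
  }
  rS <- cor(x, y, method = "spearman")
  if (p_method == "auto") p_method <- if (n < 10L) "permutation" else "asymptotic"
  p <- if (p_method == "asymptotic") {
    tval <- rS * sqrt((n - 2) / max(1 - rS^2, .Machine$double.eps))
    2 * stats::pt(-abs(tval), df = n - 2)
  } else {
    rx <- rank(x); ry <- rank(y)
    obs <- abs(rS)
    with_seed(seed, {
      hits <- sum(vapply(seq_len(n_perm), function(i)
        abs(cor(rx, sample(ry))) >= obs - 1e-12, logical(1)))
      (1 + hits) / (1 + n_perm)
    })
  }
  p <- min(p, 1)
  res <- list(rS = rS, n = n, p_value = p, significant = p < alpha)
  class(res) <- "correlation_result"
  res
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rS = %.4f (n = %d, p = %.3g)%s\n",
              x$rS, x$n, x$p_value,
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

#' Correlate an LFF profile with an FEC column
#'
#' Pairs per-band localized fragment frequencies with one strain's ectopic
#' contact frequencies on the bands common to both tables, drops NA pairs
#' (the source band, marked not-applicable, is always excluded this way),
#' and computes Spearman rS. Bands present on only one side are reported in
#' the `"coverage"` attribute.
#'
#' @param profile an `lff_profile` from [build_lff()].
#' @param fec a `fec_table`.
#' @param strain strain column to use.
#' @param exclude_band optional band name to drop explicitly (in addition
#'   to NA cells).
#' @param lff_value `"raw"` per-band hit counts (default; cytological bands
#'   are of comparable scale) or `"per_kb"` length-normalized values.
#' @param ... passed to [spearman_rs()].
#' @return a `correlation_result` with attribute `coverage` (list of
#'   `profile_only`, `fec_only`, `bands_used`).
#' @export
correlate_lff_fec <- function(profile, fec, strain, exclude_band = NULL,
                              lff_value = c("raw", "per_kb"), ...) {
  lff_value <- match.arg(lff_value)
  if (!strain %in% setdiff(names(fec), "band"))
    stop_fmt("strain '%s' not in FEC table (have: %s)", strain,
             paste(setdiff(names(fec), "band"), collapse = ", "))
  p <- data.table::as.data.table(profile)
  f <- data.table::as.data.table(fec)
  common <- intersect(p$band, f$band)
  if (!is.null(exclude_band)) common <- setdiff(common, exclude_band)
  m <- merge(p[band %in% common, c("band", lff_value), with = FALSE],
             f[band %in% common, c("band", strain), with = FALSE],
             by = "band")
  keep <- !is.na(m[[strain]])
  res <- spearman_rs(m[[lff_value]][keep], m[[strain]][keep], ...)
  attr(res, "coverage") <- list(profile_only = setdiff(p$band, f$band),
                                fec_only = setdiff(f$band, p$band),
                                bands_used = m$band[keep])
  res
}

#' Fragment-length sweep of LFF-FEC correlations
#'
#' Repeats the scan-and-correlate workflow over several fragment lengths
#' and source regions (typically the region of interest plus a control
#' region of comparable length) and every strain in the FEC table,
#' mirroring the 20/30/50 nt comparison used to pick the working fragment
#' length.
#'
#' @param genome a `genome_sequence`.
#' @param regions a named list of `region_spec` (e.g.
#'   `list(source = ..., control = ...)`).
#' @param bands a `band_map`.
#' @param fec a `fec_table`.
#' @param k_values integer vector of fragment lengths.
#' @param strains strain columns to correlate (default: all).
#' @param ... passed to [scan_region()] / [spearman_rs()] via
#'   [correlate_lff_fec()].
#' @return data.table with one row per (region, k, strain): columns
#'   `region`, `k`, `strain`, `n`, `rS`, `p_value`, `significant`.
#' @export
length_sweep <- function(genome, regions, bands, fec, k_values = c(20L, 30L, 50L),
                         strains = setdiff(names(fec), "band"), ...) {
  if (is.null(names(regions)) || any(!nzchar(names(regions))))
    stop_fmt("'regions' must be a named list of region specs")
  rows <- list()
  for (k in as.integer(k_values)) {
    for (rn in names(regions)) {
      reg <- regions[[rn]]
      if (region_length(reg) < k)
        stop_fmt("fragment length k=%d exceeds region '%s' length %s",
                 k, rn, format(region_length(reg), scientific = FALSE))
      sc <- scan_region(genome, reg, bands, k = k)
      for (s in strains) {
        cr <- correlate_lff_fec(sc$profile, fec, s, ...)
        rows[[length(rows) + 1L]] <- data.table::data.table(
          region = rn, k = k, strain = s, n = cr$n, rS = cr$rS,
          p_value = cr$p_value, significant = cr$significant)
      }
    }
  }
  data.table::rbindlist(rows)
}

#' Rank fragments by number of occurrences on the target chromosome
#'
#' Counts, for every distinct fragment sequence, its exact occurrences (NO)
#' on the target chromosome outside the source region, and reports the top
#' fragments with the bands they localize to, a per-fragment LFF-FEC
#' Spearman correlation (when an FEC table is supplied), a
#' self-complementarity score and a simple tandem-repeat annotation.
#'
#' @param fragments a `fragment_set`.
#' @param genome a `genome_sequence`.
#' @param target_chrom chromosome to scan (default: source chromosome).
#' @param exclude region whose hits are discounted from NO; defaults to the
#'   fragment source region.
#' @param top_n number of fragments to report (all distinct fragments if
#'   larger).
#' @param fec,strain optional FEC table and strain column for per-fragment
#'   correlations.
#' @param bands optional `band_map`, required for localized areas and
#'   per-fragment correlations.
#' @param strand_mode passed to [locate_matches()].
#' @return data.table sorted by decreasing `NO` (ties broken
#'   lexicographically by sequence): columns `fragment`, `NO`, `areas`
#'   (comma-separated band names), `rS`, `p_value`, `self_comp`,
#'   `repeat_unit`, `repeat_copies`.
#' @export
rank_fragments <- function(fragments, genome,
                           target_chrom = fragments$source$chrom,
                           exclude = fragments$source, top_n = 10L,
                           fec = NULL, strain = NULL, bands = NULL,
                           strand_mode = "both") {
  stopifnot(top_n >= 1L)
  hits <- locate_matches(fragments, genome, target_chrom,
                         exclude = exclude, strand_mode = strand_mode)
  all_frags <- unique(fragments$fragments$seq_)
  no <- hits[, list(NO = .N), by = fragment]
  tab <- data.table::data.table(fragment = all_frags)
  tab <- merge(tab, no, by = "fragment", all.x = TRUE)
  tab[is.na(NO), NO := 0L]
  data.table::setorder(tab, -NO, fragment)
  tab <- head(tab, top_n)

  areas <- rep(NA_character_, nrow(tab))
  rS <- rep(NA_real_, nrow(tab)); pv <- rep(NA_real_, nrow(tab))
  if (!is.null(bands)) {
    for (i in seq_len(nrow(tab))) {
      fh <- hits[fragment == tab$fragment[i]]
      prof <- build_lff(fh, bands, weighting = "unique")
      areas[i] <- paste(prof$band[prof$raw > 0], collapse = ",")
      if (!is.null(fec) && !is.null(strain)) {
        cr <- tryCatch(correlate_lff_fec(prof, fec, strain),
                       error = function(e) NULL)
        if (!is.null(cr)) { rS[i] <- cr$rS; pv[i] <- cr$p_value }
      }
    }
  }
  rep_ann <- lapply(tab$fragment, detect_simple_repeat)
  tab[, `:=`(areas = areas, rS = rS, p_value = pv,
             self_comp = vapply(fragment, self_complementarity, numeric(1)),
             repeat_unit = vapply(rep_ann, function(a) a$unit %||% NA_character_, character(1)),
             repeat_copies = vapply(rep_ann, function(a) a$copies %||% NA_integer_, integer(1)))]
  tab[]
}

#' Self-complementarity score of a sequence
#'
#' Length of the longest ungapped exact match between the sequence and its
#' reverse complement, divided by the sequence length. A perfect
#' restriction-site palindrome such as `GAATTC` scores 1; a homopolymer
#' scores 0 (its reverse complement shares no substring with it).
#'
#' @param seq a nucleotide string over `{A,C,G,T}` (N is rejected).
#' @return numeric score in `[0, 1]`.
#' @export
self_complementarity <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq))
    stop_fmt("self_complementarity requires a sequence over {A,C,G,T}")
  rc <- revcomp(seq)
  longest_common_substring(seq, rc) / nchar(seq)
}

# length of the longest common substring of two strings
# (row-rolling dynamic programme)
longest_common_substring <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- 0L
  prev <- integer(length(bv))
  for (i in seq_along(av)) {
    cur <- integer(length(bv))
    match_ <- av[i] == bv
    cur[match_] <- c(0L, prev)[which(match_)] + 1L
    best <- max(best, cur)
    prev <- cur
  }
  best
}

#' Detect a simple tandem repeat
#'
#' Searches for the shortest unit `u` (1-6 nt) whose tandem array covers at
#' least `min_cover` of the sequence, e.g. dinucleotide satellites like
#' `(AT)15`.
#'
#' @param seq nucleotide string.
#' @param max_unit longest unit length considered (default 6).
#' @param min_cover minimum fraction of the sequence covered by the tandem
#'   array (default 0.9).
#' @return list `(unit, copies)` for the best (shortest-unit) repeat, or
#'   `NULL` if none qualifies.
#' @export
detect_simple_repeat <- function(seq, max_unit = 6L, min_cover = 0.9) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  seq <- toupper(seq)
  L <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  for (ul in seq_len(min(max_unit, floor(L / 2)))) {
    # positions where the character ul bases earlier is identical
    same <- c(rep(FALSE, ul), chars[seq_len(L - ul)] == chars[(ul + 1):L])
    # longest run of period-ul self-agreement; a run of length r starting
    # after position p corresponds to a tandem array of length r + ul
    r <- rle(same)
    run_ends <- cumsum(r$lengths)
    best_len <- 0L; best_start <- NA_integer_
    for (j in which(r$values)) {
      arr_len <- r$lengths[j] + ul
      if (arr_len > best_len) {
        best_len <- arr_len
        best_start <- run_ends[j] - r$lengths[j] - ul + 1L
      }
    }
    if (best_len >= min_cover * L) {
      copies <- best_len %/% ul
      if (copies >= 2L)
        return(list(unit = substr(seq, best_start, best_start + ul - 1L),
                    copies = as.integer(copies)))
    }
  }
  NULL
}
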