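#' Extract all length-k fragments of a source region
#'
#' Slides a window of `k` nt over the region in steps of 1. Windows that
#' contain `N` are excluded (and counted); duplicated sequences are kept,
#' each with its source offset, so repeat-dense sources retain their
#' multiplicity.
#'
#' @param genome a `genome_sequence`.
#' @param region a `region_spec` lying within one chromosome of `genome`.
#' @param k fragment length in nt (default 30, the length used for the
#'   X:11AB scan).
#' @return a `fragment_set`: list with `source` (the region), `k`,
#'   `fragments` (data.table of `seq_`, `offset` — offset is the 0-based
#'   genomic start of the window), and `n_excluded_N`.
#' @export
extract_fragments <- function(genome, region, k = 30L) {
  stopifnot(inherits(region, "region_spec"), k >= 1)
  k <- as.integer(k)
  if (!region$chrom %in% names(genome))
    stop_fmt("chromosome '%s' not in genome", region$chrom)
  chrom_len <- nchar(genome[[region$chrom]])
  if (region$end > chrom_len)
    stop_fmt("region %s extends past chromosome end (%d bp)",
             format(region), chrom_len)
  if (region_length(region) < k)
    stop_fmt("region %s shorter than fragment length k=%d", format(region), k)
  sub <- substr(genome[[region$chrom]], region$start + 1L, region$end)
  windows <- sliding_windows(sub, k)
  has_n <- grepl("N", windows, fixed = TRUE)
  frags <- data.table::data.table(
    seq_ = windows[!has_n],
    offset = region$start + which(!has_n) - 1)
  structure(list(source = region, k = k, fragments = frags,
                 n_excluded_N = sum(has_n)),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("<fragment_set> %d fragments of %d nt from %s (%d N-windows excluded)\n",
              nrow(x$fragments), x$k, format(x$source), x$n_excluded_N))
  invisible(x)
}

#' Localize exact ungapped fragment matches on a target chromosome
#'
#' The target chromosome is decomposed into its k-mers, which are joined
#' against the (distinct) fragment sequences: every exact, ungapped,
#' case-insensitive occurrence is reported, overlapping occurrences
#' included. With `strand_mode = "both"` the reverse strand is scanned too
#' (a fragment matches the reverse strand at position p when its reverse
#' complement equals the forward k-mer starting at p); a palindromic
#' fragment matching both strands at one position is counted once, on the
#' forward strand.
#'
#' @param fragments a `fragment_set`.
#' @param genome a `genome_sequence`.
#' @param target_chrom chromosome to scan.
#' @param exclude optional `region_spec`: occurrences whose start lies in
#'   `[start, end)` on that chromosome are dropped (the self-exclusion used
#'   for "occurrences excluding the source region" statistics).
#' @param strand_mode `"both"` (default) or `"forward_only"`.
#' @return data.table of hits sorted by (chrom, pos, strand): columns
#'   `chrom`, `pos` (0-based match start), `strand` (`"+"`/`"-"`),
#'   `fragment` (the fragment sequence as extracted from the source), and
#'   `weight` (how many times that sequence occurs in the source region).
#' @export
locate_matches <- function(fragments, genome, target_chrom,
                           exclude = NULL,
                           strand_mode = c("both", "forward_only")) {
  stopifnot(inherits(fragments, "fragment_set"))
  strand_mode <- match.arg(strand_mode)
  if (!target_chrom %in% names(genome))
    stop_fmt("chromosome '%s' not in genome", target_chrom)
  k <- fragments$k
  frag <- fragments$fragments[, list(weight = .N), by = list(fragment = seq_)]
  target <- genome[[target_chrom]]
  kmers <- sliding_windows(target, k)
  tg <- data.table::data.table(key_ = kmers, pos = seq_along(kmers) - 1)

  fwd <- tg[frag[, list(key_ = fragment, fragment, weight)],
            on = "key_", nomatch = NULL, allow.cartesian = TRUE]
  fwd <- fwd[, list(pos, fragment, weight, strand = "+")]
  if (strand_mode == "both") {
    rc <- frag[, list(key_ = revcomp(fragment), fragment, weight)]
    rc <- rc[key_ != fragment]  # palindromes already counted forward
    rev <- tg[rc, on = "key_", nomatch = NULL, allow.cartesian = TRUE]
    rev <- rev[, list(pos, fragment, weight, strand = "-")]
    hits <- rbind(fwd, rev)
  } else hits <- fwd
  hits[, chrom := target_chrom]
  if (!is.null(exclude) && exclude$chrom == target_chrom)
    hits <- hits[pos < exclude$start | pos >= exclude$end]
  data.table::setorder(hits, chrom, pos, strand)
  hits[, list(chrom, pos, strand, fragment, weight)]
}

#' Aggregate localization hits into a per-band LFF profile
#'
#' Each hit is assigned to the band whose half-open interval contains its
#' start position. Hits outside every band are tallied separately, so that
#' per-band counts plus the outside tally always equal the total.
#'
#' @param hits hit table from [locate_matches()].
#' @param bands a `band_map` for the same chromosome.
#' @param weighting `"proportional"` (default): each occurrence of a source
#'   fragment weights its target hits, so duplicated source fragments count
#'   as many times as they occur in the source; `"unique"`: each distinct
#'   fragment sequence contributes once per target occurrence.
#' @return an `lff_profile`: data.table with columns `band`, `chrom`,
#'   `start`, `end`, `raw` (hit count), `per_kb` (hits per kb of band);
#'   attributes `total_hits` and `outside_band`.
#' @export
build_lff <- function(hits, bands, weighting = c("proportional", "unique")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(bands, "band_map"))
  h <- data.table::as.data.table(hits)
  w <- if (weighting == "proportional" && nrow(h)) h$weight else rep(1, nrow(h))
  prof <- data.table::as.data.table(bands)[, list(chrom, start, end, band)]
  raw <- numeric(nrow(prof))
  outside <- 0
  for (cn in unique(prof$chrom)) {
    rows <- which(prof$chrom == cn)
    b <- prof[rows]
    sel <- which(h$chrom == cn)
    if (!length(sel)) next
    idx <- findInterval(h$pos[sel], b$start)  # 0 => before first band
    inside <- idx >= 1L & h$pos[sel] < b$end[pmax(idx, 1L)]
    tally <- tapply(w[sel][inside], b$band[idx[inside]], sum)
    raw[rows[match(names(tally), b$band)]] <- as.numeric(tally)
    outside <- outside + sum(w[sel][!inside])
  }
  outside <- outside + sum(w[!h$chrom %in% prof$chrom])
  prof[, raw := raw]
  prof[, per_kb := raw / ((end - start) / 1000)]
  data.table::setattr(prof, "total_hits", sum(w))
  data.table::setattr(prof, "outside_band", outside)
  data.table::setattr(prof, "class", c("lff_profile", class(prof)))
  prof[]
}

#' One-call scan: fragments, localization and LFF profile
#'
#' Convenience wrapper reproducing the tool's primary workflow: extract
#' all k-mers of `region`, localize them on `target_chrom` (the region's
#' own chromosome by default), excluding self-hits inside the source
#' region, and aggregate per band.
#'
#' @inheritParams extract_fragments
#' @inheritParams locate_matches
#' @inheritParams build_lff
#' @param bands a `band_map`.
#' @param target_chrom target chromosome (defaults to the region's).
#' @param exclude_self drop hits whose start lies inside the source region
#'   (default `TRUE`, the convention under which a region's pairing with
#'   itself is not applicable).
#' @return list with `fragments`, `hits`, `profile`.
#' @export
scan_region <- function(genome, region, bands, k = 30L,
                        target_chrom = region$chrom,
                        strand_mode = c("both", "forward_only"),
                        weighting = c("proportional", "unique"),
                        exclude_self = TRUE) {
  strand_mode <- match.arg(strand_mode)
  weighting <- match.arg(weighting)
  fragments <- extract_fragments(genome, region, k)
  exclude <- if (exclude_self) region else NULL
  hits <- locate_matches(fragments, genome, target_chrom,
                         exclude = exclude, strand_mode = strand_mode)
  profile <- build_lff(hits, bands, weighting = weighting)
  list(fragments = fragments, hits = hits, profile = profile)
}

#' Write localization hits as BED6
#'
#' Columns: chrom, start, end, fragment sequence, source-occurrence count
#' (score), strand.
#'
#' @param hits hit table from [locate_matches()].
#' @param path output path.
#' @param k fragment length (match end = start + k).
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path, k) {
  h <- data.table::as.data.table(hits)
  out <- h[, list(chrom, start = pos, end = pos + k, fragment,
                  score = weight, strand)]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, scipen = 50)
  invisible(path)
}

#' Write an LFF profile as TSV
#' @param profile an `lff_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lff_tsv <- function(profile, path) {
  p <- data.table::as.data.table(profile)
  data.table::fwrite(p[, list(band, raw, per_kb)], path, sep = "\t")
  invisible(path)
}
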