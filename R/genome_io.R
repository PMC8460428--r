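#' Read a genome from a (possibly gzipped) FASTA file
#'
#' Sequences are uppercased; only the alphabet `{A,C,G,T,N}` is accepted
#' after normalization. Record order is preserved.
#'
#' @param path path to a FASTA or gzipped FASTA file.
#' @param gz_allowed allow gzipped input (default `TRUE`). When `FALSE`, a
#'   gzip-compressed file is rejected.
#' @return a named character vector of class `genome_sequence`: one
#'   uppercase sequence per chromosome, names are the first whitespace-
#'   delimited token of each header.
#' @export
read_fasta <- function(path, gz_allowed = TRUE) {
  if (!file.exists(path)) stop_fmt("FASTA file not found: %s", path)
  if (!gz_allowed && is_gzipped(path))
    stop_fmt("gzipped input not allowed here: %s", path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop_fmt("malformed FASTA in %s: %s", path, conditionMessage(e))
  )
  if (length(set) == 0L) stop_fmt("FASTA file has no records: %s", path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(names(seqs)))
    stop_fmt("duplicate chromosome name in %s: %s", path,
             names(seqs)[duplicated(names(seqs))][1L])
  if (any(!nzchar(seqs))) stop_fmt("empty sequence record in %s", path)
  bad <- gsub("[ACGTN]", "", seqs)
  if (any(nzchar(bad))) {
    rec <- which(nzchar(bad))[1L]
    # report the line of the offending record so the file can be fixed
    ln <- fasta_record_line(path, rec)
    stop_fmt("illegal character '%s' in sequence of record '%s' (record starting at line %d)",
             substr(bad[rec], 1L, 1L), names(seqs)[rec], ln)
  }
  structure(seqs, class = "genome_sequence")
}

is_gzipped <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

fasta_record_line <- function(path, record) {
  lines <- readLines(path, warn = FALSE)
  headers <- which(startsWith(lines, ">"))
  if (record <= length(headers)) headers[record] else NA_integer_
}

#' Write a genome to FASTA
#'
#' @param genome a `genome_sequence` (named character vector).
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param width line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  set <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(set, path, width = width,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Parse a region string
#'
#' Accepts `"CHROM:START:END"` with an optional leading colon
#' (`":X:11982050:12772070"` denotes the ~790 kb region X:11AB). Coordinates
#' are 0-based half-open, matching the BED convention used throughout.
#'
#' @param text region string.
#' @return a `region_spec`: list with `chrom`, `start`, `end`.
#' @examples
#' r <- parse_region(":X:11982050:12772070")
#' region_length(r)  # 790020
#' @export
parse_region <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- sub("^:", "", text)
  parts <- strsplit(s, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3L)
    stop_fmt("region must be 'CHROM:START:END', got '%s'", text)
  start <- suppressWarnings(as.numeric(parts[2]))
  end <- suppressWarnings(as.numeric(parts[3]))
  if (is.na(start) || is.na(end) || start != floor(start) || end != floor(end))
    stop_fmt("non-integer coordinates in region '%s'", text)
  region_spec(parts[1], start, end)
}

#' Construct a region specification
#'
#' @param chrom chromosome name.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must exceed `start`.
#' @return a `region_spec` list.
#' @export
region_spec <- function(chrom, start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (!nzchar(chrom)) stop_fmt("empty chromosome name in region")
  if (is.na(start) || is.na(end) || start < 0 || start >= end)
    stop_fmt("invalid region %s:%s:%s (need 0 <= start < end)",
             chrom, format(start, scientific = FALSE),
             format(end, scientific = FALSE))
  structure(list(chrom = chrom, start = start, end = end),
            class = "region_spec")
}

#' Length of a region in base pairs
#' @param region a `region_spec`.
#' @return numeric length `end - start`.
#' @export
region_length <- function(region) region$end - region$start

#' @export
format.region_spec <- function(x, ...)
  sprintf("%s:%s:%s", x$chrom, format(x$start, scientific = FALSE),
          format(x$end, scientific = FALSE))

#' @export
print.region_spec <- function(x, ...) {
  cat("<region>", format(x), sprintf("(%s bp)\n", region_length(x)))
  invisible(x)
}

#' Read a cytological band map from a BED4 file
#'
#' Columns beyond the fourth are ignored. Intervals are sorted per
#' chromosome; overlapping bands on one chromosome are an error.
#'
#' @param path path to a tab-separated BED file with columns
#'   chrom, start, end, name (0-based half-open).
#' @return a `band_map`: data.table with columns `chrom`, `start`, `end`,
#'   `band`, sorted by (chrom, start).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_fmt("BED file not found: %s", path)
  dt <- fread_skip_comments(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (ncol(dt) < 4L)
    stop_fmt("BED file %s has %d columns; need at least 4 (chrom, start, end, name)",
             path, ncol(dt))
  band_map(dt[[1]], as.numeric(dt[[2]]), as.numeric(dt[[3]]),
           as.character(dt[[4]]))
}

#' Construct and validate a band map
#'
#' @param chrom,start,end,band parallel vectors of band intervals
#'   (0-based half-open) and names.
#' @return a `band_map` data.table sorted by (chrom, start).
#' @export
band_map <- function(chrom, start, end, band) {
  dt <- data.table::data.table(chrom = as.character(chrom),
                               start = as.numeric(start),
                               end = as.numeric(end),
                               band = as.character(band))
  if (any(is.na(dt$start) | is.na(dt$end) | dt$start < 0 | dt$start >= dt$end))
    stop_fmt("invalid band interval (need 0 <= start < end)")
  data.table::setorder(dt, chrom, start)
  for (cn in unique(dt$chrom)) {
    sub <- dt[chrom == cn]
    if (anyDuplicated(sub$band))
      stop_fmt("duplicate band name '%s' on chromosome %s",
               sub$band[duplicated(sub$band)][1L], cn)
    if (nrow(sub) > 1L) {
      ovl <- which(sub$start[-1L] < sub$end[-nrow(sub)])
      if (length(ovl))
        stop_fmt("bands '%s' and '%s' overlap on chromosome %s",
                 sub$band[ovl[1L]], sub$band[ovl[1L] + 1L], cn)
    }
  }
  data.table::setattr(dt, "class", c("band_map", class(dt)))
  dt[]
}

#' Write a band map as BED4
#' @param bands a `band_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(bands, path) {
  data.table::fwrite(bands[, list(chrom, start, end, band)], path,
                     sep = "\t", col.names = FALSE, scipen = 50)
  invisible(path)
}

#' Read a table of ectopic contact frequencies (FEC)
#'
#' Expects a TSV whose first column holds band names and remaining columns
#' one strain each; values are FEC in percent of examined nuclei. The token
#' `"NA"` (case-insensitive) marks not-applicable cells (a band cannot pair
#' with itself); an empty cell means no contact was observed and is stored
#' as 0, with its position recorded in the `"empty_cells"` attribute so the
#' two states stay distinguishable.
#'
#' @param path path to the TSV file.
#' @return a `fec_table`: data.table with column `band` plus one numeric
#'   column per strain; attribute `empty_cells` is a data.table of
#'   (band, strain) for cells that were empty in the input.
#' @export
read_fec_table <- function(path) {
  if (!file.exists(path)) stop_fmt("FEC table not found: %s", path)
  dt <- fread_skip_comments(path, header = TRUE, sep = "\t",
                          colClasses = "character", na.strings = NULL)
  if (ncol(dt) < 2L) stop_fmt("FEC table %s needs a band column plus >= 1 strain", path)
  data.table::setnames(dt, 1L, "band")
  strains <- names(dt)[-1L]
  empties <- list()
  for (s in strains) {
    v <- dt[[s]]
    is_empty <- !nzchar(trimws(v))
    is_na <- toupper(trimws(v)) == "NA"
    num <- suppressWarnings(as.numeric(v))
    num[is_empty] <- 0
    num[is_na] <- NA_real_
    bad <- which(!is_empty & !is_na & is.na(num))
    if (length(bad))
      stop_fmt("non-numeric FEC value '%s' (band %s, strain %s)",
               v[bad[1L]], dt$band[bad[1L]], s)
    out_of_range <- which(!is.na(num) & (num < 0 | num > 100))
    if (length(out_of_range))
      stop_fmt("FEC value %s out of [0,100] (band %s, strain %s)",
               v[out_of_range[1L]], dt$band[out_of_range[1L]], s)
    data.table::set(dt, j = s, value = num)
    if (any(is_empty))
      empties[[s]] <- data.table::data.table(band = dt$band[is_empty], strain = s)
  }
  empty_cells <- if (length(empties)) data.table::rbindlist(empties)
                 else data.table::data.table(band = character(0), strain = character(0))
  data.table::setattr(dt, "empty_cells", empty_cells)
  data.table::setattr(dt, "class", c("fec_table", class(dt)))
  dt[]
}

#' Write an FEC table as TSV
#'
#' Not-applicable cells are written as `"NA"`; cells flagged empty on input
#' (or via the `empty_cells` attribute) are written as empty strings.
#'
#' @param fec a `fec_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fec_table <- function(fec, path) {
  out <- data.table::copy(data.table::as.data.table(fec))
  strains <- setdiff(names(out), "band")
  for (s in strains)
    data.table::set(out, j = s, value = ifelse(is.na(out[[s]]), "NA",
                                               format(out[[s]], trim = TRUE)))
  ec <- attr(fec, "empty_cells")
  if (!is.null(ec) && nrow(ec))
    for (i in seq_len(nrow(ec)))
      data.table::set(out, i = which(out$band == ec$band[i]),
                      j = ec$strain[i], value = "")
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
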