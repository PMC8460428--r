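#' Two-sample t statistic for a difference of contact proportions
#'
#' Treats each nucleus as a Bernoulli indicator (contact observed or not)
#' and computes the unpooled (Welch) two-sample t statistic for the
#' difference of the two means, i.e. of the two FECs expressed as
#' proportions. This is the `t_dif` criterion under which `|t| < 1` counts
#' as "no difference" between two strains' FEC at a band.
#'
#' @param count1,count2 number of nuclei showing the contact.
#' @param n1,n2 number of examined nuclei.
#' @return the absolute t value; 0 when both proportions are equal with
#'   zero variance, `Inf` when proportions differ but both variances are 0
#'   (e.g. 0/n vs n/n).
#' @export
fec_t_statistic <- function(count1, n1, count2, n2) {
  stopifnot(n1 > 0, n2 > 0, count1 >= 0, count2 >= 0,
            count1 <= n1, count2 <= n2)
  p1 <- count1 / n1; p2 <- count2 / n2
  # sample variance of a 0/1 vector: n/(n-1) * p(1-p); 0 when n = 1
  v1 <- if (n1 > 1) p1 * (1 - p1) * n1 / (n1 - 1) else 0
  v2 <- if (n2 > 1) p2 * (1 - p2) * n2 / (n2 - 1) else 0
  se <- sqrt(v1 / n1 + v2 / n2)
  if (se == 0) return(if (p1 == p2) 0 else Inf)
  abs(p1 - p2) / se
}

#' Construct a reciprocal-cross design
#'
#' Fixed roles follow the four-column layout of a reciprocal cross:
#' column 1 parent A, column 2 hybrid A×B (mother A), column 3 hybrid B×A
#' (mother B), column 4 parent B.
#'
#' @param data long-format data.frame with columns `band`, `strain`,
#'   `count`, `nuclei`.
#' @param roles character vector of the four strain labels in role order
#'   (parent_A, hybrid_AB, hybrid_BA, parent_B).
#' @return a `cross_design`: list with `roles` and `data` (data.table).
#' @export
cross_design <- function(data, roles) {
  stopifnot(length(roles) == 4L, !anyDuplicated(roles))
  dt <- data.table::as.data.table(data)
  need <- c("band", "strain", "count", "nuclei")
  if (!all(need %in% names(dt)))
    stop_fmt("cross design data needs columns: %s", paste(need, collapse = ", "))
  missing_roles <- setdiff(roles, dt$strain)
  if (length(missing_roles))
    stop_fmt("strain column missing from data: %s",
             paste(missing_roles, collapse = ", "))
  dt <- dt[strain %in% roles]
  if (any(dt$nuclei <= 0) || any(dt$count < 0 | dt$count > dt$nuclei))
    stop_fmt("need 0 <= count <= nuclei and nuclei > 0")
  structure(list(roles = roles, data = dt), class = "cross_design")
}

#' Read a reciprocal-cross FEC design from a long-format TSV
#'
#' @param path TSV with columns band, strain, count, nuclei.
#' @param roles the four strain labels in role order
#'   (parent_A, hybrid_AB, hybrid_BA, parent_B).
#' @return a `cross_design`.
#' @export
read_cross_design <- function(path, roles) {
  if (!file.exists(path)) stop_fmt("design file not found: %s", path)
  cross_design(fread_skip_comments(path, sep = "\t", header = TRUE), roles)
}

# per-band role counts as a 4-row table in role order
band_counts <- function(design, band_) {
  d <- design$data[band == band_]
  if (nrow(d) == 0L) stop_fmt("band '%s' not in design", band_)
  m <- d[match(design$roles, strain)]
  if (anyNA(m$count))
    stop_fmt("band '%s' lacks observations for strain %s", band_,
             design$roles[which(is.na(m$count))[1L]])
  m
}

#' Classify the mode of FEC inheritance at one band
#'
#' Applies the reciprocal-cross decision rules with "no difference"
#' operationalized as `|t| < 1`: matroclinic (maternal) when columns 1 vs 2
#' and 3 vs 4 show no difference; patroclinic (paternal) when 2 vs 4 and
#' 1 vs 3 show no difference; hybrid-specific when 2 vs 3 shows no
#' difference while both parental patterns fail; heterosis when both
#' hybrids' FEC strictly exceed both parents' and 1 vs 2 or 3 vs 4 differs
#' (`|t| >= 1`). Precedence when patterns co-occur: absent (no strain shows
#' any contact), then heterosis, then concordant (maternal and paternal
#' both satisfied, reported as unclassified), then maternal, paternal,
#' hybrid-specific; anything else is unclassified.
#'
#' @param design a `cross_design`.
#' @param band band name.
#' @return a `mode_call`: one-row data.table with the band, `mode`, the
#'   four FECs (percent), the five t statistics (`t_12`, `t_34`, `t_23`,
#'   `t_24`, `t_13`) and a `note` flagging concordant bands.
#' @export
classify_band <- function(design, band) {
  m <- band_counts(design, band)
  cnt <- m$count; nuc <- m$nuclei
  fec <- 100 * cnt / nuc
  t_of <- function(i, j) fec_t_statistic(cnt[i], nuc[i], cnt[j], nuc[j])
  t12 <- t_of(1, 2); t34 <- t_of(3, 4); t23 <- t_of(2, 3)
  t24 <- t_of(2, 4); t13 <- t_of(1, 3)
  nodiff <- function(t) t < 1
  maternal <- nodiff(t12) && nodiff(t34)
  paternal <- nodiff(t24) && nodiff(t13)
  hyb_gt_par <- min(fec[2], fec[3]) > max(fec[1], fec[4])
  heterosis <- hyb_gt_par && (t12 >= 1 || t34 >= 1)
  note <- ""
  mode <- if (all(cnt == 0)) "absent"
  else if (heterosis) "heterosis"
  else if (maternal && paternal) { note <- "concordant"; "unclassified" }
  else if (maternal) "maternal"
  else if (paternal) "paternal"
  else if (nodiff(t23)) "hybrid_specific"
  else "unclassified"
  out <- data.table::data.table(
    band = band, mode = mode,
    fec_parent_A = fec[1], fec_hybrid_AB = fec[2],
    fec_hybrid_BA = fec[3], fec_parent_B = fec[4],
    t_12 = t12, t_34 = t34, t_23 = t23, t_24 = t24, t_13 = t13,
    note = note)
  data.table::setattr(out, "class", c("mode_call", class(out)))
  out[]
}

#' Classify every band of a reciprocal-cross design
#'
#' @param design a `cross_design`.
#' @return data.table of per-band [classify_band()] calls (band order of
#'   the input), with attribute `summary`: a named count of calls per mode.
#' @export
classify_all <- function(design) {
  bands <- unique(design$data$band)
  if (!length(bands)) stop_fmt("design has no bands")
  calls <- data.table::rbindlist(lapply(bands, function(b) classify_band(design, b)))
  tab <- table(factor(calls$mode,
                      levels = c("maternal", "paternal", "hybrid_specific",
                                 "heterosis", "absent", "unclassified")))
  data.table::setattr(calls, "summary", tab)
  calls[]
}

#' Write mode calls as TSV
#' @param calls output of [classify_all()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mode_calls <- function(calls, path) {
  data.table::fwrite(data.table::as.data.table(calls), path, sep = "\t")
  invisible(path)
}
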