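#' Specification for a synthetic banded chromosome
#'
#' Describes a desk-scale chromosome for end-to-end testing: a single
#' chromosome split into equal cytological bands, an i.i.d. background of
#' configurable A/T richness, and planted tandem-free repeat families whose
#' per-band copy numbers are the ground truth that downstream LFF profiles
#' should recover. By default two families are planted: a 372 bp "driver"
#' family whose band-level density later generates the FEC response, with
#' its highest density in the designated source band, and a 200 bp
#' "bystander" family concentrated in the control band, whose band
#' placement is deliberately unrelated to the driver density so that
#' control-region scans yield no FEC correlation.
#'
#' @param chrom chromosome name.
#' @param n_bands number of equal bands.
#' @param band_length band length in bp.
#' @param at_fraction background A+T fraction (default 0.6, an A/T-rich
#'   context).
#' @param source_band index of the band acting as the fragment source
#'   region.
#' @param control_band index of the band acting as the control source
#'   region.
#' @param families optional list of repeat families, each a list with
#'   `name`, `unit` (sequence or `NULL` to draw one), `unit_length`,
#'   `mutation_rate` (per-base substitution probability applied to each
#'   planted copy) and `copies` (integer vector of per-band copy numbers).
#'   `NULL` installs the two default families described above.
#' @param seed RNG seed governing every random choice of the generator.
#' @return a `synthetic_genome_spec` list.
#' @export
synthetic_genome_spec <- function(chrom = "chrS", n_bands = 20L,
                                  band_length = 50000L, at_fraction = 0.6,
                                  source_band = 5L, control_band = 15L,
                                  families = NULL, seed = 42L) {
  stopifnot(n_bands >= 3L, band_length >= 1000L,
            at_fraction > 0, at_fraction < 1,
            source_band >= 1L, source_band <= n_bands,
            control_band >= 1L, control_band <= n_bands,
            control_band != source_band)
  if (is.null(families))
    families <- default_families(n_bands, source_band, control_band)
  for (fam in families) {
    stopifnot(length(fam$copies) == n_bands, all(fam$copies >= 0),
              fam$mutation_rate >= 0, fam$mutation_rate < 0.5)
  }
  structure(list(chrom = chrom, n_bands = as.integer(n_bands),
                 band_length = as.integer(band_length),
                 at_fraction = at_fraction,
                 source_band = as.integer(source_band),
                 control_band = as.integer(control_band),
                 families = families, seed = as.integer(seed)),
            class = "synthetic_genome_spec")
}

# Driver copies: a fixed modular permutation of 0..n-1 (distinct densities,
# so band ranks are unambiguous), with the source band raised above all
# others and the control band holding zero copies — the control region
# must share no homology with the FEC-driving family. Bystander copies:
# a handful of bands spanning low, mid and high driver densities, richest
# in the control band, so bystander placement carries no driver-density
# information.
default_families <- function(n_bands, source_band, control_band) {
  v <- ((seq_len(n_bands) - 1L) * 7L) %% n_bands
  v[source_band] <- max(v) + 12L
  v[which(v == 0L)[1L]] <- v[control_band]
  v[control_band] <- 0L
  b <- integer(n_bands)
  hosts <- setdiff(unique(c(4L, 7L, control_band, 11L, 18L)), source_band)
  hosts <- hosts[hosts >= 1L & hosts <= n_bands]
  b[hosts] <- c(5L, 6L, 20L, 4L, 3L)[seq_along(hosts)]
  b[control_band] <- 20L
  list(
    list(name = "driver", unit = NULL, unit_length = 372L,
         mutation_rate = 0, copies = v),
    list(name = "bystander", unit = NULL, unit_length = 200L,
         mutation_rate = 0, copies = b))
}

random_dna <- function(n, at_fraction) {
  sample(c("A", "T", "C", "G"), n, replace = TRUE,
         prob = c(at_fraction / 2, at_fraction / 2,
                  (1 - at_fraction) / 2, (1 - at_fraction) / 2))
}

mutate_unit <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- which(runif(length(chars)) < rate)
  for (i in hit)
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  chars
}

#' Generate a synthetic genome with planted repeat families
#'
#' Builds the chromosome described by a [synthetic_genome_spec()]: i.i.d.
#' background, equal bands named `B01`, `B02`, ..., and repeat copies
#' placed uniformly at non-overlapping positions within their assigned
#' bands (all families jointly), with per-base substitutions at each
#' family's mutation rate. Fully deterministic under the spec seed.
#'
#' @param spec a `synthetic_genome_spec`.
#' @return list with `genome` (a `genome_sequence`), `bands` (a
#'   `band_map`), and `truth` (list: the spec, per-band `densities` matrix
#'   of planted copies by family, the repeat `units`, `source_region` and
#'   `control_region` as `region_spec`s, `band_names`).
#' @export
make_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  n <- spec$n_bands; bl <- spec$band_length
  total_len <- n * bl
  for (fam in spec$families)
    if (any(fam$copies * unit_len_of(fam) > bl - 1000L))
      stop_fmt("family '%s' copies overflow band capacity", fam$name)
  with_seed(spec$seed, {
    chars <- random_dna(total_len, spec$at_fraction)
    units <- lapply(spec$families, function(fam) {
      if (!is.null(fam$unit)) toupper(fam$unit)
      else paste(random_dna(fam$unit_length, spec$at_fraction), collapse = "")
    })
    names(units) <- vapply(spec$families, `[[`, character(1), "name")
    for (b in seq_len(n)) {
      fam_idx <- rep(seq_along(spec$families),
                     vapply(spec$families, function(f) f$copies[b], numeric(1)))
      if (!length(fam_idx)) next
      fam_idx <- sample(fam_idx)
      lens <- vapply(units[fam_idx], nchar, integer(1))
      free <- bl - sum(lens)
      if (free < 0) stop_fmt("copies overflow band %d capacity", b)
      gaps <- sort(runif(length(lens), 0, free))
      starts <- (b - 1L) * bl + floor(gaps) + c(0, cumsum(lens[-length(lens)]))
      for (i in seq_along(starts)) {
        uc <- strsplit(units[[fam_idx[i]]], "")[[1]]
        uc <- mutate_unit(uc, spec$families[[fam_idx[i]]]$mutation_rate)
        chars[(starts[i] + 1):(starts[i] + lens[i])] <- uc
      }
    }
    seqs <- structure(stats::setNames(paste(chars, collapse = ""), spec$chrom),
                      class = "genome_sequence")
    band_names <- sprintf("B%02d", seq_len(n))
    bands <- band_map(rep(spec$chrom, n), (seq_len(n) - 1L) * bl,
                      seq_len(n) * bl, band_names)
    densities <- vapply(spec$families, `[[`, numeric(n), "copies")
    colnames(densities) <- names(units)
    rownames(densities) <- band_names
    truth <- list(spec = spec, densities = densities, units = units,
                  source_region = region_spec(spec$chrom,
                                              (spec$source_band - 1L) * bl,
                                              spec$source_band * bl),
                  control_region = region_spec(spec$chrom,
                                               (spec$control_band - 1L) * bl,
                                               spec$control_band * bl),
                  band_names = band_names)
    list(genome = seqs, bands = bands, truth = truth)
  })
}

unit_len_of <- function(fam)
  if (!is.null(fam$unit)) nchar(fam$unit) else fam$unit_length

# monotone link from planted density to an FEC percentage
fec_link <- function(density, base = 5, slope = 2.5)
  pmin(pmax(base + slope * density, 0), 100)

#' Generate a synthetic FEC table from planted densities
#'
#' The frequency of ectopic contacts of each band is a monotone function
#' of the driver-family planted density, `FEC = clamp(base + slope *
#' density + noise, 0, 100)`, with independent seeded Gaussian noise per
#' band and strain. The source band is set to NA for every strain (a
#' region cannot pair with itself).
#'
#' @param truth the `truth` element of [make_genome()].
#' @param strains strain column labels.
#' @param noise Gaussian noise standard deviation, in FEC percent.
#' @param seed RNG seed.
#' @param base,slope parameters of the density-to-FEC link.
#' @param densities optional per-band density vector overriding the
#'   driver-family truth (e.g. a shuffled copy, to break the LFF-FEC
#'   association while preserving the FEC value distribution).
#' @return a `fec_table`.
#' @export
make_fec <- function(truth, strains = c("strainA", "strainB"), noise = 0,
                     seed = 0L, base = 5, slope = 2.5, densities = NULL) {
  d <- densities %||% truth$densities[, 1L]
  stopifnot(length(d) == length(truth$band_names))
  with_seed(seed, {
    dt <- data.table::data.table(band = truth$band_names)
    for (s in strains) {
      v <- fec_link(d, base, slope) + rnorm(length(d), 0, noise)
      v <- pmin(pmax(v, 0), 100)
      v[truth$spec$source_band] <- NA_real_
      data.table::set(dt, j = s, value = v)
    }
    data.table::setattr(dt, "empty_cells",
                        data.table::data.table(band = character(0),
                                               strain = character(0)))
    data.table::setattr(dt, "class", c("fec_table", class(dt)))
    dt[]
  })
}

#' Generate a reciprocal-cross FEC design with a known inheritance mode
#'
#' Produces per-band contact counts for the four strains of a reciprocal
#' cross (parent A, hybrid A\eqn{\times}B, hybrid B\eqn{\times}A, parent B)
#' such that every band follows one planted mode of inheritance. Parental
#' FEC levels derive from the driver density via the same link as
#' [make_fec()]; the mode fixes the four strains' multipliers:
#' maternal (1, 1, 0.3, 0.3) — each hybrid matches its mother; paternal
#' (1, 0.3, 1, 0.3); hybrid-specific (1, 0.6, 0.6, 0.3); heterosis
#' (0.3, 1, 1, 0.3). The source band is omitted.
#'
#' @param truth the `truth` element of [make_genome()].
#' @param design planted mode for every band.
#' @param nuclei examined nuclei per strain and band.
#' @param roles the four strain labels in role order.
#' @param base,slope density-to-FEC link parameters.
#' @return a `cross_design`.
#' @export
make_cross_design <- function(truth,
                              design = c("maternal", "paternal",
                                         "hybrid_specific", "heterosis"),
                              nuclei = 500L,
                              roles = c("parentA", "hybAB", "hybBA", "parentB"),
                              base = 5, slope = 2.5) {
  design <- match.arg(design)
  mult <- switch(design,
                 maternal = c(1, 1, 0.3, 0.3),
                 paternal = c(1, 0.3, 1, 0.3),
                 hybrid_specific = c(1, 0.6, 0.6, 0.3),
                 heterosis = c(0.3, 1, 1, 0.3))
  d <- truth$densities[, 1L]
  keep <- seq_along(d) != truth$spec$source_band
  g <- fec_link(d[keep], base, slope)
  rows <- list()
  for (r in seq_along(roles)) {
    pct <- g * mult[r]
    rows[[r]] <- data.table::data.table(
      band = truth$band_names[keep], strain = roles[r],
      count = as.integer(round(pct / 100 * nuclei)), nuclei = as.integer(nuclei))
  }
  cross_design(data.table::rbindlist(rows), roles)
}

#' Build an alternating rest/run schedule
#'
#' `n_runs` bouts of `run_s` seconds at `run_speed`, each preceded by a
#' rest of `rest_s` seconds, tiling `n_runs * (rest_s + run_s)` seconds.
#'
#' @param n_runs number of run bouts.
#' @param run_s run bout duration (s).
#' @param rest_s rest duration before each run (s).
#' @param run_speed running speed (mm/s).
#' @return data.table with columns `state`, `duration`, `speed`.
#' @export
run_rest_schedule <- function(n_runs = 6L, run_s = 60, rest_s = 540,
                              run_speed = 10) {
  data.table::data.table(
    state = rep(c("resting", "moving"), n_runs),
    duration = rep(c(rest_s, run_s), n_runs),
    speed = rep(c(0, run_speed), n_runs))
}

#' Generate locomotion tracks realizing a run/rest schedule
#'
#' Samples positions at `rate` Hz. During runs the animal moves with the
#' scheduled speed perturbed by multiplicative jitter and a slowly turning
#' heading; during rests it is stationary. Schedule durations should be
#' whole seconds so that bout boundaries align with 1 s quanta and the
#' planted bout count is recovered exactly.
#'
#' @param schedule data.frame with columns `state`, `duration` (s),
#'   `speed` (mm/s), e.g. from [run_rest_schedule()].
#' @param rate sampling rate in Hz.
#' @param n_animals number of tracks to generate.
#' @param speed_jitter multiplicative speed noise sd (fraction of speed).
#' @param heading_jitter sd of the per-sample heading increment (radians).
#' @param seed RNG seed.
#' @return named list of `track` objects; attribute `truth` holds the
#'   schedule and its planted activity index, run count and run speed.
#' @export
make_tracks <- function(schedule, rate = 20L, n_animals = 1L,
                        speed_jitter = 0.05, heading_jitter = 0.3,
                        seed = 0L) {
  sch <- data.table::as.data.table(schedule)
  stopifnot(all(c("state", "duration", "speed") %in% names(sch)),
            all(sch$duration > 0))
  total <- sum(sch$duration)
  bounds <- cumsum(sch$duration)
  tracks <- with_seed(seed, {
    lapply(seq_len(n_animals), function(a) {
      t <- seq(0, total, by = 1 / rate)
      mid <- (t[-1L] + t[-length(t)]) / 2
      seg_state <- findInterval(mid, c(0, bounds), rightmost.closed = TRUE)
      spd <- sch$speed[seg_state]
      moving <- sch$state[seg_state] == "moving"
      step <- numeric(length(mid))
      step[moving] <- pmax(spd[moving] / rate *
                             (1 + rnorm(sum(moving), 0, speed_jitter)), 0)
      heading <- cumsum(rnorm(length(mid), 0, heading_jitter))
      x <- cumsum(c(0, step * cos(heading)))
      y <- cumsum(c(0, step * sin(heading)))
      track(t, x, y, id = sprintf("fly%02d", a))
    })
  })
  names(tracks) <- vapply(tracks, attr, character(1), "id")
  moving_time <- sum(sch$duration[sch$state == "moving"])
  attr(tracks, "truth") <- list(
    schedule = sch, duration = total,
    activity_index = 100 * moving_time / total,
    n_runs = sum(sch$state == "moving"),
    run_speed = stats::weighted.mean(sch$speed[sch$state == "moving"],
                                     sch$duration[sch$state == "moving"]))
  tracks
}

#' Write tracks to a TSV file
#' @param tracks list of `track` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  dt <- data.table::rbindlist(lapply(tracks, function(tr)
    data.table::data.table(animal = attr(tr, "id"), t = tr$t,
                           x = tr$x, y = tr$y)))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Generate naive/trained courtship-index samples
#'
#' Gaussian CI samples truncated to `[0, 100]`.
#'
#' @param mean_naive,mean_trained group means (percent).
#' @param sd common standard deviation.
#' @param n males per group.
#' @param seed RNG seed.
#' @return list with numeric vectors `naive`, `trained` and attribute
#'   `truth` (the planted means and expected learning index).
#' @export
make_courtship <- function(mean_naive = 50, mean_trained = 20, sd = 10,
                           n = 20L, seed = 0L) {
  stopifnot(mean_naive >= 0, mean_naive <= 100,
            mean_trained >= 0, mean_trained <= 100, n >= 1L)
  out <- with_seed(seed, {
    list(naive = pmin(pmax(rnorm(n, mean_naive, sd), 0), 100),
         trained = pmin(pmax(rnorm(n, mean_trained, sd), 0), 100))
  })
  attr(out, "truth") <- list(
    mean_naive = mean_naive, mean_trained = mean_trained, sd = sd, n = n,
    expected_LI = if (mean_naive > 0)
      100 * (mean_naive - mean_trained) / mean_naive else NA_real_)
  out
}

#' Write courtship samples to a TSV file
#' @param samples list with `naive` and `trained` CI vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_courtship <- function(samples, path) {
  dt <- data.table::rbindlist(list(
    data.table::data.table(group = "naive",
                           animal = seq_along(samples$naive),
                           CI = samples$naive),
    data.table::data.table(group = "trained",
                           animal = seq_along(samples$trained),
                           CI = samples$trained)))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Write a synthetic genome bundle to a directory
#'
#' Emits `genome.fa.gz`, `bands.bed` and `truth.json` (the machine-readable
#' ground truth: planted densities, units, source/control regions).
#'
#' @param sim output of [make_genome()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "genome.fa.gz")
  bed <- file.path(dir, "bands.bed")
  js <- file.path(dir, "truth.json")
  write_fasta(sim$genome, fa)
  write_bed(sim$bands, bed)
  truth <- sim$truth
  jsonlite::write_json(list(
    chrom = truth$spec$chrom,
    band_names = truth$band_names,
    densities = as.data.frame(truth$densities),
    units = truth$units,
    source_region = format(truth$source_region),
    control_region = format(truth$control_region),
    seed = truth$spec$seed), js, auto_unbox = TRUE, digits = NA)
  c(fasta = fa, bed = bed, truth = js)
}
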