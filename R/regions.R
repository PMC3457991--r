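#' Build miRNA region systems (pre, mature, seed, four flanks)
#'
#' For each pre-miRNA of length L, flanking regions 1 and 2 are successive
#' windows adjacent to the precursor, each exactly L long; 5'/3' assignment
#' follows the transcriptional orientation, so on the minus strand the 5'
#' flanks have larger genomic coordinates. The seed region is mature
#' positions `seed_span[1]`..`seed_span[2]` (1-based, in mature orientation).
#'
#' @param mirnas Tibble with columns `mirna`, `chrom`, `pre_start`,
#'   `pre_end`, `strand`, `mature_start`, `mature_end` (0-based half-open).
#' @param seed_span Integer pair: first and last mature position of the seed
#'   (default `c(2, 8)`, the canonical 7-nt seed).
#' @param chrom_lengths Optional named vector of chromosome lengths used to
#'   truncate flanks at chromosome ends (flanks are always clipped at 0).
#' @return Long tibble: `unit_id`, `label`, `chrom`, `start`, `end`,
#'   `strand`, `truncated`.
#' @export
mirna_regions <- function(mirnas, seed_span = c(2L, 8L), chrom_lengths = NULL) {
  stopifnot(length(seed_span) == 2, seed_span[1] >= 1, seed_span[2] > seed_span[1])
  bad <- mirnas$mature_start < mirnas$pre_start | mirnas$mature_end > mirnas$pre_end
  if (any(bad)) {
    stop("mature interval outside its pre-miRNA for: ",
         paste(mirnas$mirna[bad], collapse = ", "))
  }
  lo <- as.integer(seed_span[1]); hi <- as.integer(seed_span[2])
  rows <- purrr::pmap(mirnas, function(mirna, chrom, pre_start, pre_end, strand,
                                       mature_start, mature_end, ...) {
    L <- pre_end - pre_start
    plus <- identical(strand, "+")
    seed_start <- if (plus) mature_start + lo - 1L else mature_end - hi
    seed_end   <- if (plus) mature_start + hi      else mature_end - lo + 1L
    lab <- c("flank2_5p", "flank1_5p", "pre", "mature", "seed",
             "flank1_3p", "flank2_3p")
    if (plus) {
      s <- c(pre_start - 2L * L, pre_start - L, pre_start, mature_start,
             seed_start, pre_end, pre_end + L)
      e <- c(pre_start - L, pre_start, pre_end, mature_end,
             seed_end, pre_end + L, pre_end + 2L * L)
    } else {
      s <- c(pre_end + L, pre_end, pre_start, mature_start,
             seed_start, pre_start - L, pre_start - 2L * L)
      e <- c(pre_end + 2L * L, pre_end + L, pre_end, mature_end,
             seed_end, pre_start, pre_start - L)
    }
    tibble(unit_id = mirna, label = lab, chrom = chrom,
           start = as.integer(s), end = as.integer(e), strand = strand)
  })
  clip_regions(dplyr::bind_rows(rows), chrom_lengths)
}

#' Build footprint region systems (core plus four flanks)
#'
#' Flanks left and right of each footprint are successive windows equal in
#' length to the footprint itself. Footprints whose length is not the
#' canonical 41 nt are kept but a warning reports how many deviate.
#'
#' @param footprints Tibble with `chrom`, `start`, `end`, `name` (0-based
#'   half-open intervals).
#' @param chrom_lengths Optional named vector of chromosome lengths.
#' @return Long tibble as in [mirna_regions()] with labels `footprint`,
#'   `flank1_left`, `flank2_left`, `flank1_right`, `flank2_right`.
#' @export
footprint_regions <- function(footprints, chrom_lengths = NULL) {
  len <- footprints$end - footprints$start
  if (any(len != 41L)) {
    warning(sum(len != 41L), " footprint(s) deviate from the canonical 41 nt")
  }
  rows <- purrr::pmap(footprints[, c("chrom", "start", "end", "name")],
                      function(chrom, start, end, name) {
    L <- end - start
    s <- c(start - 2L * L, start - L, start, end, end + L)
    e <- c(start - L, start, end, end + L, end + 2L * L)
    tibble(
      unit_id = name,
      label = c("flank2_left", "flank1_left", "footprint",
                "flank1_right", "flank2_right"),
      chrom = chrom,
      start = as.integer(s),
      end = as.integer(e),
      strand = "+"
    )
  })
  clip_regions(dplyr::bind_rows(rows), chrom_lengths)
}

#' Treat stand-alone intervals (3' UTRs, validated sites) as regions
#'
#' @param intervals Tibble with `chrom`, `start`, `end`, `name`, `strand`.
#' @param label Region label to assign (e.g. `"utr3"` or `"validated_site"`).
#' @return Region tibble compatible with [region_density()].
#' @export
interval_regions <- function(intervals, label) {
  tibble(unit_id = intervals$name, label = label, chrom = intervals$chrom,
         start = intervals$start, end = intervals$end,
         strand = intervals$strand, truncated = FALSE)
}

# Clip regions to [0, chrom length); drop regions that vanish; flag clipping.
clip_regions <- function(regions, chrom_lengths = NULL) {
  s0 <- regions$start
  e0 <- regions$end
  regions$start <- pmax(regions$start, 0L)
  if (!is.null(chrom_lengths)) {
    lim <- as.integer(chrom_lengths[regions$chrom])
    regions$end <- pmin(regions$end, lim)
  }
  regions$truncated <- regions$start != s0 | regions$end != e0
  dplyr::filter(regions, .data$end > .data$start)
}

#' Variant density of a single region
#'
#' Counts variants whose anchor base (VCF position converted to 0-based)
#' lies in the half-open region, divided by region length. Deletions are
#' counted at their anchor.
#'
#' @param variants Variant tibble (`chrom`, `pos1`).
#' @param region One-row tibble or list with `chrom`, `start`, `end`.
#' @return Variants per nucleotide (double scalar).
#' @export
unit_density <- function(variants, region) {
  len <- region$end - region$start
  if (length(len) != 1 || len <= 0) stop("region must have positive length")
  anchor0 <- variants$pos1 - 1L
  n <- sum(variants$chrom == region$chrom &
             anchor0 >= region$start & anchor0 < region$end)
  n / len
}

#' Per-unit, per-label variant densities over a region system
#'
#' @param variants Variant tibble (`chrom`, `pos1`, optionally `kind`).
#' @param regions Region tibble from [mirna_regions()],
#'   [footprint_regions()] or [interval_regions()].
#' @param kinds Optional subset of variant kinds to count (e.g.
#'   `c("insertion", "deletion")` for an indels-only profile).
#' @return Tibble `unit_id`, `label`, `length`, `n_variants`, `density`.
#' @export
region_density <- function(variants, regions, kinds = NULL) {
  if (!is.null(kinds)) variants <- dplyr::filter(variants, .data$kind %in% kinds)
  v <- dplyr::transmute(variants, chrom = .data$chrom, anchor0 = .data$pos1 - 1L)
  r <- dplyr::mutate(regions, .region = dplyr::row_number())
  hits <- dplyr::inner_join(
    r, v,
    by = dplyr::join_by("chrom", "start" <= "anchor0", "end" > "anchor0")
  )
  counts <- dplyr::count(hits, .data$.region, name = "n_variants")
  r %>%
    dplyr::left_join(counts, by = ".region") %>%
    dplyr::mutate(
      n_variants = dplyr::coalesce(.data$n_variants, 0L),
      length = .data$end - .data$start,
      density = .data$n_variants / .data$length
    ) %>%
    dplyr::select("unit_id", "label", "length", "n_variants", "density")
}
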