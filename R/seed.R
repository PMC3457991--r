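#' Reverse complement of DNA sequences
#'
#' @param seq Character vector over the alphabet `A C G T N`.
#' @return Character vector of reverse complements (`N` maps to `N`).
#' @export
revcomp <- function(seq) {
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) stop("revcomp(): invalid character in '", seq[bad][1], "'")
  comp <- chartr("ACGTN", "TGCAN", seq)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' The canonical seed-site types
#'
#' Each type pairs a span of 1-based mature-miRNA positions with an optional
#' requirement for an adenosine opposite miRNA position 1 (`requires_a1`).
#' The default set holds the six canonical types; it is a plain tibble so a
#' caller can supply an edited set to [seed_motifs()].
#'
#' @return Tibble `seed_type`, `lo`, `hi`, `requires_a1`.
#' @export
seed_types <- function() {
  tibble(
    seed_type   = c("8mer", "7mer-m8", "7mer-A1", "6mer",
                    "offset-6mer", "offset-7mer"),
    lo          = c(2L, 2L, 2L, 2L, 3L, 3L),
    hi          = c(8L, 8L, 7L, 7L, 8L, 9L),
    requires_a1 = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
  )
}

#' Target-site motifs for one mature miRNA
#'
#' The site motif of a seed type spanning mature positions `lo..hi` is the
#' reverse complement (in DNA space; `U` is mapped to `T`) of that span,
#' with an `A` appended at the 3' end of the site for types requiring an A
#' opposite position 1. Types whose span extends past the mature sequence
#' are dropped with a warning.
#'
#' @param mature Mature miRNA sequence (RNA or DNA, 5'→3').
#' @param types Seed-type table as from [seed_types()].
#' @return Tibble `seed_type`, `motif` (DNA, 5'→3' on the target sense
#'   strand).
#' @export
seed_motifs <- function(mature, types = seed_types()) {
  m <- chartr("Uu", "Tt", toupper(mature))
  m <- toupper(m)
  drop <- types$hi > nchar(m)
  if (any(drop)) {
    warning("mature sequence of ", nchar(m), " nt: dropping seed type(s) ",
            paste(types$seed_type[drop], collapse = ", "))
    types <- types[!drop, ]
  }
  motif <- revcomp(substr(rep(m, nrow(types)), types$lo, types$hi))
  motif <- ifelse(types$requires_a1, paste0(motif, "A"), motif)
  tibble(seed_type = types$seed_type, motif = motif)
}

#' Target-site motif catalog for a set of miRNAs
#'
#' @param mirnas Tibble with columns `mirna` and `mature_seq`.
#' @param types Seed-type table as from [seed_types()].
#' @return Tibble `mirna`, `seed_type`, `motif`.
#' @export
mirna_motifs <- function(mirnas, types = seed_types()) {
  purrr::map2_dfr(mirnas$mirna, mirnas$mature_seq, function(name, seqs) {
    dplyr::mutate(seed_motifs(seqs, types), mirna = name, .before = 1)
  })
}

#' Extract reference and mutant windows around a variant
#'
#' The reference window spans `half_width` nucleotides on each side of the
#' reference allele (total ~2*half_width for the default 50, i.e. a 100-bp
#' window); the mutant window has the same flanks with the alternate allele
#' substituted. Windows crossing a chromosome edge are truncated and
#' flagged.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param variant One-row tibble or list with `chrom`, `pos1`, `ref`, `alt`.
#' @param half_width Flank width in nt (default 50).
#' @return List with `ref_window`, `mut_window`, `origin` (0-based genomic
#'   position of the window's left edge), `anchor_off` (0-based offset of
#'   the anchor base within the window) and `truncated`.
#' @export
extract_windows <- function(genome, variant, half_width = 50L) {
  chromseq <- genome[[variant$chrom]]
  clen <- nchar(chromseq)
  anchor0 <- variant$pos1 - 1L
  from0 <- anchor0 - half_width
  to0 <- anchor0 + nchar(variant$ref) + half_width  # exclusive
  origin <- max(0L, from0)
  stop0 <- min(clen, to0)
  ref_window <- substr(chromseq, origin + 1L, stop0)
  anchor_off <- anchor0 - origin
  seen <- substr(ref_window, anchor_off + 1L, anchor_off + nchar(variant$ref))
  if (seen != variant$ref) {
    stop("REF allele '", variant$ref, "' does not match genome ('", seen,
         "') at ", variant$chrom, ":", variant$pos1)
  }
  mut_window <- paste0(
    substr(ref_window, 1L, anchor_off),
    variant$alt,
    substr(ref_window, anchor_off + nchar(variant$ref) + 1L, nchar(ref_window))
  )
  list(ref_window = ref_window, mut_window = mut_window,
       origin = origin, anchor_off = anchor_off,
       truncated = from0 < 0L || to0 > clen)
}

#' Find all exact motif occurrences in a window
#'
#' Overlapping occurrences are reported; windows containing `N` never match
#' at positions covering the `N`.
#'
#' @param window DNA string to scan.
#' @param motifs Tibble with a `motif` column; any other columns (`mirna`,
#'   `seed_type`, ...) are carried through.
#' @return Tibble of matches: the motif row columns plus `offset` (0-based
#'   start within the window).
#' @export
scan_window <- function(window, motifs) {
  n <- nchar(window)
  out <- purrr::map_dfr(seq_len(nrow(motifs)), function(i) {
    k <- nchar(motifs$motif[i])
    if (n < k) return(NULL)
    starts <- seq_len(n - k + 1L)
    hit <- starts[substring(window, starts, starts + k - 1L) == motifs$motif[i]]
    if (length(hit) == 0) return(NULL)
    dplyr::bind_cols(motifs[rep(i, length(hit)), ], tibble(offset = hit - 1L))
  })
  if (nrow(out) == 0) out <- dplyr::mutate(motifs[0, ], offset = integer(0))
  out
}

#' Diff reference and mutant site matches into impact calls
#'
#' Mutant match offsets to the right of the indel's left edge are shifted
#' back by the net allele-length change so that unchanged downstream sites
#' cancel. A reference match with no equivalent mutant match is `disrupted`;
#' a mutant match with no equivalent reference match is `created`.
#'
#' @param ref_matches,mut_matches Outputs of [scan_window()] on the
#'   reference and mutant windows (identical motif sets).
#' @param anchor_off 0-based offset of the variant anchor base in the
#'   reference window.
#' @param net_change `nchar(alt) - nchar(ref)`.
#' @return Tibble `status` (`disrupted`/`created`), `mirna` (if present),
#'   `seed_type`, `motif`, `ref_offset`, `mut_offset`, `site_offset`
#'   (reference-space offset of the affected site).
#' @export
diff_sites <- function(ref_matches, mut_matches, anchor_off, net_change) {
  keycols <- intersect(c("mirna", "seed_type"), names(ref_matches))
  mut <- dplyr::mutate(
    mut_matches,
    mapped = ifelse(.data$offset > anchor_off,
                    .data$offset - net_change, .data$offset)
  )
  key <- function(df, off) {
    do.call(paste, c(df[keycols], list(off), sep = "\r"))
  }
  ref_keys <- key(ref_matches, ref_matches$offset)
  mut_keys <- key(mut, mut$mapped)
  disrupted <- ref_matches[!(ref_keys %in% mut_keys), , drop = FALSE]
  created <- mut[!(mut_keys %in% ref_keys), , drop = FALSE]
  dplyr::bind_rows(
    dplyr::mutate(disrupted, status = "disrupted",
                  ref_offset = .data$offset, mut_offset = NA_integer_,
                  site_offset = .data$offset),
    dplyr::mutate(created, status = "created",
                  ref_offset = NA_integer_, mut_offset = .data$offset,
                  site_offset = .data$mapped)
  ) %>%
    dplyr::select(dplyr::all_of(c("status", keycols, "motif",
                                  "ref_offset", "mut_offset", "site_offset")))
}

#' Impact calls for a set of variants against a motif catalog
#'
#' For each variant, extracts the reference and mutant windows, scans both
#' for every motif and diffs the match sets. For genes transcribed from the
#' minus strand pass `strand = "-"`: motifs are reverse-complemented for
#' scanning so that sites are detected on the transcript sense strand, while
#' reported motifs stay in transcript space.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param variants Variant tibble (`chrom`, `pos1`, `rsid`, `ref`, `alt`).
#' @param motifs Motif catalog from [mirna_motifs()].
#' @param half_width Window flank width (default 50).
#' @param strand `"+"` or `"-"`: transcript orientation of the scanned
#'   region.
#' @return Tibble: `rsid`, `chrom`, `pos1`, `ref`, `alt`, `mirna`,
#'   `seed_type`, `status`, `motif`, `ref_offset`, `mut_offset`,
#'   `site_start` (0-based genomic start of the affected site),
#'   `window_truncated`.
#' @export
variant_impacts <- function(genome, variants, motifs, half_width = 50L,
                            strand = "+") {
  scan_motifs <- motifs
  if (strand == "-") scan_motifs$motif <- revcomp(motifs$motif)
  sense <- stats::setNames(motifs$motif, paste(motifs$mirna, motifs$seed_type))
  out <- purrr::map_dfr(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    w <- extract_windows(genome, v, half_width)
    calls <- diff_sites(
      scan_window(w$ref_window, scan_motifs),
      scan_window(w$mut_window, scan_motifs),
      anchor_off = w$anchor_off,
      net_change = nchar(v$alt) - nchar(v$ref)
    )
    if (nrow(calls) == 0) return(NULL)
    dplyr::mutate(calls,
                  motif = unname(sense[paste(.data$mirna, .data$seed_type)]),
                  rsid = v$rsid, chrom = v$chrom, pos1 = v$pos1,
                  ref = v$ref, alt = v$alt,
                  site_start = w$origin + .data$site_offset,
                  window_truncated = w$truncated) %>%
      dplyr::select(dplyr::all_of(c(
        "rsid", "chrom", "pos1", "ref", "alt", "mirna", "seed_type",
        "status", "motif", "ref_offset", "mut_offset", "site_start",
        "window_truncated")))
  })
  if (nrow(out) == 0) out <- empty_impact_table()
  out
}

empty_impact_table <- function() {
  tibble(rsid = character(), chrom = character(), pos1 = integer(),
         ref = character(), alt = character(), mirna = character(),
         seed_type = character(), status = character(), motif = character(),
         ref_offset = integer(), mut_offset = integer(),
         site_start = integer(), window_truncated = logical())
}
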