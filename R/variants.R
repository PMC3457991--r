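#' Derive the kind of a variant from its alleles
#'
#' Anchor-base convention: an insertion's REF is a prefix of its ALT, a
#' deletion's ALT is a prefix of its REF. Length-1 REF and ALT is an SNV.
#' Anything else is `complex`.
#'
#' @param ref,alt Character vectors of uppercase alleles.
#' @return Character vector: `snv`, `insertion`, `deletion` or `complex`.
#' @export
variant_kind <- function(ref, alt) {
  nr <- nchar(ref)
  na <- nchar(alt)
  dplyr::case_when(
    nr == 1 & na == 1 ~ "snv",
    na > nr & substr(alt, 1, nr) == ref ~ "insertion",
    nr > na & substr(ref, 1, na) == alt ~ "deletion",
    TRUE ~ "complex"
  )
}

# Inserted/deleted sequence: the non-anchor suffix of the longer allele.
indel_changed_seq <- function(ref, alt) {
  ifelse(nchar(alt) > nchar(ref),
         substr(alt, nchar(ref) + 1L, nchar(alt)),
         substr(ref, nchar(alt) + 1L, nchar(ref)))
}

# TRUE when S is a whole number of copies of some unit u that also occurs
# immediately adjacent (right context starts with u, or left context ends
# with u). Used after the single-base-pair test, so |S| >= 2 here.
is_repeat_expansion <- function(s, left_context, right_context) {
  n <- nchar(s)
  for (l in seq_len(n)) {
    if (n %% l != 0L) next
    u <- substr(s, 1L, l)
    if (strrep(u, n %/% l) != s) next
    if (nchar(right_context) >= l && substr(right_context, 1L, l) == u) return(TRUE)
    if (nchar(left_context) >= l &&
        substr(left_context, nchar(left_context) - l + 1L, nchar(left_context)) == u) {
      return(TRUE)
    }
  }
  FALSE
}

#' Classify indels into single-base-pair, repeat-expansion and other
#'
#' Follows the size-first taxonomy: any net length-1 indel is
#' `single_base_pair`; a longer indel whose inserted/deleted sequence is a
#' whole number of copies of a unit that also occurs immediately adjacent in
#' the reference is a `repeat_expansion`; everything else is `other`.
#' Adjacency is checked on both sides of the variant site.
#'
#' @param variants Tibble of variants (see [read_vcf_min()]); every row must
#'   be an insertion or deletion.
#' @param genome Named character vector of chromosome sequences.
#' @param context Number of reference bases fetched on each side beyond the
#'   changed sequence when testing adjacency (default 20).
#' @return The input tibble with an added `class` column.
#' @export
classify_indels <- function(variants, genome, context = 20L) {
  if (nrow(variants) == 0) {
    return(dplyr::mutate(variants, class = character(0)))
  }
  if (!all(variants$kind %in% c("insertion", "deletion"))) {
    stop("classify_indels() accepts insertions and deletions only; got kind(s): ",
         paste(setdiff(unique(variants$kind), c("insertion", "deletion")),
               collapse = ", "))
  }
  cls <- purrr::pmap_chr(
    variants[, c("chrom", "pos1", "ref", "alt")],
    function(chrom, pos1, ref, alt) {
      s <- indel_changed_seq(ref, alt)
      if (nchar(s) == 1L) return("single_base_pair")
      chromseq <- genome[[chrom]]
      shorter <- min(nchar(ref), nchar(alt))
      left_end1 <- pos1 + shorter - 1L           # last base before the change
      right_start1 <- pos1 + nchar(ref)          # first ref base after it
      width <- nchar(s) + context
      left <- substr(chromseq, max(1L, left_end1 - width + 1L), left_end1)
      right <- substr(chromseq, right_start1,
                      min(nchar(chromseq), right_start1 + width - 1L))
      if (is_repeat_expansion(s, left, right)) "repeat_expansion" else "other"
    }
  )
  dplyr::mutate(variants, class = cls)
}
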