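#' Read a genome (or any DNA) FASTA file
#'
#' Reads a FASTA file into a named character vector of uppercase DNA
#' sequences. Sequence names are the first whitespace-delimited token of each
#' header line. Only the alphabet `A C G T N` is accepted.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per record.
#' @export
read_genome_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(
    strsplit(names(set), "\\s+"), `[[`, character(1), 1L
  )
  dup <- names(seqs)[duplicated(names(seqs))]
  if (length(dup) > 0) {
    stop("duplicate sequence name(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf(
      "invalid character %s in sequence '%s' at offset %d",
      substr(seqs[i], bad[i], bad[i]), names(seqs)[i], bad[i] - 1L
    ))
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a minimal VCF file of SNVs and indels
#'
#' Parses a minimal, anchor-base style VCF: tab-separated with at least the
#' five columns CHROM, POS, ID, REF, ALT; lines starting with `#` are
#' ignored and any extra columns are passed over. Multi-allelic rows are
#' split into one record per alternate allele, each classified independently.
#'
#' @param path Path to the VCF file.
#' @return A tibble with columns `chrom`, `pos1` (1-based anchor position),
#'   `rsid`, `ref`, `alt` and `kind` (one of `snv`, `insertion`, `deletion`,
#'   `complex`).
#' @export
read_vcf_min <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), pos1 = integer(), rsid = character(),
                  ref = character(), alt = character(), kind = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- vapply(fields, length, integer(1))
  if (any(ncol < 5)) {
    stop("VCF line ", which(ncol < 5)[1], " has fewer than 5 columns")
  }
  pos_chr <- vapply(fields, `[[`, character(1), 2L)
  if (any(!grepl("^[0-9]+$", pos_chr))) {
    stop("non-integer POS value: ", pos_chr[!grepl("^[0-9]+$", pos_chr)][1])
  }
  df <- tibble(
    chrom = vapply(fields, `[[`, character(1), 1L),
    pos1  = as.integer(pos_chr),
    rsid  = vapply(fields, `[[`, character(1), 3L),
    ref   = toupper(vapply(fields, `[[`, character(1), 4L)),
    alt   = toupper(vapply(fields, `[[`, character(1), 5L))
  )
  df <- tidyr::separate_longer_delim(df, "alt", delim = ",")
  bad <- !grepl("^[ACGT]+$", df$ref) | !grepl("^[ACGT]+$", df$alt)
  if (any(bad)) {
    stop("allele with characters outside ACGT: ",
         df$ref[bad][1], "/", df$alt[bad][1])
  }
  df$kind <- variant_kind(df$ref, df$alt)
  df
}

#' Write variants as a minimal VCF
#'
#' @param variants Tibble with `chrom`, `pos1`, `rsid`, `ref`, `alt`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf_min <- function(variants, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT")
  body <- sprintf("%s\t%d\t%s\t%s\t%s",
                  variants$chrom, variants$pos1, variants$rsid,
                  variants$ref, variants$alt)
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}

#' Read a BED file of genomic intervals
#'
#' BED is 0-based half-open. Columns beyond the first three are read as
#' `name`, `score`, `strand` when present; strand defaults to `+`.
#'
#' @param path Path to a BED3/BED4/BED6 file.
#' @return Tibble with `chrom`, `start`, `end`, `name`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- vapply(fields, length, integer(1))
  if (length(fields) > 0 && any(n < 3)) stop("BED line with fewer than 3 columns")
  col <- function(i, default) {
    vapply(seq_along(fields), function(j) {
      if (n[j] >= i) fields[[j]][i] else default
    }, character(1))
  }
  df <- tibble(
    chrom  = col(1L, NA_character_),
    start  = as.integer(col(2L, NA_character_)),
    end    = as.integer(col(3L, NA_character_)),
    name   = col(4L, NA_character_),
    strand = col(6L, "+")
  )
  df$strand[!df$strand %in% c("+", "-")] <- "+"
  if (any(is.na(df$start)) || any(is.na(df$end))) stop("non-integer BED coordinate")
  if (any(df$end <= df$start)) {
    i <- which(df$end <= df$start)[1]
    stop(sprintf("empty or inverted BED interval at line %d: %s:%d-%d",
                 i, df$chrom[i], df$start[i], df$end[i]))
  }
  if (anyNA(df$name)) {
    df$name[is.na(df$name)] <- sprintf("region%04d", which(is.na(df$name)))
  }
  df
}

#' Write intervals as BED6
#'
#' @param intervals Tibble with `chrom`, `start`, `end`, `name`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  readr::write_lines(sprintf("%s\t%d\t%d\t%s\t0\t%s",
                             intervals$chrom, intervals$start, intervals$end,
                             intervals$name, intervals$strand),
                     path)
  invisible(path)
}

#' Read a headered TSV table with a required schema
#'
#' Lines starting with `#` are treated as comments, so tables written by
#' [write_tsv_commented()] round-trip.
#'
#' @param path Path to the TSV file.
#' @param required Character vector of column names that must be present.
#' @return A tibble.
#' @export
read_tsv_table <- function(path, required = character()) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("table ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  df
}

#' Write a TSV with a commented provenance/semantics header
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param comments Character vector of comment lines (written as `# ...`).
#' @return `path`, invisibly.
#' @export
write_tsv_commented <- function(df, path, comments = character()) {
  if (length(comments) > 0) {
    readr::write_lines(paste0("# ", comments), path)
    readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(df, path)
  }
  invisible(path)
}

#' Read a genotype panel
#'
#' The panel TSV has columns `rsid`, `chrom`, `pos`, then one column per
#' individual holding minor-allele dosages 0/1/2 (NA for missing).
#'
#' @param path Path to the panel TSV.
#' @return A list with `markers` (tibble `rsid`, `chrom`, `pos1`) and
#'   `genotypes` (integer matrix, one row per marker, one column per
#'   individual, rownames = rsid).
#' @export
read_genotype_panel <- function(path) {
  df <- read_tsv_table(path, required = c("rsid", "chrom", "pos"))
  geno_cols <- setdiff(names(df), c("rsid", "chrom", "pos"))
  g <- as.matrix(df[, geno_cols])
  mode(g) <- "integer"
  if (any(!is.na(g) & !(g %in% 0:2))) stop("genotype dosages must be 0, 1, 2 or NA")
  rownames(g) <- df$rsid
  list(
    markers = tibble(rsid = df$rsid, chrom = df$chrom, pos1 = as.integer(df$pos)),
    genotypes = g
  )
}

#' Write a genotype panel
#'
#' @param markers Tibble with `rsid`, `chrom`, `pos1`.
#' @param genotypes Integer matrix of dosages, rows in `markers` order.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_panel <- function(markers, genotypes, path) {
  df <- dplyr::bind_cols(
    tibble(rsid = markers$rsid, chrom = markers$chrom, pos = markers$pos1),
    as_tibble(as.data.frame(genotypes), .name_repair = "minimal")
  )
  readr::write_tsv(df, path)
  invisible(path)
}
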