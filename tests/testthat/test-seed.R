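mature_demo <- "UAGCAGCACGUAAAUAUUGGCG"

test_that("revcomp handles palindromes, N and bad input", {
  expect_equal(revcomp("ACGT"), "ACGT")
  expect_equal(revcomp("AAAC"), "GTTT")
  expect_equal(revcomp("ACGN"), "NCGT")
  expect_equal(revcomp(c("AA", "CC")), c("TT", "GG"))
  expect_error(revcomp("ACGU"), "invalid character")
})

test_that("seed motifs are reverse complements of the seed spans", {
  m <- seed_motifs(mature_demo)
  motif <- function(t) m$motif[m$seed_type == t]
  expect_equal(motif("7mer-m8"), "TGCTGCT")
  expect_equal(motif("8mer"), "TGCTGCTA")
  expect_equal(motif("6mer"), "GCTGCT")
  expect_equal(motif("7mer-A1"), "GCTGCTA")
  expect_equal(motif("offset-6mer"), "TGCTGC")
  expect_equal(motif("offset-7mer"), "GTGCTGC")
})

test_that("short matures drop out-of-range seed types with a warning", {
  expect_warning(m <- seed_motifs("UAGCAGCA"), "offset-7mer")
  expect_false("offset-7mer" %in% m$seed_type)
  expect_true("8mer" %in% m$seed_type)
})

test_that("window extraction substitutes the alternate allele", {
  genome <- c(chr1 = "AAAACCCCGGGGTTTT")
  # deletion of G after the C/G junction: ref CG -> alt C
  v <- list(chrom = "chr1", pos1 = 8L, ref = "CG", alt = "C")
  w <- extract_windows(genome, v, half_width = 3L)
  expect_equal(w$ref_window, "CCCCGGGG")
  expect_equal(w$mut_window, "CCCCGGG")
  expect_equal(nchar(w$mut_window), nchar(w$ref_window) - 1)
  expect_equal(w$origin, 4L)
  expect_equal(w$anchor_off, 3L)

  v <- list(chrom = "chr1", pos1 = 8L, ref = "C", alt = "CTT")
  w <- extract_windows(genome, v, half_width = 3L)
  expect_equal(nchar(w$mut_window), nchar(w$ref_window) + 2)

  v <- list(chrom = "chr1", pos1 = 8L, ref = "C", alt = "A")
  w <- extract_windows(genome, v, half_width = 3L)
  d <- which(strsplit(w$ref_window, "")[[1]] != strsplit(w$mut_window, "")[[1]])
  expect_length(d, 1)

  # REF mismatches are caught
  v <- list(chrom = "chr1", pos1 = 8L, ref = "G", alt = "GA")
  expect_error(extract_windows(genome, v), "does not match genome")

  # windows at the chromosome edge are truncated and flagged
  v <- list(chrom = "chr1", pos1 = 2L, ref = "A", alt = "AT")
  w <- extract_windows(genome, v, half_width = 5L)
  expect_true(w$truncated)
  expect_equal(w$origin, 0L)
})

test_that("scanning finds all overlapping motif occurrences", {
  motifs <- dplyr::mutate(seed_motifs(mature_demo), mirna = "mir-demo")
  hits <- scan_window("AATGCTGCTAAA", motifs)
  at <- function(t) hits$offset[hits$seed_type == t]
  expect_equal(at("8mer"), 2L)
  expect_equal(at("7mer-m8"), 2L)
  expect_equal(at("7mer-A1"), 3L)
  expect_equal(at("6mer"), 3L)

  expect_equal(nrow(scan_window("AAAAAAAA", motifs)), 0)

  two <- scan_window("GCTGCTGCTGCT",
                     tibble::tibble(mirna = "m", seed_type = "6mer",
                                    motif = "GCTGCT"))
  expect_equal(two$offset, c(0L, 3L, 6L))

  # N never matches
  expect_equal(nrow(scan_window("AATGCTGNTAAA", motifs)), 0)
})

test_that("diffing calls disrupted and created sites with offset mapping", {
  motifs <- dplyr::mutate(seed_motifs(mature_demo), mirna = "mir-demo")
  # deletion of the internal C of the 8mer site TGCTGCTA
  genome <- c(chr1 = paste0("AAAAATGCTGCTAAAAA"))
  v <- tibble::tibble(chrom = "chr1", pos1 = 9L, rsid = "rd", ref = "TG",
                      alt = "T")
  calls <- variant_impacts(genome, v, motifs, half_width = 8L)
  expect_true(all(calls$status == "disrupted"))
  expect_true("8mer" %in% calls$seed_type)
  # nested shorter types at the destroyed locus are reported too
  expect_gte(nrow(calls), 1)

  # an insertion completing a motif absent from the reference
  genome <- c(chr1 = "AAAAATGTGCTAGGGG")  # TGCTGCTA with C3 missing
  v <- tibble::tibble(chrom = "chr1", pos1 = 7L, rsid = "rc", ref = "G",
                      alt = "GC")
  calls <- variant_impacts(genome, v, motifs, half_width = 6L)
  expect_true("created" %in% calls$status)
  expect_true("8mer" %in% calls$seed_type[calls$status == "created"])

  # an SNV outside any motif occurrence yields no calls
  genome <- c(chr1 = "AAAAATTTTTTTAAAAA")
  v <- tibble::tibble(chrom = "chr1", pos1 = 9L, rsid = "rs", ref = "T",
                      alt = "A")
  expect_equal(nrow(variant_impacts(genome, v, motifs, half_width = 6L)), 0)
})

test_that("matches clear of the variant are never called", {
  # motif far left and far right of a deletion: both must cancel
  set.seed(551)
  motifs <- tibble::tibble(mirna = "m", seed_type = "7mer-m8",
                           motif = "TGCTGCT")
  for (i in 1:200) {
    left <- random_dna(20)
    right <- random_dna(20)
    mid <- random_dna(10)
    seqs <- paste0(left, "TGCTGCT", mid, "TGCTGCT", right)
    # place a 1-nt deletion inside `mid`
    pos1 <- 20 + 7 + sample(1:8, 1)
    genome <- c(chr1 = seqs)
    ref <- substring(seqs, pos1, pos1 + 1)
    v <- tibble::tibble(chrom = "chr1", pos1 = pos1, rsid = "r",
                        ref = ref, alt = substring(ref, 1, 1))
    calls <- variant_impacts(genome, v, motifs, half_width = 30L)
    flank_sites <- c(20L, 20L + 7L + 10L)
    expect_false(any(calls$site_start %in% flank_sites),
                 info = paste("iteration", i))
  }
})

test_that("diffing equals the independent scan-and-subtract oracle", {
  set.seed(662)
  for (i in 1:300) {
    mature <- chartr("T", "U", random_dna(22))
    motifs <- dplyr::mutate(seed_motifs(mature), mirna = "m1")
    ctx <- random_dna(120)
    pos1 <- sample(40:80, 1)
    anchor <- substring(ctx, pos1, pos1)
    if (runif(1) < 0.5) {
      ref <- anchor
      alt <- paste0(anchor, random_dna(sample(1:4, 1)))
    } else {
      ref <- substring(ctx, pos1, pos1 + sample(1:4, 1))
      alt <- anchor
    }
    genome <- c(chr1 = ctx)
    v <- tibble::tibble(chrom = "chr1", pos1 = pos1, rsid = "r",
                        ref = ref, alt = alt)
    got <- variant_impacts(genome, v, motifs, half_width = 30L)
    w <- extract_windows(genome, v, half_width = 30L)
    want <- oracle_diff(w$ref_window, w$mut_window, motifs, w$anchor_off,
                        nchar(alt) - nchar(ref))
    got_keys <- sort(paste(got$seed_type, got$status,
                           got$site_start - w$origin))
    want_keys <- sort(paste(want$seed_type, want$status, want$site_offset))
    expect_equal(got_keys, want_keys, info = paste("fixture", i))
  }
})
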