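# a hand-built locus: one gene UTR containing one footprint with a planted
# 7mer-m8 site for mir-demo (mature seed AGCAGCA -> site motif TGCTGCT)
impact_fixture <- function(strand = "+") {
  motif <- if (strand == "+") "TGCTGCT" else revcomp("TGCTGCT")
  genome <- paste0(strrep("A", 60), "CCGT", motif, "TGCA", strrep("A", 60))
  mirnas <- tibble::tibble(mirna = "mir-demo",
                           mature_seq = "UAGCAGCACGUAAAUAUUGGCG")
  utrs <- tibble::tibble(chrom = "chr1", start = 10L, end = 120L,
                         name = "G1", strand = strand)
  footprints <- tibble::tibble(chrom = "chr1", start = 50L, end = 91L,
                               name = "fp1", strand = strand,
                               gene_id = "G1")
  # motif occupies 0-based 64..70; an insertion inside it
  anchor_pos1 <- 67L
  ref <- substring(genome, 67, 67)
  ins <- setdiff(c("A", "C", "G", "T"),
                 substring(genome, 68, 68))[1]
  refs <- c(ref, substring(genome, 30, 30), substring(genome, 95, 95))
  alts <- c(paste0(ref, ins), paste0(substring(genome, 30, 30), "T"),
            paste0(substring(genome, 95, 95), "T"))
  variants <- tibble::tibble(
    chrom = "chr1",
    pos1 = c(anchor_pos1, 30L, 95L),
    rsid = c("rsIn", "rsLeft", "rsOut"),
    ref = refs,
    alt = alts,
    kind = "insertion")
  list(genome = c(chr1 = genome), mirnas = mirnas, utrs = utrs,
       footprints = footprints, variants = variants)
}

test_that("footprint scan calls indels inside footprints only", {
  fx <- impact_fixture()
  out <- footprint_impact(fx$variants, fx$footprints, fx$mirnas, fx$genome)
  expect_true(all(out$unit_id == "fp1"))
  expect_true("rsIn" %in% out$rsid)
  # rsLeft (pos 30) and rsOut (pos 95) anchor outside [50, 91)
  expect_false(any(c("rsLeft", "rsOut") %in% out$rsid))
  expect_true(any(out$rsid == "rsIn" & out$seed_type == "7mer-m8" &
                    out$status == "disrupted"))
  expect_equal(unique(out$provenance), "footprint_scan")
})

test_that("footprint boundary uses the half-open convention", {
  fx <- impact_fixture()
  # anchor exactly at end (0-based 91 -> pos1 92) is excluded
  v <- tibble::tibble(chrom = "chr1", pos1 = 92L, rsid = "rsEdge",
                      ref = substring(fx$genome, 92, 92),
                      alt = paste0(substring(fx$genome, 92, 92), "T"),
                      kind = "insertion")
  out <- footprint_impact(v, fx$footprints, fx$mirnas, fx$genome)
  expect_equal(nrow(out), 0)
  # empty footprint set gives an empty table
  out <- footprint_impact(fx$variants, fx$footprints[0, ], fx$mirnas,
                          fx$genome)
  expect_equal(nrow(out), 0)
})

test_that("pair scan is restricted to supported pairs", {
  fx <- impact_fixture()
  pairs <- tibble::tibble(gene_id = "G1", mirna = "mir-demo",
                          source = "test")
  out <- pair_impact(fx$variants, fx$utrs, pairs, fx$mirnas, fx$genome)
  expect_true(any(out$rsid == "rsIn" & out$status == "disrupted"))
  expect_true(all(out$unit_id == "G1"))
  expect_equal(unique(out$provenance), "pair_scan")

  # same indel, but the pair list lacks (G1, mir-demo): zero calls
  other <- tibble::tibble(gene_id = "G1", mirna = "mir-other",
                          source = "test")
  expect_message(
    out2 <- pair_impact(fx$variants, fx$utrs, other, fx$mirnas, fx$genome),
    "skipping")
  expect_equal(nrow(out2), 0)
})

test_that("minus-strand genes are scanned in transcript sense", {
  fx <- impact_fixture(strand = "-")
  pairs <- tibble::tibble(gene_id = "G1", mirna = "mir-demo",
                          source = "test")
  out <- pair_impact(fx$variants, fx$utrs, pairs, fx$mirnas, fx$genome)
  hit <- out[out$rsid == "rsIn" & out$seed_type == "7mer-m8", ]
  expect_gte(nrow(hit), 1)
  expect_equal(unique(hit$status), "disrupted")
  # the reported motif stays in transcript space
  expect_equal(unique(hit$motif), "TGCTGCT")
})

test_that("SNVs flow through the same scan when requested", {
  fx <- impact_fixture()
  # SNV breaking the motif core
  v <- tibble::tibble(chrom = "chr1", pos1 = 68L, rsid = "rsSnv",
                      ref = substring(fx$genome, 68, 68),
                      alt = setdiff(c("A", "C", "G", "T"),
                                    substring(fx$genome, 68, 68))[1],
                      kind = "snv")
  pairs <- tibble::tibble(gene_id = "G1", mirna = "mir-demo",
                          source = "test")
  out <- pair_impact(v, fx$utrs, pairs, fx$mirnas, fx$genome, kinds = "snv")
  expect_true(any(out$status == "disrupted"))
})

test_that("pathway table reproduces shared-denominator percentages", {
  membership <- tibble::tibble(
    pathway_id = "hsa05212", pathway_name = "Pancreatic cancer",
    gene_id = sprintf("g%02d", 1:70))
  indel_genes <- sprintf("g%02d", 1:13)
  snp_genes <- sprintf("g%02d", 1:26)
  out <- pathway_table(indel_genes, snp_genes, membership, min_genes = 10)
  expect_equal(out$n_pathway_genes, 70L)
  expect_equal(out$pct_indel, 18.57)
  expect_equal(out$pct_snp, 37.14)
  # shared denominator: the percentage ratio equals the count ratio
  expect_equal(out$pct_snp / out$pct_indel,
               out$n_genes_with_snp_impacts / out$n_genes_with_indel_impacts,
               tolerance = 1e-3)
})

test_that("pathway table filters, sorts and handles empty input", {
  membership <- dplyr::bind_rows(
    tibble::tibble(pathway_id = "p1", pathway_name = "Big",
                   gene_id = sprintf("a%02d", 1:40)),
    tibble::tibble(pathway_id = "p2", pathway_name = "Small",
                   gene_id = sprintf("b%02d", 1:20)),
    tibble::tibble(pathway_id = "p3", pathway_name = "Cold",
                   gene_id = sprintf("c%02d", 1:30)))
  indel <- c(sprintf("a%02d", 1:12), sprintf("b%02d", 1:15))
  out <- pathway_table(indel, character(0), membership, min_genes = 10)
  expect_equal(out$pathway_id, c("p2", "p1"))   # sorted by indel gene count
  expect_false("p3" %in% out$pathway_id)        # 0 flagged -> filtered
  expect_equal(nrow(pathway_table(indel, indel, membership[0, ])), 0)
  # the optional enrichment column is only added on request
  expect_false("hypergeom_p_indel" %in% names(out))
  out2 <- pathway_table(indel, character(0), membership, min_genes = 10,
                        hypergeom = TRUE)
  expect_true(all(out2$hypergeom_p_indel >= 0 & out2$hypergeom_p_indel <= 1))
})

test_that("percentages round half-up to two decimals", {
  membership <- tibble::tibble(pathway_id = "p", pathway_name = "P",
                               gene_id = sprintf("g%03d", 1:800))
  out <- pathway_table(sprintf("g%03d", 1:100), character(0), membership,
                       min_genes = 1)
  expect_equal(out$pct_indel, 12.5)
  out <- pathway_table(sprintf("g%03d", 1:101), character(0), membership,
                       min_genes = 1)
  expect_equal(out$pct_indel, 12.63)  # 12.625 rounds up, not to even
})
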