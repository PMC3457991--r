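# simulate one two-founder block panel: within-block pairs have |D'| = 1
block_panel <- function(n_ind, n_markers_per_block, freqs, positions) {
  g <- list()
  for (b in seq_along(freqs)) {
    gb <- rbinom(n_ind, 1, freqs[b]) + rbinom(n_ind, 1, freqs[b])
    g[[b]] <- matrix(rep(gb, each = n_markers_per_block),
                     nrow = n_markers_per_block)
  }
  geno <- do.call(rbind, g)
  markers <- tibble::tibble(
    rsid = sprintf("m%02d", seq_len(nrow(geno))),
    chrom = "chr1", pos1 = positions)
  rownames(geno) <- markers$rsid
  list(markers = markers, genotypes = geno)
}

test_that("EM equals direct counting when phase is unambiguous", {
  # no double heterozygotes: haplotypes are countable by hand
  ga <- c(2L, 2L, 0L, 0L, 2L, 0L)
  gb <- c(2L, 2L, 0L, 0L, 2L, 0L)
  em <- em_haplotype_freqs(ga, gb)
  expect_true(em$ok)
  expect_equal(unname(em$freqs["p11"]), 0.5, tolerance = 1e-9)
  expect_equal(unname(em$freqs["p00"]), 0.5, tolerance = 1e-9)
  expect_equal(sum(em$freqs), 1, tolerance = 1e-12)

  # no double heterozygotes again; haplotypes counted by hand:
  # (2,0) x2 -> 4 Ab; (1,0) -> Ab + ab; (0,2) x3 -> 6 aB; (1,2) x2 -> 2 AB + 2 aB
  ga <- c(2L, 1L, 0L, 1L, 2L, 0L, 1L, 0L)
  gb <- c(0L, 0L, 2L, 2L, 0L, 2L, 2L, 2L)
  em <- em_haplotype_freqs(ga, gb)
  expect_equal(sum(em$freqs), 1, tolerance = 1e-12)
  expect_equal(unname(em$freqs),
               c(2, 5, 8, 1) / 16, tolerance = 1e-9)
})

test_that("EM agrees with the grid-search likelihood oracle", {
  set.seed(99)
  for (i in 1:10) {
    # genotypes with plenty of double heterozygotes
    n <- 60
    hap_freq <- c(0.4, 0.15, 0.15, 0.3)
    haps <- sample(4, 2 * n, replace = TRUE, prob = hap_freq)
    a_allele <- c(1, 1, 0, 0)[haps]
    b_allele <- c(1, 0, 1, 0)[haps]
    ga <- a_allele[1:n] + a_allele[(n + 1):(2 * n)]
    gb <- b_allele[1:n] + b_allele[(n + 1):(2 * n)]
    fa <- mean(ga) / 2
    fb <- mean(gb) / 2
    if (fa %in% c(0, 1) || fb %in% c(0, 1)) next
    em <- em_haplotype_freqs(ga, gb)
    grid <- oracle_em_grid(ga, gb)
    expect_equal(unname(em$freqs), unname(grid), tolerance = 1e-3)
    expect_equal(sum(em$freqs), 1, tolerance = 1e-12)
  }
})

test_that("monomorphic markers are flagged as undefined", {
  em <- em_haplotype_freqs(rep(0L, 10), rbinom(10, 2, 0.5))
  expect_false(em$ok)
  expect_true(all(is.na(em$freqs)))
  ld <- dprime_ci(rep(2L, 20), rbinom(20, 2, 0.5))
  expect_false(ld$ok)
})

test_that("missing genotypes are dropped pairwise", {
  ga <- c(2L, 2L, 0L, 0L, NA, 1L)
  gb <- c(2L, 2L, 0L, 0L, 1L, NA)
  em <- em_haplotype_freqs(ga, gb)
  expect_equal(em$n, 4)
})

test_that("D' is zero at product frequencies and one when coupled", {
  # exact product table: independent alleles
  ga <- c(rep(2L, 4), rep(1L, 8), rep(0L, 4))
  gb <- c(2L, 1L, 1L, 0L, rep(c(2L, 1L, 1L, 0L), 2), 2L, 1L, 1L, 0L)
  ld <- dprime_ci(ga, gb)
  expect_true(ld$ok)
  expect_lt(ld$d_prime, 0.3)

  set.seed(41)
  pn <- block_panel(100, 2, 0.5, c(100L, 200L))
  ld <- dprime_ci(pn$genotypes[1, ], pn$genotypes[2, ])
  expect_equal(ld$d_prime, 1, tolerance = 1e-6)
  expect_gte(ld$cl, 0.7)
  expect_gte(ld$cu, 0.98)
})

test_that("independent markers show strong recombination at n = 200", {
  set.seed(42)
  ga <- rbinom(200, 2, 0.4)
  gb <- rbinom(200, 2, 0.4)
  ld <- dprime_ci(ga, gb)
  expect_lt(ld$d_prime, 0.25)
  expect_lt(ld$cu, 0.9)
})

test_that("|D'| is invariant under allele-label swap at either marker", {
  set.seed(43)
  for (i in 1:20) {
    ga <- rbinom(80, 2, runif(1, 0.2, 0.8))
    gb <- rbinom(80, 2, runif(1, 0.2, 0.8))
    fa <- mean(ga) / 2
    fb <- mean(gb) / 2
    if (fa %in% c(0, 1) || fb %in% c(0, 1)) next
    a <- dprime_ci(ga, gb)
    b <- dprime_ci(2L - ga, gb)
    cc <- dprime_ci(ga, 2L - gb)
    expect_equal(a$d_prime, b$d_prime, tolerance = 1e-6)
    expect_equal(a$d_prime, cc$d_prime, tolerance = 1e-6)
  }
})

test_that("the MLE |D'| lies inside the likelihood interval", {
  set.seed(44)
  inside <- 0; total <- 0
  for (i in 1:50) {
    ga <- rbinom(100, 2, runif(1, 0.2, 0.8))
    gb <- rbinom(100, 2, runif(1, 0.2, 0.8))
    ld <- dprime_ci(ga, gb)
    if (!ld$ok) next
    total <- total + 1
    if (ld$d_prime >= ld$cl - 1e-9 && ld$d_prime <= ld$cu + 1e-9) {
      inside <- inside + 1
    }
  }
  expect_gte(inside / total, 0.99)
})

test_that("two-block panels are recovered with exact membership", {
  set.seed(45)
  pn <- block_panel(120, 5, c(0.4, 0.6),
                    c(seq(1000L, 5000L, 1000L), seq(50000L, 54000L, 1000L)))
  blocks <- gabriel_blocks(pn$markers, pn$genotypes)
  expect_equal(nrow(blocks), 2)
  expect_equal(blocks$members[[1]], sprintf("m%02d", 1:5))
  expect_equal(blocks$members[[2]], sprintf("m%02d", 6:10))
  expect_equal(blocks$left_pos1, c(1000L, 50000L))
  expect_equal(blocks$right_pos1, c(5000L, 54000L))
})

test_that("markers below the MAF floor are excluded from blocks", {
  set.seed(46)
  pn <- block_panel(120, 5, 0.5, seq(1000L, 5000L, 1000L))
  # insert a rare marker mid-block
  rare <- matrix(rbinom(120, 2, 0.02), nrow = 1,
                 dimnames = list("rare", NULL))
  markers <- dplyr::bind_rows(
    pn$markers[1:3, ],
    tibble::tibble(rsid = "rare", chrom = "chr1", pos1 = 3500L),
    pn$markers[4:5, ])
  geno <- rbind(pn$genotypes, rare)
  blocks <- gabriel_blocks(markers, geno)
  expect_equal(nrow(blocks), 1)
  expect_false("rare" %in% blocks$members[[1]])
  expect_equal(blocks$members[[1]], sprintf("m%02d", 1:5))
})

test_that("independent panels produce no blocks", {
  set.seed(47)
  geno <- matrix(rbinom(8 * 150, 2, 0.5), nrow = 8)
  rownames(geno) <- sprintf("x%d", 1:8)
  markers <- tibble::tibble(rsid = rownames(geno), chrom = "chr1",
                            pos1 = seq(1000L, 8000L, 1000L))
  blocks <- gabriel_blocks(markers, geno)
  expect_equal(nrow(blocks), 0)
})

test_that("a stricter informative fraction never enlarges blocks", {
  set.seed(48)
  pn <- block_panel(100, 6, 0.5, seq(1000L, 6000L, 1000L))
  spans <- vapply(c(0.5, 0.8, 0.95, 1), function(f) {
    b <- gabriel_blocks(pn$markers, pn$genotypes, informative_fraction = f)
    if (nrow(b) == 0) 0L else max(b$n_markers)
  }, integer(1))
  expect_true(all(diff(spans) <= 0))
})

test_that("indels link to markers through a shared block", {
  set.seed(49)
  # positions mirror a body-mass-index locus: indel at 25166699, marker at
  # 25158008, block spanning 25150296..25182193
  pos <- c(25150296L, 25158008L, 25166699L, 25182193L)
  pn <- block_panel(120, 4, 0.45, pos)
  pn$markers$rsid <- c("rsEdgeL", "rs713586", "rs34922018", "rsEdgeR")
  rownames(pn$genotypes) <- pn$markers$rsid
  gwas <- tibble::tibble(rsid = "rs713586", chrom = "chr1",
                         pos = 25158008, p = 6e-22,
                         trait = "Body Mass Index")
  indels <- tibble::tibble(rsid = "rs34922018", chrom = "chr1",
                           pos1 = 25166699L, feature = "DNAJC27")
  links <- link_indels(indels, gwas, list(markers = pn$markers,
                                          genotypes = pn$genotypes))
  expect_equal(nrow(links), 1)
  expect_equal(links$block_left, 25150296L)
  expect_equal(links$block_right, 25182193L)
  expect_equal(links$trait, "Body Mass Index")

  # an indel 150 kb from the nearest marker is never linked
  far <- tibble::tibble(rsid = "rsEdgeR", chrom = "chr1",
                        pos1 = 25182193L, feature = "X")
  gwas_far <- dplyr::mutate(gwas, pos = pos - 150000L)
  expect_equal(nrow(link_indels(far, gwas_far,
                                list(markers = pn$markers,
                                     genotypes = pn$genotypes))), 0)

  # indels absent from the panel are skipped with a message
  ghost <- tibble::tibble(rsid = "rsGhost", chrom = "chr1",
                          pos1 = 25160000L, feature = "Y")
  expect_message(out <- link_indels(ghost, gwas,
                                    list(markers = pn$markers,
                                         genotypes = pn$genotypes)),
                 "skipping")
  expect_equal(nrow(out), 0)
})
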