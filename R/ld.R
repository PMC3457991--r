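#' Two-locus haplotype frequencies by EM
#'
#' Estimates the four haplotype frequencies for a pair of biallelic markers
#' from unphased dosage genotypes (0/1/2 copies of the tracked allele).
#' Phase is known for every genotype combination except double
#' heterozygotes, whose expected split is re-estimated each iteration.
#'
#' @param ga,gb Integer dosage vectors for the two markers (NA = missing;
#'   individuals missing either genotype are dropped pairwise).
#' @param tol Convergence tolerance on the largest frequency change
#'   (default 1e-9).
#' @param max_iter Iteration cap (default 1000).
#' @return List: `freqs` (named vector `p11`, `p10`, `p01`, `p00` for
#'   haplotypes carrying the tracked allele at markers a/b), `n` individuals
#'   used, `iterations`, `converged`, and `ok` (FALSE when a marker is
#'   monomorphic, leaving frequencies undefined).
#' @export
em_haplotype_freqs <- function(ga, gb, tol = 1e-9, max_iter = 1000L) {
  keep <- !is.na(ga) & !is.na(gb)
  ga <- ga[keep]; gb <- gb[keep]
  n <- length(ga)
  if (n < 2) stop("need at least 2 informative individuals")
  fa <- mean(ga) / 2
  fb <- mean(gb) / 2
  if (fa %in% c(0, 1) || fb %in% c(0, 1)) {
    return(list(freqs = stats::setNames(rep(NA_real_, 4),
                                        c("p11", "p10", "p01", "p00")),
                n = n, iterations = 0L, converged = FALSE, ok = FALSE))
  }
  cnt <- matrix(0, 3, 3)
  for (i in seq_len(n)) cnt[ga[i] + 1L, gb[i] + 1L] <- cnt[ga[i] + 1L, gb[i] + 1L] + 1
  # phase-known haplotype counts; cnt[ga+1, gb+1]
  known <- c(
    p11 = 2 * cnt[3, 3] + cnt[3, 2] + cnt[2, 3],
    p10 = 2 * cnt[3, 1] + cnt[3, 2] + cnt[2, 1],
    p01 = 2 * cnt[1, 3] + cnt[2, 3] + cnt[1, 2],
    p00 = 2 * cnt[1, 1] + cnt[2, 1] + cnt[1, 2]
  )
  ndh <- cnt[2, 2]
  total <- 2 * n
  p <- c(p11 = fa * fb, p10 = fa * (1 - fb), p01 = (1 - fa) * fb,
         p00 = (1 - fa) * (1 - fb))
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    denom <- p["p11"] * p["p00"] + p["p10"] * p["p01"]
    q <- if (denom > 0) unname(p["p11"] * p["p00"] / denom) else 0.5
    new <- (known + ndh * c(q, 1 - q, 1 - q, q)) / total
    names(new) <- names(p)
    if (max(abs(new - p)) < tol) {
      p <- new
      converged <- TRUE
      break
    }
    p <- new
  }
  list(freqs = p, n = n, iterations = it, converged = converged, ok = TRUE)
}

# linear interpolation of the |D'| value where the cumulative likelihood
# crosses probability q
interp_quantile <- function(grid, cum, q) {
  idx <- which(cum >= q)[1]
  if (idx == 1L) return(grid[1])
  c0 <- cum[idx - 1L]
  grid[idx - 1L] + (grid[idx] - grid[idx - 1L]) * (q - c0) / (cum[idx] - c0)
}

#' |D'| with a likelihood-based confidence interval for one marker pair
#'
#' The point estimate is |D'| at the EM haplotype-frequency solution. The
#' one-sided 95% bounds (`cl`, `cu`) come from evaluating the multinomial
#' genotype likelihood on a grid of |D'| in [0, 1] (allele frequencies held
#' at their MLE, disequilibrium in the direction of the observed D),
#' normalizing, and interpolating the 5th and 95th percentiles of the
#' cumulative likelihood.
#'
#' @inheritParams em_haplotype_freqs
#' @param grid Grid of |D'| values (default 101 points, step 0.01).
#' @return One-row tibble: `d_prime`, `cl`, `cu`, `n`, `ok` (FALSE for
#'   degenerate pairs, which block calling treats as non-informative).
#' @export
dprime_ci <- function(ga, gb, grid = seq(0, 1, by = 0.01)) {
  em <- em_haplotype_freqs(ga, gb)
  bad <- tibble(d_prime = NA_real_, cl = NA_real_, cu = NA_real_,
                n = em$n, ok = FALSE)
  if (!em$ok) return(bad)
  p <- em$freqs
  pa <- unname(p["p11"] + p["p10"])
  pb <- unname(p["p11"] + p["p01"])
  d <- unname(p["p11"]) - pa * pb
  dmax <- if (d >= 0) min(pa * (1 - pb), (1 - pa) * pb) else
    min(pa * pb, (1 - pa) * (1 - pb))
  if (dmax <= 0) return(bad)
  d_prime <- abs(d) / dmax
  # genotype counts reused for the likelihood grid
  keep <- !is.na(ga) & !is.na(gb)
  ga <- ga[keep]; gb <- gb[keep]
  cnt <- matrix(0, 3, 3)
  for (i in seq_along(ga)) cnt[ga[i] + 1L, gb[i] + 1L] <- cnt[ga[i] + 1L, gb[i] + 1L] + 1
  sgn <- if (d >= 0) 1 else -1
  ll <- vapply(grid, function(dp) {
    dd <- sgn * dp * dmax
    h11 <- max(pa * pb + dd, 1e-12)
    h10 <- max(pa * (1 - pb) - dd, 1e-12)
    h01 <- max((1 - pa) * pb - dd, 1e-12)
    h00 <- max((1 - pa) * (1 - pb) + dd, 1e-12)
    pg <- matrix(c(
      h00^2,            2 * h01 * h00,            h01^2,
      2 * h10 * h00,    2 * h11 * h00 + 2 * h10 * h01, 2 * h11 * h01,
      h10^2,            2 * h11 * h10,            h11^2
    ), 3, 3, byrow = TRUE)  # rows ga = 0,1,2; cols gb = 0,1,2
    sum(cnt * log(pg))
  }, numeric(1))
  lik <- exp(ll - max(ll))
  cum <- cumsum(lik) / sum(lik)
  tibble(
    d_prime = min(d_prime, 1),
    cl = interp_quantile(grid, cum, 0.05),
    cu = interp_quantile(grid, cum, 0.95),
    n = em$n, ok = TRUE
  )
}

# minor allele frequency of one dosage vector
marker_maf <- function(g) {
  f <- mean(g, na.rm = TRUE) / 2
  min(f, 1 - f)
}

#' Call confidence-interval (Gabriel) LD blocks on one chromosome
#'
#' Markers with minor allele frequency below `maf_min` are excluded. A
#' candidate marker run qualifies as a block when its end pair is in strong
#' LD (`cl >= ci_low` and `cu >= ci_high`) and, among all informative pairs
#' inside the run (strong LD plus strong recombination, the latter defined
#' by `cu < recomb_high`), the strong-LD fraction is at least
#' `informative_fraction`. Non-overlapping qualifying runs are selected
#' greedily, largest genomic span first, ties to the leftmost.
#'
#' @param markers Tibble `rsid`, `chrom`, `pos1`, sorted or not; all rows
#'   must share one chromosome.
#' @param genotypes Dosage matrix, one row per marker (rownames = rsid).
#' @param maf_min Minor-allele-frequency floor (default 0.05).
#' @param ci_low Lower-bound minimum for strong LD (default 0.7).
#' @param ci_high Upper-bound minimum for strong LD (default 0.98).
#' @param recomb_high Upper-bound maximum for strong recombination
#'   (default 0.9).
#' @param informative_fraction Required strong-LD share of informative
#'   pairs (default 0.95).
#' @return Tibble `chrom`, `left_pos1`, `right_pos1`, `n_markers`,
#'   `members` (list column of member rsids), ordered by position.
#' @export
gabriel_blocks <- function(markers, genotypes, maf_min = 0.05,
                           ci_low = 0.7, ci_high = 0.98,
                           recomb_high = 0.9,
                           informative_fraction = 0.95) {
  stopifnot(dplyr::n_distinct(markers$chrom) <= 1)
  empty <- tibble(chrom = character(), left_pos1 = integer(),
                  right_pos1 = integer(), n_markers = integer(),
                  members = list())
  if (nrow(markers) == 0) return(empty)
  g <- genotypes[markers$rsid, , drop = FALSE]
  keep <- apply(g, 1, marker_maf) >= maf_min
  markers <- markers[keep, , drop = FALSE]
  g <- g[keep, , drop = FALSE]
  m <- nrow(markers)
  if (m < 2) return(empty)
  ord <- order(markers$pos1)
  markers <- markers[ord, ]
  g <- g[ord, , drop = FALSE]

  strong <- matrix(FALSE, m, m)
  informative <- matrix(FALSE, m, m)
  for (i in seq_len(m - 1)) {
    for (j in seq(i + 1, m)) {
      ld <- dprime_ci(g[i, ], g[j, ])
      if (!ld$ok) next
      s <- ld$cl >= ci_low && ld$cu >= ci_high
      r <- ld$cu < recomb_high
      strong[i, j] <- s
      informative[i, j] <- s || r
    }
  }

  cand <- list()
  for (i in seq_len(m - 1)) {
    for (j in seq(i + 1, m)) {
      if (!strong[i, j]) next
      idx <- i:j
      inf_n <- sum(informative[idx, idx])
      str_n <- sum(strong[idx, idx])
      if (inf_n > 0 && str_n / inf_n >= informative_fraction) {
        cand[[length(cand) + 1L]] <-
          c(i = i, j = j, span = markers$pos1[j] - markers$pos1[i])
      }
    }
  }
  if (length(cand) == 0) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand[, "span"], cand[, "i"]), , drop = FALSE]
  used <- rep(FALSE, m)
  blocks <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, "i"]; j <- cand[r, "j"]
    if (any(used[i:j])) next
    used[i:j] <- TRUE
    blocks[[length(blocks) + 1L]] <- tibble(
      chrom = markers$chrom[1],
      left_pos1 = markers$pos1[i],
      right_pos1 = markers$pos1[j],
      n_markers = j - i + 1L,
      members = list(markers$rsid[i:j])
    )
  }
  dplyr::arrange(dplyr::bind_rows(blocks), .data$left_pos1)
}

#' Link miRNA-related indels to association-study markers through LD blocks
#'
#' For every (indel, GWAS marker) pair on the same chromosome within
#' `window` base pairs, LD blocks are called on the genotype panel's
#' markers for that chromosome; a link is reported when indel and marker
#' fall inside the same block. Indels or markers absent from the panel are
#' skipped with a message.
#'
#' @param indels Tibble `rsid`, `chrom`, `pos1`, `feature` (the miRNA or
#'   target gene the indel affects).
#' @param gwas Tibble `rsid`, `chrom`, `pos`, `p`, `trait`.
#' @param panel List with `markers` and `genotypes` as produced by
#'   [read_genotype_panel()].
#' @param window Maximum indel-marker distance in bp (default 100000).
#' @param ... Block-calling parameters passed to [gabriel_blocks()].
#' @return Tibble, one row per link: indel rsid/location, `feature`, marker
#'   rsid/p/location, block boundaries, `trait`.
#' @export
link_indels <- function(indels, gwas, panel, window = 100000L, ...) {
  empty <- tibble(indel_rsid = character(), indel_chrom = character(),
                  indel_pos1 = integer(), feature = character(),
                  marker_rsid = character(), marker_p = double(),
                  marker_pos1 = integer(), block_left = integer(),
                  block_right = integer(), trait = character())
  in_panel <- indels$rsid %in% panel$markers$rsid
  if (any(!in_panel)) {
    message("link_indels(): skipping ", sum(!in_panel),
            " indel(s) absent from the genotype panel")
    indels <- indels[in_panel, , drop = FALSE]
  }
  gwas_in <- gwas$rsid %in% panel$markers$rsid
  if (any(!gwas_in)) {
    message("link_indels(): skipping ", sum(!gwas_in),
            " GWAS marker(s) absent from the genotype panel")
    gwas <- gwas[gwas_in, , drop = FALSE]
  }
  if (nrow(indels) == 0 || nrow(gwas) == 0) return(empty)
  block_cache <- new.env(parent = emptyenv())
  chrom_blocks <- function(chrom) {
    if (!is.null(block_cache[[chrom]])) return(block_cache[[chrom]])
    mk <- dplyr::filter(panel$markers, .data$chrom == !!chrom)
    b <- gabriel_blocks(mk, panel$genotypes, ...)
    block_cache[[chrom]] <- b
    b
  }
  out <- purrr::map_dfr(seq_len(nrow(indels)), function(i) {
    ind <- indels[i, ]
    near <- dplyr::filter(gwas, .data$chrom == ind$chrom,
                          abs(.data$pos - ind$pos1) <= window)
    if (nrow(near) == 0) return(NULL)
    blocks <- chrom_blocks(ind$chrom)
    if (nrow(blocks) == 0) return(NULL)
    purrr::map_dfr(seq_len(nrow(near)), function(k) {
      mk <- near[k, ]
      hit <- dplyr::filter(blocks,
                           .data$left_pos1 <= ind$pos1,
                           .data$right_pos1 >= ind$pos1,
                           .data$left_pos1 <= mk$pos,
                           .data$right_pos1 >= mk$pos)
      if (nrow(hit) == 0) return(NULL)
      tibble(indel_rsid = ind$rsid, indel_chrom = ind$chrom,
             indel_pos1 = ind$pos1, feature = ind$feature,
             marker_rsid = mk$rsid, marker_p = mk$p,
             marker_pos1 = as.integer(mk$pos),
             block_left = hit$left_pos1[1], block_right = hit$right_pos1[1],
             trait = mk$trait)
    })
  })
  if (nrow(out) == 0) empty else out
}
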