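BASES <- c("A", "C", "G", "T")

# stable per-component sub-seed so each generator stage has its own stream
sub_seed <- function(seed, component) {
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

#' Configuration for the synthetic-data generator
#'
#' Defaults encode the study conditions the generator emulates: ~100-nt
#' pre-miRNAs with one 22-nt mature sequence each, 41-nt footprints inside
#' 3' UTRs, indel densities lower in mature miRNAs and footprints than in
#' flanks, the three indel classes in proportions 0.55/0.14/0.31, a
#' fraction of UTR indels planted to overlap a seed motif with a known
#' expected impact, and a genotype panel with block LD structure.
#'
#' @param rng_seed Integer seed; every generator output is a pure function
#'   of this configuration.
#' @param gc_fraction Genome GC content (i.i.d. bases).
#' @param n_mirnas,pre_length,mature_length miRNA annotation counts/sizes.
#' @param n_utrs,utr_length_range 3' UTR count and length range (nt).
#' @param footprints_per_utr,footprint_length Footprint placement.
#' @param region_density_map Indel densities (variants per nt) per region
#'   class: `flank`, `pre` (precursor outside the mature), `mature`,
#'   `utr3`, `footprint`.
#' @param snv_density_factor SNVs are generated at `factor` times the indel
#'   density of each region.
#' @param indel_class_mix Proportions of the three indel classes (must sum
#'   to 1).
#' @param planted_site_fraction Fraction of UTR indels positioned to
#'   overlap a planted seed-match site with a recorded expected status.
#' @param pairs_per_gene Range of supported miRNA pairs per gene.
#' @param n_pathways Number of pathway groups genes are assigned to.
#' @param panel List of genotype-panel settings: `n_individuals`,
#'   `n_blocks`, `markers_per_block`, `block_span`, `block_gap`,
#'   `founder_freq_range`.
#' @return A `generator_config` list.
#' @export
generator_config <- function(rng_seed = 1L,
                             gc_fraction = 0.5,
                             n_mirnas = 60L,
                             pre_length = 100L,
                             mature_length = 22L,
                             n_utrs = 40L,
                             utr_length_range = c(800L, 1500L),
                             footprints_per_utr = 2L,
                             footprint_length = 41L,
                             region_density_map = c(flank = 0.010,
                                                    pre = 0.008,
                                                    mature = 0.005,
                                                    utr3 = 0.010,
                                                    footprint = 0.004),
                             snv_density_factor = 3,
                             indel_class_mix = c(single_base_pair = 0.55,
                                                 repeat_expansion = 0.14,
                                                 other = 0.31),
                             planted_site_fraction = 0.2,
                             pairs_per_gene = c(1L, 3L),
                             n_pathways = 4L,
                             panel = list(n_individuals = 120L,
                                          n_blocks = 2L,
                                          markers_per_block = 5L,
                                          block_span = 20000L,
                                          block_gap = 60000L,
                                          founder_freq_range = c(0.25, 0.75))) {
  stopifnot(
    abs(sum(indel_class_mix) - 1) < 1e-9,
    all(region_density_map >= 0),
    gc_fraction >= 0, gc_fraction <= 1,
    planted_site_fraction >= 0, planted_site_fraction < 1,
    n_mirnas > 0, n_utrs > 0, pre_length > mature_length
  )
  required <- c("flank", "pre", "mature", "utr3", "footprint")
  if (!all(required %in% names(region_density_map))) {
    stop("region_density_map must name: ", paste(required, collapse = ", "))
  }
  structure(
    list(rng_seed = as.integer(rng_seed), gc_fraction = gc_fraction,
         n_mirnas = as.integer(n_mirnas), pre_length = as.integer(pre_length),
         mature_length = as.integer(mature_length),
         n_utrs = as.integer(n_utrs),
         utr_length_range = as.integer(utr_length_range),
         footprints_per_utr = as.integer(footprints_per_utr),
         footprint_length = as.integer(footprint_length),
         region_density_map = region_density_map,
         snv_density_factor = snv_density_factor,
         indel_class_mix = indel_class_mix,
         planted_site_fraction = planted_site_fraction,
         pairs_per_gene = as.integer(pairs_per_gene),
         n_pathways = as.integer(n_pathways),
         panel = panel),
    class = "generator_config"
  )
}

# genome sized to hold the miRNA territory and the largest possible UTRs
required_genome_length <- function(cfg) {
  cfg$n_mirnas * 6L * cfg$pre_length +
    cfg$n_utrs * (max(cfg$utr_length_range) + 200L) + 1000L
}

#' Generate the synthetic genome
#'
#' @param cfg A [generator_config()].
#' @return Named character vector with one chromosome, `chr1`, of i.i.d.
#'   bases at the configured GC fraction.
#' @export
gen_genome <- function(cfg) {
  set.seed(sub_seed(cfg$rng_seed, "genome"))
  n <- required_genome_length(cfg)
  p <- c((1 - cfg$gc_fraction) / 2, cfg$gc_fraction / 2,
         cfg$gc_fraction / 2, (1 - cfg$gc_fraction) / 2)
  c(chr1 = paste(sample(BASES, n, replace = TRUE, prob = p), collapse = ""))
}

#' Generate miRNA, UTR, footprint, pair and pathway annotations
#'
#' miRNAs occupy evenly spaced slots so that each precursor's four
#' equal-length flanks never collide with a neighbour; 3' UTRs follow in a
#' separate territory with footprints placed inside them.
#'
#' @param cfg A [generator_config()].
#' @param genome Output of [gen_genome()].
#' @return List of tibbles: `mirnas` (`mirna`, `chrom`, `pre_start`,
#'   `pre_end`, `strand`, `mature_start`, `mature_end`, `mature_seq` in RNA
#'   letters), `utrs`, `footprints`, `pairs`, `pathways`.
#' @export
gen_annotations <- function(cfg, genome) {
  set.seed(sub_seed(cfg$rng_seed, "annotations"))
  L <- cfg$pre_length
  ml <- cfg$mature_length
  chromseq <- genome[["chr1"]]

  slot <- 6L * L
  pre_start <- (seq_len(cfg$n_mirnas) - 1L) * slot + 2L * L
  strand <- sample(c("+", "-"), cfg$n_mirnas, replace = TRUE)
  moff <- sample(5:(L - ml - 5L), cfg$n_mirnas, replace = TRUE)
  mirnas <- tibble(
    mirna = sprintf("mir-%03d", seq_len(cfg$n_mirnas)),
    chrom = "chr1",
    pre_start = as.integer(pre_start),
    pre_end = as.integer(pre_start + L),
    strand = strand,
    mature_start = as.integer(pre_start + moff),
    mature_end = as.integer(pre_start + moff + ml)
  )
  mat_dna <- substr(rep(chromseq, cfg$n_mirnas),
                    mirnas$mature_start + 1L, mirnas$mature_end)
  mat_dna[strand == "-"] <- revcomp(mat_dna[strand == "-"])
  mirnas$mature_seq <- chartr("T", "U", mat_dna)

  utr_base <- cfg$n_mirnas * slot
  utr_len <- sample(seq(cfg$utr_length_range[1], cfg$utr_length_range[2]),
                    cfg$n_utrs, replace = TRUE)
  utr_start <- utr_base + cumsum(c(0L, utr_len[-cfg$n_utrs] + 200L))
  utrs <- tibble(
    chrom = "chr1",
    start = as.integer(utr_start),
    end = as.integer(utr_start + utr_len),
    name = sprintf("gene%03d", seq_len(cfg$n_utrs)),
    strand = sample(c("+", "-"), cfg$n_utrs, replace = TRUE)
  )

  fp <- purrr::map_dfr(seq_len(cfg$n_utrs), function(j) {
    len <- utr_len[j]
    k <- cfg$footprints_per_utr
    anchors <- utr_start[j] + round(seq_len(k) * len / (k + 1L))
    tibble(chrom = "chr1",
           start = as.integer(anchors),
           end = as.integer(anchors + cfg$footprint_length),
           name = sprintf("fp_%s_%d", utrs$name[j], seq_len(k)),
           strand = utrs$strand[j],
           gene_id = utrs$name[j])
  })

  pairs <- purrr::map_dfr(seq_len(cfg$n_utrs), function(j) {
    k <- sample(seq(cfg$pairs_per_gene[1], cfg$pairs_per_gene[2]), 1)
    tibble(gene_id = utrs$name[j],
           mirna = sample(mirnas$mirna, k),
           source = "synthetic")
  })

  pw_primary <- sample(seq_len(cfg$n_pathways), cfg$n_utrs, replace = TRUE)
  extra <- sample(c(TRUE, FALSE), cfg$n_utrs, replace = TRUE, prob = c(0.3, 0.7))
  pw_extra <- sample(seq_len(cfg$n_pathways), cfg$n_utrs, replace = TRUE)
  pathways <- dplyr::bind_rows(
    tibble(pw = pw_primary, gene_id = utrs$name),
    tibble(pw = pw_extra[extra], gene_id = utrs$name[extra])
  ) %>%
    dplyr::distinct() %>%
    dplyr::transmute(pathway_id = sprintf("pw%02d", .data$pw),
                     pathway_name = paste("Synthetic pathway", .data$pw),
                     gene_id = .data$gene_id) %>%
    dplyr::arrange(.data$pathway_id, .data$gene_id)

  list(mirnas = mirnas, utrs = utrs, footprints = fp,
       pairs = pairs, pathways = pathways)
}

# placement intervals (disjoint) with density labels for one annotation set
placement_intervals <- function(ann) {
  mir <- purrr::pmap_dfr(
    ann$mirnas[, c("pre_start", "pre_end", "mature_start", "mature_end")],
    function(pre_start, pre_end, mature_start, mature_end) {
      L <- pre_end - pre_start
      tibble(
        label = c("flank", "flank", "flank", "flank", "pre", "pre", "mature"),
        start = c(pre_start - 2L * L, pre_start - L, pre_end, pre_end + L,
                  pre_start, mature_end, mature_start),
        end = c(pre_start - L, pre_start, pre_end + L, pre_end + 2L * L,
                mature_start, pre_end, mature_end),
        gene_id = NA_character_
      )
    })
  utr <- purrr::map_dfr(seq_len(nrow(ann$utrs)), function(j) {
    u <- ann$utrs[j, ]
    fps <- dplyr::arrange(
      dplyr::filter(ann$footprints, .data$gene_id == u$name), .data$start)
    dplyr::bind_rows(
      tibble(label = "utr3",
             start = c(u$start, fps$end),
             end = c(fps$start, u$end),
             gene_id = u$name),
      tibble(label = "footprint", start = fps$start, end = fps$end,
             gene_id = u$name)
    )
  })
  dplyr::filter(dplyr::bind_rows(mir, utr), .data$end > .data$start)
}

# engineer one background indel of a requested class at 0-based anchor p0
construct_indel <- function(chromseq, p0, cls) {
  a <- substr(chromseq, p0 + 1L, p0 + 1L)
  clen <- nchar(chromseq)
  if (cls == "single_base_pair") {
    if (stats::runif(1) < 0.5 || p0 + 2L > clen) {
      list(ref = a, alt = paste0(a, sample(BASES, 1)))
    } else {
      list(ref = paste0(a, substr(chromseq, p0 + 2L, p0 + 2L)), alt = a)
    }
  } else if (cls == "repeat_expansion") {
    ul <- sample(1:2, 1)
    u <- substr(chromseq, p0 + 2L, p0 + 1L + ul)
    if (nchar(u) < ul) {
      ul <- 1L
      u <- substr(chromseq, p0 + 2L, p0 + 2L)
    }
    k <- if (ul == 1L) 2L else sample(1:2, 1)
    list(ref = a, alt = paste0(a, strrep(u, k)))
  } else {
    # "other": a multi-base change that the repeat rule must not capture
    for (try in 1:100) {
      len <- sample(2:5, 1)
      del <- stats::runif(1) < 0.5 && p0 + 1L + len <= clen
      s <- if (del) substr(chromseq, p0 + 2L, p0 + 1L + len) else
        paste(sample(BASES, len, replace = TRUE), collapse = "")
      left <- substr(chromseq, max(1L, p0 - 30L), p0 + 1L)
      rstart <- if (del) p0 + 2L + len else p0 + 2L
      right <- substr(chromseq, rstart, min(clen, rstart + 30L))
      if (!is_repeat_expansion(s, left, right)) {
        return(if (del) list(ref = paste0(a, s), alt = a) else
                 list(ref = a, alt = paste0(a, s)))
      }
    }
    stop("could not engineer an 'other'-class indel at position ", p0)
  }
}

# Base to insert inside a planted motif (after 1-based position off+1 of gm)
# such that the motif match at the site's own offset is destroyed AND the
# insertion cannot regenerate a shifted copy of the motif one base to the
# right (which would offset-map back onto the original site). Returns NA
# when no base works for this cut point.
disrupting_base <- function(gm, off) {
  k <- nchar(gm)
  gm_chars <- strsplit(gm, "")[[1]]
  for (ins in sample(setdiff(BASES, gm_chars[off + 2L]))) {
    mut_site <- paste0(substr(gm, 1L, off + 1L), ins,
                       substr(gm, off + 2L, k))
    if (substr(mut_site, 2L, k + 1L) != gm) return(ins)
  }
  NA_character_
}

#' Generate variants with engineered classes and planted seed-site impacts
#'
#' Background variants are placed by a Poisson draw per region at the
#' configured density, with indel classes drawn from the class mix and
#' sequence contexts engineered to satisfy the classifier's definitions.
#' Within 3' UTRs and footprints, a configured fraction of the drawn indels
#' is planted to overlap a seed-match site of a paired miRNA (the site is
#' written into the genome), with the expected impact status recorded in
#' the truth table; planted indels replace background draws, so region
#' densities are unchanged. Planting edits the reference genome, so the
#' returned `genome` replaces the input downstream.
#'
#' @param cfg A [generator_config()].
#' @param ann Output of [gen_annotations()].
#' @param genome Output of [gen_genome()].
#' @return List: `variants` (VCF-style tibble), `truth` (one row per
#'   variant: region label, class, planted-impact fields), `genome`
#'   (possibly modified by planting).
#' @export
gen_variants <- function(cfg, ann, genome) {
  set.seed(sub_seed(cfg$rng_seed, "variants"))
  chromseq <- genome[["chr1"]]
  clen <- nchar(chromseq)
  dm <- cfg$region_density_map

  iv <- placement_intervals(ann)
  iv$len <- iv$end - iv$start
  iv$dens <- unname(dm[iv$label])
  iv$n_indel <- stats::rpois(nrow(iv), iv$len * iv$dens)
  iv$n_snv <- stats::rpois(nrow(iv), iv$len * iv$dens * cfg$snv_density_factor)
  if (any(iv$n_indel + iv$n_snv > iv$len * 0.8)) {
    stop("configured density too high for region length")
  }

  types <- seed_types()
  motif_cat <- mirna_motifs(ann$mirnas, types)
  blocked <- rep(FALSE, clen)  # 1-based genome positions closed to reuse

  # planted impacts: thin the fraction out of each UTR/footprint draw
  plantable <- which(iv$label %in% c("utr3", "footprint"))
  iv$n_planted <- 0L
  iv$n_planted[plantable] <- stats::rbinom(length(plantable),
                                           iv$n_indel[plantable],
                                           cfg$planted_site_fraction)
  iv$n_indel <- iv$n_indel - iv$n_planted

  planted_rows <- list()
  for (r in which(iv$n_planted > 0L)) {
    gene <- ann$utrs[ann$utrs$name == iv$gene_id[r], ]
    gpairs <- ann$pairs[ann$pairs$gene_id == gene$name, ]
    for (i in seq_len(iv$n_planted[r])) {
      placed <- FALSE
      for (try in 1:100) {
        pr <- gpairs[sample(nrow(gpairs), 1), ]
        st <- types$seed_type[sample(nrow(types), 1)]
        motif <- motif_cat$motif[motif_cat$mirna == pr$mirna &
                                   motif_cat$seed_type == st]
        k <- nchar(motif)
        lo <- iv$start[r] + 1L
        hi <- iv$end[r] - k - 1L
        if (hi <= lo) next
        s0 <- sample(lo:hi, 1)
        if (any(blocked[seq(max(1L, s0 - 11L), s0 + k + 12L)])) next
        gm <- if (gene$strand == "-") revcomp(motif) else motif
        gm_chars <- strsplit(gm, "")[[1]]
        status <- sample(c("disrupted", "created"), 1)
        if (status == "created") {
          cuts <- which(gm_chars[-k] != gm_chars[-1])
          cuts <- cuts[cuts >= 2 & cuts <= k - 1]
          if (length(cuts) == 0) status <- "disrupted"
        }
        if (status == "disrupted") {
          off <- sample(0:(k - 2L), 1)
          ins <- disrupting_base(gm, off)
          if (is.na(ins)) next
          substr(chromseq, s0 + 1L, s0 + k) <- gm
          anchor0 <- s0 + off
          ref <- gm_chars[off + 1L]
          alt <- paste0(ref, ins)
        } else {
          cc <- if (length(cuts) == 1) cuts else sample(cuts, 1)
          broken <- paste0(substr(gm, 1L, cc - 1L), substr(gm, cc + 1L, k))
          substr(chromseq, s0 + 1L, s0 + k - 1L) <- broken
          substr(chromseq, s0 + k, s0 + k) <-
            sample(setdiff(BASES, gm_chars[k]), 1)
          anchor0 <- s0 + cc - 2L
          ref <- gm_chars[cc - 1L]
          alt <- paste0(ref, gm_chars[cc])
        }
        planted_rows[[length(planted_rows) + 1L]] <- tibble(
          chrom = "chr1", pos1 = anchor0 + 1L, ref = ref, alt = alt,
          kind = "insertion", class = "single_base_pair",
          region_label = iv$label[r],
          planted = TRUE, gene_id = gene$name, mirna = pr$mirna,
          seed_type = st, expected_status = status, site_start = s0
        )
        blocked[seq(max(1L, s0 - 11L), s0 + k + 12L)] <- TRUE
        placed <- TRUE
        break
      }
      if (!placed) stop("failed to place a planted site after bounded retries")
    }
  }
  planted_df <- dplyr::bind_rows(planted_rows)

  bg_rows <- purrr::map_dfr(seq_len(nrow(iv)), function(r) {
    n_tot <- iv$n_indel[r] + iv$n_snv[r]
    if (n_tot == 0) return(NULL)
    cand <- seq(iv$start[r], iv$end[r] - 1L)
    cand <- cand[cand + 8L <= clen & cand >= 1L]
    cand <- cand[!blocked[cand + 1L]]
    if (length(cand) < n_tot) stop("density too high for region length")
    pos <- sample(cand, n_tot)
    n_ind <- iv$n_indel[r]
    cls <- if (n_ind > 0) sample(names(cfg$indel_class_mix), n_ind,
                                 replace = TRUE,
                                 prob = cfg$indel_class_mix) else character(0)
    indels <- purrr::map_dfr(seq_len(n_ind), function(m) {
      al <- construct_indel(chromseq, pos[m], cls[m])
      tibble(pos1 = pos[m] + 1L, ref = al$ref, alt = al$alt, class = cls[m])
    })
    n_snv <- iv$n_snv[r]
    snvs <- NULL
    if (n_snv > 0) {
      snv_pos <- pos[n_ind + seq_len(n_snv)]
      snv_ref <- substring(chromseq, snv_pos + 1L, snv_pos + 1L)
      snvs <- tibble(
        pos1 = snv_pos + 1L,
        ref = snv_ref,
        alt = vapply(snv_ref, function(a) sample(setdiff(BASES, a), 1),
                     character(1), USE.NAMES = FALSE),
        class = NA_character_
      )
    }
    dplyr::mutate(dplyr::bind_rows(indels, snvs),
                  chrom = "chr1",
                  kind = variant_kind(.data$ref, .data$alt),
                  region_label = iv$label[r], planted = FALSE,
                  gene_id = NA_character_, mirna = NA_character_,
                  seed_type = NA_character_,
                  expected_status = NA_character_,
                  site_start = NA_integer_)
  })

  truth <- dplyr::bind_rows(planted_df, bg_rows) %>%
    dplyr::arrange(.data$pos1)
  truth$rsid <- sprintf("rs%06d", seq_len(nrow(truth)))
  variants <- dplyr::select(truth, "chrom", "pos1", "rsid", "ref", "alt",
                            "kind")
  truth <- dplyr::select(truth, "rsid", "chrom", "pos1", "ref", "alt",
                         "kind", "class", "region_label", "planted",
                         "gene_id", "mirna", "seed_type", "expected_status",
                         "site_start")
  list(variants = variants, truth = truth,
       genome = c(chr1 = chromseq))
}

#' Generate a genotype panel with block LD structure
#'
#' Each block descends from two complementary founder haplotypes, so every
#' within-block marker pair has |D'| = 1 in expectation, while blocks
#' recombine freely between each other. One mid-block marker is designated
#' a GWAS marker (with a stated p-value and trait) and another the
#' genotyped indel, so block calling and indel-marker linking can be tested
#' against construction truth.
#'
#' @param cfg A [generator_config()].
#' @return List: `markers` (tibble `rsid`, `chrom`, `pos1`), `genotypes`
#'   (dosage matrix), `gwas` (marker table), `truth` (block membership,
#'   designated rsids, founder frequencies).
#' @export
gen_panel <- function(cfg) {
  set.seed(sub_seed(cfg$rng_seed, "panel"))
  p <- cfg$panel
  n <- p$n_individuals
  base <- 10000000L
  rows <- list()
  geno <- list()
  freqs <- numeric(p$n_blocks)
  for (b in seq_len(p$n_blocks)) {
    start_b <- base + (b - 1L) * (p$block_span + p$block_gap)
    pos <- start_b + round(seq(0, p$block_span,
                               length.out = p$markers_per_block))
    f <- stats::runif(1, p$founder_freq_range[1], p$founder_freq_range[2])
    freqs[b] <- f
    g <- stats::rbinom(n, 1, f) + stats::rbinom(n, 1, f)
    rows[[b]] <- tibble(
      rsid = sprintf("rsP%d_%d", b, seq_len(p$markers_per_block)),
      chrom = "chr1", pos1 = as.integer(pos), block = b
    )
    geno[[b]] <- matrix(rep(g, each = p$markers_per_block),
                        nrow = p$markers_per_block)
  }
  markers <- dplyr::bind_rows(rows)
  g <- do.call(rbind, geno)
  mid <- ceiling(p$markers_per_block / 2)
  gwas_rsid <- markers$rsid[mid]                      # block 1, middle
  indel_idx <- if (p$markers_per_block >= 2) 2L else 1L
  markers$rsid[indel_idx] <- "rsIndel1"               # block 1, second marker
  indel_rsid <- "rsIndel1"
  rownames(g) <- markers$rsid
  gwas <- tibble(rsid = gwas_rsid, chrom = "chr1",
                 pos = markers$pos1[markers$rsid == gwas_rsid],
                 p = 6e-8, trait = "synthetic trait")
  truth <- list(
    blocks = split(markers$rsid, markers$block),
    founder_freqs = freqs,
    indel_rsid = indel_rsid,
    gwas_rsid = gwas_rsid
  )
  list(markers = dplyr::select(markers, -"block"), genotypes = g,
       gwas = gwas, truth = truth)
}

#' Generate the full synthetic study
#'
#' Runs all generators under one configuration and (optionally) writes
#' every pipeline input to `dir` in the formats the readers consume, plus a
#' `truth/` directory, a `config.yaml` echo and a `manifest.json` with
#' checksums.
#'
#' @param cfg A [generator_config()].
#' @param dir Optional output directory.
#' @return (Invisibly when writing) a list: `genome`, `mirnas`, `utrs`,
#'   `footprints`, `pairs`, `pathways`, `variants`, `truth`, `panel`,
#'   `gwas`, `panel_truth`, `config`.
#' @export
simulate_study <- function(cfg = generator_config(), dir = NULL) {
  genome <- gen_genome(cfg)
  ann <- gen_annotations(cfg, genome)
  vv <- gen_variants(cfg, ann, genome)
  pan <- gen_panel(cfg)
  res <- list(genome = vv$genome, mirnas = ann$mirnas, utrs = ann$utrs,
              footprints = ann$footprints, pairs = ann$pairs,
              pathways = ann$pathways, variants = vv$variants,
              truth = vv$truth,
              panel = list(markers = pan$markers, genotypes = pan$genotypes),
              gwas = pan$gwas, panel_truth = pan$truth,
              # the panel's designated genotyped indel, attributed to the
              # first miRNA, so the linking stage has a usable candidate
              link_candidates = tibble(
                rsid = pan$truth$indel_rsid,
                chrom = pan$markers$chrom[pan$markers$rsid ==
                                            pan$truth$indel_rsid],
                pos1 = pan$markers$pos1[pan$markers$rsid ==
                                          pan$truth$indel_rsid],
                feature = ann$mirnas$mirna[1]),
              config = cfg)
  if (!is.null(dir)) {
    dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
    write_genome_fasta(res$genome, file.path(dir, "genome.fa"))
    readr::write_tsv(res$mirnas, file.path(dir, "mirnas.tsv"))
    write_bed(res$utrs, file.path(dir, "utr3.bed"))
    write_bed(res$footprints, file.path(dir, "footprints.bed"))
    readr::write_tsv(res$pairs, file.path(dir, "pairs.tsv"))
    readr::write_tsv(res$pathways, file.path(dir, "pathways.tsv"))
    write_vcf_min(res$variants, file.path(dir, "variants.vcf"))
    readr::write_tsv(res$gwas, file.path(dir, "gwas.tsv"))
    write_genotype_panel(res$panel$markers, res$panel$genotypes,
                         file.path(dir, "panel.tsv"))
    readr::write_tsv(res$truth, file.path(dir, "truth", "variants_truth.tsv"))
    readr::write_tsv(
      tibble(block = rep(names(res$panel_truth$blocks),
                         lengths(res$panel_truth$blocks)),
             rsid = unlist(res$panel_truth$blocks, use.names = FALSE)),
      file.path(dir, "truth", "panel_blocks.tsv"))
    yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
    files <- setdiff(list.files(dir, recursive = TRUE), "manifest.json")
    manifest <- list(
      files = lapply(stats::setNames(files, files), function(fp) {
        unname(tools::md5sum(file.path(dir, fp)))
      })
    )
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(res))
  }
  res
}
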