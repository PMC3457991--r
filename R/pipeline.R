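# standard header comment for every output TSV: version + config hash
output_comments <- function(config, semantics) {
  c(paste0("mirindel ", as.character(utils::packageVersion("mirindel")),
           " | config ", rlang::hash(config)),
    semantics)
}

#' Load pipeline inputs from files
#'
#' Reads every input named in a path list (`genome`, `mirnas`, `utrs`,
#' `footprints`, `variants`, `pairs`, `pathways`, `gwas`, `panel`), each in
#' the format its reader expects. Missing names are left NULL so partial
#' pipelines (density only, impact only, ...) can run.
#'
#' @param paths Named list of file paths.
#' @return Named list of parsed inputs.
#' @export
load_inputs <- function(paths) {
  pick <- function(name, reader) {
    if (is.null(paths[[name]])) NULL else reader(paths[[name]])
  }
  list(
    genome = pick("genome", read_genome_fasta),
    mirnas = pick("mirnas", function(p) {
      read_tsv_table(p, c("mirna", "chrom", "pre_start", "pre_end",
                          "strand", "mature_start", "mature_end",
                          "mature_seq"))
    }),
    utrs = pick("utrs", read_bed),
    footprints = pick("footprints", read_bed),
    variants = pick("variants", read_vcf_min),
    pairs = pick("pairs", function(p) read_tsv_table(p, c("gene_id", "mirna"))),
    pathways = pick("pathways", function(p) {
      read_tsv_table(p, c("pathway_id", "pathway_name", "gene_id"))
    }),
    gwas = pick("gwas", function(p) {
      read_tsv_table(p, c("rsid", "chrom", "pos", "p", "trait"))
    }),
    panel = pick("panel", read_genotype_panel)
  )
}

#' Run the synthetic-study generator as a pipeline step
#'
#' @param cfg A [generator_config()].
#' @param out_dir Directory to write the fixture set (with manifest) into.
#' @return The simulated study list, invisibly.
#' @export
run_simulate <- function(cfg = generator_config(), out_dir) {
  simulate_study(cfg, dir = out_dir)
}

#' Density profiling over miRNA and footprint region systems
#'
#' Computes per-unit densities, label summaries and the caption-style
#' comparisons for both variant subsets (all variants; indels only), for
#' the miRNA system and — when footprints and UTRs are available — the
#' footprint system.
#'
#' @param data Input list as from [load_inputs()] or [simulate_study()]
#'   (needs `mirnas`, `variants`; optionally `footprints`, `utrs`).
#' @param out_dir Optional directory for `density_*.tsv` outputs.
#' @param seed_span Seed definition passed to [mirna_regions()].
#' @return List with `summaries` and `comparisons` tibbles (columns
#'   `system` and `subset` identify the panel).
#' @export
run_density <- function(data, out_dir = NULL, seed_span = c(2L, 8L)) {
  if (nrow(data$variants) == 0) stop("no variants: density summaries refused")
  chrom_lengths <- vapply(data$genome, nchar, numeric(1))
  subsets <- list(all = NULL, indels_only = c("insertion", "deletion"))
  systems <- list()
  systems$mirna <- list(
    regions = mirna_regions(data$mirnas, seed_span, chrom_lengths),
    flanks = c("flank2_5p", "flank1_5p", "flank1_3p", "flank2_3p"),
    pairs = list(c("mature", "flank_avg"), c("pre", "flank_avg"),
                 c("seed", "pre"))
  )
  if (!is.null(data$footprints)) {
    systems$footprint <- list(
      regions = dplyr::bind_rows(
        footprint_regions(data$footprints, chrom_lengths),
        if (!is.null(data$utrs)) interval_regions(data$utrs, "utr3")
      ),
      flanks = c("flank2_left", "flank1_left", "flank1_right", "flank2_right"),
      pairs = c(list(c("footprint", "flank_avg")),
                if (!is.null(data$utrs)) list(c("footprint", "utr3")))
    )
  }
  summaries <- list()
  comparisons <- list()
  for (sys in names(systems)) {
    s <- systems[[sys]]
    for (sub in names(subsets)) {
      dens <- region_density(data$variants, s$regions, kinds = subsets[[sub]])
      dens <- add_flank_average(dens, s$flanks)
      summaries[[paste(sys, sub)]] <-
        dplyr::mutate(density_summary(dens), system = sys, subset = sub,
                      .before = 1)
      comparisons[[paste(sys, sub)]] <-
        dplyr::mutate(density_compare(dens, s$pairs), system = sys,
                      subset = sub, .before = 1)
    }
  }
  out <- list(summaries = dplyr::bind_rows(summaries),
              comparisons = dplyr::bind_rows(comparisons))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_commented(
      out$summaries, file.path(out_dir, "density_summary.tsv"),
      output_comments(data$config, c(
        "per-label variant density summary",
        "columns: system, subset, label, n_units, mean_density (variants/nt), sem")))
    write_tsv_commented(
      out$comparisons, file.path(out_dir, "density_comparisons.tsv"),
      output_comments(data$config, c(
        "Welch two-sided t-tests between region labels",
        "columns: system, subset, label_a, label_b, t_stat, df, p_value")))
  }
  out
}

#' Impact scans and pathway summary
#'
#' Runs the footprint scan (every indel in a footprint against the full
#' miRNA catalog) and the pair scan (indels in 3' UTRs of supported pairs
#' against the paired miRNAs only; SNVs scanned the same way for the
#' pathway table's SNP column), then summarizes flagged genes per pathway.
#'
#' @param data Input list (needs `genome`, `variants`, `mirnas`,
#'   `footprints`, `utrs`, `pairs`; optionally `pathways`).
#' @param out_dir Optional directory for the impact/pathway TSVs.
#' @param half_width Scan window flank width (default 50).
#' @param min_genes Pathway reporting threshold (default 10).
#' @param types Seed-type table.
#' @return List: `footprint` and `pairs` impact tables (sorted), `snp_pairs`
#'   (SNV calls), `pathways` summary tibble (NULL without membership data).
#' @export
run_impact <- function(data, out_dir = NULL, half_width = 50L,
                       min_genes = 10L, types = seed_types()) {
  sort_calls <- function(df) {
    dplyr::arrange(df, .data$chrom, .data$pos1, .data$mirna, .data$seed_type)
  }
  fp <- sort_calls(footprint_impact(data$variants, data$footprints,
                                    data$mirnas, data$genome, half_width,
                                    types = types))
  pr <- sort_calls(pair_impact(data$variants, data$utrs, data$pairs,
                               data$mirnas, data$genome, half_width,
                               types = types))
  sn <- sort_calls(pair_impact(data$variants, data$utrs, data$pairs,
                               data$mirnas, data$genome, half_width,
                               kinds = "snv", types = types))
  pw <- NULL
  if (!is.null(data$pathways)) {
    pw <- pathway_table(unique(pr$unit_id), unique(sn$unit_id),
                        data$pathways, min_genes = min_genes)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cols <- paste("columns: rsid, chrom, pos1, ref, alt, mirna, seed_type,",
                  "status, motif, ref_offset, mut_offset, site_start,",
                  "window_truncated, unit_id, provenance")
    write_tsv_commented(fp, file.path(out_dir, "impacts_footprint.tsv"),
                        output_comments(data$config,
                                        c("seed-site impacts in footprints", cols)))
    write_tsv_commented(pr, file.path(out_dir, "impacts_pairs.tsv"),
                        output_comments(data$config,
                                        c("seed-site impacts in supported pairs", cols)))
    if (!is.null(pw)) {
      write_tsv_commented(pw, file.path(out_dir, "pathway_summary.tsv"),
                          output_comments(data$config, c(
                            "pathways by genes with target-site impacts",
                            "percentages = 100 * flagged genes / pathway genes")))
    }
  }
  list(footprint = fp, pairs = pr, snp_pairs = sn, pathways = pw)
}

#' Candidate indels for GWAS linking
#'
#' Indels inside pre-miRNAs (feature = the miRNA) plus indels with a
#' target-site impact call (feature = the impacted gene or footprint).
#'
#' @param variants Variant tibble.
#' @param mirnas miRNA annotation tibble.
#' @param impacts Optional impact table(s) from [run_impact()].
#' @return Tibble `rsid`, `chrom`, `pos1`, `feature`.
#' @export
link_candidates <- function(variants, mirnas, impacts = NULL) {
  v <- dplyr::filter(variants, .data$kind %in% c("insertion", "deletion")) %>%
    dplyr::mutate(anchor0 = .data$pos1 - 1L)
  in_mir <- dplyr::inner_join(
    dplyr::select(mirnas, "mirna", "chrom", "pre_start", "pre_end"), v,
    by = dplyr::join_by("chrom", "pre_start" <= "anchor0",
                        "pre_end" > "anchor0")
  ) %>%
    dplyr::transmute(.data$rsid, .data$chrom, .data$pos1,
                     feature = .data$mirna)
  from_impacts <- NULL
  if (!is.null(impacts) && nrow(impacts) > 0) {
    from_impacts <- dplyr::distinct(
      dplyr::transmute(impacts, .data$rsid, .data$chrom, .data$pos1,
                       feature = .data$unit_id))
  }
  dplyr::distinct(dplyr::bind_rows(in_mir, from_impacts))
}

#' Link candidate indels to GWAS markers through LD blocks
#'
#' @param candidates Tibble `rsid`, `chrom`, `pos1`, `feature` (see
#'   [link_candidates()]); each must be genotyped in the panel to be
#'   usable.
#' @param gwas GWAS marker tibble (`rsid`, `chrom`, `pos`, `p`, `trait`).
#' @param panel Genotype panel list (see [read_genotype_panel()]).
#' @param out_dir Optional directory for `links.tsv`.
#' @param config Configuration echoed into output headers.
#' @param window Indel-marker distance cutoff in bp (default 100000).
#' @param ... Parameters for [gabriel_blocks()].
#' @return Link tibble (see [link_indels()]).
#' @export
run_link <- function(candidates, gwas, panel, out_dir = NULL, config = NULL,
                     window = 100000L, ...) {
  links <- link_indels(candidates, gwas, panel, window = window, ...)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_commented(links, file.path(out_dir, "links.tsv"),
                        output_comments(config, c(
                          "indels linked to association markers via LD blocks",
                          paste("columns: indel rsid/chrom/pos, feature,",
                                "marker rsid/p/pos, block left/right, trait"))))
  }
  links
}

#' Run the full pipeline on one input set
#'
#' @param data Input list from [load_inputs()] or [simulate_study()].
#' @param out_dir Optional output directory for all TSVs.
#' @param ... Passed on to the stage functions.
#' @return List with `density`, `impact` and `links` results.
#' @export
run_all <- function(data, out_dir = NULL, ...) {
  density <- run_density(data, out_dir)
  impact <- run_impact(data, out_dir)
  cand <- link_candidates(data$variants,
                          data$mirnas,
                          dplyr::bind_rows(impact$footprint, impact$pairs))
  if (!is.null(data$link_candidates)) {
    cand <- dplyr::distinct(dplyr::bind_rows(cand, data$link_candidates))
  }
  links <- NULL
  if (!is.null(data$gwas) && !is.null(data$panel)) {
    links <- run_link(cand, data$gwas, data$panel, out_dir,
                      config = data$config)
  }
  list(density = density, impact = impact, links = links)
}
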