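# round half up (Table-style percentage formatting; R's round() is half-even)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Seed-site impacts of variants inside PAR-CLIP footprints
#'
#' Every variant of the requested kinds whose anchor base lies inside a
#' footprint is scanned against the full miRNA catalog; reference-vs-mutant
#' site differences become disrupted/created calls.
#'
#' @param variants Variant tibble (see [read_vcf_min()]).
#' @param footprints Footprint tibble (`chrom`, `start`, `end`, `name`,
#'   optional `strand`).
#' @param mirnas miRNA tibble with `mirna` and `mature_seq`.
#' @param genome Named character vector of chromosome sequences.
#' @param half_width Window flank width passed to the scanner (default 50).
#' @param kinds Variant kinds to consider (default: indels).
#' @param types Seed-type table (default [seed_types()]).
#' @return Impact tibble (one row per call) with `unit_id` (footprint name)
#'   and `provenance = "footprint_scan"`.
#' @export
footprint_impact <- function(variants, footprints, mirnas, genome,
                             half_width = 50L,
                             kinds = c("insertion", "deletion"),
                             types = seed_types()) {
  v <- dplyr::filter(variants, .data$kind %in% kinds) %>%
    dplyr::mutate(anchor0 = .data$pos1 - 1L)
  if (!"strand" %in% names(footprints)) footprints$strand <- "+"
  hits <- dplyr::inner_join(
    dplyr::select(footprints, unit_id = "name", "chrom", "start", "end",
                  fp_strand = "strand"),
    v,
    by = dplyr::join_by("chrom", "start" <= "anchor0", "end" > "anchor0")
  )
  motifs <- mirna_motifs(mirnas, types)
  out <- purrr::map_dfr(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    calls <- variant_impacts(genome, h, motifs, half_width,
                             strand = h$fp_strand)
    if (nrow(calls) == 0) return(NULL)
    dplyr::mutate(calls, unit_id = h$unit_id)
  })
  if (nrow(out) == 0) {
    out <- dplyr::mutate(empty_impact_table(), unit_id = character(0))
  }
  dplyr::mutate(out, provenance = "footprint_scan")
}

#' Seed-site impacts restricted to experimentally supported pairs
#'
#' For each variant inside the 3' UTR of a gene with at least one supported
#' mRNA:miRNA pair, only the motifs of that gene's paired miRNAs are
#' scanned. Pairs naming a gene without a UTR annotation or an unknown
#' miRNA are skipped with a message.
#'
#' @param variants Variant tibble.
#' @param utrs 3' UTR tibble (`chrom`, `start`, `end`, `name` = gene id,
#'   `strand`).
#' @param pairs Pair tibble (`gene_id`, `mirna`, optional `source`).
#' @param mirnas miRNA tibble with `mirna` and `mature_seq`.
#' @inheritParams footprint_impact
#' @return Impact tibble with `unit_id` (gene id) and
#'   `provenance = "pair_scan"`; only (gene, miRNA) combinations present in
#'   `pairs` can appear.
#' @export
pair_impact <- function(variants, utrs, pairs, mirnas, genome,
                        half_width = 50L,
                        kinds = c("insertion", "deletion"),
                        types = seed_types()) {
  known_gene <- pairs$gene_id %in% utrs$name
  known_mir <- pairs$mirna %in% mirnas$mirna
  skip <- !(known_gene & known_mir)
  if (any(skip)) {
    message("pair_impact(): skipping ", sum(skip),
            " pair(s) with unknown gene or miRNA")
    pairs <- pairs[!skip, ]
  }
  v <- dplyr::filter(variants, .data$kind %in% kinds) %>%
    dplyr::mutate(anchor0 = .data$pos1 - 1L)
  hits <- dplyr::inner_join(
    dplyr::select(utrs, gene_id = "name", "chrom", "start", "end",
                  gene_strand = "strand"),
    v,
    by = dplyr::join_by("chrom", "start" <= "anchor0", "end" > "anchor0")
  ) %>%
    dplyr::semi_join(pairs, by = "gene_id")
  motif_catalog <- mirna_motifs(
    dplyr::filter(mirnas, .data$mirna %in% pairs$mirna), types
  )
  out <- purrr::map_dfr(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    paired <- pairs$mirna[pairs$gene_id == h$gene_id]
    motifs <- dplyr::filter(motif_catalog, .data$mirna %in% paired)
    if (nrow(motifs) == 0) return(NULL)
    calls <- variant_impacts(genome, h, motifs, half_width,
                             strand = h$gene_strand)
    if (nrow(calls) == 0) return(NULL)
    dplyr::mutate(calls, unit_id = h$gene_id)
  })
  if (nrow(out) == 0) {
    out <- dplyr::mutate(empty_impact_table(), unit_id = character(0))
  }
  dplyr::mutate(out, provenance = "pair_scan")
}

#' Pathway summary of genes with target-site impacts
#'
#' Counts, per pathway, the member genes flagged by indel impacts and by
#' SNP impacts, with percentages over the pathway's gene count (rounded
#' half-up to 2 decimals). A gene is flagged if at least one impact call
#' touches any of its variants, regardless of call count. Pathways with
#' fewer than `min_genes` indel-flagged genes are dropped; rows are sorted
#' by descending indel gene count.
#'
#' @param indel_genes Character vector of gene ids with >=1 indel impact.
#' @param snp_genes Character vector of gene ids with >=1 SNP impact.
#' @param membership Tibble `pathway_id`, `pathway_name`, `gene_id`.
#' @param min_genes Minimum indel-flagged genes for a pathway to be
#'   reported (default 10).
#' @param hypergeom If `TRUE`, adds a hypergeometric enrichment p-value
#'   column for the indel gene set (a convenience beyond the plain counts;
#'   universe = all genes in `membership`).
#' @return Tibble `pathway_id`, `pathway_name`, `n_pathway_genes`,
#'   `n_genes_with_indel_impacts`, `pct_indel`,
#'   `n_genes_with_snp_impacts`, `pct_snp` (+ `hypergeom_p_indel`).
#' @export
pathway_table <- function(indel_genes, snp_genes, membership,
                          min_genes = 10L, hypergeom = FALSE) {
  if (nrow(membership) == 0) return(membership[0, ])
  out <- membership %>%
    dplyr::distinct(.data$pathway_id, .data$pathway_name, .data$gene_id) %>%
    dplyr::group_by(.data$pathway_id, .data$pathway_name) %>%
    dplyr::summarise(
      n_pathway_genes = dplyr::n(),
      n_genes_with_indel_impacts = sum(.data$gene_id %in% indel_genes),
      n_genes_with_snp_impacts = sum(.data$gene_id %in% snp_genes),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      pct_indel = round_half_up(
        100 * .data$n_genes_with_indel_impacts / .data$n_pathway_genes),
      pct_snp = round_half_up(
        100 * .data$n_genes_with_snp_impacts / .data$n_pathway_genes)
    )
  if (hypergeom) {
    universe <- dplyr::n_distinct(membership$gene_id)
    n_flagged <- sum(unique(membership$gene_id) %in% indel_genes)
    out <- dplyr::mutate(
      out,
      hypergeom_p_indel = stats::phyper(
        .data$n_genes_with_indel_impacts - 1, n_flagged,
        universe - n_flagged, .data$n_pathway_genes, lower.tail = FALSE)
    )
  }
  out %>%
    dplyr::filter(.data$n_genes_with_indel_impacts >= min_genes) %>%
    dplyr::arrange(dplyr::desc(.data$n_genes_with_indel_impacts)) %>%
    dplyr::select(dplyr::all_of(c(
      "pathway_id", "pathway_name", "n_pathway_genes",
      "n_genes_with_indel_impacts", "pct_indel",
      "n_genes_with_snp_impacts", "pct_snp")),
      dplyr::any_of("hypergeom_p_indel"))
}
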