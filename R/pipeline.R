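#' Run the full codon-usage-bias analysis
#'
#' Orchestrates every stage on a strains x genes CDS panel: length
#' filtering, per-gene codon counts, composition and usage indices,
#' selection diagnostics (neutrality regression, ENC-GC3s expectation and
#' ratio, PR2 bias), per-strain correspondence analysis of RSCU, indicator
#' correlations, optimal-codon determination, and RSCU-based hierarchical
#' clustering of strains. Entirely deterministic given its inputs.
#'
#' @param seqs Tibble with columns `strain`, `gene`, `seq` -- from
#'   [read_cds()] (bound over strains) or [simulate_cds()].
#' @param code A [genetic_code()] object.
#' @param min_len Minimum CDS length in nt (default 300).
#' @param gene_whitelist Optional gene-name filter.
#' @param fraction Expression-split fraction (default 0.10).
#' @param delta_threshold,rscu_threshold Optimal-codon cut-offs (defaults
#'   0.08 and 1.0, strict inequalities).
#' @param pr2_mode PR2 denominator: `"fourfold"` (default) or
#'   `"all_synonymous"`.
#' @param metric,linkage Clustering settings (defaults Euclidean, average).
#' @return Object of class `cub_analysis`: a list with tibbles
#'   `sequences`, `gene_indices`, `diagnostics`, `rscu_gene` (per-gene
#'   RSCU), `rscu_strain` (strain-aggregate RSCU), `optimal_codons`
#'   (per-strain classification), `neutrality` (per-strain fit summaries,
#'   with fit objects in `neutrality_fits`), `coa` (named list of per-strain
#'   `cub_coa` objects) with `coa_inertia` (their inertia shares),
#'   `correlations` (per-strain `cub_cormat` list and a bound tibble),
#'   `tree` (a `cub_tree`, `NULL` if fewer than 2 strains),
#'   `strain_summary`, and `config`.
#' @export
run_codon_pipeline <- function(seqs,
                               code = genetic_code(),
                               min_len = 300,
                               gene_whitelist = NULL,
                               fraction = 0.10,
                               delta_threshold = 0.08,
                               rscu_threshold = 1.0,
                               pr2_mode = c("fourfold", "all_synonymous"),
                               metric = "euclidean",
                               linkage = "average") {
  assert_genetic_code(code)
  pr2_mode <- match.arg(pr2_mode)
  stopifnot(fraction > 0, fraction < 0.5,
            delta_threshold > 0, rscu_threshold > 0)

  seqs <- filter_core_genes(seqs, min_len = min_len,
                            gene_whitelist = gene_whitelist)
  counts <- count_codons(seqs, code)
  idx <- gene_indices(seqs, code, fraction = fraction)
  diag <- selection_diagnostics(seqs, code, pr2_mode = pr2_mode)

  rscu_gene <- rscu(counts, code)
  strain_counts <- pool_counts(counts, by = "strain")
  rscu_strain <- rscu(strain_counts, code)

  opt <- optimal_codon_analysis(counts, code, fraction = fraction,
                                delta_threshold = delta_threshold,
                                rscu_threshold = rscu_threshold)

  strains <- unique(seqs$strain)
  neut_fits <- list()
  coa <- list()
  cors <- list()
  indicator_cols <- c("enc", "cai", "cbi", "fop", "gravy", "aromo",
                      "gc1", "gc2", "gc3", "gc12", "gc", "gc3s")
  for (s in strains) {
    sdiag <- diag[diag$strain == s, , drop = FALSE]
    neut_fits[[s]] <- tryCatch(neutrality_fit(sdiag),
                               warning = function(w) {
                                 suppressWarnings(neutrality_fit(sdiag))
                               })
    mat <- rscu_matrix(rscu_gene[rscu_gene$strain == s, , drop = FALSE],
                       rows = "gene", code = code)
    coa[[s]] <- correspondence_analysis(mat)
    cors[[s]] <- indicator_correlations(idx[idx$strain == s, , drop = FALSE],
                                        indicators = indicator_cols)
  }
  neutrality <- purrr::map_dfr(strains, function(s) {
    f <- neut_fits[[s]]
    tibble::tibble(strain = s, slope = f$slope, intercept = f$intercept,
                   r_squared = f$r_squared, p_value = f$p_value,
                   n_points = f$n_points,
                   mutation_dominant = f$mutation_dominant)
  })
  coa_inertia <- purrr::map_dfr(strains, function(s) {
    dplyr::bind_cols(tibble::tibble(strain = s), coa[[s]]$inertia)
  })
  correlations <- purrr::map_dfr(strains, function(s) {
    dplyr::bind_cols(tibble::tibble(strain = s), tibble::as_tibble(cors[[s]]))
  })

  tree <- if (length(strains) >= 2) {
    rscu_cluster(rscu_matrix(rscu_strain, rows = "strain", code = code),
                 metric = metric, linkage = linkage)
  } else {
    NULL
  }

  strain_summary <- idx |>
    dplyr::group_by(.data$strain) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(c(indicator_cols,
                                    "frac_a", "frac_t", "frac_g", "frac_c",
                                    "gc3s", "a3s", "t3s", "g3s", "c3s")),
                    \(v) mean(v, na.rm = TRUE)),
      n_genes = dplyr::n(),
      .groups = "drop"
    )

  structure(
    list(
      sequences = seqs,
      counts = counts,
      gene_indices = idx,
      diagnostics = diag,
      rscu_gene = rscu_gene,
      rscu_strain = rscu_strain,
      optimal_codons = opt,
      neutrality = neutrality,
      neutrality_fits = neut_fits,
      coa = coa,
      coa_inertia = coa_inertia,
      correlations = correlations,
      correlation_objects = cors,
      tree = tree,
      strain_summary = strain_summary,
      config = list(
        code_table = code$table_id, min_len = min_len,
        gene_whitelist = gene_whitelist, fraction = fraction,
        delta_threshold = delta_threshold, rscu_threshold = rscu_threshold,
        pr2_mode = pr2_mode, metric = metric, linkage = linkage
      )
    ),
    class = "cub_analysis"
  )
}

#' @export
print.cub_analysis <- function(x, ...) {
  cat("<cub_analysis>", length(unique(x$sequences$strain)), "strains x",
      length(unique(x$sequences$gene)), "genes\n")
  cat(sprintf("  mean ENC %.2f, mean GC3s %.2f%%, mean ENC ratio %.2f%%\n",
              mean(x$gene_indices$enc, na.rm = TRUE),
              100 * mean(x$gene_indices$gc3s, na.rm = TRUE),
              mean(x$diagnostics$enc_ratio_pct, na.rm = TRUE)))
  n_opt <- x$optimal_codons |>
    dplyr::group_by(.data$strain) |>
    dplyr::summarise(n = sum(.data$optimal), .groups = "drop")
  cat("  optimal codons per strain:",
      paste(sprintf("%s=%d", n_opt$strain, n_opt$n), collapse = ", "), "\n")
  if (!is.null(x$tree)) cat("  strain tree:", x$tree$newick, "\n")
  invisible(x)
}

#' Write the analysis report bundle to disk
#'
#' Emits the tab-separated tables, the Newick strain tree and a JSON
#' manifest (configuration echo plus row counts per output) into a
#' directory. Percentages and indices are written at full precision;
#' re-running the same analysis reproduces the files byte-identically.
#'
#' @param x A `cub_analysis` from [run_codon_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
write_cub_results <- function(x, dir) {
  stopifnot(inherits(x, "cub_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- list(
    gene_indices = x$gene_indices,
    diagnostics = x$diagnostics,
    rscu_gene = x$rscu_gene,
    rscu_strain = x$rscu_strain,
    optimal_codons = x$optimal_codons,
    neutrality = x$neutrality,
    coa_inertia = x$coa_inertia,
    correlations = x$correlations,
    strain_summary = x$strain_summary
  )
  for (nm in names(tables)) {
    readr::write_tsv(tables[[nm]], file.path(dir, paste0(nm, ".tsv")),
                     progress = FALSE)
  }
  coa_rows <- purrr::map_dfr(names(x$coa), function(s) {
    dplyr::bind_cols(tibble::tibble(strain = s), x$coa[[s]]$row_coords)
  })
  coa_cols <- purrr::map_dfr(names(x$coa), function(s) {
    dplyr::bind_cols(tibble::tibble(strain = s), x$coa[[s]]$col_coords)
  })
  readr::write_tsv(coa_rows, file.path(dir, "coa_row_coords.tsv"),
                   progress = FALSE)
  readr::write_tsv(coa_cols, file.path(dir, "coa_col_coords.tsv"),
                   progress = FALSE)
  if (!is.null(x$tree)) {
    writeLines(x$tree$newick, file.path(dir, "strain_tree.nwk"))
  }
  manifest <- list(
    config = x$config,
    n_rows = c(lapply(tables, nrow),
               list(coa_row_coords = nrow(coa_rows),
                    coa_col_coords = nrow(coa_cols)))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
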