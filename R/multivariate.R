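#' Correspondence analysis of an RSCU matrix
#'
#' Standard correspondence analysis applied to a nonnegative genes x codons
#' matrix of RSCU values (the codon-usage convention: RSCU rather than raw
#' counts, so amino-acid composition is factored out before decomposition).
#' The matrix is divided by its grand total, standardized residuals from the
#' independence model are formed, and their singular value decomposition
#' yields principal coordinates for rows (genes) and columns (codons); each
#' axis's share of total inertia is its squared singular value over the sum.
#'
#' Missing RSCU values (unobserved families) should be imputed as 0 before
#' calling; [rscu_matrix()] does this.
#'
#' @param x Numeric matrix (rows = genes/strains, columns = codons) or a
#'   wide data frame whose non-numeric columns are treated as row labels.
#' @param n_axes_report Number of leading axes kept in the coordinate
#'   tibbles (default 4; all axes are retained in `inertia`).
#' @return Object of class `cub_coa`: list with `row_coords` and
#'   `col_coords` tibbles (`label`, `axis1`, `axis2`, ...), `inertia` tibble
#'   (`axis`, `singular_value`, `inertia`, `inertia_pct`), `total_inertia`
#'   and `n_axes`. Supports `tidy()`, `glance()` and [plot_coa()].
#' @export
correspondence_analysis <- function(x, n_axes_report = 4) {
  m <- as_row_labelled_matrix(x)
  if (any(m < 0, na.rm = TRUE)) {
    stop("correspondence analysis needs a nonnegative matrix", call. = FALSE)
  }
  if (nrow(m) < 2) stop("need at least 2 rows", call. = FALSE)
  m[is.na(m)] <- 0
  gt <- sum(m)
  if (gt <= 0) stop("matrix has zero grand total", call. = FALSE)

  p <- m / gt
  r <- rowSums(p)
  cl <- colSums(p)
  if (any(r == 0)) stop("rows with zero total are not allowed", call. = FALSE)
  keep_col <- cl > 0
  p <- p[, keep_col, drop = FALSE]
  cl <- cl[keep_col]

  e <- outer(r, cl)
  s <- (p - e) / sqrt(e)
  sv <- svd(s)
  total <- sum(sv$d^2)

  tol <- max(sv$d) * 1e-10
  nz <- which(sv$d > tol)
  n_axes <- length(nz)
  axes_lab <- paste0("axis", seq_len(n_axes))

  if (n_axes == 0) {
    row_coords <- tibble::tibble(label = rownames(m))
    col_coords <- tibble::tibble(label = colnames(p))
    inertia <- tibble::tibble(axis = integer(0), singular_value = numeric(0),
                              inertia = numeric(0), inertia_pct = numeric(0))
  } else {
    d <- sv$d[nz]
    # principal coordinates: profiles scaled so axis variance = inertia
    rc <- sweep(sv$u[, nz, drop = FALSE] %*% diag(d, n_axes), 1, sqrt(r), "/")
    cc <- sweep(sv$v[, nz, drop = FALSE] %*% diag(d, n_axes), 1, sqrt(cl), "/")
    colnames(rc) <- axes_lab
    colnames(cc) <- axes_lab
    n_keep <- min(n_axes_report, n_axes)
    row_coords <- dplyr::bind_cols(
      tibble::tibble(label = rownames(m)),
      tibble::as_tibble(rc[, seq_len(n_keep), drop = FALSE])
    )
    col_coords <- dplyr::bind_cols(
      tibble::tibble(label = colnames(p)),
      tibble::as_tibble(cc[, seq_len(n_keep), drop = FALSE])
    )
    inertia <- tibble::tibble(
      axis = seq_len(n_axes),
      singular_value = d,
      inertia = d^2,
      inertia_pct = 100 * d^2 / total
    )
  }

  structure(
    list(row_coords = row_coords, col_coords = col_coords,
         inertia = inertia, total_inertia = total, n_axes = n_axes),
    class = "cub_coa"
  )
}

as_row_labelled_matrix <- function(x) {
  if (is.matrix(x)) {
    m <- x
    if (is.null(rownames(m))) rownames(m) <- paste0("row", seq_len(nrow(m)))
    if (is.null(colnames(m))) colnames(m) <- paste0("col", seq_len(ncol(m)))
    return(m)
  }
  num <- vapply(x, is.numeric, logical(1))
  m <- as.matrix(x[, num, drop = FALSE])
  labs <- x[, !num, drop = FALSE]
  rownames(m) <- if (ncol(labs) > 0) {
    do.call(paste, c(as.list(labs), sep = "|"))
  } else {
    paste0("row", seq_len(nrow(m)))
  }
  m
}

#' @export
print.cub_coa <- function(x, ...) {
  cat("<cub_coa> correspondence analysis:",
      nrow(x$row_coords), "rows x", nrow(x$col_coords), "columns,",
      x$n_axes, "axes\n")
  if (x$n_axes > 0) {
    top <- utils::head(x$inertia, 4)
    cat("  inertia share (%):",
        paste(sprintf("axis%d %.2f", top$axis, top$inertia_pct),
              collapse = ", "), "\n")
  }
  cat(sprintf("  total inertia: %.6g\n", x$total_inertia))
  invisible(x)
}

#' Wide RSCU matrix for multivariate analysis
#'
#' Pivots a tidy RSCU table (from [rscu()]) to the wide genes-x-codons (or
#' strains-x-codons) layout used by [correspondence_analysis()] and
#' [rscu_cluster()], restricted to the codons of synonymous families with
#' single-codon amino acids excluded (59 columns under the standard code).
#' Missing RSCU values are imputed as 0 so the codon space stays fixed.
#'
#' @param rscu_tbl Tidy table with `codon`, `rscu` and grouping columns.
#' @param rows Column(s) identifying rows (default whichever of
#'   `strain`/`gene` are present).
#' @param code A [genetic_code()] object.
#' @return Wide tibble: the `rows` columns then one numeric column per
#'   codon.
#' @export
rscu_matrix <- function(rscu_tbl, rows = NULL,
                        code = genetic_code()) {
  assert_genetic_code(code)
  if (is.null(rows)) rows <- intersect(c("strain", "gene"), names(rscu_tbl))
  keep <- synonymous_codons(code)
  wide <- rscu_tbl |>
    dplyr::filter(.data$codon %in% keep) |>
    dplyr::select(dplyr::all_of(rows), "codon", "rscu") |>
    tidyr::pivot_wider(names_from = "codon", values_from = "rscu",
                       values_fill = 0)
  missing_cols <- setdiff(keep, names(wide))
  for (cc in missing_cols) wide[[cc]] <- 0
  wide |>
    dplyr::mutate(dplyr::across(dplyr::all_of(keep),
                                \(v) tidyr::replace_na(v, 0))) |>
    dplyr::select(dplyr::all_of(rows), dplyr::all_of(keep))
}

#' Pairwise Pearson correlations between codon-usage indicators
#'
#' Correlates every pair of indicator columns across genes (pairwise
#' complete observations), attaching two-sided p-values and the
#' conventional significance stars (`*` p < 0.05, `**` p < 0.01). Constant
#' columns yield `NA` correlations.
#'
#' @param index_table Tibble with one row per gene (e.g. [gene_indices()]).
#' @param indicators Character vector of columns to correlate; default all
#'   numeric columns except lengths/counts.
#' @return Object of class `cub_cormat`: a long tibble (`var1`, `var2`,
#'   `r`, `p`, `n`, `stars`) including the unit diagonal, with the full
#'   symmetric grid of pairs.
#' @export
indicator_correlations <- function(index_table, indicators = NULL) {
  if (is.null(indicators)) {
    num <- names(index_table)[vapply(index_table, is.numeric, logical(1))]
    indicators <- setdiff(num, c("length_nt", "n_codons", "n_syn"))
  }
  stopifnot(length(indicators) >= 2, nrow(index_table) >= 3)
  d <- index_table[indicators]
  pairs <- expand.grid(var1 = indicators, var2 = indicators,
                       stringsAsFactors = FALSE)
  res <- purrr::pmap_dfr(pairs, function(var1, var2) {
    x <- d[[var1]]; y <- d[[var2]]
    ok <- stats::complete.cases(x, y)
    n <- sum(ok)
    if (var1 == var2) {
      return(tibble::tibble(var1 = var1, var2 = var2, r = 1, p = 0, n = n))
    }
    ct <- tryCatch(
      suppressWarnings(stats::cor.test(x[ok], y[ok], method = "pearson")),
      error = function(e) NULL
    )
    if (!is.null(ct) && is.na(ct$estimate)) ct <- NULL
    if (is.null(ct) || n < 3) {
      tibble::tibble(var1 = var1, var2 = var2, r = NA_real_, p = NA_real_,
                     n = n)
    } else {
      tibble::tibble(var1 = var1, var2 = var2, r = unname(ct$estimate),
                     p = ct$p.value, n = n)
    }
  })
  res$stars <- dplyr::case_when(
    is.na(res$p) | res$var1 == res$var2 ~ "",
    res$p < 0.01 ~ "**",
    res$p < 0.05 ~ "*",
    TRUE ~ ""
  )
  structure(res, class = c("cub_cormat", class(res)))
}

#' Correlation matrix in square form
#'
#' @param x A `cub_cormat` object from [indicator_correlations()].
#' @param value Which quantity to spread: `"r"`, `"p"` or `"stars"`.
#' @return A matrix with indicator rows/columns.
#' @export
cor_matrix <- function(x, value = c("r", "p", "stars")) {
  value <- match.arg(value)
  vars <- unique(x$var1)
  m <- matrix(if (value == "stars") "" else NA_real_,
              length(vars), length(vars), dimnames = list(vars, vars))
  for (i in seq_len(nrow(x))) m[x$var1[[i]], x$var2[[i]]] <- x[[value]][[i]]
  m
}

#' Hierarchical clustering of strains on RSCU profiles
#'
#' Agglomerative clustering of strains in codon-usage space: each strain is
#' its aggregate RSCU vector over the 59 synonymous sense codons, distances
#' default to Euclidean and linkage to average (UPGMA). The dendrogram is
#' serialised as a Newick tree whose branch lengths derive from merge
#' heights, for direct comparison with sequence-based phylogenies.
#'
#' @param strain_rscu Wide strains x codons tibble (see [rscu_matrix()]) or
#'   a numeric matrix with strain rownames.
#' @param metric Distance metric passed to [stats::dist()] (default
#'   `"euclidean"`).
#' @param linkage Agglomeration method passed to [stats::hclust()] (default
#'   `"average"`).
#' @return Object of class `cub_tree`: list with `phylo` (an [ape]
#'   phylogeny), `newick` (string), `hclust`, `linkage_method`,
#'   `distance_metric`, `labels`.
#' @export
rscu_cluster <- function(strain_rscu, metric = "euclidean",
                         linkage = "average") {
  m <- as_row_labelled_matrix(strain_rscu)
  if (anyDuplicated(rownames(m))) {
    stop("duplicate strain labels: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(m) < 2) stop("need at least 2 strains", call. = FALSE)
  m[is.na(m)] <- 0
  hc <- stats::hclust(stats::dist(m, method = metric), method = linkage)
  phy <- ape::as.phylo(hc)
  structure(
    list(
      phylo = phy,
      newick = ape::write.tree(phy),
      hclust = hc,
      linkage_method = linkage,
      distance_metric = metric,
      labels = rownames(m)
    ),
    class = "cub_tree"
  )
}

#' @export
print.cub_tree <- function(x, ...) {
  cat("<cub_tree>", length(x$labels), "strains,",
      x$distance_metric, "distance,", x$linkage_method, "linkage\n")
  cat(" ", x$newick, "\n")
  invisible(x)
}

#' @export
plot.cub_tree <- function(x, ...) {
  ape::plot.phylo(x$phylo, ...)
  invisible(x)
}
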