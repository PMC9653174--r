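#' Differential expression between a niche region and CT
#'
#' A fully specified, self-contained statistic: per gene, the log2 ratio
#' of region means with a +1 offset, log2(mean(region)+1) -
#' log2(mean(CT)+1), a two-sided tie-corrected Mann-Whitney test across
#' samples, and Benjamini-Hochberg adjustment across genes. A gene is
#' selected when both cutoffs hold: adjusted p below `fdr` and raw p
#' below `p`. The default cutoffs are applied conjunctively as
#' configured.
#'
#' @param table An [expression_table()].
#' @param region Niche to compare against CT ("PPN" or "PNZ").
#' @param cutoffs List with `fdr` (default 0.01) and `p` (default 0.1).
#' @return Data frame: gene, log2fc, p, p_bh, selected; one row per gene.
#' @export
differential_expression <- function(table, region = c("PPN", "PNZ"),
                                    cutoffs = list(fdr = 0.01, p = 0.1)) {
  stopifnot(inherits(table, "expression_table"))
  region <- match.arg(region)
  in_region <- table$region == region
  in_ct <- table$region == "CT"
  if (sum(in_region) < 2 || sum(in_ct) < 2)
    stop("differential_expression: need >= 2 samples in ", region, " and CT")
  genes <- table$genes
  log2fc <- numeric(length(genes))
  p <- numeric(length(genes))
  for (i in seq_along(genes)) {
    xr <- table$expr[i, in_region]
    xc <- table$expr[i, in_ct]
    log2fc[i] <- log2(mean(xr) + 1) - log2(mean(xc) + 1)
    p[i] <- mann_whitney_u(xr, xc)$p_two_sided
  }
  p_bh <- bh_adjust(p)
  data.frame(gene = genes, log2fc = log2fc, p = p, p_bh = p_bh,
             selected = (p_bh < cutoffs$fdr) & (p < cutoffs$p),
             stringsAsFactors = FALSE)
}

#' Top differentially expressed genes
#'
#' The `n` selected genes with the smallest adjusted p (ties broken by
#' raw p, then gene name for determinism).
#'
#' @param deg A [differential_expression()] result.
#' @param n Number of genes (default 40).
#' @return Character vector of gene names.
#' @export
top_degs <- function(deg, n = 40L) {
  sel <- deg[deg$selected, , drop = FALSE]
  sel <- sel[order(sel$p_bh, sel$p, sel$gene), , drop = FALSE]
  utils::head(sel$gene, n)
}

#' Spearman correlation of OATP genes with a gene set
#'
#' Spearman correlation matrix (with BH adjustment) over samples for the
#' union of the OATP genes and the gene set, with rows/columns ordered by
#' average-linkage hierarchical clustering on 1 - rho distance. Genes are
#' sorted alphabetically before clustering so the order is deterministic
#' given the correlation matrix.
#'
#' @param table An [expression_table()].
#' @param oatp_genes Character vector (must be present in the table).
#' @param gene_set Character vector (must be present in the table).
#' @return A `correlation_matrix` with an extra `order` element giving
#'   the clustered display order of the variables.
#' @export
oatp_gene_correlation <- function(table, oatp_genes, gene_set) {
  stopifnot(inherits(table, "expression_table"))
  genes <- union(oatp_genes, gene_set)
  missing <- setdiff(genes, table$genes)
  if (length(missing) > 0)
    stop("oatp_gene_correlation: missing gene(s): ",
         paste(missing, collapse = ", "))
  genes <- sort(genes)
  df <- as.data.frame(t(table$expr[genes, , drop = FALSE]))
  cm <- correlation_matrix(df, genes)
  rho <- cm$rho
  rho[!is.finite(rho)] <- 0
  d <- stats::as.dist(1 - rho)
  cm$order <- if (length(genes) > 2) {
    hc <- stats::hclust(d, method = "average")
    genes[hc$order]
  } else genes
  cm
}

#' Overlap of DEG selections between two niches
#'
#' Splits each region's selected genes by the sign of their log2 fold
#' change and reports shared and region-unique genes, plus shared
#' fractions of the union (computed per direction and overall).
#'
#' @param deg_ppn,deg_pnz [differential_expression()] results computed on
#'   the same table.
#' @return List: `shared_up`, `shared_down`, `unique_ppn`, `unique_pnz`
#'   (character vectors), `shared_up_fraction`, `shared_down_fraction`,
#'   `shared_fraction` (of the union of selected genes).
#' @export
region_overlap <- function(deg_ppn, deg_pnz) {
  up <- function(d) d$gene[d$selected & d$log2fc > 0]
  down <- function(d) d$gene[d$selected & d$log2fc < 0]
  sel <- function(d) d$gene[d$selected]
  shared_up <- intersect(up(deg_ppn), up(deg_pnz))
  shared_down <- intersect(down(deg_ppn), down(deg_pnz))
  union_up <- union(up(deg_ppn), up(deg_pnz))
  union_down <- union(down(deg_ppn), down(deg_pnz))
  union_all <- union(sel(deg_ppn), sel(deg_pnz))
  shared_all <- union(shared_up, shared_down)
  frac <- function(a, b) if (length(b) == 0) NA_real_ else length(a) / length(b)
  list(shared_up = shared_up,
       shared_down = shared_down,
       unique_ppn = setdiff(sel(deg_ppn), sel(deg_pnz)),
       unique_pnz = setdiff(sel(deg_pnz), sel(deg_ppn)),
       shared_up_fraction = frac(shared_up, union_up),
       shared_down_fraction = frac(shared_down, union_down),
       shared_fraction = frac(shared_all, union_all))
}

#' Read an expression table from CSV/TSV plus sample annotation
#'
#' Expression file: genes as rows (first column = gene name), header =
#' sample ids. Annotation file: two columns, sample_id and region.
#'
#' @param expr_path Path to the expression CSV/TSV.
#' @param annot_path Path to the sample-annotation CSV.
#' @param sep Field separator for the expression file ("," or "\t").
#' @return An [expression_table()].
#' @export
read_expression_table <- function(expr_path, annot_path, sep = ",") {
  raw <- utils::read.table(expr_path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  genes <- raw[[1]]
  expr <- as.matrix(raw[, -1, drop = FALSE])
  rownames(expr) <- genes
  annot <- utils::read.csv(annot_path, stringsAsFactors = FALSE)
  if (!all(colnames(expr) %in% annot[[1]]))
    stop("read_expression_table: samples missing from annotation")
  regions <- annot[[2]][match(colnames(expr), annot[[1]])]
  expression_table(expr, regions)
}
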