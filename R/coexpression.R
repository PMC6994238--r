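# Tissue co-expression.  Genes encoding subunits of one complex tend to be
# co-expressed across tissues; a high Pearson r between two candidate genes
# over consensus normalized expression supports a physical or functional
# link.  Excluding named tissues re-runs the analysis without outlier
# tissues (e.g. testis) that can dominate the correlation.

#' Pearson co-expression of gene pairs across tissues
#'
#' For each requested pair, computes the Pearson correlation coefficient
#' over the retained tissue columns and the two-sided p-value from the
#' exact t-transform of r with n - 2 degrees of freedom
#' (via \code{stats::cor.test}).  Values are used untransformed by default;
#' consensus normalized expression is already on a comparable scale.
#'
#' @param matrix genes x tissues expression matrix
#'   (\code{\link{read_expression_matrix}}).
#' @param pairs two-column data frame or matrix of gene label pairs.
#' @param exclude_tissues tissue labels to drop (exact match) before
#'   correlating.
#' @param log1p_transform apply \code{log1p} to expression first (off by
#'   default).
#' @return data frame of class \code{coexpr_table}: \code{gene_a},
#'   \code{gene_b}, \code{n_tissues}, \code{r}, \code{p_value}, in input
#'   pair order; excluded tissues recorded as an attribute.
#' @examples
#' m <- simulate_expression_pairs(data.frame(gene_a = "g1", gene_b = "g2",
#'                                           r = 0.9), seed = 1)
#' correlate_pairs(m$matrix, data.frame(gene_a = "g1", gene_b = "g2"))
#' @export
correlate_pairs <- function(matrix, pairs, exclude_tissues = character(0),
                            log1p_transform = FALSE) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (ncol(pairs) < 2L) stop("pairs must have two columns of gene labels")
  names(pairs)[1:2] <- c("gene_a", "gene_b")
  unknown_genes <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)),
                           rownames(matrix))
  if (length(unknown_genes) > 0L) {
    stop(sprintf("unknown gene label(s): %s",
                 paste(unknown_genes, collapse = ", ")))
  }
  unknown_tissues <- setdiff(exclude_tissues, colnames(matrix))
  if (length(unknown_tissues) > 0L) {
    stop(sprintf("unknown tissue label(s): %s",
                 paste(unknown_tissues, collapse = ", ")))
  }
  keep <- setdiff(colnames(matrix), exclude_tissues)
  if (length(keep) < 3L) {
    stop("fewer than 3 tissues remain after exclusion; r is undefined")
  }
  m <- matrix[, keep, drop = FALSE]
  if (log1p_transform) m <- log1p(m)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    x <- m[pairs$gene_a[i], ]
    y <- m[pairs$gene_b[i], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      stop(sprintf("zero-variance expression vector in pair %s/%s: r undefined",
                   pairs$gene_a[i], pairs$gene_b[i]))
    }
    ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
    data.frame(gene_a = pairs$gene_a[i], gene_b = pairs$gene_b[i],
               n_tissues = length(x), r = unname(ct$estimate),
               p_value = ct$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "excluded_tissues") <- exclude_tissues
  class(out) <- c("coexpr_table", "data.frame")
  out
}

#' @export
print.coexpr_table <- function(x, ...) {
  ex <- attr(x, "excluded_tissues")
  cat(sprintf("co-expression over %s tissues%s\n",
              if (nrow(x) > 0L) x$n_tissues[1L] else "?",
              if (length(ex)) sprintf(" (excluding: %s)", paste(ex, collapse = ", "))
              else ""))
  y <- as.data.frame(x)
  y$r <- round(y$r, 3)
  y$p_value <- signif(y$p_value, 3)
  print(y, row.names = FALSE, ...)
  invisible(x)
}
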