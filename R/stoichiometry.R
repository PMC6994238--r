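# Rough Stoichiometric Peptide Abundance (RSPA): a copy-number proxy for
# axonemal proteins.  RSPA = (AQV / MW) * 10, where AQV is the mean of the
# replicate normalized quantitative values and MW the molecular weight in
# kDa.  Scaling by 10 puts typical doublet proteins on a convenient
# single-digit-to-hundreds scale; it cancels in any between-protein
# comparison.

#' Rough Stoichiometric Peptide Abundance
#'
#' RSPA is the averaged quantitative value of a protein normalized by its
#' molecular weight, times ten: \code{(aqv / mw_kda) * 10}.  Because spectral
#' counting yields signal roughly proportional to copy number times protein
#' size, dividing by molecular weight gives a rough per-copy abundance that
#' can be compared between proteins.
#'
#' @param mw_kda molecular weight in kDa (> 0); vectorized.
#' @param aqv averaged quantitative value (mean over replicates, >= 0).
#' @return unitless RSPA at full precision (round for display only).
#' @examples
#' compute_rspa(27, 29.81)   # ~11.04
#' compute_rspa(15, 16.89)   # ~11.26
#' @export
compute_rspa <- function(mw_kda, aqv) {
  if (any(is.na(mw_kda)) || any(mw_kda <= 0)) {
    stop("mw_kda must be > 0")
  }
  if (any(aqv < 0)) stop("aqv must be non-negative")
  aqv / mw_kda * 10
}

#' Rank proteins by RSPA
#'
#' Computes RSPA for every protein and sorts by descending RSPA; ties are
#' broken by ascending protein id (a stable, documented rule).  Input is
#' either a \code{\link{quant_table}} plus a condition name (AQV is then the
#' arithmetic mean of that condition's replicates) or a data frame with
#' columns \code{protein_id}, \code{mw_kda} and \code{aqv}.
#'
#' @param x a \code{\link{quant_table}} or a data frame (see above).
#' @param condition condition name when \code{x} is a quant_table.
#' @param top_n optionally keep only the first \code{top_n} ranks.
#' @return a data frame of class \code{stoich_table} with columns
#'   \code{protein_id}, \code{mw_kda}, \code{aqv}, \code{rspa}, \code{rank}.
#' @export
rank_by_rspa <- function(x, condition = NULL, top_n = NULL) {
  if (inherits(x, "quant_table")) {
    if (is.null(condition)) stop("'condition' is required for a quant_table")
    if (!condition %in% names(x$values)) {
      stop(sprintf("condition not found: %s", condition))
    }
    df <- data.frame(protein_id = x$ids, mw_kda = x$mw_kda,
                     aqv = rowMeans(x$values[[condition]]),
                     stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(x, stringsAsFactors = FALSE)
    need <- c("protein_id", "mw_kda", "aqv")
    if (!all(need %in% names(df))) {
      stop(sprintf("need columns: %s", paste(need, collapse = ", ")))
    }
    df <- df[, need]
  }
  if (nrow(df) == 0L) {
    out <- cbind(df, rspa = numeric(0), rank = integer(0))
    class(out) <- c("stoich_table", "data.frame")
    return(out)
  }
  df$rspa <- compute_rspa(df$mw_kda, df$aqv)
  ord <- order(-df$rspa, df$protein_id)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  if (!is.null(top_n)) df <- df[seq_len(min(top_n, nrow(df))), , drop = FALSE]
  class(df) <- c("stoich_table", "data.frame")
  df
}

#' @export
print.stoich_table <- function(x, digits = 2, ...) {
  cat(sprintf("RSPA stoichiometry ranking: %d protein(s)\n", nrow(x)))
  y <- as.data.frame(x)
  y$rspa <- round(y$rspa, digits)
  print(y, row.names = FALSE, ...)
  invisible(x)
}

#' @export
summary.stoich_table <- function(object, ...) {
  cat(sprintf("%d proteins; RSPA range %.2f-%.2f (median %.2f)\n",
              nrow(object), min(object$rspa), max(object$rspa),
              stats::median(object$rspa)))
  invisible(object)
}
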