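# Wild-type vs knockout differential classification.  A protein is
# "missing" when no peptide (or, lacking peptide counts, no signal at all)
# is detected in the knockout while it was detected in wild type; otherwise
# fold change on replicate means decides reduced / increased / unchanged.
# The replicate test p-value is reported alongside but never overrides the
# category.

fold_or_inf <- function(num, den) {
  if (den == 0) Inf else num / den
}

welch_p <- function(a, b) {
  # degenerate replicate vectors (zero variance on both sides) have no
  # defined t statistic; report NA rather than fail
  p <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) NA_real_)
  p
}

#' Classify one protein's change between wild type and knockout
#'
#' Categories, evaluated in order:
#' \describe{
#'   \item{missing}{every knockout observation is zero (peptide counts when
#'     available, else quantitative values) while wild type has signal —
#'     "no peptide detected".}
#'   \item{reduced}{\code{mean(wt) / mean(ko) >= reduction_threshold}.}
#'   \item{increased}{\code{mean(ko) / mean(wt) >= reduction_threshold}.}
#'   \item{unchanged}{otherwise.}
#' }
#' A protein with all-zero observations in both conditions is an error
#' (not detected anywhere).  Fold change is \code{mean(wt)/mean(ko)}, with
#' \code{Inf} when the knockout mean is zero — no pseudocount, so "missing"
#' and "reduced" stay disjoint.
#'
#' @param wt,ko non-empty non-negative replicate vectors of quantitative
#'   values.
#' @param wt_peptides,ko_peptides optional exclusive unique peptide counts;
#'   when given, "missing" is keyed on them.
#' @param reduction_threshold fold-change threshold (default 2: "reduced by
#'   at least twofold").
#' @param test replicate test for the reported p-value; default Welch's
#'   two-sided two-sample t.  Any \code{function(wt, ko) -> p} is accepted.
#' @return one-row data frame with \code{wt_mean}, \code{ko_mean},
#'   \code{fold_change}, \code{p_value} and \code{status}.
#' @examples
#' classify_protein(c(59, 73, 105), c(0, 0, 0))$status   # "missing"
#' classify_protein(c(10, 10, 10), c(4, 5, 6))$status    # "reduced"
#' @export
classify_protein <- function(wt, ko, wt_peptides = NULL, ko_peptides = NULL,
                             reduction_threshold = 2.0, test = welch_p) {
  if (length(wt) == 0L || length(ko) == 0L) {
    stop("replicate vectors must be non-empty")
  }
  if (any(wt < 0) || any(ko < 0)) stop("replicate values must be non-negative")
  if (reduction_threshold <= 1) stop("reduction_threshold must be > 1")
  det_wt <- if (!is.null(wt_peptides)) any(wt_peptides > 0) else any(wt > 0)
  det_ko <- if (!is.null(ko_peptides)) any(ko_peptides > 0) else any(ko > 0)
  if (!det_wt && !det_ko && all(wt == 0) && all(ko == 0)) {
    stop("protein not detected in either condition: status undefined")
  }
  wt_mean <- mean(wt)
  ko_mean <- mean(ko)
  fc <- fold_or_inf(wt_mean, ko_mean)
  status <- if (!det_ko && det_wt) {
    "missing"
  } else if (ko_mean > 0 && wt_mean / ko_mean >= reduction_threshold) {
    "reduced"
  } else if (ko_mean == 0 && wt_mean > 0) {
    # detected in KO by peptides but quantitatively zero: still a reduction
    "reduced"
  } else if (wt_mean > 0 && ko_mean / wt_mean >= reduction_threshold) {
    "increased"
  } else if (wt_mean == 0 && ko_mean > 0) {
    "increased"
  } else {
    "unchanged"
  }
  data.frame(
    wt_mean = wt_mean, ko_mean = ko_mean, fold_change = fc,
    p_value = test(wt, ko), status = status, stringsAsFactors = FALSE
  )
}

#' Compare two conditions of a quant table
#'
#' Classifies every protein detected in either condition (proteins with
#' all-zero observations in both are dropped) and tabulates the per-status
#' counts.  Rows are ordered by descending fold change, then id, so
#' completely-missing proteins head the table.
#'
#' @param x a \code{\link{quant_table}} containing both conditions.
#' @param wt,ko condition names for wild type and knockout.
#' @param reduction_threshold see \code{\link{classify_protein}}.
#' @param normalize if TRUE, replicate columns are rescaled to a common
#'   total before classification (total-value scaling).  Off by default:
#'   published tables usually hold values that are already normalized.
#' @param test replicate test passed through to
#'   \code{\link{classify_protein}}.
#' @return a data frame of class \code{diff_table} with one row per protein
#'   and an attribute \code{summary}: named counts per status.
#' @export
compare_conditions <- function(x, wt = "WT", ko = "KO",
                               reduction_threshold = 2.0,
                               normalize = FALSE, test = welch_p) {
  stopifnot(inherits(x, "quant_table"))
  for (cond in c(wt, ko)) {
    if (!cond %in% names(x$values)) {
      stop(sprintf("condition not found: %s", cond))
    }
  }
  vw <- x$values[[wt]]
  vk <- x$values[[ko]]
  if (normalize) {
    scale_cols <- function(m) {
      tot <- colSums(m)
      target <- mean(tot[tot > 0])
      sweep(m, 2, ifelse(tot > 0, tot / target, 1), "/")
    }
    vw <- scale_cols(vw)
    vk <- scale_cols(vk)
  }
  pw <- if (!is.null(x$peptides)) x$peptides[[wt]] else NULL
  pk <- if (!is.null(x$peptides)) x$peptides[[ko]] else NULL
  detected <- vapply(seq_along(x$ids), function(i) {
    any(vw[i, ] > 0) || any(vk[i, ] > 0) ||
      (!is.null(pw) && any(pw[i, ] > 0)) ||
      (!is.null(pk) && any(pk[i, ] > 0))
  }, logical(1))
  idx <- which(detected)
  rows <- lapply(idx, function(i) {
    rec <- classify_protein(vw[i, ], vk[i, ],
                            wt_peptides = if (!is.null(pw)) pw[i, ],
                            ko_peptides = if (!is.null(pk)) pk[i, ],
                            reduction_threshold = reduction_threshold,
                            test = test)
    cbind(data.frame(protein_id = x$ids[i], stringsAsFactors = FALSE), rec)
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(protein_id = character(0), wt_mean = numeric(0),
               ko_mean = numeric(0), fold_change = numeric(0),
               p_value = numeric(0), status = character(0),
               stringsAsFactors = FALSE)
  out <- out[order(-out$fold_change, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  counts <- table(factor(out$status,
                         levels = c("missing", "reduced", "unchanged", "increased")))
  attr(out, "summary") <- setNames(as.integer(counts), names(counts))
  attr(out, "conditions") <- c(wt = wt, ko = ko)
  attr(out, "reduction_threshold") <- reduction_threshold
  class(out) <- c("diff_table", "data.frame")
  out
}

#' @export
print.diff_table <- function(x, ...) {
  s <- attr(x, "summary")
  cond <- attr(x, "conditions")
  cat(sprintf("Differential classification (%s vs %s), %.1f-fold threshold\n",
              cond[["wt"]], cond[["ko"]], attr(x, "reduction_threshold")))
  cat(sprintf("  %s\n", paste(sprintf("%s: %d", names(s), s), collapse = ", ")))
  print(as.data.frame(x), row.names = FALSE, ...)
  invisible(x)
}

#' Per-status counts of a differential table
#'
#' @param x a \code{diff_table} from \code{\link{compare_conditions}}.
#' @return named integer vector (missing, reduced, unchanged, increased).
#' @export
status_counts <- function(x) {
  stopifnot(inherits(x, "diff_table"))
  attr(x, "summary")
}
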