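# Multi-criteria candidate screening.  An unassigned density constrains the
# protein behind it: its repeat spacing fixes the stoichiometry, the trace
# fixes an approximate size, presence of the density in several species
# demands conservation (or its absence in one species demands a
# species-specific protein), and proteins already placed elsewhere in the
# axoneme cannot be the answer.  Each constraint becomes an explicit flag;
# the shortlist is the set passing all active flags, ordered by
# stoichiometry rank.

#' Build a screen criteria set
#'
#' Every threshold of the candidate screen is explicit here; unset criteria
#' are inactive.  Flags are evaluated in a fixed documented order
#' (stoichiometry rank, molecular weight window, conservation, homolog size,
#' localization/blacklist, knockout status); the order only determines which
#' failure is recorded as the exclusion reason, never membership.
#'
#' @param top_n keep proteins within the first \code{top_n} RSPA ranks
#'   ("high stoichiometry"); default 35.
#' @param mw_min,mw_max inclusive molecular-weight window in kDa.
#' @param conservation_required_in species names in which a homolog must be
#'   present.
#' @param conservation_absent_in species names in which a homolog must be
#'   absent (the \code{"-"} marker), for species-specific screens.
#' @param homolog_size_max_ratio reject candidates whose homolog (in any
#'   required species with a known size) exceeds this ratio of the
#'   candidate's own molecular weight — a homolog "too big" to fit the same
#'   density.  NULL disables the check; 2.0 is a sensible default when
#'   enabled.
#' @param excluded_localizations localization labels excluded from
#'   candidacy (e.g. "Radial Spoke", "Central Pair", "Dynein",
#'   "Cytoplasmic").
#' @param blacklist protein ids already assigned to known densities.
#' @param required_diff_status optionally require a knockout differential
#'   status ("missing" or "reduced").
#' @return an object of class \code{screen_criteria}.
#' @export
screen_criteria <- function(top_n = 35L, mw_min = -Inf, mw_max = Inf,
                            conservation_required_in = character(0),
                            conservation_absent_in = character(0),
                            homolog_size_max_ratio = NULL,
                            excluded_localizations = character(0),
                            blacklist = character(0),
                            required_diff_status = NULL) {
  if (top_n < 1L) stop("top_n must be >= 1")
  if (mw_min > mw_max) stop("mw_min must be <= mw_max")
  if (!is.null(required_diff_status) &&
      !required_diff_status %in% c("missing", "reduced")) {
    stop("required_diff_status must be 'missing' or 'reduced'")
  }
  structure(
    list(top_n = as.integer(top_n), mw_min = mw_min, mw_max = mw_max,
         conservation_required_in = conservation_required_in,
         conservation_absent_in = conservation_absent_in,
         homolog_size_max_ratio = homolog_size_max_ratio,
         excluded_localizations = excluded_localizations,
         blacklist = blacklist,
         required_diff_status = required_diff_status),
    class = "screen_criteria"
  )
}

#' @export
print.screen_criteria <- function(x, ...) {
  cat("screen_criteria:\n")
  cat(sprintf("  top_n: %d; MW window: [%s, %s] kDa\n", x$top_n,
              format(x$mw_min), format(x$mw_max)))
  if (length(x$conservation_required_in))
    cat("  homolog required in:", paste(x$conservation_required_in, collapse = ", "), "\n")
  if (length(x$conservation_absent_in))
    cat("  homolog absent in:", paste(x$conservation_absent_in, collapse = ", "), "\n")
  if (!is.null(x$homolog_size_max_ratio))
    cat(sprintf("  homolog size max ratio: %.2f\n", x$homolog_size_max_ratio))
  if (length(x$excluded_localizations))
    cat("  excluded localizations:", paste(x$excluded_localizations, collapse = ", "), "\n")
  if (length(x$blacklist))
    cat(sprintf("  blacklist: %d protein(s)\n", length(x$blacklist)))
  if (!is.null(x$required_diff_status))
    cat("  required knockout status:", x$required_diff_status, "\n")
  invisible(x)
}

homolog_lookup <- function(homologs, pid, species) {
  i <- which(homologs$protein_id == pid & homologs$species == species)
  if (length(i) == 0L) return(NULL)
  homologs[i[1L], , drop = FALSE]
}

#' Apply screen criteria to a stoichiometry ranking
#'
#' @param stoich a \code{\link{rank_by_rspa}} table covering the candidate
#'   universe.
#' @param criteria a \code{\link{screen_criteria}} set.
#' @param annotations data frame with \code{protein_id} and
#'   \code{localization}; required when localization exclusion is active.
#' @param homologs a \code{\link{read_homolog_map}}-style data frame;
#'   required when a conservation or homolog-size criterion is active.
#' @param diff a \code{\link{compare_conditions}} table; required when
#'   \code{required_diff_status} is set.
#' @return a data frame of class \code{candidate_report}: one row per
#'   protein with its rank, per-criterion logical flags, \code{verdict}
#'   ("shortlisted" or "excluded") and the first failing criterion as
#'   \code{reason}; attribute \code{shortlist} holds the shortlisted ids in
#'   rank order.
#' @export
apply_criteria <- function(stoich, criteria, annotations = NULL,
                           homologs = NULL, diff = NULL) {
  stopifnot(inherits(stoich, "stoich_table"), inherits(criteria, "screen_criteria"))
  needs_cons <- length(criteria$conservation_required_in) > 0L ||
    length(criteria$conservation_absent_in) > 0L
  missing_ann <- character(0)
  if (length(criteria$excluded_localizations) > 0L && is.null(annotations))
    missing_ann <- c(missing_ann, "localization annotations")
  if ((needs_cons || !is.null(criteria$homolog_size_max_ratio)) && is.null(homologs))
    missing_ann <- c(missing_ann, "homolog map")
  if (!is.null(criteria$required_diff_status) && is.null(diff))
    missing_ann <- c(missing_ann, "differential table")
  if (length(missing_ann) > 0L) {
    stop(sprintf("criteria reference unannotated fields; missing: %s",
                 paste(missing_ann, collapse = ", ")))
  }
  n <- nrow(stoich)
  if (n == 0L) {
    out <- data.frame(protein_id = character(0), rank = integer(0),
                      mw_kda = numeric(0), verdict = character(0),
                      reason = character(0), stringsAsFactors = FALSE)
    attr(out, "shortlist") <- character(0)
    class(out) <- c("candidate_report", "data.frame")
    return(out)
  }

  flag <- list()
  flag$stoichiometry <- stoich$rank <= criteria$top_n
  flag$mw_window <- stoich$mw_kda >= criteria$mw_min &
    stoich$mw_kda <= criteria$mw_max

  if (needs_cons) {
    flag$conservation <- vapply(seq_len(n), function(i) {
      pid <- stoich$protein_id[i]
      for (sp in criteria$conservation_required_in) {
        h <- homolog_lookup(homologs, pid, sp)
        if (is.null(h)) {
          stop(sprintf("no homolog annotation for protein '%s' in species '%s'",
                       pid, sp))
        }
        if (h$homolog_id == "-") return(FALSE)
      }
      for (sp in criteria$conservation_absent_in) {
        h <- homolog_lookup(homologs, pid, sp)
        if (is.null(h)) {
          stop(sprintf("no homolog annotation for protein '%s' in species '%s'",
                       pid, sp))
        }
        if (h$homolog_id != "-") return(FALSE)
      }
      TRUE
    }, logical(1))
  }

  if (!is.null(criteria$homolog_size_max_ratio)) {
    species_checked <- if (length(criteria$conservation_required_in) > 0L)
      criteria$conservation_required_in else unique(homologs$species)
    flag$homolog_size <- vapply(seq_len(n), function(i) {
      pid <- stoich$protein_id[i]
      for (sp in species_checked) {
        h <- homolog_lookup(homologs, pid, sp)
        if (is.null(h) || h$homolog_id == "-" || is.na(h$homolog_mw_kda)) next
        if (h$homolog_mw_kda / stoich$mw_kda[i] > criteria$homolog_size_max_ratio)
          return(FALSE)
      }
      TRUE
    }, logical(1))
  }

  if (length(criteria$excluded_localizations) > 0L ||
      length(criteria$blacklist) > 0L) {
    loc <- if (!is.null(annotations)) {
      annotations$localization[match(stoich$protein_id, annotations$protein_id)]
    } else {
      rep(NA_character_, n)
    }
    # an unknown localization is not grounds for exclusion
    flag$localization <- !(loc %in% criteria$excluded_localizations) &
      !(stoich$protein_id %in% criteria$blacklist)
  }

  if (!is.null(criteria$required_diff_status)) {
    st <- diff$status[match(stoich$protein_id, diff$protein_id)]
    flag$diff_status <- !is.na(st) & st == criteria$required_diff_status
  }

  fm <- do.call(cbind, flag)
  pass <- rowSums(!fm) == 0L
  reason <- apply(fm, 1L, function(r) {
    f <- which(!r)
    if (length(f) == 0L) NA_character_ else colnames(fm)[f[1L]]
  })
  out <- data.frame(
    protein_id = stoich$protein_id, rank = stoich$rank,
    mw_kda = stoich$mw_kda, stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(fm))
  out$verdict <- ifelse(pass, "shortlisted", "excluded")
  out$reason <- reason
  rownames(out) <- NULL
  attr(out, "shortlist") <- out$protein_id[pass][order(out$rank[pass])]
  attr(out, "criteria") <- criteria
  class(out) <- c("candidate_report", "data.frame")
  out
}

#' Shortlisted ids of a candidate report, in stoichiometry-rank order
#'
#' @param x a \code{candidate_report}.
#' @return character vector of protein ids.
#' @export
shortlist <- function(x) {
  stopifnot(inherits(x, "candidate_report"))
  attr(x, "shortlist")
}

#' @export
print.candidate_report <- function(x, ...) {
  sl <- attr(x, "shortlist")
  cat(sprintf("candidate_report: %d screened, %d shortlisted\n", nrow(x),
              length(sl)))
  if (length(sl) > 0L) cat("  shortlist:", paste(sl, collapse = ", "), "\n")
  excl <- x[x$verdict == "excluded", c("protein_id", "reason")]
  if (nrow(excl) > 0L) {
    tab <- table(excl$reason)
    cat("  exclusions:", paste(sprintf("%s (%d)", names(tab), tab),
                               collapse = ", "), "\n")
  }
  invisible(x)
}

#' Match a density trace to knockout-supported candidates by size
#'
#' A segmented density traced to an approximate residue count and mass
#' constrains its protein to "approximately this size"; intersecting the
#' size window with proteins carrying the required knockout status (default:
#' completely missing) typically reduces the candidates to one.
#'
#' @param trace_length_aa estimated residue count of the trace (used to
#'   filter on sequence length when \code{lengths} is supplied).
#' @param trace_mw_kda estimated mass of the trace in kDa.
#' @param candidates a \code{\link{quant_table}} or data frame with
#'   \code{protein_id} and \code{mw_kda}.
#' @param diff optional \code{\link{compare_conditions}} table supplying
#'   knockout statuses.
#' @param tolerance relative size window: a candidate is kept when its MW is
#'   within \code{tolerance * trace_mw_kda} of the trace mass (and, when
#'   lengths are known, its length within the same fraction of
#'   \code{trace_length_aa}).  Default 0.15.
#' @param required_status knockout status required of candidates when
#'   \code{diff} is given; default "missing".
#' @param lengths optional named vector of sequence lengths per protein id.
#' @return data frame of candidates sorted by \code{|mw - trace_mw|} (ties
#'   by id), with columns \code{protein_id}, \code{mw_kda}, \code{mw_delta},
#'   and \code{status} when \code{diff} was given.  Possibly empty.
#' @export
identify_from_trace <- function(trace_length_aa, trace_mw_kda, candidates,
                                diff = NULL, tolerance = 0.15,
                                required_status = "missing",
                                lengths = NULL) {
  if (tolerance <= 0 || tolerance > 1) stop("tolerance must be in (0, 1]")
  if (inherits(candidates, "quant_table")) {
    cand <- data.frame(protein_id = candidates$ids,
                       mw_kda = candidates$mw_kda, stringsAsFactors = FALSE)
  } else {
    cand <- as.data.frame(candidates, stringsAsFactors = FALSE)
    stopifnot(all(c("protein_id", "mw_kda") %in% names(cand)))
  }
  keep <- abs(cand$mw_kda - trace_mw_kda) <= tolerance * trace_mw_kda
  if (!is.null(lengths)) {
    len <- lengths[cand$protein_id]
    keep <- keep & !is.na(len) &
      abs(len - trace_length_aa) <= tolerance * trace_length_aa
  }
  cand <- cand[keep, , drop = FALSE]
  if (!is.null(diff)) {
    cand$status <- diff$status[match(cand$protein_id, diff$protein_id)]
    cand <- cand[!is.na(cand$status) & cand$status == required_status, ,
                 drop = FALSE]
  }
  cand$mw_delta <- abs(cand$mw_kda - trace_mw_kda)
  cand <- cand[order(cand$mw_delta, cand$protein_id), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}
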