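# Bundled reference datasets: the published top-35 stoichiometry table of
# salt-stable Chlamydomonas doublet proteins (wild-type label-free MS, with
# cross-species homolog ids and localization calls) and the published list
# of proteins completely missing from FAP52-knockout axonemes.  These are
# small curated tables, used as worked examples and regression anchors.

ref_path <- function(file) {
  p <- system.file("extdata", file, package = "mipscreen")
  if (!nzchar(p)) stop(sprintf("bundled data file not found: %s", file))
  p
}

#' Reference doublet stoichiometry table (top 35 proteins)
#'
#' The 35 most abundant salt-stable axonemal proteins of wild-type
#' \emph{Chlamydomonas} doublet microtubules by RSPA, with printed molecular
#' weight (kDa), averaged quantitative value, the RSPA value as printed
#' (2 decimals), \emph{T. thermophila} and human homolog ids (\code{"-"} =
#' no homolog) and the localization call.  Recomputing RSPA from the
#' \code{mw_kda} and \code{aqv} columns reproduces the printed values to
#' within 0.01 (the printed columns are themselves rounded).
#'
#' @return data frame with 35 rows.
#' @export
doublet_stoich_ref <- function() {
  read.delim(ref_path("doublet_stoich_ref.tsv"), stringsAsFactors = FALSE)
}

#' Homolog map derived from the reference stoichiometry table
#'
#' Long format (\code{protein_id}, \code{species}, \code{homolog_id},
#' \code{homolog_mw_kda}) for the two annotated species.  Homolog molecular
#' weights are unknown in the reference table and reported as NA; see
#' \code{\link{tt_homolog_mw_synthetic}} for a synthetic size table.
#'
#' @return data frame in \code{\link{read_homolog_map}} layout.
#' @export
doublet_homolog_map <- function() {
  ref <- doublet_stoich_ref()
  rbind(
    data.frame(protein_id = ref$protein_id, species = "T. thermophila",
               homolog_id = ref$homolog_t_thermophila,
               homolog_mw_kda = NA_real_, stringsAsFactors = FALSE),
    data.frame(protein_id = ref$protein_id, species = "Human",
               homolog_id = ref$homolog_human,
               homolog_mw_kda = NA_real_, stringsAsFactors = FALSE)
  )
}

#' Synthetic homolog molecular weights for the T. thermophila homologs
#'
#' The reference table names \emph{T. thermophila} homologs but not their
#' sizes.  This synthetic stand-in table assigns plausible molecular
#' weights encoding the qualitative size relations used in screening (the
#' FAP115 and FAP161 homologs are much larger than the query proteins; the
#' rest are near-sized).  It exists to exercise the homolog-size criterion
#' and is \emph{not} measured data.
#'
#' @return data frame in \code{\link{read_homolog_map}} layout.
#' @export
tt_homolog_mw_synthetic <- function() {
  read_homolog_map(ref_path("tt_homolog_mw_synthetic.tsv"))
}

#' Reference FAP52-knockout "completely missing" table
#'
#' The twelve axonemal proteins with no peptide detected in FAP52-knockout
#' \emph{Chlamydomonas} axonemes: molecular weight, the printed replicate
#' test p-value, and the printed wild-type field "peptide counts
#' (normalized quantitative values)".  \code{as_quant_table = TRUE} expands
#' the printed fields into a \code{\link{quant_table}} with triplicate WT
#' values and peptide counts and an all-zero KO condition (the table's
#' defining property).
#'
#' @param as_quant_table return a \code{\link{quant_table}} instead of the
#'   raw data frame.
#' @return data frame (12 rows) or \code{\link{quant_table}}.
#' @export
fap52ko_missing_ref <- function(as_quant_table = FALSE) {
  df <- read.delim(ref_path("fap52ko_missing_ref.tsv"),
                   stringsAsFactors = FALSE)
  if (!as_quant_table) return(df)
  parsed <- parse_counts_field(df$wt_counts)
  wt_vals <- do.call(rbind, parsed$values)
  wt_peps <- do.call(rbind, parsed$peptides)
  zeros <- matrix(0, nrow = nrow(df), ncol = ncol(wt_vals))
  quant_table(
    df$protein_id, df$mw_kda,
    values = list(WT = wt_vals, KO = zeros),
    peptides = list(WT = wt_peps, KO = zeros)
  )
}
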