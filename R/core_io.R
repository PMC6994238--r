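# Data model and readers/writers. Everything downstream consumes the
# `proteome` and `quant_table` containers built here, never raw files.

# Average residue masses in Da (monomer minus water); X is a generic
# unknown-residue placeholder at 110 Da.
AA_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326,
  X = 110.0000
)
WATER_MASS <- 18.01528

#' Molecular weight of a protein sequence in kilodaltons
#'
#' Uses average (not monoisotopic) residue masses plus one water, matching
#' the kDa scale on which label-free proteomics tables report molecular
#' weight.  The letter \code{X} counts as a generic residue of 110 Da.
#'
#' @param sequence character vector of amino-acid sequences (20 standard
#'   one-letter codes plus \code{X}; case-insensitive).
#' @return numeric vector of molecular weights in kDa.
#' @examples
#' mw_from_sequence("MKWVTFISLLLLFSSAYS")
#' @export
mw_from_sequence <- function(sequence) {
  vapply(sequence, function(s) {
    s <- toupper(s)
    if (nchar(s) == 0L) {
      stop("cannot compute molecular weight of a 0-residue sequence")
    }
    aa <- strsplit(s, "")[[1]]
    bad <- which(!aa %in% names(AA_RESIDUE_MASS))
    if (length(bad) > 0L) {
      stop(sprintf("non-amino-acid character '%s' at position %d",
                   aa[bad[1L]], bad[1L]))
    }
    (sum(AA_RESIDUE_MASS[aa]) + WATER_MASS) / 1000
  }, numeric(1), USE.NAMES = FALSE)
}

validate_sequences <- function(ids, sequences) {
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop(sprintf("duplicate protein id '%s'", dup[1L]))
  }
  for (i in seq_along(sequences)) {
    s <- toupper(sequences[i])
    m <- regexpr("[^ACDEFGHIKLMNPQRSTVWYX]", s)
    if (m > 0L) {
      stop(sprintf("protein '%s': non-amino-acid character '%s' at position %d",
                   ids[i], substr(s, m, m), m))
    }
  }
  invisible(TRUE)
}

#' Construct a proteome table
#'
#' A proteome is a data frame with one row per protein: \code{id},
#' \code{description}, \code{sequence}, \code{length}, \code{mw_kda} and an
#' optional \code{localization} label.  Molecular weight is computed from the
#' sequence unless supplied (a value from a curated table overrides the
#' sequence-derived one, since downstream stoichiometry arithmetic should use
#' the reported weight).
#'
#' @param id character vector of unique accessions.
#' @param sequence character vector of amino-acid sequences.
#' @param description optional free-text descriptions.
#' @param mw_kda optional molecular weights in kDa overriding the computed
#'   values (NA entries fall back to the computed weight).
#' @param localization optional category labels (e.g. "Radial Spoke", "MIP").
#' @return a data frame of class \code{proteome}.
#' @export
proteome <- function(id, sequence, description = "", mw_kda = NULL,
                     localization = NA_character_) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  validate_sequences(id, sequence)
  computed <- mw_from_sequence(sequence)
  if (is.null(mw_kda)) {
    mw <- computed
  } else {
    mw <- ifelse(is.na(mw_kda), computed, mw_kda)
  }
  if (any(mw <= 0)) stop("mw_kda must be > 0")
  out <- data.frame(
    id = id,
    description = rep_len(as.character(description), length(id)),
    sequence = sequence,
    length = nchar(sequence),
    mw_kda = mw,
    localization = rep_len(as.character(localization), length(id)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("proteome", "data.frame")
  out
}

#' Read a proteome from a FASTA file
#'
#' @param path FASTA file (line-wrapped sequences allowed).
#' @param mw_table optional data frame with columns \code{id} and
#'   \code{mw_kda}; matching entries override sequence-derived weights.
#' @return a \code{\link{proteome}} data frame, record order preserved.
#' @export
read_proteome <- function(path, mw_table = NULL) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) {
    return(proteome(character(0), character(0)))
  }
  header <- names(aa)
  id <- sub("\\s.*$", "", header)
  desc <- ifelse(grepl("\\s", header), sub("^\\S+\\s+", "", header), "")
  seqs <- as.character(aa)
  mw <- NULL
  if (!is.null(mw_table)) {
    mw <- mw_table$mw_kda[match(id, mw_table$id)]
  }
  proteome(id, seqs, description = desc, mw_kda = mw)
}

#' Write a proteome to a FASTA file
#'
#' @param x a \code{\link{proteome}}.
#' @param path output path.
#' @param width line-wrap width.
#' @return \code{path}, invisibly.
#' @export
write_proteome <- function(x, path, width = 60L) {
  aa <- Biostrings::AAStringSet(setNames(x$sequence, ifelse(
    nzchar(x$description), paste(x$id, x$description), x$id)))
  Biostrings::writeXStringSet(aa, path, width = width)
  invisible(path)
}

#' Construct a quantitative proteomics table
#'
#' Container for per-protein replicate quantitative values across named
#' conditions, with optional exclusive unique peptide counts.  All replicate
#' matrices share row order with \code{ids}; every condition must have at
#' least one replicate and the same replicate count for every protein.
#'
#' @param ids character vector of protein ids (unique).
#' @param mw_kda numeric vector of molecular weights in kDa (> 0).
#' @param values named list of numeric matrices (proteins x replicates),
#'   one per condition; all values must be non-negative.
#' @param peptides optional named list of integer matrices of exclusive
#'   unique peptide counts, same shapes as \code{values}.
#' @return an object of class \code{quant_table}.
#' @export
quant_table <- function(ids, mw_kda, values, peptides = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate protein id '%s'", ids[duplicated(ids)][1L]))
  }
  if (any(mw_kda <= 0)) stop("mw_kda must be > 0 for all proteins")
  if (!is.list(values) || is.null(names(values)) || any(!nzchar(names(values)))) {
    stop("'values' must be a named list of condition matrices")
  }
  values <- lapply(values, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    dimnames(m) <- NULL
    m
  })
  for (cond in names(values)) {
    m <- values[[cond]]
    if (nrow(m) != length(ids)) {
      stop(sprintf("condition '%s': %d rows but %d protein ids",
                   cond, nrow(m), length(ids)))
    }
    if (ncol(m) < 1L) stop(sprintf("condition '%s' has no replicates", cond))
    if (anyNA(m)) stop(sprintf("condition '%s' contains missing values", cond))
    if (any(m < 0)) stop(sprintf("condition '%s' contains negative values", cond))
  }
  if (!is.null(peptides)) {
    peptides <- lapply(peptides, function(m) {
      m <- as.matrix(m)
      storage.mode(m) <- "double"
      dimnames(m) <- NULL
      m
    })
    for (cond in names(peptides)) {
      if (!cond %in% names(values)) {
        stop(sprintf("peptide counts for unknown condition '%s'", cond))
      }
      if (!identical(dim(peptides[[cond]]), dim(values[[cond]]))) {
        stop(sprintf("peptide matrix shape mismatch for condition '%s'", cond))
      }
      if (any(peptides[[cond]] < 0)) {
        stop(sprintf("condition '%s' contains negative peptide counts", cond))
      }
    }
  }
  structure(
    list(ids = ids, mw_kda = as.numeric(mw_kda),
         values = values, peptides = peptides),
    class = "quant_table"
  )
}

#' @export
print.quant_table <- function(x, ...) {
  reps <- vapply(x$values, ncol, integer(1))
  cat(sprintf("quant_table: %d proteins, %d condition(s)\n",
              length(x$ids), length(x$values)))
  for (cond in names(x$values)) {
    cat(sprintf("  %s: %d replicate(s)%s\n", cond, reps[[cond]],
                if (!is.null(x$peptides) && cond %in% names(x$peptides))
                  " [+peptide counts]" else ""))
  }
  invisible(x)
}

#' @export
conditions <- function(x) UseMethod("conditions")

#' @export
conditions.quant_table <- function(x) names(x$values)

#' Parse a quantitative table from TSV/CSV
#'
#' Expected layout: a header line; columns \code{protein_id}, \code{mw_kda},
#' then replicate value columns named \code{<condition>_r<k>} and optional
#' peptide-count columns \code{<condition>_pep<k>}.
#'
#' @param path file path.
#' @param conditions character vector of condition names to extract; the
#'   default extracts every condition found in the header.
#' @param sep field separator; \code{"\t"} by default, use \code{","} for CSV.
#' @param absent_as_zero if TRUE, empty/NA cells are read as 0; otherwise
#'   missing cells are an error.
#' @return a \code{\link{quant_table}}.
#' @export
parse_quant_table <- function(path, conditions = NULL, sep = "\t",
                              absent_as_zero = FALSE) {
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!all(c("protein_id", "mw_kda") %in% names(df))) {
    stop("quant table must have 'protein_id' and 'mw_kda' columns")
  }
  rep_cols <- grep("^.+_r[0-9]+$", names(df), value = TRUE)
  found <- unique(sub("_r[0-9]+$", "", rep_cols))
  if (is.null(conditions)) conditions <- found
  missing_cond <- setdiff(conditions, found)
  if (length(missing_cond) > 0L) {
    stop(sprintf("condition not found: %s", paste(missing_cond, collapse = ", ")))
  }
  take <- function(cols) {
    m <- as.matrix(df[, cols, drop = FALSE])
    storage.mode(m) <- "double"
    if (anyNA(m)) {
      if (absent_as_zero) m[is.na(m)] <- 0
      else stop("missing cells in quant table (set absent_as_zero = TRUE to read them as 0)")
    }
    m
  }
  values <- lapply(conditions, function(cond) {
    cols <- grep(sprintf("^%s_r[0-9]+$", cond), names(df), value = TRUE)
    take(cols[order(as.integer(sub("^.*_r", "", cols)))])
  })
  names(values) <- conditions
  peptides <- NULL
  pep_conds <- Filter(function(cond) {
    any(grepl(sprintf("^%s_pep[0-9]+$", cond), names(df)))
  }, conditions)
  if (length(pep_conds) > 0L) {
    peptides <- lapply(pep_conds, function(cond) {
      cols <- grep(sprintf("^%s_pep[0-9]+$", cond), names(df), value = TRUE)
      take(cols[order(as.integer(sub("^.*_pep", "", cols)))])
    })
    names(peptides) <- pep_conds
  }
  quant_table(df$protein_id, df$mw_kda, values, peptides)
}

#' Write a quant_table to TSV
#'
#' Column layout matches what \code{\link{parse_quant_table}} reads, so
#' write-then-parse round-trips exactly.
#'
#' @param x a \code{\link{quant_table}}.
#' @param path output path.
#' @param sep field separator.
#' @return \code{path}, invisibly.
#' @export
write_quant_table <- function(x, path, sep = "\t") {
  df <- data.frame(protein_id = x$ids, mw_kda = x$mw_kda,
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (cond in names(x$values)) {
    m <- x$values[[cond]]
    colnames(m) <- sprintf("%s_r%d", cond, seq_len(ncol(m)))
    df <- cbind(df, m)
  }
  if (!is.null(x$peptides)) {
    for (cond in names(x$peptides)) {
      m <- x$peptides[[cond]]
      colnames(m) <- sprintf("%s_pep%d", cond, seq_len(ncol(m)))
      df <- cbind(df, m)
    }
  }
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse a printed counts field like "27, 21, 15 (59, 73, 105)"
#'
#' Published knockout tables often print exclusive unique peptide counts with
#' the normalized quantitative values in parentheses.  This helper splits the
#' two replicate vectors.
#'
#' @param field character vector of printed fields.
#' @return list with elements \code{peptides} and \code{values}, each a list
#'   of numeric vectors (one per input field).
#' @export
parse_counts_field <- function(field) {
  parse_one <- function(s) {
    m <- regmatches(s, regexec("^\\s*([0-9, .]+?)\\s*\\(([0-9, .]+)\\)\\s*$", s))[[1]]
    if (length(m) != 3L) {
      stop(sprintf("cannot parse counts field '%s'", s))
    }
    nums <- function(txt) as.numeric(strsplit(txt, ",")[[1]])
    list(peptides = nums(m[2]), values = nums(m[3]))
  }
  parsed <- lapply(field, parse_one)
  list(peptides = lapply(parsed, `[[`, "peptides"),
       values = lapply(parsed, `[[`, "values"))
}

#' Read a homolog map
#'
#' Long-format TSV with columns \code{protein_id}, \code{species},
#' \code{homolog_id} and optional \code{homolog_mw_kda}.  The marker
#' \code{"-"} in \code{homolog_id} means "no homolog in that species",
#' distinct from a protein/species pair that is simply absent from the table
#' (unknown).
#'
#' @param path file path.
#' @param sep field separator.
#' @return data frame with the columns above.
#' @export
read_homolog_map <- function(path, sep = "\t") {
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("protein_id", "species", "homolog_id")
  if (!all(need %in% names(df))) {
    stop(sprintf("homolog map must have columns: %s", paste(need, collapse = ", ")))
  }
  if (!"homolog_mw_kda" %in% names(df)) df$homolog_mw_kda <- NA_real_
  df
}

#' Read a consensus expression matrix
#'
#' TSV with genes as rows (first column \code{gene}) and tissues as the
#' remaining columns.  Values are unitless consensus normalized expression
#' levels and must be non-negative.
#'
#' @param path file path.
#' @param sep field separator.
#' @return numeric matrix, genes x tissues, with dimnames.
#' @export
read_expression_matrix <- function(path, sep = "\t") {
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (names(df)[1L] != "gene") stop("first column must be 'gene'")
  genes <- df$gene
  if (anyDuplicated(genes)) stop("gene labels must be unique")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  if (anyDuplicated(colnames(m))) stop("tissue labels must be unique")
  if (anyNA(m) || any(m < 0)) stop("expression values must be non-negative")
  m
}

#' Write an expression matrix to TSV
#'
#' @param m numeric matrix, genes x tissues.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
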