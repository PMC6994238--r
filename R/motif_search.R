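# Density-signature searching.  A traced cryo-EM backbone shows a pattern of
# bulky side chains (e.g. a Trp, a Pro, five unidentifiable residues, a
# Trp); such a pattern is written as a signature over three token kinds:
# a literal residue letter, a bracket class like [FHY], and the wildcard
# 'x' (any residue).  Because the direction of an unassigned trace is
# unknown, the signature can be searched as written ("forward"), as its
# reversed token list ("reverse"), or both.  Whole-protein length windows
# encode the trace-length estimate.

#' Parse and compile a density-signature pattern
#'
#' Tokens: an uppercase residue letter matches that residue (uppercase
#' \code{X} is a literal unknown-residue match); \code{[ABC]} matches any
#' listed residue; lowercase \code{x} matches any single residue.  Matching
#' over sequences is case-insensitive.  The reverse compilation reverses the
#' token list (the trace read in the opposite direction), never complements.
#'
#' @param signature signature string, e.g. \code{"[FHY]xWxxKxx[FHY]"}.
#' @param direction one of \code{"forward"}, \code{"reverse"}, \code{"both"}.
#' @return an object of class \code{motif_matcher} holding the token list
#'   and one compiled regular expression per searched direction.
#' @examples
#' m <- compile_signature("WPxxxxxW")
#' motif_match(m, "AAWPQRSTVWAA")
#' @export
compile_signature <- function(signature,
                              direction = c("forward", "reverse", "both")) {
  direction <- match.arg(direction)
  tokens <- tokenize_signature(signature)
  dirs <- switch(direction, forward = "forward", reverse = "reverse",
                 both = c("forward", "reverse"))
  regex <- lapply(dirs, function(d) {
    toks <- if (d == "reverse") rev(tokens) else tokens
    tokens_to_regex(toks)
  })
  names(regex) <- dirs
  structure(
    list(signature = signature, tokens = tokens, direction = direction,
         regex = regex),
    class = "motif_matcher"
  )
}

tokenize_signature <- function(signature) {
  if (!is.character(signature) || length(signature) != 1L || !nzchar(signature)) {
    stop("signature must be a non-empty string")
  }
  chars <- strsplit(signature, "")[[1]]
  tokens <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      cls <- character(0)
      while (j <= n && chars[j] != "]") {
        if (!grepl("^[ACDEFGHIKLMNPQRSTVWYX]$", chars[j])) {
          stop(sprintf("illegal character '%s' in class at position %d",
                       chars[j], j))
        }
        cls <- c(cls, chars[j])
        j <- j + 1L
      }
      if (j > n) stop(sprintf("unbalanced bracket opened at position %d", i))
      if (length(cls) == 0L) stop(sprintf("empty class at position %d", i))
      tokens[[length(tokens) + 1L]] <- list(kind = "class", residues = cls)
      i <- j + 1L
    } else if (ch == "x") {
      tokens[[length(tokens) + 1L]] <- list(kind = "any")
      i <- i + 1L
    } else if (grepl("^[ACDEFGHIKLMNPQRSTVWYX]$", ch)) {
      tokens[[length(tokens) + 1L]] <- list(kind = "literal", residue = ch)
      i <- i + 1L
    } else {
      stop(sprintf("illegal character '%s' at position %d", ch, i))
    }
  }
  if (length(tokens) == 0L) stop("signature parses to no tokens")
  tokens
}

tokens_to_regex <- function(tokens) {
  paste(vapply(tokens, function(t) {
    switch(t$kind,
           any = ".",
           literal = t$residue,
           class = paste0("[", paste(t$residues, collapse = ""), "]"))
  }, character(1)), collapse = "")
}

#' @export
print.motif_matcher <- function(x, ...) {
  cat(sprintf("motif_matcher: \"%s\" (%d tokens, direction %s)\n",
              x$signature, length(x$tokens), x$direction))
  invisible(x)
}

#' Match a compiled signature against one sequence
#'
#' Reports all (including overlapping) match positions, per searched
#' direction.  Coordinates are 0-based half-open over the sequence as given.
#'
#' @param matcher a \code{\link{compile_signature}} result.
#' @param sequence one amino-acid string.
#' @return data frame with \code{start}, \code{end}, \code{matched_seq},
#'   \code{direction}.
#' @export
motif_match <- function(matcher, sequence) {
  stopifnot(inherits(matcher, "motif_matcher"))
  seq_up <- toupper(sequence)
  k <- length(matcher$tokens)
  out <- lapply(names(matcher$regex), function(d) {
    # lookahead makes overlapping matches visible to gregexpr
    pat <- paste0("(?=", matcher$regex[[d]], ")")
    m <- gregexpr(pat, seq_up, perl = TRUE)[[1]]
    if (m[1] == -1L) {
      return(data.frame(start = integer(0), end = integer(0),
                        matched_seq = character(0), direction = character(0),
                        stringsAsFactors = FALSE))
    }
    start0 <- as.integer(m) - 1L
    data.frame(start = start0, end = start0 + k,
               matched_seq = substr(rep(seq_up, length(start0)),
                                    start0 + 1L, start0 + k),
               direction = d, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res[order(res$start, res$direction), , drop = FALSE]
}

#' Search a proteome for a density signature
#'
#' Only proteins whose whole-sequence length lies inside the inclusive
#' length window are scanned (the window encodes the residue-count estimate
#' of the density trace); set \code{apply_length_filter = FALSE} to scan
#' everything.  All match positions are reported, overlapping included.
#'
#' @param proteome a \code{\link{proteome}} data frame.
#' @param signature signature string or a precompiled
#'   \code{\link{compile_signature}} matcher.
#' @param min_len,max_len inclusive whole-protein length bounds (residues).
#' @param direction search direction if \code{signature} is a string.
#' @param apply_length_filter apply the length window at scan time.
#' @return data frame of class \code{motif_hits} with columns
#'   \code{protein_id}, \code{start}, \code{end} (0-based half-open),
#'   \code{matched_seq}, \code{direction}, sorted by protein id then start;
#'   attribute \code{proteins} lists the distinct matched protein ids.
#' @export
search_proteome <- function(proteome, signature, min_len = 1L,
                            max_len = Inf,
                            direction = c("forward", "reverse", "both"),
                            apply_length_filter = TRUE) {
  if (min_len > max_len) stop("min_len must be <= max_len")
  matcher <- if (inherits(signature, "motif_matcher")) signature
             else compile_signature(signature, match.arg(direction))
  scan <- if (apply_length_filter) {
    which(proteome$length >= min_len & proteome$length <= max_len)
  } else {
    seq_len(nrow(proteome))
  }
  hits <- lapply(scan, function(i) {
    h <- motif_match(matcher, proteome$sequence[i])
    if (nrow(h) == 0L) return(NULL)
    cbind(data.frame(protein_id = proteome$id[i], stringsAsFactors = FALSE), h)
  })
  hits <- hits[!vapply(hits, is.null, logical(1))]
  out <- if (length(hits) > 0L) do.call(rbind, hits) else
    data.frame(protein_id = character(0), start = integer(0),
               end = integer(0), matched_seq = character(0),
               direction = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$protein_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "proteins") <- unique(out$protein_id)
  attr(out, "query") <- matcher$signature
  class(out) <- c("motif_hits", "data.frame")
  out
}

#' @export
print.motif_hits <- function(x, ...) {
  cat(sprintf("motif hits for \"%s\": %d match(es) in %d protein(s)\n",
              attr(x, "query"), nrow(x), length(attr(x, "proteins"))))
  if (nrow(x) > 0L) {
    y <- as.data.frame(x)
    # human-readable coordinates are 1-based inclusive
    y$start <- y$start + 1L
    names(y)[names(y) == "start"] <- "from"
    names(y)[names(y) == "end"] <- "to"
    print(y, row.names = FALSE, ...)
  }
  invisible(x)
}
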