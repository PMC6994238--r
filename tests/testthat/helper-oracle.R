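# Independent brute-force oracle for signature matching: its own tokenizer
# and a position-by-position sliding check, sharing no code with the
# package matcher.

oracle_tokenize <- function(signature) {
  toks <- regmatches(signature,
                     gregexpr("\\[[A-Z]+\\]|x|[A-Z]", signature))[[1]]
  stopifnot(sum(nchar(toks)) == nchar(signature))
  toks
}

oracle_token_ok <- function(token, residue) {
  if (token == "x") return(TRUE)
  if (startsWith(token, "[")) {
    cls <- strsplit(gsub("\\[|\\]", "", token), "")[[1]]
    return(residue %in% cls)
  }
  token == residue
}

oracle_match_dir <- function(tokens, sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  k <- length(tokens)
  n <- length(chars)
  if (n < k) return(integer(0))
  starts <- integer(0)
  for (p in seq_len(n - k + 1L)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!oracle_token_ok(tokens[j], chars[p + j - 1L])) {
        ok <- FALSE
        break
      }
    }
    if (ok) starts <- c(starts, p - 1L)  # 0-based
  }
  starts
}

# all hits over a proteome data frame, same column layout as search_proteome
oracle_search <- function(prot, signature, min_len = 1L, max_len = Inf,
                          direction = "forward") {
  toks <- oracle_tokenize(signature)
  dirs <- switch(direction, forward = "forward", reverse = "reverse",
                 both = c("forward", "reverse"))
  rows <- list()
  for (i in seq_len(nrow(prot))) {
    if (prot$length[i] < min_len || prot$length[i] > max_len) next
    for (d in dirs) {
      tk <- if (d == "reverse") rev(toks) else toks
      for (s0 in oracle_match_dir(tk, prot$sequence[i])) {
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = prot$id[i], start = s0, end = s0 + length(toks),
          matched_seq = substr(prot$sequence[i], s0 + 1L, s0 + length(toks)),
          direction = d, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(protein_id = character(0), start = integer(0),
               end = integer(0), matched_seq = character(0),
               direction = character(0), stringsAsFactors = FALSE)
  out[order(out$protein_id, out$start, out$direction), , drop = FALSE]
}

random_proteome <- function(n, len_range = c(30L, 80L)) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  proteome(sprintf("rp_%03d", seq_len(n)),
           vapply(lens, function(L) paste(sample(aa, L, replace = TRUE),
                                          collapse = ""), character(1)))
}

# sorted comparable view of a hit table
hit_key <- function(h) {
  h <- as.data.frame(h)[, c("protein_id", "start", "end", "direction")]
  h <- h[order(h$protein_id, h$start, h$direction), , drop = FALSE]
  rownames(h) <- NULL
  h
}
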