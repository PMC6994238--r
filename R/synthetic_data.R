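# Seeded generators producing inputs with the statistical structure the
# analysis assumes, plus machine-readable ground truth.  The quantitative
# simulator inverts the RSPA relation -- expected AQV = copies * MW / 10 --
# so that RSPA is an unbiased copy-number readout by construction and rank
# recovery is a meaningful test of the statistic.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# default copy-number levels: small integers per 16-nm axonemal repeat,
# spread >= 1.33x apart so that ordering is identifiable under replicate noise
DEFAULT_COPY_LEVELS <- c(1L, 2L, 3L, 4L, 6L, 8L, 12L, 16L)

#' Simulate a replicate label-free quantification experiment
#'
#' Per-protein expected abundance is \code{copies * mw_kda / 10}, the
#' inverse of the RSPA relation, so the planted copy number is exactly what
#' RSPA should recover.  Replicates add either mean-preserving lognormal
#' multiplicative noise (label-free CV ~ \code{sigma}) or Poisson counting
#' noise.  A knockout condition is generated alongside wild type: ablated
#' proteins lose all signal ("no peptide detected"), reduced proteins keep
#' \code{1/k} of their expected abundance.
#'
#' @param n_proteins number of proteins (ignored when \code{ids} given).
#' @param ids,copy_numbers,mw_kda optional explicit per-protein vectors;
#'   defaults are generated (ids \code{prot_001}...; copies sampled from
#'   \code{c(1,2,3,4,6,8,12,16)}; MW uniform over \code{mw_range_kda}).
#' @param mw_range_kda molecular-weight range for generated proteins.
#' @param n_replicates replicates per condition (default 3, the usual
#'   triplicate design).
#' @param noise \code{"lognormal"} (multiplicative, sd \code{sigma} on the
#'   log scale, mean-preserving) or \code{"poisson"} (counting semantics).
#' @param sigma lognormal noise sd; 0.2 emulates a ~20\% label-free CV;
#'   0 gives noise-free values.
#' @param ablate protein ids completely lost in the knockout.
#' @param reduce named numeric vector: ids -> fold reduction k (mean
#'   scaled by 1/k in the knockout).
#' @param with_peptides also emit Poisson exclusive-unique-peptide counts.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return list with \code{quant} (a \code{\link{quant_table}} with
#'   conditions WT and KO) and \code{truth} (a data frame: protein id,
#'   planted copies, MW, expected AQV, planted status).
#' @export
simulate_quant_experiment <- function(n_proteins = 200L, ids = NULL,
                                      copy_numbers = NULL, mw_kda = NULL,
                                      mw_range_kda = c(10, 100),
                                      n_replicates = 3L,
                                      noise = c("lognormal", "poisson"),
                                      sigma = 0.2,
                                      ablate = character(0),
                                      reduce = numeric(0),
                                      with_peptides = FALSE,
                                      seed = 1L) {
  noise <- match.arg(noise)
  set.seed(seed)
  if (is.null(ids)) {
    ids <- sprintf("prot_%03d", seq_len(n_proteins))
  }
  n <- length(ids)
  if (is.null(copy_numbers)) {
    copy_numbers <- sample(DEFAULT_COPY_LEVELS, n, replace = TRUE)
  }
  if (any(copy_numbers < 1)) stop("copy numbers must be >= 1")
  if (is.null(mw_kda)) {
    mw_kda <- runif(n, mw_range_kda[1], mw_range_kda[2])
  }
  unknown <- setdiff(c(ablate, names(reduce)), ids)
  if (length(unknown) > 0L) {
    stop(sprintf("knockout id not in protein set: %s",
                 paste(unknown, collapse = ", ")))
  }
  expected <- copy_numbers * mw_kda / 10
  ko_expected <- expected
  ko_expected[match(ablate, ids)] <- 0
  if (length(reduce) > 0L) {
    if (any(reduce <= 1)) stop("reduction factors must be > 1")
    i <- match(names(reduce), ids)
    ko_expected[i] <- expected[i] / reduce
  }
  draw <- function(mu) {
    m <- matrix(0, nrow = n, ncol = n_replicates)
    for (j in seq_len(n_replicates)) {
      m[, j] <- if (noise == "lognormal") {
        mu * exp(rnorm(n, 0, sigma) - sigma^2 / 2)
      } else {
        rpois(n, mu)
      }
    }
    m
  }
  values <- list(WT = draw(expected), KO = draw(ko_expected))
  peptides <- NULL
  if (with_peptides) {
    pep <- function(mu) {
      matrix(rpois(n * n_replicates, rep(pmax(mu / 5, 0), n_replicates)),
             nrow = n)
    }
    peptides <- list(WT = pep(expected), KO = pep(ko_expected))
  }
  status <- rep("unchanged", n)
  status[match(names(reduce), ids)] <- "reduced"
  status[match(ablate, ids)] <- "missing"
  list(
    quant = quant_table(ids, mw_kda, values, peptides),
    truth = data.frame(protein_id = ids, copies = copy_numbers,
                       mw_kda = mw_kda, expected_aqv = expected,
                       status = status, stringsAsFactors = FALSE)
  )
}

realize_motif <- function(tokens) {
  paste(vapply(tokens, function(t) {
    switch(t$kind,
           any = sample(AA20, 1L),
           literal = t$residue,
           class = sample(t$residues, 1L))
  }, character(1)), collapse = "")
}

random_sequence <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

count_matches <- function(matcher, sequence) {
  nrow(motif_match(matcher, sequence))
}

#' Simulate a proteome with planted signature motifs
#'
#' Background sequences are drawn from uniform residue frequencies and
#' rejection-sampled so that they contain no accidental occurrence of the
#' planted signature (in either trace direction); motif instances are then
#' written in at recorded positions, and the whole sequence is re-checked so
#' the emitted ground truth is exactly what a matcher must find.
#'
#' @param n_proteins number of proteins.
#' @param length_range inclusive range of sequence lengths; or supply
#'   \code{lengths} explicitly.
#' @param lengths optional explicit per-protein lengths.
#' @param signature signature string to plant (see
#'   \code{\link{compile_signature}}); NULL plants nothing.
#' @param n_with_motif how many proteins receive one planted instance
#'   (the first \code{n_with_motif} unless \code{motif_hosts} names them).
#' @param motif_hosts optional indices of the host proteins.
#' @param plant_direction direction of each planted instance
#'   ("forward"/"reverse", recycled over hosts).
#' @param seed integer seed; fixed seed gives byte-identical sequences.
#' @param ids optional protein ids (default \code{syn_001}...).
#' @return list with \code{proteome} (a \code{\link{proteome}}) and
#'   \code{truth} (data frame of planted hits: protein_id, start, end in
#'   0-based half-open coordinates, direction, matched_seq).
#' @export
simulate_proteome_with_motifs <- function(n_proteins = 10L,
                                          length_range = c(150L, 350L),
                                          lengths = NULL,
                                          signature = NULL,
                                          n_with_motif = 0L,
                                          motif_hosts = NULL,
                                          plant_direction = "forward",
                                          seed = 1L, ids = NULL) {
  set.seed(seed)
  if (is.null(ids)) ids <- sprintf("syn_%03d", seq_len(n_proteins))
  n <- length(ids)
  if (is.null(lengths)) {
    lengths <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
  }
  matcher <- if (!is.null(signature)) compile_signature(signature, "both")
  k <- if (!is.null(matcher)) length(matcher$tokens) else 0L
  if (!is.null(signature) && n_with_motif > 0L) {
    if (is.null(motif_hosts)) motif_hosts <- seq_len(n_with_motif)
    if (any(lengths[motif_hosts] < k)) {
      stop("impossible placement: motif longer than host sequence")
    }
    plant_direction <- rep_len(plant_direction, length(motif_hosts))
  } else {
    motif_hosts <- integer(0)
  }

  clean_background <- function(len) {
    for (try in 1:1000) {
      s <- random_sequence(len)
      if (is.null(matcher) || count_matches(matcher, s) == 0L) return(s)
    }
    stop("could not sample a motif-free background sequence")
  }

  seqs <- character(n)
  truth <- list()
  for (i in seq_len(n)) {
    host_slot <- match(i, motif_hosts)
    if (is.na(host_slot)) {
      seqs[i] <- clean_background(lengths[i])
      next
    }
    dirn <- plant_direction[host_slot]
    placed <- FALSE
    for (try in 1:1000) {
      s <- clean_background(lengths[i])
      toks <- if (dirn == "reverse") rev(matcher$tokens) else matcher$tokens
      instance <- realize_motif(toks)
      pos <- sample(seq_len(lengths[i] - k + 1L), 1L)
      cand <- paste0(substr(s, 1L, pos - 1L), instance,
                     substr(s, pos + k, lengths[i]))
      hits <- motif_match(matcher, cand)
      if (nrow(hits) == 1L && hits$start == pos - 1L &&
          hits$direction == dirn) {
        seqs[i] <- cand
        truth[[length(truth) + 1L]] <- cbind(
          data.frame(protein_id = ids[i], stringsAsFactors = FALSE), hits)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place motif without accidental extra matches")
  }
  truth <- if (length(truth) > 0L) do.call(rbind, truth) else
    data.frame(protein_id = character(0), start = integer(0),
               end = integer(0), matched_seq = character(0),
               direction = character(0), stringsAsFactors = FALSE)
  list(proteome = proteome(ids, seqs), truth = truth)
}

#' Simulate tissue expression for gene pairs with planted correlation
#'
#' Each pair is drawn from a bivariate normal with the planted Pearson
#' correlation, then shifted to non-negative "consensus normalized
#' expression" levels (an affine shift, so the sample correlation is
#' untouched).  Optionally a shared high-expression regime is added to named
#' tissues for both genes of a pair, inflating the overall correlation —
#' excluding those tissues then recovers the within-regime correlation, the
#' situation the tissue-exclusion re-analysis addresses.
#'
#' @param pairs data frame with columns \code{gene_a}, \code{gene_b},
#'   \code{r} (planted correlation, in [-1, 1]); gene labels must not
#'   repeat across pairs.
#' @param n_tissues number of tissue columns (>= 3).  Default 62: 55 tissue
#'   types plus seven blood cell types, the consensus-expression convention.
#' @param special_tissues labels given to the last few columns, available
#'   for exclusion experiments; the remainder are \code{tissue_01}...
#' @param shared_high_tissues labels (among the tissue labels) receiving a
#'   shared high-expression boost for both genes of every pair.
#' @param high_boost size range of the shared boost.
#' @param seed integer seed.
#' @return list with \code{matrix} (genes x tissues) and \code{truth}
#'   (the pairs with planted r).
#' @export
simulate_expression_pairs <- function(pairs, n_tissues = 62L,
                                      special_tissues = c("testis",
                                                          "corpus callosum",
                                                          "pons and medulla",
                                                          "fallopian tube"),
                                      shared_high_tissues = character(0),
                                      high_boost = c(20, 40),
                                      seed = 1L) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_a", "gene_b", "r") %in% names(pairs)))
  if (n_tissues < 3L) stop("n_tissues must be >= 3")
  if (any(abs(pairs$r) > 1)) stop("planted r must lie in [-1, 1]")
  genes <- c(rbind(pairs$gene_a, pairs$gene_b))
  if (anyDuplicated(genes)) {
    stop("gene labels must not repeat across pairs")
  }
  set.seed(seed)
  n_special <- min(length(special_tissues), n_tissues)
  labels <- c(sprintf("tissue_%02d", seq_len(n_tissues - n_special)),
              special_tissues[seq_len(n_special)])
  boost_idx <- match(shared_high_tissues, labels)
  if (anyNA(boost_idx)) stop("shared_high_tissues must be tissue labels")
  m <- matrix(0, nrow = length(genes), ncol = n_tissues,
              dimnames = list(genes, labels))
  for (i in seq_len(nrow(pairs))) {
    r <- pairs$r[i]
    z1 <- rnorm(n_tissues)
    z2 <- rnorm(n_tissues)
    x <- 10 + 3 * z1
    y <- 10 + 3 * (r * z1 + sqrt(1 - r^2) * z2)
    if (length(boost_idx) > 0L) {
      b <- runif(length(boost_idx), high_boost[1], high_boost[2])
      x[boost_idx] <- x[boost_idx] + b
      y[boost_idx] <- y[boost_idx] + b
    }
    # affine shift to non-negative values; correlation is unaffected
    x <- x - min(0, min(x))
    y <- y - min(0, min(y))
    m[pairs$gene_a[i], ] <- x
    m[pairs$gene_b[i], ] <- y
  }
  list(matrix = m, truth = pairs)
}

#' Simulate a full identification scenario with one planted answer
#'
#' Builds a synthetic "world" for the end-to-end screen: one planted tether
#' protein with the correct stoichiometry (4 copies per repeat), molecular
#' weight (27 kDa), cross-species conservation, neutral localization and a
#' planted density signature in a trace-compatible sequence — surrounded by
#' decoys that each fail exactly one criterion (wrong size, no homolog,
#' excluded localization, or low abundance).
#'
#' @param seed integer seed.
#' @param sigma replicate noise sd (lognormal scale).
#' @param signature density signature planted into the tether protein.
#' @return list with \code{quant}, \code{proteome}, \code{annotations},
#'   \code{homologs}, \code{criteria} (a ready \code{\link{screen_criteria}}),
#'   \code{signature}, \code{length_window}, and \code{truth} (the planted
#'   tether id plus per-protein roles).
#' @export
simulate_screen_world <- function(seed = 1L, sigma = 0.2,
                                  signature = "[FHY]xWxxKxx[FHY]") {
  set.seed(seed)
  roles <- c("tether",
             rep("decoy_size", 15), rep("decoy_conservation", 15),
             rep("decoy_localization", 10), rep("decoy_lowcopy", 19))
  n <- length(roles)
  ids <- sprintf("cand_%03d", seq_len(n))
  tether_id <- ids[1L]
  mw <- numeric(n)
  mw[roles == "tether"] <- 27
  mw[roles == "decoy_size"] <- sample(c(runif(8, 8, 20), runif(7, 50, 90)))
  mw[roles == "decoy_conservation"] <- runif(15, 25, 45)
  mw[roles == "decoy_localization"] <- runif(10, 25, 45)
  mw[roles == "decoy_lowcopy"] <- runif(19, 25, 45)
  copies <- ifelse(roles == "decoy_lowcopy", 1L,
                   ifelse(roles == "tether", 4L, 5L))
  sim <- simulate_quant_experiment(
    ids = ids, copy_numbers = copies, mw_kda = mw,
    n_replicates = 3L, noise = "lognormal", sigma = sigma,
    seed = seed + 1L
  )
  annotations <- data.frame(
    protein_id = ids,
    localization = ifelse(roles == "decoy_localization", "Radial Spoke",
                          NA_character_),
    stringsAsFactors = FALSE
  )
  homologs <- data.frame(
    protein_id = ids, species = "T. thermophila",
    homolog_id = ifelse(roles == "decoy_conservation", "-",
                        paste0("TT_", ids)),
    homolog_mw_kda = ifelse(roles == "decoy_conservation", NA, mw * 1.05),
    stringsAsFactors = FALSE
  )
  lengths <- sample(100:400, n, replace = TRUE)
  lengths[1L] <- 230L  # tether trace length inside the search window
  prot <- simulate_proteome_with_motifs(
    n_proteins = n, lengths = lengths, signature = signature,
    n_with_motif = 1L, motif_hosts = 1L, seed = seed + 2L, ids = ids
  )
  criteria <- screen_criteria(
    top_n = 41L, mw_min = 25, mw_max = 45,
    conservation_required_in = "T. thermophila",
    homolog_size_max_ratio = 2.0,
    excluded_localizations = c("Radial Spoke", "Central Pair", "Dynein",
                               "Cytoplasmic")
  )
  list(
    quant = sim$quant, proteome = prot$proteome,
    annotations = annotations, homologs = homologs, criteria = criteria,
    signature = signature, length_window = c(220L, 280L),
    truth = list(tether_id = tether_id,
                 roles = data.frame(protein_id = ids, role = roles,
                                    copies = copies, mw_kda = mw,
                                    stringsAsFactors = FALSE),
                 motif_hits = prot$truth)
  )
}
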