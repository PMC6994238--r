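# End-to-end orchestration of the identification workflows: stoichiometry
# ranking, knockout differential, multi-criteria screen, density-signature
# search and co-expression, run from one configuration and emitted as a
# consolidated report.  The pipeline only composes the stage functions --
# there is no orchestration-only logic that could diverge from running the
# stages by hand.

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  config
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the identification pipeline end to end
#'
#' Executes, in order and as configured: RSPA ranking, wild-type vs
#' knockout differential classification, the multi-criteria candidate
#' screen, the density-signature proteome search, and pairwise tissue
#' co-expression.  Inputs may be file paths (TSV/FASTA) or in-memory
#' objects.  When \code{outdir} is set, a machine-readable JSON report, a
#' human-readable shortlist TSV (a projection of the JSON, never computed
#' separately) and a run manifest are written; re-running with the same
#' config and seed reproduces them byte for byte.
#'
#' Recognized config fields: \code{quant} (path or \code{quant_table}),
#' \code{wt_condition}/\code{ko_condition}, \code{reduction_threshold},
#' \code{criteria} (argument list for \code{\link{screen_criteria}}),
#' \code{annotations}/\code{homologs} (paths or data frames),
#' \code{proteome} (path or \code{\link{proteome}}), \code{signature},
#' \code{min_len}/\code{max_len}/\code{direction}, \code{expression}
#' (path or matrix), \code{pairs}, \code{exclude_tissues},
#' \code{workflow}, \code{outdir}, \code{seed}.
#'
#' @param config list or YAML file path.
#' @return (invisibly) the report: a list with elements \code{stoich},
#'   \code{diff}, \code{screen}, \code{shortlist}, \code{motif},
#'   \code{coexpr} and \code{manifest}.
#' @export
run_screen_pipeline <- function(config) {
  config <- read_run_config(config)
  if (is.null(config$quant)) stop("config must name a 'quant' input")
  for (field in c("quant", "proteome", "annotations", "homologs", "expression")) {
    v <- config[[field]]
    if (is.character(v) && !file.exists(v)) {
      stop(sprintf("input path for '%s' does not exist: %s", field, v))
    }
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  wt <- config$wt_condition %||% "WT"
  ko <- config$ko_condition

  qt <- stage("load-quant", {
    if (inherits(config$quant, "quant_table")) config$quant
    else parse_quant_table(config$quant)
  })

  stoich <- stage("rspa", rank_by_rspa(qt, condition = wt))

  diff <- NULL
  if (!is.null(ko)) {
    diff <- stage("diff", compare_conditions(
      qt, wt = wt, ko = ko,
      reduction_threshold = config$reduction_threshold %||% 2.0))
  }

  annotations <- NULL
  if (!is.null(config$annotations)) {
    annotations <- stage("load-annotations", {
      if (is.data.frame(config$annotations)) config$annotations
      else read.delim(config$annotations, stringsAsFactors = FALSE)
    })
  }
  homologs <- NULL
  if (!is.null(config$homologs)) {
    homologs <- stage("load-homologs", {
      if (is.data.frame(config$homologs)) config$homologs
      else read_homolog_map(config$homologs)
    })
  }

  screen <- NULL
  if (!is.null(config$criteria)) {
    criteria <- stage("criteria", {
      if (inherits(config$criteria, "screen_criteria")) config$criteria
      else do.call(screen_criteria, config$criteria)
    })
    screen <- stage("screen", apply_criteria(
      stoich, criteria, annotations = annotations, homologs = homologs,
      diff = diff))
  }

  motif <- NULL
  if (!is.null(config$signature)) {
    prot <- stage("load-proteome", {
      if (inherits(config$proteome, "proteome")) config$proteome
      else if (is.null(config$proteome)) stop("signature given but no proteome")
      else read_proteome(config$proteome)
    })
    motif <- stage("motif-search", search_proteome(
      prot, config$signature,
      min_len = config$min_len %||% 1L,
      max_len = config$max_len %||% Inf,
      direction = config$direction %||% "both"))
  }

  coexpr <- NULL
  if (!is.null(config$expression) && !is.null(config$pairs)) {
    expr <- stage("load-expression", {
      if (is.matrix(config$expression)) config$expression
      else read_expression_matrix(config$expression)
    })
    pairs <- config$pairs
    if (is.list(pairs) && !is.data.frame(pairs)) {
      pairs <- do.call(rbind, lapply(pairs, function(p) {
        data.frame(gene_a = p[[1]], gene_b = p[[2]], stringsAsFactors = FALSE)
      }))
    }
    coexpr <- stage("coexpr", correlate_pairs(
      expr, pairs,
      exclude_tissues = as.character(config$exclude_tissues %||% character(0))))
  }

  short <- if (!is.null(screen)) shortlist(screen) else character(0)
  if (!is.null(motif) && length(short) > 0L) {
    # motif evidence re-orders, never removes: hits first, by rank
    hit_ids <- attr(motif, "proteins")
    short <- c(short[short %in% hit_ids], short[!short %in% hit_ids])
  }

  manifest <- list(
    schema_version = "1.0",
    package_version = as.character(utils::packageVersion("mipscreen")),
    workflow = config$workflow %||% "tether-screen",
    seed = config$seed,
    wt_condition = wt, ko_condition = ko
  )
  report <- list(stoich = stoich, diff = diff, screen = screen,
                 shortlist = short, motif = motif, coexpr = coexpr,
                 manifest = manifest)

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    json <- list(
      manifest = manifest,
      stoich = as.data.frame(stoich),
      diff = if (!is.null(diff))
        list(records = as.data.frame(diff),
             summary = as.list(status_counts(diff))),
      screen = if (!is.null(screen)) as.data.frame(screen),
      shortlist = short,
      motif = if (!is.null(motif)) as.data.frame(motif),
      coexpr = if (!is.null(coexpr)) as.data.frame(coexpr)
    )
    jsonlite::write_json(json, file.path(config$outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    # human-readable TSV is a projection of the JSON shortlist
    sl_df <- if (!is.null(screen)) {
      df <- as.data.frame(screen)
      df[match(short, df$protein_id), c("protein_id", "rank", "mw_kda"),
         drop = FALSE]
    } else {
      data.frame(protein_id = short)
    }
    write.table(sl_df, file.path(config$outdir, "shortlist.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    yaml::write_yaml(manifest, file.path(config$outdir, "manifest.yaml"))
  }
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
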