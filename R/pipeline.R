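#' Read / write long-format trait tables
#'
#' @param path TSV with columns `variety`, `parent1`, `parent2`, `day`,
#'   `replicate`, `value` (optional `trait`).
#' @return Data frame.
#' @export
read_trait_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", na.strings = c("NA", ""))
}

#' Per-term tallies of overdominant pattern membership
#'
#' Joins a pattern classification with a flat term map and counts, per
#' term, the member genes in each expression category — the
#' "N genes with up-regulated overdominant expression in pathway X" style
#' summary.
#'
#' @param patterns Data frame from [classify_patterns()].
#' @param terms Named list term_id -> gene ids.
#' @return Data frame `term`, `n_members` (classified genes annotated to
#'   the term), `n_overdominant_up`, `n_overdominant_down`, `n_dominant`,
#'   `n_additive`, `genes` (semicolon-joined `gene:code` pairs).
#' @export
pathway_summary <- function(patterns, terms) {
  cls <- patterns[patterns$pattern_code != "UNCLASSIFIED", , drop = FALSE]
  rows <- lapply(names(terms), function(t) {
    hit <- cls[cls$gene_id %in% terms[[t]], , drop = FALSE]
    data.frame(
      term = t, n_members = nrow(hit),
      n_overdominant_up = sum(hit$category == "overdominant_up"),
      n_overdominant_down = sum(hit$category == "overdominant_down"),
      n_dominant = sum(hit$category == "dominant"),
      n_additive = sum(hit$category == "additive"),
      genes = paste(sprintf("%s:%s", hit$gene_id, hit$pattern_code),
                    collapse = ";"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pipeline configuration
#'
#' Either real input paths (`counts_path` + `design_path`, and optionally
#' `trait_path`, `term_map_path`, `ct_path`) or simulation blocks
#' (`triad_sim`, `biomass_sim`) must be supplied.
#'
#' @param counts_path,design_path,trait_path,term_map_path,ct_path Optional
#'   input TSV paths.
#' @param triad_sim Optional [triad_sim_config()] used when no count input
#'   is given.
#' @param biomass_sim Optional [biomass_sim_config()] used when no trait
#'   input is given.
#' @param de [de_config()].
#' @param enrich_alpha Significance level of the enrichment stage.
#' @param calibrator,reference_gene qPCR settings (see [ddct()]).
#' @param outdir Output directory for the stage TSVs, or `NULL` to skip
#'   writing.
#' @param seed Global seed recorded in every output header.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(counts_path = NULL, design_path = NULL,
                            trait_path = NULL, term_map_path = NULL,
                            ct_path = NULL, triad_sim = NULL,
                            biomass_sim = NULL, de = de_config(),
                            enrich_alpha = 0.05, calibrator = "hybrid",
                            reference_gene = NULL, outdir = NULL,
                            seed = 1) {
  if (is.null(counts_path) && is.null(triad_sim))
    stop("config error: provide counts_path/design_path or a triad_sim block")
  if (!is.null(counts_path) && is.null(design_path))
    stop("config error: counts_path requires design_path")
  structure(list(counts_path = counts_path, design_path = design_path,
                 trait_path = trait_path, term_map_path = term_map_path,
                 ct_path = ct_path, triad_sim = triad_sim,
                 biomass_sim = biomass_sim, de = de,
                 enrich_alpha = enrich_alpha, calibrator = calibrator,
                 reference_gene = reference_gene, outdir = outdir,
                 seed = seed),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full triad heterosis analysis
#'
#' Simulates or ingests the inputs, then runs differential expression over
#' the three triad contrasts, pattern classification and summary, Venn
#' counts of the DEG sets, term enrichment of the overdominant gene sets,
#' per-pathway pattern tallies, the trait heterosis time course with its
#' key period and Duncan letters, and (when Ct data is present) qPCR
#' concordance. Deterministic given the seed; when `outdir` is set every
#' stage table is written as TSV with a seeded header comment.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report` list with elements `de`, `deg_counts`,
#'   `venn`, `patterns`, `pattern_summary`, `enrichment`,
#'   `pathway_summary`, `heterosis` (`series`, `deltas`, `key_period`,
#'   `letters`), `qpcr`, `truth` (simulation only) and `seed`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  report <- list(seed = config$seed)

  truth <- NULL
  em <- stage("input", {
    if (!is.null(config$counts_path)) {
      read_expression_tsv(config$counts_path, config$design_path)
    } else {
      sim <- simulate_triad(config$triad_sim)
      truth <- sim$truth
      sim$em
    }
  })
  report$truth <- truth

  de <- stage("diffexpr", triad_de(em, config$de))
  report$de <- de
  report$deg_counts <- do.call(rbind, lapply(names(de$results), function(nm) {
    r <- de$results[[nm]]
    data.frame(contrast = nm,
               up = sum(r$significant & r$log2FC > 0),
               down = sum(r$significant & r$log2FC < 0))
  }))
  report$venn <- stage("venn", venn_counts(
    deg_set(de, "F1vsP1"), deg_set(de, "F1vsP2"), deg_set(de, "P1vsP2")))

  patterns <- stage("patterns", classify_patterns(de))
  report$patterns <- patterns
  report$pattern_summary <- stage("patterns", summarize_patterns(patterns))

  if (!is.null(config$term_map_path)) {
    terms <- stage("enrichment", read_term_map_tsv(config$term_map_path))
    background <- de$genes_tested
    report$enrichment <- stage("enrichment", {
      od <- patterns$gene_id[patterns$category %in%
                               c("overdominant_up", "overdominant_down")]
      enrich(intersect(od, background), background, terms,
             alpha = config$enrich_alpha)
    })
    report$pathway_summary <- stage("enrichment",
                                    pathway_summary(patterns, terms))
  }

  trait_tab <- NULL
  if (!is.null(config$trait_path)) {
    trait_tab <- stage("heterosis", read_trait_tsv(config$trait_path))
  } else if (!is.null(config$biomass_sim)) {
    trait_tab <- stage("heterosis", simulate_biomass(config$biomass_sim))
  }
  if (!is.null(trait_tab)) {
    series <- stage("heterosis", mph_series(trait_tab))
    deltas <- stage("heterosis", trend_deltas(series))
    keyrow <- deltas[deltas$hybrid == "(mean)" & deltas$key_period, ,
                     drop = FALSE]
    if (!nrow(keyrow)) keyrow <- deltas[deltas$key_period, , drop = FALSE]
    key_day <- if (nrow(keyrow)) keyrow$day_from[1] else NA_integer_
    letters_at_key <- if (!is.na(key_day))
      stage("heterosis", duncan_letters(trait_tab, key_day)) else NULL
    report$heterosis <- list(series = series, deltas = deltas,
                             key_period = keyrow[1, c("day_from", "day_to")],
                             letters = letters_at_key)
  }

  if (!is.null(config$ct_path)) {
    ct <- stage("qpcr", utils::read.delim(config$ct_path,
                                          comment.char = "#"))
    folds <- stage("qpcr", ddct(ct, config$calibrator,
                                config$reference_gene))
    report$qpcr <- list(folds = folds)
  }

  if (!is.null(config$outdir))
    write_report(report, config)
  class(report) <- "pipeline_report"
  report
}

write_report <- function(report, config) {
  dir <- config$outdir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hdr <- c(sprintf("triadheterosis %s",
                   as.character(utils::packageVersion("triadheterosis"))),
           sprintf("seed: %d", config$seed))
  w <- function(df, name) write_tsv_commented(df, file.path(dir, name), hdr)
  for (nm in names(report$de$results))
    w(report$de$results[[nm]], sprintf("de_%s.tsv", nm))
  w(report$deg_counts, "deg_counts.tsv")
  w(data.frame(region = names(report$venn), n = as.integer(report$venn)),
    "venn.tsv")
  w(report$patterns, "patterns.tsv")
  w(report$pattern_summary$per_code, "pattern_summary_codes.tsv")
  w(report$pattern_summary$per_category, "pattern_summary_categories.tsv")
  if (!is.null(report$enrichment)) w(report$enrichment, "enrichment.tsv")
  if (!is.null(report$pathway_summary))
    w(report$pathway_summary, "pathway_summary.tsv")
  if (!is.null(report$heterosis)) {
    w(report$heterosis$series, "heterosis.tsv")
    w(report$heterosis$deltas, "heterosis_deltas.tsv")
    if (!is.null(report$heterosis$letters))
      w(report$heterosis$letters$groups, "duncan_letters.tsv")
  }
  if (!is.null(report$qpcr)) w(report$qpcr$folds, "qpcr_folds.tsv")
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("triad heterosis pipeline report (seed ", x$seed, ")\n", sep = "")
  print(x$deg_counts, row.names = FALSE)
  print(x$pattern_summary)
  if (!is.null(x$heterosis) && nrow(x$heterosis$key_period))
    cat(sprintf("key heterosis period: days %d-%d\n",
                x$heterosis$key_period$day_from,
                x$heterosis$key_period$day_to))
  invisible(x)
}
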