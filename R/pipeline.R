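#' Run the sequence-to-specificity pipeline from a single configuration
#'
#' Orchestrates the analysis chain — motif extraction (pairwise anchoring or
#' MSA columns), specificity classification, census, per-class sequence
#' logos, phylogenetic state mapping, genome co-occurrence, and the kinetics
#' side-channel — writing each stage's output plus a manifest with file
#' checksums to `out_dir`. Stages whose inputs are absent from the
#' configuration are skipped and noted in the manifest; a failing stage
#' aborts with an error naming the stage.
#'
#' Recognised configuration fields (all optional unless a stage needs
#' them): `query_fasta` (sequences to anchor pairwise), `msa_fasta` +
#' `apical_columns` (column-based extraction), `ref_fasta` + `apical_span`
#' (custom reference; defaults to the built-in [reference_anchor()]),
#' `lexicon_csv`, `logo` (logical, per-class logos from the MSA),
#' `tree_newick` (+ optional `states_csv` with columns `tip_id`, `state`;
#' otherwise states come from the classified sequences), `genome_map_csv`
#' (columns `genome_id`, `query_id`), `kinetics_csv` (+ `kinetics_model`,
#' `kinetics_smax`), and `seed`.
#'
#' @param config A named list, or a path to a JSON/YAML configuration file.
#' @param out_dir Output directory (created if needed).
#' @return The manifest list, invisibly. Also written as `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("YAML configuration requires the 'yaml' package")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L

  stages <- character(0)
  outputs <- character(0)
  note <- function(stage, status) stages[stage] <<- status
  emit <- function(path) outputs <<- c(outputs, path)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  lexicon <- if (!is.null(config$lexicon_csv)) motif_lexicon(config$lexicon_csv)
             else motif_lexicon()

  ## --- motif extraction -------------------------------------------------
  calls <- NULL
  msa <- NULL
  if (!is.null(config$msa_fasta)) {
    run_stage("anchor-msa", {
      msa <- read_fasta(config$msa_fasta)
      calls <- extract_motif_msa(msa, as.integer(config$apical_columns))
    })
    note("anchor", "done (msa columns)")
  } else if (!is.null(config$query_fasta)) {
    run_stage("anchor", {
      ref <- if (!is.null(config$ref_fasta)) {
        rseq <- read_fasta(config$ref_fasta)
        reference_anchor(sequence = rseq[[1]],
                         apical_span = as.integer(config$apical_span),
                         reference_id = names(rseq)[1])
      } else reference_anchor()
      calls <- extract_motifs(read_fasta(config$query_fasta), ref)
    })
    note("anchor", "done (pairwise)")
  } else note("anchor", "skipped (no query_fasta/msa_fasta)")

  classified <- NULL
  if (!is.null(calls)) {
    run_stage("classify", {
      write_motif_calls(calls, file.path(out_dir, "motif_calls.csv"))
      emit(file.path(out_dir, "motif_calls.csv"))
      classified <- classify_calls(calls, lexicon)
      utils::write.csv(classified, file.path(out_dir, "classifications.csv"),
                       row.names = FALSE)
      emit(file.path(out_dir, "classifications.csv"))
      cen <- census(classified, lexicon)
      jsonlite::write_json(
        list(total = cen$total,
             per_pattern_counts = as.list(cen$per_pattern_counts),
             per_label_counts = as.list(cen$per_label_counts),
             per_label_fractions = as.list(cen$per_label_fractions)),
        file.path(out_dir, "census.json"), auto_unbox = TRUE, digits = NA)
      emit(file.path(out_dir, "census.json"))
    })
    note("classify", "done")
  } else note("classify", "skipped (no motif calls)")

  ## --- per-class logos --------------------------------------------------
  if (isTRUE(config$logo) && !is.null(msa) && !is.null(classified)) {
    run_stage("logo", {
      logos <- logo_by_class(msa, classified,
                             columns = as.integer(config$apical_columns))
      for (cls in names(logos)) {
        p <- file.path(out_dir, paste0("logo_", cls, ".csv"))
        logo_table(logos[[cls]], p)
        emit(p)
      }
    })
    note("logo", "done")
  } else note("logo", "skipped")

  ## --- phylogeny --------------------------------------------------------
  if (!is.null(config$tree_newick)) {
    run_stage("phylo", {
      tree <- parse_newick(file = config$tree_newick)
      states <- if (!is.null(config$states_csv)) {
        st <- utils::read.csv(config$states_csv)
        stats::setNames(st$state, st$tip_id)
      } else if (!is.null(classified)) {
        stats::setNames(classified$label, classified$query_id)
      } else stop("no states_csv and no classified sequences for the tree")
      rpt <- phylo_state_report(tree, states)
      jsonlite::write_json(rpt, file.path(out_dir, "phylo_report.json"),
                           auto_unbox = TRUE, digits = NA)
      emit(file.path(out_dir, "phylo_report.json"))
    })
    note("phylo", "done")
  } else note("phylo", "skipped (no tree_newick)")

  ## --- co-occurrence ----------------------------------------------------
  if (!is.null(config$genome_map_csv) && !is.null(classified)) {
    run_stage("cooccur", {
      gm <- utils::read.csv(config$genome_map_csv)
      stopifnot(all(c("genome_id", "query_id") %in% names(gm)))
      gm$label <- classified$label[match(gm$query_id, classified$query_id)]
      if (anyNA(gm$label))
        stop("genome map refers to unclassified sequence ids")
      summ <- summarize_cooccurrence(gm)
      cooccurrence_json(summ, file.path(out_dir, "cooccurrence.json"),
                        digits = 0)
      emit(file.path(out_dir, "cooccurrence.json"))
      utils::write.csv(summ$per_genome,
                       file.path(out_dir, "genome_categories.csv"),
                       row.names = FALSE)
      emit(file.path(out_dir, "genome_categories.csv"))
    })
    note("cooccur", "done")
  } else note("cooccur", "skipped")

  ## --- kinetics ---------------------------------------------------------
  if (!is.null(config$kinetics_csv)) {
    run_stage("kinetics", {
      kd <- utils::read.csv(config$kinetics_csv)
      model <- if (!is.null(config$kinetics_model)) config$kinetics_model else "MM"
      fit <- if (!is.null(config$kinetics_smax))
        apparent_fit(kd, s_max = config$kinetics_smax)
      else fit_model(kd, model = model)
      jsonlite::write_json(
        list(model = fit$model, kcat = fit$kcat, km = fit$km, ki = fit$ki,
             se = as.list(fit$se), rss = fit$rss, converged = fit$converged,
             apparent = fit$apparent, n_points = fit$n_points),
        file.path(out_dir, "kinetics_fit.json"), auto_unbox = TRUE,
        digits = NA, null = "null")
      emit(file.path(out_dir, "kinetics_fit.json"))
    })
    note("kinetics", "done")
  } else note("kinetics", "skipped (no kinetics_csv)")

  manifest <- list(
    package = "rnrspec",
    version = as.character(utils::packageVersion("rnrspec")),
    seed = seed,
    stages = as.list(stages),
    files = stats::setNames(as.list(md5_of(outputs)), basename(outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
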