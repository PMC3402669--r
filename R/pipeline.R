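#' Run the full comparative-mitogenomics analysis
#'
#' Orchestrates alignment (or an aligned-input bypass), D-loop exclusion,
#' variant cataloguing with micro-event merging and branch mapping,
#' distance and standard-error matrices, fixed-topology maximum-likelihood
#' fitting with aLRT branch supports, the molecular-clock LRT,
#' fossil-calibrated dating, and (for exactly two genomes) a difference
#' report with islands. All outputs are written to `outdir` together with
#' a JSON run manifest (package version, parameters, seed, input
#' checksums); reruns with the same config and seed are byte-identical.
#'
#' @param config A list or path to a JSON file with entries:
#'   `genomes` (named list of file paths) or `aligned_input` (aligned
#'   FASTA path), optional `regions` (named list of region-TSV paths),
#'   `root_id`, `focal_taxa`, `topology` (newick string or path),
#'   `calibration` (list: `taxa`, `age_years`), optional `alpha`
#'   (default 0.1), `bootstrap` (default 0), `complete_deletion`,
#'   `merge` (`max_gap`, `min_components`), `islands` (`max_island_gap`,
#'   `min_events`), `optimize_model` (default TRUE), `outdir`, `seed`.
#' @param genomes Optional named list of [annotated_genome()] objects,
#'   overriding `config$genomes` (lets simulated data run end-to-end
#'   without touching disk for inputs).
#' @return (Invisibly) a list with every intermediate result and the
#'   manifest.
#' @export
run_pipeline <- function(config, genomes = NULL) {
  if (is.character(config)) {
    config <- jsonlite::read_json(normalizePath(config), simplifyVector = TRUE)
  }
  defaults <- list(alpha = 0.1, bootstrap = 0L, complete_deletion = FALSE,
                   merge = list(max_gap = 2L, min_components = 3L),
                   islands = list(max_island_gap = 60L, min_events = 4L),
                   optimize_model = TRUE, seed = 1L)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  stopifnot(!is.null(config$outdir), !is.null(config$root_id))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  checksums <- list()

  # --- inputs ---------------------------------------------------------
  if (is.null(genomes)) {
    genomes <- stage("read_genomes", {
      if (is.null(config$genomes)) list() else {
        out <- lapply(names(config$genomes), function(nm) {
          p <- config$genomes[[nm]]
          checksums[[p]] <<- unname(tools::md5sum(p))
          g <- read_genome(p, regions_path = config$regions[[nm]])
          g$id <- nm
          g
        })
        setNames(out, names(config$genomes))
      }
    })
  }
  aln <- stage("align", {
    if (!is.null(config$aligned_input)) {
      checksums[[config$aligned_input]] <-
        unname(tools::md5sum(config$aligned_input))
      read_alignment(config$aligned_input, ref_id = config$root_id)
    } else {
      align_genomes(genomes, ref_id = config$root_id)
    }
  })
  write_alignment(aln, file.path(config$outdir, "aligned.fasta"))

  coding <- stage("exclude_d_loop", {
    if (length(genomes) > 0) extract_coding_alignment(aln, genomes) else aln
  })
  write_alignment(coding, file.path(config$outdir, "coding.fasta"))

  # --- variant catalogue ----------------------------------------------
  root_genome <- genomes[[config$root_id]]
  events <- stage("call_events", call_events(coding, config$root_id))
  merged <- stage("merge_micro_events", merge_micro_events(
    events, config$merge$max_gap, config$merge$min_components))
  if (!is.null(root_genome) && nrow(root_genome$regions) > 0) {
    merged <- stage("annotate_effect", annotate_effect(merged, root_genome))
  }
  write_event_tsv(merged, file.path(config$outdir, "events.tsv"))

  topology <- stage("topology", {
    if (is.null(config$topology)) NULL
    else if (file.exists(config$topology)) ape::read.tree(config$topology)
    else ape::read.tree(text = config$topology)
  })

  classified <- branch_counts <- NULL
  if (!is.null(config$focal_taxa)) {
    classified <- stage("classify_sharing",
                        classify_sharing(merged, config$focal_taxa))
    write.table(pattern_counts(classified),
                file.path(config$outdir, "pattern_counts.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(topology)) {
      branch_counts <- stage("map_to_branches",
                             map_to_branches(classified, topology))
      write.table(branch_counts$branches,
                  file.path(config$outdir, "branch_counts.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  # --- distances ------------------------------------------------------
  dists <- stage("distances", distance_table(
    coding, shape = config$alpha,
    complete_deletion = isTRUE(config$complete_deletion),
    bootstrap = config$bootstrap, seed = config$seed))
  write.table(dists, file.path(config$outdir, "distances.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_distance_matrix(dists, file.path(config$outdir,
                                         "distance_matrix.tsv"))

  # --- likelihood, clock, chronology ----------------------------------
  fit <- lrt <- supports <- rate <- chronology <- NULL
  if (!is.null(topology) && length(coding$taxa) >= 3 &&
        setequal(topology$tip.label, coding$taxa)) {
    freqs <- empirical_frequencies(coding)
    model0 <- substitution_model(rates = c(1, 10, 1, 1, 10, 1), pi = freqs,
                                 alpha = if (config$alpha > 0)
                                   config$alpha else Inf)
    tr0 <- topology
    if (is.null(tr0$edge.length)) tr0$edge.length <- rep(0.05,
                                                         nrow(tr0$edge))
    fit <- stage("ml_fit", optimize_branch_lengths(
      coding, tr0, model0, optimize_model = isTRUE(config$optimize_model)))
    supports <- stage("alrt", alrt_support(fit, coding))
    tree_out <- fit$tree
    tree_out$node.label <- NULL
    lab <- rep(NA_real_, tree_out$Nnode)
    lab[supports$node - length(tree_out$tip.label)] <-
      round(supports$support, 4)
    tree_out$node.label <- ifelse(is.na(lab), "", format(lab))
    ape::write.tree(tree_out, file.path(config$outdir, "tree_ml.nwk"))
    lrt <- stage("clock_lrt", clock_lrt(coding, topology, fit$model))
    writeLines(jsonlite::toJSON(glance(lrt), auto_unbox = TRUE, digits = 10,
                                pretty = TRUE),
               file.path(config$outdir, "clock_lrt.json"))
    if (!is.null(config$calibration)) {
      rate <- stage("calibrate_rate", calibrate_rate(
        fit$tree, config$calibration$taxa, config$calibration$age_years))
      chronology <- stage("date_nodes", date_nodes(fit$tree, rate))
      write_chronology_tsv(chronology,
                           file.path(config$outdir, "chronology.tsv"))
    }
  }

  # --- two-genome comparison ------------------------------------------
  comparison <- NULL
  if (length(coding$taxa) == 2L) {
    isl <- stage("find_islands", find_islands(
      merged, config$islands$max_island_gap, config$islands$min_events,
      genome = root_genome))
    comparison <- list(
      n_differences = sum(merged$component_count),
      n_substitutions = sum(merged$component_count[
        merged$kind %in% c("substitution", "micro_reorganization")]),
      n_indels = sum(merged$kind %in% c("insertion", "deletion")),
      islands = isl)
    write.table(isl, file.path(config$outdir, "islands.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package = "mitocomp",
    version = as.character(utils::packageVersion("mitocomp")),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("genomes", "outdir"))],
    inputs = checksums,
    taxa = coding$taxa,
    alignment_columns = aln_ncol(aln),
    coding_columns = aln_ncol(coding))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              null = "null"),
             file.path(config$outdir, "manifest.json"))

  invisible(list(alignment = aln, coding = coding, events = merged,
                 classified = classified, branch_counts = branch_counts,
                 distances = dists, fit = fit, supports = supports,
                 clock = lrt, rate = rate, chronology = chronology,
                 comparison = comparison, manifest = manifest))
}

#' Empirical base frequencies of an alignment
#' @param aln A [multi_alignment()].
#' @return Numeric(4): frequencies of A, C, G, T among unambiguous bases.
#' @export
empirical_frequencies <- function(aln) {
  M <- aln_matrix(aln)
  tab <- table(factor(M, levels = c("A", "C", "G", "T")))
  as.numeric(tab / sum(tab))
}
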