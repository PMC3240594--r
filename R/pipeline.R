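#' Pipeline configuration
#'
#' Collects every stage threshold with its published default: 80/20
#' percentile split with minimum group size 3, derivation significance
#' 1e-4 (BH-adjusted), robustness with 1000 permutations at FDR < 5%,
#' validation at q < 0.25 with a 10000-permutation global test, network
#' edges at FDR < 0.05, overlap-class cutoffs 0.6/0.4, sequence-similarity
#' threshold -5, and 1000 random graphs for topology nulls.
#'
#' @param pct_high,pct_low,min_n Split parameters.
#' @param alpha,adjust Derivation threshold and whether it applies to
#'   BH-adjusted values.
#' @param robustness_n_perm,robustness_fdr Robustness filter parameters.
#' @param validation_q,validation_n_perm Validation parameters.
#' @param network_fdr Edge significance threshold.
#' @param overlap_large,overlap_small Overlap-class cutoffs.
#' @param similarity_threshold Sequence-similarity retention cutoff.
#' @param topology_n_random Null-ensemble size for the small-world test.
#' @param require_cohort Optional cohort required for miRNA-pathway edges.
#' @param seed Top-level seed; stages draw deterministic substreams.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(pct_high = 80, pct_low = 20, min_n = 3,
                       alpha = 1e-4, adjust = TRUE,
                       robustness_n_perm = 1000, robustness_fdr = 0.05,
                       validation_q = 0.25, validation_n_perm = 10000,
                       network_fdr = 0.05,
                       overlap_large = 0.6, overlap_small = 0.4,
                       similarity_threshold = -5,
                       topology_n_random = 1000,
                       require_cohort = NULL, seed = 1L) {
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (validation_q <= 0 || validation_q > 1) stop("validation_q in (0, 1]")
  if (network_fdr <= 0 || network_fdr > 1) stop("network_fdr in (0, 1]")
  if (robustness_fdr <= 0 || robustness_fdr > 1) stop("robustness_fdr in (0, 1]")
  if (robustness_n_perm < 1 || validation_n_perm < 1 ||
      topology_n_random < 1) stop("permutation counts must be >= 1")
  if (!(pct_low < pct_high)) stop("pct_low must be below pct_high")
  if (overlap_small > overlap_large) stop("overlap cutoffs out of order")
  structure(as.list(environment()), class = "run_config")
}

#' Run the full signature-to-network pipeline
#'
#' Orchestrates derive -> score -> validate -> network -> topology ->
#' cotargeting over a set of cohorts: miRNA signatures are derived from the
#' training cohort and robustness-filtered, all retained miRNA signatures
#' plus the curated pathway signatures are scored on every cohort, scores
#' are validated against measured miRNA expression where available, the
#' signed network is merged across cohorts, and topology and cotargeting
#' statistics are computed on the result. Reruns with the same inputs and
#' configuration are reproducible.
#'
#' @param cohorts Named list of [cohort()] objects; the training cohort must
#'   carry paired miRNA data.
#' @param pathway_signatures Named list of curated pathway
#'   [gene_signature()]s.
#' @param assignment Data frame mapping `signature` to `pathway`.
#' @param config A [run_config()].
#' @param training_cohort Name or index of the cohort used for derivation.
#' @param knockdown Optional knockdown table enabling modulator nomination.
#' @param modulator_pathway Pathway id used with `knockdown`.
#' @param outdir Optional directory; when given, per-stage outputs
#'   (signatures GMT, derivation report, validation table, network TSV,
#'   manifest JSON) are written there.
#' @return List with `signatures`, `derivation_report`, `scores` (per
#'   cohort), `validation`, `global_test`, `network`, `topology`,
#'   `small_world`, `cotargeting` (where annotations permit), `modulators`
#'   (when a knockdown table is supplied), and `manifest`.
#' @export
run_pipeline <- function(cohorts, pathway_signatures, assignment, config,
                         training_cohort = 1, knockdown = NULL,
                         modulator_pathway = NULL, outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.numeric(training_cohort)) {
    training_cohort <- names(cohorts)[training_cohort]
  }
  train <- cohorts[[training_cohort]]
  if (is.null(train) || is.null(train$mirna)) {
    stop("training cohort must exist and carry paired miRNA data")
  }

  derived <- derive_all_signatures(
    train, alpha = config$alpha, adjust = config$adjust,
    pct_high = config$pct_high, pct_low = config$pct_low,
    min_n = config$min_n, n_perm = config$robustness_n_perm,
    fdr_threshold = config$robustness_fdr,
    seed = seed_stream(config$seed, 1))

  all_sigs <- c(derived$signatures, pathway_signatures)
  if (length(derived$signatures) == 0) {
    warning("no robust miRNA signatures; network will lack miRNA nodes")
  }
  scores <- lapply(cohorts, function(ch) score_signatures(ch$mrna, all_sigs))

  validation <- NULL; global_test <- NULL
  if (length(derived$signatures) > 0) {
    mir_scores <- scores[[training_cohort]][names(derived$signatures), ,
                                            drop = FALSE]
    validation <- validate_signatures(mir_scores, train$mirna,
                                      q_threshold = config$validation_q)
    if (length(derived$signatures) >= 2) {
      global_test <- global_permutation_test(
        mir_scores, train$mirna, n_perm = config$validation_n_perm,
        seed = seed_stream(config$seed, 2),
        q_threshold = config$validation_q)
    }
  }

  nb <- build_network(scores, assignment, fdr = config$network_fdr,
                      require_cohort = config$require_cohort)
  net <- nb$network

  topology <- NULL; small_world <- NULL
  if (nrow(net$edges) > 0) {
    topology <- topology_summary(net)
    g <- largest_comp(as_topology_graph(net))
    small_world <- small_world_test(g, n_random = config$topology_n_random,
                                    seed = seed_stream(config$seed, 3))
  }

  ann <- train$annotations
  cot <- list()
  safely <- function(expr) tryCatch(expr, error = function(e) {
    list(error = conditionMessage(e))
  })
  if (!is.null(ann$family_of)) {
    cot$family_redundancy <- safely(family_redundancy_test(net, ann$family_of))
  }
  if (!is.null(ann$targets_of)) {
    cot$overlap_redundancy <- safely(overlap_redundancy_test(
      net, ann$targets_of, large = config$overlap_large,
      small = config$overlap_small))
    cot$overlap_cotargeting <- safely(overlap_cotargeting_test(
      net, ann$targets_of, large = config$overlap_large,
      small = config$overlap_small))
  }
  if (!is.null(ann$cluster_of)) {
    cot$cluster_cotargeting <- safely(cluster_cotargeting_test(
      net, ann$cluster_of))
  }

  modulators <- NULL
  if (!is.null(knockdown) && !is.null(modulator_pathway) &&
      modulator_pathway %in% net$nodes$id) {
    modulators <- nominate_modulators(net, modulator_pathway, knockdown,
                                      n_cohorts = length(cohorts))
  }

  manifest <- list(
    seed = config$seed,
    parameters = unclass(config),
    cohorts = names(cohorts),
    training_cohort = training_cohort,
    counts = list(
      mirnas_total = nrow(train$mirna),
      eligible = sum(derived$report$eligible),
      derived = sum(derived$report$size > 0 & derived$report$eligible),
      robust = sum(derived$report$retained),
      validated = if (is.null(validation)) 0L else attr(validation, "n_pass"),
      nodes = nrow(net$nodes),
      edges = nrow(net$edges)))

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (length(derived$signatures) > 0) {
      write_gmt(derived$signatures, file.path(outdir, "signatures.gmt"))
    }
    write.table(derived$report, file.path(outdir, "derivation_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(validation)) {
      write.table(validation, file.path(outdir, "validation.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_network(net, file.path(outdir, "network.tsv"))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(signatures = derived$signatures,
       derivation_report = derived$report,
       scores = scores, validation = validation, global_test = global_test,
       network = net, records = nb$records, topology = topology,
       small_world = small_world, cotargeting = cot,
       modulators = modulators, manifest = manifest)
}
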