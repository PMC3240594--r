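#' Configuration for the synthetic multi-cohort generator
#'
#' Defines the planted structure shared by all generated cohorts: miRNA
#' target sets, miRNA families (shared targets), genomic clusters
#' (coexpression), pathway gene programs, and signed miRNA-pathway links.
#' Defaults describe the package's reference simulation: five cohorts of 60
#' samples, 2000 genes, 20 miRNAs, 5 pathways, and per-target effect sizes
#' twice the measurement noise.
#'
#' @param n_genes,n_mirnas,n_pathways,n_samples_per_cohort,n_cohorts
#'   Problem dimensions (all >= 1).
#' @param targets_per_mirna Number of target genes per miRNA.
#' @param effect_mirna Per-target log-expression shift per unit miRNA
#'   activity; negative for repression.
#' @param effect_pathway Per-gene shift per unit pathway activity applied to
#'   pathway up-genes (negated for down-genes); positive.
#' @param noise_sd Standard deviation of i.i.d. Gaussian measurement noise.
#' @param frac_cluster_mirnas Fraction of miRNAs grouped into coexpressed
#'   genomic clusters (pairs).
#' @param frac_family Fraction of miRNAs grouped into families (pairs)
#'   sharing `family_shared_frac` of their targets.
#' @param family_shared_frac Fraction of targets shared within a family;
#'   must exceed 0.6 so same-family pairs fall in the large-overlap class.
#' @param link_strength Latent coefficient of each planted link (units of
#'   latent standard deviation; default 1).
#' @param mirna_pathway_links Optional data frame with columns `mirna`,
#'   `pathway`, `sign` (`+1`/`-1`) and `direction`
#'   (`"pathway_to_mirna"` for miRNAs transcriptionally driven by the
#'   pathway, `"mirna_to_pathway"` for upstream modulators). When `NULL`,
#'   two links per pathway are planted (one of each direction, alternating
#'   signs for the downstream links).
#' @param signatures_per_pathway Number of curated signatures emitted per
#'   pathway (each a random subset of the pathway's gene program), feeding
#'   the pathway-aggregation rule.
#' @param seed Integer seed; the generator is deterministic given the
#'   configuration.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 2000, n_mirnas = 20, n_pathways = 5,
                       n_samples_per_cohort = 60, n_cohorts = 5,
                       targets_per_mirna = 50,
                       effect_mirna = -1, effect_pathway = 1,
                       noise_sd = 0.5,
                       frac_cluster_mirnas = 0.4, frac_family = 0.4,
                       family_shared_frac = 0.7,
                       link_strength = 1,
                       mirna_pathway_links = NULL,
                       signatures_per_pathway = 2,
                       seed = 1L) {
  counts <- c(n_genes, n_mirnas, n_pathways, n_samples_per_cohort, n_cohorts,
              targets_per_mirna, signatures_per_pathway)
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (link_strength < 0) stop("link_strength must be >= 0")
  if (effect_pathway < 0) stop("effect_pathway must be >= 0")
  fr <- c(frac_cluster_mirnas, frac_family, family_shared_frac)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (targets_per_mirna > n_genes) {
    stop("targets_per_mirna cannot exceed n_genes")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Generate synthetic paired miRNA/mRNA cohorts with planted ground truth
#'
#' Samples carry latent pathway activities; miRNA activity combines a
#' cluster/family coexpression latent with pathway-driven terms for planted
#' downstream links; upstream-modulator miRNAs feed into pathway activity
#' instead. mRNA expression adds the miRNA effect over each miRNA's targets
#' and the pathway effect over each pathway's up/down genes, plus Gaussian
#' noise. Cohorts share the structural ground truth but draw independent
#' latents and noise.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `cohorts` (named list of [cohort()] objects,
#'   each with paired matrices and annotations) and `truth` (target sets,
#'   family/cluster maps, pathway gene programs, planted links, curated
#'   pathway signatures with their pathway assignment, and the per-cohort
#'   latent activity matrices).
#' @export
generate_cohorts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, generate_cohorts_impl(cfg))
}

generate_cohorts_impl <- function(cfg) {
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  mirnas <- sprintf("MIR%02d", seq_len(cfg$n_mirnas))
  pathways <- sprintf("PW%d", seq_len(cfg$n_pathways))

  pair_up <- function(ids, prefix) {
    # group ids into consecutive pairs; singleton leftovers stay unassigned
    out <- setNames(rep(NA_character_, length(ids)), ids)
    n_pairs <- length(ids) %/% 2
    if (n_pairs > 0) {
      for (k in seq_len(n_pairs)) {
        out[ids[c(2 * k - 1, 2 * k)]] <- paste0(prefix, k)
      }
    }
    out
  }
  shuffled <- sample(mirnas)
  n_cl <- round(cfg$frac_cluster_mirnas * cfg$n_mirnas)
  n_fam <- round(cfg$frac_family * cfg$n_mirnas)
  cl_members <- shuffled[seq_len(n_cl)]
  fam_members <- shuffled[n_cl + seq_len(min(n_fam, cfg$n_mirnas - n_cl))]
  cluster_of <- setNames(rep(NA_character_, cfg$n_mirnas), mirnas)
  family_of <- setNames(rep(NA_character_, cfg$n_mirnas), mirnas)
  cluster_of[names(pair_up(cl_members, "CL"))] <- pair_up(cl_members, "CL")
  family_of[names(pair_up(fam_members, "FAM"))] <- pair_up(fam_members, "FAM")

  # target sets: family members share family_shared_frac of their targets
  targets_of <- setNames(vector("list", cfg$n_mirnas), mirnas)
  n_shared <- round(cfg$family_shared_frac * cfg$targets_per_mirna)
  for (fam in unique(na.omit(family_of))) {
    members <- names(family_of)[!is.na(family_of) & family_of == fam]
    shared <- sample(genes, n_shared)
    for (m in members) {
      own <- sample(setdiff(genes, shared), cfg$targets_per_mirna - n_shared)
      targets_of[[m]] <- c(shared, own)
    }
  }
  for (m in mirnas[vapply(targets_of, is.null, logical(1))]) {
    targets_of[[m]] <- sample(genes, cfg$targets_per_mirna)
  }

  # disjoint pathway gene programs (30 up, 15 down each when room permits)
  n_up <- min(30L, max(1L, cfg$n_genes %/% (3L * cfg$n_pathways)))
  n_dn <- max(1L, n_up %/% 2L)
  pool <- sample(genes)
  pathway_genes <- list()
  off <- 0
  for (p in pathways) {
    pathway_genes[[p]] <- list(up = pool[off + seq_len(n_up)],
                               down = pool[off + n_up + seq_len(n_dn)])
    off <- off + n_up + n_dn
  }

  links <- cfg$mirna_pathway_links
  if (is.null(links)) {
    if (2L * cfg$n_pathways > cfg$n_mirnas) {
      stop("need at least 2 miRNAs per pathway for default planted links")
    }
    links <- data.frame(
      mirna = mirnas[seq_len(2L * cfg$n_pathways)],
      pathway = rep(pathways, each = 2),
      sign = rep_len(c(1, -1, 1, 1), 2L * cfg$n_pathways),
      direction = rep(c("pathway_to_mirna", "mirna_to_pathway"),
                      cfg$n_pathways),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(links$mirna %in% mirnas), all(links$pathway %in% pathways),
            all(links$sign %in% c(-1, 1)),
            all(links$direction %in% c("pathway_to_mirna",
                                       "mirna_to_pathway")))

  # curated pathway signatures: random subsets of each pathway's program
  pathway_signatures <- list()
  assignment <- data.frame(signature = character(), pathway = character(),
                           stringsAsFactors = FALSE)
  for (p in pathways) {
    for (k in seq_len(cfg$signatures_per_pathway)) {
      nm <- sprintf("%s_sig%d", p, k)
      up <- sample(pathway_genes[[p]]$up,
                   max(1, round(0.7 * length(pathway_genes[[p]]$up))))
      dn <- sample(pathway_genes[[p]]$down,
                   max(1, round(0.7 * length(pathway_genes[[p]]$down))))
      pathway_signatures[[nm]] <- gene_signature(nm, up, dn,
                                                 source = "curated_pathway")
      assignment <- rbind(assignment,
                          data.frame(signature = nm, pathway = p,
                                     stringsAsFactors = FALSE))
    }
  }

  group_of <- ifelse(!is.na(cluster_of), cluster_of, family_of)
  annotations <- list(family_of = family_of, cluster_of = cluster_of,
                      targets_of = targets_of)
  S <- cfg$n_samples_per_cohort
  cohorts <- list()
  latent <- list()
  for (ci in seq_len(cfg$n_cohorts)) {
    cname <- sprintf("cohort%d", ci)
    samples <- sprintf("%s_S%02d", cname, seq_len(S))
    A <- matrix(rnorm(cfg$n_pathways * S), cfg$n_pathways, S,
                dimnames = list(pathways, samples))
    groups <- unique(na.omit(group_of))
    Z <- matrix(rnorm(length(groups) * S), length(groups), S,
                dimnames = list(groups, samples))
    U <- matrix(rnorm(cfg$n_mirnas * S), cfg$n_mirnas, S,
                dimnames = list(mirnas, samples))
    for (m in mirnas[!is.na(group_of)]) {
      # equal shared/individual variance -> within-group correlation 0.5
      U[m, ] <- sqrt(0.5) * Z[group_of[m], ] + sqrt(0.5) * U[m, ]
    }
    up_links <- links[links$direction == "mirna_to_pathway", , drop = FALSE]
    for (i in seq_len(nrow(up_links))) {
      A[up_links$pathway[i], ] <- A[up_links$pathway[i], ] +
        cfg$link_strength * up_links$sign[i] * U[up_links$mirna[i], ]
    }
    Tm <- U
    dn_links <- links[links$direction == "pathway_to_mirna", , drop = FALSE]
    for (i in seq_len(nrow(dn_links))) {
      Tm[dn_links$mirna[i], ] <- Tm[dn_links$mirna[i], ] +
        cfg$link_strength * dn_links$sign[i] * A[dn_links$pathway[i], ]
    }
    mirna_expr <- Tm + matrix(rnorm(length(Tm), sd = cfg$noise_sd),
                              nrow(Tm), ncol(Tm))
    X <- matrix(rnorm(cfg$n_genes * S, sd = cfg$noise_sd), cfg$n_genes, S,
                dimnames = list(genes, samples))
    for (p in pathways) {
      X[pathway_genes[[p]]$up, ] <- X[pathway_genes[[p]]$up, ] +
        rep(cfg$effect_pathway * A[p, ], each = length(pathway_genes[[p]]$up))
      X[pathway_genes[[p]]$down, ] <- X[pathway_genes[[p]]$down, ] -
        rep(cfg$effect_pathway * A[p, ], each = length(pathway_genes[[p]]$down))
    }
    for (m in mirnas) {
      tg <- targets_of[[m]]
      X[tg, ] <- X[tg, ] + rep(cfg$effect_mirna * Tm[m, ], each = length(tg))
    }
    cohorts[[cname]] <- cohort(cname, mrna = X, mirna = mirna_expr,
                               annotations = annotations)
    latent[[cname]] <- list(pathway = A, mirna = Tm)
  }
  truth <- list(targets_of = targets_of, family_of = family_of,
                cluster_of = cluster_of, pathway_genes = pathway_genes,
                planted_links = links,
                pathway_signatures = pathway_signatures,
                assignment = assignment, latent = latent)
  list(cohorts = cohorts, truth = truth)
}

#' Simulate a pathway-knockdown differential miRNA table
#'
#' Emulates a knockdown of the pathway's effector followed by miRNA
#' profiling of three treated vs three control replicates: miRNAs planted as
#' transcriptional targets of the pathway shift strongly (sign opposite to
#' their planted link), all other miRNAs stay at noise level.
#'
#' @param truth Ground truth from [generate_cohorts()].
#' @param pathway Pathway identifier present in the truth.
#' @param seed Integer seed.
#' @param n_rep Replicates per condition.
#' @param effect Absolute log-fold-change planted for pathway-driven miRNAs.
#' @param noise_sd Replicate noise.
#' @return Data frame with columns `mirna`, `lfc`, `p` (Welch t-test).
#' @export
generate_knockdown_table <- function(truth, pathway, seed = 1L, n_rep = 3,
                                     effect = 2, noise_sd = 0.3) {
  if (!pathway %in% truth$planted_links$pathway &&
      !pathway %in% names(truth$pathway_genes)) {
    stop("unknown pathway: ", pathway)
  }
  mirnas <- names(truth$targets_of)
  dn <- truth$planted_links
  dn <- dn[dn$direction == "pathway_to_mirna" & dn$pathway == pathway, ,
           drop = FALSE]
  shift <- setNames(rep(0, length(mirnas)), mirnas)
  shift[dn$mirna] <- -dn$sign * effect
  withr::with_seed(seed, {
    res <- lapply(mirnas, function(m) {
      ctrl <- rnorm(n_rep, 0, noise_sd)
      trt <- rnorm(n_rep, shift[m], noise_sd)
      data.frame(mirna = m, lfc = mean(trt) - mean(ctrl),
                 p = t.test(trt, ctrl)$p.value, stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
}
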