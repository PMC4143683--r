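# Top-level orchestration: simulate (or load) a family study, fit the
# repeatability model, prepare markers (prune, stratify, collapse), run the
# prediction experiment and the blending regressions, and write every stage's
# artifacts and counts.

#' Pipeline configuration
#'
#' @param sim A [sim_config()] for synthetic data, or NULL to read data from
#'   `paths`.
#' @param paths Named list with `pedigree`, `phenotypes`, `genotypes` when
#'   reading data from disk (ignored when `sim` is given).
#' @param out_dir Output directory (created if missing); NULL writes nothing.
#' @param do_prune,do_collapse Stage toggles.
#' @param r2_threshold LD-pruning threshold on founders.
#' @param maf_threshold Common/rare MAF boundary.
#' @param window_size Rare-variant collapsing window (markers).
#' @param mcmc [mcmc_settings()] for the prediction samplers.
#' @param k Across-family fold count.
#' @param designs Validation designs to run.
#' @param variance_ratio GBLUP variance ratio.
#' @param pi_init BayesC-pi initial pi.
#' @param seed_collapse Seed of the collapsing stage.
#' @return List of class `famgp_pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), paths = NULL, out_dir = NULL,
                            do_prune = TRUE, do_collapse = TRUE,
                            r2_threshold = 0.9, maf_threshold = 0.05,
                            window_size = 100L,
                            mcmc = mcmc_settings(),
                            k = 5L,
                            designs = c("within_family", "across_family"),
                            variance_ratio = 2 / 3, pi_init = 0.9,
                            seed_collapse = 1L) {
  structure(list(sim = sim, paths = paths, out_dir = out_dir,
                 do_prune = do_prune, do_collapse = do_collapse,
                 r2_threshold = r2_threshold, maf_threshold = maf_threshold,
                 window_size = as.integer(window_size), mcmc = mcmc, k = k,
                 designs = designs, variance_ratio = variance_ratio,
                 pi_init = pi_init, seed_collapse = as.integer(seed_collapse)),
            class = "famgp_pipeline_config")
}

#' Run the whole analysis pipeline
#'
#' Stage order: data (simulated or read) -> pedigree A-matrix -> REML fit of
#' the repeatability model -> LD pruning on founders -> MAF stratification ->
#' k-means collapsing of rare variants -> marker sets -> GBLUP / BayesC-pi
#' under the requested validation designs -> blending regressions on the
#' within-family test set. Every stage logs its counts; outputs are written
#' under `out_dir` when given. Deterministic given the configured seeds.
#'
#' @param config A [pipeline_config()].
#' @return List: `report` (accuracy table), `blend` (R2 triple, when the
#'   within-family design ran), `vc_fit`, `marker_sets` sizes, `counts` (log
#'   of bookkeeping numbers), plus the data objects.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  counts <- list()
  if (!is.null(config$sim)) {
    sim <- simulate_study(config$sim)
    ped <- sim$pedigree; geno <- sim$genotypes; phen <- sim$phenotypes
  } else {
    p <- config$paths
    if (is.null(p$pedigree) || is.null(p$phenotypes) || is.null(p$genotypes))
      stop_famgp("paths must name pedigree, phenotypes and genotypes files")
    ped <- read_pedigree(p$pedigree)
    phen <- read_phenotypes(p$phenotypes)
    geno <- read_genotypes(p$genotypes)
    sim <- NULL
  }
  phen <- phen[!is.na(phen$y), , drop = FALSE]
  counts$n_records <- nrow(phen)
  counts$n_individuals <- length(unique(phen$id))
  counts$n_families <- length(unique(ped$family))

  A <- additive_relationship_matrix(ped)
  vc_fit <- fit_repeatability_model(phen, A)
  counts$h2 <- vc_fit$h2

  founders <- as.character(ped$id[ped$sire == 0 & ped$dam == 0])
  counts$n_founders <- length(founders)
  if (config$do_prune) {
    kept <- ld_prune(geno, founders, config$r2_threshold)
    counts$n_markers_input <- ncol(geno$dosages)
    counts$n_markers_pruned_away <- ncol(geno$dosages) - length(kept)
    geno <- geno_subset(geno, marker_ids = kept)
  }
  strata <- split_by_maf(geno, config$maf_threshold)
  counts$n_common <- ncol(strata$common$dosages)
  counts$n_rare <- ncol(strata$rare$dosages)
  counts$n_monomorphic_dropped <- strata$n_dropped

  collapsed <- NULL
  if (config$do_collapse && counts$n_rare > 0) {
    collapsed <- collapse_rare(strata$rare, config$window_size,
                               seed = config$seed_collapse)
    counts$n_collapsed <- nrow(collapsed$windows)
    counts$n_collapsed_rare <- sum(collapsed$windows$maf < config$maf_threshold)
  }
  sets <- assemble_marker_sets(strata$common, collapsed)
  if (!config$do_collapse) sets$set2 <- NULL
  counts$set_sizes <- vapply(sets, function(s) ncol(s$dosages), integer(1))

  report <- run_experiment(ped, vc_fit$u_hat, sets, config$mcmc,
                           designs = config$designs, k = config$k,
                           variance_ratio = config$variance_ratio,
                           pi_init = config$pi_init)

  blend <- NULL
  if ("within_family" %in% config$designs) {
    sp <- within_family_split(ped, intersect(names(vc_fit$u_hat),
                                             rownames(dosages(sets$set1))))
    m_b <- config$mcmc
    m_b$seed <- config$mcmc$seed + 999983L
    fit <- fit_gblup(vc_fit$u_hat[sp$trn_ids],
                     dosages(sets$set1)[sp$trn_ids, , drop = FALSE],
                     config$variance_ratio, m_b)
    yhat <- predict(fit, dosages(sets$set1)[sp$tst_ids, , drop = FALSE])
    blend <- blend_experiment(ped, vc_fit$u_hat, yhat, sp)
    counts$n_blend <- blend$n_blend
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    od <- function(f) file.path(config$out_dir, f)
    write_pedigree(ped, od("pedigree.tsv"))
    write_phenotypes(phen, od("phenotypes.csv"))
    write_genotypes_raw(geno, od("genotypes.raw"), ped)
    write_fit_json(vc_fit, od("vc_fit.json"))
    if (!is.null(collapsed)) write_window_map(collapsed, od("window_map.bed"))
    utils::write.csv(report, od("report.csv"), row.names = FALSE)
    if (!is.null(blend))
      jsonlite::write_json(blend[c("r2_genomic", "r2_parent_avg",
                                   "r2_combined", "n_blend")],
                           od("blending.json"), auto_unbox = TRUE, digits = NA)
    writeLines(paste(names(counts),
                     vapply(counts, function(x) paste(x, collapse = " "),
                            character(1)), sep = ": "),
               od("log.txt"))
  }
  list(report = report, blend = blend, vc_fit = vc_fit, counts = counts,
       pedigree = ped, marker_sets = sets,
       truth = if (!is.null(sim)) sim$truth)
}
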