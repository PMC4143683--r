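# Synthetic family-study generator: pedigrees, gene-dropped genotypes and
# repeated-measures phenotypes with additive-genetic, permanent-environmental
# and residual components.

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic family study: pedigree structure,
#' founder marker spectrum, causal architecture, variance components of the
#' repeatability model, visit structure and fixed-effect coefficients.
#'
#' Defaults emulate a family study of 20 multi-generation families with around
#' 900 individuals, up to 4 visits each, a founder allele-frequency spectrum
#' straddling the 0.05 minor-allele-frequency boundary, and trait variance
#' components (44.4, 61.5, 135.0) for the additive genetic,
#' permanent-environmental and residual parts (heritability 0.18).
#'
#' @param n_families Number of disjoint families.
#' @param generations Number of non-overlapping generations (>= 2).
#' @param mean_children_per_mating Mean number of children per mating; each
#'   mating has at least one child (1 + Poisson(mean - 1)).
#' @param founder_couples Founder couples per family in generation 1.
#' @param p_mate Probability a child marries (a new founder spouse) and
#'   reproduces in the next generation.
#' @param n_common_markers,n_rare_markers Marker counts per founder MAF class.
#' @param common_maf_range Founder allele-frequency range for common markers,
#'   within [0.05, 0.5].
#' @param rare_maf_range Founder allele-frequency range for rare markers,
#'   within (0, 0.05); frequencies are drawn log-uniformly over this range
#'   (a 1/x site-frequency spectrum).
#' @param n_chromosomes Number of chromosomes markers are spread over.
#' @param n_causal Number of causal markers driving the true breeding values;
#'   0 gives a purely polygenic (pedigree-driven) trait.
#' @param sigma_u2,sigma_c2,sigma_e2 Additive genetic, permanent environmental
#'   and residual variances (trait units squared).
#' @param n_visits Maximum visits per individual (1..4); actual visit counts
#'   are uniform on 1..n_visits.
#' @param covariate_effects Named numeric length-5 vector of fixed-effect
#'   coefficients for year, age, sex, meds, smoking.
#' @param baseline Trait baseline (intercept) added to every record.
#' @param seed Integer seed; every simulation stage derives its stream from it.
#' @return A list of class `famgp_sim_config`.
#' @export
sim_config <- function(n_families = 20,
                       generations = 5,
                       mean_children_per_mating = 2.2,
                       founder_couples = 3,
                       p_mate = 0.5,
                       n_common_markers = 800,
                       n_rare_markers = 2000,
                       common_maf_range = c(0.05, 0.5),
                       rare_maf_range = c(1e-4, 0.05),
                       n_chromosomes = 5,
                       n_causal = 390,
                       sigma_u2 = 44.4,
                       sigma_c2 = 61.5,
                       sigma_e2 = 135.0,
                       n_visits = 4,
                       covariate_effects = c(year = 0.5, age = 0.35, sex = 3.0,
                                             meds = -8.0, smoking = 2.0),
                       baseline = 120,
                       seed = 1L) {
  cfg <- list(n_families = as.integer(n_families),
              generations = as.integer(generations),
              mean_children_per_mating = mean_children_per_mating,
              founder_couples = as.integer(founder_couples),
              p_mate = p_mate,
              n_common_markers = as.integer(n_common_markers),
              n_rare_markers = as.integer(n_rare_markers),
              common_maf_range = common_maf_range,
              rare_maf_range = rare_maf_range,
              n_chromosomes = as.integer(n_chromosomes),
              n_causal = as.integer(n_causal),
              sigma_u2 = sigma_u2, sigma_c2 = sigma_c2, sigma_e2 = sigma_e2,
              n_visits = as.integer(n_visits),
              covariate_effects = covariate_effects,
              baseline = baseline,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "famgp_sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_families < 1L) stop_famgp("n_families must be >= 1")
  if (cfg$generations < 2L) stop_famgp("generations must be >= 2")
  if (cfg$mean_children_per_mating < 1)
    stop_famgp("mean_children_per_mating must be >= 1 so every generation is populated")
  if (cfg$founder_couples < 1L) stop_famgp("founder_couples must be >= 1")
  if (cfg$p_mate <= 0 || cfg$p_mate > 1) stop_famgp("p_mate must be in (0, 1]")
  if (any(c(cfg$sigma_u2, cfg$sigma_c2, cfg$sigma_e2) < 0))
    stop_famgp("variance components must be >= 0")
  if (cfg$n_causal > cfg$n_common_markers + cfg$n_rare_markers)
    stop_famgp("n_causal exceeds the total marker count")
  if (cfg$common_maf_range[1] < 0.05 || cfg$common_maf_range[2] > 0.5)
    stop_famgp("common_maf_range must lie within [0.05, 0.5]")
  if (cfg$rare_maf_range[1] <= 0 || cfg$rare_maf_range[2] > 0.05)
    stop_famgp("rare_maf_range must lie within (0, 0.05]")
  if (cfg$n_visits < 1L || cfg$n_visits > 4L) stop_famgp("n_visits must be 1..4")
  if (length(cfg$covariate_effects) != 5L)
    stop_famgp("covariate_effects must have length 5")
  invisible(cfg)
}

#' Simulate a multi-family, multi-generation pedigree
#'
#' Families are disjoint. Generation 1 holds `founder_couples` founder couples
#' per family; each mating produces 1 + Poisson(mean - 1) children; each child
#' (except in the last generation) marries a newly introduced founder spouse
#' with probability `p_mate`. If a generation would otherwise produce no
#' mating, one child is forced to marry so every generation is populated.
#' Founders (generation-1 members and married-in spouses) have unknown parents,
#' coded 0.
#'
#' @param config A [sim_config()] object.
#' @return Data frame with columns `id`, `sire`, `dam`, `sex` ("M"/"F"),
#'   `family`, `generation`, topologically ordered (parents precede
#'   offspring). Deterministic given `config$seed`.
#' @export
simulate_pedigree <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  G <- config$generations
  rows <- vector("list", 2048L); nrow_used <- 0L
  next_id <- 1L
  add_row <- function(sire, dam, sex, family, generation) {
    nrow_used <<- nrow_used + 1L
    rows[[nrow_used]] <<- list(id = next_id, sire = sire, dam = dam,
                               sex = sex, family = family,
                               generation = generation)
    id <- next_id
    next_id <<- next_id + 1L
    id
  }
  for (fam in seq_len(config$n_families)) {
    # couples: list of c(sire_id, dam_id) whose children belong to gen g+1
    couples <- lapply(seq_len(config$founder_couples), function(i) {
      m <- add_row(0L, 0L, "M", fam, 1L)
      f <- add_row(0L, 0L, "F", fam, 1L)
      c(m, f)
    })
    for (g in 2:G) {
      children <- integer(0)
      child_sex <- character(0)
      for (cp in couples) {
        nk <- 1L + rpois(1L, config$mean_children_per_mating - 1)
        for (k in seq_len(nk)) {
          sx <- if (runif(1) < 0.5) "M" else "F"
          id <- add_row(cp[1], cp[2], sx, fam, g)
          children <- c(children, id)
          child_sex <- c(child_sex, sx)
        }
      }
      if (g == G) break
      marries <- runif(length(children)) < config$p_mate
      if (!any(marries)) marries[sample.int(length(children), 1L)] <- TRUE
      couples <- lapply(which(marries), function(i) {
        spouse_sex <- if (child_sex[i] == "M") "F" else "M"
        sp <- add_row(0L, 0L, spouse_sex, fam, g)
        if (child_sex[i] == "M") c(children[i], sp) else c(sp, children[i])
      })
    }
  }
  ped <- do.call(rbind, lapply(rows[seq_len(nrow_used)], as.data.frame))
  rownames(ped) <- NULL
  ped$sex <- as.character(ped$sex)
  ped
}

# transmit one allele per marker from a parent dosage vector
transmit <- function(dose) {
  out <- integer(length(dose))
  het <- dose == 1L
  out[dose == 2L] <- 1L
  out[het] <- as.integer(runif(sum(het)) < 0.5)
  out
}

#' Gene-drop genotypes down a pedigree
#'
#' Founder allele frequencies are drawn per marker from the configured common
#' and rare ranges; founder genotypes are Binomial(2, p); each offspring
#' receives one allele from each parent, sampled uniformly at random at
#' heterozygous loci (markers are unlinked). Marker positions are laid out
#' over `n_chromosomes` chromosomes with common and rare markers interleaved
#' at random positions.
#'
#' @param pedigree Pedigree data frame from [simulate_pedigree()].
#' @param config A [sim_config()] object.
#' @return A `famgp_geno` object: `dosages` (individuals x markers, rownames =
#'   ids) and `map` (marker id, chrom, pos, founder_maf, class).
#' @export
simulate_genotypes <- function(pedigree, config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  m_common <- config$n_common_markers
  m_rare <- config$n_rare_markers
  m <- m_common + m_rare
  if (m < 1L) stop_famgp("at least one marker is required")
  # common markers: uniform founder frequencies; rare markers: log-uniform
  # (density ~ 1/x, emulating a neutral site-frequency spectrum dominated by
  # very rare alleles; frequencies below the realizable founder minimum come
  # out monomorphic and are dropped downstream, as in sequencing data)
  p <- c(runif(m_common, config$common_maf_range[1], config$common_maf_range[2]),
         exp(runif(m_rare, log(config$rare_maf_range[1]),
                   log(config$rare_maf_range[2]))))
  class_lab <- rep(c("common", "rare"), c(m_common, m_rare))
  # random layout: shuffle markers, then assign chromosomes and sorted positions
  ord <- sample.int(m)
  p <- p[ord]; class_lab <- class_lab[ord]
  chrom <- sort(rep_len(seq_len(config$n_chromosomes), m))
  pos <- unlist(lapply(split(seq_len(m), chrom), function(ix)
    cumsum(sample(100:5000, length(ix), replace = TRUE))), use.names = FALSE)
  map <- data.frame(id = paste0("m", seq_len(m)), chrom = chrom, pos = pos,
                    founder_maf = p, class = class_lab,
                    stringsAsFactors = FALSE)

  n <- nrow(pedigree)
  dos <- matrix(0L, n, m, dimnames = list(as.character(pedigree$id), map$id))
  idx <- match(pedigree$id, pedigree$id)  # identity; ids are row order
  row_of <- seq_len(n); names(row_of) <- as.character(pedigree$id)
  for (i in seq_len(n)) {
    s <- pedigree$sire[i]; d <- pedigree$dam[i]
    if (s == 0L && d == 0L) {
      dos[i, ] <- rbinom(m, 2L, p)
    } else {
      a1 <- if (s == 0L) rbinom(m, 1L, p) else transmit(dos[row_of[[as.character(s)]], ])
      a2 <- if (d == 0L) rbinom(m, 1L, p) else transmit(dos[row_of[[as.character(d)]], ])
      dos[i, ] <- a1 + a2
    }
  }
  new_geno(dos, map)
}

#' Simulate repeated-measures phenotypes under the repeatability model
#'
#' The trait follows y_ij = baseline + sum_k beta_k x_ijk + u_i + c_i + e_ij.
#' True breeding values u are marker-driven: a random subset of `n_causal`
#' markers receives N(0,1) effects, the genetic score is centred and rescaled
#' so its sample variance equals `sigma_u2` (with `n_causal = 0`, u is drawn
#' polygenically from N(0, A sigma_u2)). The permanent-environmental effect
#' c_i ~ N(0, sigma_c2) is drawn once per individual; residuals e_ij ~
#' N(0, sigma_e2) per visit. Visit counts are uniform on 1..n_visits.
#' Covariates: year = visit index; age increases down generations and across
#' visits; sex is taken from the pedigree (M = 1); medication use and smoking
#' are Bernoulli(0.2) per individual.
#'
#' @param pedigree Pedigree data frame.
#' @param genotypes `famgp_geno` covering all pedigree individuals (required
#'   when `n_causal > 0`).
#' @param config A [sim_config()] object.
#' @return List with `phenotypes` (long data frame: id, visit, y, year, age,
#'   sex, meds, smoking) and `truth` (true breeding values, causal marker ids
#'   and effects, and the per-individual c); `truth` is for tests only.
#' @export
simulate_phenotypes <- function(pedigree, genotypes, config) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  n <- nrow(pedigree)
  ids <- as.character(pedigree$id)

  causal_ids <- character(0); causal_eff <- numeric(0)
  u <- numeric(n)
  if (config$sigma_u2 > 0) {
    ok_marker_u <- FALSE
    if (config$n_causal > 0L) {
      M <- dosages(genotypes)
      if (!all(ids %in% rownames(M)))
        stop_famgp("genotypes must cover all pedigree individuals when n_causal > 0")
      M <- M[ids, , drop = FALSE]
      cidx <- sample.int(ncol(M), config$n_causal)
      alpha <- rnorm(config$n_causal)
      score <- drop(M[, cidx, drop = FALSE] %*% alpha)
      if (sd(score) > 1e-10) {
        scl <- sqrt(config$sigma_u2) / sd(score)
        u <- (score - mean(score)) * scl
        causal_ids <- colnames(M)[cidx]
        causal_eff <- alpha * scl
        ok_marker_u <- TRUE
      }
    }
    if (!ok_marker_u) {
      # polygenic fallback: u ~ N(0, A sigma_u2)
      A <- additive_relationship_matrix(pedigree)
      L <- t(chol(A + diag(1e-8, n)))
      u <- drop(L %*% rnorm(n)) * sqrt(config$sigma_u2)
    }
  }
  cc <- rnorm(n, 0, sqrt(config$sigma_c2))
  meds <- rbinom(n, 1L, 0.2)
  smoke <- rbinom(n, 1L, 0.2)
  sexn <- as.integer(pedigree$sex == "M")
  nv <- sample.int(config$n_visits, n, replace = TRUE)

  idx <- rep(seq_len(n), nv)
  visit <- unlist(lapply(nv, seq_len), use.names = FALSE)
  year <- visit
  age <- 20 + 12 * (config$generations - pedigree$generation[idx]) +
    3 * (visit - 1) + round(rnorm(length(idx), 0, 2), 1)
  b <- config$covariate_effects
  e <- rnorm(length(idx), 0, sqrt(config$sigma_e2))
  y <- config$baseline + b[1] * year + b[2] * age + b[3] * sexn[idx] +
    b[4] * meds[idx] + b[5] * smoke[idx] + u[idx] + cc[idx] + e

  phen <- data.frame(id = pedigree$id[idx], visit = visit, y = y,
                     year = year, age = age, sex = sexn[idx],
                     meds = meds[idx], smoking = smoke[idx])
  names(u) <- ids; names(cc) <- ids
  list(phenotypes = phen,
       truth = list(true_breeding_values = u,
                    causal_marker_ids = causal_ids,
                    causal_effects = causal_eff,
                    permanent_env = cc))
}

#' Simulate a complete family study
#'
#' Convenience wrapper running [simulate_pedigree()], [simulate_genotypes()]
#' and [simulate_phenotypes()] under one configuration.
#'
#' @param config A [sim_config()] object.
#' @return List with `pedigree`, `genotypes`, `phenotypes`, `truth`, `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  ped <- simulate_pedigree(config)
  geno <- simulate_genotypes(ped, config)
  ph <- simulate_phenotypes(ped, geno, config)
  list(pedigree = ped, genotypes = geno, phenotypes = ph$phenotypes,
       truth = ph$truth, config = config)
}
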