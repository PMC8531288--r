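# Synthetic-data generators with planted ground truth.
#
# The single-cell generator emulates the statistical structure the pipeline
# assumes: negative-binomial counts over four tumor-progression stages
# (W07/W09/W11/W17), an epithelial and an immune compartment with different
# sequencing depth and mitochondrial-content profiles, marker-defined cell
# types including a stem-like epithelial subpopulation, and a planted cancer
# signature (up-genes multiplied, down-genes divided by a common effect) in
# the cells flagged cancerous. Everything is deterministic given the seed.

#' Build a simulation configuration
#'
#' Returns the default study conditions used throughout the package's tests
#' and the shipped pipeline config; any field can be overridden. Fractions
#' are in [0,1]; means and dispersions are positive. The negative binomial is
#' parameterized by mean and dispersion d with variance mu + mu^2 * d.
#'
#' @param n_genes Number of genes in the universe (mitochondrial genes and
#'   named cross-talk genes included).
#' @param cells_per_stage Named integer vector of cells per stage, in stage
#'   order (default four stages W07/W09/W11/W17).
#' @param epithelial_fraction Per-stage fraction of cells that are
#'   epithelial; the remainder is immune.
#' @param stem_fraction Fraction of epithelial cells that are stem-like.
#' @param cancer_scope Which cells can be cancerous: `"stem"` (stem-like
#'   cells only, the default) or `"epithelial"` (any epithelial cell).
#' @param cancer_fraction_by_stage Per-stage fraction of in-scope cells that
#'   are cancerous.
#' @param signature_effect Multiplicative shift applied to planted up-genes
#'   (and divided into down-genes) in cancer cells.
#' @param n_sig_up,n_sig_down Numbers of planted cancer up/down genes.
#' @param nb_dispersion Negative-binomial dispersion for single-cell counts.
#' @param depth_mean Named vector: mean library size per compartment. Immune
#'   libraries are smaller than epithelial ones by default, which is what
#'   motivates compartment-specific QC.
#' @param depth_sdlog Log-normal sd of per-cell depth around its compartment
#'   mean.
#' @param mito_fraction Named vector: expected fraction of counts from
#'   mitochondrial genes per compartment.
#' @param mito_concentration Beta concentration for per-cell mitochondrial
#'   fraction (larger = tighter around the compartment mean).
#' @param n_mito Number of mitochondrial genes (ids prefixed `mito_prefix`).
#' @param mito_prefix Mitochondrial gene-id prefix; `"mt-"` (mouse
#'   convention, default) or `"MT-"` for human-style ids.
#' @param n_markers Marker genes per cell type.
#' @param marker_fold Fold-change of a marker in its own cell type.
#' @param crosstalk_genes Named list mapping cell-type names to character
#'   vectors of named genes planted as additional markers of that type; used
#'   to plant ligand/receptor structure (default: Cxcl1/Cxcl16 in stem cells,
#'   Cxcr6 in T cells, Cxcr2 in macrophages).
#' @param seed Global seed; per-stage seeds are derived from it.
#' @param ... Further overrides merged into the returned list.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       cells_per_stage = c(W07 = 120, W09 = 120, W11 = 120, W17 = 120),
                       epithelial_fraction = c(W07 = 0.60, W09 = 0.60, W11 = 0.65, W17 = 0.70),
                       stem_fraction = 0.15,
                       cancer_scope = c("stem", "epithelial"),
                       cancer_fraction_by_stage = c(W07 = 0.10, W09 = 0.30, W11 = 0.60, W17 = 0.90),
                       signature_effect = 8,
                       n_sig_up = 60,
                       n_sig_down = 40,
                       nb_dispersion = 0.3,
                       depth_mean = c(epithelial = 20000, immune = 4000),
                       depth_sdlog = 0.35,
                       mito_fraction = c(epithelial = 0.04, immune = 0.05),
                       mito_concentration = 60,
                       n_mito = 10,
                       mito_prefix = "mt-",
                       n_markers = 40,
                       marker_fold = 6,
                       crosstalk_genes = list(
                         stem = c("Cxcl1", "Cxcl16"),
                         tcell = "Cxcr6",
                         macrophage = "Cxcr2"),
                       seed = 1,
                       ...) {
  cfg <- list(
    n_genes = n_genes,
    cells_per_stage = cells_per_stage,
    epithelial_fraction = epithelial_fraction,
    stem_fraction = stem_fraction,
    cancer_scope = match.arg(cancer_scope),
    cancer_fraction_by_stage = cancer_fraction_by_stage,
    signature_effect = signature_effect,
    n_sig_up = n_sig_up,
    n_sig_down = n_sig_down,
    nb_dispersion = nb_dispersion,
    depth_mean = depth_mean,
    depth_sdlog = depth_sdlog,
    mito_fraction = mito_fraction,
    mito_concentration = mito_concentration,
    n_mito = n_mito,
    mito_prefix = mito_prefix,
    n_markers = n_markers,
    marker_fold = marker_fold,
    crosstalk_genes = crosstalk_genes,
    seed = seed)
  extra <- list(...)
  cfg[names(extra)] <- extra
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @keywords internal
#' @noRd
validate_sim_config <- function(cfg) {
  fr <- c(cfg$epithelial_fraction, cfg$stem_fraction, cfg$cancer_fraction_by_stage,
          cfg$mito_fraction)
  if (any(fr < 0 | fr > 1)) stopf("sim_config: all fractions must be in [0,1]")
  pos <- c(cfg$signature_effect, cfg$nb_dispersion, cfg$depth_mean,
           cfg$depth_sdlog, cfg$mito_concentration, cfg$marker_fold)
  if (any(pos <= 0)) stopf("sim_config: means, effects and dispersions must be > 0")
  n_named <- length(unlist(cfg$crosstalk_genes))
  if (cfg$n_genes - cfg$n_mito - n_named <
      5 * cfg$n_markers + cfg$n_sig_up + cfg$n_sig_down) {
    stopf("sim_config: n_genes too small for the configured marker/signature/mito sets")
  }
  stages <- names(cfg$cells_per_stage)
  if (is.null(stages) || anyDuplicated(stages)) stopf("sim_config: cells_per_stage must be uniquely named by stage")
  for (f in c("epithelial_fraction", "cancer_fraction_by_stage")) {
    if (!all(stages %in% names(cfg[[f]]))) stopf("sim_config: %s must name every stage", f)
  }
  invisible(cfg)
}

# Cell types: three epithelial (luminal, basal, stem) and two immune
# (tcell, macrophage). Marker blocks are disjoint gene slices.
#' @keywords internal
#' @noRd
sim_gene_plan <- function(cfg) {
  types <- data.frame(
    name = c("luminal", "basal", "stem", "tcell", "macrophage"),
    compartment = c("epithelial", "epithelial", "epithelial", "immune", "immune"),
    stringsAsFactors = FALSE)
  n_named <- length(unlist(cfg$crosstalk_genes))
  n_plain <- cfg$n_genes - cfg$n_mito - n_named
  genes <- c(sprintf("g%05d", seq_len(n_plain)),
             unlist(cfg$crosstalk_genes, use.names = FALSE),
             paste0(cfg$mito_prefix, seq_len(cfg$n_mito)))
  mito <- genes[(cfg$n_genes - cfg$n_mito + 1):cfg$n_genes]
  markers <- list()
  at <- 1L
  for (ty in types$name) {
    mk <- genes[at:(at + cfg$n_markers - 1L)]
    at <- at + cfg$n_markers
    extra <- cfg$crosstalk_genes[[ty]]
    markers[[ty]] <- c(mk, extra)
  }
  sig_up <- if (cfg$n_sig_up > 0) genes[at:(at + cfg$n_sig_up - 1L)] else character()
  sig_dn <- if (cfg$n_sig_down > 0) {
    genes[(at + cfg$n_sig_up):(at + cfg$n_sig_up + cfg$n_sig_down - 1L)]
  } else character()
  list(genes = genes, mito = mito, types = types, markers = markers,
       sig_up = sig_up, sig_dn = sig_dn)
}

#' Simulate a staged single-cell count matrix with planted ground truth
#'
#' Draws negative-binomial counts for four progression stages with an
#' epithelial and an immune compartment, marker-defined cell types including
#' a stem-like epithelial subpopulation, compartment-specific library sizes
#' and mitochondrial fractions, and a planted cancer signature in the cells
#' flagged cancerous. Each stage is generated under its own derived seed, so
#' the whole object is reproducible from the global seed.
#'
#' @param config A [sim_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{counts}{sparse gene-by-cell count matrix}
#'     \item{cells}{data.frame of per-cell annotations (cell_id, stage,
#'       compartment)}
#'     \item{truth}{planted ground truth: per-cell data.frame (`cells` plus
#'       cell_type, stem and cancer flags), the planted cancer
#'       [gene_signature()], per-type marker lists, and mito gene ids}
#'   }
#' @export
simulate_single_cell <- function(config) {
  validate_sim_config(config)
  plan <- sim_gene_plan(config)
  stages <- names(config$cells_per_stage)

  set.seed(child_seed(config$seed, 0L))
  base_mean <- stats::rlnorm(config$n_genes, meanlog = 0, sdlog = 1)
  names(base_mean) <- plan$genes
  # marker genes are, by definition, well detected in their cell type:
  # floor their baseline at the universe median so the planted fold-change
  # is visible above sampling noise
  marker_ids <- unique(unlist(plan$markers, use.names = FALSE))
  base_mean[marker_ids] <- pmax(base_mean[marker_ids], stats::median(base_mean))
  mito_w <- base_mean[plan$mito] / sum(base_mean[plan$mito])

  all_counts <- vector("list", length(stages))
  all_cells <- vector("list", length(stages))
  for (si in seq_along(stages)) {
    st <- stages[si]
    set.seed(child_seed(config$seed, si))
    n <- config$cells_per_stage[[st]]
    n_epi <- round(n * config$epithelial_fraction[[st]])
    comp <- c(rep("epithelial", n_epi), rep("immune", n - n_epi))

    ct <- character(n)
    epi_idx <- which(comp == "epithelial")
    n_stem <- round(length(epi_idx) * config$stem_fraction)
    stem_idx <- if (n_stem > 0) sample(epi_idx, n_stem) else integer()
    rest <- setdiff(epi_idx, stem_idx)
    n_bas <- round(length(rest) * 0.3)
    bas_idx <- if (n_bas > 0) sample(rest, n_bas) else integer()
    ct[stem_idx] <- "stem"
    ct[bas_idx] <- "basal"
    ct[setdiff(rest, bas_idx)] <- "luminal"
    imm_idx <- which(comp == "immune")
    n_mac <- round(length(imm_idx) * 0.4)
    mac_idx <- if (n_mac > 0) sample(imm_idx, n_mac) else integer()
    ct[mac_idx] <- "macrophage"
    ct[setdiff(imm_idx, mac_idx)] <- "tcell"

    scope_idx <- if (config$cancer_scope == "stem") stem_idx else epi_idx
    n_can <- round(length(scope_idx) * config$cancer_fraction_by_stage[[st]])
    can_idx <- if (n_can > 0) sample(scope_idx, n_can) else integer()
    cancer <- seq_len(n) %in% can_idx

    depth <- stats::rlnorm(n,
      meanlog = log(config$depth_mean[comp]) - config$depth_sdlog^2 / 2,
      sdlog = config$depth_sdlog)
    mf_mean <- config$mito_fraction[comp]
    mito_frac <- stats::rbeta(n,
      shape1 = mf_mean * config$mito_concentration,
      shape2 = (1 - mf_mean) * config$mito_concentration)

    mu <- matrix(base_mean, nrow = config$n_genes, ncol = n,
                 dimnames = list(plan$genes, NULL))
    for (ty in plan$types$name) {
      cols <- which(ct == ty)
      if (length(cols)) mu[plan$markers[[ty]], cols] <- mu[plan$markers[[ty]], cols] * config$marker_fold
    }
    if (any(cancer)) {
      mu[plan$sig_up, cancer] <- mu[plan$sig_up, cancer] * config$signature_effect
      mu[plan$sig_dn, cancer] <- mu[plan$sig_dn, cancer] / config$signature_effect
    }
    # Allocate each cell's expected depth: mito genes get mito_frac of it,
    # the rest is shared by the non-mito genes in proportion to mu.
    non_mito <- setdiff(plan$genes, plan$mito)
    col_tot <- colSums(mu[non_mito, , drop = FALSE])
    mu[non_mito, ] <- sweep(mu[non_mito, , drop = FALSE], 2,
                            depth * (1 - mito_frac) / col_tot, `*`)
    mu[plan$mito, ] <- outer(mito_w, depth * mito_frac)

    counts <- matrix(
      stats::rnbinom(length(mu), mu = as.vector(mu), size = 1 / config$nb_dispersion),
      nrow = config$n_genes)
    cell_ids <- sprintf("%s_c%04d", st, seq_len(n))
    dimnames(counts) <- list(plan$genes, cell_ids)
    all_counts[[si]] <- as_dgc(counts)
    all_cells[[si]] <- data.frame(
      cell_id = cell_ids, stage = st, compartment = comp, cell_type = ct,
      stem = ct == "stem", cancer = cancer, stringsAsFactors = FALSE)
  }

  counts <- do.call(cbind, all_counts)
  truth_cells <- do.call(rbind, all_cells)
  rownames(truth_cells) <- NULL
  cells <- truth_cells[, c("cell_id", "stage", "compartment")]
  sd_log("simulated %d genes x %d cells over %d stages",
         nrow(counts), ncol(counts), length(stages))
  list(counts = counts,
       cells = cells,
       truth = list(cells = truth_cells,
                    signature = gene_signature("planted_cancer",
                                               plan$sig_up, plan$sig_dn),
                    markers = plan$markers,
                    mito_genes = plan$mito))
}

#' Simulate a tumor-vs-normal bulk RNA-seq count table
#'
#' Negative-binomial replicate counts over the same gene universe as
#' [simulate_single_cell()], with the planted cancer up-genes multiplied (and
#' down-genes divided) by `fold_change` in the tumor group. A fold change of
#' 1 plants nothing and the recorded truth lists are empty.
#'
#' @param config A [sim_config()]; its planted signature genes and seed are
#'   reused so bulk and single-cell objects share ground truth.
#' @param n_per_group Replicates per group (>= 2).
#' @param fold_change Tumor-vs-normal fold change for the planted genes.
#' @param dispersion Negative-binomial dispersion for bulk counts.
#' @param lib_size Mean library size per replicate.
#' @return A list: `counts` (gene-by-sample matrix), `groups` (named vector,
#'   `"tumor"`/`"normal"`), and `truth` (planted up/down gene ids).
#' @export
simulate_bulk <- function(config, n_per_group = 3, fold_change = 4,
                          dispersion = 0.05, lib_size = 1e6) {
  validate_sim_config(config)
  if (n_per_group < 2) stopf("simulate_bulk: need >= 2 replicates per group")
  if (fold_change <= 0 || dispersion <= 0) stopf("simulate_bulk: fold_change and dispersion must be > 0")
  plan <- sim_gene_plan(config)
  set.seed(child_seed(config$seed, 101L))
  base_mean <- stats::rlnorm(config$n_genes, meanlog = 0, sdlog = 1)
  names(base_mean) <- plan$genes

  planted <- fold_change != 1
  groups <- c(rep("normal", n_per_group), rep("tumor", n_per_group))
  sample_ids <- sprintf("%s_%d", groups, c(seq_len(n_per_group), seq_len(n_per_group)))
  mu <- matrix(base_mean, nrow = config$n_genes, ncol = length(groups),
               dimnames = list(plan$genes, sample_ids))
  if (planted) {
    tum <- groups == "tumor"
    mu[plan$sig_up, tum] <- mu[plan$sig_up, tum] * fold_change
    mu[plan$sig_dn, tum] <- mu[plan$sig_dn, tum] / fold_change
  }
  depth <- stats::rlnorm(length(groups), meanlog = log(lib_size) - 0.1^2 / 2, sdlog = 0.1)
  mu <- sweep(mu, 2, depth / colSums(mu), `*`)
  counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu), size = 1 / dispersion),
                   nrow = config$n_genes, dimnames = dimnames(mu))
  names(groups) <- sample_ids
  list(counts = counts,
       groups = groups,
       truth = list(up = if (planted) plan$sig_up else character(),
                    down = if (planted) plan$sig_dn else character()))
}

#' Simulate a survival cohort with signature-dependent hazard
#'
#' Subjects are split into a high- and a low-expression group; high-group
#' subjects have their signature genes shifted upward in the expression
#' matrix and their exponential event hazard multiplied by `hazard_ratio`.
#' Censoring times are independent exponentials with rate
#' `censor_rate * baseline_hazard`, so `censor_rate` is the censoring
#' intensity relative to the baseline event hazard (0 disables censoring).
#'
#' @param n_subjects Number of subjects (>= 4).
#' @param hazard_ratio Event-hazard multiplier for the high-expression group.
#' @param censor_rate Censoring intensity relative to baseline hazard (>= 0).
#' @param seed Seed.
#' @param n_genes Number of signature genes in the expression matrix.
#' @param baseline_hazard Exponential event rate in the low group.
#' @param effect_size Mean expression shift of signature genes in the high
#'   group (units of within-gene sd).
#' @return A list: `cohort` (subject_id, time, event, group — the planted
#'   group), `expression` (gene-by-subject matrix), `signature` (the planted
#'   up-gene [gene_signature()]).
#' @export
simulate_cohort <- function(n_subjects, hazard_ratio = 3, censor_rate = 0.2,
                            seed = 1, n_genes = 20, baseline_hazard = 0.1,
                            effect_size = 2) {
  if (n_subjects < 4) stopf("simulate_cohort: need n_subjects >= 4")
  if (hazard_ratio <= 0) stopf("simulate_cohort: hazard_ratio must be > 0")
  if (censor_rate < 0) stopf("simulate_cohort: censor_rate must be >= 0")
  set.seed(child_seed(seed, 202L))
  high <- sample(c(rep(TRUE, floor(n_subjects / 2)),
                   rep(FALSE, ceiling(n_subjects / 2))))
  subj <- sprintf("s%04d", seq_len(n_subjects))
  genes <- sprintf("survgene%03d", seq_len(n_genes))
  expr <- matrix(stats::rnorm(n_genes * n_subjects, mean = 5, sd = 1),
                 nrow = n_genes, dimnames = list(genes, subj))
  expr[, high] <- expr[, high] + effect_size

  rate <- baseline_hazard * ifelse(high, hazard_ratio, 1)
  t_event <- stats::rexp(n_subjects, rate = rate)
  if (censor_rate > 0) {
    t_cens <- stats::rexp(n_subjects, rate = censor_rate * baseline_hazard)
  } else {
    t_cens <- rep(Inf, n_subjects)
  }
  cohort <- data.frame(
    subject_id = subj,
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    group = ifelse(high, "high", "low"),
    stringsAsFactors = FALSE)
  list(cohort = cohort,
       expression = expr,
       signature = gene_signature("planted_survival", genes))
}
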