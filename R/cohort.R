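# Synthetic lymphoma cohort generator: plants spot-like co-expression
# modules with subtype-specific activation on a log2 additive Gaussian model,
# x[g,s] = mu_g + a~[s, m(g)] * e_m + eps, where a~ adds per-sample activation
# jitter (the continuum between subtypes) to the subtype activation row.

# Case counts of the ten lymphoma strata (DLBCL further split into its
# cell-of-origin groups GCB/ABC/unclassified plus DHL; together 430).
mmml_strata_counts_fine <- c(
  BL = 74L, DLBCL_GCB = 142L, DLBCL_ABC = 133L, DLBCL_unc = 97L, DHL = 58L,
  FL = 145L, Intermediate = 81L, FL_DLBCL = 48L, PMBL = 23L, MM = 20L,
  IRF4_LCL = 10L, mnBLL_11q = 6L, MCL = 4L)

# Planted module letters (J unused, matching the A..K spot lettering) and
# default module gene counts; D and E bracket the printed spot-size range.
mmml_module_sizes <- c(A = 600L, B = 400L, C = 200L, D = 1154L, E = 129L,
                       F = 500L, G = 300L, H = 250L, I = 350L, K = 200L)

# Subtype activation of the planted modules. Signs follow the spot
# expression pattern of the lymphoma landscape (BL up in A/B/D and down in
# F/G; DLBCL up in F/G and weakly in D, its proliferative face; ABC up in H;
# GCB weakly up in A; DHL up in A, down in F; FL up in I and weakly in A).
# Magnitudes (1.0 primary, 0.5 secondary/shared) are calibrated so that,
# after per-gene centering, every module's tallest group-mean bump lies in a
# common band (~0.6-1.0 log2 units) and module profiles are pairwise
# separable relative to the measurement noise.
mmml_activation <- function() {
  strata <- names(mmml_strata_counts_fine)
  mods <- names(mmml_module_sizes)
  a <- matrix(0, length(strata), length(mods), dimnames = list(strata, mods))
  a["BL", c("A", "B", "D", "F", "G")]    <- c(0.5, 1, 1, -1, -1)
  a["DLBCL_GCB", c("A", "D", "F", "G")]  <- c(0.5, 0.5, 1, 1)
  a["DLBCL_ABC", c("D", "F", "G", "H")]  <- c(0.5, 1, 1, 1)
  a["DLBCL_unc", c("D", "F", "G")]       <- c(0.5, 1, 1)
  a["DHL", c("A", "F")]                  <- c(1, -1)
  a["FL", c("A", "I")]                   <- c(0.5, 1)
  a["Intermediate", ] <- 0.5 * a["BL", ] + 0.5 * a["DLBCL_unc", ]
  a["FL_DLBCL", ]     <- 0.5 * a["FL", ] + 0.5 * a["DLBCL_unc", ]
  a["PMBL", "C"]                         <- 1
  a["MM", "H"]                           <- 1
  a["IRF4_LCL", c("H", "K")]             <- c(0.5, 1)
  a["mnBLL_11q", ]    <- a["BL", ]
  a["MCL", "E"]                          <- 1
  a
}

#' Specify a synthetic cohort
#'
#' Defines the strata, planted co-expression modules, activation pattern and
#' noise model of a synthetic expression cohort. The activation matrix entry
#' `a[subtype, module]` in `[-1, 1]` gives the sign and strength of the
#' module in that subtype; each sample draws its own realized activation
#' `a + N(0, sigma_act^2)` per module, which blurs the borders between
#' subtypes into a continuum.
#'
#' @param strata_counts named positive integer vector of samples per subtype.
#' @param activation numeric matrix, subtypes x modules, entries in `[-1, 1]`;
#'   row names must cover all strata.
#' @param module_sizes named positive integer vector (>= 10) of genes per
#'   planted module; module gene sets are pairwise disjoint.
#' @param module_effects module effect sizes in log2 units; recycled.
#' @param sigma_act per-sample activation jitter sd.
#' @param sigma_eps per-entry Gaussian measurement noise sd (log2 units).
#' @param background_genes number of genes with no module term.
#' @param baseline_mean,baseline_sd distribution of per-gene baselines mu_g.
#' @param seed integer seed driving all randomness of the generator.
#' @return an object of class `CohortSpec`.
#' @export
cohort_spec <- function(strata_counts, activation, module_sizes,
                        module_effects = 1, sigma_act = 0.15,
                        sigma_eps = 0.5, background_genes = 4000L,
                        baseline_mean = 8, baseline_sd = 1, seed = 1L) {
  strata_counts <- stats::setNames(as.integer(strata_counts),
                                   names(strata_counts))
  module_sizes <- stats::setNames(as.integer(module_sizes),
                                  names(module_sizes))
  if (is.null(names(strata_counts)) || anyDuplicated(names(strata_counts)))
    stop("strata must be uniquely named")
  if (any(strata_counts <= 0)) stop("all strata counts must be positive")
  if (is.null(names(module_sizes)) || anyDuplicated(names(module_sizes)))
    stop("module letters must be unique")
  if (any(module_sizes < 10L)) stop("module gene counts must be >= 10")
  if (sigma_act < 0 || sigma_eps < 0) stop("noise sds must be >= 0")
  if (!all(names(strata_counts) %in% rownames(activation)))
    stop("activation matrix rows must cover all strata")
  if (!all(names(module_sizes) %in% colnames(activation)))
    stop("activation matrix columns must cover all modules")
  if (any(abs(activation) > 1)) stop("activation entries must lie in [-1, 1]")
  activation <- activation[names(strata_counts), names(module_sizes),
                           drop = FALSE]
  effects <- rep_len(as.numeric(module_effects), length(module_sizes))
  names(effects) <- names(module_sizes)
  structure(list(strata_counts = strata_counts, activation = activation,
                 module_sizes = module_sizes, module_effects = effects,
                 sigma_act = sigma_act, sigma_eps = sigma_eps,
                 background_genes = as.integer(background_genes),
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 seed = as.integer(seed)),
            class = "CohortSpec")
}

#' Default synthetic cohort emulating the MMML lymphoma strata
#'
#' Strata proportions follow the printed case counts of the ten lymphoma
#' strata (with DLBCL split into GCB/ABC/unclassified/DHL), scaled to
#' `total_samples` by largest-remainder apportionment; at the native total of
#' 841 listed cases the printed counts are reproduced exactly. Ten modules
#' A-K (J unused) are planted with subtype activation following the
#' spot-expression pattern of the lymphoma landscape: BL up in B, D (and
#' weakly A), down in F and G; DLBCL up in F, G and weakly in D (its
#' proliferative face); ABC up in H; GCB weakly up in A; DHL up in A, down
#' in F; FL up in I and weakly in A; see `mmml_activation` in the source for
#' the full matrix and the calibration rationale.
#'
#' @param total_samples cohort size; strata are scaled proportionally.
#' @param seed integer seed.
#' @param ... overrides passed to [cohort_spec()] (e.g. `sigma_eps`,
#'   `background_genes`).
#' @return a `CohortSpec`.
#' @export
default_mmml_spec <- function(total_samples = 300L, seed = 1L, ...) {
  counts <- apportion_counts(mmml_strata_counts_fine, total_samples)
  cohort_spec(strata_counts = counts, activation = mmml_activation(),
              module_sizes = mmml_module_sizes, seed = seed, ...)
}

#' Generate a synthetic expression cohort
#'
#' Draws `x[g,s] = mu_g + a~[s, m(g)] * e_m + eps` on log2 scale with
#' `mu_g ~ N(baseline_mean, baseline_sd^2)`, realized activation
#' `a~[s, m] = a[subtype(s), m] + N(0, sigma_act^2)` and measurement noise
#' `eps ~ N(0, sigma_eps^2)`; background genes carry no module term. All
#' randomness derives from `spec$seed`, so identical specs give identical
#' cohorts.
#'
#' @param spec a [cohort_spec()].
#' @return a list with elements `expression` (an [expression_matrix()] with
#'   subtype labels) and `truth` (a `CohortTruth`: `module` maps each gene to
#'   its module letter or `"background"`, `activation` holds the realized
#'   samples x modules activation, `labels` the subtype labels).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  set.seed(spec$seed)
  n_mod_genes <- sum(spec$module_sizes)
  n_genes <- n_mod_genes + spec$background_genes
  gene_idv <- sprintf("g%05d", seq_len(n_genes))
  module_of <- stats::setNames(
    c(rep(names(spec$module_sizes), spec$module_sizes),
      rep("background", spec$background_genes)), gene_idv)

  labels <- rep(names(spec$strata_counts), spec$strata_counts)
  n_samples <- length(labels)
  sample_idv <- sprintf("s%04d", seq_len(n_samples))
  names(labels) <- sample_idv

  mu <- stats::rnorm(n_genes, spec$baseline_mean, spec$baseline_sd)
  act <- spec$activation[labels, , drop = FALSE] +
    matrix(stats::rnorm(n_samples * ncol(spec$activation), 0, spec$sigma_act),
           n_samples, ncol(spec$activation))
  dimnames(act) <- list(sample_idv, colnames(spec$activation))

  x <- matrix(stats::rnorm(n_genes * n_samples, 0, spec$sigma_eps),
              n_genes, n_samples, dimnames = list(gene_idv, sample_idv))
  x <- x + mu
  for (m in names(spec$module_sizes)) {
    rows <- which(module_of == m)
    x[rows, ] <- x[rows, ] +
      rep(act[, m] * spec$module_effects[[m]], each = length(rows))
  }
  truth <- structure(list(module = module_of, activation = act,
                          labels = labels), class = "CohortTruth")
  list(expression = expression_matrix(x, sample_labels = labels),
       truth = truth)
}

#' Module gene sets of a cohort truth
#'
#' @param truth a `CohortTruth` from [generate_cohort()].
#' @return named list of gene id vectors, one per planted module.
#' @export
truth_module_genes <- function(truth) {
  mods <- setdiff(unique(truth$module), "background")
  stats::setNames(lapply(mods, function(m) names(truth$module)[truth$module == m]),
                  mods)
}

# Emulated literature classifier sets: name, printed size, source module.
default_signature_specs <- function() {
  data.frame(
    name = c("hummel_BL_up", "hummel_DLBCL_up", "sha_BL_up", "sha_DLBCL_up",
             "masque_BL_up", "masque_DLBCL_up", "masque_ABC_up",
             "masque_GCB_up", "scott_ABC_up", "scott_GCB_up", "wright_ABC_up",
             "wright_GCB_up", "ennishi_DHL_up", "ennishi_nonDHL_up"),
    size = c(47L, 18L, 16L, 11L, 6L, 4L, 9L, 11L, 7L, 6L, 13L, 7L, 31L, 47L),
    module = c("B", "F", "B", "F", "B", "F", "H", "A", "H", "A", "H", "A",
               "A", "F"),
    stringsAsFactors = FALSE)
}

#' Emulate literature classifier signatures from planted modules
#'
#' Each emulated signature draws `(1 - decoy_fraction) * size` genes from its
#' source module and the remainder from background genes, without
#' replacement. The default roster reproduces the printed cardinalities of
#' the literature classifier sets (e.g. BL_up sets of 47, 16 and 6 genes all
#' drawn from module B), so that sets targeting the same subtype overlap only
#' partially, as the published classifiers do.
#'
#' @param truth a `CohortTruth`.
#' @param sizes named integer vector of signature sizes; defaults to the
#'   literature roster.
#' @param sources named character vector mapping signature name to source
#'   module letter; required when `sizes` is not the default roster.
#' @param decoy_fraction fraction of each set drawn from background genes,
#'   in `[0, 0.5)`.
#' @param seed integer seed.
#' @return named list of [signature()] objects.
#' @export
make_reference_signatures <- function(truth, sizes = NULL, sources = NULL,
                                      decoy_fraction = 0.1, seed = 1L) {
  stopifnot(inherits(truth, "CohortTruth"))
  if (decoy_fraction < 0 || decoy_fraction >= 0.5)
    stop("decoy_fraction must lie in [0, 0.5)")
  if (is.null(sizes)) {
    roster <- default_signature_specs()
    sizes <- stats::setNames(roster$size, roster$name)
    sources <- stats::setNames(roster$module, roster$name)
  }
  if (is.null(sources) || !all(names(sizes) %in% names(sources)))
    stop("`sources` must name a source module for every signature")
  mod_genes <- truth_module_genes(truth)
  background <- names(truth$module)[truth$module == "background"]
  set.seed(seed)
  sigs <- lapply(names(sizes), function(nm) {
    size <- sizes[[nm]]
    src <- sources[[nm]]
    if (!src %in% names(mod_genes)) stop("unknown source module: ", src)
    n_core <- ceiling((1 - decoy_fraction) * size)
    n_decoy <- size - n_core
    if (n_core > length(mod_genes[[src]]))
      stop(sprintf("signature %s requests %d genes but module %s has %d",
                   nm, n_core, src, length(mod_genes[[src]])))
    genes <- c(sample(mod_genes[[src]], n_core),
               if (n_decoy > 0) sample(background, n_decoy))
    signature(nm, genes, direction = "up",
              provenance = sprintf("emulated from module %s", src))
  })
  stats::setNames(sigs, names(sizes))
}

#' Label groups for the standard two-group contrasts
#'
#' The coarse contrast groups used throughout: `BL` is the BL stratum,
#' `DLBCL` the three cell-of-origin DLBCL strata (DHL kept separate, as the
#' DHL contrast treats it as its own entity), `ABC`/`GCB` the respective COO
#' strata, `DHL` the double-hit stratum and `nonDHL_DLBCL` = GCB + ABC.
#'
#' @return named list of character vectors of stratum labels.
#' @export
mmml_contrasts <- function() {
  list(BL = "BL",
       DLBCL = c("DLBCL_GCB", "DLBCL_ABC", "DLBCL_unc"),
       ABC = "DLBCL_ABC",
       GCB = "DLBCL_GCB",
       DHL = "DHL",
       nonDHL_DLBCL = c("DLBCL_GCB", "DLBCL_ABC"))
}
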