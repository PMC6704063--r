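#' Specification for the synthetic tumor-microenvironment generator
#'
#' Collects and validates all parameters of [generate()]. The defaults
#' describe a small but structurally realistic tumor microenvironment:
#' several non-malignant cell types plus a malignant population split
#' across tumors, patient-specific expression shifts confined to the
#' malignant cells, pathway up-regulation planted in chosen cell types, a
#' shared per-cell latent factor (a "hypoxia"-like axis) loading on named
#' gene programs, expression-dependent dropout (low expression drops out
#' more often, on a logistic curve), and per-cell library-size variation.
#'
#' @param n_genes number of genes (default 1000).
#' @param set_sizes sizes of the generated gene sets (default 20 sets of
#'   25 genes); sets are disjoint blocks unless `set_overlap` > 0.
#' @param set_overlap number of genes shared between consecutive sets
#'   (default 0).
#' @param cell_types named integer vector of cells per type; names are the
#'   type labels (default 250 malignant, 150 T cells, 100 B cells, 100
#'   macrophages).
#' @param malignant_types which cell types carry the malignant flag.
#' @param n_tumors number of tumors; every cell is assigned a tumor of
#'   origin uniformly at random (default 2).
#' @param planted_effects data.frame with columns `pathway`, `cell_type`,
#'   `log2fc`: additive log2 fold-changes applied to the pathway's genes
#'   in the target cell type (default none).
#' @param tumor_effect_sd sd (log2 units) of tumor-specific shifts applied
#'   to a random `tumor_effect_frac` of genes in malignant cells only
#'   (default 0.5).
#' @param tumor_effect_frac fraction of genes receiving a tumor shift
#'   (default 0.2).
#' @param latent_loadings named numeric vector: log2-scale loading of each
#'   named gene set on the standard-normal per-cell latent factor
#'   (default none).
#' @param set_noise_mult named numeric vector: multiplier on `noise_sd`
#'   for the member genes of the named sets, planting gene sets whose
#'   genes carry more (or less) independent expression variance than the
#'   rest (default none).
#' @param dropout list(midpoint, slope) of the logistic dropout curve on
#'   log2 expression — P(zero) = plogis(slope * (midpoint - x)) — or NULL
#'   for no dropout (default midpoint 1, slope 1).
#' @param library_size_sd sd of per-cell log-normal library scaling
#'   (default 0.3).
#' @param base_mean,base_sd mean/sd of per-gene baseline log2 expression
#'   (LogNormal base expression; defaults 1.5 and 1.5).
#' @param noise_sd per-cell log2 expression noise sd (default 1).
#' @param tpm_normalize renormalize every cell to a TPM column sum of 1e6
#'   (default TRUE; FALSE keeps raw expression for exact-recovery checks).
#' @param seed RNG seed (default 1).
#' @return a validated `simulation_spec` list.
#' @export
simulation_spec <- function(n_genes = 1000,
                            set_sizes = rep(25L, 20L),
                            set_overlap = 0L,
                            cell_types = c(malignant = 250L, Tcell = 150L,
                                           Bcell = 100L, Macrophage = 100L),
                            malignant_types = "malignant",
                            n_tumors = 2L,
                            planted_effects = NULL,
                            tumor_effect_sd = 0.5,
                            tumor_effect_frac = 0.2,
                            latent_loadings = NULL,
                            set_noise_mult = NULL,
                            dropout = list(midpoint = 1, slope = 1),
                            library_size_sd = 0.3,
                            base_mean = 1.5, base_sd = 1.5,
                            noise_sd = 1,
                            tpm_normalize = TRUE,
                            seed = 1) {
  if (any(cell_types < 1L)) stop("cell type counts must be >= 1")
  if (is.null(names(cell_types))) stop("cell_types must be named")
  need <- sum(set_sizes) - set_overlap * max(0L, length(set_sizes) - 1L)
  if (need > n_genes)
    stop("gene sets need ", need, " genes but n_genes = ", n_genes)
  if (!is.null(planted_effects)) {
    stopifnot(all(c("pathway", "cell_type", "log2fc") %in%
                    names(planted_effects)))
    if (any(!is.finite(planted_effects$log2fc)))
      stop("planted fold-changes must be finite")
    if (any(!planted_effects$cell_type %in% names(cell_types)))
      stop("planted effect targets unknown cell type")
  }
  if (!is.null(dropout)) {
    stopifnot(is.list(dropout), all(c("midpoint", "slope") %in%
                                      names(dropout)))
    if (dropout$slope < 0) stop("dropout slope must be >= 0")
  }
  spec <- list(n_genes = as.integer(n_genes), set_sizes = set_sizes,
               set_overlap = as.integer(set_overlap),
               cell_types = cell_types, malignant_types = malignant_types,
               n_tumors = as.integer(n_tumors),
               planted_effects = planted_effects,
               tumor_effect_sd = tumor_effect_sd,
               tumor_effect_frac = tumor_effect_frac,
               latent_loadings = latent_loadings,
               set_noise_mult = set_noise_mult, dropout = dropout,
               library_size_sd = library_size_sd, base_mean = base_mean,
               base_sd = base_sd, noise_sd = noise_sd,
               tpm_normalize = tpm_normalize, seed = as.integer(seed))
  class(spec) <- "simulation_spec"
  spec
}

#' Generate a synthetic tumor-microenvironment dataset
#'
#' Draws a gene x cell log2(TPM + 1) matrix with the structure described
#' by a [simulation_spec()], together with the matching cell annotation,
#' gene sets, and a truth record holding every planted parameter. Fully
#' reproducible given the spec's seed.
#'
#' Generation order: per-gene LogNormal baseline; i.i.d. per-cell log2
#' noise; planted pathway effects; tumor-specific shifts (malignant cells
#' only, on a random gene subset per tumor); the latent factor's
#' contribution to loaded sets; un-log to expression scale; per-cell
#' library scaling; expression-dependent dropout; TPM renormalization;
#' log2(TPM + 1).
#'
#' @param spec a [simulation_spec()].
#' @return list with `matrix` ([expression_matrix()], `log2tpm1`),
#'   `annotation`, `gene_sets`, `lengths` (synthetic
#'   [gene_length_table()]) and `truth` (planted parameters: baseline,
#'   latent factor values, library factors, tumor shifts, the spec).
#' @export
generate <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  n_genes <- spec$n_genes
  genes <- sprintf("G%04d", seq_len(n_genes))

  # gene sets as (optionally overlapping) blocks
  sets <- list()
  pos <- 1L
  for (s in seq_along(spec$set_sizes)) {
    sz <- spec$set_sizes[s]
    sets[[sprintf("PATHWAY_%02d", s)]] <- genes[pos:(pos + sz - 1L)]
    pos <- pos + sz - spec$set_overlap
  }
  gene_sets <- gene_set_collection(sets)

  # cells, types, tumors
  n_cells <- sum(spec$cell_types)
  cells <- sprintf("C%05d", seq_len(n_cells))
  type <- rep(names(spec$cell_types), times = spec$cell_types)
  tumor <- sample(sprintf("TU%02d", seq_len(spec$n_tumors)), n_cells,
                  replace = TRUE)
  malignant <- type %in% spec$malignant_types
  annotation <- data.frame(cell_id = cells, tumor_id = tumor,
                           cell_type = type, malignant = malignant,
                           stringsAsFactors = FALSE)

  # baseline + noise on log2 scale; per-gene noise sd can be inflated
  # for planted high-variance sets
  base <- stats::rnorm(n_genes, spec$base_mean, spec$base_sd)
  gene_noise <- rep(spec$noise_sd, n_genes)
  names(gene_noise) <- genes
  if (!is.null(spec$set_noise_mult)) {
    for (nm in names(spec$set_noise_mult)) {
      if (!nm %in% names(sets)) stop("unknown noise-mult set: ", nm)
      gene_noise[sets[[nm]]] <- gene_noise[sets[[nm]]] *
        spec$set_noise_mult[[nm]]
    }
  }
  x <- base + matrix(stats::rnorm(n_genes * n_cells, 0, gene_noise),
                     n_genes, n_cells)
  dimnames(x) <- list(genes, cells)

  # planted pathway effects
  if (!is.null(spec$planted_effects)) {
    for (e in seq_len(nrow(spec$planted_effects))) {
      pw <- spec$planted_effects$pathway[e]
      if (!pw %in% names(sets)) stop("unknown planted pathway: ", pw)
      tgt <- type == spec$planted_effects$cell_type[e]
      x[sets[[pw]], tgt] <- x[sets[[pw]], tgt] +
        spec$planted_effects$log2fc[e]
    }
  }

  # tumor-specific shifts, malignant cells only
  tumor_shifts <- list()
  if (spec$tumor_effect_sd > 0) {
    for (tu in unique(tumor)) {
      sel <- sample(n_genes, round(spec$tumor_effect_frac * n_genes))
      shift <- stats::rnorm(length(sel), 0, spec$tumor_effect_sd)
      cols <- malignant & tumor == tu
      if (any(cols)) x[sel, cols] <- x[sel, cols] + shift
      tumor_shifts[[tu]] <- stats::setNames(shift, genes[sel])
    }
  }

  # shared latent factor ("hypoxia" axis)
  latent <- stats::rnorm(n_cells)
  if (!is.null(spec$latent_loadings)) {
    for (nm in names(spec$latent_loadings)) {
      if (!nm %in% names(sets)) stop("unknown loaded set: ", nm)
      x[sets[[nm]], ] <- x[sets[[nm]], ] +
        rep(spec$latent_loadings[[nm]] * latent, each = length(sets[[nm]]))
    }
  }

  # to expression scale, library scaling, dropout, TPM, log
  expr <- 2^x
  lib <- stats::rlnorm(n_cells, 0, spec$library_size_sd)
  expr <- sweep(expr, 2, lib, "*")
  if (!is.null(spec$dropout) && spec$dropout$slope > 0) {
    p_drop <- stats::plogis(spec$dropout$slope *
                              (spec$dropout$midpoint - x))
    expr[stats::runif(length(expr)) < p_drop] <- 0
  }
  if (spec$tpm_normalize) {
    cs <- colSums(expr)
    if (any(cs == 0)) stop("a cell lost all expression to dropout")
    expr <- sweep(expr, 2, cs, "/") * 1e6
  }
  mat <- expression_matrix(log2(expr + 1), unit = "log2tpm1")

  lengths <- gene_length_table(
    stats::setNames(sample(200:10000, n_genes, replace = TRUE), genes))

  list(matrix = mat, annotation = annotation, gene_sets = gene_sets,
       lengths = lengths,
       truth = list(spec = spec, baseline_log2 = stats::setNames(base, genes),
                    latent = stats::setNames(latent, cells),
                    lib_factors = stats::setNames(lib, cells),
                    tumor_shifts = tumor_shifts,
                    planted_effects = spec$planted_effects))
}

#' Generate structureless null data
#'
#' All cells are i.i.d. — no planted effects, no tumor shifts, no latent
#' factor — with cell-type labels assigned in a balanced way, so any
#' detected cell-type difference is a false positive. Used for type-I
#' error calibration of the permutation test and of GSEA.
#'
#' @param n_genes,n_cells,n_types,n_sets dimensions (defaults 500 genes,
#'   200 cells, 4 types, 100 disjoint gene sets tiling the genes).
#' @param seed RNG seed.
#' @param dropout as in [simulation_spec()].
#' @return same structure as [generate()].
#' @export
generate_null <- function(n_genes = 500, n_cells = 200, n_types = 4,
                          n_sets = 100, seed = 1,
                          dropout = list(midpoint = 1, slope = 1)) {
  per_type <- diff(round(seq(0, n_cells, length.out = n_types + 1)))
  types <- stats::setNames(as.integer(per_type),
                           sprintf("type%02d", seq_len(n_types)))
  spec <- simulation_spec(
    n_genes = n_genes,
    set_sizes = rep(n_genes %/% n_sets, n_sets),
    cell_types = types, malignant_types = character(0), n_tumors = 1L,
    planted_effects = NULL, tumor_effect_sd = 0,
    latent_loadings = NULL, dropout = dropout, seed = seed)
  generate(spec)
}
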