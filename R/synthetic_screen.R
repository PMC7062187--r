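# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic screen generator
#'
#' Captures the statistical structure of a plate-based parkin-recruitment
#' screen: correlated blocks among the readout parameters, an informative
#' subset that responds to perturbations, strong suppression of the
#' informative readouts in positive-control (siPINK1) wells, planted
#' positive/negative modulator genes, linear row/column gradients,
#' degraded-quality plates, and replicate noise.
#'
#' Readouts are generated on a standardized scale: the per-well noise S.D.
#' is `noise_sd` (default 1), so `effect_size_sd_units` and
#' `control_separation_sd_units` are literally in noise-S.D. units.
#' Knocking down a *positive* modulator suppresses recruitment, shifting
#' the informative readouts by `-effect_size_sd_units`; a *negative*
#' modulator elevates them by `+effect_size_sd_units`.
#'
#' Sample wells are assigned gene ids `g0001, g0002, ...` in plate/well
#' order (with `sirnas_per_gene` consecutive wells per gene, siRNA ids
#' `<gene>_s1..`), so planted lists can name genes deterministically.
#'
#' @param n_plates number of library plates.
#' @param replicates plate replicates (3 for primary, 6 for secondary).
#' @param layout_name `"primary"` or `"secondary"`.
#' @param n_parameters readouts per well (default 84).
#' @param informative_parameter_count leading readouts that respond to
#'   perturbations and separate the controls (default 65; the rest never
#'   respond).
#' @param planted_positive_modulators,planted_negative_modulators disjoint
#'   gene id lists.
#' @param effect_size_sd_units planted knockdown effect, in noise S.D. units.
#' @param control_separation_sd_units negative- minus positive-control
#'   separation on informative readouts (default 6; a very strong positive
#'   control).
#' @param row_slope,col_slope injected linear positional gradient per row /
#'   column unit (applied to every readout).
#' @param bad_plate_ids plates generated with control separation shrunk by
#'   `bad_plate_factor`, so they fail the -2 QC rule.
#' @param bad_plate_factor multiplier for control separation on bad plates.
#' @param noise_sd replicate noise S.D.
#' @param correlation_block_size parameters per correlated block (shared
#'   latent factor; default 7). Blocks are assigned round robin, so the
#'   three lead readouts fall in distinct blocks.
#' @param block_rho fraction of each readout's variance carried by its
#'   block's latent factor.
#' @param sirnas_per_gene consecutive sample wells per gene (1 for pooled
#'   primary, 3 for the non-pooled secondary).
#' @param seed RNG seed; generation is bit-reproducible from it.
#' @return a `ScreenSimConfig` list.
#' @export
screen_sim_config <- function(n_plates = 4L, replicates = 3L,
                              layout_name = "primary",
                              n_parameters = 84L,
                              informative_parameter_count = 65L,
                              planted_positive_modulators = character(),
                              planted_negative_modulators = character(),
                              effect_size_sd_units = 4,
                              control_separation_sd_units = 6,
                              row_slope = 0, col_slope = 0,
                              bad_plate_ids = character(),
                              bad_plate_factor = 0.2,
                              noise_sd = 1,
                              correlation_block_size = 7L,
                              block_rho = 0.6,
                              sirnas_per_gene = 1L,
                              seed = 1L) {
  stopifnot(informative_parameter_count <= n_parameters,
            noise_sd > 0, effect_size_sd_units >= 0,
            control_separation_sd_units >= 0,
            length(intersect(planted_positive_modulators,
                             planted_negative_modulators)) == 0)
  structure(
    list(n_plates = as.integer(n_plates), replicates = as.integer(replicates),
         layout_name = layout_name, n_parameters = as.integer(n_parameters),
         informative_parameter_count = as.integer(informative_parameter_count),
         planted_positive_modulators = planted_positive_modulators,
         planted_negative_modulators = planted_negative_modulators,
         effect_size_sd_units = effect_size_sd_units,
         control_separation_sd_units = control_separation_sd_units,
         row_slope = row_slope, col_slope = col_slope,
         bad_plate_ids = bad_plate_ids, bad_plate_factor = bad_plate_factor,
         noise_sd = noise_sd,
         correlation_block_size = as.integer(correlation_block_size),
         block_rho = block_rho,
         sirnas_per_gene = as.integer(sirnas_per_gene),
         seed = as.integer(seed)),
    class = "ScreenSimConfig"
  )
}

#' Simulate a plate screen with planted ground truth
#'
#' Generates a [screen_dataset()] under the structure described in
#' [screen_sim_config()], together with the ground truth needed to score
#' recovery: per-gene true direction (the sign of the induced mean shift on
#' informative readouts: -1 for knockdowns of positive modulators, +1 for
#' negative modulators, 0 otherwise), the injected per-plate gradient, and
#' the per-parameter informative flag.
#'
#' @param config a `ScreenSimConfig`.
#' @return list with `dataset` (a `ScreenDataset`) and `truth` (list:
#'   `genes` data frame, `informative` logical vector, `row_slope`,
#'   `col_slope`, `bad_plate_ids`).
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "ScreenSimConfig"))
  cf <- config
  lay <- plate_layout(cf$layout_name)
  params <- default_parameters(cf$n_parameters)
  plate_ids <- sprintf("P%02d", seq_len(cf$n_plates))

  sample_wells <- lay$roles$well[lay$roles$role == "sample"]
  slots_per_plate <- length(sample_wells)
  n_slots <- slots_per_plate * cf$n_plates
  n_genes <- as.integer(ceiling(n_slots / cf$sirnas_per_gene))
  if (n_genes < 1L) stop("capacity error: no room for any gene")
  planted <- c(cf$planted_positive_modulators, cf$planted_negative_modulators)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  if (!all(planted %in% gene_ids)) {
    stop("capacity error: planted gene(s) not among the ", n_genes,
         " available gene ids (g0001..)")
  }
  direction <- ifelse(gene_ids %in% cf$planted_positive_modulators, -1,
               ifelse(gene_ids %in% cf$planted_negative_modulators, +1, 0))

  # well-record skeleton: plates x replicates x 96 wells
  grid <- expand.grid(well_i = seq_len(nrow(lay$roles)),
                      replicate = seq_len(cf$replicates),
                      plate = seq_len(cf$n_plates))
  w <- data.frame(
    plate_id = plate_ids[grid$plate],
    replicate = as.integer(grid$replicate),
    well = lay$roles$well[grid$well_i],
    role = lay$roles$role[grid$well_i],
    stringsAsFactors = FALSE
  )
  # map each sample well to its slot (plate-major, layout order)
  sample_idx <- match(w$well, sample_wells)  # NA for controls
  slot_of <- (match(w$plate_id, plate_ids) - 1L) * slots_per_plate + sample_idx

  n_rec <- nrow(w)
  n_par <- cf$n_parameters
  n_blocks <- max(1L, ceiling(n_par / cf$correlation_block_size))
  block_of <- ((seq_len(n_par) - 1L) %% n_blocks) + 1L
  informative <- seq_len(n_par) <= cf$informative_parameter_count

  sim <- with_seed(cf$seed, {
    # genes land on random (but replicate-constant) sample wells, as in an
    # arbitrarily plated library; a gene's siRNAs stay adjacent
    perm <- sample.int(n_genes)
    Z <- matrix(stats::rnorm(n_rec * n_blocks), n_rec, n_blocks)
    E <- matrix(stats::rnorm(n_rec * n_par), n_rec, n_par)
    V <- cf$noise_sd * (sqrt(cf$block_rho) * Z[, block_of, drop = FALSE] +
                        sqrt(1 - cf$block_rho) * E)
    list(perm = perm, V = V)
  })
  V <- sim$V
  slot_group <- ceiling(seq_len(n_slots) / cf$sirnas_per_gene)
  slot_gene <- gene_ids[sim$perm[slot_group]]
  slot_sirna <- if (cf$sirnas_per_gene == 1L) slot_gene else
    paste0(slot_gene, "_s", ((seq_len(n_slots) - 1L) %% cf$sirnas_per_gene) + 1L)
  w$gene_id <- ifelse(w$role == "sample", slot_gene[slot_of], NA_character_)
  w$sirna_id <- ifelse(w$role == "sample", slot_sirna[slot_of], NA_character_)

  # planted and control shifts on informative parameters
  shift <- numeric(n_rec)
  is_sample <- w$role == "sample"
  shift[is_sample] <- direction[match(w$gene_id[is_sample], gene_ids)] *
    cf$effect_size_sd_units * cf$noise_sd
  sep <- rep(cf$control_separation_sd_units, n_rec)
  sep[w$plate_id %in% cf$bad_plate_ids] <-
    cf$control_separation_sd_units * cf$bad_plate_factor
  is_pos <- w$role == "positive_control"
  shift[is_pos] <- -sep[is_pos] * cf$noise_sd
  V[, informative] <- V[, informative] + shift

  # positional gradient on every readout, plus a common baseline
  rr <- well_row(w$well); cc <- well_col(w$well)
  V <- V + 10 + cf$row_slope * rr + cf$col_slope * cc

  colnames(V) <- params
  wells <- cbind(w, as.data.frame(V))
  dataset <- screen_dataset(wells, layout = lay, parameter_names = params,
                            replicates_per_plate = cf$replicates)
  truth <- list(
    genes = data.frame(
      gene_id = gene_ids,
      direction = direction,
      modulator = ifelse(direction < 0, "positive",
                  ifelse(direction > 0, "negative", "none")),
      stringsAsFactors = FALSE
    ),
    informative = stats::setNames(informative, params),
    row_slope = cf$row_slope, col_slope = cf$col_slope,
    bad_plate_ids = cf$bad_plate_ids
  )
  list(dataset = dataset, truth = truth)
}

#' Simulate a bimodal gene-expression matrix
#'
#' Emulates a normalized log-intensity matrix pooled from heterogeneous
#' control samples of one cell line: each gene's mean intensity is drawn
#' from a two-component Gaussian mixture (the lower component representing
#' non-expressed genes, the upper expressed genes), and per-sample values
#' scatter around the gene mean with `noise_sd` (cross-platform sample
#' noise).
#'
#' @param n_genes number of genes.
#' @param expressed_fraction probability a gene is expressed (upper
#'   component).
#' @param mu_off,mu_on component means (log-intensity; `mu_on > mu_off`
#'   expected, equal means are allowed with a warning).
#' @param sigma_off,sigma_on component S.D.s (> 0).
#' @param n_samples columns of the matrix (11 mirrors an 8 + 3 sample
#'   design pooled from two repositories).
#' @param noise_sd per-sample measurement noise around the gene mean.
#' @param seed RNG seed.
#' @return list with `matrix` (genes x samples, dimnames set), `expressed`
#'   (logical per gene), `gene_mean` (numeric per gene).
#' @export
simulate_expression <- function(n_genes, expressed_fraction = 0.5,
                                mu_off = 4, mu_on = 9,
                                sigma_off = 1, sigma_on = 1,
                                n_samples = 11L, noise_sd = 1,
                                seed = 1L) {
  stopifnot(n_genes >= 1, expressed_fraction >= 0, expressed_fraction <= 1,
            sigma_off > 0, sigma_on > 0, n_samples >= 2)
  if (mu_on == mu_off) {
    warning("degenerate mixture: mu_on == mu_off; generating anyway")
  } else {
    stopifnot(mu_on > mu_off)
  }
  with_seed(seed, {
    expressed <- stats::runif(n_genes) < expressed_fraction
    gene_mean <- ifelse(expressed,
                        stats::rnorm(n_genes, mu_on, sigma_on),
                        stats::rnorm(n_genes, mu_off, sigma_off))
    mat <- gene_mean + matrix(stats::rnorm(n_genes * n_samples, 0, noise_sd),
                              n_genes, n_samples)
    dimnames(mat) <- list(sprintf("gene_%05d", seq_len(n_genes)),
                          sprintf("sample_%02d", seq_len(n_samples)))
    list(matrix = mat, expressed = expressed, gene_mean = gene_mean)
  })
}
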