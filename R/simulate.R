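#' Simulation configuration for trio RNA-seq counts
#'
#' Describes the stated world of the generator: a hybrid/parent trio
#' (genotypes P1, P2, F1) measured in `n_replicates` biological replicates at
#' each stage, with gene-wise additive and dominance effects acting on the
#' log2 expression scale. For a gene with baseline log2 expression `u`,
#' additive effect `a` and dominance effect `d`, the expected log2 expression
#' is `u + a` for P1, `u - a` for P2 and `u + d` for F1 (so positive `d`
#' means the hybrid sits above the mid-parent). Counts are drawn from a
#' negative binomial with variance `mu + phi * mu^2`, scaled by gene length
#' and per-sample library size.
#'
#' @param n_genes number of genes (>= 1).
#' @param n_replicates replicates per genotype per stage (>= 1, default 2).
#' @param stages character vector of stage labels.
#' @param mean_log_expression c(location, scale) of the Gaussian baseline
#'   log2 mean expression (units: log2 RPKM).
#' @param additive_sd sd of true additive effects a_g (log2 units).
#' @param dominance_sd sd of true dominance effects d_g (log2 units).
#' @param frac_null fraction of genes with a_g = d_g = 0.
#' @param dispersion either a single NB dispersion phi >= 0 (0 = Poisson) or
#'   c(shape, rate) for gene-wise gamma-distributed dispersions.
#' @param library_sizes per-sample total-count targets; either one number
#'   (recycled) or a vector of length genotypes x replicates x stages.
#' @param gene_length_range c(min, max) summed exon length in bp (min >= 100).
#' @param replicate_effect_sd sd of the per-(stage, replicate) block effect
#'   (log2 units).
#' @param seed RNG seed (integer).
#' @return a list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_genes = 2000,
                              n_replicates = 2,
                              stages = c("tillering", "heading"),
                              mean_log_expression = c(location = 5, scale = 2),
                              additive_sd = 1,
                              dominance_sd = 0.8,
                              frac_null = 0.7,
                              dispersion = 0.1,
                              library_sizes = 2e6,
                              gene_length_range = c(200, 10000),
                              replicate_effect_sd = 0.05,
                              seed = 1L) {
  cfg <- list(n_genes = n_genes, n_replicates = n_replicates, stages = stages,
              mean_log_expression = mean_log_expression,
              additive_sd = additive_sd, dominance_sd = dominance_sd,
              frac_null = frac_null, dispersion = dispersion,
              library_sizes = library_sizes,
              gene_length_range = gene_length_range,
              replicate_effect_sd = replicate_effect_sd,
              seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  validate_simulation_config(cfg)
}

validate_simulation_config <- function(cfg) {
  chk <- function(ok, field, why)
    if (!ok) stop("invalid simulation config field '", field, "': ", why)
  chk(is.numeric(cfg$n_genes) && cfg$n_genes >= 1, "n_genes", "must be >= 1")
  chk(cfg$n_replicates >= 1, "n_replicates", "must be >= 1")
  chk(length(cfg$stages) >= 1, "stages", "need at least one stage")
  chk(length(cfg$mean_log_expression) == 2 &&
        cfg$mean_log_expression[2] >= 0,
      "mean_log_expression", "need c(location, scale >= 0)")
  chk(cfg$additive_sd >= 0, "additive_sd", "must be >= 0")
  chk(cfg$dominance_sd >= 0, "dominance_sd", "must be >= 0")
  chk(cfg$frac_null >= 0 && cfg$frac_null <= 1, "frac_null",
      "must be in [0, 1]")
  if (length(cfg$dispersion) == 1) {
    chk(cfg$dispersion >= 0, "dispersion", "must be >= 0")
  } else {
    chk(length(cfg$dispersion) == 2 && all(cfg$dispersion > 0), "dispersion",
        "gene-wise form needs c(shape > 0, rate > 0)")
  }
  chk(all(cfg$library_sizes > 0), "library_sizes", "must be positive")
  chk(length(cfg$gene_length_range) == 2 &&
        cfg$gene_length_range[1] >= 100 &&
        diff(cfg$gene_length_range) >= 0,
      "gene_length_range", "need c(min >= 100, max >= min)")
  chk(cfg$replicate_effect_sd >= 0, "replicate_effect_sd", "must be >= 0")
  cfg
}

# True pattern class implied by noiseless effects, mirroring the CI
# classifier's decision boundaries ([a] enters as |a|).
#' Ground-truth dominance-ratio class for given effects
#'
#' Deterministic classification of the dominance ratio h_p = d / \[a\] from
#' noiseless effects: for d > 0, d - |a| positive / zero / negative gives
#' AHP / HPL / MPL; for d < 0, d + |a| negative / zero / positive gives
#' BLP / LPL / MPL; d = 0 gives "none".
#'
#' @param a additive effects (signed, log2 units).
#' @param d dominance effects (signed, log2 units).
#' @return character vector of classes in
#'   `c("AHP", "HPL", "MPL", "LPL", "BLP", "none")`.
#' @export
hp_true_class <- function(a, d) {
  stopifnot(length(a) == length(d))
  cls <- rep("none", length(d))
  up <- d > 0
  dn <- d < 0
  x <- d - abs(a)
  cls[up & x > 0] <- "AHP"
  cls[up & x == 0] <- "HPL"
  cls[up & x < 0] <- "MPL"
  y <- d + abs(a)
  cls[dn & y < 0] <- "BLP"
  cls[dn & y == 0] <- "LPL"
  cls[dn & y > 0] <- "MPL"
  cls
}

#' Simulate trio expression counts with known truth
#'
#' Draws negative-binomial counts for a P1/P2/F1 trio under the model in
#' [simulation_config()]. The expected count for gene g in sample s is
#' `2^(u_g + effect + block) * (length_g / 1000) * (lib_s / 1e6)`, i.e. the
#' baseline is interpreted as a true RPKM; library sizes therefore act as
#' exact per-sample scale factors and realized column totals approximate the
#' configured targets.
#'
#' @param config a [simulation_config()].
#' @param effects optional list with elements `a` and `d`: either vectors of
#'   length `n_genes` (shared across stages) or `n_genes x length(stages)`
#'   matrices (stage-specific), overriding the random effect draw. Useful for
#'   constructing fixtures with prescribed structure.
#' @return list with `matrix` (an [expression_matrix()]) and `truth`
#'   (data.frame: gene, stage, u, a, d, class, deg_RF, deg_XF, deg_RX, where
#'   the deg_* flags mark |true log2 fold change| >= 1 for the F1-vs-P1,
#'   F1-vs-P2 and P1-vs-P2 contrasts).
#' @examples
#' sim <- simulate_trio_counts(simulation_config(n_genes = 100, seed = 7))
#' head(sim$truth)
#' @export
simulate_trio_counts <- function(config, effects = NULL) {
  cfg <- validate_simulation_config(config)
  set.seed(cfg$seed)
  G <- as.integer(cfg$n_genes)
  stages <- as.character(cfg$stages)
  R <- as.integer(cfg$n_replicates)
  genos <- c("P1", "P2", "F1")

  u <- stats::rnorm(G, cfg$mean_log_expression[1], cfg$mean_log_expression[2])
  if (is.null(effects)) {
    is_null <- stats::runif(G) < cfg$frac_null
    a1 <- ifelse(is_null, 0, stats::rnorm(G, 0, cfg$additive_sd))
    d1 <- ifelse(is_null, 0, stats::rnorm(G, 0, cfg$dominance_sd))
    a_mat <- matrix(a1, G, length(stages))
    d_mat <- matrix(d1, G, length(stages))
  } else {
    a_mat <- if (is.matrix(effects$a)) effects$a else
      matrix(effects$a, G, length(stages))
    d_mat <- if (is.matrix(effects$d)) effects$d else
      matrix(effects$d, G, length(stages))
    if (nrow(a_mat) != G || nrow(d_mat) != G)
      stop("invalid simulation config field 'effects': need n_genes rows")
  }

  phi <- if (length(cfg$dispersion) == 1) rep(cfg$dispersion, G) else
    stats::rgamma(G, shape = cfg$dispersion[1], rate = cfg$dispersion[2])

  len <- round(stats::runif(G, cfg$gene_length_range[1],
                            cfg$gene_length_range[2]))
  gene_ids <- sprintf("g%05d", seq_len(G))
  chrom <- sample(paste0("chr", 1:12), G, replace = TRUE)
  start <- sample.int(4e7, G, replace = TRUE)
  genes <- data.frame(gene = gene_ids, chrom = chrom, start = start,
                      end = start + len - 1L, length = len,
                      stringsAsFactors = FALSE)

  n_samp <- length(genos) * R * length(stages)
  libs <- rep_len(cfg$library_sizes, n_samp)
  samples <- expand.grid(replicate = seq_len(R), genotype = genos,
                         stage = stages, KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)
  samples <- samples[, c("genotype", "stage", "replicate")]
  samples$sample <- with(samples, paste0(genotype, "_", stage, "_r", replicate))
  samples <- samples[, c("sample", "genotype", "stage", "replicate")]

  # block effect shared by all samples of one (stage, replicate) batch
  block <- matrix(stats::rnorm(length(stages) * R, 0, cfg$replicate_effect_sd),
                  nrow = R, ncol = length(stages),
                  dimnames = list(NULL, stages))

  counts <- matrix(0L, G, n_samp,
                   dimnames = list(gene_ids, samples$sample))
  for (j in seq_len(n_samp)) {
    st <- samples$stage[j]
    si <- match(st, stages)
    eff <- switch(samples$genotype[j],
                  P1 = a_mat[, si], P2 = -a_mat[, si], F1 = d_mat[, si])
    eta <- u + eff + block[samples$replicate[j], st]
    mu <- 2^eta * (len / 1000) * (libs[j] / 1e6)
    counts[, j] <- ifelse(phi == 0,
                          stats::rpois(G, mu),
                          stats::rnbinom(G, mu = mu, size = 1 / pmax(phi, 1e-12)))
  }
  storage.mode(counts) <- "integer"

  truth <- do.call(rbind, lapply(seq_along(stages), function(si) {
    a <- a_mat[, si]; d <- d_mat[, si]
    data.frame(gene = gene_ids, stage = stages[si], u = u, a = a, d = d,
               class = hp_true_class(a, d),
               deg_RF = abs(d - a) >= 1,
               deg_XF = abs(d + a) >= 1,
               deg_RX = abs(2 * a) >= 1,
               stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL

  list(matrix = expression_matrix(counts, samples, genes), truth = truth)
}

#' Simulate replicated trait measurements for the trio
#'
#' Gaussian replicate values around specified genotype means, with the
#' implied true mid-parent and high-parent heterosis recorded alongside.
#'
#' @param trait_specs data.frame with columns `trait`, `p1_mean`, `p2_mean`,
#'   `f1_mean`, `noise_sd`, `n_replicates` (and optionally `stage`).
#' @param seed RNG seed.
#' @return list with `measurements` (long data.frame: trait, genotype,
#'   replicate, value, and stage if given) and `truth` (trait, true_mph,
#'   true_hph, in percent).
#' @export
simulate_trait_measurements <- function(trait_specs, seed = 1L) {
  ts <- as.data.frame(trait_specs, stringsAsFactors = FALSE)
  need <- c("trait", "p1_mean", "p2_mean", "f1_mean", "noise_sd",
            "n_replicates")
  if (!all(need %in% names(ts)))
    stop("trait_specs must contain columns: ",
         paste(setdiff(need, names(ts)), collapse = ", "))
  if (any(ts$n_replicates < 2))
    stop("n_replicates must be >= 2 (t-test undefined otherwise)")
  if (any(ts$noise_sd < 0)) stop("noise_sd must be >= 0")
  set.seed(as.integer(seed))
  has_stage <- "stage" %in% names(ts)
  key <- if (has_stage) paste(ts$trait, ts$stage, sep = " @ ") else ts$trait
  if (anyDuplicated(key)) stop("duplicate trait (per stage) in trait_specs")

  rows <- lapply(seq_len(nrow(ts)), function(i) {
    n <- ts$n_replicates[i]
    df <- data.frame(
      trait = ts$trait[i],
      genotype = rep(c("P1", "P2", "F1"), each = n),
      replicate = rep(seq_len(n), 3),
      value = c(stats::rnorm(n, ts$p1_mean[i], ts$noise_sd[i]),
                stats::rnorm(n, ts$p2_mean[i], ts$noise_sd[i]),
                stats::rnorm(n, ts$f1_mean[i], ts$noise_sd[i])),
      stringsAsFactors = FALSE)
    if (has_stage) df$stage <- ts$stage[i]
    df
  })
  mp <- (ts$p1_mean + ts$p2_mean) / 2
  hp <- pmax(ts$p1_mean, ts$p2_mean)
  truth <- data.frame(trait = ts$trait,
                      true_mph = 100 * (ts$f1_mean - mp) / mp,
                      true_hph = 100 * (ts$f1_mean - hp) / hp,
                      stringsAsFactors = FALSE)
  if (has_stage) truth$stage <- ts$stage
  list(measurements = do.call(rbind, rows), truth = truth)
}

#' Default trait specifications: published Xieyou 9308 root traits
#'
#' Genotype means and standard deviations for root and shoot traits of the
#' super-hybrid rice Xieyou 9308 (F1), its restorer line R9308 (P1) and
#' maternal line Xieqingzao B (P2) at tillering and heading stages, with ten
#' replicates per genotype. These published summary statistics define the
#' generator's stated world for phenotype simulation.
#'
#' @return data.frame usable as `trait_specs` in
#'   [simulate_trait_measurements()], with extra columns carrying the
#'   published per-genotype sds and printed MPH/HPH percentages.
#' @export
default_trait_specs <- function() {
  path <- system.file("extdata", "xieyou9308_root_traits.tsv",
                      package = "heteroseq", mustWork = TRUE)
  tab <- read_tsv_strict(path)
  data.frame(trait = tab$trait, stage = tab$stage,
             p1_mean = tab$p1_mean, p2_mean = tab$p2_mean,
             f1_mean = tab$f1_mean,
             noise_sd = pmax(tab$p1_sd, tab$p2_sd, tab$f1_sd),
             n_replicates = 10L,
             mph_printed = tab$mph_printed, hph_printed = tab$hph_printed,
             stringsAsFactors = FALSE)
}

#' Write a complete synthetic fixture set
#'
#' Generates a trio count dataset, trait measurements, a random term
#' annotation and a QTL interval table, and writes them as TSV files plus a
#' JSON manifest. The files round-trip through the package readers.
#'
#' @param output_dir writable directory (created if absent).
#' @param config a [simulation_config()].
#' @param trait_specs passed to [simulate_trait_measurements()]; default
#'   [default_trait_specs()].
#' @param n_terms number of synthetic annotation terms.
#' @param n_intervals number of synthetic QTL intervals.
#' @return invisibly, the manifest as a list (also written to
#'   `manifest.json`): file names, seed, per-file row counts.
#' @export
write_fixture_set <- function(output_dir, config = simulation_config(),
                              trait_specs = default_trait_specs(),
                              n_terms = 20, n_intervals = 8) {
  cfg <- validate_simulation_config(config)
  if (!dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE)
  sim <- simulate_trio_counts(cfg)
  m <- sim$matrix
  # reuse the simulation stream (seeded inside simulate_trio_counts) for the
  # annotation and interval draws so the whole set is one deterministic draw
  genes <- m$genes

  term_ids <- sprintf("T%03d", seq_len(n_terms))
  n_annot <- pmin(nrow(genes), pmax(2, stats::rpois(n_terms, 25)))
  terms <- do.call(rbind, lapply(seq_len(n_terms), function(i) {
    data.frame(gene = sample(genes$gene, n_annot[i]),
               term = term_ids[i],
               name = paste("synthetic process", i),
               namespace = if (i %% 2 == 0) "pathway" else
                 "biological_process",
               stringsAsFactors = FALSE)
  }))

  anchor <- genes[sample.int(nrow(genes), n_intervals), ]
  half <- round(stats::runif(n_intervals, 5e5, 3e6))
  qtl <- data.frame(
    trait = sample(c("RL", "RDW", "RS", "GYD"), n_intervals, replace = TRUE),
    chrom = anchor$chrom,
    start = pmax(1, anchor$start - half),
    end = anchor$end + half,
    marker_left = sprintf("RM%04d", sample.int(9999, n_intervals)),
    marker_right = sprintf("RM%04d", sample.int(9999, n_intervals)),
    stringsAsFactors = FALSE)

  tm <- simulate_trait_measurements(trait_specs, seed = cfg$seed)

  p <- function(f) file.path(output_dir, f)
  write_expression_set(m, p("counts.tsv"), p("samples.tsv"), p("genes.tsv"))
  write_tsv_strict(terms, p("terms.tsv"))
  write_tsv_strict(tm$measurements, p("traits.tsv"))
  write_tsv_strict(qtl, p("qtl_intervals.tsv"))
  write_tsv_strict(sim$truth, p("truth.tsv"))

  files <- c("counts.tsv", "samples.tsv", "genes.tsv", "terms.tsv",
             "traits.tsv", "qtl_intervals.tsv", "truth.tsv")
  manifest <- list(files = files, seed = cfg$seed,
                   n_genes = nrow(m$counts), n_samples = ncol(m$counts),
                   md5 = as.list(tools::md5sum(file.path(output_dir, files))))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
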