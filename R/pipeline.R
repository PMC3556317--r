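#' Pipeline configuration
#'
#' Assembles and validates the configuration driving [run_pipeline()].
#' Accepts either a JSON file path or a named list; missing fields take the
#' defaults below.
#'
#' @param config list or path to a JSON config file. Recognized keys:
#'   `counts`, `samples`, `genes`, `terms`, `traits`, `qtl_intervals`
#'   (input paths; the last three optional), `output_dir`,
#'   `fdr_max` (0.05), `min_abs_log2fc` (1), `ci_level` (0.998),
#'   `enrichment_p_max` (0.05), `variance_mode` ("pooled"),
#'   `cluster_metric` ("pearson"), `cluster_linkage` ("average"),
#'   `overlap_rule` ("contained"), `seed` (1), `simulate` (logical; when
#'   TRUE a fixture set is generated into `output_dir/fixtures` and used as
#'   input), `n_genes` (simulation size, default 2000).
#' @return validated config list of class `PipelineConfig`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- list(counts = NULL, samples = NULL, genes = NULL,
                   terms = NULL, traits = NULL, qtl_intervals = NULL,
                   output_dir = "heteroseq_out",
                   fdr_max = 0.05, min_abs_log2fc = 1, ci_level = 0.998,
                   enrichment_p_max = 0.05, variance_mode = "pooled",
                   cluster_metric = "pearson", cluster_linkage = "average",
                   overlap_rule = "contained", seed = 1L,
                   simulate = FALSE, n_genes = 2000)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config[!vapply(config, is.null,
                                                    logical(1))])
  if (!(cfg$ci_level > 0 && cfg$ci_level < 1))
    stop("ci_level must lie in (0, 1)")
  for (f in c("fdr_max", "min_abs_log2fc", "enrichment_p_max"))
    if (cfg[[f]] <= 0) stop(f, " must be positive")
  if (!cfg$variance_mode %in% c("pooled", "per_gene"))
    stop("variance_mode must be 'pooled' or 'per_gene'")
  if (!cfg$overlap_rule %in% c("contained", "overlap"))
    stop("overlap_rule must be 'contained' or 'overlap'")
  if (!isTRUE(cfg$simulate)) {
    for (f in c("counts", "samples", "genes")) {
      if (is.null(cfg[[f]]))
        stop("config must name an input file for '", f,
             "' (or set simulate: true)")
      if (!file.exists(cfg[[f]]))
        stop("input file for '", f, "' not found: ", cfg[[f]])
    }
  }
  class(cfg) <- "PipelineConfig"
  cfg
}

log_stage <- function(stage, msg) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full trio heterosis pipeline
#'
#' Sequences the stages: (optional) simulate -> normalize (RPKM, detection)
#' -> DE exact tests per contrast per stage -> DEG partition -> trio ANOVA +
#' h_p classification -> pattern summary -> phenotype heterosis -> term
#' enrichment -> sample clustering -> QTL overlap. All result tables are
#' written as TSV under `output_dir`, plus a JSON manifest with input
#' checksums, the echoed configuration and per-stage row counts. Output is
#' a pure function of inputs + config (the seed covers the simulation).
#'
#' @param config a [pipeline_config()] (or list / JSON path accepted by it).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "PipelineConfig")) config else
    pipeline_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$output_dir, f)
  stages_run <- list()
  note <- function(stage, n) stages_run[[stage]] <<- list(status = "ok",
                                                          rows = n)

  if (isTRUE(cfg$simulate)) {
    log_stage("simulate", paste("generating fixture set, n_genes =",
                                cfg$n_genes))
    fx <- file.path(cfg$output_dir, "fixtures")
    run_stage("simulate", write_fixture_set(
      fx, simulation_config(n_genes = cfg$n_genes, seed = cfg$seed)))
    cfg$counts <- file.path(fx, "counts.tsv")
    cfg$samples <- file.path(fx, "samples.tsv")
    cfg$genes <- file.path(fx, "genes.tsv")
    if (is.null(cfg$terms)) cfg$terms <- file.path(fx, "terms.tsv")
    if (is.null(cfg$traits)) cfg$traits <- file.path(fx, "traits.tsv")
    if (is.null(cfg$qtl_intervals))
      cfg$qtl_intervals <- file.path(fx, "qtl_intervals.tsv")
    note("simulate", cfg$n_genes)
  }

  log_stage("normalize", "reading counts and computing RPKM")
  m <- run_stage("normalize",
                 read_expression_set(cfg$counts, cfg$samples, cfg$genes))
  r <- run_stage("normalize", compute_rpkm(m))
  y <- log2_rpkm(r)
  det <- detection_summary(m)
  write_tsv_strict(data.frame(gene = rownames(r$rpkm), r$rpkm,
                              check.names = FALSE), out("rpkm.tsv"))
  note("normalize", nrow(m$counts))

  stages <- unique(m$samples$stage)
  partitions <- list()
  for (st in stages) {
    degs <- list()
    for (lab in c("R/F", "X/F", "R/X")) {
      log_stage("de", paste(st, lab))
      res <- run_stage("de", de_contrast(m, st, lab, cfg$fdr_max,
                                         cfg$min_abs_log2fc))
      tag <- sub("/", "", lab)
      write_tsv_strict(res, out(sprintf("de_%s_%s.tsv", st, tag)))
      degs[[tag]] <- res$gene[res$is_deg]
    }
    part <- run_stage("partition", partition_degs(degs, st))
    write_tsv_strict(data.frame(region = names(part$venn),
                                count = as.integer(part$venn)),
                     out(sprintf("venn_%s.tsv", st)))
    partitions[[st]] <- part
  }
  note("de", length(stages) * 3)
  note("partition", length(stages))

  summaries <- list()
  for (st in stages) {
    log_stage("classify", st)
    eff <- run_stage("classify", {
      e <- fit_trio_anova(y, m$samples, st)
      classify_hp(e, level = cfg$ci_level,
                  variance_mode = cfg$variance_mode)
    })
    write_tsv_strict(eff, out(sprintf("trio_effects_%s.tsv", st)))
    summaries[[st]] <- run_stage("summarize",
                                 summarize_patterns(eff,
                                                    partitions[[st]]$dg_hp))
  }
  ps <- do.call(rbind, lapply(names(summaries), function(st) {
    s <- summaries[[st]]
    data.frame(stage = st, n_dg_hp = s$n,
               t(as.matrix(s$counts)),
               up_fraction = s$up_fraction, down_fraction = s$down_fraction,
               check.names = FALSE)
  }))
  write_tsv_strict(ps, out("pattern_summary.tsv"))
  note("classify", nrow(ps))

  if (!is.null(cfg$traits)) {
    log_stage("heterosis", cfg$traits)
    meas <- run_stage("heterosis", read_tsv_strict(cfg$traits))
    ht <- run_stage("heterosis", heterosis_table(meas))
    write_tsv_strict(ht, out("heterosis.tsv"))
    note("heterosis", nrow(ht))
  }

  if (!is.null(cfg$terms)) {
    ann <- run_stage("enrich", read_tsv_strict(cfg$terms))
    background <- rownames(m$counts)[rowSums(m$counts) >= 1]
    for (st in stages) {
      log_stage("enrich", st)
      set <- intersect(partitions[[st]]$dg_hp, background)
      if (length(set) > 0) {
        er <- run_stage("enrich", enrich(set, background, ann,
                                         cfg$enrichment_p_max))
        write_tsv_strict(er, out(sprintf("enrichment_%s.tsv", st)))
      }
    }
    note("enrich", length(stages))
  }

  log_stage("cluster", paste(cfg$cluster_metric, cfg$cluster_linkage))
  tree <- run_stage("cluster", cluster_samples(y, cfg$cluster_metric,
                                               cfg$cluster_linkage))
  write_cluster_newick(tree, out("tree.nwk"))
  write_tsv_strict(data.frame(order = seq_along(tree$order),
                              sample = tree$labels[tree$order]),
                   out("leaf_order.tsv"))
  note("cluster", ncol(m$counts))

  if (!is.null(cfg$qtl_intervals)) {
    log_stage("qtl-overlap", cfg$qtl_intervals)
    qtl <- run_stage("qtl-overlap", read_tsv_strict(cfg$qtl_intervals))
    dg_all <- unique(unlist(lapply(partitions, function(p) p$dg_hp)))
    # map against the full annotation (so interval chromosomes validate),
    # then restrict the report to the DG_HP candidates
    ovr <- run_stage("qtl-overlap",
                     map_genes_to_intervals(m$genes, qtl, cfg$overlap_rule))
    ovr$pairs <- ovr$pairs[ovr$pairs$gene %in% dg_all, , drop = FALSE]
    ovr$per_trait <- vapply(split(ovr$pairs$gene, ovr$pairs$trait),
                            function(g) length(unique(g)), integer(1))
    write_tsv_strict(ovr$pairs, out("overlaps.tsv"))
    note("qtl-overlap", nrow(ovr$pairs))
  }

  inputs <- Filter(Negate(is.null),
                   cfg[c("counts", "samples", "genes", "terms", "traits",
                         "qtl_intervals")])
  manifest <- list(
    package = "heteroseq",
    version = as.character(utils::packageVersion("heteroseq")),
    config = unclass(cfg),
    inputs_md5 = as.list(tools::md5sum(unlist(inputs))),
    detection = det,
    deg_counts = lapply(partitions, function(p) as.list(p$counts)),
    stages = stages_run)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  log_stage("done", cfg$output_dir)
  invisible(manifest)
}

#' Command-line entry point
#'
#' Subcommand dispatcher used by the `inst/cli/heteroseq.R` script:
#' `simulate`, `heterosis`, `enrich`, `cluster`, `qtl-overlap` run single
#' stages; `run` executes the whole pipeline from a JSON config.
#'
#' @param argv character vector of arguments (default: the command line).
#' @return exit status integer, invisibly (0 on success).
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: heteroseq <command> [options]",
    "commands:",
    "  run         --config cfg.json",
    "  simulate    --out DIR [--n-genes N] [--seed S]",
    "  heterosis   --traits traits.tsv --out FILE",
    "  cluster     --counts c.tsv --samples s.tsv --genes g.tsv --out FILE",
    sep = "\n")
  if (length(argv) < 1) { message(usage); return(invisible(1L)) }
  cmd <- argv[1]
  rest <- argv[-1]
  getopt <- function(flag, default = NULL) {
    i <- which(rest == flag)
    if (length(i) == 1 && i < length(rest)) rest[i + 1] else default
  }
  status <- tryCatch({
    switch(cmd,
      run = {
        cfgp <- getopt("--config")
        if (is.null(cfgp)) stop("run requires --config")
        run_pipeline(cfgp)
      },
      simulate = {
        outd <- getopt("--out")
        if (is.null(outd)) stop("simulate requires --out")
        write_fixture_set(outd, simulation_config(
          n_genes = as.integer(getopt("--n-genes", "2000")),
          seed = as.integer(getopt("--seed", "1"))))
      },
      heterosis = {
        tp <- getopt("--traits"); op <- getopt("--out")
        if (is.null(tp) || is.null(op))
          stop("heterosis requires --traits and --out")
        write_tsv_strict(heterosis_table(read_tsv_strict(tp)), op)
      },
      cluster = {
        m <- read_expression_set(getopt("--counts"), getopt("--samples"),
                                 getopt("--genes"))
        tree <- cluster_samples(log2_rpkm(compute_rpkm(m)))
        write_cluster_newick(tree, getopt("--out"))
      },
      stop("unknown command: ", cmd, "\n", usage))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
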