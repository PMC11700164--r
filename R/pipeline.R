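#' Validate a pipeline configuration file
#'
#' Reads a YAML file holding `sim:` (fields of [sim_config()]), optional
#' `enrichment:` (`window_kb`, `n_blocks`, `exclude_emhc`), optional
#' `regions:` (`exclude` dissection list), and optional `fmri:` (fields of
#' [fmri_config()] plus `n_folds`, `min_rois`, `n_perm`). Unknown keys and
#' range violations are reported together.
#'
#' @param path YAML file path.
#' @return validated pipeline configuration list.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  errs <- character(0)

  known_top <- c("sim", "enrichment", "regions", "fmri")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown)) {
    errs <- c(errs, paste0("unknown top-level key(s): ",
                           paste(unknown, collapse = ", ")))
  }
  if (is.null(raw$sim)) errs <- c(errs, "missing 'sim' section")
  if (!is.null(raw$sim) && is.null(raw$sim$seed)) {
    errs <- c(errs, "missing field: sim.seed")
  }
  sim <- NULL
  if (!length(errs)) {
    sim_args <- raw$sim
    bad <- setdiff(names(sim_args), names(formals(sim_config)))
    if (length(bad)) {
      errs <- c(errs, paste0("unknown sim field(s): ",
                             paste(bad, collapse = ", ")))
    } else {
      if (!is.null(sim_args$delta_pairs)) {
        sim_args$delta_pairs <- lapply(sim_args$delta_pairs, unlist)
      }
      sim <- tryCatch(do.call(sim_config, sim_args),
                      error = function(e) {
                        errs <<- c(errs, conditionMessage(e))
                        NULL
                      })
    }
  }
  if (length(errs)) {
    stop("invalid pipeline config:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  enr <- utils::modifyList(list(window_kb = 100, n_blocks = 200,
                                exclude_emhc = TRUE),
                           raw$enrichment %||% list())
  fmri_raw <- raw$fmri %||% list()
  fm <- utils::modifyList(list(n_folds = 3, min_rois = 2, n_perm = 100,
                               backend = "logistic"), fmri_raw)
  list(sim = sim, enrichment = enr,
       regions = raw$regions %||% list(exclude = character(0)), fmri = fm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full synthetic pipeline
#'
#' Executes simulate -> TDEP -> enrichment (with a self-diagonal
#' conditional row) -> regional aggregation -> gene-set/co-occurrence ->
#' connectivity RFE, writes every table as TSV under `out_dir`, and returns
#' (and writes) a JSON manifest with file paths, the seed, and file
#' checksums so the whole run is re-derivable.
#'
#' @param config list from [validate_config()], or a [sim_config()] (then
#'   stage defaults are used).
#' @param out_dir output directory (created if needed).
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (inherits(config, "sim_config")) {
    config <- list(sim = config,
                   enrichment = list(window_kb = 100, n_blocks = 200,
                                     exclude_emhc = TRUE),
                   regions = list(exclude = character(0)),
                   fmri = list(n_folds = 3, min_rois = 2, n_perm = 100,
                               backend = "logistic"))
  }
  cfg <- config$sim
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  put <- function(obj, name) {
    f <- file.path(out_dir, name)
    utils::write.table(obj, f, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[name]] <<- f
    f
  }

  # stage 1: simulate
  ann <- generate_gene_annotation(cfg)
  atlas <- generate_atlas(cfg)
  put(ann, "gene_annotation.tsv")
  put(data.frame(gene = rownames(atlas$expr), atlas$expr,
                 check.names = FALSE), "expression_counts.tsv")
  put(atlas$hierarchy, "hierarchy.tsv")
  put(data.frame(cluster = rownames(atlas$composition), atlas$composition,
                 check.names = FALSE), "composition.tsv")

  # stage 2: specificity / TDEP (cluster level)
  background <- filter_background(atlas$expr, ann)
  spec <- specificity_table(atlas$expr, background)
  tdep_long <- data.frame(
    cell_type = rep(colnames(spec$tdep), each = nrow(spec$tdep)),
    gene = rep(rownames(spec$tdep), ncol(spec$tdep)),
    tdep = as.vector(spec$tdep)
  )
  put(tdep_long[tdep_long$tdep, c("cell_type", "gene")], "tdep_sets.tsv")

  # stage 3: GWAS + enrichment for the first cluster's TDEP set
  target_ct <- names(which.max(lengths(spec$tdep_sets)))
  smap <- snp_map(cfg)
  target_ann <- build_annotation(spec$tdep_sets[[target_ct]], ann, smap,
                                 window_kb = config$enrichment$window_kb,
                                 name = target_ct)
  gwas <- generate_gwas(cfg, target_ann)
  put(gwas$sumstats, "sumstats.tsv")
  annotations <- list(base = rep(1, cfg$n_snps), target = target_ann)
  names(annotations)[2] <- target_ct
  ld <- compute_ld_scores(gwas$panel, annotations,
                          window_snps = cfg$ld_block_size)
  excl <- if (isTRUE(config$enrichment$exclude_emhc)) {
    emhc_snps(cfg, gwas$sumstats)
  }
  enr <- sldsc_fit(gwas$sumstats, ld, annotations, target = target_ct,
                   n_blocks = config$enrichment$n_blocks, exclude = excl)
  enr$trait <- "synthetic_trait"
  enr <- fdr_adjust(enr)
  put(enr, "enrichment.tsv")

  # stage 4: regional aggregation (planted Z map from the enrichment run,
  # cluster-level Z equal to the fitted target z for TDEP-target cluster,
  # 0 for the rest: a minimal demonstration wiring)
  cz <- stats::setNames(rep(0, cfg$n_clusters), atlas$hierarchy$cluster)
  cz[target_ct] <- enr$z[1]
  prop <- cluster_proportions(atlas$composition, atlas$hierarchy,
                              exclude = config$regions$exclude)
  reg <- dissection_enrichment(prop, cz)
  put(reg, "regional_enrichment.tsv")

  # stage 5: gene sets + genomic co-occurrence
  bg_ann <- ann[ann$gene %in% background, ]
  chrom_lengths <- stats::setNames(rep(cfg$chrom_length, cfg$n_chrom),
                                   paste0("chr", seq_len(cfg$n_chrom)))
  bins <- bin_genome(bg_ann, chrom_lengths, spec$tdep_sets)
  cooc <- cooccurrence_residuals(bins)
  put(bins, "bins.tsv")
  put(data.frame(cell_type = rownames(cooc$spearman), cooc$spearman,
                 check.names = FALSE), "cooccurrence_spearman.tsv")

  # stage 6: connectivity classification
  fmri <- generate_fmri(cfg)
  conn <- lapply(fmri$ts, compute_connectivity)
  folds <- make_folds(fmri$labels, vapply(fmri$ts, nrow, 1L),
                      n_folds = config$fmri$n_folds, seed = cfg$seed)
  fcfg <- fmri_config(backend = config$fmri$backend)
  traces <- lapply(seq_len(config$fmri$n_folds), function(f) {
    rfe(conn, fmri$labels, folds, f, config = fcfg,
        min_rois = config$fmri$min_rois, n_perm = config$fmri$n_perm,
        seed = cfg$seed + f)
  })
  agg <- aggregate_fi(traces)
  flagged <- fmri$roi_meta$roi[fmri$roi_meta$group == "limbic"]
  topn <- topn_enrichment(`dimnames<-`(agg, list(fmri$roi_meta$roi,
                                                 fmri$roi_meta$roi)),
                          flagged)
  put(data.frame(roi = fmri$roi_meta$roi, agg, check.names = FALSE),
      "aggregated_fi.tsv")
  put(topn, "topn_enrichment.tsv")

  manifest <- list(
    seed = cfg$seed,
    files = lapply(paths, function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    }),
    stages = c("simulate", "tdep", "enrich", "regions", "cooccur", "fmri")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' SNPs inside the synthetic extended MHC
#'
#' @param cfg a [sim_config()].
#' @param sumstats sumstats table with `chrom`, `pos`.
#' @return logical exclusion mask over SNPs.
#' @export
emhc_snps <- function(cfg, sumstats) {
  reg <- emhc_region(cfg)
  sumstats$chrom == reg$chrom & sumstats$pos >= reg$start &
    sumstats$pos < reg$end
}
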