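# End-to-end pipeline: classify -> cluster -> pair -> summarize -> cohort
# statistics, driven by a single validated config, with machine-readable
# reports and a manifest.

PIPELINE_DEFAULTS <- list(
  reference = NULL,
  vcf_dir = NULL,
  variants_tsv = NULL,
  sample_table = NULL,
  out_dir = NULL,
  seed = 1L,
  normalize = TRUE,
  min_mh = 1L,
  hrdetect_cutoff = 0.70,
  cluster = list(imd_threshold = NULL, null_q = 0.01, min_size = 2L,
                 apobec_fraction_threshold = 2 / 3,
                 require_strand_coordination = TRUE),
  proximity = list(window = 1e5, indel_anchor = "left_breakpoint",
                   dedupe = FALSE, restrict_to = "mmd"))

#' Validate a pipeline run configuration
#'
#' Accepts a YAML file path or a list. All problems are collected and
#' reported at once; unknown keys produce a warning (forward
#' compatibility), missing keys are filled with defaults.
#'
#' @param config Path to a YAML config or a named list.
#' @return The completed config list (class `run_config`); errors if any
#'   check fails, with every failure in the message.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  unknown <- setdiff(names(config), names(PIPELINE_DEFAULTS))
  if (length(unknown)) {
    warning("unknown config key(s) ignored: ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(PIPELINE_DEFAULTS, config, keep.null = TRUE)
  errs <- character()
  add_err <- function(msg) errs <<- c(errs, msg)

  if (is.null(cfg$reference)) add_err("reference: required")
  else if (!file.exists(cfg$reference)) {
    add_err(paste0("reference: file not found (", cfg$reference, ")"))
  }
  if (is.null(cfg$vcf_dir) && is.null(cfg$variants_tsv)) {
    add_err("one of vcf_dir / variants_tsv is required")
  }
  if (!is.null(cfg$vcf_dir) && !dir.exists(cfg$vcf_dir)) {
    add_err(paste0("vcf_dir: directory not found (", cfg$vcf_dir, ")"))
  }
  if (!is.null(cfg$variants_tsv) && !file.exists(cfg$variants_tsv)) {
    add_err(paste0("variants_tsv: file not found (", cfg$variants_tsv, ")"))
  }
  if (!is.null(cfg$sample_table) && !file.exists(cfg$sample_table)) {
    add_err(paste0("sample_table: file not found (", cfg$sample_table, ")"))
  }
  if (is.null(cfg$out_dir)) add_err("out_dir: required")
  if (!is.null(cfg$cluster$imd_threshold) && cfg$cluster$imd_threshold <= 0) {
    add_err("cluster$imd_threshold: must be > 0 when set")
  }
  if (cfg$cluster$null_q <= 0 || cfg$cluster$null_q >= 1) {
    add_err("cluster$null_q: must lie in (0, 1)")
  }
  if (cfg$cluster$min_size < 2) add_err("cluster$min_size: must be >= 2")
  if (abs(cfg$cluster$apobec_fraction_threshold - 2 / 3) > 1e-12) {
    warning("cluster$apobec_fraction_threshold differs from the defining ",
            "2/3 rule; results will not follow the standard categorization")
  }
  if (cfg$proximity$window <= 0) add_err("proximity$window: must be > 0")
  if (!cfg$proximity$indel_anchor %in% c("left_breakpoint", "midpoint")) {
    add_err("proximity$indel_anchor: must be left_breakpoint or midpoint")
  }
  if (!cfg$proximity$restrict_to %in% c("mmd", "all")) {
    add_err("proximity$restrict_to: must be mmd or all")
  }
  if (cfg$hrdetect_cutoff <= 0 || cfg$hrdetect_cutoff >= 1) {
    add_err("hrdetect_cutoff: must lie in (0, 1)")
  }
  if (cfg$min_mh < 1) add_err("min_mh: must be >= 1")
  if (length(errs)) {
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  }
  structure(cfg, class = "run_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

pipe_log <- function(...) message("[tmejscan] ", ...)

#' Run the full footprint analysis pipeline
#'
#' Stages: load reference and variant calls; normalize; SBS-96
#' classification and APOBEC3 burden; ID83 classification and MMD burden;
#' per-sample cluster detection and categorization; cluster-indel pairing
#' and proximity summary; cohort statistics (HR-deficiency exclusion,
#' burden correlations, treated-vs-control MMD comparison).  Writes TSV
#' reports plus a JSON manifest with the package version, the echoed
#' config, and input/output checksums.  Deterministic given identical
#' inputs and config.
#'
#' @param config Path to a YAML config or a list (see [validate_config()]).
#' @return Invisibly, a list with every intermediate table (`sbs`, `indel`,
#'   `clusters`, `pairs`, `proximity`, `sample_summary`, `correlations`,
#'   `mmd_comparison`, `dropped`, `out_dir`).
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()

  genome <- with_stage("load_reference", load_reference(cfg$reference))
  pipe_log("reference loaded: ", length(genome$seq), " contig(s)")

  records <- with_stage("read_variants", {
    if (!is.null(cfg$vcf_dir)) {
      vcfs <- list.files(cfg$vcf_dir, pattern = "\\.vcf(\\.gz|\\.bgz)?$",
                         full.names = TRUE)
      if (length(vcfs) == 0L) stop("no VCF files in ", cfg$vcf_dir)
      do.call(rbind, lapply(vcfs, function(p) {
        sid <- sub("\\.vcf(\\.gz|\\.bgz)?$", "", basename(p))
        read_variants(p, sample_id = sid)
      }))
    } else {
      read_variants_tsv(cfg$variants_tsv)
    }
  })
  pipe_log(nrow(records), " variant record(s) read")

  nv <- with_stage("normalize", {
    if (isTRUE(cfg$normalize)) normalize_variants(records, genome)
    else stop("normalize=false is not supported for VCF-convention input")
  })
  samples <- sort(unique(nv$sample_id))

  sbs <- with_stage("sbs_catalog", build_sbs_burden(nv, genome, samples))
  indel <- with_stage("indel_catalog",
                      build_indel_burden(nv, genome, samples,
                                         min_mh = cfg$min_mh))
  pipe_log("classified ", sum(sbs$summary$total), " SNV(s) and ",
           sum(indel$summary$total), " indel(s)")

  cl_res <- with_stage("clusters", {
    snv <- nv[nv$kind == "SNV", , drop = FALSE]
    cls <- classify_sbs96(snv, genome)
    subs <- data.frame(sample_id = snv$sample_id, contig = snv$contig,
                       pos = snv$start, is_apobec3 = cls$is_apobec3,
                       orientation = cls$orientation,
                       stringsAsFactors = FALSE)
    subs <- subs[!is.na(subs$is_apobec3), , drop = FALSE]
    subs <- subs[order(subs$sample_id, subs$contig, subs$pos), , drop = FALSE]
    params <- cluster_params(
      imd_threshold = cfg$cluster$imd_threshold,
      null_q = cfg$cluster$null_q, min_size = cfg$cluster$min_size,
      apobec_fraction_threshold = cfg$cluster$apobec_fraction_threshold,
      require_strand_coordination = cfg$cluster$require_strand_coordination)
    detect_clusters(subs, params, callable_length_bp = genome_length(genome))
  })
  pipe_log(nrow(cl_res$clusters), " substitution cluster(s) detected")

  pairs <- with_stage("proximity", {
    pair_within_window(cl_res$clusters, indel$annotations,
                       proximity_params(window = cfg$proximity$window,
                                        indel_anchor = cfg$proximity$indel_anchor,
                                        dedupe = cfg$proximity$dedupe))
  })
  prox <- with_stage("proximity_summary",
                     summarize_proximity(pairs,
                                         restrict_to = cfg$proximity$restrict_to))

  # cohort statistics
  sample_summary <- merge(sbs$summary, indel$summary[, c("sample_id",
                                                         "total", "mmd_count")],
                          by = "sample_id", suffixes = c("_snv", "_indel"))
  names(sample_summary)[names(sample_summary) == "total_snv"] <- "snv_total"
  names(sample_summary)[names(sample_summary) == "total_indel"] <- "indel_total"
  if (!is.null(cfg$sample_table)) {
    st <- utils::read.delim(cfg$sample_table, stringsAsFactors = FALSE)
    sample_summary <- merge(sample_summary, st, by = "sample_id", all.x = TRUE)
  }
  if (!"group" %in% names(sample_summary)) sample_summary$group <- "cohort"
  if (!"hrdetect_prob" %in% names(sample_summary)) {
    sample_summary$hrdetect_prob <- NA_real_
  }
  sample_summary <- sample_summary[order(sample_summary$sample_id), ,
                                   drop = FALSE]

  hr <- with_stage("hrdetect_filter", suppressWarnings(
    filter_hrdetect(sample_summary, cutoff = cfg$hrdetect_cutoff)))
  retained <- hr$retained

  correlations <- list()
  if (nrow(retained) >= 3L && stats::sd(retained$apobec_count) > 0 &&
      stats::sd(retained$mmd_count) > 0) {
    correlations$apobec_vs_mmd <- with_stage("correlations",
      correlate(retained$apobec_count, retained$mmd_count, "pearson"))
  }
  if ("external_score" %in% names(retained)) {
    ok <- !is.na(retained$external_score)
    if (sum(ok) >= 3L && stats::sd(retained$external_score[ok]) > 0) {
      correlations$apobec_vs_external <- with_stage("correlations",
        correlate(retained$apobec_count[ok], retained$external_score[ok],
                  "spearman"))
    }
  }

  mmd_comparison <- NULL
  tr <- retained$mmd_count[retained$group == "treated"]
  co <- retained$mmd_count[retained$group == "control"]
  if (length(tr) >= 2L && length(co) >= 2L) {
    mmd_comparison <- with_stage("mmd_comparison",
                                 compare_replicate_mmds(tr, co))
  }

  with_stage("write_reports", {
    out <- cfg$out_dir
    w <- function(x, f) utils::write.table(x, file.path(out, f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
    mat_df <- function(m) cbind(data.frame(channel = rownames(m),
                                           stringsAsFactors = FALSE),
                                as.data.frame(m))
    w(mat_df(sbs$matrix), "sbs96_matrix.tsv")
    w(mat_df(indel$matrix), "id83_matrix.tsv")
    w(sample_summary, "sample_summary.tsv")
    cl_out <- cl_res$clusters
    if (nrow(cl_out) > 0L) {
      cl_out <- data.frame(contig = cl_out$contig,
                           span_start = cl_out$span_start,
                           span_end = cl_out$span_end + 1L,  # half-open
                           cluster_id = cl_out$cluster_id,
                           sample_id = cl_out$sample_id,
                           n_total = cl_out$n_total,
                           n_apobec = cl_out$n_apobec,
                           category = cl_out$category,
                           center = cl_out$center,
                           threshold = cl_out$threshold,
                           stringsAsFactors = FALSE)
    }
    w(cl_out, "clusters.tsv")
    p_out <- pairs
    if (nrow(p_out) > 0L) {
      p_out$distance_mb <- sprintf("%.3f", p_out$distance / 1e6)
    } else {
      p_out$distance_mb <- character(0)
    }
    w(p_out, "pairs.tsv")
    prox_df <- prox$per_category
    prox_df$ratio_of_medians <- prox$ratio_of_medians
    prox_df$t_statistic <- prox$t_statistic
    prox_df$p_one_sided <- prox$p_one_sided
    prox_df$test <- prox$test
    w(prox_df, "proximity_summary.tsv")
    if (length(correlations)) {
      w(do.call(rbind, lapply(names(correlations), function(nm) {
        cr <- correlations[[nm]]
        data.frame(contrast = nm, method = cr$method, r = cr$r, p = cr$p,
                   n = cr$n, stringsAsFactors = FALSE)
      })), "correlations.tsv")
    }
    if (!is.null(mmd_comparison)) {
      w(as.data.frame(mmd_comparison), "mmd_comparison.tsv")
    }
    w(hr$excluded, "hrdetect_exclusions.tsv")

    inputs <- c(cfg$reference, cfg$variants_tsv, cfg$sample_table)
    if (!is.null(cfg$vcf_dir)) {
      inputs <- c(inputs, list.files(cfg$vcf_dir, full.names = TRUE,
                                     pattern = "\\.vcf(\\.gz|\\.bgz)?$"))
    }
    inputs <- inputs[!vapply(inputs, is.null, logical(1))]
    outputs <- list.files(out, pattern = "\\.tsv$", full.names = TRUE)
    manifest <- list(
      tool = "tmejscan",
      version = as.character(utils::packageVersion("tmejscan")),
      seed = cfg$seed,
      config = unclass(cfg),
      input_md5 = as.list(tools::md5sum(unlist(inputs))),
      output_md5 = as.list(tools::md5sum(outputs)),
      n_variants = nrow(records),
      dropped = as.list(attr(nv, "dropped")))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null",
                         digits = NA)
  })
  pipe_log("done in ", sprintf("%.1f", as.numeric(Sys.time() - t0,
                                                  units = "secs")), " s")

  invisible(list(sbs = sbs, indel = indel, clusters = cl_res, pairs = pairs,
                 proximity = prox, sample_summary = sample_summary,
                 correlations = correlations, mmd_comparison = mmd_comparison,
                 hrdetect = hr, dropped = attr(nv, "dropped"),
                 out_dir = cfg$out_dir))
}
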