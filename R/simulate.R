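# Seeded synthetic-cohort generator.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: treated samples carry double-strand-break (DSB) loci at which
# kataegis-like substitution clusters are planted (TCW C>T/G members on one
# strand for APOBEC3 clusters, non-TCW substitutions for clusters from
# other mutagenic factors) together with microhomology-mediated deletions
# (MMDs) at Gaussian offsets from the DSB; control samples carry a scaled
# baseline MMD load and background noise only.  The reference is locally
# edited when an MMD is planted so the requested microhomology length holds
# exactly, giving exact truth labels at any genome size.  Every emitted
# variant has one truth-table row.

BASES <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' Defaults describe a doxycycline-inducible APOBEC3A exposure experiment:
#' 5 treated and 3 control replicates, ~13 expected DSB-associated MMDs per
#' treated replicate against a control baseline of ~9 (`13 *
#' control_mmd_multiplier`), MMD offsets of sigma 20 kb around APOBEC3
#' cluster loci and 40 kb around other-cluster loci, and kataegis tracts of
#' about 1 kb.
#'
#' @param seed Integer seed fixing every draw.
#' @param n_contigs,contig_length Simulated genome shape.
#' @param n_samples_treated,n_samples_control Replicate design.
#' @param n_dsb_sites DSB loci per treated sample.
#' @param p_cluster_at_dsb Probability a DSB locus carries a substitution
#'   cluster.
#' @param p_apobec_cluster Probability a planted cluster is APOBEC3-type
#'   (vs "other").
#' @param cluster_size_mean Mean cluster size (member count is
#'   `2 + Poisson(mean - 2)`, so clusters always have >= 2 members).
#' @param cluster_span Span in bp within which cluster members are placed.
#' @param apobec_fraction_in_clusters Expected fraction of TCW C>T/G
#'   members within an APOBEC3-type cluster.
#' @param background_snv_rate,background_indel_rate Background event rates
#'   per bp per sample.
#' @param mmd_per_dsb Expected MMD count per DSB locus.
#' @param mmd_count_model `"poisson"` (replicate-to-replicate count noise)
#'   or `"fixed"` (exact planted counts).
#' @param mmd_length_range,mmd_mh_length_range Deletion length and
#'   microhomology length ranges (mh is capped at length - 1).
#' @param mmd_offset_sigma_apobec,mmd_offset_sigma_other Gaussian sd (bp)
#'   of MMD offsets from their parent DSB, by cluster category.
#' @param control_mmd_multiplier Control-sample MMD load relative to the
#'   treated per-sample expectation, in \[0, 1\].
#' @param min_dsb_separation Minimum spacing between DSB loci of one
#'   sample (bp).
#' @return Validated config list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_contigs = 6L,
                       contig_length = 4e6,
                       n_samples_treated = 5L,
                       n_samples_control = 3L,
                       n_dsb_sites = 13L,
                       p_cluster_at_dsb = 0.8,
                       p_apobec_cluster = 0.5,
                       cluster_size_mean = 6,
                       cluster_span = 1000L,
                       apobec_fraction_in_clusters = 0.9,
                       background_snv_rate = 1e-6,
                       background_indel_rate = 3e-7,
                       mmd_per_dsb = 1,
                       mmd_count_model = c("poisson", "fixed"),
                       mmd_length_range = c(2L, 20L),
                       mmd_mh_length_range = c(1L, 5L),
                       mmd_offset_sigma_apobec = 2e4,
                       mmd_offset_sigma_other = 4e4,
                       control_mmd_multiplier = 9 / 13,
                       min_dsb_separation = 2e5) {
  cfg <- list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
              contig_length = contig_length,
              n_samples_treated = as.integer(n_samples_treated),
              n_samples_control = as.integer(n_samples_control),
              n_dsb_sites = as.integer(n_dsb_sites),
              p_cluster_at_dsb = p_cluster_at_dsb,
              p_apobec_cluster = p_apobec_cluster,
              cluster_size_mean = cluster_size_mean,
              cluster_span = as.integer(cluster_span),
              apobec_fraction_in_clusters = apobec_fraction_in_clusters,
              background_snv_rate = background_snv_rate,
              background_indel_rate = background_indel_rate,
              mmd_per_dsb = mmd_per_dsb,
              mmd_count_model = match.arg(mmd_count_model),
              mmd_length_range = as.integer(mmd_length_range),
              mmd_mh_length_range = as.integer(mmd_mh_length_range),
              mmd_offset_sigma_apobec = mmd_offset_sigma_apobec,
              mmd_offset_sigma_other = mmd_offset_sigma_other,
              control_mmd_multiplier = control_mmd_multiplier,
              min_dsb_separation = min_dsb_separation)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_contigs < 1L) stop("n_contigs must be >= 1")
  if (cfg$contig_length < 1000) stop("contig_length must be >= 1000 bp")
  rates <- c(cfg$p_cluster_at_dsb, cfg$p_apobec_cluster,
             cfg$apobec_fraction_in_clusters, cfg$control_mmd_multiplier)
  if (any(rates < 0 | rates > 1)) stop("probabilities must lie in [0, 1]")
  if (any(c(cfg$background_snv_rate, cfg$background_indel_rate,
            cfg$mmd_per_dsb) < 0)) stop("rates must be >= 0")
  if (cfg$mmd_length_range[1L] < 2L) stop("MMD deletions must be >= 2 bp")
  if (cfg$mmd_mh_length_range[1L] < 1L) stop("MMD microhomology must be >= 1 bp")
  if (cfg$mmd_mh_length_range[1L] >= cfg$mmd_length_range[1L]) {
    stop("microhomology lower bound must be below the deletion length lower bound")
  }
  if (any(c(cfg$mmd_offset_sigma_apobec, cfg$mmd_offset_sigma_other) <= 0)) {
    stop("offset sigmas must be > 0")
  }
  invisible(cfg)
}

#' Simulate a reference genome of i.i.d. uniform bases
#'
#' @param config A [sim_config()].
#' @return A [ref_genome()] with contigs `chr1..chrN`. Identical seeds give
#'   identical genomes.
#' @export
simulate_reference <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  seqs <- vapply(seq_len(config$n_contigs), function(i) {
    paste(sample(BASES, config$contig_length, replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- paste0("chr", seq_len(config$n_contigs))
  ref_genome(seqs)
}

# ---- occupancy bookkeeping ------------------------------------------------

new_occupancy <- function(genome) {
  occ <- new.env(parent = emptyenv())
  for (ctg in names(genome$seq)) assign(ctg, cbind(s = numeric(0), e = numeric(0)), occ)
  occ
}

occ_free <- function(occ, contig, s, e) {
  iv <- get(contig, occ)
  !any(iv[, "s"] <= e & iv[, "e"] >= s)
}

occ_reserve <- function(occ, contig, s, e) {
  assign(contig, rbind(get(contig, occ), c(s = s, e = e)), occ)
}

# ---- MMD planting ---------------------------------------------------------

#' Plant a microhomology-mediated deletion at a locus
#'
#' Locally edits the reference so the deletion of `[del_start, del_start +
#' del_len)` has microhomology length exactly `mh_len`: the `mh_len`-prefix
#' of the deleted segment is copied immediately 3' of it, capped by a
#' mismatching base (so no full adjacent copy exists and the measured
#' microhomology cannot exceed `mh_len`), and the base 5' of the deletion
#' is forced to differ from the deletion's last base (so the event is
#' already left-aligned and carries no 5'-side microhomology).  With
#' `mh_len = 0` the flanks are scrambled so the deletion is a
#' non-repeat, non-microhomology event.
#'
#' @param genome A [ref_genome()] (returned edited).
#' @param contig Contig name.
#' @param del_start 0-based start of the deletion.
#' @param del_len Deletion length (>= 2).
#' @param mh_len Target microhomology length, `0 <= mh_len < del_len`.
#' @return List: `genome` (edited), `start`, `deleted_seq`, `mh_length`.
#' @export
plant_mmd <- function(genome, contig, del_start, del_len, mh_len) {
  if (del_len < 2L) stop("MMD deletions must be >= 2 bp")
  if (mh_len < 0L || mh_len >= del_len) {
    stop("mh_len must satisfy 0 <= mh_len < del_len (proper prefix)")
  }
  len <- genome$lengths[[contig]]
  if (del_start < 1L || del_start + 2L * del_len + 1L > len) {
    stop("MMD locus too close to a contig edge")
  }
  D <- ref_fetch(genome, contig, del_start, del_start + del_len)
  if (mh_len > 0L) {
    genome <- ref_replace(genome, contig, del_start + del_len,
                          substr(D, 1L, mh_len))
  }
  cap_pos <- del_start + del_len + mh_len
  need_diff <- substr(D, mh_len + 1L, mh_len + 1L)
  if (ref_fetch(genome, contig, cap_pos, cap_pos + 1L) == need_diff) {
    genome <- ref_replace(genome, contig, cap_pos,
                          sample(setdiff(BASES, need_diff), 1L))
  }
  tail_base <- substr(D, del_len, del_len)
  if (ref_fetch(genome, contig, del_start - 1L, del_start) == tail_base) {
    genome <- ref_replace(genome, contig, del_start - 1L,
                          sample(setdiff(BASES, tail_base), 1L))
  }
  list(genome = genome, start = del_start, deleted_seq = D,
       mh_length = as.integer(mh_len))
}

# TCW site scan: 0-based positions of the mutated C (or G on the minus
# strand) within [start0, end0) whose full trinucleotide lies in bounds.
scan_tcw_sites <- function(genome, contig, start0, end0, strand) {
  win <- ref_fetch(genome, contig, start0, end0)
  pat <- if (strand == "+") "(?=TC[AT])" else "(?=[AT]GA)"
  m <- gregexpr(pat, win, perl = TRUE)[[1]]
  if (m[1L] == -1L) return(integer(0))
  pos <- start0 + as.integer(m)  # motif start 0-based = start0 + m - 1; center +1
  pos[pos - 1L >= 0L & pos + 2L <= genome$lengths[[contig]]]
}

# Choose an alt allele at pos0 that is guaranteed non-APOBEC3.
non_apobec_alt <- function(genome, contig, pos0) {
  ref <- ref_fetch(genome, contig, pos0, pos0 + 1L)
  ctx <- get_context(genome, contig, pos0, 1L)
  pyr_ctx <- if (ref %in% PURINES) revcomp(ctx) else ctx
  tcw <- substr(pyr_ctx, 1L, 1L) == "T" && substr(pyr_ctx, 2L, 2L) == "C" &&
    substr(pyr_ctx, 3L, 3L) %in% c("A", "T")
  if (tcw) {
    # C>A on the pyrimidine strand is never an APOBEC3 call
    if (ref %in% PURINES) "T" else "A"
  } else {
    sample(setdiff(BASES, ref), 1L)
  }
}

# Draw a contig (length-weighted) and a position with margins.
draw_locus <- function(genome, margin) {
  ctg <- sample(names(genome$seq), 1L,
                prob = as.numeric(genome$lengths) / genome_length(genome))
  len <- genome$lengths[[ctg]]
  list(contig = ctg, pos = sample.int(len - 2L * margin, 1L) + margin)
}

# ---- cohort simulation ----------------------------------------------------

#' Simulate a treated/control somatic cohort with ground truth
#'
#' See the package vignette for the generative model. All randomness is
#' governed by `config$seed`; identical seeds give identical outputs (and
#' byte-identical files when `dir` is given).
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory; when given, writes `ref.fa`, one
#'   `<sample>.vcf` per sample, `truth.tsv`, `truth_clusters.tsv` and
#'   `config.yaml`.
#' @return List: `genome` (edited [ref_genome()]), `variants`
#'   (VariantRecord data.frame over all samples, 1-based `pos`),
#'   `truth` (per-event truth table), `truth_clusters`, `dsb_sites`,
#'   `sample_table` (sample_id, group), `config`, and (with `dir`) `paths`.
#' @export
simulate_cohort <- function(config, dir = NULL) {
  validate_sim_config(config)
  genome <- simulate_reference(config)  # seeds the RNG with config$seed
  occ <- new_occupancy(genome)
  margin <- 100L
  max_try <- 500L

  treated <- sprintf("treated_%d", seq_len(config$n_samples_treated))
  control <- sprintf("control_%d", seq_len(config$n_samples_control))
  sample_table <- data.frame(
    sample_id = c(treated, control),
    group = rep(c("treated", "control"),
                c(length(treated), length(control))),
    stringsAsFactors = FALSE)

  truth <- list(); events <- list(); dsb_rows <- list()
  ev_n <- 0L
  add_event <- function(nv_row, truth_row) {
    ev_n <<- ev_n + 1L
    truth_row$event_id <- sprintf("ev%06d", ev_n)
    events[[ev_n]] <<- nv_row
    truth[[ev_n]] <<- truth_row
  }

  draw_count <- function(lambda) {
    if (config$mmd_count_model == "poisson") stats::rpois(1L, lambda)
    else as.integer(round(lambda))
  }

  plant_one_mmd <- function(sid, anchor_contig, anchor_pos, sigma,
                            category, dsb_id) {
    for (k in seq_len(max_try)) {
      if (is.null(anchor_pos)) {
        loc <- draw_locus(genome, margin)
        ctg <- loc$contig; pos <- loc$pos
      } else {
        ctg <- anchor_contig
        pos <- anchor_pos + as.integer(round(stats::rnorm(1L, 0, sigma)))
      }
      del_len <- sample(seq(config$mmd_length_range[1L],
                            config$mmd_length_range[2L]), 1L)
      mh_len <- sample(seq(config$mmd_mh_length_range[1L],
                           config$mmd_mh_length_range[2L]), 1L)
      mh_len <- min(mh_len, del_len - 1L)
      lo <- pos - 2L; hi <- pos + 2L * del_len + 2L
      if (lo < margin || hi > genome$lengths[[ctg]] - margin) next
      if (!occ_free(occ, ctg, lo, hi)) next
      res <- plant_mmd(genome, ctg, pos, del_len, mh_len)
      genome <<- res$genome
      occ_reserve(occ, ctg, lo, hi)
      add_event(
        data.frame(contig = ctg, start = pos, kind = "deletion",
                   deleted_seq = res$deleted_seq, inserted_seq = "",
                   ref_base = NA_character_, alt_base = NA_character_,
                   sample_id = sid, stringsAsFactors = FALSE),
        data.frame(sample_id = sid, contig = ctg, position = pos,
                   event_type = "mmd", planted_category = category,
                   planted_mh_length = mh_len, parent_dsb_id = dsb_id,
                   planted_is_apobec = NA, stringsAsFactors = FALSE))
      return(invisible(TRUE))
    }
    stop("could not place an MMD after ", max_try,
         " tries; event density exceeds genome capacity")
  }

  # Phase 1: DSB loci and all genome-editing events (MMDs).
  for (sid in treated) {
    dsb_pos <- list()
    for (d in seq_len(config$n_dsb_sites)) {
      placed <- FALSE
      for (k in seq_len(max_try)) {
        loc <- draw_locus(genome, margin + config$cluster_span)
        same <- vapply(dsb_pos, function(p) {
          p$contig == loc$contig &&
            abs(p$pos - loc$pos) < config$min_dsb_separation
        }, logical(1))
        if (!any(same)) { placed <- TRUE; break }
      }
      if (!placed) stop("could not place DSB sites at the requested density")
      dsb_id <- sprintf("%s_dsb%02d", sid, d)
      category <- if (stats::runif(1L) < config$p_apobec_cluster) "APOBEC3" else "other"
      has_cluster <- stats::runif(1L) < config$p_cluster_at_dsb
      dsb_pos[[d]] <- list(contig = loc$contig, pos = loc$pos)
      dsb_rows[[dsb_id]] <- data.frame(
        dsb_id = dsb_id, sample_id = sid, contig = loc$contig,
        pos = loc$pos, category = category, has_cluster = has_cluster,
        stringsAsFactors = FALSE)
      sigma <- if (category == "APOBEC3") config$mmd_offset_sigma_apobec
               else config$mmd_offset_sigma_other
      for (m in seq_len(draw_count(config$mmd_per_dsb))) {
        plant_one_mmd(sid, loc$contig, loc$pos, sigma, category, dsb_id)
      }
    }
  }
  for (sid in control) {
    lambda <- config$control_mmd_multiplier * config$n_dsb_sites *
      config$mmd_per_dsb
    for (m in seq_len(draw_count(lambda))) {
      plant_one_mmd(sid, NULL, NULL, NA, "none", NA_character_)
    }
  }

  dsb_sites <- if (length(dsb_rows)) do.call(rbind, dsb_rows) else
    data.frame(dsb_id = character(), sample_id = character(),
               contig = character(), pos = integer(), category = character(),
               has_cluster = logical(), stringsAsFactors = FALSE)
  rownames(dsb_sites) <- NULL

  # Phase 2a: substitution clusters at DSB loci (read-only on the genome).
  cluster_rows <- list()
  for (i in seq_len(nrow(dsb_sites))) {
    if (!dsb_sites$has_cluster[i]) next
    sid <- dsb_sites$sample_id[i]; ctg <- dsb_sites$contig[i]
    center <- dsb_sites$pos[i]; category <- dsb_sites$category[i]
    dsb_id <- dsb_sites$dsb_id[i]
    k <- 2L + stats::rpois(1L, max(config$cluster_size_mean - 2, 0))
    half <- floor(config$cluster_span / 2)
    lo <- max(margin, center - half); hi <- min(genome$lengths[[ctg]] - margin,
                                                center + half)
    strand <- sample(c("+", "-"), 1L)
    n_apo_target <- if (category == "APOBEC3") {
      stats::rbinom(1L, k, config$apobec_fraction_in_clusters)
    } else 0L
    tcw <- scan_tcw_sites(genome, ctg, lo, hi, strand)
    tcw <- tcw[vapply(tcw, function(p) occ_free(occ, ctg, p - 1L, p + 1L),
                      logical(1))]
    n_apo <- min(n_apo_target, length(tcw))
    apo_pos <- if (n_apo > 0L) sort(sample(tcw, n_apo)) else integer(0)
    for (p in apo_pos) occ_reserve(occ, ctg, p - 1L, p + 1L)
    n_other <- k - n_apo
    oth_pos <- integer(0)
    while (length(oth_pos) < n_other) {
      p <- sample(seq(lo, hi), 1L)
      if (!occ_free(occ, ctg, p - 1L, p + 1L)) next
      occ_reserve(occ, ctg, p - 1L, p + 1L)
      oth_pos <- c(oth_pos, p)
    }
    for (p in apo_pos) {
      ref <- ref_fetch(genome, ctg, p, p + 1L)
      alt <- if (strand == "+") sample(c("T", "G"), 1L) else sample(c("A", "C"), 1L)
      add_event(
        data.frame(contig = ctg, start = p, kind = "SNV", deleted_seq = "",
                   inserted_seq = "", ref_base = ref, alt_base = alt,
                   sample_id = sid, stringsAsFactors = FALSE),
        data.frame(sample_id = sid, contig = ctg, position = p,
                   event_type = "cluster_member", planted_category = category,
                   planted_mh_length = NA_integer_, parent_dsb_id = dsb_id,
                   planted_is_apobec = TRUE, stringsAsFactors = FALSE))
    }
    for (p in oth_pos) {
      ref <- ref_fetch(genome, ctg, p, p + 1L)
      alt <- non_apobec_alt(genome, ctg, p)
      add_event(
        data.frame(contig = ctg, start = p, kind = "SNV", deleted_seq = "",
                   inserted_seq = "", ref_base = ref, alt_base = alt,
                   sample_id = sid, stringsAsFactors = FALSE),
        data.frame(sample_id = sid, contig = ctg, position = p,
                   event_type = "cluster_member", planted_category = category,
                   planted_mh_length = NA_integer_, parent_dsb_id = dsb_id,
                   planted_is_apobec = FALSE, stringsAsFactors = FALSE))
    }
    cluster_rows[[dsb_id]] <- data.frame(
      dsb_id = dsb_id, sample_id = sid, contig = ctg, dsb_pos = center,
      category = category, strand = strand, n_members = n_apo + n_other,
      n_apobec = n_apo, apobec_fraction = (n_apo) / (n_apo + n_other),
      stringsAsFactors = FALSE)
  }
  truth_clusters <- if (length(cluster_rows)) do.call(rbind, cluster_rows) else
    data.frame(dsb_id = character(), sample_id = character(),
               contig = character(), dsb_pos = integer(),
               category = character(), strand = character(),
               n_members = integer(), n_apobec = integer(),
               apobec_fraction = numeric(), stringsAsFactors = FALSE)
  rownames(truth_clusters) <- NULL

  # Phase 2b: background noise (read-only on the genome).
  glen <- genome_length(genome)
  for (sid in c(treated, control)) {
    for (b in seq_len(stats::rpois(1L, config$background_snv_rate * glen))) {
      for (k in seq_len(max_try)) {
        loc <- draw_locus(genome, margin)
        if (!occ_free(occ, loc$contig, loc$pos - 1L, loc$pos + 1L)) next
        occ_reserve(occ, loc$contig, loc$pos - 1L, loc$pos + 1L)
        ref <- ref_fetch(genome, loc$contig, loc$pos, loc$pos + 1L)
        add_event(
          data.frame(contig = loc$contig, start = loc$pos, kind = "SNV",
                     deleted_seq = "", inserted_seq = "", ref_base = ref,
                     alt_base = sample(setdiff(BASES, ref), 1L),
                     sample_id = sid, stringsAsFactors = FALSE),
          data.frame(sample_id = sid, contig = loc$contig,
                     position = loc$pos, event_type = "background_snv",
                     planted_category = "none",
                     planted_mh_length = NA_integer_,
                     parent_dsb_id = NA_character_, planted_is_apobec = NA,
                     stringsAsFactors = FALSE))
        break
      }
    }
    for (b in seq_len(stats::rpois(1L, config$background_indel_rate * glen))) {
      type <- sample(c("ins1", "del1", "rep_del", "plain_del"), 1L,
                     prob = c(0.35, 0.3, 0.2, 0.15))
      plant_background_indel(type, sid, genome, occ, margin, max_try,
                             add_event)
    }
  }

  truth_df <- do.call(rbind, truth); rownames(truth_df) <- NULL
  truth_df <- truth_df[, c("event_id", "sample_id", "contig", "position",
                           "event_type", "planted_category",
                           "planted_mh_length", "parent_dsb_id",
                           "planted_is_apobec")]
  nv_df <- do.call(rbind, events); rownames(nv_df) <- NULL

  # Emit VariantRecord form (VCF convention) against the final genome.
  recs <- vector("list", nrow(nv_df))
  for (i in seq_len(nrow(nv_df))) {
    dn <- denormalize_variant(nv_df[i, ], genome)
    depth <- 30L + stats::rpois(1L, 30L)
    alt_count <- max(3L, stats::rbinom(1L, depth, 0.35))
    recs[[i]] <- data.frame(
      contig = nv_df$contig[i], pos = dn$pos, ref = dn$ref, alt = dn$alt,
      sample_id = nv_df$sample_id[i], caller = NA_character_,
      depth = depth, alt_count = alt_count, stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, recs)
  ord <- order(variants$sample_id, match(variants$contig, names(genome$seq)),
               variants$pos)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL

  out <- list(genome = genome, variants = variants, truth = truth_df,
              truth_clusters = truth_clusters, dsb_sites = dsb_sites,
              sample_table = sample_table, config = config)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(reference = file.path(dir, "ref.fa"),
                  truth = file.path(dir, "truth.tsv"),
                  truth_clusters = file.path(dir, "truth_clusters.tsv"),
                  sample_table = file.path(dir, "sample_table.tsv"),
                  config = file.path(dir, "config.yaml"))
    write_reference(genome, paths$reference)
    utils::write.table(truth_df, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(truth_clusters, paths$truth_clusters, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(sample_table, paths$sample_table, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    yaml::write_yaml(unclass(config), paths$config)
    paths$vcf <- character(0)
    for (sid in sample_table$sample_id) {
      p <- file.path(dir, paste0(sid, ".vcf"))
      write_variants_vcf(variants[variants$sample_id == sid, , drop = FALSE],
                         p, genome, sample_id = sid)
      paths$vcf[sid] <- p
    }
    out$paths <- paths
  }
  out
}

plant_background_indel <- function(type, sid, genome, occ, margin, max_try,
                                   add_event) {
  for (k in seq_len(max_try)) {
    loc <- draw_locus(genome, margin)
    ctg <- loc$contig; p <- loc$pos
    if (type == "ins1") {
      b <- sample(BASES, 1L)
      while (p > 0L && ref_fetch(genome, ctg, p - 1L, p) == b) p <- p - 1L
      if (p < margin || !occ_free(occ, ctg, p - 2L, p + 6L)) next
      occ_reserve(occ, ctg, p - 2L, p + 6L)
      nv <- data.frame(contig = ctg, start = p, kind = "insertion",
                       deleted_seq = "", inserted_seq = b,
                       ref_base = NA_character_, alt_base = NA_character_,
                       sample_id = sid, stringsAsFactors = FALSE)
    } else if (type == "del1") {
      b <- ref_fetch(genome, ctg, p, p + 1L)
      while (p > 0L && ref_fetch(genome, ctg, p - 1L, p) == b) p <- p - 1L
      if (p < margin || !occ_free(occ, ctg, p - 2L, p + 6L)) next
      occ_reserve(occ, ctg, p - 2L, p + 6L)
      nv <- data.frame(contig = ctg, start = p, kind = "deletion",
                       deleted_seq = b, inserted_seq = "",
                       ref_base = NA_character_, alt_base = NA_character_,
                       sample_id = sid, stringsAsFactors = FALSE)
    } else if (type == "rep_del") {
      # find a natural tandem copy near the locus: genome[s, s+u) ==
      # genome[s+u, s+2u)
      found <- FALSE
      for (s in seq(p, min(p + 200L, genome$lengths[[ctg]] - margin - 10L))) {
        for (u in 2:4) {
          if (ref_fetch(genome, ctg, s, s + u) ==
              ref_fetch(genome, ctg, s + u, s + 2L * u)) {
            found <- TRUE; break
          }
        }
        if (found) break
      }
      if (!found) next
      payload <- ref_fetch(genome, ctg, s, s + u)
      # left-align within the repeat
      while (s > 0L && ref_fetch(genome, ctg, s - 1L, s) ==
             substr(payload, u, u)) {
        payload <- paste0(ref_fetch(genome, ctg, s - 1L, s),
                          substr(payload, 1L, u - 1L))
        s <- s - 1L
      }
      if (s < margin || !occ_free(occ, ctg, s - 2L, s + 3L * u + 2L)) next
      occ_reserve(occ, ctg, s - 2L, s + 3L * u + 2L)
      nv <- data.frame(contig = ctg, start = s, kind = "deletion",
                       deleted_seq = payload, inserted_seq = "",
                       ref_base = NA_character_, alt_base = NA_character_,
                       sample_id = sid, stringsAsFactors = FALSE)
    } else {  # plain multi-bp deletion with no repeat and no microhomology
      l <- sample(2:6, 1L)
      if (p + 2L * l + 2L > genome$lengths[[ctg]] - margin) next
      D <- ref_fetch(genome, ctg, p, p + l)
      if (ref_fetch(genome, ctg, p + l, p + l + 1L) == substr(D, 1L, 1L)) next
      if (ref_fetch(genome, ctg, p - 1L, p) == substr(D, l, l)) next
      if (!occ_free(occ, ctg, p - 2L, p + 2L * l + 2L)) next
      occ_reserve(occ, ctg, p - 2L, p + 2L * l + 2L)
      nv <- data.frame(contig = ctg, start = p, kind = "deletion",
                       deleted_seq = D, inserted_seq = "",
                       ref_base = NA_character_, alt_base = NA_character_,
                       sample_id = sid, stringsAsFactors = FALSE)
    }
    add_event(nv, data.frame(
      sample_id = sid, contig = nv$contig, position = nv$start,
      event_type = "background_indel", planted_category = "none",
      planted_mh_length = NA_integer_, parent_dsb_id = NA_character_,
      planted_is_apobec = NA, stringsAsFactors = FALSE))
    return(invisible(TRUE))
  }
  stop("could not place a background indel; genome too crowded")
}

#' Position-level cluster simulation
#'
#' Places planted substitution clusters and uniform background substitutions
#' on a virtual callable genome by coordinate only — no sequence is
#' generated, so arbitrarily large callable lengths (matching whole-genome
#' mutation densities) can be simulated cheaply.  APOBEC membership and
#' strand orientation are assigned per the planted composition; all APOBEC
#' members of one cluster share one strand (coordinated deamination).
#'
#' @param n_clusters Number of planted clusters.
#' @param callable_length_bp Virtual callable length.
#' @param background_rate Background substitutions per bp.
#' @param size_range Cluster size range (min >= 2).
#' @param span_max Maximum cluster span in bp.
#' @param apobec_count_fun Function(k) giving the planted APOBEC member
#'   count for a cluster of size k; default draws uniformly over 0..k.
#' @param min_separation Minimum distance between planted cluster centers.
#' @param sample_id Sample label.
#' @return List: `subs` (position-sorted substitution table with
#'   `is_apobec3`, `orientation`, `planted_cluster`) and `truth_clusters`
#'   (cluster_id, n, n_apobec, apobec_fraction).
#' @export
simulate_cluster_positions <- function(n_clusters, callable_length_bp,
                                       background_rate,
                                       size_range = c(2L, 10L),
                                       span_max = 2000L,
                                       apobec_count_fun = NULL,
                                       min_separation = 5e4,
                                       sample_id = "S1") {
  if (is.null(apobec_count_fun)) {
    apobec_count_fun <- function(k) sample(0:k, 1L)
  }
  centers <- numeric(0)
  while (length(centers) < n_clusters) {
    c0 <- stats::runif(1L, span_max, callable_length_bp - span_max)
    if (length(centers) == 0L || min(abs(centers - c0)) >= min_separation) {
      centers <- c(centers, c0)
    }
  }
  rows <- list()
  truth <- list()
  for (i in seq_len(n_clusters)) {
    k <- sample(seq(size_range[1L], size_range[2L]), 1L)
    span <- stats::runif(1L, 0, span_max)
    pos <- sort(round(centers[i] + stats::runif(k, -span / 2, span / 2)))
    pos <- pos + seq_along(pos) * 0  # keep numeric
    n_apo <- apobec_count_fun(k)
    strand <- sample(c("+", "-"), 1L)
    is_apo <- c(rep(TRUE, n_apo), rep(FALSE, k - n_apo))[sample.int(k)]
    ori <- ifelse(is_apo, strand, sample(c("+", "-"), k, replace = TRUE))
    cid <- sprintf("planted_%03d", i)
    rows[[i]] <- data.frame(sample_id = sample_id, contig = "virtual",
                            pos = pos, is_apobec3 = is_apo, orientation = ori,
                            planted_cluster = cid, stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(cluster_id = cid, n = k, n_apobec = n_apo,
                             apobec_fraction = n_apo / k,
                             stringsAsFactors = FALSE)
  }
  n_bg <- stats::rpois(1L, background_rate * callable_length_bp)
  if (n_bg > 0L) {
    rows[[n_clusters + 1L]] <- data.frame(
      sample_id = sample_id, contig = "virtual",
      pos = round(stats::runif(n_bg, 1, callable_length_bp)),
      is_apobec3 = FALSE,
      orientation = sample(c("+", "-"), n_bg, replace = TRUE),
      planted_cluster = NA_character_, stringsAsFactors = FALSE)
  }
  subs <- do.call(rbind, rows)
  subs <- subs[order(subs$pos), , drop = FALSE]
  rownames(subs) <- NULL
  list(subs = subs, truth_clusters = do.call(rbind, truth))
}
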