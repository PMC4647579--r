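#' Parameters for the synthetic cohort simulator
#'
#' Defines the study conditions the simulator emulates: a small cell-line
#' cohort (default 4 samples) profiled on three platforms, with hyperploid
#' copy-number segments, log-normal background FPKM over a bimodal
#' expressed-versus-noise structure, germline/somatic variant mixtures with
#' functional-prediction verdicts, fusion candidates, and planted
#' multi-altered genes that the full pipeline must recover.
#'
#' @param n_samples Cohort size. Default 4.
#' @param n_genes Size of the gene universe. Default 2000.
#' @param genome Named numeric vector of chromosome lengths in bases.
#'   Default 5 chromosomes of 50 Mb.
#' @param seed Master seed; one fixed random stream per data type is derived
#'   from it, so adding one data type never perturbs another's draws.
#' @param n_multi_altered Genes planted with two or more distinct alteration
#'   types (the positives the pipeline must recover). Default 20.
#' @param n_single_altered Decoy genes planted with exactly one passing
#'   alteration. Default 100.
#' @param fpkm_lognormal_mu,fpkm_lognormal_sigma Meanlog/sdlog of the
#'   log-normal background FPKM of expressed genes. Defaults 1 and 1.
#' @param frac_not_expressed Fraction of genes per sample drawn at noise-level
#'   FPKM (uniform below the expression floor). Default 0.25.
#' @param germline_rate Per-clean-gene rate of dbSNP-only decoy variants.
#'   Default 0.02.
#' @param somatic_rate Per-clean-gene rate of exome-only decoy variants that
#'   fail transcriptome cross-validation. Default 0.01.
#' @param coverage_mean Mean exome read coverage (Poisson). Default 80.
#' @return A `simulation_params` list.
#' @export
simulation_params <- function(n_samples = 4,
                              n_genes = 2000,
                              genome = stats::setNames(rep(50e6, 5),
                                                       as.character(1:5)),
                              seed = 20151101,
                              n_multi_altered = 20,
                              n_single_altered = 100,
                              fpkm_lognormal_mu = 1,
                              fpkm_lognormal_sigma = 1,
                              frac_not_expressed = 0.25,
                              germline_rate = 0.02,
                              somatic_rate = 0.01,
                              coverage_mean = 80) {
  p <- list(n_samples = n_samples, n_genes = n_genes, genome = genome,
            seed = as.integer(seed), n_multi_altered = n_multi_altered,
            n_single_altered = n_single_altered,
            fpkm_lognormal_mu = fpkm_lognormal_mu,
            fpkm_lognormal_sigma = fpkm_lognormal_sigma,
            frac_not_expressed = frac_not_expressed,
            germline_rate = germline_rate, somatic_rate = somatic_rate,
            coverage_mean = coverage_mean)
  if (p$n_multi_altered + p$n_single_altered > p$n_genes) {
    stop("n_multi_altered + n_single_altered exceeds n_genes", call. = FALSE)
  }
  if (any(c(p$germline_rate, p$somatic_rate) < 0)) {
    stop("rates must be >= 0", call. = FALSE)
  }
  structure(p, class = "simulation_params")
}

bases <- c("A", "C", "G", "T")

#' Simulate a multi-platform cohort with planted ground truth
#'
#' Generates gene models, copy-number segments, an FPKM matrix, exome and
#' transcriptome variant tables and fusion candidates for a small cohort,
#' together with a truth table partitioning the gene universe into
#' multi-altered genes (each planted with >= 2 distinct alteration types,
#' arranged both within one sample and split across samples), single-altered
#' decoys (exactly one passing event: a mutation, a focal CNV, an expression
#' change or a fusion), and clean genes that receive only records constructed
#' to *fail* a specific filter (coverage 1-4, dbSNP-only, < 2 deleterious
#' votes, exome-only, synonymous, unassigned gene, copy-neutral focal
#' segments, arm-level segments, fusions below 10 read pairs, noise-level
#' expression) so that every filter's behaviour is observable. Planted events
#' are re-verified against the stage predicates (including re-running
#' expression classification on the finished matrix) before the cohort is
#' accepted; generation is fully deterministic given the seed.
#'
#' @param params A [simulation_params()] object.
#' @param config The [pipeline_config()] the cohort is built to satisfy.
#' @return A list with components `genes`, `segments`, `expression` (long
#'   data.frame with `fpkm` and `log_expr`), `exome`, `transcriptome`,
#'   `fusions`, `truth` (list with `multi_altered`, `single_altered`,
#'   `clean`, `events`) and `params`.
#' @export
simulate_cohort <- function(params = simulation_params(),
                            config = pipeline_config()) {
  stopifnot(inherits(params, "simulation_params"))
  samples <- sprintf("S%d", seq_len(params$n_samples))

  genes <- sim_genes(params, config)
  roles <- sim_roles(params, genes)
  plan <- sim_plan(params, roles, samples)
  segments <- sim_segments(params, config, genes, roles, plan, samples)
  expression <- sim_expression(params, config, genes, roles, plan, samples)
  variants <- sim_variants(params, config, genes, roles, plan, samples)
  fusions <- sim_fusions(params, genes, roles, plan, samples)

  truth <- list(
    multi_altered = sort(roles$multi),
    single_altered = sort(roles$single),
    clean = sort(roles$clean),
    events = plan$events[order(plan$events$gene_id, plan$events$sample_id,
                               plan$events$alteration_type), , drop = FALSE]
  )
  cohort <- list(genes = genes, segments = segments, expression = expression,
                 exome = variants$exome, transcriptome = variants$transcriptome,
                 fusions = fusions, truth = truth, params = params)
  verify_cohort(cohort, config)
  cohort
}

# Non-overlapping genes on a per-chromosome grid; the inter-gene margin keeps
# a planted focal segment (gene interval +/- 2 kb) from touching neighbours.
sim_genes <- function(params, config) {
  set.seed(params$seed + 1L)
  chroms <- names(params$genome)
  per_chrom <- ceiling(params$n_genes / length(chroms))
  slot <- floor(min(params$genome) / per_chrom)
  if (slot < 75000) {
    stop("genome too small for ", params$n_genes,
         " non-overlapping genes with planting margins", call. = FALSE)
  }
  out <- list()
  made <- 0L
  for (chrom in chroms) {
    n_here <- min(per_chrom, params$n_genes - made)
    if (n_here <= 0) break
    slot_start <- (seq_len(n_here) - 1L) * slot
    len <- sample(5000:60000, n_here, replace = TRUE)
    start <- slot_start + 10000L
    idx <- made + seq_len(n_here)
    out[[chrom]] <- data.frame(
      gene_id = sprintf("G%04d", idx),
      symbol = sprintf("SYM%04d", idx),
      chrom = chrom, start = start, end = start + len,
      strand = sample(c("+", "-"), n_here, replace = TRUE),
      stringsAsFactors = FALSE
    )
    made <- made + n_here
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

sim_roles <- function(params, genes) {
  set.seed(params$seed + 2L)
  shuffled <- sample(genes$gene_id)
  multi <- shuffled[seq_len(params$n_multi_altered)]
  single <- shuffled[params$n_multi_altered + seq_len(params$n_single_altered)]
  clean <- setdiff(shuffled, c(multi, single))
  single_cat <- rep(c("mutation", "cnv", "expression", "fusion"),
                    length.out = length(single))
  list(multi = multi, single = single, single_cat = single_cat, clean = clean)
}

# Decide every planted passing event up front: which gene gets which
# alteration types in which samples. Multi-altered genes cycle four patterns,
# two within-sample and two split across samples.
sim_plan <- function(params, roles, samples) {
  set.seed(params$seed + 3L)
  ev <- list()
  add <- function(gene, sample, type, direction) {
    ev[[length(ev) + 1L]] <<- data.frame(
      gene_id = gene, sample_id = sample, alteration_type = type,
      direction = direction, stringsAsFactors = FALSE)
  }
  pattern <- rep(1:4, length.out = length(roles$multi))
  for (i in seq_along(roles$multi)) {
    g <- roles$multi[i]
    s <- samples[(i - 1L) %% length(samples) + 1L]
    s2 <- samples[i %% length(samples) + 1L]  # a different sample
    occ <- ceiling(i / 4)  # alternate gain/loss across occurrences
    switch(pattern[i],
      { # concordant focal CNV + expression in one sample (gain or loss)
        if (occ %% 2 == 0) {
          add(g, s, "cnv", "loss"); add(g, s, "expression", "loss")
        } else {
          add(g, s, "cnv", "gain"); add(g, s, "expression", "gain")
        }
      },
      { # mutation in one sample, focal amplification in another
        add(g, s, "mutation", "not_applicable"); add(g, s2, "cnv", "gain")
      },
      { # mutation + overexpression, copy-neutral, same sample
        add(g, s, "mutation", "not_applicable"); add(g, s, "expression", "gain")
      },
      { # all three mechanisms in one sample
        add(g, s, "cnv", "gain"); add(g, s, "expression", "gain")
        add(g, s, "mutation", "not_applicable")
      })
  }
  for (i in seq_along(roles$single)) {
    g <- roles$single[i]
    s <- samples[(i - 1L) %% length(samples) + 1L]
    occ <- ceiling(i / 4)
    switch(roles$single_cat[i],
      mutation = add(g, s, "mutation", "not_applicable"),
      cnv = add(g, s, "cnv", if (occ %% 2 == 0) "loss" else "gain"),
      expression = add(g, s, "expression",
                       if (occ %% 2 == 0) "loss" else "gain"),
      fusion = NULL)  # fusion events are planted per pair below
  }
  # passing fusions pair consecutive fusion-category genes; an odd leftover
  # becomes a read-through (gene5 == gene3); both partners share the sample
  fusion_genes <- roles$single[roles$single_cat == "fusion"]
  pairs <- NULL
  if (length(fusion_genes) > 0) {
    half <- floor(length(fusion_genes) / 2)
    g5 <- fusion_genes[seq_len(half) * 2 - 1]
    g3 <- fusion_genes[seq_len(half) * 2]
    if (length(fusion_genes) %% 2 == 1) {
      last <- fusion_genes[length(fusion_genes)]
      g5 <- c(g5, last); g3 <- c(g3, last)
    }
    pairs <- data.frame(gene5 = g5, gene3 = g3,
                        sample_id = samples[(seq_along(g5) - 1L) %%
                                              length(samples) + 1L],
                        stringsAsFactors = FALSE)
    for (k in seq_len(nrow(pairs))) {
      add(pairs$gene5[k], pairs$sample_id[k], "fusion", "not_applicable")
      if (pairs$gene3[k] != pairs$gene5[k]) {
        add(pairs$gene3[k], pairs$sample_id[k], "fusion", "not_applicable")
      }
    }
  }
  events <- do.call(rbind, ev)
  list(events = events, fusion_pairs = pairs)
}

plan_events <- function(plan, type) {
  plan$events[plan$events$alteration_type == type, , drop = FALSE]
}

sim_segments <- function(params, config, genes, roles, plan, samples) {
  set.seed(params$seed + 4L)
  gidx <- function(g) match(g, genes$gene_id)
  cnv <- plan_events(plan, "cnv")
  seg <- list()
  if (nrow(cnv) > 0) {
    i <- gidx(cnv$gene_id)
    amp <- cnv$direction == "gain"
    seg[[1]] <- data.frame(
      sample_id = cnv$sample_id,
      chrom = genes$chrom[i],
      start = genes$start[i] - 2000L,
      end = genes$end[i] + 2000L,
      copy_number = ifelse(amp,
                           sample(config$amp_min_copies:(config$amp_min_copies + 3),
                                  nrow(cnv), replace = TRUE),
                           sample(0:config$del_max_copies, nrow(cnv),
                                  replace = TRUE)),
      n_probes = NA_integer_, stringsAsFactors = FALSE)
  }
  # filter-observability decoys on clean genes: copy-neutral focal segments
  neutral_genes <- roles$clean[seq_len(min(10, length(roles$clean)))]
  i <- gidx(neutral_genes)
  seg[[length(seg) + 1L]] <- data.frame(
    sample_id = samples[seq_along(neutral_genes) %% length(samples) + 1L],
    chrom = genes$chrom[i], start = genes$start[i] - 2000L,
    end = genes$end[i] + 2000L, copy_number = config$neutral_copies,
    n_probes = NA_integer_, stringsAsFactors = FALSE)
  # arm-level segments (>= focal_max_length): excluded from gene calling.
  # Placed in a window free of the sample's other segments, as a single
  # segmentation never emits overlapping segments for one sample.
  so_far <- do.call(rbind, seg)
  arm_len <- config$focal_max_length + 5e6
  arm_cn <- sample(c(0, 6), length(samples), replace = TRUE)
  for (k in seq_along(samples)) {
    s <- samples[k]
    mine <- so_far[so_far$sample_id == s, , drop = FALSE]
    placed <- FALSE
    for (chrom in rev(names(params$genome))) {
      if (placed) break
      for (start in seq(0, params$genome[[chrom]] - arm_len, by = 5e6)) {
        clash <- mine$chrom == chrom & mine$start < start + arm_len &
          start < mine$end
        if (!any(clash)) {
          seg[[length(seg) + 1L]] <- data.frame(
            sample_id = s, chrom = chrom, start = start,
            end = start + arm_len, copy_number = arm_cn[k],
            n_probes = NA_integer_, stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
      }
    }
    if (!placed) stop("no window free for an arm-level decoy segment",
                      call. = FALSE)
  }
  out <- do.call(rbind, seg)
  out$start <- as.integer(out$start); out$end <- as.integer(out$end)
  out[order(out$sample_id, out$chrom, out$start), , drop = FALSE]
}

# Background FPKM is log-normal for expressed genes and uniform below the
# noise floor for a fixed fraction of clean genes per sample. Planted values
# are placed by rank against the clean background (top for high, just above
# the floor for low, at the median for intermediate) and re-checked after
# classification, since percentiles shift once plants join the distribution.
sim_expression <- function(params, config, genes, roles, plan, samples) {
  set.seed(params$seed + 5L)
  floor_fpkm <- 10^config$expr_noise_floor - 1
  n <- nrow(genes)
  role_genes <- c(roles$multi, roles$single)
  expr_plan <- plan_events(plan, "expression")
  out <- list()
  for (s in samples) {
    fpkm <- stats::rlnorm(n, params$fpkm_lognormal_mu,
                          params$fpkm_lognormal_sigma)
    n_off <- round(params$frac_not_expressed * n)
    off <- sample(roles$clean, n_off)
    fpkm[match(off, genes$gene_id)] <- stats::runif(n_off, 0, floor_fpkm * 0.95)
    clean_bg <- fpkm[match(setdiff(roles$clean, off), genes$gene_id)]
    clean_log <- log10(clean_bg + 1)
    med <- stats::median(clean_log)
    top <- max(clean_log)
    # role genes default to mid-distribution (detectable, not an alteration)
    ri <- match(role_genes, genes$gene_id)
    mid_log <- med + stats::runif(length(ri), -0.02, 0.02)
    fpkm[ri] <- 10^mid_log - 1
    here <- expr_plan[expr_plan$sample_id == s, , drop = FALSE]
    if (nrow(here) > 0) {
      hi <- here$gene_id[here$direction == "gain"]
      lo <- here$gene_id[here$direction == "loss"]
      fpkm[match(hi, genes$gene_id)] <-
        10^(top + stats::runif(length(hi), 0.1, 0.5)) - 1
      fpkm[match(lo, genes$gene_id)] <-
        10^(config$expr_noise_floor + stats::runif(length(lo), 0.002, 0.02)) - 1
    }
    out[[s]] <- data.frame(gene_id = genes$gene_id, sample_id = s,
                           fpkm = fpkm, stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  long$log_expr <- log10(long$fpkm + 1)
  long
}

sim_variants <- function(params, config, genes, roles, plan, samples) {
  set.seed(params$seed + 6L)
  counter <- 0L
  rows <- list()
  add_variant <- function(gene_id, sample_id, effect, coverage, dbsnp, cosmic,
                          preds, platforms) {
    counter <<- counter + 1L
    i <- match(gene_id, genes$gene_id)
    chrom <- if (is.na(i)) names(params$genome)[1] else genes$chrom[i]
    pos <- if (is.na(i)) 1000L + counter * 13L else
      genes$start[i] + (counter * 13L) %% (genes$end[i] - genes$start[i])
    ra <- sample(bases, 2)
    for (pf in platforms) {
      rows[[length(rows) + 1L]] <<- data.frame(
        sample_id = sample_id, chrom = chrom, pos = pos,
        ref = ra[1], alt = ra[2],
        gene_id = if (is.na(i)) "" else gene_id,
        effect = effect,
        coverage = if (pf == "exome") coverage else
          max(5L, stats::rpois(1, 30)),
        in_dbsnp = dbsnp, in_cosmic = cosmic,
        pred1 = preds[1], pred2 = preds[2], pred3 = preds[3],
        platform = pf, stringsAsFactors = FALSE)
    }
  }
  pass_cov <- function() max(config$min_coverage,
                             stats::rpois(1, params$coverage_mean))
  # planted passing mutations; effect/verdict profiles cycle so that the
  # missense vote and the truncating bypass are both exercised
  profiles <- list(list("missense", c("D", "D", "T")),
                   list("missense", c("D", "D", "D")),
                   list("nonsense", c(".", ".", ".")),
                   list("frameshift", c(".", ".", ".")),
                   list("inframe", c("D", "T", "D")),
                   list("splice", c("D", ".", ".")))
  mut <- plan_events(plan, "mutation")
  for (k in seq_len(nrow(mut))) {
    pr <- profiles[[(k - 1L) %% length(profiles) + 1L]]
    # one planted variant is dbSNP+COSMIC: somatic-catalog membership rescues
    dbsnp <- k == 1L
    add_variant(mut$gene_id[k], mut$sample_id[k], pr[[1]], pass_cov(),
                dbsnp = dbsnp, cosmic = dbsnp, preds = pr[[2]],
                platforms = c("exome", "transcriptome"))
  }
  # failing decoys, each on its own clean gene
  clean_pool <- roles$clean
  take_clean <- function(k) {
    g <- clean_pool[seq_len(k)]
    clean_pool <<- clean_pool[-seq_len(k)]
    g
  }
  decoy_sample <- function(g) samples[(match(g, roles$clean) - 1L) %%
                                        length(samples) + 1L]
  n_germ <- max(3L, round(params$germline_rate * length(roles$clean)))
  for (g in take_clean(n_germ)) {
    add_variant(g, decoy_sample(g), "missense", pass_cov(),
                dbsnp = TRUE, cosmic = FALSE, preds = c("D", "D", "D"),
                platforms = c("exome", "transcriptome"))
  }
  n_som <- max(3L, round(params$somatic_rate * length(roles$clean)))
  for (g in take_clean(n_som)) {  # exome-only: fails cross-validation
    add_variant(g, decoy_sample(g), "missense", pass_cov(),
                dbsnp = FALSE, cosmic = FALSE, preds = c("D", "D", "T"),
                platforms = "exome")
  }
  for (g in take_clean(4L)) {  # below the 5X hard filter
    add_variant(g, decoy_sample(g), "missense",
                sample(seq_len(config$min_coverage - 1L), 1),
                dbsnp = FALSE, cosmic = FALSE, preds = c("D", "D", "D"),
                platforms = c("exome", "transcriptome"))
  }
  for (g in take_clean(4L)) {  # only one deleterious vote of three
    add_variant(g, decoy_sample(g), "missense", pass_cov(),
                dbsnp = FALSE, cosmic = FALSE, preds = c("D", "T", "."),
                platforms = c("exome", "transcriptome"))
  }
  for (g in take_clean(4L)) {  # synonymous: dropped by the effect screen
    add_variant(g, decoy_sample(g), "synonymous", pass_cov(),
                dbsnp = FALSE, cosmic = FALSE, preds = c(".", ".", "."),
                platforms = c("exome", "transcriptome"))
  }
  for (k in 1:2) {  # intergenic: passes filters but has no assignable gene
    add_variant(NA_character_, samples[k], "missense", pass_cov(),
                dbsnp = FALSE, cosmic = FALSE, preds = c("D", "D", "T"),
                platforms = c("exome", "transcriptome"))
  }
  all_rows <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  list(exome = all_rows[all_rows$platform == "exome", , drop = FALSE],
       transcriptome = all_rows[all_rows$platform == "transcriptome", ,
                                drop = FALSE])
}

sim_fusions <- function(params, genes, roles, plan, samples) {
  set.seed(params$seed + 7L)
  fus <- list()
  pairs <- plan$fusion_pairs
  if (!is.null(pairs) && nrow(pairs) > 0) {
    fus[[1]] <- data.frame(
      sample_id = pairs$sample_id, gene5 = pairs$gene5, gene3 = pairs$gene3,
      read_pairs = sample(10:30, nrow(pairs), replace = TRUE),
      stringsAsFactors = FALSE)
  }
  # under-supported decoys between clean genes
  lo <- utils::tail(roles$clean, 8)
  fus[[length(fus) + 1L]] <- data.frame(
    sample_id = samples[seq_len(4) %% length(samples) + 1L],
    gene5 = lo[1:4], gene3 = lo[5:8],
    read_pairs = sample(1:9, 4, replace = TRUE), stringsAsFactors = FALSE)
  do.call(rbind, c(fus, list(make.row.names = FALSE)))
}

# Re-verify every planted event against the stage predicates before the
# cohort is accepted; a violation is a simulator bug, not a data property.
verify_cohort <- function(cohort, config) {
  truth <- cohort$truth
  ec <- classify_expression(cohort$expression, config)
  ekey <- paste(ec$gene_id, ec$sample_id)
  expr_ev <- truth$events[truth$events$alteration_type == "expression", ,
                          drop = FALSE]
  got <- ec$status[match(paste(expr_ev$gene_id, expr_ev$sample_id), ekey)]
  want <- ifelse(expr_ev$direction == "gain", "high", "low")
  if (!all(got == want)) {
    stop("simulator: planted expression event not recovered after ",
         "classification", call. = FALSE)
  }
  # role genes must stay intermediate wherever no expression event was
  # planted, or a decoy could pick up a spurious second alteration type
  role_genes <- c(truth$multi_altered, truth$single_altered)
  samples <- unique(cohort$expression$sample_id)
  rkey <- as.vector(outer(role_genes, samples, paste))
  planted <- paste(expr_ev$gene_id, expr_ev$sample_id)
  rest <- setdiff(rkey, planted)
  if (!all(ec$status[match(rest, ekey)] == "intermediate")) {
    stop("simulator: a role gene drifted out of the intermediate expression ",
         "band", call. = FALSE)
  }
  # planted CNV events must be focal and non-neutral
  cnv_calls <- call_gene_cnv(cohort$segments, cohort$genes, config)
  cnv_ev <- truth$events[truth$events$alteration_type == "cnv", , drop = FALSE]
  ckey <- paste(cnv_calls$gene_id, cnv_calls$sample_id)
  hit <- match(paste(cnv_ev$gene_id, cnv_ev$sample_id), ckey)
  ok <- !is.na(hit) &
    (cnv_calls$status[hit] == ifelse(cnv_ev$direction == "gain",
                                     "amplified", "deleted"))
  if (!all(ok)) stop("simulator: planted CNV event not recovered", call. = FALSE)
  # planted mutations must survive the full variant stage
  vs <- run_variant_stage(cohort$exome, cohort$transcriptome, config)
  mut_ev <- truth$events[truth$events$alteration_type == "mutation", ,
                         drop = FALSE]
  pk <- paste(vs$passed$gene_id, vs$passed$sample_id)
  if (!all(paste(mut_ev$gene_id, mut_ev$sample_id) %in% pk)) {
    stop("simulator: planted mutation rejected by the variant stage",
         call. = FALSE)
  }
  # planted fusions must clear the read-pair threshold
  kept <- filter_fusions(cohort$fusions, config)
  fus_ev <- truth$events[truth$events$alteration_type == "fusion", ,
                         drop = FALSE]
  fk <- c(paste(kept$gene5, kept$sample_id), paste(kept$gene3, kept$sample_id))
  if (!all(paste(fus_ev$gene_id, fus_ev$sample_id) %in% fk)) {
    stop("simulator: planted fusion below the read-pair threshold",
         call. = FALSE)
  }
  invisible(cohort)
}

#' Write a simulated cohort to disk
#'
#' Emits every table in exactly the dialect the corresponding reader ingests:
#' genes as BED, segments and variants and fusions as TSV, expression as a
#' wide gene-by-sample FPKM matrix, and the truth table as JSON. Re-running
#' with the same seed overwrites with identical bytes.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param out_dir Output directory (created if absent).
#' @return Named character vector of the files written, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genes = file.path(out_dir, "genes.bed"),
    segments = file.path(out_dir, "segments.tsv"),
    expression = file.path(out_dir, "expression.tsv"),
    exome = file.path(out_dir, "exome_variants.tsv"),
    transcriptome = file.path(out_dir, "transcriptome_variants.tsv"),
    fusions = file.path(out_dir, "fusions.tsv"),
    truth = file.path(out_dir, "truth.json")
  )
  g <- cohort$genes
  bed <- data.frame(g$chrom, g$start, g$end, g$gene_id, 0L, g$strand)
  write_tsv_raw(bed, paths["genes"], col.names = FALSE)
  write_tsv_raw(cohort$segments, paths["segments"])
  wide <- stats::reshape(
    cohort$expression[c("gene_id", "sample_id", "fpkm")],
    idvar = "gene_id", timevar = "sample_id", direction = "wide")
  names(wide) <- sub("^fpkm\\.", "", names(wide))
  wide <- wide[order(wide$gene_id), , drop = FALSE]
  write_tsv_raw(wide, paths["expression"])
  write_tsv_raw(cohort$exome, paths["exome"])
  write_tsv_raw(cohort$transcriptome, paths["transcriptome"])
  write_tsv_raw(cohort$fusions, paths["fusions"])
  jsonlite::write_json(cohort$truth, paths["truth"], dataframe = "columns",
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read a written cohort back into memory
#'
#' Counterpart of [write_cohort()]; every table round-trips field-equal.
#'
#' @param dir Directory written by [write_cohort()].
#' @return A cohort list (without `params`).
#' @export
read_cohort <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  truth$events <- as.data.frame(truth$events, stringsAsFactors = FALSE)
  list(
    genes = read_gene_models(file.path(dir, "genes.bed"), "bed"),
    segments = read_segments(file.path(dir, "segments.tsv")),
    expression = read_expression_matrix(file.path(dir, "expression.tsv")),
    exome = read_variants(file.path(dir, "exome_variants.tsv"), "exome"),
    transcriptome = read_variants(file.path(dir, "transcriptome_variants.tsv"),
                                  "transcriptome"),
    fusions = read_fusions(file.path(dir, "fusions.tsv")),
    truth = truth
  )
}

write_tsv_raw <- function(df, path, col.names = TRUE) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = col.names)
  invisible(path)
}
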