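# Synthetic DIP-Seq / RNA-Seq generator with planted ground truth.
#
# Tags are drawn from a piecewise-constant intensity: a uniform background,
# multiplied by an enrichment fold inside planted enriched regions, by
# condition-specific folds inside planted differential regions, and by
# expression-coupled profiles (5mC dips at active TSSs, 5hmC tracks activity
# across gene bodies). Replicate variability enters as gamma-distributed
# region intensities (gamma-Poisson, i.e. NB marginal counts), matching the
# model the differential test assumes.

#' Simulation parameters
#'
#' Desk-scale defaults: 2 chromosomes x 10 Mb, 200 non-overlapping genes of
#' which ~20% exceed 200 kb, background 5 tags/kb, 5x enrichment, 4x
#' condition folds, NB dispersion 0.05, 2 replicate pools per condition.
#' Sequencing-scale depth is deliberately not simulated.
#'
#' @param ... overrides for any field
#' @return list of class `sim_params`
#' @export
sim_params <- function(...) {
  p <- list(
    n_chroms = 2L, chrom_length_bp = 1e7, n_genes = 200L,
    frac_long_genes = 0.2, short_gene_range = c(5e3, 5e4),
    long_gene_range = c(2.2e5, 3.5e5),
    background_tag_density = 5,      # tags per kb per library
    enrichment_fold = 5, differential_fold = 4,
    nb_dispersion = 0.05, n_replicates_per_condition = 2L,
    depth_per_library = NULL,        # NULL: integral of the intensity field
    enriched_region_bp = 2000,
    tss_dip_fold = 0.25, tss_dip_halfwidth_bp = 2000,
    body_fold_by_class = c(low = 1, mid = 1.6, high = 2.5),   # 5hmC bodies
    mc_body_fold_by_class = c(low = 1.8, mid = 1.3, high = 1),# 5mC bodies
    min_gene_length_bp = 2e5,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stop("unknown sim_params fields: ",
                            paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  stopifnot(p$n_chroms >= 1, p$chrom_length_bp > 0, p$n_genes >= 0,
            p$n_replicates_per_condition >= 1,
            p$background_tag_density > 0, p$enrichment_fold > 0,
            p$differential_fold > 0, p$nb_dispersion >= 0)
  structure(p, class = "sim_params")
}

#' Simulate a toy genome with non-overlapping gene models
#'
#' Gene lengths are a two-component mixture: a `frac_long_genes` share drawn
#' uniformly from `long_gene_range` (all >= 200 kb under the defaults, so
#' the gene-length filter of the bidirectional analysis has material to work
#' on) and the rest from `short_gene_range`. Genes are placed uniformly
#' without overlap, strands alternate randomly, and each gene receives a
#' log-normal expression level with tertile class labels (`low`, `mid`,
#' `high`) used by the expression-coupled DIP-Seq profiles.
#'
#' @param params a [sim_params()]
#' @return list with `genome` (named lengths) and `genes` (a [gene_models()]
#'   table with extra `expr_level`, `expr_class` columns)
#' @export
simulate_genome <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(as.integer(params$seed))
  genome <- setNames(rep(params$chrom_length_bp, params$n_chroms),
                     paste0("chr", seq_len(params$n_chroms)))
  if (params$n_genes == 0) {
    genes <- gene_models(data.frame(
      gene_id = character(), chrom = character(), start = integer(),
      end = integer(), strand = character(), stringsAsFactors = FALSE))
    genes$expr_level <- numeric(0); genes$expr_class <- character(0)
    return(list(genome = genome, genes = genes))
  }
  # deterministic split: the requested long-gene fraction is honored exactly,
  # so the genome occupancy stays bounded for every seed
  n_long <- round(params$frac_long_genes * params$n_genes)
  lens <- c(round(runif(n_long, params$long_gene_range[1],
                        params$long_gene_range[2])),
            round(runif(params$n_genes - n_long, params$short_gene_range[1],
                        params$short_gene_range[2])))
  if (sum(lens) + params$n_genes >= 0.9 * sum(genome)) {
    stop(sprintf("cannot place %d genes (%d bp) in a %d bp genome without overlap",
                 params$n_genes, sum(lens), as.integer(sum(genome))))
  }
  # greedy balance: longest genes first, each to the emptiest chromosome
  chrom_of <- character(length(lens))
  free_bp <- genome
  for (i in order(-lens)) {
    ch <- names(free_bp)[which.max(free_bp)]
    chrom_of[i] <- ch
    free_bp[[ch]] <- free_bp[[ch]] - lens[i]
  }
  rows <- list()
  for (ch in names(genome)) {
    li <- lens[chrom_of == ch]
    if (!length(li)) next
    free <- genome[[ch]] - sum(li)
    if (free <= length(li)) {
      stop(sprintf("cannot place %d genes (%d bp) on %s (%d bp) without overlap",
                   length(li), sum(li), ch, as.integer(genome[[ch]])))
    }
    gaps <- diff(c(0, sort(runif(length(li), 0, free))))
    starts <- cumsum(gaps) + cumsum(c(0, li[-length(li)]))
    rows[[ch]] <- data.frame(chrom = ch, start = round(starts),
                             end = round(starts) + li,
                             stringsAsFactors = FALSE)
  }
  g <- do.call(rbind, rows)
  g <- g[order(g$chrom, g$start), ]
  g$gene_id <- sprintf("gene%03d", seq_len(nrow(g)))
  g$strand <- sample(c("+", "-"), nrow(g), replace = TRUE)
  genes <- gene_models(g)
  expr <- exp(rnorm(nrow(genes), mean = 2, sd = 1.2))
  genes$expr_level <- expr
  tert <- cut(rank(expr, ties.method = "first"),
              breaks = 3, labels = c("low", "mid", "high"))
  genes$expr_class <- as.character(tert)
  list(genome = genome, genes = genes)
}

# Sample n non-overlapping intervals of the given width inside [lo, hi),
# also avoiding `occupied` (data.frame chrom/start/end on one chromosome,
# starts/ends numeric). Returns starts, or fewer if space runs out.
place_nonoverlapping <- function(n, width, lo, hi, occ_start, occ_end,
                                 max_tries = 2000L) {
  starts <- numeric(0)
  tries <- 0
  while (length(starts) < n && tries < max_tries) {
    tries <- tries + 1
    s <- floor(runif(1, lo, hi - width))
    if (!any(s < occ_end & s + width > occ_start)) {
      starts <- c(starts, s)
      occ_start <- c(occ_start, s); occ_end <- c(occ_end, s + width)
    }
  }
  list(starts = starts, occ_start = occ_start, occ_end = occ_end)
}

#' Specification of planted truth for [simulate_dipseq()]
#'
#' @param n_enriched_per_mark shared (non-differential) enriched regions per
#'   mark
#' @param n_differential_per_mark differential regions per mark planted
#'   outside the class-labelled genes (half up, half down)
#' @param n_bidirectional long genes planted with both up- and down-regulated
#'   5hmC regions (in distinct 50 kb body bins)
#' @param n_up_only,n_down_only long genes planted with unidirectional 5hmC
#'   regions (the contrast classes of the density analysis)
#' @param dhrs_per_gene_class how many DHRs each planted gene receives per
#'   direction it carries
#' @return list of class `truth_spec`
#' @export
truth_spec <- function(n_enriched_per_mark = 40L, n_differential_per_mark = 30L,
                       n_bidirectional = 8L, n_up_only = 8L, n_down_only = 8L,
                       dhrs_per_gene_class = 2L) {
  structure(list(n_enriched_per_mark = n_enriched_per_mark,
                 n_differential_per_mark = n_differential_per_mark,
                 n_bidirectional = n_bidirectional, n_up_only = n_up_only,
                 n_down_only = n_down_only,
                 dhrs_per_gene_class = dhrs_per_gene_class),
            class = "truth_spec")
}

# Build the planted region tables for one simulation.
plant_truth <- function(params, genome, genes, spec) {
  long <- genes[genes$length >= params$min_gene_length_bp, , drop = FALSE]
  need <- spec$n_bidirectional + spec$n_up_only + spec$n_down_only
  if (nrow(long) < need) {
    stop(sprintf("only %d genes >= %d bp; need %d for the planted classes",
                 nrow(long), as.integer(params$min_gene_length_bp), need))
  }
  pick <- sample(nrow(long), need)
  bid <- long[pick[seq_len(spec$n_bidirectional)], , drop = FALSE]
  upo <- long[pick[spec$n_bidirectional + seq_len(spec$n_up_only)], , drop = FALSE]
  dno <- long[pick[spec$n_bidirectional + spec$n_up_only +
                   seq_len(spec$n_down_only)], , drop = FALSE]
  w <- params$enriched_region_bp
  n_bins <- floor(params$min_gene_length_bp / 5e4)

  gene_regions <- function(gene, directions) {
    # one region per direction entry, each in a distinct 50 kb body bin
    bins <- sample(n_bins, length(directions))
    off <- (bins - 1) * 5e4 + floor(runif(length(bins), 1e3, 5e4 - w - 1e3))
    start <- if (gene$strand == "+") gene$start + off else gene$end - off - w
    data.frame(chrom = gene$chrom, start = start, end = start + w,
               mark = "5hmC", direction = directions,
               gene_id = gene$gene_id, stringsAsFactors = FALSE)
  }
  per_gene <- list()
  for (i in seq_len(nrow(bid))) {
    per_gene[[length(per_gene) + 1]] <- gene_regions(
      bid[i, ], rep(c("up", "down"), each = spec$dhrs_per_gene_class))
  }
  for (i in seq_len(nrow(upo))) {
    per_gene[[length(per_gene) + 1]] <- gene_regions(
      upo[i, ], rep("up", spec$dhrs_per_gene_class))
  }
  for (i in seq_len(nrow(dno))) {
    per_gene[[length(per_gene) + 1]] <- gene_regions(
      dno[i, ], rep("down", spec$dhrs_per_gene_class))
  }
  gene_diff <- if (length(per_gene)) do.call(rbind, per_gene) else NULL

  # free-placed enriched and differential regions per mark, avoiding the
  # gene-planted ones
  all_regions <- list(gene_diff[c("chrom", "start", "end", "mark")])
  free <- list()
  for (mk in c("5mC", "5hmC")) {
    for (kind in c("enriched", "differential")) {
      n_mk <- if (kind == "enriched") spec$n_enriched_per_mark else
        spec$n_differential_per_mark
      if (!n_mk) next
      per_chrom <- table(factor(sample(names(genome), n_mk, replace = TRUE),
                                levels = names(genome)))
      for (ch in names(genome)) {
        k <- as.integer(per_chrom[[ch]])
        if (!k) next
        occ <- do.call(rbind, all_regions)
        if (is.null(occ)) {
          occ <- data.frame(chrom = character(), start = numeric(),
                            end = numeric(), stringsAsFactors = FALSE)
        }
        occ <- occ[occ$chrom == ch, , drop = FALSE]
        pl <- place_nonoverlapping(k, w, 0, genome[[ch]],
                                   occ$start, occ$end)
        if (length(pl$starts) < k) stop("could not place planted regions without overlap")
        df <- data.frame(chrom = ch, start = pl$starts,
                         end = pl$starts + w, mark = mk,
                         kind = kind, stringsAsFactors = FALSE)
        free[[length(free) + 1]] <- df
        all_regions[[length(all_regions) + 1]] <- df[c("chrom", "start", "end", "mark")]
      }
    }
  }
  free <- do.call(rbind, free)
  if (is.null(free)) {
    free <- data.frame(chrom = character(), start = numeric(),
                       end = numeric(), mark = character(),
                       kind = character(), stringsAsFactors = FALSE)
  }
  free_diff <- free[free$kind == "differential", , drop = FALSE]
  free_diff$direction <- rep_len(c("up", "down"), length.out = nrow(free_diff))
  free_diff$gene_id <- rep(NA_character_, nrow(free_diff))

  differential <- rbind(
    gene_diff[c("chrom", "start", "end", "mark", "direction", "gene_id")],
    free_diff[c("chrom", "start", "end", "mark", "direction", "gene_id")]
  )
  if (is.null(differential)) {
    differential <- data.frame(chrom = character(), start = numeric(),
                               end = numeric(), mark = character(),
                               direction = character(),
                               gene_id = character(),
                               stringsAsFactors = FALSE)
  }
  differential$fold_change <- rep(params$differential_fold, nrow(differential))
  enriched <- rbind(
    free[free$kind == "enriched", c("chrom", "start", "end", "mark")],
    differential[c("chrom", "start", "end", "mark")]
  )
  enriched$base_enrichment_fold <- rep(params$enrichment_fold, nrow(enriched))
  up_g <- unique(differential$gene_id[differential$mark == "5hmC" &
                                      differential$direction == "up" &
                                      !is.na(differential$gene_id)])
  down_g <- unique(differential$gene_id[differential$mark == "5hmC" &
                                        differential$direction == "down" &
                                        !is.na(differential$gene_id)])
  structure(
    list(enriched_regions = enriched,
         differential_regions = differential,
         bidirectional_genes = sort(bid$gene_id),
         up_genes = sort(up_g), down_genes = sort(down_g),
         de_genes = data.frame(gene_id = character(), direction = character(),
                               stringsAsFactors = FALSE),
         seed = params$seed),
    class = "sim_truth"
  )
}

# Piecewise-constant intensity for one library on one chromosome:
# start from breakpoints of all modifier intervals, multiply overlapping
# multipliers. Returns data.frame(start, end, rate) with rate in tags/bp
# (before depth scaling).
compose_intensity <- function(chrom_len, base_rate, mods) {
  bp <- sort(unique(c(0, chrom_len, mods$start, mods$end)))
  bp <- bp[bp >= 0 & bp <= chrom_len]
  seg <- data.frame(start = bp[-length(bp)], end = bp[-1])
  rate <- rep(base_rate, nrow(seg))
  if (nrow(mods)) {
    for (i in seq_len(nrow(mods))) {
      hit <- seg$start >= mods$start[i] & seg$end <= mods$end[i]
      rate[hit] <- rate[hit] * mods$mult[i]
    }
  }
  seg$rate <- rate
  seg
}

#' Simulate DIP-Seq tag sets with planted ground truth
#'
#' Generates `2 x n_replicates_per_condition` libraries per mark (sham and
#' irradiated pools). Tag positions are drawn from a piecewise-constant
#' intensity: background everywhere; `enrichment_fold` inside planted
#' enriched regions; differential regions get an extra
#' `differential_fold` in the condition they favor (`up` = irradiated,
#' `down` = sham); 5mC is depleted around active TSSs and elevated across
#' low-expression gene bodies while 5hmC tracks expression class across gene
#' bodies. Each planted region's intensity is further multiplied, per
#' library, by a Gamma(1/dispersion, dispersion) factor so replicate region
#' counts are NB-distributed. Per library the total tag count is fixed
#' (multinomial allocation over intensity segments).
#'
#' @param params a [sim_params()]
#' @param genome,genes output of [simulate_genome()]
#' @param spec a [truth_spec()]
#' @param marks which marks to simulate
#' @return list with `tagsets` (list of [tag_set()]) and `truth`
#'   (`sim_truth`: planted enriched/differential regions, bidirectional /
#'   up-only / down-only gene ids, seed)
#' @export
simulate_dipseq <- function(params = sim_params(), genome = NULL, genes = NULL,
                            spec = truth_spec(), marks = c("5mC", "5hmC")) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(genome) || is.null(genes)) {
    gg <- simulate_genome(params)
    genome <- gg$genome; genes <- gg$genes
  }
  set.seed(as.integer(params$seed) + 1L)
  truth <- plant_truth(params, genome, genes, spec)
  base_rate <- params$background_tag_density / 1000  # tags per bp

  # expression-coupled modifiers, fixed across libraries
  expr_mods <- function(mk) {
    if (!nrow(genes)) return(NULL)
    out <- list()
    if (mk == "5mC") {
      act <- genes[genes$expr_class == "high", , drop = FALSE]
      if (nrow(act)) {
        out$dip <- data.frame(
          chrom = act$chrom,
          start = pmax(act$tss - params$tss_dip_halfwidth_bp, 0),
          end = act$tss + params$tss_dip_halfwidth_bp,
          mult = params$tss_dip_fold)
      }
      out$body <- data.frame(
        chrom = genes$chrom, start = genes$start, end = genes$end,
        mult = unname(params$mc_body_fold_by_class[genes$expr_class]))
    } else {
      out$body <- data.frame(
        chrom = genes$chrom, start = genes$start, end = genes$end,
        mult = unname(params$body_fold_by_class[genes$expr_class]))
    }
    do.call(rbind, out)
  }

  tagsets <- list()
  for (mk in marks) {
    enr <- truth$enriched_regions[truth$enriched_regions$mark == mk, , drop = FALSE]
    dif <- truth$differential_regions[truth$differential_regions$mark == mk, , drop = FALSE]
    emods <- expr_mods(mk)
    for (cond in c("sham", "irradiated")) {
      for (r in seq_len(params$n_replicates_per_condition)) {
        mods_list <- list(emods)
        if (nrow(enr)) {
          noise <- if (params$nb_dispersion > 0) {
            rgamma(nrow(enr), shape = 1 / params$nb_dispersion,
                   scale = params$nb_dispersion)
          } else rep(1, nrow(enr))
          mods_list$enr <- data.frame(
            chrom = enr$chrom, start = enr$start, end = enr$end,
            mult = enr$base_enrichment_fold * noise)
        }
        if (nrow(dif)) {
          favored <- ifelse(dif$direction == "up", "irradiated", "sham")
          mods_list$dif <- data.frame(
            chrom = dif$chrom, start = dif$start, end = dif$end,
            mult = ifelse(favored == cond, dif$fold_change, 1))
        }
        mods <- do.call(rbind, mods_list)
        segs <- lapply(names(genome), function(ch) {
          m <- if (is.null(mods)) mods else mods[mods$chrom == ch, , drop = FALSE]
          if (is.null(m)) m <- data.frame(start = numeric(), end = numeric(),
                                          mult = numeric())
          s <- compose_intensity(genome[[ch]], base_rate, m)
          s$chrom <- ch
          s
        })
        segs <- do.call(rbind, segs)
        wgt <- (segs$end - segs$start) * segs$rate
        if (any(wgt < 0) || sum(wgt) <= 0) stop("non-positive intensity field")
        depth <- params$depth_per_library %||% round(sum(wgt))
        if (depth < 1) stop("intensity field yields zero expected tags")
        alloc <- as.vector(rmultinom(1, depth, wgt / sum(wgt)))
        idx <- rep.int(seq_len(nrow(segs)), alloc)
        pos <- floor(runif(length(idx), segs$start[idx], segs$end[idx]))
        tags <- data.frame(chrom = segs$chrom[idx], pos = pos,
                           strand = sample(c("+", "-"), length(idx),
                                           replace = TRUE),
                           stringsAsFactors = FALSE)
        lid <- sprintf("%s_%s_rep%d", mk, cond, r)
        tagsets[[lid]] <- tag_set(tags, genome, library_id = lid,
                                  mark = mk, condition = cond)
      }
    }
  }
  list(tagsets = tagsets, truth = truth, genome = genome, genes = genes)
}

#' Simulate RNA-Seq counts coupled to the planted 5hmC changes
#'
#' Gene-level NB counts with means proportional to each gene's expression
#' level. A `frac_coupled` fraction of the genes planted with up-regulated
#' 5hmC also receives an expression fold-change `de_fold` in the irradiated
#' condition, so the planted 5hmC-up / RNA-up overlap is enriched; the truth
#' object records them as `de_genes`.
#'
#' @param params a [sim_params()]
#' @param genes gene table from [simulate_genome()] (needs `expr_level`)
#' @param truth `sim_truth` from [simulate_dipseq()]
#' @param frac_coupled fraction of 5hmC-up genes made differentially
#'   expressed (default 0.5)
#' @param de_fold expression fold-change of coupled genes (default 2)
#' @param mean_depth_factor scales expression levels to mean counts
#'   (default 20)
#' @return list with `counts` (genes x libraries), `design` (condition per
#'   library), and `truth` updated with `de_genes`
#' @export
simulate_rnaseq <- function(params, genes, truth, frac_coupled = 0.5,
                            de_fold = 2, mean_depth_factor = 20) {
  stopifnot(inherits(truth, "sim_truth"), frac_coupled >= 0, frac_coupled <= 1)
  set.seed(as.integer(params$seed) + 2L)
  up_pool <- truth$up_genes
  n_de <- round(frac_coupled * length(up_pool))
  de <- if (n_de) sort(sample(up_pool, n_de)) else character(0)
  truth$de_genes <- data.frame(gene_id = de,
                               direction = rep("up", length(de)),
                               stringsAsFactors = FALSE)
  nrep <- params$n_replicates_per_condition
  design <- rep(c("sham", "irradiated"), each = nrep)
  mu0 <- genes$expr_level * mean_depth_factor
  fc <- ifelse(genes$gene_id %in% de, de_fold, 1)
  counts <- sapply(seq_along(design), function(j) {
    mu <- if (design[j] == "irradiated") mu0 * fc else mu0
    if (params$nb_dispersion > 0) {
      rnbinom(length(mu), mu = mu, size = 1 / params$nb_dispersion)
    } else rpois(length(mu), mu)
  })
  counts <- matrix(counts, nrow = nrow(genes),
                   dimnames = list(genes$gene_id,
                                   paste0("rna_", design, "_rep",
                                          rep(seq_len(nrep), 2))))
  list(counts = counts, design = design, truth = truth)
}

#' Write a `sim_truth` object to TSV files
#'
#' @param truth a `sim_truth`
#' @param dir output directory (created if missing)
#' @export
write_sim_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "sim_truth"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.table(truth$enriched_regions, file.path(dir, "enriched_regions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(truth$differential_regions,
              file.path(dir, "differential_regions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(truth$bidirectional_genes,
             file.path(dir, "bidirectional_genes.txt"))
  write.table(truth$de_genes, file.path(dir, "de_genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
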