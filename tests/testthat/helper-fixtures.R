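# Shared fixtures: all synthetic, built in code.

# sim_params with the expression-coupled intensity profiles switched off:
# background + planted regions only (the conditions of the recovery checks).
flat_params <- function(...) {
  sim_params(body_fold_by_class = c(low = 1, mid = 1, high = 1),
             mc_body_fold_by_class = c(low = 1, mid = 1, high = 1),
             tss_dip_fold = 1, ...)
}

# region_counts object from a bare count matrix
mk_region_counts <- function(m, cond, mark = "5mC") {
  m <- as.matrix(m)
  regions <- data.frame(chrom = "chr1",
                        start = seq_len(nrow(m)) * 1000L,
                        end = seq_len(nrow(m)) * 1000L + 500L)
  structure(list(
    regions = regions, counts = m,
    meta = data.frame(library_id = paste0("lib", seq_len(ncol(m))),
                      mark = mark, condition = cond,
                      stringsAsFactors = FALSE),
    size_factors = rep(1, ncol(m))
  ), class = "region_counts")
}

# tag_set with tags at given positions on one chromosome
mk_tags <- function(pos, chrom_len = 1e5, chrom = "chr1", ...) {
  tag_set(data.frame(chrom = rep(chrom, length(pos)), pos = pos,
                     strand = rep("+", length(pos)),
                     stringsAsFactors = FALSE),
          setNames(chrom_len, chrom), ...)
}

# gene model table from vectors
mk_genes <- function(chrom, start, end, strand,
                     gene_id = sprintf("g%02d", seq_along(start))) {
  gene_models(data.frame(gene_id = gene_id, chrom = chrom, start = start,
                         end = end, strand = strand,
                         stringsAsFactors = FALSE))
}

# fraction of reciprocal-overlap matches: a row of `a` matches `b` if some
# interval of `b` overlaps it by >= frac of both widths
reciprocal_matches <- function(a, b, frac = 0.5) {
  if (!nrow(a)) return(logical(0))
  vapply(seq_len(nrow(a)), function(i) {
    same <- b[b$chrom == a$chrom[i], , drop = FALSE]
    if (!nrow(same)) return(FALSE)
    ov <- pmin(same$end, a$end[i]) - pmax(same$start, a$start[i])
    any(ov >= frac * (a$end[i] - a$start[i]) &
        ov >= frac * (same$end - same$start))
  }, logical(1))
}
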