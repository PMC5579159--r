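# Readers/writers for the plain-text formats the pipeline touches (BED,
# refFlat/BED12 gene models, TSV result tables, YAML config) plus the tag_set
# container every downstream stage consumes.

#' Read a BED3+ file of genomic intervals
#'
#' Coordinates are kept 0-based half-open (BED-native); no conversion is
#' applied anywhere in the package.
#'
#' @param path path to a tab-separated BED3+ file (no header)
#' @return data.frame with columns `chrom`, `start`, `end`, and, when present
#'   in the file, `name`, `score`, `strand`; rows in file order
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop(sprintf("malformed BED line %d: fewer than 3 tab-separated fields",
                 which(nf < 3)[1]))
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop(sprintf("malformed BED line %d: non-integer coordinates",
                 which(is.na(start) | is.na(end))[1]))
  }
  bad <- which(!(start >= 0 & start < end))
  if (length(bad)) {
    stop(sprintf("invalid interval at line %d: start=%d end=%d (need 0 <= start < end)",
                 bad[1], start[bad[1]], end[bad[1]]))
  }
  out <- data.frame(
    chrom = vapply(fields, `[`, "", 1L),
    start = start, end = end, stringsAsFactors = FALSE
  )
  if (all(nf >= 4)) out$name <- vapply(fields, `[`, "", 4L)
  if (all(nf >= 5)) out$score <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 5L)))
  if (all(nf >= 6)) {
    s <- vapply(fields, `[`, "", 6L)
    if (any(!s %in% c("+", "-", "."))) {
      stop(sprintf("invalid strand at line %d: '%s'",
                   which(!s %in% c("+", "-", "."))[1], s[!s %in% c("+", "-", ".")][1]))
    }
    out$strand <- s
  }
  out
}

#' Write intervals as BED
#'
#' @param x data.frame with `chrom`, `start`, `end` and optional `name`,
#'   `score`, `strand`
#' @param path output path
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"), names(x))
  # BED columns are positional: stop at the first absent one
  keep <- cols[seq_len(match(FALSE, c("chrom", "start", "end", "name", "score",
                                      "strand") %in% cols, nomatch = 7) - 1)]
  write.table(x[keep], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read chromosome sizes
#'
#' @param path two-column TSV: chromosome name, length in bp
#' @return named numeric vector of chromosome lengths
#' @export
read_genome_sizes <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) < 2) stop("genome sizes file needs two columns: chrom, length")
  setNames(as.numeric(x[[2]]), as.character(x[[1]]))
}

#' Construct a tag set
#'
#' A tag set holds the uniquely-mapped single-end tag coordinates of one
#' DIP-Seq (or RNA-Seq) library. Tags are stored as 5' positions; any fragment
#' handling happens downstream, not at I/O.
#'
#' @param tags data.frame with columns `chrom`, `pos` (0-based), `strand`
#' @param genome named numeric vector of chromosome lengths (bp)
#' @param library_id library label
#' @param mark one of `"5mC"`, `"5hmC"`, `"RNA"`
#' @param condition one of `"sham"`, `"irradiated"`
#' @return object of class `tag_set`
#' @export
tag_set <- function(tags, genome, library_id = "lib", mark = "5mC",
                    condition = "sham") {
  stopifnot(is.data.frame(tags), all(c("chrom", "pos") %in% names(tags)))
  mark <- match.arg(mark, c("5mC", "5hmC", "RNA"))
  condition <- match.arg(condition, c("sham", "irradiated"))
  if (!all(tags$chrom %in% names(genome))) {
    stop("tags on chromosomes absent from the genome map: ",
         paste(setdiff(unique(tags$chrom), names(genome)), collapse = ", "))
  }
  if (nrow(tags)) {
    lim <- genome[tags$chrom]
    if (any(tags$pos < 0 | tags$pos >= lim)) {
      stop("tag positions outside [0, chromosome length)")
    }
  }
  if (is.null(tags$strand)) tags$strand <- "+"
  structure(
    list(library_id = library_id, mark = mark, condition = condition,
         tags = tags[c("chrom", "pos", "strand")], genome = genome),
    class = "tag_set"
  )
}

#' @export
print.tag_set <- function(x, ...) {
  cat(sprintf("tag_set '%s': %s / %s, %d tags on %d chromosome(s)\n",
              x$library_id, x$mark, x$condition, nrow(x$tags),
              length(x$genome)))
  invisible(x)
}

#' Read a tag set from a BED file
#'
#' Each BED record contributes one tag at its 5' position: `start` for `+`
#' strand records, `end - 1` for `-` strand (BED without strand is taken
#' as `+`).
#'
#' @inheritParams tag_set
#' @param path BED3/BED6 file of tag intervals
#' @export
read_tags_bed <- function(path, genome, library_id = basename(path),
                          mark = "5mC", condition = "sham") {
  bed <- read_bed(path)
  strand <- if ("strand" %in% names(bed)) bed$strand else rep("+", nrow(bed))
  strand[strand == "."] <- "+"
  pos <- ifelse(strand == "-", bed$end - 1L, bed$start)
  tag_set(data.frame(chrom = bed$chrom, pos = pos, strand = strand,
                     stringsAsFactors = FALSE),
          genome, library_id = library_id, mark = mark, condition = condition)
}

#' Write a tag set as BED6 (1 bp intervals at tag positions)
#' @param x a [tag_set()]
#' @param path output path
#' @export
write_tags_bed <- function(x, path) {
  stopifnot(inherits(x, "tag_set"))
  bed <- data.frame(chrom = x$tags$chrom, start = x$tags$pos,
                    end = x$tags$pos + 1L, name = x$library_id, score = 0L,
                    strand = x$tags$strand, stringsAsFactors = FALSE)
  write_bed(bed, path)
}

#' Read gene models (refFlat or BED12)
#'
#' The TSS is `start` for plus-strand genes and `end - 1` for minus-strand
#' genes. Multiple records sharing a `gene_id` are collapsed to the longest
#' transcript, so downstream gene-level analyses are non-redundant.
#'
#' @param path path to the gene model file
#' @param dialect `"refFlat"` (geneName, name, chrom, strand, txStart, txEnd,
#'   ...) or `"BED12"` (gene id taken from the name column)
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`, `length`
#' @export
read_gene_models <- function(path, dialect = c("refFlat", "BED12")) {
  dialect <- match.arg(dialect)
  x <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (dialect == "refFlat") {
    if (ncol(x) < 6) stop("refFlat needs >= 6 columns")
    g <- data.frame(gene_id = x[[1]], chrom = x[[3]], strand = x[[4]],
                    start = as.integer(x[[5]]), end = as.integer(x[[6]]),
                    stringsAsFactors = FALSE)
  } else {
    if (ncol(x) < 6) stop("BED12 needs >= 6 columns")
    g <- data.frame(gene_id = x[[4]], chrom = x[[1]], strand = x[[6]],
                    start = as.integer(x[[2]]), end = as.integer(x[[3]]),
                    stringsAsFactors = FALSE)
  }
  if (any(!g$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'")
  }
  validate_intervals(g, "gene model")
  gene_models(g)
}

#' Build a gene model table from interval data
#'
#' @param g data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`
#' @return data.frame with `tss` and `length` added; one row per `gene_id`
#'   (longest transcript kept), sorted by (chrom, start, gene_id)
#' @export
gene_models <- function(g) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(g)))
  g$length <- g$end - g$start
  # collapse duplicate gene ids to the longest transcript
  g <- g[order(g$gene_id, -g$length), ]
  g <- g[!duplicated(g$gene_id), ]
  g$tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
  g <- g[order(g$chrom, g$start, g$gene_id), ]
  rownames(g) <- NULL
  g[c("gene_id", "chrom", "start", "end", "strand", "tss", "length")]
}

#' Write gene models as refFlat
#' @param genes gene model data.frame (see [gene_models()])
#' @param path output path
#' @export
write_gene_models_refflat <- function(genes, path) {
  out <- data.frame(
    geneName = genes$gene_id, name = genes$gene_id, chrom = genes$chrom,
    strand = genes$strand, txStart = genes$start, txEnd = genes$end,
    cdsStart = genes$start, cdsEnd = genes$end, exonCount = 1L,
    exonStarts = paste0(genes$start, ","), exonEnds = paste0(genes$end, ","),
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a differential-region table as TSV
#'
#' Numeric columns are serialized at full double precision so that
#' [read_region_table()] round-trips losslessly.
#'
#' @param regions data.frame of differential regions
#' @param path output path
#' @export
write_region_table <- function(regions, path) {
  stopifnot(is.data.frame(regions))
  out <- regions
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read a TSV region table written by [write_region_table()]
#' @param path input path
#' @export
read_region_table <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Default run configuration
#'
#' Thresholds mirror the published analysis: 1000 bp sliding windows, FDR
#' q < 0.01 significance, a permissive p < 0.1 tier for density analyses,
#' 50 kb TSS annotation windows, 25 kb TSS proximity, a 200 kb minimum gene
#' length with four 50 kb gene-body bins, and top-2000 region selection.
#'
#' @param ... overrides for any field
#' @return list of class `dip_config`
#' @export
dip_config <- function(...) {
  cfg <- list(
    window_bp = 1000L, window_step_bp = 500L, n_permutations = 100L,
    enrichment_alpha = 0.001, fdr_threshold = 0.01, permissive_p = 0.1,
    tss_window_bp = 50000L, proximity_bp = 25000L,
    min_gene_length_bp = 200000L, density_bin_bp = 50000L,
    n_density_bins = 4L, top_n_regions = 2000L, seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  lens <- c("window_bp", "window_step_bp", "tss_window_bp", "proximity_bp",
            "min_gene_length_bp", "density_bin_bp")
  if (any(unlist(cfg[lens]) <= 0)) stop("all length parameters must be > 0")
  probs <- c("enrichment_alpha", "fdr_threshold", "permissive_p")
  if (any(unlist(cfg[probs]) <= 0 | unlist(cfg[probs]) >= 1)) {
    stop("probability parameters must lie in (0,1)")
  }
  structure(cfg, class = "dip_config")
}

#' Read / write a YAML run configuration
#' @param path YAML file mapping [dip_config()] fields 1:1
#' @export
read_config <- function(path) {
  do.call(dip_config, yaml::read_yaml(path))
}

#' @rdname read_config
#' @param cfg a [dip_config()]
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
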