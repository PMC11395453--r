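#' Load gene models from GFF3 or BED
#'
#' GFF3 input keeps `gene`-typed features only and uses the file's 1-based
#' inclusive coordinates; BED input converts 0-based half-open intervals to
#' 1-based inclusive.
#'
#' @param path input file.
#' @param format "gff3" or "bed".
#' @return data.frame: gene, chr, start_bp, end_bp, strand (1-based
#'   inclusive).
#' @export
load_genes <- function(path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path)
  out <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (format == "gff3") {
      if (length(f) < 9L)
        stop("malformed GFF3 record at line ", i, ": expected 9 fields, got ",
             length(f))
      if (f[3L] != "gene") next
      start <- suppressWarnings(as.numeric(f[4L]))
      end <- suppressWarnings(as.numeric(f[5L]))
      if (is.na(start) || is.na(end) || start > end)
        stop("malformed GFF3 coordinates at line ", i)
      attr_str <- f[9L]
      gene <- sub(".*(?:^|;)(?:Name|ID|gene_id)=([^;]+).*", "\\1", attr_str)
      if (identical(gene, attr_str)) gene <- paste0("gene_", i)
      out[[length(out) + 1L]] <- data.frame(
        gene = gene, chr = f[1L], start_bp = start, end_bp = end,
        strand = f[7L], stringsAsFactors = FALSE)
    } else {
      if (length(f) < 3L)
        stop("malformed BED record at line ", i, ": expected >= 3 fields")
      start <- suppressWarnings(as.numeric(f[2L]))
      end <- suppressWarnings(as.numeric(f[3L]))
      if (is.na(start) || is.na(end) || start >= end)
        stop("malformed BED coordinates at line ", i)
      out[[length(out) + 1L]] <- data.frame(
        gene = if (length(f) >= 4L) f[4L] else paste0("gene_", i),
        chr = f[1L], start_bp = start + 1, end_bp = end,
        strand = if (length(f) >= 6L) f[6L] else "*",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) stop("no gene records found in ", path)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write gene models as BED (0-based half-open)
#' @param genes data.frame from [load_genes()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genes_bed <- function(genes, path) {
  utils::write.table(
    data.frame(genes$chr, as.integer(genes$start_bp - 1),
               as.integer(genes$end_bp), genes$gene, 0, genes$strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Annotate regions or SNPs with overlapping genes
#'
#' SNP queries (a `pos` column) are expanded to `[pos - flank_bp,
#' pos + flank_bp]` clipped at 1; interval queries (`start_bp`/`end_bp`)
#' are used as given. A gene is reported for a query when their 1-based
#' inclusive intervals share at least one bp, regardless of strand.
#'
#' @param queries data.frame with `chr` and either `pos` (SNPs) or
#'   `start_bp`/`end_bp` (regions); an optional `id` column labels the
#'   output.
#' @param genes data.frame from [load_genes()].
#' @param flank_bp flank added to SNP queries.
#' @return data.frame: query_id, chr, query_start, query_end, gene,
#'   gene_start, gene_end, strand.
#' @export
annotate_regions <- function(queries, genes, flank_bp = 250000) {
  if (!nrow(queries)) stop("no queries supplied")
  if ("pos" %in% names(queries)) {
    qstart <- pmax(1, queries$pos - flank_bp)
    qend <- queries$pos + flank_bp
  } else {
    qstart <- queries$start_bp
    qend <- queries$end_bp
  }
  qid <- if ("id" %in% names(queries)) as.character(queries$id)
  else sprintf("query_%d", seq_len(nrow(queries)))
  unmatched <- setdiff(unique(queries$chr), unique(genes$chr))
  if (length(unmatched))
    warning("query chromosomes absent from the gene set: ",
            paste(unmatched, collapse = ", "))
  common <- union(unique(queries$chr), unique(genes$chr))
  qgr <- GenomicRanges::GRanges(factor(queries$chr, levels = common),
                                IRanges::IRanges(qstart, qend))
  ggr <- GenomicRanges::GRanges(factor(genes$chr, levels = common),
                                IRanges::IRanges(genes$start_bp, genes$end_bp))
  hits <- GenomicRanges::findOverlaps(qgr, ggr)
  qi <- S4Vectors::queryHits(hits); gi <- S4Vectors::subjectHits(hits)
  data.frame(query_id = qid[qi], chr = as.character(queries$chr[qi]),
             query_start = qstart[qi], query_end = qend[qi],
             gene = genes$gene[gi], gene_start = genes$start_bp[gi],
             gene_end = genes$end_bp[gi], strand = genes$strand[gi],
             stringsAsFactors = FALSE)
}

#' Write an annotation table as tab-separated text
#' @param annotation data.frame from [annotate_regions()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
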