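#' Write intervals as BED6
#'
#' Coordinates are 0-based half-open and rows are sorted by (chrom, start).
#'
#' @param df data.frame with chrom, start, end plus the columns named by
#'   `name`, `score`, `strand` (missing ones default to ".", 0, ".").
#' @param path output file.
#' @param name,score,strand column names supplying the BED name/score/strand.
#' @export
write_bed6 <- function(df, path, name = NULL, score = NULL, strand = NULL) {
  pull <- function(col, default) {
    if (is.null(col)) rep(default, nrow(df)) else df[[col]]
  }
  bed <- data.frame(chrom = df$chrom,
                    start = format(df$start, scientific = FALSE, trim = TRUE),
                    end = format(df$end, scientific = FALSE, trim = TRUE),
                    name = pull(name, "."),
                    score = pull(score, 0),
                    strand = pull(strand, "."))
  bed <- bed[order(df$chrom, df$start), ]
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file written by [write_bed6()]
#' @param path input file.
#' @return data.frame: chrom, start, end, name, score, strand.
#' @export
read_bed6 <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "name", "score", "strand")[seq_len(ncol(df))]
  df
}

#' Write promoter annotation as GFF3
#'
#' Emits one `promoter` feature per gene (1-based closed coordinates as GFF3
#' requires, converted from the model's 0-based half-open windows).
#' @param genome a `genome_model`.
#' @param path output file.
#' @export
write_gff3_promoters <- function(genome, path) {
  p <- genome$promoters
  lines <- c("##gff-version 3",
             sprintf("%s\tmedipdmr\tpromoter\t%d\t%d\t.\t%s\t.\tID=%s;gene=%s;entrez=%d",
                     p$chrom, p$window_start + 1, p$window_end, p$strand,
                     p$gene_symbol, p$gene_symbol, p$entrez_id))
  writeLines(lines, path)
  invisible(path)
}

#' Write a probe design as TSV (0-based half-open coordinates)
#' @param design a `probe_design`.
#' @param path output file.
#' @export
write_probe_design <- function(design, path) {
  write.table(design$probes[c("probe_id", "chrom", "start", "end",
                              "gc_count", "promoter_index")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write/read a simple key-value configuration file
#'
#' One `key=value` pair per line; numbers are restored as numerics on read.
#' A `seed` key is mandatory.
#' @param config named list of scalars.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  stopifnot(!is.null(config$seed))
  writeLines(sprintf("%s=%s", names(config),
                     vapply(config, function(v) as.character(v)[1], character(1))),
             path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- lapply(kv, function(x) {
    v <- paste(x[-1], collapse = "=")
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(out) <- vapply(kv, `[[`, character(1), 1)
  if (is.null(out$seed)) stop("config file lacks a mandatory `seed` key")
  out
}

#' Read the packaged DMR reference table
#'
#' Loads the digitized 43-row DMR reference table shipped with the package
#' (columns: gene_symbol, gene_description, entrez_id, significance, chr,
#' start, end, region_size) and validates that every row satisfies
#' `region_size == end - start` and carries a significance value.
#'
#' @param path path to the TSV; defaults to the packaged copy.
#' @return validated data.frame of DMR records.
#' @export
read_table2_fixture <- function(path = system.file("extdata", "table2_dmr.tsv",
                                                   package = "medipdmr")) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                   colClasses = c(chr = "character"))
  required <- c("gene_symbol", "gene_description", "entrez_id", "significance",
                "chr", "start", "end", "region_size")
  if (!all(required %in% names(df))) {
    stop("DMR table lacks required columns: ",
         paste(setdiff(required, names(df)), collapse = ", "))
  }
  bad <- which(df$region_size != df$end - df$start)
  if (length(bad)) {
    stop(sprintf("row %d (%s): region_size %d != end - start = %d",
                 bad[1], df$gene_symbol[bad[1]], df$region_size[bad[1]],
                 df$end[bad[1]] - df$start[bad[1]]))
  }
  if (any(!is.finite(df$significance) | df$significance <= 0)) {
    stop("significance column must be positive and finite")
  }
  df
}

#' Read a one-column gene-symbol list
#'
#' Used for differentially-expressed gene lists such as the packaged
#' synthetic stand-in for the study's 523-gene list.
#' @param path TSV with a `gene_symbol` column (comment lines start with `#`).
#' @return character vector of symbols.
#' @export
read_gene_list <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!"gene_symbol" %in% names(df)) stop("gene list lacks a gene_symbol column")
  df$gene_symbol
}
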