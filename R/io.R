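.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

.read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Read / write a two-channel signal table
#'
#' Long-format TSV with header
#' `probeset_id  sample_id  signal_a  signal_b`.
#'
#' @param path File path.
#' @return For the reader, a data.frame; the writer returns `path`
#'   invisibly.
#' @export
read_signal_table <- function(path) {
  x <- .read_tsv(path)
  req <- c("probeset_id", "sample_id", "signal_a", "signal_b")
  if (!identical(names(x)[seq_along(req)], req)) {
    stop("signal table must have columns: ", paste(req, collapse = ", "))
  }
  if (ncol(x) != length(req)) {
    stop("unknown column(s) in signal table: ",
         paste(setdiff(names(x), req), collapse = ", "))
  }
  x
}

#' @rdname read_signal_table
#' @param x Signal table data.frame.
#' @export
write_signal_table <- function(x, path) .write_tsv(x, path)

#' Read / write a genotype-call matrix
#'
#' TSV with samples as rows and loci as columns; the first column
#' (`sample_id`) holds row names; calls in `AA/AB/BB/OO/NN`.
#'
#' @param path File path.
#' @return For the reader, a character matrix with sample row names.
#' @export
read_genotype_matrix <- function(path) {
  x <- .read_tsv(path)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x[[1]]
  bad <- setdiff(unique(as.vector(m)), c("AA", "AB", "BB", "OO", "NN"))
  if (length(bad)) stop("invalid call value(s): ", paste(bad, collapse = ", "))
  m
}

#' @rdname read_genotype_matrix
#' @param x Character matrix, samples x loci.
#' @export
write_genotype_matrix <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE)
  .write_tsv(df, path)
}

#' Read / write a genetic map table
#'
#' TSV with columns `marker`, `chromosome`, `position_cM`.
#'
#' @param path File path.
#' @export
read_genetic_map <- function(path) {
  x <- .read_tsv(path)
  req <- c("marker", "chromosome", "position_cM")
  if (!all(req %in% names(x))) {
    stop("map must have columns: ", paste(req, collapse = ", "))
  }
  x
}

#' @rdname read_genetic_map
#' @param x Map data.frame.
#' @export
write_genetic_map <- function(x, path) .write_tsv(x, path)

.GT_CODE <- c(AA = "0/0", AB = "0/1", BB = "1/1", NN = "./.")

#' Write variant records as plain-text VCF v4.2
#'
#' INFO carries `DP` (total depth) and `MQ` (RMS mapping quality); per-line
#' genotypes go into `GT` sample columns (`AA` = 0/0 homozygous reference,
#' `AB` = 0/1, `BB` = 1/1, `NN` = ./.). Positions are 1-based.
#'
#' @param records Variant records data.frame (see
#'   [generate_variant_records()]).
#' @param path Output file.
#' @return `path` invisibly.
#' @export
write_variant_vcf <- function(records, path) {
  lines <- .line_columns(records)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth of coverage\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", lines), collapse = "\t"))
  gt <- as.matrix(records[, lines, drop = FALSE])
  gtc <- matrix(.GT_CODE[gt], nrow(gt), ncol(gt))
  body <- paste(records$chrom, records$pos, records$id, records$ref,
                records$alt, ".", "PASS",
                sprintf("DP=%d;MQ=%g", records$depth, records$rms_mq),
                "GT", apply(gtc, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF into a variant-record table
#'
#' Parses a VCF v4.2 (via the vcfR package) into the flat variant-record
#' layout used throughout: `chrom`, `pos`, `id`, `ref`, `alt`, `depth`
#' (INFO DP), `rms_mq` (INFO MQ) and one genotype column per sample
#' decoded to `AA/AB/BB/NN`.
#'
#' @param path VCF file.
#' @return data.frame of variant records.
#' @export
read_variant_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("the vcfR package is required to read VCF files")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info <- vcfR::extract.info(v, "DP")
  mq <- vcfR::extract.info(v, "MQ")
  gt_raw <- vcfR::extract.gt(v, "GT")
  decode <- c("0/0" = "AA", "0|0" = "AA", "0/1" = "AB", "0|1" = "AB",
              "1/0" = "AB", "1|0" = "AB", "1/1" = "BB", "1|1" = "BB")
  gt <- matrix(decode[gt_raw], nrow(gt_raw), ncol(gt_raw))
  gt[is.na(gt)] <- "NN"
  colnames(gt) <- colnames(gt_raw)
  out <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                    id = fix$ID, ref = fix$REF, alt = fix$ALT,
                    depth = as.integer(info), rms_mq = as.numeric(mq),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(gt, stringsAsFactors = FALSE))
}

#' Annotate variant records with genomic-fraction labels
#'
#' Joins a BED-like annotation table (0-based half-open intervals,
#' columns `chrom`, `start`, `end`, `label`) onto variant records by
#' position.
#'
#' @param records Variant records.
#' @param bed Annotation data.frame.
#' @return `records` with a `fraction` column.
#' @export
annotate_variants <- function(records, bed) {
  stopifnot(all(c("chrom", "start", "end", "label") %in% names(bed)))
  frac <- rep(NA_character_, nrow(records))
  for (i in seq_len(nrow(bed))) {
    hit <- records$chrom == bed$chrom[i] &
      records$pos > bed$start[i] & records$pos <= bed$end[i]
    frac[hit] <- bed$label[i]
  }
  records$fraction <- frac
  records
}
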