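.line_columns <- function(records) {
  std <- c("chrom", "pos", "id", "ref", "alt", "qual", "depth", "rms_mq",
           "fraction", "hit_count", "genome", "pool", "class", "usable",
           "drop_reason")
  setdiff(names(records), std)
}

#' Filter variant records on depth and mapping quality
#'
#' Keeps records with `depth >= min_depth` and `rms_mq >= min_rms_mq`
#' (boundary values kept).
#'
#' @param records data.frame of variant records (see
#'   [generate_variant_records()] / [read_variant_vcf()]).
#' @param min_depth Minimum depth of coverage (default 5).
#' @param min_rms_mq Minimum root-mean-square mapping quality (default 30).
#' @return list with `kept` and `dropped` (the latter with a
#'   `drop_reason` column: `depth`, `mq` or `depth,mq`).
#' @export
filter_variants <- function(records, min_depth = 5, min_rms_mq = 30) {
  low_d <- records$depth < min_depth
  low_m <- records$rms_mq < min_rms_mq
  keep <- !low_d & !low_m
  dropped <- records[!keep, , drop = FALSE]
  if (nrow(dropped)) {
    dropped$drop_reason <- paste0(ifelse(low_d[!keep], "depth", ""),
                                  ifelse(low_d[!keep] & low_m[!keep], ",", ""),
                                  ifelse(low_m[!keep], "mq", ""))
  } else {
    dropped$drop_reason <- character(0)
  }
  list(kept = records[keep, , drop = FALSE], dropped = dropped)
}

#' Classify a locus by its genotype pattern across lines
#'
#' Class 1: only homozygous AA and BB among the lines; class 2: AA, BB and
#' heterozygous AB; class 3: only one homozygote plus AB; class 4: AB in
#' every line. Missing genotypes are ignored when forming the observed set.
#' By default the one-sided class-3 definition is applied symmetrically
#' (BB + AB patterns also map to class 3); `strict = TRUE` returns
#' `UNCLASSIFIED` for patterns not literally matching a definition. Only
#' classes 1 and 2 are flagged usable for downstream array design.
#'
#' @param genotypes Character vector of per-line genotypes
#'   (`AA`/`AB`/`BB`/`NN`).
#' @param strict Apply the class definitions literally (default FALSE).
#' @return list with `class` (`CLASS1`..`CLASS4` or `UNCLASSIFIED`) and
#'   `usable`.
#' @export
classify_locus <- function(genotypes, strict = FALSE) {
  obs <- genotypes[!genotypes %in% c("NN", NA_character_)]
  if (length(obs) < 2) stop("need at least 2 informative lines")
  s <- sort(unique(obs))
  cls <- if (setequal(s, c("AA", "BB"))) "CLASS1"
  else if (setequal(s, c("AA", "AB", "BB"))) "CLASS2"
  else if (setequal(s, c("AA", "AB"))) "CLASS3"
  else if (setequal(s, "AB")) "CLASS4"
  else if (!strict && setequal(s, c("AB", "BB"))) "CLASS3"
  else "UNCLASSIFIED"
  list(class = cls, usable = cls %in% c("CLASS1", "CLASS2"))
}

#' Classify every record in a variant table
#'
#' @param records Variant records with per-line genotype columns.
#' @param strict Passed to [classify_locus()].
#' @return `records` with `class` and `usable` columns appended.
#' @export
classify_variants <- function(records, strict = FALSE) {
  lines <- .line_columns(records)
  gt <- as.matrix(records[, lines, drop = FALSE])
  res <- apply(gt, 1L, classify_locus, strict = strict)
  records$class <- vapply(res, `[[`, character(1), "class")
  records$usable <- vapply(res, `[[`, logical(1), "usable")
  records
}

#' Transition/transversion accounting
#'
#' A substitution is a transition when `{ref, alt}` is `{A, G}` or
#' `{C, T}`, a transversion otherwise.
#'
#' @param records Variant records with single-nucleotide `ref`/`alt`.
#' @return list with `ts`, `tv` and `ratio` (`NA` when `tv` is 0).
#' @export
ts_tv <- function(records) {
  ref <- toupper(records$ref)
  alt <- toupper(records$alt)
  nts <- c("A", "C", "G", "T")
  if (!all(ref %in% nts) || !all(alt %in% nts)) {
    stop("ref/alt must be single nucleotides")
  }
  purine <- c("A", "G")
  is_ts <- (ref %in% purine) == (alt %in% purine)
  ts <- sum(is_ts)
  tv <- sum(!is_ts)
  list(ts = ts, tv = tv, ratio = if (tv == 0) NA_real_ else ts / tv)
}

#' Private-SNP counts and fractions per line and per genome
#'
#' A record is private when exactly one line carries the non-reference
#' allele (AB or BB) among non-missing lines; records with fewer than two
#' informative lines are excluded from the denominators.
#'
#' @param records Variant records with per-line genotype columns and
#'   (optionally) a `genome` column.
#' @return list with `per_line` (data.frame `line`, `n_private`,
#'   `fraction` of assessable records private to that line) and
#'   `per_genome` (data.frame `genome`, `n`, `n_private`, `fraction` of
#'   that genome's assessable records private to any single line).
#' @export
private_snp_fractions <- function(records) {
  lines <- .line_columns(records)
  if (length(lines) < 2) stop("need at least 2 lines")
  gt <- as.matrix(records[, lines, drop = FALSE])
  carrier <- gt %in% c("AB", "BB")
  dim(carrier) <- dim(gt)
  informative <- gt != "NN" & !is.na(gt)
  n_inf <- rowSums(informative)
  n_carrier <- rowSums(carrier & informative)
  assessable <- n_inf >= 2
  private <- assessable & n_carrier == 1
  who <- rep(NA_character_, nrow(gt))
  who[private] <- lines[apply(carrier[private, , drop = FALSE], 1L,
                              which.max)]
  per_line <- data.frame(
    line = lines,
    n_private = vapply(lines, function(l) sum(who == l, na.rm = TRUE),
                       integer(1)),
    row.names = NULL)
  per_line$fraction <- per_line$n_private / sum(assessable)
  out <- list(per_line = per_line)
  if ("genome" %in% names(records)) {
    per_genome <- do.call(rbind, lapply(
      split(seq_len(nrow(records)), records$genome), function(idx) {
        data.frame(genome = records$genome[idx[1]],
                   n = sum(assessable[idx]),
                   n_private = sum(private[idx]),
                   fraction = sum(private[idx]) / sum(assessable[idx]))
      }))
    rownames(per_genome) <- NULL
    out$per_genome <- per_genome
  }
  out
}

#' Chromosome-by-fraction SNP accounting
#'
#' Counts records by chromosome and genomic fraction, with per-genome
#' subtotals and a grand total; totals always equal the sum of their
#' parts.
#'
#' @param records Variant records with `chrom` and `fraction` columns.
#' @param fractions Column order of the output (default the four standard
#'   fraction labels).
#' @return data.frame with one row per chromosome, one per genome, and a
#'   `Total` row; columns per fraction plus `total`.
#' @export
summarize_snps <- function(records,
                           fractions = .FRACTIONS) {
  bad <- setdiff(unique(records$fraction), fractions)
  if (length(bad)) stop("unknown fraction label(s): ",
                        paste(bad, collapse = ", "))
  tab <- table(factor(records$chrom), factor(records$fraction,
                                             levels = fractions))
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  df <- data.frame(chromosome = rownames(m), m, check.names = FALSE,
                   row.names = NULL)
  df$total <- rowSums(m)
  genome <- sub("^.*([A-Z])$", "\\1", df$chromosome)
  agg <- function(sub, label) {
    row <- data.frame(chromosome = label, check.names = FALSE)
    for (f in c(fractions, "total")) row[[f]] <- sum(sub[[f]])
    row
  }
  rows <- lapply(sort(unique(genome)), function(g) {
    agg(df[genome == g, , drop = FALSE], paste0(g, "-genome"))
  })
  out <- rbind(df, do.call(rbind, rows), agg(df, "Total"))
  rownames(out) <- NULL
  out
}

#' Aggregate pre-tabulated SNP counts
#'
#' Sums a table of per-chromosome counts by genomic fraction (as printed in
#' published per-genome accounts) into a grand total per fraction and
#' overall.
#'
#' @param counts data.frame whose first column is the chromosome and whose
#'   remaining numeric columns are per-fraction counts.
#' @return Named numeric vector of per-fraction totals plus `total`.
#' @export
total_snp_counts <- function(counts) {
  num <- counts[, vapply(counts, is.numeric, logical(1)), drop = FALSE]
  tot <- colSums(num)
  c(tot, total = sum(tot))
}

#' Allocate array SNP quotas across chromosome arms
#'
#' Allocation is proportional to arm physical size with D-genome arms
#' weighted by `d_multiplier` (default 2, doubling the D-genome share to
#' compensate its lower polymorphism), integerized by largest remainder so
#' allocations sum exactly to the requested total.
#'
#' @param arms data.frame with columns `arm`, `size`, `genome`.
#' @param total Total number of SNPs to allocate (> 0).
#' @param d_multiplier Weight multiplier for D-genome arms.
#' @return `arms` with an `allocated` column.
#' @export
allocate_quota <- function(arms, total, d_multiplier = 2) {
  stopifnot(nrow(arms) >= 1, total > 0, all(arms$size > 0))
  w <- arms$size * ifelse(arms$genome == "D", d_multiplier, 1)
  exact <- total * w / sum(w)
  base <- floor(exact)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  arms$allocated <- as.integer(base)
  arms
}

#' Select array candidate SNPs under eligibility rules and arm quotas
#'
#' A record is eligible when the non-reference allele is observed in at
#' least `min_lines` lines, both alleles are present within the European
#' pool, its context sequence has a single genomic hit, and its locus
#' class is usable (class 1 or 2). Eligible records fill each arm's quota
#' in order of descending carrier-line count, then position, then
#' identifier.
#'
#' @param records Variant records with per-line genotype columns, `class`/
#'   `usable` columns (see [classify_variants()]) and `hit_count`.
#' @param pools Named character vector or two-column data.frame mapping
#'   line names to pools (`European` / other).
#' @param quotas data.frame with `arm` (matching `records$chrom` here at
#'   chromosome resolution) and `allocated` (see [allocate_quota()]).
#' @param min_lines Minimum carrier lines (default 2).
#' @return list with `selected` (chosen records) and `audit` (per-record
#'   eligibility and exclusion reasons).
#' @export
select_candidates <- function(records, pools, quotas, min_lines = 2) {
  if (is.data.frame(pools)) {
    pools <- stats::setNames(as.character(pools[[2]]),
                             as.character(pools[[1]]))
  }
  lines <- .line_columns(records)
  if (!all(lines %in% names(pools))) {
    stop("every line needs a pool label")
  }
  if (!all(c("class", "usable") %in% names(records))) {
    records <- classify_variants(records)
  }
  gt <- as.matrix(records[, lines, drop = FALSE])
  informative <- gt != "NN" & !is.na(gt)
  carrier <- (gt %in% c("AB", "BB"))
  dim(carrier) <- dim(gt)
  n_carrier <- rowSums(carrier & informative)
  eu <- lines[pools[lines] == "European"]
  eu_gt <- gt[, eu, drop = FALSE]
  eu_has_alt <- rowSums((eu_gt %in% c("AB", "BB")) &
                          (eu_gt != "NN")) > 0
  eu_has_ref <- rowSums((eu_gt %in% c("AA", "AB")) &
                          (eu_gt != "NN")) > 0
  reasons <- lapply(seq_len(nrow(records)), function(i) {
    r <- character(0)
    if (n_carrier[i] < min_lines) r <- c(r, "too_few_carrier_lines")
    if (!(eu_has_alt[i] && eu_has_ref[i])) r <- c(r, "monomorphic_in_european")
    if (records$hit_count[i] != 1) r <- c(r, "multi_hit")
    if (!records$usable[i]) r <- c(r, "unusable_class")
    r
  })
  eligible <- lengths(reasons) == 0L
  audit <- data.frame(id = records$id, chrom = records$chrom,
                      eligible = eligible,
                      exclusion_reasons = vapply(reasons, paste,
                                                 character(1),
                                                 collapse = ","))
  sel_idx <- integer(0)
  for (j in seq_len(nrow(quotas))) {
    arm <- quotas$arm[j]
    pool_idx <- which(eligible & records$chrom == arm)
    ord <- pool_idx[order(-n_carrier[pool_idx], records$pos[pool_idx],
                          records$id[pool_idx])]
    q <- quotas$allocated[j]
    if (length(ord) < q) {
      warning("arm ", arm, " under-filled: ", length(ord), " eligible of ",
              q, " requested")
    }
    sel_idx <- c(sel_idx, utils::head(ord, q))
  }
  list(selected = records[sel_idx, , drop = FALSE], audit = audit)
}
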