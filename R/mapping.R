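#' Chi-square test of 1:1 segregation
#'
#' One-degree-of-freedom goodness-of-fit of the two parental homozygote
#' counts against equal expectation; heterozygous and missing calls are
#' excluded. No continuity correction (the conventional marker-distortion
#' test).
#'
#' @param n_A,n_B Counts of parent-1 and parent-2 homozygotes.
#' @return list with `statistic` and `p_value`.
#' @export
segregation_chi_square <- function(n_A, n_B) {
  if (n_A + n_B < 1) stop("no informative genotypes")
  stat <- (n_A - n_B)^2 / (n_A + n_B)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Filter mapping-population markers
#'
#' Applies, in order, the marker selection rules for an inbred mapping
#' population, recording every violated rule: the probeset must be PHR;
#' it must be diploidized; both parents must be called, homozygous and
#' opposite; the progeny missing fraction must not exceed
#' `max_missing`; and the 1:1 segregation test must not reject at
#' `distortion_p`.
#'
#' @param genotypes Character matrix, (parents + individuals) x markers.
#' @param categories Per-marker category vector (aligned with columns).
#' @param diploidized Per-marker logical vector.
#' @param parents Length-2 vector of parent row names (default
#'   `c("P1", "P2")`).
#' @param max_missing Maximum tolerated progeny missing fraction (default
#'   0.15).
#' @param distortion_p Significance level of the distortion test (default
#'   0.01); markers with p <= this level are rejected.
#' @return data.frame of class `marker_filter_report`: `marker`, `kept`,
#'   `rejection_reasons` (comma-separated), `chi_square`, `p_value`,
#'   `missing_fraction`.
#' @export
filter_mapping_markers <- function(genotypes, categories, diploidized,
                                   parents = c("P1", "P2"),
                                   max_missing = 0.15,
                                   distortion_p = 0.01) {
  if (!all(parents %in% rownames(genotypes))) {
    stop("parent rows ", paste(parents, collapse = ", "),
         " must be present in the genotype matrix")
  }
  stopifnot(ncol(genotypes) == length(categories),
            ncol(genotypes) == length(diploidized))
  prog <- genotypes[!(rownames(genotypes) %in% parents), , drop = FALSE]
  p1 <- genotypes[parents[1], ]
  p2 <- genotypes[parents[2], ]
  markers <- colnames(genotypes)
  if (is.null(markers)) markers <- sprintf("M%05d", seq_len(ncol(genotypes)))

  out <- lapply(seq_len(ncol(genotypes)), function(j) {
    reasons <- character(0)
    if (categories[j] != "PHR") reasons <- c(reasons, "not_PHR")
    if (!isTRUE(diploidized[j])) reasons <- c(reasons, "not_diploidized")
    par_ok <- p1[j] %in% c("AA", "BB") && p2[j] %in% c("AA", "BB") &&
      p1[j] != p2[j]
    if (!par_ok) reasons <- c(reasons, "parent_missing_or_het")
    missing_frac <- mean(prog[, j] == "NN")
    if (missing_frac > max_missing) reasons <- c(reasons, "excess_missing")
    ## orient counts to parent alleles when known, else raw AA/BB
    a_call <- if (par_ok) p1[j] else "AA"
    b_call <- if (par_ok) p2[j] else "BB"
    n_a <- sum(prog[, j] == a_call)
    n_b <- sum(prog[, j] == b_call)
    stat <- NA_real_; pval <- NA_real_
    if (n_a + n_b >= 1) {
      cs <- segregation_chi_square(n_a, n_b)
      stat <- cs$statistic; pval <- cs$p_value
      if (pval <= distortion_p) reasons <- c(reasons, "distorted")
    } else {
      reasons <- c(reasons, "distorted")
    }
    data.frame(marker = markers[j], kept = length(reasons) == 0L,
               rejection_reasons = paste(reasons, collapse = ","),
               chi_square = stat, p_value = pval,
               missing_fraction = missing_frac)
  })
  rep <- do.call(rbind, out)
  class(rep) <- c("marker_filter_report", class(rep))
  rep
}

#' Group markers into cosegregation bins
#'
#' Two markers are linked when their genotype vectors agree at every
#' individual where both are non-missing (and they share at least one such
#' individual); bins are the single-linkage transitive closure of that
#' relation. Because missing-tolerant equality is not transitive, bins
#' whose members are not pairwise compatible are flagged. The
#' representative of a bin is its member with the fewest missing calls,
#' ties broken by identifier order.
#'
#' @param genotypes Character matrix, individuals x markers (parent rows,
#'   if any, should be removed first).
#' @return data.frame: `marker`, `bin`, `representative`, `bin_size`,
#'   `bin_consistent`.
#' @export
cosegregation_bins <- function(genotypes) {
  m <- ncol(genotypes)
  stopifnot(m >= 1)
  markers <- colnames(genotypes)
  if (is.null(markers)) markers <- sprintf("M%05d", seq_len(m))
  g <- genotypes
  g[g == "NN"] <- NA_character_
  obs <- !is.na(g)
  mode(obs) <- "numeric"
  compared <- crossprod(obs)
  matches <- matrix(0, m, m)
  for (s in setdiff(unique(as.vector(g)), NA_character_)) {
    ind <- (g == s) & !is.na(g)
    mode(ind) <- "numeric"
    matches <- matches + crossprod(ind)
  }
  compatible <- (compared - matches == 0) & (compared >= 1)
  gr <- igraph::graph_from_adjacency_matrix(compatible, mode = "undirected",
                                            diag = FALSE)
  comp <- igraph::components(gr)$membership
  n_missing <- colSums(!obs)
  out <- data.frame(marker = markers, bin = comp,
                    n_missing = n_missing, stringsAsFactors = FALSE)
  reps <- vapply(split(seq_len(m), comp), function(idx) {
    idx <- idx[order(n_missing[idx], markers[idx])]
    markers[idx[1]]
  }, character(1))
  cons <- vapply(split(seq_len(m), comp), function(idx) {
    all(compatible[idx, idx] | diag(length(idx)) == 1)
  }, logical(1))
  out$representative <- reps[as.character(comp)]
  out$bin_size <- tabulate(comp)[comp]
  out$bin_consistent <- cons[as.character(comp)]
  out$n_missing <- NULL
  rownames(out) <- NULL
  out
}

#' Genetic-map summary statistics
#'
#' Per chromosome, per genome (when chromosome names end in a genome
#' letter) and in total: marker count, map length (max - min position),
#' number of unique genetic positions, number of non-redundant markers
#' (singleton cosegregation bins), and mean bin length = length / unique
#' positions (reported rounded to 2 decimals).
#'
#' @param map data.frame with columns `marker`, `chromosome`,
#'   `position_cM` (no missing positions).
#' @param bins Optional output of [cosegregation_bins()]; without it the
#'   non-redundant column is `NA`.
#' @return data.frame with one row per chromosome plus a `Total` row.
#' @export
map_summary <- function(map, bins = NULL) {
  stopifnot(all(c("marker", "chromosome", "position_cM") %in% names(map)))
  if (anyNA(map$position_cM)) stop("marker without a position")
  singleton <- NULL
  if (!is.null(bins)) {
    singleton <- bins$marker[bins$bin_size == 1L]
  }
  one <- function(sub) {
    len <- max(sub$position_cM) - min(sub$position_cM)
    uniq <- length(unique(sub$position_cM))
    data.frame(n_markers = nrow(sub), length_cM = len,
               unique_positions = uniq,
               non_redundant = if (is.null(singleton)) NA_integer_ else
                 sum(sub$marker %in% singleton),
               bin_length_cM = round(len / uniq, 2))
  }
  per_chr <- do.call(rbind, lapply(split(map, map$chromosome), one))
  per_chr <- cbind(chromosome = rownames(per_chr), per_chr)
  tot_len <- sum(per_chr$length_cM)
  tot_uniq <- sum(per_chr$unique_positions)
  total <- data.frame(chromosome = "Total", n_markers = nrow(map),
                      length_cM = tot_len, unique_positions = tot_uniq,
                      non_redundant = if (is.null(singleton)) NA_integer_
                        else sum(per_chr$non_redundant),
                      bin_length_cM = round(tot_len / tot_uniq, 2))
  out <- rbind(per_chr, total)
  rownames(out) <- NULL
  out
}

#' Combine per-chromosome map statistics into genome and total rows
#'
#' Aggregates a table of per-chromosome map statistics (as produced by
#' [map_summary()] or entered from published per-chromosome accounts) into
#' per-genome subtotals (grouping chromosomes by their trailing genome
#' letter) and a grand total, recomputing the mean bin length as summed
#' length over summed unique positions.
#'
#' @param stats data.frame with columns `chromosome`, `n_markers`,
#'   `length_cM`, `unique_positions`, `non_redundant`.
#' @return data.frame with genome rows and a `Total` row appended.
#' @export
summarize_map_table <- function(stats) {
  req <- c("chromosome", "n_markers", "length_cM", "unique_positions",
           "non_redundant")
  stopifnot(all(req %in% names(stats)))
  chr <- stats[!stats$chromosome %in% c("Total") &
                 !grepl("genome", stats$chromosome), , drop = FALSE]
  agg <- function(sub, label) {
    data.frame(chromosome = label,
               n_markers = sum(sub$n_markers),
               length_cM = sum(sub$length_cM),
               unique_positions = sum(sub$unique_positions),
               non_redundant = sum(sub$non_redundant),
               bin_length_cM = round(sum(sub$length_cM) /
                                       sum(sub$unique_positions), 2))
  }
  genome <- sub("^.*([A-Z])$", "\\1", chr$chromosome)
  rows <- lapply(sort(unique(genome)), function(g) {
    agg(chr[genome == g, , drop = FALSE], paste0(g, "-genome"))
  })
  chr$bin_length_cM <- round(chr$length_cM / chr$unique_positions, 2)
  out <- rbind(chr, do.call(rbind, rows), agg(chr, "Total"))
  rownames(out) <- NULL
  out
}

#' Rank concordance between two genetic maps
#'
#' Spearman rank correlation of marker positions over shared markers, per
#' chromosome (of the first map), plus the unweighted average.
#'
#' @param map_a,map_b data.frames with `marker`, `chromosome`,
#'   `position_cM`.
#' @param min_shared Minimum shared markers per chromosome (default 3);
#'   chromosomes below this are skipped with a warning.
#' @return list with `per_chromosome` (data.frame `chromosome`, `n_shared`,
#'   `rho`) and `average`.
#' @export
compare_maps <- function(map_a, map_b, min_shared = 3) {
  shared <- intersect(map_a$marker, map_b$marker)
  a <- map_a[map_a$marker %in% shared, ]
  b <- map_b[match(a$marker, map_b$marker), ]
  rows <- lapply(split(seq_len(nrow(a)), a$chromosome), function(idx) {
    if (length(idx) < min_shared) {
      warning("chromosome ", a$chromosome[idx[1]], " has fewer than ",
              min_shared, " shared markers; skipped")
      return(NULL)
    }
    data.frame(chromosome = a$chromosome[idx[1]], n_shared = length(idx),
               rho = stats::cor(a$position_cM[idx], b$position_cM[idx],
                                method = "spearman"))
  })
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  list(per_chromosome = per,
       average = if (is.null(per)) NA_real_ else mean(per$rho))
}
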