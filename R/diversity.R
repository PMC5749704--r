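#' Polymorphism information content
#'
#' `PIC = 1 - sum(p_i^2)` over the allele frequency spectrum of a locus.
#'
#' @param spectrum Numeric vector of allele frequencies summing to 1
#'   (tolerance 1e-9).
#' @return Scalar in `[0, 1 - 1/n]` for `n` alleles.
#' @export
pic <- function(spectrum) {
  if (abs(sum(spectrum) - 1) > 1e-9 || any(spectrum < 0)) {
    stop("allele frequencies must be non-negative and sum to 1")
  }
  1 - sum(spectrum^2)
}

#' Allele frequency spectrum from a column of genotype calls
#'
#' Counts A and B alleles from `AA`/`AB`/`BB` calls (two per homozygote,
#' one each per het). Missing (`NN`) calls are excluded; null-allele (`OO`)
#' calls carry neither the A nor the B allele and are likewise excluded.
#'
#' @param calls Character vector of calls.
#' @return Named numeric vector of frequencies over the observed alleles.
#' @export
allele_frequencies <- function(calls) {
  calls <- calls[!calls %in% c("NN", "OO")]
  if (!length(calls)) stop("no informative calls in column")
  n_a <- 2 * sum(calls == "AA") + sum(calls == "AB")
  n_b <- 2 * sum(calls == "BB") + sum(calls == "AB")
  f <- c(A = n_a, B = n_b) / (n_a + n_b)
  f[f > 0]
}

#' Per-locus PIC over a genotype matrix
#'
#' @param genotypes Character matrix, samples x loci.
#' @return Numeric vector of PIC values (NA for loci without informative
#'   calls).
#' @export
pic_by_locus <- function(genotypes) {
  apply(genotypes, 2L, function(col) {
    col <- col[!col %in% c("NN", "OO")]
    if (!length(col)) return(NA_real_)
    pic(allele_frequencies(col))
  })
}

#' Simple-matching dissimilarity matrix
#'
#' For each pair of samples, the fraction of mismatching loci among loci
#' where both calls are non-missing (pairwise-complete). By default the
#' null-allele call `OO` is treated as a fourth genotype state that can
#' match or mismatch like any other; `oo` = "missing" drops it from the
#' comparison instead, and `oo` = "mismatch" makes it mismatch every
#' called genotype (including another `OO`).
#'
#' @param genotypes Character matrix, samples x loci, calls in
#'   `AA/AB/BB/OO/NN`.
#' @param oo How to treat `OO` calls: `"state"` (default), `"missing"`,
#'   `"mismatch"`.
#' @return list of class `sm_dist`: `d` (symmetric matrix of
#'   dissimilarities with zero diagonal), `n_compared` (per-pair compared
#'   locus counts); pairs with no compared loci get `NA` distance and a
#'   warning.
#' @export
simple_matching_distance <- function(genotypes,
                                     oo = c("state", "missing", "mismatch")) {
  oo <- match.arg(oo)
  stopifnot(is.matrix(genotypes), nrow(genotypes) >= 2)
  g <- genotypes
  g[g == "NN"] <- NA_character_
  if (oo == "missing") g[g == "OO"] <- NA_character_
  states <- setdiff(unique(as.vector(g)), NA_character_)
  if (oo == "mismatch") states <- setdiff(states, "OO")
  obs <- !is.na(g)
  mode(obs) <- "numeric"
  compared <- tcrossprod(obs)
  matches <- matrix(0, nrow(g), nrow(g))
  for (s in states) {
    ind <- (g == s) & !is.na(g)
    mode(ind) <- "numeric"
    matches <- matches + tcrossprod(ind)
  }
  d <- 1 - matches / compared
  d[compared == 0] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- list(rownames(genotypes), rownames(genotypes))
  if (any(compared[upper.tri(compared)] == 0)) {
    warning("some sample pairs share no compared loci; distance set to NA")
  }
  structure(list(d = d, n_compared = compared), class = "sm_dist")
}

.as_dist_matrix <- function(dist) {
  d <- if (inherits(dist, "sm_dist")) dist$d else as.matrix(dist)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12))) {
    stop("distance matrix must be symmetric")
  }
  d
}

#' Ward minimum-variance dendrogram
#'
#' Agglomerative clustering under Ward's criterion (Lance--Williams update
#' on squared dissimilarities, i.e. `hclust` method `ward.D2`). Merge
#' heights are non-decreasing.
#'
#' @param dist An `sm_dist`, `dist` or symmetric matrix.
#' @return list of class `tree_result`: `tree` (an `ape` phylo), `hclust`
#'   (the raw hclust object), `method = "ward"`.
#' @export
ward_cluster <- function(dist) {
  d <- .as_dist_matrix(dist)
  hc <- stats::hclust(stats::as.dist(d), method = "ward.D2")
  structure(list(tree = ape::as.phylo(hc), hclust = hc, method = "ward"),
            class = "tree_result")
}

#' Neighbor-joining tree
#'
#' Saitou--Nei neighbor joining (via `ape::nj`); on an additive
#' (tree-metric) input the generating topology and branch lengths are
#' recovered exactly. Negative branch lengths are clamped to zero with the
#' deficit transferred to the sibling branch so path lengths through the
#' parent are preserved.
#'
#' @param dist An `sm_dist`, `dist` or symmetric matrix over at least 3
#'   samples.
#' @return list of class `tree_result` with elements `tree` and
#'   `method = "nj"`.
#' @export
nj_tree <- function(dist) {
  d <- .as_dist_matrix(dist)
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 samples")
  tr <- ape::nj(stats::as.dist(d))
  ## clamp negative branch lengths, moving the deficit to the sibling
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1]
    sibs <- which(tr$edge[, 1] == parent)
    sibs <- setdiff(sibs, e)
    if (length(sibs)) {
      tr$edge.length[sibs[1]] <- tr$edge.length[sibs[1]] + tr$edge.length[e]
    }
    tr$edge.length[e] <- 0
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  structure(list(tree = tr, method = "nj"), class = "tree_result")
}

#' @export
print.tree_result <- function(x, ...) {
  cat("tree_result (", x$method, "), ", length(x$tree$tip.label),
      " tips\n", sep = "")
  invisible(x)
}

#' Write a tree to a Newick file
#'
#' @param x A `tree_result`.
#' @param path Output file.
#' @return `path` invisibly.
#' @export
write_tree_newick <- function(x, path) {
  stopifnot(inherits(x, "tree_result"))
  ape::write.tree(x$tree, file = path)
  invisible(path)
}

#' Presence/absence matrix from off-target-variant loci
#'
#' Restricts a genotype matrix to loci categorized OTV, drops any locus
#' with at least one missing call, and encodes the null-allele call `OO`
#' as 0 (probe target absent) and any called genotype as 1 (present).
#'
#' @param genotypes Character matrix, samples x loci.
#' @param categories Character vector of per-locus categories (aligned with
#'   the columns of `genotypes`).
#' @return Binary integer matrix, samples x qualifying loci; an empty
#'   matrix (with a warning) when no locus qualifies.
#' @export
otv_pav_matrix <- function(genotypes, categories) {
  stopifnot(ncol(genotypes) == length(categories))
  keep <- categories == "OTV" & !apply(genotypes == "NN", 2L, any)
  if (!any(keep)) {
    warning("no fully-called OTV loci; returning empty PAV matrix")
    return(matrix(integer(0), nrow(genotypes), 0,
                  dimnames = list(rownames(genotypes), NULL)))
  }
  sub <- genotypes[, keep, drop = FALSE]
  pav <- (sub != "OO") * 1L
  dimnames(pav) <- dimnames(sub)
  pav
}
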