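# small simulation helpers shared across tests

# points from labelled Gaussian clusters in contrast/size space
make_cluster_points <- function(centers, n_per, sd_contrast = 0.1,
                                size = 11, sd_size = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gt <- rep(names(centers), n_per)
  data.frame(contrast = centers[gt] + rnorm(length(gt), 0, sd_contrast),
             size = size + rnorm(length(gt), 0, sd_size),
             truth = gt, stringsAsFactors = FALSE)
}

# a probeset_model built directly from cluster parameters
manual_model <- function(labels, mean_contrast, mean_size, var_contrast,
                         var_size, weight = NULL, mass = 10,
                         inbred_penalty = 4) {
  k <- length(labels)
  if (is.null(weight)) weight <- rep(1 / k, k)
  structure(list(
    clusters = data.frame(label = labels, weight = weight,
                          mean_contrast = mean_contrast,
                          mean_size = mean_size,
                          var_contrast = var_contrast,
                          var_size = var_size,
                          mass = rep_len(mass, k)),
    inbred_penalty = inbred_penalty, converged = TRUE,
    log_likelihood = NA_real_, objective_trace = numeric(0),
    n = sum(rep_len(mass, k)), degenerate = FALSE),
    class = "probeset_model")
}

# an additive distance matrix from a random tree with known branch lengths
random_additive_matrix <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa, br = function(n) runif(n, 0.1, 1))
  tr <- ape::unroot(tr)
  list(tree = tr, d = as.matrix(ape::cophenetic.phylo(tr)))
}
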