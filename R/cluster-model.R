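#' @keywords internal
.GENO_LABELS <- c("BB", "AB", "AA")

## penalized prior over genotype components: AB down-weighted by 2^-penalty
.penalized_weights <- function(labels, inbred_penalty) {
  w <- ifelse(labels == "AB", 2^(-inbred_penalty), 1)
  w / sum(w)
}

.row_log_sum_exp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

## component log-densities (diagonal Gaussian in contrast x size)
.comp_logdens <- function(contrast, size, cl) {
  n <- length(contrast)
  k <- nrow(cl)
  out <- matrix(NA_real_, n, k)
  for (j in seq_len(k)) {
    out[, j] <- stats::dnorm(contrast, cl$mean_contrast[j],
                             sqrt(cl$var_contrast[j]), log = TRUE) +
      stats::dnorm(size, cl$mean_size[j], sqrt(cl$var_size[j]), log = TRUE)
  }
  out
}

## score a candidate label assignment for models with < 3 components:
## penalized prior weight plus a Gaussian anchor on the contrast position
## (BB/AB/AA expected near -1 / 0 / +1). The same 2^-penalty factor that
## down-weights AB during fitting also discourages a het reading here, so a
## strong inbred penalty re-interprets a near-zero cluster as a compressed
## homozygote.
.label_score <- function(means, labels, inbred_penalty, anchors, anchor_sd) {
  w <- .penalized_weights(labels, inbred_penalty)
  a <- anchors[match(labels, .GENO_LABELS)]
  sum(log(w) + stats::dnorm(means, a, anchor_sd, log = TRUE))
}

.assign_labels <- function(means, inbred_penalty, anchors, anchor_sd) {
  k <- length(means)
  ord <- order(means)
  if (k >= 3) {
    labs <- character(k)
    labs[ord] <- .GENO_LABELS
    return(labs)
  }
  cands <- if (k == 2) {
    list(c("BB", "AB"), c("BB", "AA"), c("AB", "AA"))
  } else {
    list("BB", "AB", "AA")
  }
  scores <- vapply(cands, function(labs) {
    .label_score(sort(means), labs, inbred_penalty, anchors, anchor_sd)
  }, numeric(1))
  best <- cands[[which.max(scores)]]
  labs <- character(k)
  labs[ord] <- best
  labs
}

## one EM run with fixed penalized mixture weights; only means and
## variances are re-estimated, so the data log-likelihood is
## non-decreasing (variance floors act as box constraints).
.em_run <- function(contrast, size, cl, weights, max_iter, tol,
                    var_floor = 1e-8) {
  n <- length(contrast)
  k <- nrow(cl)
  obj_trace <- numeric(0)
  ll <- NA_real_
  converged <- FALSE
  r <- NULL
  for (it in seq_len(max_iter)) {
    ld <- sweep(.comp_logdens(contrast, size, cl), 2L, log(weights), "+")
    lse <- .row_log_sum_exp(ld)
    ll <- sum(lse)
    obj_trace <- c(obj_trace, ll)
    if (it > 1L) {
      prev <- obj_trace[it - 1L]
      if (abs(ll - prev) <= tol * (abs(prev) + 1e-12)) {
        converged <- TRUE
        break
      }
    }
    r <- exp(ld - lse)
    Nj <- colSums(r) + 1e-300
    mu_c <- colSums(r * contrast) / Nj
    mu_s <- colSums(r * size) / Nj
    for (j in seq_len(k)) {
      cl$mean_contrast[j] <- mu_c[j]
      cl$mean_size[j] <- mu_s[j]
      cl$var_contrast[j] <- max(var_floor,
        sum(r[, j] * (contrast - mu_c[j])^2) / Nj[j])
      cl$var_size[j] <- max(var_floor,
        sum(r[, j] * (size - mu_s[j])^2) / Nj[j])
    }
  }
  if (is.null(r)) {
    ld <- sweep(.comp_logdens(contrast, size, cl), 2L, log(weights), "+")
    r <- exp(ld - .row_log_sum_exp(ld))
  }
  cl$mass <- colSums(r)
  cl$weight <- weights
  list(clusters = cl, log_likelihood = ll, objective_trace = obj_trace,
       converged = converged, resp = r)
}

#' Fit per-probeset genotype clusters in contrast/size space
#'
#' Expectation--maximization over up to three diagonal-covariance Gaussian
#' components (BB, AB, AA by increasing contrast). The AB component's prior
#' mixing weight is divided by `2^inbred_penalty` and renormalized; mixture
#' weights are held at these penalized prior values so the data
#' log-likelihood is provably non-decreasing across iterations. Components
#' retaining less than half an expected sample of posterior mass
#' (mass < 1/2, i.e. a mixing fraction below 1/(2n)) are pruned and the
#' remaining components refit; near-coincident components are merged.
#'
#' @param points data.frame with columns `contrast` and `size` (one row per
#'   sample; rows with `NA` are ignored for fitting).
#' @param inbred_penalty Non-negative scalar; 4 is a mild penalty, 16 a
#'   strong one for fully inbred material.
#' @param init_seed Optional integer; initialization is a deterministic
#'   quantile split of contrast so the seed only matters for tie-breaking.
#' @param max_iter,tol EM iteration cap and relative objective tolerance.
#' @param anchors Contrast anchor positions for BB/AB/AA, used when
#'   scoring label assignments for models with fewer than three surviving
#'   components.
#' @param anchor_sd Anchor scale for that labelling score.
#' @return An object of class `probeset_model`: a list with elements
#'   `clusters` (data.frame: label, weight, mean_contrast, mean_size,
#'   var_contrast, var_size, mass), `inbred_penalty`, `converged`,
#'   `log_likelihood`, `objective_trace`, `n`, `degenerate`.
#' @export
fit_genotype_clusters <- function(points, inbred_penalty = 4,
                                  init_seed = NULL, max_iter = 200,
                                  tol = 1e-8, anchors = c(-1, 0, 1),
                                  anchor_sd = 0.35) {
  stopifnot(is.data.frame(points), all(c("contrast", "size") %in% names(points)))
  if (inbred_penalty < 0) stop("inbred_penalty must be non-negative")
  ok <- stats::complete.cases(points[, c("contrast", "size")])
  contrast <- points$contrast[ok]
  size <- points$size[ok]
  n <- length(contrast)
  if (n < 5) stop("need at least 5 non-missing points to fit a probeset model")
  if (!is.null(init_seed)) set.seed(as.integer(init_seed) %% .Machine$integer.max)

  u <- length(unique(contrast))
  k0 <- min(3L, u)
  ## degenerate: all points identical
  if (u == 1L && length(unique(size)) == 1L) {
    lab <- .assign_labels(contrast[1], inbred_penalty, anchors, anchor_sd)
    cl <- data.frame(label = lab, weight = 1, mean_contrast = contrast[1],
                     mean_size = size[1], var_contrast = 1e-8,
                     var_size = 1e-8, mass = n)
    return(structure(list(clusters = cl, inbred_penalty = inbred_penalty,
                          converged = TRUE, log_likelihood = NA_real_,
                          objective_trace = numeric(0), n = n,
                          degenerate = FALSE),
                     class = "probeset_model"))
  }

  ## quantile-split initialization (contiguous groups of the contrast
  ## order, ties by sample order), refined by deterministic 1-D Lloyd
  ## iterations on contrast so minority clusters obtain their own centre
  ord <- order(contrast, seq_along(contrast))
  grp_q <- cut(seq_len(n), breaks = k0, labels = FALSE)
  centres <- vapply(seq_len(k0), function(j) mean(contrast[ord[grp_q == j]]),
                    numeric(1))
  assign <- integer(n)
  for (it in 1:25) {
    assign_new <- max.col(-abs(outer(contrast, centres, "-")),
                          ties.method = "first")
    if (identical(assign_new, assign)) break
    assign <- assign_new
    for (j in seq_len(k0)) {
      if (any(assign == j)) centres[j] <- mean(contrast[assign == j])
    }
  }
  init_lab <- if (k0 == 3L) .GENO_LABELS else .GENO_LABELS[c(1, 3)][seq_len(k0)]
  centre_order <- order(centres)
  cl <- do.call(rbind, lapply(seq_len(k0), function(j) {
    jj <- centre_order[j]
    idx <- if (any(assign == jj)) which(assign == jj) else ord[grp_q == jj]
    data.frame(label = init_lab[j],
               weight = NA_real_,
               mean_contrast = mean(contrast[idx]),
               mean_size = mean(size[idx]),
               var_contrast = max(1e-4, stats::var(contrast[idx]) *
                                    (length(idx) - 1) / max(1, length(idx))),
               var_size = max(1e-4, stats::var(size[idx]) *
                                (length(idx) - 1) / max(1, length(idx))),
               mass = NA_real_)
  }))
  cl$var_contrast[is.na(cl$var_contrast)] <- 1e-4
  cl$var_size[is.na(cl$var_size)] <- 1e-4

  fit <- NULL
  for (pass in 1:6) {
    w <- .penalized_weights(cl$label, inbred_penalty)
    fit <- .em_run(contrast, size, cl, w, max_iter, tol)
    cl <- fit$clusters
    ## prune components holding less than half an expected sample of
    ## posterior mass, or fewer than two hard-assigned members (a single
    ## point is not a cluster: every downstream metric needs >= 2)
    if (nrow(cl) > 1L && any(cl$mass < 0.5)) {
      cl <- cl[-which.min(cl$mass), , drop = FALSE]
      next
    }
    if (nrow(cl) > 1L) {
      n_members <- tabulate(max.col(fit$resp, ties.method = "first"),
                            nbins = nrow(cl))
      if (any(n_members < 2L)) {
        cl <- cl[-which.min(n_members), , drop = FALSE]
        next
      }
    }
    ## merge components only when a merged model explains the data nearly
    ## as well (BIC: log-likelihood loss below 2 log n for the 4 freed
    ## parameters). Duplicate fits of one cloud merge; a component holding
    ## a genuinely distinct cluster survives because removing it costs
    ## far more likelihood than the complexity credit.
    if (nrow(cl) > 1L) {
      member_of <- max.col(fit$resp, ties.method = "first")
      best_loss <- Inf
      best_cl <- NULL
      for (j in seq_len(nrow(cl) - 1L)) {
        for (jj in seq(j + 1L, nrow(cl))) {
          keep <- if (cl$mass[j] >= cl$mass[jj]) j else jj
          drop <- if (keep == j) jj else j
          idx <- member_of %in% c(j, jj)
          if (sum(idx) < 2L) next
          cand <- cl[-drop, , drop = FALSE]
          kk <- which(seq_len(nrow(cl))[-drop] == keep)
          cand$mean_contrast[kk] <- mean(contrast[idx])
          cand$mean_size[kk] <- mean(size[idx])
          cand$var_contrast[kk] <- max(1e-8, stats::var(contrast[idx]))
          cand$var_size[kk] <- max(1e-8, stats::var(size[idx]))
          w_cand <- .penalized_weights(cand$label, inbred_penalty)
          cand_fit <- .em_run(contrast, size, cand, w_cand, 25, 1e-6)
          loss <- fit$log_likelihood - cand_fit$log_likelihood
          if (loss < 2 * log(n) && loss < best_loss) {
            best_loss <- loss
            best_cl <- cand_fit$clusters
          }
        }
      }
      if (!is.null(best_cl)) {
        cl <- best_cl
        next
      }
    }
    ## final label assignment by contrast ordering / penalized scoring
    labs <- .assign_labels(cl$mean_contrast, inbred_penalty, anchors, anchor_sd)
    if (!identical(labs, cl$label)) {
      cl$label <- labs
      next   # weights depend on labels; refit once under the new labels
    }
    break
  }
  cl <- cl[order(cl$mean_contrast), , drop = FALSE]
  rownames(cl) <- NULL
  structure(list(clusters = cl, inbred_penalty = inbred_penalty,
                 converged = fit$converged,
                 log_likelihood = fit$log_likelihood,
                 objective_trace = fit$objective_trace, n = n,
                 degenerate = FALSE),
            class = "probeset_model")
}

#' @export
print.probeset_model <- function(x, ...) {
  cat("probeset_model:", nrow(x$clusters), "component(s), inbred penalty",
      x$inbred_penalty, if (isTRUE(x$degenerate)) "(degenerate)" else "", "\n")
  print(x$clusters, ...)
  invisible(x)
}

#' Assign genotype calls under a fitted probeset model
#'
#' Each point receives the maximum-posterior component label (`OO` for an
#' off-target-variant component) with confidence equal to that posterior
#' probability; points with posterior below `confidence_threshold`, or with
#' missing signals, are called `NN`.
#'
#' @param model A `probeset_model`.
#' @param points data.frame with `contrast` and `size` columns; `NA` rows
#'   yield `NN`.
#' @param confidence_threshold Posterior probability below which a call is
#'   set to `NN` (default 0.95).
#' @return data.frame with columns `call` and `confidence`.
#' @export
call_genotypes <- function(model, points, confidence_threshold = 0.95) {
  if (!inherits(model, "probeset_model")) stop("model must be a probeset_model")
  stopifnot(is.data.frame(points))
  n <- nrow(points)
  out <- data.frame(call = rep("NN", n), confidence = rep(NA_real_, n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  ok <- stats::complete.cases(points[, c("contrast", "size")])
  if (!any(ok)) return(out)
  cl <- model$clusters
  ld <- sweep(.comp_logdens(points$contrast[ok], points$size[ok], cl),
              2L, log(cl$weight), "+")
  post <- exp(ld - .row_log_sum_exp(ld))
  best <- max.col(post, ties.method = "first")
  conf <- post[cbind(seq_len(nrow(post)), best)]
  lab <- cl$label[best]
  lab[lab == "OTV"] <- "OO"
  lab[conf < confidence_threshold] <- "NN"
  out$call[ok] <- lab
  out$confidence[ok] <- conf
  out
}

#' Detect an off-target-variant (null allele) cluster
#'
#' Looks for a subpopulation whose signal size lies well below the genotype
#' clusters: either a fitted component whose mean size is at least
#' `otv_size_gap` pooled size-SDs below the other components, or (fallback)
#' at least three points below the lowest genotype-cluster mean size minus
#' `otv_size_gap` pooled SDs whose median size sits at least twice that gap
#' below. On detection the genotype mixture is refit on the remaining
#' points, an OTV component is added from the members' moments, and members
#' are re-called `OO`. Without a detection, model and calls are returned
#' unchanged. If every point lies in the low-size cloud the probeset is
#' flagged degenerate and no split is made.
#'
#' @param model A fitted `probeset_model`.
#' @param points data.frame with `contrast` and `size`.
#' @param otv_size_gap Detection gap in pooled size-SD units (default 2).
#' @param confidence_threshold Passed to [call_genotypes()].
#' @return list with elements `model` and `calls`.
#' @export
detect_otv <- function(model, points, otv_size_gap = 2,
                       confidence_threshold = 0.95) {
  if (!inherits(model, "probeset_model")) stop("model must be a probeset_model")
  cl <- model$clusters[model$clusters$label != "OTV", , drop = FALSE]
  ok <- stats::complete.cases(points[, c("contrast", "size")])
  s <- points$size
  members <- rep(FALSE, nrow(points))
  fired <- FALSE

  ## component-level rule: only substantive components (>= 2 members) can
  ## define the size gap, and the null cloud must be a minority of them
  subst <- which(cl$mass >= 2)
  if (length(subst) >= 2L) {
    low <- subst[which.min(cl$mean_size[subst])]
    others <- cl[setdiff(subst, low), , drop = FALSE]
    pooled <- max(1e-3,
                  sqrt(sum(others$mass * others$var_size) / sum(others$mass)))
    ## the low component's centre must sit a confirmed 2x gap below the
    ## rest, and carry a minority of the mass, to count as a null cloud
    if (min(others$mean_size) - cl$mean_size[low] >=
          2 * otv_size_gap * pooled &&
        cl$mass[low] <= 0.5 * sum(cl$mass[subst])) {
      ld <- sweep(.comp_logdens(points$contrast[ok], points$size[ok], cl),
                  2L, log(cl$weight[seq_len(nrow(cl))] /
                            sum(cl$weight[seq_len(nrow(cl))])), "+")
      best <- max.col(exp(ld - .row_log_sum_exp(ld)), ties.method = "first")
      members[ok] <- best == low
      fired <- TRUE
    }
  }
  if (!fired) {
    ## robust fallback: a minority low-size cloud shows up against the
    ## median/MAD of the size distribution even when the mixture fit has
    ## absorbed it into an inflated genotype component
    s_ok <- s[ok]
    ctr <- stats::median(s_ok)
    scl <- max(stats::mad(s_ok), 0.05)
    cand <- ok & !is.na(s) & s < ctr - otv_size_gap * scl
    if (sum(cand) >= 3L && sum(cand) < sum(ok)) {
      ## confirm against the clean (non-candidate) points: their median and
      ## MAD are uncontaminated by the putative null cloud
      clean <- s[ok & !cand]
      ctr2 <- stats::median(clean)
      scl2 <- max(stats::mad(clean), 0.05)
      if (stats::median(s[cand]) < ctr2 - 2 * otv_size_gap * scl2) {
        members <- cand
        fired <- TRUE
      }
    }
  }
  if (!fired) {
    return(list(model = model,
                calls = call_genotypes(model, points, confidence_threshold)))
  }
  if (all(members[ok])) {
    model$degenerate <- TRUE
    return(list(model = model,
                calls = call_genotypes(model, points, confidence_threshold)))
  }

  rest <- points[ok & !members, , drop = FALSE]
  geno <- if (nrow(rest) >= 5L) {
    fit_genotype_clusters(rest, inbred_penalty = model$inbred_penalty)$clusters
  } else {
    cl
  }
  frac <- sum(members) / sum(ok)
  otv_row <- data.frame(
    label = "OTV", weight = frac,
    mean_contrast = mean(points$contrast[members]),
    mean_size = mean(points$size[members]),
    var_contrast = max(1e-8, stats::var(points$contrast[members]) *
                         (sum(members) - 1) / sum(members)),
    var_size = max(1e-8, stats::var(points$size[members]) *
                     (sum(members) - 1) / sum(members)),
    mass = sum(members))
  otv_row$var_contrast[is.na(otv_row$var_contrast)] <- 1e-8
  otv_row$var_size[is.na(otv_row$var_size)] <- 1e-8
  geno$weight <- geno$weight * (1 - frac)
  aug <- rbind(geno, otv_row)
  rownames(aug) <- NULL
  new_model <- structure(
    list(clusters = aug, inbred_penalty = model$inbred_penalty,
         converged = model$converged, log_likelihood = model$log_likelihood,
         objective_trace = model$objective_trace, n = model$n,
         degenerate = FALSE),
    class = "probeset_model")
  list(model = new_model,
       calls = call_genotypes(new_model, points, confidence_threshold))
}

#' Does a fitted model carry an off-target-variant component?
#' @param model A `probeset_model`.
#' @return Logical scalar.
#' @export
has_otv <- function(model) {
  inherits(model, "probeset_model") && "OTV" %in% model$clusters$label
}
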