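#' QC thresholds for probeset classification
#'
#' @param call_rate_min Minimum call rate before a probeset is set aside as
#'   CRBT (call rate below threshold); default 0.97, the usual Axiom
#'   convention.
#' @param hom_fld_min Minimum HomFLD for a polymorphic probeset to qualify
#'   as PHR; default 3.6.
#' @param min_minor_hom Minimum number of minor-homozygote calls separating
#'   PHR from NMH; default 2.
#' @param diploid_hom_ro_min,diploid_hom_fld_min HomRO and HomFLD cutoffs
#'   for the diploidization flag (defaults 0.3 and 10).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(call_rate_min = 0.97, hom_fld_min = 3.6,
                          min_minor_hom = 2, diploid_hom_ro_min = 0.3,
                          diploid_hom_fld_min = 10) {
  th <- list(call_rate_min = call_rate_min, hom_fld_min = hom_fld_min,
             min_minor_hom = min_minor_hom,
             diploid_hom_ro_min = diploid_hom_ro_min,
             diploid_hom_fld_min = diploid_hom_fld_min)
  if (any(unlist(th) < 0)) stop("all thresholds must be >= 0")
  class(th) <- "qc_thresholds"
  th
}

#' Homozygote ratio offset (HomRO)
#'
#' Signed contrast position of the homozygous cluster closest to zero, with
#' AA expected at positive and BB at negative contrast: both present gives
#' `min(c_AA, -c_BB)`; a lone AA gives `c_AA`; a lone BB gives `-c_BB`.
#' Positive values mean the observed homozygous clusters flank zero as a
#' diploid locus would; negative values flag both clusters on the same side
#' (the homoeologous-compression signature of polyploids).
#'
#' @param model A `probeset_model` (fitted or empirical, see
#'   [empirical_cluster_model()]).
#' @return Signed scalar, or `NA` when no homozygous component exists.
#' @export
hom_ro <- function(model) {
  cl <- model$clusters
  c_aa <- cl$mean_contrast[cl$label == "AA"]
  c_bb <- cl$mean_contrast[cl$label == "BB"]
  if (length(c_aa) && length(c_bb)) return(min(c_aa, -c_bb))
  if (length(c_aa)) return(c_aa)
  if (length(c_bb)) return(-c_bb)
  NA_real_
}

#' Homozygote Fisher's linear discriminant (HomFLD)
#'
#' Distance between the two homozygous cluster centres in contrast divided
#' by their membership-weighted pooled within-cluster standard deviation.
#' Large values indicate well-separated, tight homozygous clusters.
#'
#' @param model A `probeset_model`. Both homozygous components must carry at
#'   least two members each, otherwise `NA` is returned.
#' @return Non-negative scalar or `NA`.
#' @export
hom_fld <- function(model) {
  cl <- model$clusters
  aa <- cl[cl$label == "AA", , drop = FALSE]
  bb <- cl[cl$label == "BB", , drop = FALSE]
  if (nrow(aa) != 1L || nrow(bb) != 1L) return(NA_real_)
  if (aa$mass < 2 || bb$mass < 2) return(NA_real_)
  pooled <- sqrt((aa$mass * aa$var_contrast + bb$mass * bb$var_contrast) /
                   (aa$mass + bb$mass))
  if (pooled == 0) {
    if (aa$mean_contrast == bb$mean_contrast) return(0)
    return(Inf)
  }
  abs(aa$mean_contrast - bb$mean_contrast) / pooled
}

#' Build an empirical cluster model from calls and points
#'
#' Summarises each called genotype class by the mean, maximum-likelihood
#' variance and count of its member points. QC metrics are computed from
#' this call-based summary so they can be recomputed from raw calls and
#' points directly.
#'
#' @param points data.frame with `contrast` and `size`.
#' @param calls Character vector of calls (`AA`, `AB`, `BB`, `OO`, `NN`).
#' @return A `probeset_model` whose clusters are empirical summaries.
#' @export
empirical_cluster_model <- function(points, calls) {
  stopifnot(nrow(points) == length(calls))
  labs <- intersect(c("BB", "AB", "AA", "OO"), unique(calls))
  rows <- lapply(labs, function(g) {
    idx <- which(calls == g & stats::complete.cases(points))
    if (!length(idx)) return(NULL)
    mv <- function(x) c(mean(x), sum((x - mean(x))^2) / length(x))
    cc <- mv(points$contrast[idx]); ss <- mv(points$size[idx])
    data.frame(label = if (g == "OO") "OTV" else g, weight = length(idx),
               mean_contrast = cc[1], mean_size = ss[1],
               var_contrast = cc[2], var_size = ss[2], mass = length(idx))
  })
  cl <- do.call(rbind, rows)
  if (is.null(cl)) {
    cl <- data.frame(label = character(0), weight = numeric(0),
                     mean_contrast = numeric(0), mean_size = numeric(0),
                     var_contrast = numeric(0), var_size = numeric(0),
                     mass = numeric(0))
  } else {
    cl$weight <- cl$weight / sum(cl$weight)
  }
  structure(list(clusters = cl, inbred_penalty = NA_real_, converged = TRUE,
                 log_likelihood = NA_real_, objective_trace = numeric(0),
                 n = nrow(points), degenerate = FALSE),
            class = "probeset_model")
}

#' Per-probeset QC metrics
#'
#' Call rate, het rate and genotype counts from the calls; HomRO and HomFLD
#' from the empirical clusters of the called points.
#'
#' @param calls Character vector of calls.
#' @param points Optional data.frame of `contrast`/`size` matching `calls`;
#'   without it HomRO/HomFLD are `NA`.
#' @return One-row data.frame: `call_rate`, `het_rate`, `hom_ro`, `hom_fld`,
#'   `n_AA`, `n_AB`, `n_BB`, `n_OO`, `n_NN`.
#' @export
qc_metrics <- function(calls, points = NULL) {
  n <- length(calls)
  cnt <- function(g) sum(calls == g)
  n_nn <- cnt("NN")
  called <- n - n_nn
  hr <- NA_real_; hf <- NA_real_
  if (!is.null(points) && called > 0) {
    emp <- empirical_cluster_model(points, calls)
    hr <- hom_ro(emp)
    hf <- hom_fld(emp)
  }
  data.frame(call_rate = if (n > 0) 1 - n_nn / n else NA_real_,
             het_rate = if (called > 0) cnt("AB") / called else NA_real_,
             hom_ro = hr, hom_fld = hf,
             n_AA = cnt("AA"), n_AB = cnt("AB"), n_BB = cnt("BB"),
             n_OO = cnt("OO"), n_NN = n_nn)
}

#' Classify a probeset into the six-way category
#'
#' Decision cascade: call rate below threshold gives CRBT; an off-target
#' (null allele) component gives OTV; a single called genotype gives MHR
#' (monomorphic); a polymorphic probeset with both homozygous clusters, at
#' least `min_minor_hom` minor-homozygote calls and HomFLD at or above
#' `hom_fld_min` gives PHR; a polymorphic probeset missing the minor
#' homozygote (or with too few) gives NMH; anything else (for example a low
#' HomFLD) is Other. A probeset is `diploidized` when converted (PHR or
#' OTV) with HomRO above 0.3 and HomFLD above 10; undefined metrics (`NA`)
#' fail every threshold comparison.
#'
#' @param metrics One-row data.frame from [qc_metrics()].
#' @param model The `probeset_model` used for the calls (may be `NULL` when
#'   no model could be fitted).
#' @param thresholds A [qc_thresholds()] list.
#' @return One-row data.frame: `category`, `converted`, `diploidized`.
#' @export
classify_probeset <- function(metrics, model = NULL,
                              thresholds = qc_thresholds()) {
  th <- thresholds
  cat_ <- NULL
  otv_present <- (!is.null(model) && has_otv(model)) || metrics$n_OO > 0
  geno_present <- c(AA = metrics$n_AA, AB = metrics$n_AB, BB = metrics$n_BB) > 0
  n_geno <- sum(geno_present)
  if (is.na(metrics$call_rate) || metrics$call_rate < th$call_rate_min) {
    cat_ <- "CRBT"
  } else if (otv_present) {
    cat_ <- "OTV"
  } else if (n_geno <= 1L) {
    cat_ <- "MHR"
  } else {
    both_hom <- geno_present["AA"] && geno_present["BB"]
    minor <- if (both_hom) min(metrics$n_AA, metrics$n_BB) else 0L
    fld_ok <- !is.na(metrics$hom_fld) && metrics$hom_fld >= th$hom_fld_min
    if (both_hom && minor >= th$min_minor_hom && fld_ok) {
      cat_ <- "PHR"
    } else if (!both_hom || minor < th$min_minor_hom) {
      cat_ <- "NMH"
    } else {
      cat_ <- "Other"
    }
  }
  conv <- cat_ %in% c("PHR", "OTV")
  dip <- conv &&
    !is.na(metrics$hom_ro) && metrics$hom_ro > th$diploid_hom_ro_min &&
    !is.na(metrics$hom_fld) && metrics$hom_fld > th$diploid_hom_fld_min
  data.frame(category = cat_, converted = conv, diploidized = dip)
}

.CATEGORIES <- c("PHR", "OTV", "MHR", "NMH", "CRBT", "Other")

#' Conversion accounting from pre-tabulated category counts
#'
#' Computes converted counts (PHR + OTV), conversion rates and, when a
#' `Diploidized` row is present, the diploidized share of converted
#' probesets, from a table of per-category counts overall and by
#' genic/intergenic annotation.
#'
#' @param counts data.frame with columns `category`, `total`, `genic`,
#'   `intergenic`; rows for the six categories plus optionally
#'   `Diploidized`.
#' @return list with `counts`, `converted`, `conversion_rate` (fractions in
#'   each column) and, if available, `diploidized` and
#'   `diploidized_rate_of_converted`.
#' @export
summarize_category_counts <- function(counts) {
  stopifnot(all(c("category", "total") %in% names(counts)))
  cols <- intersect(c("total", "genic", "intergenic"), names(counts))
  cat_rows <- counts[counts$category %in% .CATEGORIES, , drop = FALSE]
  tot <- colSums(cat_rows[, cols, drop = FALSE])
  conv <- colSums(cat_rows[cat_rows$category %in% c("PHR", "OTV"),
                           cols, drop = FALSE])
  out <- list(counts = cat_rows, total = tot, converted = conv,
              conversion_rate = conv / tot)
  if ("Diploidized" %in% counts$category) {
    dip <- unlist(counts[counts$category == "Diploidized", cols])
    out$diploidized <- dip
    out$diploidized_rate_of_converted <- dip / conv
  }
  out
}

#' Category accounting across probesets
#'
#' Tabulates categories overall and by genic/intergenic annotation and
#' derives conversion and diploidization rates.
#'
#' @param categories Character vector of per-probeset categories.
#' @param annotations Character vector (`"genic"`/`"intergenic"`), one per
#'   probeset; an `NA` annotation is an error.
#' @param diploidized Optional logical vector of diploidized flags.
#' @return As [summarize_category_counts()], with the assembled counts
#'   table under `$counts`.
#' @export
qc_summary <- function(categories, annotations = NULL, diploidized = NULL) {
  if (is.null(annotations)) annotations <- rep("intergenic", length(categories))
  if (length(annotations) != length(categories)) {
    stop("annotations must match categories in length")
  }
  if (anyNA(annotations)) stop("annotation missing for a probeset")
  bad <- setdiff(unique(categories), .CATEGORIES)
  if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "))
  tab <- function(keep) {
    as.integer(table(factor(categories[keep], levels = .CATEGORIES)))
  }
  counts <- data.frame(category = .CATEGORIES,
                       total = tab(rep(TRUE, length(categories))),
                       genic = tab(annotations == "genic"),
                       intergenic = tab(annotations == "intergenic"))
  if (!is.null(diploidized)) {
    counts <- rbind(counts, data.frame(
      category = "Diploidized",
      total = sum(diploidized),
      genic = sum(diploidized & annotations == "genic"),
      intergenic = sum(diploidized & annotations == "intergenic")))
  }
  summarize_category_counts(counts)
}
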