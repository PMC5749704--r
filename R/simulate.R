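## child seeds derived from one master seed by fixed offsets, kept inside
## 32-bit integer range
.child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 1000003 * k) %% 2147483647L)
}

.check_prob <- function(x, nm) {
  if (any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop(nm, " must lie in [0, 1]")
  }
}

.ARRAY_CLASSES <- c("diploidized", "homoeologous", "monomorphic",
                    "null_allele", "low_quality")

## per-class cluster geometry: contrast centres for BB/AB/AA, spreads and
## the size offset of the null-allele cloud. Diploidized probesets have
## well-separated clusters flanking zero; homoeologous-offset probesets
## have both homozygous centres on the same side (HomRO < 0.3); null-allele
## carriers sit markedly lower in size; low-quality probesets overlap.
.default_geometry <- function() {
  list(
    diploidized = list(centers = c(BB = -1.2, AB = 0, AA = 1.2),
                       sd_contrast = 0.1, size = 11, sd_size = 0.3),
    homoeologous = list(centers = c(BB = 0.1, AB = 0.55, AA = 1.0),
                        sd_contrast = 0.08, size = 11, sd_size = 0.3),
    monomorphic = list(centers = c(AA = 1.2), sd_contrast = 0.1,
                       size = 11, sd_size = 0.3),
    null_allele = list(centers = c(BB = -1.2, AB = 0, AA = 1.2),
                       sd_contrast = 0.1, size = 11, sd_size = 0.3,
                       otv_size = 8, otv_contrast = 0, otv_sd_contrast = 0.3),
    low_quality = list(centers = c(BB = -0.35, AB = 0, AA = 0.35),
                       sd_contrast = 0.25, size = 11, sd_size = 0.3,
                       extra_missing = 0.05)
  )
}

#' Configuration for a synthetic array experiment
#'
#' Defines the probeset-class spectrum and cluster geometry of a simulated
#' two-channel SNP-array run on inbred polyploid material. The default
#' class mix mirrors the category spectrum observed on a real hexaploid
#' wheat array (roughly 59% polymorphic high-resolution split into
#' diploidized and homoeologous-compressed geometry, 9% null-allele, 17%
#' monomorphic, the rest low quality), and the default het rate the ~1.5%
#' residual heterozygosity of inbred lines. The default signal-level
#' missing rate of 0.5% reflects that the ~1% overall missing-call rate of
#' a good run combines absent signals with low-confidence calls.
#'
#' @param n_samples,n_probesets Positive counts.
#' @param category_mix Named proportions over
#'   `diploidized`, `homoeologous`, `monomorphic`, `null_allele`,
#'   `low_quality`; must sum to 1.
#' @param cluster_geometry Per-class geometry list; see
#'   `polyarray:::.default_geometry`.
#' @param otv_frequency Fraction of samples carrying the null allele at
#'   null-allele probesets.
#' @param missing_rate,het_rate Probabilities.
#' @param seed Master integer seed.
#' @return list of class `array_scenario`.
#' @export
array_scenario <- function(n_samples = 96, n_probesets = 1000,
                           category_mix = c(diploidized = 0.45,
                                            homoeologous = 0.14,
                                            monomorphic = 0.17,
                                            null_allele = 0.09,
                                            low_quality = 0.15),
                           cluster_geometry = .default_geometry(),
                           otv_frequency = 0.3, missing_rate = 0.005,
                           het_rate = 0.015, seed = 1L) {
  if (n_samples <= 0 || n_probesets <= 0) stop("counts must be positive")
  if (!setequal(names(category_mix), .ARRAY_CLASSES)) {
    stop("category_mix must be named over: ",
         paste(.ARRAY_CLASSES, collapse = ", "))
  }
  if (abs(sum(category_mix) - 1) > 1e-8) stop("category_mix must sum to 1")
  .check_prob(c(otv_frequency, missing_rate, het_rate),
              "otv_frequency/missing_rate/het_rate")
  for (g in cluster_geometry) {
    if (any(unlist(g[grep("^sd", names(g))]) <= 0)) stop("spreads must be > 0")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_probesets = as.integer(n_probesets),
                 category_mix = category_mix[.ARRAY_CLASSES],
                 cluster_geometry = cluster_geometry,
                 otv_frequency = otv_frequency, missing_rate = missing_rate,
                 het_rate = het_rate, seed = as.integer(seed)),
            class = "array_scenario")
}

#' Generate a synthetic two-channel signal table with known truth
#'
#' For each probeset a class is drawn from the configured mix, true
#' genotypes are assigned (allele frequency uniform on 0.2--0.8 for
#' polymorphic classes; hets at `het_rate`; null-allele carriers at
#' `otv_frequency`), true (contrast, size) coordinates are sampled from the
#' class geometry with Gaussian noise, and channel signals are obtained by
#' inverting the contrast/size transform so the forward transform
#' reproduces the sampled coordinates exactly. Missing signals are
#' missing-completely-at-random.
#'
#' @param config An [array_scenario()].
#' @return list with `signal` (long data.frame `probeset_id`, `sample_id`,
#'   `signal_a`, `signal_b`) and `truth` (list: `genotypes` samples x
#'   probesets matrix, `classes`, `points` with the sampled true
#'   contrast/size per call, `cluster_params`, `config`).
#' @export
generate_array_experiment <- function(config) {
  stopifnot(inherits(config, "array_scenario"))
  set.seed(.child_seed(config$seed, 1L))
  ns <- config$n_samples
  np <- config$n_probesets
  samples <- sprintf("S%03d", seq_len(ns))
  probesets <- sprintf("AX%05d", seq_len(np))
  classes <- sample(.ARRAY_CLASSES, np, replace = TRUE,
                    prob = config$category_mix)

  geno <- matrix(NA_character_, ns, np, dimnames = list(samples, probesets))
  tc <- matrix(NA_real_, ns, np)
  ts <- matrix(NA_real_, ns, np)
  params <- vector("list", np)

  for (i in seq_len(np)) {
    g <- config$cluster_geometry[[classes[i]]]
    centers <- g$centers
    if (classes[i] == "monomorphic") {
      gt <- rep(names(centers)[1], ns)
    } else {
      p <- stats::runif(1, 0.2, 0.8)
      gt <- ifelse(stats::runif(ns) < config$het_rate, "AB",
                   ifelse(stats::runif(ns) < p, "AA", "BB"))
    }
    if (classes[i] == "null_allele") {
      gt[stats::runif(ns) < config$otv_frequency] <- "OO"
    }
    cc <- ifelse(gt == "OO", g$otv_contrast, centers[gt]) +
      stats::rnorm(ns, 0, ifelse(gt == "OO", g$otv_sd_contrast %||% g$sd_contrast,
                                 g$sd_contrast))
    ss <- ifelse(gt == "OO", g$otv_size, g$size) +
      stats::rnorm(ns, 0, g$sd_size)
    ## channel intensities cannot be negative: clamp sampled coordinates
    ## to the invertible region (affects only extreme low-size tails)
    ss <- pmax(ss, log2(100) + abs(cc) / 2 + 1e-6)
    geno[, i] <- gt
    tc[, i] <- cc
    ts[, i] <- ss
    params[[i]] <- data.frame(probeset_id = probesets[i], class = classes[i],
                              cluster = names(centers),
                              center_contrast = unname(centers),
                              sd_contrast = g$sd_contrast,
                              center_size = g$size, sd_size = g$sd_size)
  }

  miss_p <- matrix(config$missing_rate, ns, np)
  extra <- vapply(classes, function(cl) {
    config$cluster_geometry[[cl]]$extra_missing %||% 0
  }, numeric(1))
  miss_p <- sweep(miss_p, 2L, extra, "+")
  miss <- matrix(stats::runif(ns * np) < miss_p, ns, np)

  sig <- contrast_size_to_signals(as.vector(tc), as.vector(ts))
  signal <- data.frame(
    probeset_id = rep(probesets, each = ns),
    sample_id = rep(samples, np),
    signal_a = ifelse(as.vector(miss), NA_real_, sig$signal_a),
    signal_b = ifelse(as.vector(miss), NA_real_, sig$signal_b))

  points <- data.frame(probeset_id = rep(probesets, each = ns),
                       sample_id = rep(samples, np),
                       true_contrast = as.vector(tc),
                       true_size = as.vector(ts),
                       missing = as.vector(miss))
  truth <- list(genotypes = geno,
                classes = data.frame(probeset_id = probesets, class = classes),
                points = points,
                cluster_params = do.call(rbind, params),
                config = config)
  structure(list(signal = signal, truth = truth), class = "array_experiment")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Configuration for a structured diversity panel
#'
#' @param n_groups Number of geographic groups.
#' @param samples_per_group Integer vector (recycled over groups).
#' @param n_loci Number of biallelic loci.
#' @param fst Divergence parameter in (0, 1); group allele frequencies are
#'   Balding--Nichols Beta draws around the ancestral frequency with
#'   variance `fst * p * (1 - p)`.
#' @param ancestral_freq_range Interval inside (0, 1) for ancestral
#'   frequencies.
#' @param missing_rate Probability of a missing call.
#' @param seed Master integer seed.
#' @return list of class `panel_scenario`.
#' @export
panel_scenario <- function(n_groups = 5, samples_per_group = 20,
                           n_loci = 500, fst = 0.3,
                           ancestral_freq_range = c(0.1, 0.9),
                           missing_rate = 0.01, seed = 1L) {
  if (fst <= 0 || fst >= 1) stop("fst must lie strictly in (0, 1)")
  if (any(samples_per_group <= 0) || n_groups <= 0 || n_loci <= 0) {
    stop("counts must be positive")
  }
  .check_prob(missing_rate, "missing_rate")
  structure(list(n_groups = as.integer(n_groups),
                 samples_per_group = rep_len(as.integer(samples_per_group),
                                             n_groups),
                 n_loci = as.integer(n_loci), fst = fst,
                 ancestral_freq_range = ancestral_freq_range,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "panel_scenario")
}

#' Generate an inbred diversity panel with group structure
#'
#' @param config A [panel_scenario()].
#' @return list with `genotypes` (samples x loci character matrix in
#'   `AA/BB/NN`) and `truth` (group labels, ancestral and per-group allele
#'   frequencies, config).
#' @export
generate_population_panel <- function(config) {
  stopifnot(inherits(config, "panel_scenario"))
  set.seed(.child_seed(config$seed, 2L))
  ng <- config$n_groups
  nl <- config$n_loci
  p_anc <- stats::runif(nl, config$ancestral_freq_range[1],
                        config$ancestral_freq_range[2])
  f <- config$fst
  shape_scale <- (1 - f) / f
  pg <- matrix(stats::rbeta(ng * nl,
                            rep(p_anc, each = ng) * shape_scale,
                            rep(1 - p_anc, each = ng) * shape_scale),
               ng, nl)
  groups <- rep(seq_len(ng), config$samples_per_group)
  n <- length(groups)
  samples <- sprintf("G%d_S%03d", groups,
                     unlist(lapply(config$samples_per_group, seq_len)))
  gmat <- matrix(ifelse(stats::runif(n * nl) <
                          pg[cbind(rep(groups, nl),
                                   rep(seq_len(nl), each = n))],
                        "AA", "BB"),
                 n, nl,
                 dimnames = list(samples, sprintf("L%05d", seq_len(nl))))
  gmat[matrix(stats::runif(n * nl) < config$missing_rate, n, nl)] <- "NN"
  truth <- list(groups = data.frame(sample_id = samples,
                                    group = paste0("G", groups)),
                ancestral_freq = p_anc, group_freq = pg, config = config)
  structure(list(genotypes = gmat, truth = truth), class = "panel_experiment")
}

#' Inverse genetic mapping function
#'
#' Converts a map distance in cM to the expected recombination fraction
#' under the Kosambi (`r = tanh(2d)/2`, d in Morgans) or Haldane
#' (`r = (1 - exp(-2d))/2`) mapping function.
#'
#' @param d_cM Non-negative distance(s) in centimorgans.
#' @param mapping_function `"kosambi"` or `"haldane"`.
#' @return Recombination fraction(s) in [0, 0.5).
#' @export
inverse_mapping_function <- function(d_cM, mapping_function = c("kosambi",
                                                                "haldane")) {
  mapping_function <- match.arg(mapping_function)
  d <- d_cM / 100
  if (mapping_function == "kosambi") tanh(2 * d) / 2 else (1 - exp(-2 * d)) / 2
}

#' Configuration for a single-seed-descent RIL population
#'
#' @param n_individuals Population size (default 430).
#' @param n_chromosomes Number of chromosomes.
#' @param markers_per_chromosome Integer vector (recycled).
#' @param chromosome_length_cM Numeric vector (recycled).
#' @param generation F-generation (default 6; residual per-locus
#'   heterozygosity is `(1/2)^(generation - 1)`).
#' @param distortion_loci Optional data.frame `chromosome`, `position`,
#'   `bias` (transmission probability of the parent-1 allele, in (0,1)).
#' @param missing_rate Probability of a missing progeny call.
#' @param mapping_function `"kosambi"` (default) or `"haldane"`.
#' @param seed Master integer seed.
#' @return list of class `ril_scenario`.
#' @export
ril_scenario <- function(n_individuals = 430, n_chromosomes = 3,
                         markers_per_chromosome = 100,
                         chromosome_length_cM = 150, generation = 6,
                         distortion_loci = NULL, missing_rate = 0.01,
                         mapping_function = c("kosambi", "haldane"),
                         seed = 1L) {
  mapping_function <- match.arg(mapping_function)
  if (generation < 2) stop("generation must be >= 2")
  if (n_individuals <= 0 || n_chromosomes <= 0) stop("counts must be positive")
  .check_prob(missing_rate, "missing_rate")
  mpc <- rep_len(as.integer(markers_per_chromosome), n_chromosomes)
  len <- rep_len(as.numeric(chromosome_length_cM), n_chromosomes)
  if (!is.null(distortion_loci)) {
    stopifnot(all(c("chromosome", "position", "bias") %in%
                    names(distortion_loci)))
    if (any(distortion_loci$bias <= 0 | distortion_loci$bias >= 1)) {
      stop("distortion bias must lie strictly in (0, 1)")
    }
    if (any(distortion_loci$chromosome > n_chromosomes) ||
        any(distortion_loci$position < 0) ||
        any(distortion_loci$position >
              len[distortion_loci$chromosome])) {
      stop("distortion positions must lie within their chromosome")
    }
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 n_chromosomes = as.integer(n_chromosomes),
                 markers_per_chromosome = mpc,
                 chromosome_length_cM = len,
                 generation = as.integer(generation),
                 distortion_loci = distortion_loci,
                 missing_rate = missing_rate,
                 mapping_function = mapping_function,
                 seed = as.integer(seed)),
            class = "ril_scenario")
}

#' Generate an F-generation single-seed-descent RIL population
#'
#' Parents are fixed opposite homozygotes (`P1` all AA, `P2` all BB).
#' Per individual and chromosome the inherited (consensus) allele follows a
#' Markov chain along the marker order whose adjacent-marker switch
#' probability equals the inverse mapping function of the cM gap; residual
#' heterozygosity is overlaid as a second Markov mask with stationary rate
#' `(1/2)^(generation - 1)` whose re-draw probability also vanishes at zero
#' distance, so fully linked markers give identical genotype columns.
#' Distortion loci resample the consensus allele with the configured
#' transmission bias. Missingness is missing-completely-at-random and only
#' affects progeny.
#'
#' @param config A [ril_scenario()].
#' @return list with `genotypes` ((2 + n) x markers character matrix, rows
#'   `P1`, `P2`, then individuals) and `truth` (the true `map` data.frame
#'   `marker`, `chromosome`, `position_cM`, expected het rate, config).
#' @export
generate_ril_f6 <- function(config) {
  stopifnot(inherits(config, "ril_scenario"))
  set.seed(.child_seed(config$seed, 3L))
  n <- config$n_individuals
  h <- (1 / 2)^(config$generation - 1)
  maps <- list()
  blocks <- list()
  for (ch in seq_len(config$n_chromosomes)) {
    m <- config$markers_per_chromosome[ch]
    len <- config$chromosome_length_cM[ch]
    pos <- round(sort(stats::runif(m, 0, len)), 1)
    gaps <- diff(pos)
    r <- inverse_mapping_function(gaps, config$mapping_function)
    cons <- matrix(0L, n, m)          # 0 = parent-1 (A) allele, 1 = parent-2
    het <- matrix(FALSE, n, m)
    cons[, 1] <- stats::rbinom(n, 1, 0.5)
    het[, 1] <- stats::runif(n) < h
    if (m > 1) {
      for (k in 2:m) {
        sw <- stats::runif(n) < r[k - 1]
        cons[, k] <- ifelse(sw, 1L - cons[, k - 1], cons[, k - 1])
        ## residual-het tract boundaries accumulate over the g-1 meioses
        redraw <- stats::runif(n) <
          pmin(1, 2 * (config$generation - 1) * r[k - 1])
        het[, k] <- ifelse(redraw, stats::runif(n) < h, het[, k - 1])
      }
    }
    if (!is.null(config$distortion_loci)) {
      dl <- config$distortion_loci[config$distortion_loci$chromosome == ch, ,
                                   drop = FALSE]
      for (j in seq_len(nrow(dl))) {
        k <- which.min(abs(pos - dl$position[j]))
        cons[, k] <- stats::rbinom(n, 1, 1 - dl$bias[j])
      }
    }
    g <- matrix(ifelse(het, "AB", ifelse(cons == 0L, "AA", "BB")), n, m)
    blocks[[ch]] <- g
    maps[[ch]] <- data.frame(marker = sprintf("chr%d_m%04d", ch, seq_len(m)),
                             chromosome = paste0("chr", ch),
                             position_cM = pos)
  }
  map <- do.call(rbind, maps)
  prog <- do.call(cbind, blocks)
  prog[matrix(stats::runif(length(prog)) < config$missing_rate,
              nrow(prog), ncol(prog))] <- "NN"
  gmat <- rbind(matrix("AA", 1, nrow(map)), matrix("BB", 1, nrow(map)), prog)
  dimnames(gmat) <- list(c("P1", "P2", sprintf("RIL%04d", seq_len(n))),
                         map$marker)
  truth <- list(map = map, expected_het_rate = h, config = config)
  structure(list(genotypes = gmat, truth = truth), class = "ril_experiment")
}

.TS_PAIRS <- list(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))
.TV_PAIRS <- list(c("A", "C"), c("C", "A"), c("A", "T"), c("T", "A"),
                  c("G", "C"), c("C", "G"), c("G", "T"), c("T", "G"))

.FRACTIONS <- c("ISBP-derived", "intergenic", "exonic", "intronic")

#' Generate synthetic resequencing variant records
#'
#' Emits VCF-style single-nucleotide variant records across a set of inbred
#' lines, realizing a requested mix of the four locus classes (1: only
#' homozygous AA and BB; 2: AA, BB and AB; 3: only AA and AB; 4: AB in all
#' lines), a target transition fraction of `tstv_target/(1+tstv_target)`,
#' and per-record depth and RMS mapping quality drawn from the supplied
#' distributions.
#'
#' @param n_loci,n_lines Counts; class 1 needs at least 2 lines, class 2 at
#'   least 3.
#' @param class_mix Numeric length-4 proportions over classes 1--4 (must
#'   sum to 1).
#' @param tstv_target Target transition/transversion ratio.
#' @param depth_distribution,mq_distribution Either a single number
#'   (constant) or a `function(n)` returning n draws.
#' @param seed Integer seed.
#' @param chromosomes Chromosome name pool (default the 21 hexaploid wheat
#'   chromosomes 1A--7D).
#' @param fraction_mix Named proportions over the genomic fractions
#'   `ISBP-derived`, `intergenic`, `exonic`, `intronic`.
#' @param multi_hit_rate Fraction of records whose context sequence has
#'   more than one genomic hit (`hit_count` 2).
#' @return list with `records` (data.frame: `chrom`, `pos`, `id`, `ref`,
#'   `alt`, `depth`, `rms_mq`, `fraction`, `hit_count`, `genome`, plus one
#'   genotype column per line) and `truth` (`class` per record, config
#'   echo).
#' @export
generate_variant_records <- function(n_loci, n_lines = 8,
                                     class_mix = c(0.55, 0.25, 0.15, 0.05),
                                     tstv_target = 2.12,
                                     depth_distribution = function(n)
                                       stats::rpois(n, 20),
                                     mq_distribution = function(n)
                                       pmin(60, round(stats::rnorm(n, 45, 8))),
                                     seed = 1L,
                                     chromosomes = paste0(rep(1:7, each = 3),
                                                          c("A", "B", "D")),
                                     fraction_mix = c(`ISBP-derived` = 0.29,
                                                      intergenic = 0.635,
                                                      exonic = 0.03,
                                                      intronic = 0.045),
                                     multi_hit_rate = 0.05) {
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  if (length(class_mix) != 4L) stop("class_mix must cover classes 1-4")
  if (n_lines < 2 && any(class_mix[c(1, 2, 4)] > 0)) {
    stop("classes need at least 2 lines")
  }
  if (n_lines < 3 && class_mix[2] > 0) stop("class 2 needs at least 3 lines")
  set.seed(.child_seed(seed, 4L))
  draw <- function(d, n) if (is.function(d)) d(n) else rep(d, n)
  cls <- sample(1:4, n_loci, replace = TRUE, prob = class_mix)
  lines <- sprintf("Line%02d", seq_len(n_lines))

  gt <- matrix(NA_character_, n_loci, n_lines, dimnames = list(NULL, lines))
  for (i in seq_len(n_loci)) {
    g <- switch(cls[i],
      c("AA", "BB", sample(c("AA", "BB"), n_lines - 2, TRUE)),
      c("AA", "BB", "AB",
        sample(c("AA", "AB", "BB"), n_lines - 3, TRUE, prob = c(.4, .2, .4))),
      c("AA", "AB", sample(c("AA", "AB"), n_lines - 2, TRUE)),
      rep("AB", n_lines))
    gt[i, ] <- sample(g)
  }

  is_ts <- stats::runif(n_loci) < tstv_target / (1 + tstv_target)
  pair_idx <- ifelse(is_ts, sample.int(4, n_loci, TRUE),
                     sample.int(8, n_loci, TRUE))
  alleles <- t(vapply(seq_len(n_loci), function(i) {
    if (is_ts[i]) unlist(.TS_PAIRS[pair_idx[i]]) else
      unlist(.TV_PAIRS[pair_idx[i]])
  }, character(2)))

  chrom <- sample(chromosomes, n_loci, replace = TRUE)
  pos <- integer(n_loci)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    pos[idx] <- sort(sample.int(1e8, length(idx)))
  }
  records <- data.frame(
    chrom = chrom, pos = pos,
    id = sprintf("SNP%06d", seq_len(n_loci)),
    ref = alleles[, 1], alt = alleles[, 2],
    depth = as.integer(draw(depth_distribution, n_loci)),
    rms_mq = as.numeric(draw(mq_distribution, n_loci)),
    fraction = sample(names(fraction_mix), n_loci, replace = TRUE,
                      prob = fraction_mix),
    hit_count = ifelse(stats::runif(n_loci) < multi_hit_rate, 2L, 1L),
    genome = sub("^[0-9]+", "", chrom),
    stringsAsFactors = FALSE)
  records <- cbind(records, as.data.frame(gt, stringsAsFactors = FALSE))
  records <- records[order(records$chrom, records$pos), ]
  rownames(records) <- NULL
  truth <- data.frame(id = records$id,
                      class = cls[match(records$id,
                                        sprintf("SNP%06d", seq_len(n_loci)))])
  list(records = records, truth = truth,
       line_names = lines)
}

#' Check dimensional consistency of a generator's truth bundle
#'
#' @param x The list returned by one of the generators.
#' @return `TRUE` invisibly; errors if the truth bundle does not match the
#'   emitted data.
#' @export
validate_truth_bundle <- function(x) {
  if (inherits(x, "array_experiment")) {
    stopifnot(
      nrow(x$signal) == length(x$truth$genotypes),
      nrow(x$truth$points) == length(x$truth$genotypes),
      ncol(x$truth$genotypes) == nrow(x$truth$classes),
      identical(colnames(x$truth$genotypes), x$truth$classes$probeset_id))
  } else if (inherits(x, "panel_experiment")) {
    stopifnot(
      nrow(x$genotypes) == nrow(x$truth$groups),
      ncol(x$genotypes) == length(x$truth$ancestral_freq),
      identical(rownames(x$genotypes), x$truth$groups$sample_id))
  } else if (inherits(x, "ril_experiment")) {
    stopifnot(
      ncol(x$genotypes) == nrow(x$truth$map),
      identical(colnames(x$genotypes), x$truth$map$marker),
      nrow(x$genotypes) == x$truth$config$n_individuals + 2L)
  } else {
    stop("not a recognised generator output")
  }
  invisible(TRUE)
}
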