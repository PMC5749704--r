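.STAGES <- c("simulate", "call", "qc", "diversity", "mapprep", "discover",
             "all")

.CONFIG_KEYS <- list(
  top = c("seed", "simulate", "call", "qc", "diversity", "mapprep",
          "discover"),
  simulate = c("array", "panel", "ril", "variants"),
  call = c("penalty_step1", "penalty_step2", "confidence_threshold",
           "otv_size_gap", "call_rate_min", "hom_fld_min", "min_minor_hom"),
  qc = character(0),
  diversity = c("oo"),
  mapprep = c("max_missing", "distortion_p"),
  discover = c("min_depth", "min_rms_mq"))

#' Build and validate a pipeline run configuration
#'
#' Merges user settings over the documented defaults; unknown keys are
#' rejected.
#'
#' @param config Named list (for example from [yaml::read_yaml()]) or
#'   `NULL` for all defaults.
#' @param seed Master seed overriding `config$seed`.
#' @return Validated configuration list of class `run_config`.
#' @export
run_config <- function(config = NULL, seed = NULL) {
  config <- config %||% list()
  bad <- setdiff(names(config), .CONFIG_KEYS$top)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (sec in setdiff(.CONFIG_KEYS$top, "seed")) {
    extra <- setdiff(names(config[[sec]]), .CONFIG_KEYS[[sec]])
    if (sec %in% c("simulate") && length(extra)) {
      stop("unknown config key(s) in ", sec, ": ",
           paste(extra, collapse = ", "))
    }
    if (!sec %in% c("simulate") && length(extra)) {
      stop("unknown config key(s) in ", sec, ": ",
           paste(extra, collapse = ", "))
    }
  }
  defaults <- list(
    seed = 1L,
    simulate = list(array = list(), panel = list(), ril = list(),
                    variants = list(n_loci = 2000)),
    call = list(penalty_step1 = 4, penalty_step2 = 16,
                confidence_threshold = 0.95, otv_size_gap = 2,
                call_rate_min = 0.97, hom_fld_min = 3.6, min_minor_hom = 2),
    qc = list(),
    diversity = list(oo = "state"),
    mapprep = list(max_missing = 0.15, distortion_p = 0.01),
    discover = list(min_depth = 5, min_rms_mq = 30))
  out <- utils::modifyList(defaults, config)
  if (!is.null(seed)) out$seed <- as.integer(seed)
  structure(out, class = "run_config")
}

.manifest <- function(stage, config, inputs, counts, t0) {
  files <- inputs[file.exists(inputs)]
  list(tool = "polyarray",
       version = as.character(utils::packageVersion("polyarray")),
       stage = stage,
       config = unclass(config),
       input_checksums = as.list(tools::md5sum(files)),
       counts = counts,
       started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
       finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

.write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest,
                       file.path(out_dir,
                                 paste0("manifest_", manifest$stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

.log_stage <- function(verbose, ...) if (verbose) message("[polyarray] ", ...)

#' Run a pipeline stage
#'
#' Stages: `simulate` writes synthetic inputs (signal table, truth
#' sidecars, diversity panel, RIL population, variant VCF); `call` runs
#' two-step genotyping plus QC classification over the signal table; `qc`
#' summarises the QC report; `diversity` computes PIC, simple-matching
#' distances, Ward/NJ trees and the OTV presence/absence matrix from the
#' calls; `mapprep` filters RIL markers, bins cosegregating markers and
#' summarises the map; `discover` applies the variant filters,
#' classification and accounting; `all` chains every stage. Artifacts are
#' plain-text TSV/VCF/Newick files under `out_dir`, and every stage writes
#' a JSON run manifest with configuration, input checksums and record
#' counts.
#'
#' @param stage One of `simulate`, `call`, `qc`, `diversity`, `mapprep`,
#'   `discover`, `all`.
#' @param config A [run_config()] (or plain list passed through it).
#' @param out_dir Output directory (created if needed); also where earlier
#'   stages' artifacts are looked up.
#' @param verbose Log stage boundaries and record counts.
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(stage = .STAGES, config = run_config(),
                         out_dir = ".", verbose = TRUE) {
  stage <- match.arg(stage)
  if (!inherits(config, "run_config")) config <- run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (stage == "all") {
    for (s in setdiff(.STAGES, "all")) {
      man <- run_pipeline(s, config, out_dir, verbose)
    }
    return(invisible(man))
  }
  t0 <- Sys.time()
  .log_stage(verbose, "stage ", stage, " started")
  p <- function(f) file.path(out_dir, f)
  counts <- list()
  inputs <- character(0)

  if (stage == "simulate") {
    arr <- generate_array_experiment(
      do.call(array_scenario, utils::modifyList(
        list(seed = config$seed), config$simulate$array)))
    validate_truth_bundle(arr)
    write_signal_table(arr$signal, p("signal_table.tsv"))
    write_genotype_matrix(arr$truth$genotypes, p("truth_genotypes.tsv"))
    .write_tsv(arr$truth$classes, p("truth_classes.tsv"))
    pan <- generate_population_panel(
      do.call(panel_scenario, utils::modifyList(
        list(seed = config$seed), config$simulate$panel)))
    validate_truth_bundle(pan)
    write_genotype_matrix(pan$genotypes, p("panel_genotypes.tsv"))
    .write_tsv(pan$truth$groups, p("panel_groups.tsv"))
    ril <- generate_ril_f6(
      do.call(ril_scenario, utils::modifyList(
        list(seed = config$seed), config$simulate$ril)))
    validate_truth_bundle(ril)
    write_genotype_matrix(ril$genotypes, p("ril_genotypes.tsv"))
    write_genetic_map(ril$truth$map, p("ril_map.tsv"))
    vr <- do.call(generate_variant_records, utils::modifyList(
      list(seed = config$seed), config$simulate$variants))
    write_variant_vcf(vr$records, p("variants.vcf"))
    .write_tsv(vr$records[, c("id", "chrom", "fraction", "hit_count",
                              "genome")], p("variant_annotations.tsv"))
    .write_tsv(vr$truth, p("variant_truth.tsv"))
    counts <- list(probesets = ncol(arr$truth$genotypes),
                   samples = nrow(arr$truth$genotypes),
                   panel_samples = nrow(pan$genotypes),
                   ril_individuals = nrow(ril$genotypes) - 2L,
                   ril_markers = ncol(ril$genotypes),
                   variant_records = nrow(vr$records))
  } else if (stage == "call") {
    inputs <- p("signal_table.tsv")
    st <- read_signal_table(inputs)
    th <- qc_thresholds(call_rate_min = config$call$call_rate_min,
                        hom_fld_min = config$call$hom_fld_min,
                        min_minor_hom = config$call$min_minor_hom)
    res <- two_step_genotyping(
      st, penalty_step1 = config$call$penalty_step1,
      penalty_step2 = config$call$penalty_step2, thresholds = th,
      otv_size_gap = config$call$otv_size_gap,
      confidence_threshold = config$call$confidence_threshold)
    write_genotype_matrix(res$calls, p("calls.tsv"))
    .write_tsv(res$qc, p("qc_report.tsv"))
    .write_tsv(res$step_log, p("step_log.tsv"))
    counts <- list(probesets = nrow(res$qc),
                   reprocessed = sum(res$step_log$reprocessed),
                   categories = as.list(table(res$qc$category)))
  } else if (stage == "qc") {
    inputs <- p("qc_report.tsv")
    qc <- .read_tsv(inputs)
    smry <- qc_summary(qc$category, diploidized = qc$diploidized)
    .write_tsv(smry$counts, p("qc_summary.tsv"))
    counts <- list(probesets = nrow(qc),
                   converted = unname(smry$converted["total"]),
                   conversion_rate = unname(smry$conversion_rate["total"]))
  } else if (stage == "diversity") {
    inputs <- c(p("calls.tsv"), p("qc_report.tsv"))
    calls <- read_genotype_matrix(inputs[1])
    qc <- .read_tsv(inputs[2])
    conv <- qc$probeset_id[qc$converted]
    sub <- calls[, colnames(calls) %in% conv, drop = FALSE]
    pics <- pic_by_locus(sub)
    .write_tsv(data.frame(probeset_id = colnames(sub), pic = pics),
               p("pic.tsv"))
    d <- simple_matching_distance(sub, oo = config$diversity$oo)
    .write_tsv(data.frame(sample_id = rownames(d$d), d$d,
                          check.names = FALSE), p("distance_matrix.tsv"))
    write_tree_newick(ward_cluster(d), p("ward.nwk"))
    write_tree_newick(nj_tree(d), p("nj.nwk"))
    cats <- qc$category[match(colnames(calls), qc$probeset_id)]
    pav <- suppressWarnings(otv_pav_matrix(calls, cats))
    if (ncol(pav)) {
      .write_tsv(data.frame(sample_id = rownames(pav), pav,
                            check.names = FALSE), p("pav_matrix.tsv"))
    }
    counts <- list(loci = ncol(sub), mean_pic = mean(pics, na.rm = TRUE),
                   pav_loci = ncol(pav))
  } else if (stage == "mapprep") {
    inputs <- c(p("ril_genotypes.tsv"), p("ril_map.tsv"))
    g <- read_genotype_matrix(inputs[1])
    map <- read_genetic_map(inputs[2])
    cats <- rep("PHR", ncol(g))
    dip <- rep(TRUE, ncol(g))
    rep_f <- filter_mapping_markers(g, cats, dip,
                                    max_missing = config$mapprep$max_missing,
                                    distortion_p = config$mapprep$distortion_p)
    .write_tsv(rep_f, p("marker_filter_report.tsv"))
    keep <- rep_f$marker[rep_f$kept]
    prog <- g[!(rownames(g) %in% c("P1", "P2")), keep, drop = FALSE]
    bins <- cosegregation_bins(prog)
    .write_tsv(bins, p("cosegregation_bins.tsv"))
    smry <- map_summary(map[map$marker %in% keep, ], bins)
    .write_tsv(smry, p("map_summary.tsv"))
    counts <- list(markers = ncol(g), kept = length(keep),
                   bins = length(unique(bins$bin)))
  } else if (stage == "discover") {
    inputs <- c(p("variants.vcf"), p("variant_annotations.tsv"))
    rec <- read_variant_vcf(inputs[1])
    ann <- .read_tsv(inputs[2])
    rec <- merge(rec, ann, by = c("id", "chrom"), sort = FALSE)
    flt <- filter_variants(rec, min_depth = config$discover$min_depth,
                           min_rms_mq = config$discover$min_rms_mq)
    kept <- classify_variants(flt$kept)
    write_variant_vcf(kept[, setdiff(names(kept),
                                     c("fraction", "hit_count", "genome",
                                       "class", "usable"))],
                      p("variants_kept.vcf"))
    .write_tsv(flt$dropped[, c("id", "chrom", "drop_reason")],
               p("variants_dropped.tsv"))
    tt <- ts_tv(kept)
    smry <- summarize_snps(kept)
    .write_tsv(smry, p("snp_summary.tsv"))
    counts <- list(input = nrow(rec), kept = nrow(kept),
                   dropped = nrow(flt$dropped), ts = tt$ts, tv = tt$tv,
                   tstv_ratio = tt$ratio)
  }
  man <- .manifest(stage, config, inputs, counts, t0)
  .write_manifest(man, out_dir)
  .log_stage(verbose, "stage ", stage, " finished: ",
             paste(names(counts)[1], counts[[1]], collapse = " "))
  invisible(man)
}
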