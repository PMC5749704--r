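make_records <- function(gt_rows, depth = 20, mq = 45, hit = 1,
                         chrom = "1A", ref = "A", alt = "G") {
  n <- length(gt_rows)
  gt <- do.call(rbind, gt_rows)
  colnames(gt) <- sprintf("Line%02d", seq_len(ncol(gt)))
  cbind(data.frame(chrom = rep_len(chrom, n), pos = seq_len(n) * 100,
                   id = sprintf("S%03d", seq_len(n)),
                   ref = rep_len(ref, n), alt = rep_len(alt, n),
                   depth = rep_len(depth, n), rms_mq = rep_len(mq, n),
                   fraction = "intergenic", hit_count = rep_len(hit, n),
                   genome = sub("^[0-9]+", "", rep_len(chrom, n)),
                   stringsAsFactors = FALSE),
        as.data.frame(gt, stringsAsFactors = FALSE))
}

test_that("depth/MQ filter keeps boundary values and labels drops", {
  rec <- make_records(list(c("AA", "BB")), depth = 5, mq = 30)
  expect_equal(nrow(filter_variants(rec)$kept), 1L)
  low_d <- make_records(list(c("AA", "BB")), depth = 4, mq = 60)
  out <- filter_variants(low_d)
  expect_equal(nrow(out$kept), 0L)
  expect_identical(out$dropped$drop_reason, "depth")
  low_m <- make_records(list(c("AA", "BB")), depth = 100, mq = 29)
  expect_identical(filter_variants(low_m)$dropped$drop_reason, "mq")
  both <- make_records(list(c("AA", "BB")), depth = 1, mq = 1)
  expect_identical(filter_variants(both)$dropped$drop_reason, "depth,mq")
})

test_that("locus classification follows the four-class taxonomy", {
  expect_identical(classify_locus(c("AA", "BB", "AA", "BB"))$class, "CLASS1")
  expect_true(classify_locus(c("AA", "BB", "AA", "BB"))$usable)
  expect_identical(classify_locus(c("AA", "AB", "BB"))$class, "CLASS2")
  expect_identical(classify_locus(c("AA", "AB", "AA"))$class, "CLASS3")
  expect_false(classify_locus(c("AA", "AB", "AA"))$usable)
  expect_identical(classify_locus(c("AB", "AB", "AB"))$class, "CLASS4")
  # missing genotypes are ignored when forming the observed set
  expect_identical(classify_locus(c("AA", "BB", "NN"))$class, "CLASS1")
  # one-sided definition applied symmetrically unless strict
  expect_identical(classify_locus(c("BB", "AB"))$class, "CLASS3")
  expect_identical(classify_locus(c("BB", "AB"), strict = TRUE)$class,
                   "UNCLASSIFIED")
  expect_identical(classify_locus(c("AA", "AA"))$class, "UNCLASSIFIED")
  expect_error(classify_locus(c("AA", "NN")), "at least 2")
})

test_that("transition/transversion accounting matches the definitions", {
  rec <- make_records(list(c("AA", "BB"), c("AA", "BB"), c("AA", "BB")))
  rec$ref <- c("A", "C", "A")
  rec$alt <- c("G", "T", "C")
  tt <- ts_tv(rec)
  expect_equal(tt$ts, 2)
  expect_equal(tt$tv, 1)
  expect_equal(tt$ratio, 2)
  rec$ref <- c("A", "A", "G")
  rec$alt <- c("C", "T", "C")
  tt2 <- ts_tv(rec)
  expect_equal(tt2$tv, 3)
  expect_equal(tt2$ratio, 0)
  rec$ref <- c("A", "C", "G")
  rec$alt <- c("G", "T", "A")
  tt3 <- ts_tv(rec)   # all transitions: ratio undefined
  expect_equal(tt3$ts, 3)
  expect_true(is.na(tt3$ratio))
  rec$alt <- c("C", "T", "CA")
  expect_error(ts_tv(rec), "single nucleotides")
})

test_that("private SNPs require a single carrier among informative lines", {
  rec <- make_records(list(
    c("BB", "AA", "AA", "AA"),   # private to Line01
    c("BB", "BB", "AA", "AA"),   # two carriers
    c("AB", "AA", "NN", "AA"),   # het carrier still private
    c("BB", "NN", "NN", "NN")))  # unassessable: one informative line
  pf <- private_snp_fractions(rec)
  expect_equal(pf$per_line$n_private[pf$per_line$line == "Line01"], 2)
  expect_equal(sum(pf$per_line$n_private), 2)
  expect_equal(pf$per_genome$n, 3)        # the unassessable record excluded
  expect_equal(pf$per_genome$fraction, 2 / 3)
})

test_that("SNP summaries equal brute-force counts with consistent totals", {
  set.seed(40)
  vr <- generate_variant_records(800, seed = 41)
  s <- summarize_snps(vr$records)
  tot <- s[s$chromosome == "Total", ]
  expect_equal(tot$total, 800)
  for (f in c("ISBP-derived", "intergenic", "exonic", "intronic")) {
    expect_equal(tot[[f]], sum(vr$records$fraction == f))
  }
  chr_rows <- s[!grepl("genome|Total", s$chromosome), ]
  expect_equal(sum(chr_rows$total), 800)
  one <- chr_rows$chromosome[1]
  expect_equal(chr_rows$total[1], sum(vr$records$chrom == one))
  expect_error(summarize_snps(data.frame(chrom = "1A", fraction = "weird")),
               "unknown fraction")
})

test_that("quota allocation is size-proportional with D-genome doubling and
           sums exactly to the requested total", {
  arms <- data.frame(arm = c("a", "b", "c"), size = c(300, 300, 150),
                     genome = c("A", "B", "D"))
  q <- allocate_quota(arms, 90)
  expect_equal(q$allocated, c(30L, 30L, 30L))
  expect_equal(allocate_quota(arms[1, ], 17)$allocated, 17L)
  q1 <- allocate_quota(arms, 90, d_multiplier = 1)
  expect_equal(q1$allocated, c(36L, 36L, 18L))
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:42, 1)
    arms_r <- data.frame(arm = seq_len(n),
                         size = runif(n, 50, 500),
                         genome = sample(c("A", "B", "D"), n, TRUE))
    total <- sample(100:5000, 1)
    qr <- allocate_quota(arms_r, total)
    expect_equal(sum(qr$allocated), total)
    qn <- allocate_quota(arms_r, total, d_multiplier = 1)
    expect_true(all(abs(qn$allocated -
                          total * arms_r$size / sum(arms_r$size)) < 1))
  }
})

test_that("candidate selection enforces every eligibility predicate", {
  rec <- make_records(list(
    c("BB", "AA", "AA", "AA"),       # single carrier line
    c("BB", "AA", "BB", "AA"),       # eligible
    c("AA", "AA", "BB", "BB"),       # monomorphic among European lines
    c("BB", "AB", "AA", "AA"),       # eligible
    c("AB", "AB", "AB", "AB"),       # class 4, unusable
    c("BB", "AA", "BB", "AA")))      # multi-hit
  rec$hit_count[6] <- 2
  pools <- c(Line01 = "European", Line02 = "European",
             Line03 = "Other", Line04 = "Other")
  quotas <- data.frame(arm = "1A", allocated = 10)
  expect_warning(res <- select_candidates(rec, pools, quotas), "under-filled")
  expect_setequal(res$selected$id, c("S002", "S004"))
  aud <- res$audit
  expect_match(aud$exclusion_reasons[1], "too_few_carrier_lines")
  expect_match(aud$exclusion_reasons[3], "monomorphic_in_european")
  expect_match(aud$exclusion_reasons[5], "unusable_class")
  expect_match(aud$exclusion_reasons[6], "multi_hit")
  # never selects an ineligible record
  expect_true(all(aud$eligible[match(res$selected$id, aud$id)]))
})

test_that("selection fills quotas by descending carrier count then position", {
  rec <- make_records(list(
    c("BB", "AA", "BB", "AA"),    # 2 carrier lines, pos 100
    c("BB", "AA", "BB", "BB"),    # 3 carrier lines, pos 200
    c("AB", "AA", "BB", "AA")))   # 2 carrier lines, pos 300
  pools <- c(Line01 = "European", Line02 = "European",
             Line03 = "Other", Line04 = "Other")
  quotas <- data.frame(arm = "1A", allocated = 2)
  res <- select_candidates(rec, pools, quotas)
  expect_identical(res$selected$id, c("S002", "S001"))
})
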