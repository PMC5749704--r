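test_that("1:1 chi-square matches the closed form", {
  perfect <- segregation_chi_square(50, 50)
  expect_equal(perfect$statistic, 0)
  expect_equal(perfect$p_value, 1)
  mild <- segregation_chi_square(60, 40)
  expect_equal(mild$statistic, 4)
  expect_equal(mild$p_value, pchisq(4, 1, lower.tail = FALSE))
  expect_gt(mild$p_value, 0.01)  # kept at P <= 0.01
  strong <- segregation_chi_square(70, 30)
  expect_equal(strong$statistic, 16)
  expect_lt(strong$p_value, 0.01)
  expect_error(segregation_chi_square(0, 0), "no informative")
})

test_that("marker filtering applies every rule and records all reasons", {
  set.seed(31)
  n <- 430
  base <- function(p_miss = 0, p1 = "AA", p2 = "BB", n_a = 215) {
    col <- c(p1, p2, sample(c(rep("AA", n_a), rep("BB", n - n_a))))
    nn <- sample(seq(3, n + 2), round(p_miss * n))
    col[nn] <- "NN"
    col
  }
  g <- cbind(ok = base(),
             miss = base(p_miss = 0.152),
             hetpar = base(p1 = "AB"),
             distorted = base(n_a = 300),
             multi = base(p_miss = 0.2, p1 = "NN", n_a = 300))
  rownames(g) <- c("P1", "P2", sprintf("I%03d", seq_len(n)))
  cats <- c("PHR", "PHR", "PHR", "PHR", "NMH")
  dip <- c(TRUE, TRUE, TRUE, TRUE, FALSE)
  rep_f <- filter_mapping_markers(g, cats, dip)
  expect_true(rep_f$kept[1])
  expect_identical(rep_f$rejection_reasons[1], "")
  expect_match(rep_f$rejection_reasons[2], "excess_missing")
  expect_match(rep_f$rejection_reasons[3], "parent_missing_or_het")
  expect_match(rep_f$rejection_reasons[4], "distorted")
  for (r in c("not_PHR", "not_diploidized", "parent_missing_or_het",
              "excess_missing")) {
    expect_match(rep_f$rejection_reasons[5], r)
  }
  # exhaustive: kept + rejected = input; every rejection carries a reason
  expect_equal(sum(rep_f$kept) + sum(!rep_f$kept), ncol(g))
  expect_true(all(nchar(rep_f$rejection_reasons[!rep_f$kept]) > 0))
  expect_error(filter_mapping_markers(g[-1, ], cats, dip), "parent rows")
})

test_that("under a true 1:1 null about 1% of markers are rejected", {
  set.seed(32)
  n_a <- rbinom(10000, 430, 0.5)
  p <- vapply(n_a, function(a) {
    segregation_chi_square(a, 430 - a)$p_value
  }, numeric(1))
  rate <- mean(p <= 0.01)
  expect_lt(abs(rate - 0.01), 3 * sqrt(0.01 * 0.99 / 10000))
})

test_that("cosegregation bins group missing-compatible identical markers", {
  g <- cbind(A = c("AA", "BB", "AA", "BB"),
             B = c("AA", "BB", "NN", "BB"),
             C = c("BB", "AA", "BB", "AA"),
             D = c("BB", "AA", "BB", "AA"),
             E = c("AA", "AA", "BB", "BB"))
  bins <- cosegregation_bins(g)
  grp <- split(bins$marker, bins$bin)
  expect_setequal(vapply(grp, paste, character(1), collapse = ","),
                  c("A,B", "C,D", "E"))
  expect_equal(sum(bins$bin_size == 1), 1)   # E is the only non-redundant
  # representative has fewest missing calls
  expect_identical(unique(bins$representative[bins$marker %in% c("A", "B")]),
                   "A")
  # a single doubly-called difference separates markers
  g2 <- cbind(X = c("AA", "BB"), Y = c("AA", "AA"))
  expect_equal(length(unique(cosegregation_bins(g2)$bin)), 2L)
})

test_that("bins partition the marker set on random inputs", {
  set.seed(33)
  for (rep in 1:5) {
    g <- matrix(sample(c("AA", "BB", "NN"), 30 * 25, TRUE,
                       prob = c(.45, .45, .1)), 30, 25,
                dimnames = list(NULL, sprintf("m%02d", 1:25)))
    bins <- cosegregation_bins(g)
    expect_equal(nrow(bins), 25L)
    expect_equal(sort(unique(bins$marker)), sort(colnames(g)))
    sizes <- table(bins$bin)
    expect_equal(sum(sizes), 25)
  }
})

test_that("map summary computes lengths, unique positions and bin length", {
  map <- data.frame(marker = paste0("m", 1:5), chromosome = "1A",
                    position_cM = c(0, 0, 10, 10, 20))
  g <- cbind(m1 = rep("AA", 4), m2 = rep("AA", 4), m3 = rep("BB", 4),
             m4 = rep("BB", 4), m5 = c("AA", "BB", "AA", "BB"))
  s <- map_summary(map, cosegregation_bins(g))
  row <- s[s$chromosome == "1A", ]
  expect_equal(row$length_cM, 20)
  expect_equal(row$unique_positions, 3)
  expect_equal(row$non_redundant, 1)
  expect_equal(row$bin_length_cM, 6.67)
  single <- map_summary(data.frame(marker = "m", chromosome = "2B",
                                   position_cM = 5))
  expect_equal(single$length_cM[1], 0)
  expect_equal(single$unique_positions[1], 1)
  expect_equal(single$bin_length_cM[1], 0)
  expect_error(map_summary(data.frame(marker = "m", chromosome = "2B",
                                      position_cM = NA)), "position")
})

test_that("RIL markers simulated at identical positions share a bin and
           unique positions match the generator", {
  ril <- generate_ril_f6(ril_scenario(n_individuals = 80, n_chromosomes = 1,
                                      markers_per_chromosome = 60,
                                      chromosome_length_cM = 20,
                                      missing_rate = 0, seed = 34))
  g <- ril$genotypes[-(1:2), ]
  map <- ril$truth$map
  bins <- cosegregation_bins(g)
  bin_of <- setNames(bins$bin, bins$marker)
  same_pos <- split(map$marker, map$position_cM)
  for (grpm in same_pos[lengths(same_pos) > 1]) {
    expect_equal(length(unique(bin_of[grpm])), 1L)
  }
  s <- map_summary(map, bins)
  expect_equal(s$unique_positions[1], length(unique(map$position_cM)))
})

test_that("map concordance is rank-based per chromosome", {
  map <- data.frame(marker = paste0("m", 1:10),
                    chromosome = rep("3B", 10), position_cM = 1:10)
  expect_equal(compare_maps(map, map)$average, 1)
  rev_map <- map
  rev_map$position_cM <- rev(map$position_cM)
  expect_equal(compare_maps(map, rev_map)$average, -1)
  # one 3-marker segment inverted: compare to the closed-form Spearman
  inv <- map
  inv$position_cM[4:6] <- map$position_cM[6:4]
  rho_hand <- 1 - 6 * sum((rank(map$position_cM) -
                             rank(inv$position_cM))^2) / (10 * (100 - 1))
  expect_equal(compare_maps(map, inv)$per_chromosome$rho, rho_hand)
  small <- map[1:2, ]
  expect_warning(res <- compare_maps(small, small), "fewer than")
  expect_true(is.na(res$average))
})

test_that("aggregating per-chromosome stats recomputes genome/total rows", {
  stats <- data.frame(chromosome = c("1A", "2A", "1D"),
                      n_markers = c(100, 200, 50),
                      length_cM = c(150, 100, 200),
                      unique_positions = c(300, 200, 250),
                      non_redundant = c(10, 20, 30))
  out <- summarize_map_table(stats)
  tot <- out[out$chromosome == "Total", ]
  expect_equal(tot$n_markers, 350)
  expect_equal(tot$bin_length_cM, round(450 / 750, 2))
  a <- out[out$chromosome == "A-genome", ]
  expect_equal(a$n_markers, 300)
  expect_equal(a$unique_positions, 500)
})
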