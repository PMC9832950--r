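test_that("allele frequencies divide counts by depth and flag thin sites", {
  fv <- allele_frequencies(pool_counts(c(C = 32, T = 12)))
  expect_equal(unname(fv$freq["C"]), 32 / 44, tolerance = 1e-12)
  expect_equal(unname(fv$freq["T"]), 12 / 44, tolerance = 1e-12)
  expect_equal(fv$depth, 44)
  expect_true(fv$usable)
  expect_equal(sum(fv$freq), 1, tolerance = 1e-9)

  sym <- allele_frequencies(pool_counts(c(A = 10, C = 10, G = 10, T = 10)))
  expect_equal(unname(sym$freq), rep(0.25, 4))

  thin <- allele_frequencies(pool_counts(c(C = 0, T = 0)), min_depth = 5)
  expect_false(thin$usable)
  expect_false(any(is.nan(thin$freq))) # depth 0 never divides by zero
})

test_that("ED matches hand evaluation, is symmetric and bounded", {
  f_same <- allele_frequencies(pool_counts(c(C = 20, T = 20)))
  expect_equal(ed_statistic(f_same, f_same), 0)

  f_t <- allele_frequencies(pool_counts(c(A = 0, C = 0, G = 0, T = 30)))
  f_c <- allele_frequencies(pool_counts(c(A = 0, C = 30, G = 0, T = 0)))
  expect_equal(ed_statistic(f_t, f_c), sqrt(2), tolerance = 1e-12)

  # depth quartet of the reported donor-site SNV: sqrt(2 * (32/44)^2)
  f_mut <- allele_frequencies(pool_counts(c(C = 0, T = 37)))
  f_wt <- allele_frequencies(pool_counts(c(C = 32, T = 12)))
  expect_equal(ed_statistic(f_mut, f_wt), sqrt(2 * (32 / 44)^2), tolerance = 1e-12)
  expect_equal(round(ed_statistic(f_mut, f_wt), 5), 1.02852)

  snp <- allele_frequencies(pool_counts(c(C = 10, T = 10)))
  indel <- allele_frequencies(pool_counts(c(ref = 10, alt = 10)))
  expect_error(ed_statistic(snp, indel), "allele space")

  set.seed(1)
  for (i in 1:1000) {
    a <- random_freq_vector()
    b <- random_freq_vector()
    ed <- ed_statistic(a, b)
    expect_identical(ed, ed_statistic(b, a))
    expect_gte(ed, 0)
    expect_lte(ed, sqrt(2) + 1e-12)
  }
})

test_that("vectorized scan track equals the scalar statistic on full vectors", {
  set.seed(3)
  rows <- lapply(1:25, function(i) {
    make_variant_row(pos = i * 1000L, ref = "C", alt = "T",
                     counts = list(mutant_parent = c(0, 20),
                                   wildtype_parent = c(20, 0),
                                   mutant_pool = sample.int(40, 2),
                                   wildtype_pool = sample.int(40, 2)))
  })
  variants <- do.call(rbind, rows)
  pts <- ed_profile(variants, min_depth = 1)
  for (j in seq_len(nrow(pts))) {
    v <- variants[pts$vid[j], ]
    fm <- allele_frequencies(pool_counts(
      setNames(c(v$mutant_pool_ref, v$mutant_pool_alt), c(v$ref, v$alt))))
    fw <- allele_frequencies(pool_counts(
      setNames(c(v$wildtype_pool_ref, v$wildtype_pool_alt), c(v$ref, v$alt))))
    expect_equal(pts$ed[j], ed_statistic(fm, fw), tolerance = 1e-12)
  }
})

test_that("smoothing reproduces a brute-force tricube mean and its limits", {
  pts <- data.frame(vid = 1:5, chrom = "c1", pos = c(1, 2, 3, 4, 5) * 1000,
                    class = "SNP", ed = c(0.1, 0.4, 0.9, 0.2, 0.3))
  fitted <- fit_profile(pts, window_bp = 4000, k = 1)$ed_fitted
  h <- 2000
  oracle <- sapply(seq_len(5), function(i) {
    d <- abs(pts$pos - pts$pos[i])
    sel <- d <= h
    w <- (1 - (d[sel] / h)^3)^3
    sum(w * pts$ed[sel]) / sum(w)
  })
  expect_equal(fitted, oracle, tolerance = 1e-12)

  # constant profile is a fixed point at any k
  const <- pts
  const$ed <- 0.5
  expect_equal(fit_profile(const, 4000, k = 2)$ed_fitted, rep(0.25, 5))

  # a spike is never amplified
  spike <- pts
  spike$ed <- c(0, 0, 1, 0, 0)
  expect_lte(max(fit_profile(spike, 4000)$ed_fitted), 1)

  # window -> 0 recovers raw ed^k; window -> Inf the global tricube mean
  expect_equal(fit_profile(pts, window_bp = 1, k = 2)$ed_fitted, pts$ed^2)
  wide <- fit_profile(pts, window_bp = 1e9, k = 1)$ed_fitted
  expect_equal(wide, rep(mean(pts$ed), 5), tolerance = 1e-6)
})

test_that("smoothing never bleeds across chromosomes", {
  pts <- data.frame(vid = 1:4, chrom = c("c1", "c1", "c2", "c2"),
                    pos = c(1000, 2000, 1000, 2000), class = "SNP",
                    ed = c(1, 1, 0, 0))
  fitted <- fit_profile(pts, window_bp = 1e6)$ed_fitted
  expect_equal(fitted, c(1, 1, 0, 0))
})

test_that("threshold is median + 3 sample SDs of the fitted profile", {
  mk <- function(v) data.frame(ed_fitted = v)
  expect_equal(compute_threshold(mk(rep(0.3, 10))), 0.3)
  x <- c(0.1, 0.1, 0.1, 0.1, 0.9)
  hand_sd <- sqrt(sum((x - mean(x))^2) / 4)
  expect_equal(compute_threshold(mk(x)), 0.1 + 3 * hand_sd, tolerance = 1e-12)
  expect_equal(round(compute_threshold(mk(x)), 5), 1.17331)
  # appending a value below the median never raises the median term
  y <- c(x, 0.05)
  expect_lte(stats::median(y), stats::median(x))
})

test_that("region calling merges, filters, snaps bounds, and counts genes", {
  mkpts <- function(pos, fitted, chrom = "c1") {
    data.frame(vid = seq_along(pos), chrom = chrom, pos = pos, class = "SNP",
               ed = fitted, ed_fitted = fitted)
  }
  # all below threshold: empty
  expect_equal(nrow(call_regions(mkpts(1:20 * 1e4, rep(0.1, 20)), 0.5)), 0)

  # one run of 12 above-threshold variants
  pos <- seq(1e6, by = 1e4, length.out = 30)
  fitted <- c(rep(0.1, 9), rep(0.9, 12), rep(0.1, 9))
  r <- call_regions(mkpts(pos, fitted), 0.5, min_variants = 10)
  expect_equal(nrow(r), 1)
  expect_equal(r$n_variants, 12L)
  expect_lte(r$start, pos[10])
  expect_gte(r$end, pos[21])
  expect_equal(r$start %% 1e4, 0)
  expect_equal(r$end %% 1e4, 0)

  # two 6-variant runs 50 kb apart (below-threshold variants in between):
  # merged under a 100-kb gap, split under 10 kb
  pos2 <- c(seq(1e6, by = 5e3, length.out = 6),
            seq(1e6 + 30e3, by = 5e3, length.out = 3),
            seq(1e6 + 25e3 + 50e3, by = 5e3, length.out = 6))
  fitted2 <- c(rep(0.9, 6), rep(0.1, 3), rep(0.9, 6))
  merged <- call_regions(mkpts(pos2, fitted2), 0.5, min_variants = 10,
                         merge_gap_bp = 1e5)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$n_variants, 12L)
  split <- call_regions(mkpts(pos2, fitted2), 0.5, min_variants = 5,
                        merge_gap_bp = 1e4)
  expect_equal(nrow(split), 2)

  # gene counting over a synthetic gene set
  genes <- list(gene_model("g1", "c1",
                           "+", data.frame(start = 1.15e6, end = 1.16e6),
                           cds_start = 1.15e6, cds_end = 1.16e6),
                gene_model("g2", "c2",
                           "+", data.frame(start = 1.15e6, end = 1.16e6),
                           cds_start = 1.15e6, cds_end = 1.16e6))
  r2 <- call_regions(mkpts(pos, fitted), 0.5, min_variants = 10,
                     gene_models = genes)
  expect_equal(r2$n_genes, 1L)
})

test_that("region calling agrees with an exhaustive oracle on small instances", {
  # oracle: enumerate maximal above-threshold runs directly, merge by gap,
  # drop small ones, snap outward
  oracle_regions <- function(pos, fitted, thr, min_var, gap) {
    above <- fitted >= thr
    runs <- list()
    i <- 1
    while (i <= length(pos)) {
      if (above[i]) {
        j <- i
        while (j < length(pos) && above[j + 1]) j <- j + 1
        runs[[length(runs) + 1]] <- c(i, j)
        i <- j + 1
      } else i <- i + 1
    }
    if (length(runs) == 0) return(NULL)
    merged <- list(runs[[1]])
    nv <- runs[[1]][2] - runs[[1]][1] + 1
    if (length(runs) > 1) for (r in runs[-1]) {
      last <- merged[[length(merged)]]
      if (pos[r[1]] - pos[last[2]] < gap) {
        merged[[length(merged)]] <- c(last[1], r[2])
        nv[length(nv)] <- nv[length(nv)] + r[2] - r[1] + 1
      } else {
        merged[[length(merged) + 1]] <- r
        nv <- c(nv, r[2] - r[1] + 1)
      }
    }
    keep <- nv >= min_var
    if (!any(keep)) return(NULL)
    do.call(rbind, lapply(which(keep), function(m) {
      data.frame(start = floor(pos[merged[[m]][1]] / 1e4) * 1e4,
                 end = ceiling(pos[merged[[m]][2]] / 1e4) * 1e4,
                 n_variants = as.integer(nv[m]))
    }))
  }
  set.seed(11)
  for (rep_i in 1:30) {
    n <- sample(5:50, 1)
    pos <- sort(sample.int(5e6, n))
    fitted <- stats::runif(n)
    thr <- stats::runif(1, 0.3, 0.7)
    min_var <- sample(1:5, 1)
    gap <- sample(c(1e4, 1e5, 1e6), 1)
    pts <- data.frame(vid = 1:n, chrom = "c1", pos = pos, class = "SNP",
                      ed = fitted, ed_fitted = fitted)
    got <- call_regions(pts, thr, min_variants = min_var, merge_gap_bp = gap)
    want <- oracle_regions(pos, fitted, thr, min_var, gap)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got[, c("start", "end", "n_variants")], want,
                   ignore_attr = TRUE)
      # partition property: every above-threshold variant inside a surviving
      # run lies in exactly one region
      for (i in which(fitted >= thr)) {
        hits <- sum(pos[i] >= got$start & pos[i] <= got$end)
        expect_lte(hits, 1)
      }
    }
  }
})

test_that("region sizes match the printed 2-decimal Mb convention", {
  expect_equal(region_size_mb(11620000, 24230000), 12.61)
  expect_equal(region_size_mb(16300000, 18240000), 1.94)
  expect_equal(region_size_mb(100, 100), 0)
  expect_equal(region_size_mb(0, 125000), 0.13) # half-up, not banker's
})
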