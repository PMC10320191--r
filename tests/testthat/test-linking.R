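# SNP thresholding + LD expansion, the three evidence linkers, and score
# combination.

mk_snps <- function(rsid, chrom, pos, pvalue) {
  data.frame(rsid = rsid, chrom = chrom, pos = as.integer(pos),
             pvalue = pvalue, stringsAsFactors = FALSE)
}

mk_panel <- function(seed, proxy, r2, chrom = "chr1", pos = 1000L) {
  structure(data.frame(seed = seed, proxy = proxy, r2 = r2,
                       proxy_chrom = chrom, proxy_pos = as.integer(pos),
                       stringsAsFactors = FALSE),
            class = c("xgr_ld_panel", "data.frame"), population = "test")
}

test_that("SNP thresholding and LD expansion follow the r2 and p rules", {
  snps <- mk_snps(c("s1", "s2"), "chr1", c(100, 200), c(1e-9, 0.5))
  out <- suppressMessages(filter_and_expand_snps(snps, NULL))
  expect_identical(out$rsid, "s1")

  panel <- mk_panel("s1", c("s2x", "s3x"), c(0.9, 0.5))
  out2 <- suppressMessages(filter_and_expand_snps(snps, panel))
  expect_identical(sort(out2$rsid), c("s1", "s2x"))
  expect_identical(out2$pvalue[out2$rsid == "s2x"], 1e-9)
  expect_identical(out2$seed_rsid[out2$rsid == "s2x"], "s1")

  expect_error(
    suppressMessages(filter_and_expand_snps(
      mk_snps("s9", "chr1", 5, 0.2), NULL)),
    "--p-threshold")

  # proxy reachable from two seeds keeps the most significant seed
  snps3 <- mk_snps(c("a", "b"), "chr1", c(1, 2), c(1e-12, 1e-9))
  panel3 <- mk_panel(c("a", "b"), c("px", "px"), c(0.9, 0.95))
  out3 <- suppressMessages(filter_and_expand_snps(snps3, panel3))
  expect_identical(out3$seed_rsid[out3$rsid == "px"], "a")
})

test_that("LD expansion equals the brute-force set construction", {
  set.seed(21)
  for (rep in 1:5) {
    snps <- mk_snps(sprintf("s%03d", 1:100), "chr1", 1:100 * 10,
                    10^-runif(100, 0, 12))
    panel <- mk_panel(sample(snps$rsid, 150, TRUE),
                      sprintf("p%03d", sample(1:80, 150, TRUE)),
                      runif(150), pos = sample.int(1e6, 150))
    out <- suppressMessages(filter_and_expand_snps(snps, panel))
    seeds <- snps$rsid[snps$pvalue < 5e-8]
    want <- union(seeds,
                  panel$proxy[panel$seed %in% seeds & panel$r2 >= 0.8])
    expect_identical(sort(out$rsid), sort(want))

    # monotonicity: relaxing either threshold never removes SNPs
    out_r <- suppressMessages(filter_and_expand_snps(snps, panel,
                                                     r2_min = 0.5))
    out_p <- suppressMessages(filter_and_expand_snps(snps, panel,
                                                     p_threshold = 1e-5))
    expect_true(all(out$rsid %in% out_r$rsid))
    expect_true(all(out$rsid %in% out_p$rsid))
  }
})

mk_tss <- function(gene, chrom, tss) {
  structure(data.frame(gene = gene, chrom = chrom, tss = as.integer(tss),
                       strand = "+", stringsAsFactors = FALSE),
            class = c("xgr_tss", "data.frame"), kind = "proximity")
}

test_that("proximity linking decays linearly and is strict at the window", {
  tss <- mk_tss(c("G1", "G2"), "chr1", c(1000, 900000))
  snps <- mk_snps(c("s1", "s2", "s3"), "chr1",
                  c(1000, 51000, 26000), rep(1e-9, 3))
  ev <- suppressMessages(link_by_proximity(snps, tss, window = 50000))
  expect_identical(ev$raw_weight[ev$entity_id == "s1"], 1.0)
  expect_false("s2" %in% ev$entity_id)  # d == W: dropped
  expect_equal(ev$raw_weight[ev$entity_id == "s3"], 0.5)

  # unknown chromosome: silently no evidence
  snps_off <- mk_snps("s4", "chrX", 500, 1e-9)
  expect_identical(nrow(suppressMessages(link_by_proximity(snps_off, tss))), 0L)

  # regions: distance 0 when the TSS lies inside
  regions <- data.frame(chrom = "chr1", start = 900L, end = 1100L,
                        region_id = "chr1:900-1100", score = NA_real_)
  evr <- suppressMessages(link_by_proximity(regions, tss, window = 50000))
  expect_identical(evr$raw_weight[evr$gene == "G1"], 1.0)
})

test_that("proximity evidence equals the all-pairs distance scan", {
  set.seed(8)
  tss <- mk_tss(sprintf("G%03d", 1:100), sample(c("chr1", "chr2"), 100, TRUE),
                sample.int(5e6, 100))
  snps <- mk_snps(sprintf("s%03d", 1:200), sample(c("chr1", "chr2"), 200, TRUE),
                  sample.int(5e6, 200), rep(1e-9, 200))
  W <- 50000
  ev <- suppressMessages(link_by_proximity(snps, tss, W))
  brute <- do.call(rbind, lapply(1:200, function(i) {
    d <- abs(snps$pos[i] - tss$tss)
    hit <- tss$chrom == snps$chrom[i] & d < W
    if (!any(hit)) return(NULL)
    data.frame(entity_id = snps$rsid[i], gene = tss$gene[hit],
               raw_weight = 1 - d[hit] / W)
  }))
  key <- function(df) sort(sprintf("%s|%s|%.9f", df$entity_id, df$gene,
                                   df$raw_weight))
  expect_identical(key(ev), key(brute))
})

mk_iv <- function(chrom, start, end, gene, strength, kind = "pchic") {
  structure(data.frame(chrom = chrom, start = as.integer(start),
                       end = as.integer(end), gene = gene,
                       strength = strength, stringsAsFactors = FALSE),
            class = c("xgr_interval_evidence", "data.frame"), kind = kind)
}

test_that("interval linking uses half-open overlap and dataset-max weights", {
  ds <- mk_iv("chr1", c(100, 500), c(200, 600), c("G1", "G2"), c(2, 4))
  r <- data.frame(chrom = "chr1", start = c(100L, 200L),
                  end = c(200L, 500L),
                  region_id = c("chr1:100-200", "chr1:200-500"),
                  score = NA_real_)
  ev <- link_by_interval_map(r, ds)
  expect_identical(ev$gene, "G1")
  expect_equal(ev$raw_weight, 0.5)  # strength 2 / max 4; [200,500) misses both

  expect_error(link_by_interval_map(r, mk_iv("chr1", 1, 2, "G", 0)),
               "positive strengths")

  # SNPs are 1-bp intervals [pos-1, pos)
  s <- mk_snps("s1", "chr1", 100, 1e-9)  # occupies [99,100): inside [100,200)? no
  expect_identical(nrow(link_by_interval_map(s, ds)), 0L)
  s2 <- mk_snps("s2", "chr1", 101, 1e-9)  # [100,101): overlaps
  expect_identical(link_by_interval_map(s2, ds)$gene, "G1")
})

test_that("interval overlaps equal the quadratic scan and are shift-invariant", {
  set.seed(13)
  ds <- mk_iv(sample(c("chr1", "chr2"), 300, TRUE),
              st <- sample.int(1e6, 300), st + sample.int(5000, 300),
              sprintf("G%03d", sample(1:50, 300, TRUE)),
              runif(300, 0.1, 9), kind = "abc")
  rs <- sample.int(1e6, 500)
  r <- data.frame(chrom = sample(c("chr1", "chr2"), 500, TRUE),
                  start = rs, end = rs + sample.int(3000, 500))
  r$region_id <- sprintf("%s:%d-%d", r$chrom, r$start, r$end)
  r$score <- NA_real_
  ev <- link_by_interval_map(r, ds)
  pairs <- unlist(lapply(seq_len(500), function(i) {
    hit <- ds$chrom == r$chrom[i] & ds$start < r$end[i] & r$start[i] < ds$end
    if (any(hit)) paste(r$region_id[i], ds$gene[hit])
  }))
  expect_setequal(paste(ev$entity_id, ev$gene), unique(pairs))

  shifted <- r
  shifted$start <- r$start + 7777L; shifted$end <- r$end + 7777L
  shifted$region_id <- r$region_id  # keep ids to compare sets
  ds2 <- ds
  ds2$start <- ds$start + 7777L; ds2$end <- ds$end + 7777L
  ev2 <- link_by_interval_map(shifted, ds2)
  strip <- function(df) {
    df <- df[order(df$entity_id, df$gene), c("gene", "raw_weight")]
    rownames(df) <- NULL
    df
  }
  expect_identical(strip(ev), strip(ev2))
})

test_that("QTL linking is a relational join on rsid", {
  ds <- structure(data.frame(rsid = c("s1", "s1", "s9"),
                             gene = c("G1", "G2", "G3"),
                             weight = c(0.5, 0.9, 0.4),
                             stringsAsFactors = FALSE),
                  class = c("xgr_qtl_evidence", "data.frame"), kind = "eqtl")
  snps <- mk_snps(c("s1", "s2"), "chr1", c(1, 2), c(1e-9, 1e-9))
  snps$seed_rsid <- snps$rsid
  ev <- link_by_qtl(snps, ds)
  expect_identical(ev$gene, c("G1", "G2"))
  expect_identical(ev$raw_weight, c(0.5, 0.9))
  expect_identical(nrow(link_by_qtl(mk_snps("sx", "chr1", 1, 0.5), ds)), 0L)
})

test_that("score combination rescales additively to the 1-10 display range", {
  ev3 <- xgrkit:::new_evidence(c("r1", "r2", "r3"), c("r1", "r2", "r3"),
                               c("GA", "GB", "GC"), "abc", c(0.2, 0.4, 0.6))
  # region evidence: s = 1, raw scores 0.2/0.4/0.6 -> display 1/5.5/10
  res <- combine_scores(ev3, NULL)
  expect_equal(res$genes$display_score[match(c("GA", "GB", "GC"),
                                             res$genes$gene)],
               c(1, 5.5, 10))

  single <- combine_scores(ev3[1, ], NULL)
  expect_identical(single$genes$display_score, 10)

  tied <- combine_scores(xgrkit:::new_evidence(c("r1", "r2"), c("r1", "r2"),
                                               c("GA", "GB"), "abc",
                                               c(0.3, 0.3)), NULL)
  expect_identical(tied$genes$display_score, c(10, 10))

  # SNP evidence scales by the capped -log10 seed p
  evs <- xgrkit:::new_evidence("s1", "s1", "GA", "eqtl", 0.5)
  res2 <- combine_scores(evs, c(s1 = 1e-4))
  expect_equal(res2$genes$raw_score, 0.5 * 0.4)
  res3 <- combine_scores(evs, c(s1 = 1e-15))  # capped at 10
  expect_equal(res3$genes$raw_score, 0.5)
})

test_that("display scores stay in [1,10] and raw scores are additive", {
  set.seed(17)
  for (rep in 1:50) {
    n <- sample(1:30, 1)
    ev <- xgrkit:::new_evidence(sprintf("e%02d", 1:n), sprintf("e%02d", 1:n),
                                sample(sprintf("G%02d", 1:10), n, TRUE),
                                sample(c("abc", "pchic"), n, TRUE),
                                runif(n))
    res <- combine_scores(ev, NULL)
    expect_true(all(res$genes$display_score >= 1 - 1e-12 &
                    res$genes$display_score <= 10 + 1e-12))
    # adding a dataset never decreases any raw score
    extra <- xgrkit:::new_evidence("ex", "ex", sample(sprintf("G%02d", 1:10), 1),
                                   "eqtl", runif(1))
    res2 <- combine_scores(rbind(ev, extra), NULL)
    common <- match(res$genes$gene, res2$genes$gene)
    expect_true(all(res2$genes$raw_score[common] >= res$genes$raw_score - 1e-12))
  }
})
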