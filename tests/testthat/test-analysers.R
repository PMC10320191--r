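# Fixture bundles, the six analyser compositions and the CLI.

test_that("fixture bundles are reproducible and internally consistent", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- suppressMessages(generate_fixtures(d1, seed = 6))
  m2 <- suppressMessages(generate_fixtures(d2, seed = 6))
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)

  # planted-term genes appear on that term's GMT line
  gmt <- readLines(file.path(d1, "ontology.gmt"))
  line <- strsplit(grep(paste0("^", m1$planted_term, "\t"), gmt,
                        value = TRUE), "\t")[[1]]
  expect_true(all(m1$planted_term_genes %in% line[-(1:2)]))

  # the whole bundle passes the loaders' validation
  ont <- propagate_annotations(attach_dag(load_gmt(file.path(d1, "ontology.gmt")),
                                          file.path(d1, "dag.tsv")))
  net <- suppressMessages(load_network(file.path(d1, "network.tsv"),
                                       tier = "custom", threshold = 0))
  kb <- synth_knowledgebase(6)
  expect_identical(ont$propagated, kb$ontology$propagated)
  expect_identical(net$edges, kb$network$edges)
  expect_s3_class(load_ld_panel(file.path(d1, "ld.tsv")), "xgr_ld_panel")
  expect_s3_class(load_tss(file.path(d1, "tss.tsv")), "xgr_tss")
  expect_s3_class(load_interval_evidence(file.path(d1, "pchic.tsv"), "pchic"),
                  "xgr_interval_evidence")
  expect_s3_class(load_qtl_evidence(file.path(d1, "eqtl.tsv"), "eqtl"),
                  "xgr_qtl_evidence")
  expect_s3_class(load_interval_evidence(file.path(d1, "abc.tsv"), "abc"),
                  "xgr_interval_evidence")
  snps <- read_snps(file.path(d1, "snps.tsv"))
  expect_true(all(snps$pvalue > 0 & snps$pvalue <= 1))
  regions <- read_regions(file.path(d1, "regions.bed"))
  expect_true(all(regions$start < regions$end))

  expect_error(suppressMessages(synth_knowledgebase(1,
    sizes = list(module = 500L))), "module")
})

test_that("EAG recovers the planted term and matches the custom universe", {
  kb <- synth_knowledgebase(31)
  res <- suppressMessages(run_eag(kb$genes_input, kb$ontology))
  expect_identical(res$term_id[1], kb$manifest$planted_term)
  expect_lt(res$fdr[1], 0.05)

  ann <- sort(unique(unlist(kb$ontology$propagated, use.names = FALSE)))
  res2 <- suppressMessages(run_eag(kb$genes_input, kb$ontology,
                                   universe_mode = "custom",
                                   custom_universe = ann))
  expect_identical(res, res2)
})

test_that("EAS threads SNPs through linking into enrichment", {
  kb <- synth_knowledgebase(12)
  out <- suppressMessages(run_eas(kb$snps, kb$ontology, ld = kb$ld,
                                  tss = kb$tss, pchic = kb$pchic,
                                  eqtl = kb$eqtl, pqtl = kb$pqtl))
  expect_identical(out$enrichment$term_id[1], kb$manifest$planted_term)
  expect_true(all(out$linked$genes$display_score >= 1 &
                  out$linked$genes$display_score <= 10))
  # evidence provenance ties entities to datasets
  expect_true(all(out$linked$evidence$dataset_kind %in%
                  c("proximity", "pchic", "eqtl", "pqtl")))

  # no SNP below threshold: advisory error
  weak <- kb$snps
  weak$pvalue <- pmax(weak$pvalue, 1e-6)
  expect_error(suppressMessages(run_eas(weak, kb$ontology, tss = kb$tss)),
               "--p-threshold")
})

test_that("EAR links one region to one interval gene with display score 10", {
  ds <- structure(data.frame(chrom = "chr1", start = 100L, end = 200L,
                             gene = "G0001", strength = 5,
                             stringsAsFactors = FALSE),
                  class = c("xgr_interval_evidence", "data.frame"),
                  kind = "abc")
  regions <- data.frame(chrom = "chr1", start = 100L, end = 200L,
                        region_id = "chr1:100-200", score = NA_real_)
  kb <- synth_knowledgebase(2, sizes = list(genes = 300L, terms = 12L))
  out <- suppressMessages(run_ear(regions, kb$ontology, abc = ds,
                                  min_term = 1, min_overlap = 1))
  expect_identical(out$linked$genes$gene, "G0001")
  expect_identical(out$linked$genes$display_score, 10)
})

test_that("subnetwork analysers recover planted structure and write outputs", {
  kb <- synth_knowledgebase(44)
  dir <- withr::local_tempdir()
  sub <- suppressMessages(run_sag(kb$gene_pvalues, kb$network, target_n = 10,
                                  B = 10, seed = 3, out_dir = dir))
  expect_gte(jaccard(sub$nodes, kb$manifest$planted_module), 0.6)
  expect_true(file.exists(file.path(dir, "subnetwork_nodes.tsv")))
  expect_true(file.exists(file.path(dir, "subnetwork_edges.tsv")))
  summ <- jsonlite::read_json(file.path(dir, "subnetwork_summary.json"))
  expect_identical(summ$n_nodes, length(sub$nodes))
  expect_identical(summ$seed, 3L)

  # SAS on a single linked gene: the subnetwork is that node
  one_eqtl <- structure(data.frame(rsid = "rs00001",
                                   gene = kb$network$nodes[1], weight = 0.9,
                                   stringsAsFactors = FALSE),
                        class = c("xgr_qtl_evidence", "data.frame"),
                        kind = "eqtl")
  snp1 <- kb$snps[kb$snps$rsid == "rs00001", ]
  out <- suppressMessages(run_sas(snp1, kb$network, eqtl = one_eqtl,
                                  target_n = 1, tol = 0, B = 5, seed = 1))
  expect_identical(out$subnetwork$nodes, kb$network$nodes[1])
})

test_that("SAR composes region linking with the subnetwork search", {
  kb <- synth_knowledgebase(51)
  out <- suppressMessages(run_sar(kb$regions, kb$network, tss = kb$tss,
                                  abc = kb$abc, target_n = 5, B = 5, seed = 2))
  expect_tree(out$subnetwork, kb$network)
  expect_true(all(out$linked$genes$display_score >= 1))
})

test_that("CLI runs are reproducible byte for byte and add no values", {
  fix <- withr::local_tempdir()
  o1 <- withr::local_tempdir()
  o2 <- withr::local_tempdir()
  expect_identical(suppressMessages(xgr_cli(
    c("fixtures", "--seed", "5", "--out", fix))), 0L)

  args <- function(out) c("sag", "--input", file.path(fix, "gene_pvalues.tsv"),
                          "--network", file.path(fix, "network.tsv"),
                          "--tier", "custom", "--threshold", "0",
                          "--target-n", "10", "--permutations", "10",
                          "--seed", "5", "--out", out)
  expect_identical(suppressMessages(xgr_cli(args(o1))), 0L)
  expect_identical(suppressMessages(xgr_cli(args(o2))), 0L)
  for (f in list.files(o1))
    expect_identical(readLines(file.path(o1, f), warn = FALSE),
                     readLines(file.path(o2, f), warn = FALSE), label = f)

  # CLI output equals the module-level API result
  kb <- synth_knowledgebase(5)
  api <- suppressMessages(run_sag(kb$gene_pvalues, kb$network, target_n = 10,
                                  B = 10, seed = 5))
  nodes_tsv <- read.table(file.path(o1, "subnetwork_nodes.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  expect_identical(sort(nodes_tsv$gene), api$nodes)

  # eag subcommand end-to-end
  o3 <- withr::local_tempdir()
  expect_identical(suppressMessages(xgr_cli(
    c("eag", "--input", file.path(fix, "genes_input.txt"),
      "--ontology", file.path(fix, "ontology.gmt"),
      "--dag", file.path(fix, "dag.tsv"), "--out", o3))), 0L)
  enr <- read.table(file.path(o3, "enrichment.tsv"), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  man <- jsonlite::read_json(file.path(fix, "manifest.json"))
  expect_identical(enr$term_id[1], man$planted_term)

  expect_identical(suppressMessages(xgr_cli(
    c("bogus", "--out", o3))), 1L)
})
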