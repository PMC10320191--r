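# Synthetic knowledgebase and input generator.  Produces a coherent toy
# genome (gene TSS on a grid), an ontology with one designated plantable
# term, a scale-free network with a planted dense module, LD blocks,
# evidence datasets and analyser inputs with planted signal -- everything
# needed to run the six analysers without downloading real resources.

default_sizes <- function() {
  list(genes = 2000L,     # genes in the toy genome / ontology universe
       terms = 50L,       # ontology terms, sizes drawn 20-200
       planted_term_size = 40L,
       network = 100L,    # network nodes (a subset of the genes)
       module = 10L,      # planted dense high-score module
       snps = 200L,       # input SNPs
       planted_snps = 15L,
       regions = 50L,
       planted_regions = 12L,
       ld_block = 3L)     # LD proxies per significant seed
}

#' Generate an in-memory synthetic knowledgebase with planted signal
#'
#' The toy genome lays gene TSS on a 200 kb grid over two chromosomes, so a
#' 50 kb proximity window links each variant to at most one gene.  One
#' ontology term is designated "planted"; SNP and region inputs carry
#' significant signal near that term's genes, and the network hides a dense
#' module of high-scoring genes.
#'
#' @param seed Integer RNG seed; the same seed reproduces the same bundle.
#' @param sizes Named list overriding any of the default dimensions
#'   (`genes`, `terms`, `planted_term_size`, `network`, `module`, `snps`,
#'   `planted_snps`, `regions`, `planted_regions`, `ld_block`).
#' @return A list with the knowledgebase objects (`ontology`, `dag`,
#'   `network`, `ld`, `tss`, `pchic`, `abc`, `eqtl`, `pqtl`), the analyser
#'   inputs (`genes_input`, `gene_pvalues`, `snps`, `regions`) and a
#'   `manifest` recording the planted truth.
#' @export
synth_knowledgebase <- function(seed, sizes = list()) {
  sz <- utils::modifyList(default_sizes(), sizes)
  if (sz$module > sz$network)
    stop("planted module larger than the network", call. = FALSE)
  if (sz$planted_term_size > sz$genes || sz$network > sz$genes)
    stop("inconsistent sizes: components larger than the gene pool",
         call. = FALSE)
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(sz$genes))

  # --- toy genome: TSS on a 200kb grid over two chromosomes --------------
  half <- ceiling(sz$genes / 2)
  chrom <- rep(c("chr1", "chr2"), c(half, sz$genes - half))
  idx_on_chr <- c(seq_len(half), seq_len(sz$genes - half))
  tss <- structure(
    data.frame(gene = genes, chrom = chrom,
               tss = 100000L + (idx_on_chr - 1L) * 200000L,
               strand = sample(c("+", "-"), sz$genes, replace = TRUE),
               stringsAsFactors = FALSE),
    class = c("xgr_tss", "data.frame"), kind = "proximity")

  # --- ontology: random term sizes 20-200, one planted term --------------
  term_ids <- sprintf("T%03d", seq_len(sz$terms))
  term_sizes <- sample(20:200, sz$terms, replace = TRUE)
  planted_term <- term_ids[max(min(5L, sz$terms), sz$terms %/% 2L)]
  term_sizes[term_ids == planted_term] <- sz$planted_term_size
  direct <- lapply(term_sizes, function(s) sort(sample(genes, s)))
  names(direct) <- term_ids
  ont <- structure(
    list(terms = data.frame(term_id = term_ids,
                            name = paste("synthetic process", seq_len(sz$terms)),
                            stringsAsFactors = FALSE),
         direct = direct,
         dag = data.frame(child = character(0), parent = character(0),
                          stringsAsFactors = FALSE),
         propagated = direct,
         gene2term = invert_annotations(direct)),
    class = "xgr_ontology")
  # shallow random forest: some terms become children of one of the first
  # four "top-level" terms (the planted term never gains descendants)
  if (sz$terms >= 6) {
    dag_child <- term_ids[5:sz$terms][rbinom(sz$terms - 4, 1, 0.4) == 1]
    dag_parent <- vapply(dag_child, function(t) {
      term_ids[sample.int(4L, 1)]
    }, character(1))
    dag <- data.frame(child = dag_child, parent = unname(dag_parent),
                      stringsAsFactors = FALSE)
  } else {
    dag <- data.frame(child = character(0), parent = character(0),
                      stringsAsFactors = FALSE)
  }
  ont <- propagate_annotations(attach_dag(ont, dag))
  planted_genes <- ont$direct[[planted_term]]

  # --- network: preferential attachment + planted dense module -----------
  net_genes <- sort(c(sample(setdiff(genes, planted_genes),
                             sz$network - min(sz$module, sz$network))))
  module_genes <- sort(sample(planted_genes, sz$module))
  net_genes <- sort(c(net_genes, module_genes))
  g <- igraph::sample_pa(sz$network, m = 2, directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- data.frame(gene_a = net_genes[el[, 1]], gene_b = net_genes[el[, 2]],
                      weight = round(runif(nrow(el), 0.70, 1.0), 4),
                      stringsAsFactors = FALSE)
  if (sz$module >= 2) {
    # densify the module: a ring plus random chords, high confidence
    mod_ring <- data.frame(gene_a = module_genes,
                           gene_b = module_genes[c(2:sz$module, 1)],
                           weight = round(runif(sz$module, 0.85, 1.0), 4),
                           stringsAsFactors = FALSE)
    chord <- t(utils::combn(module_genes, 2))
    pick <- runif(nrow(chord)) < 0.4
    mod_chords <- data.frame(gene_a = chord[pick, 1], gene_b = chord[pick, 2],
                             weight = round(runif(sum(pick), 0.85, 1.0), 4),
                             stringsAsFactors = FALSE)
    edges <- rbind(edges, mod_ring, mod_chords)
  }
  network <- new_network(canonical_edges(edges), "custom")

  # --- SNP input: significant SNPs near planted-term gene TSS ------------
  planted_snp_genes <- sort(sample(planted_genes, sz$planted_snps))
  ti <- match(planted_snp_genes, tss$gene)
  planted_snps <- data.frame(
    rsid = sprintf("rs%05d", seq_len(sz$planted_snps)),
    chrom = tss$chrom[ti],
    pos = tss$tss[ti] + sample(-20000:20000, sz$planted_snps, replace = TRUE),
    pvalue = 10^-runif(sz$planted_snps, 9, 12),
    stringsAsFactors = FALSE)
  n_bg <- sz$snps - sz$planted_snps
  bg_snps <- data.frame(
    rsid = sprintf("rs%05d", sz$planted_snps + seq_len(n_bg)),
    chrom = sample(c("chr1", "chr2"), n_bg, replace = TRUE),
    pos = sample.int(half * 200000L, n_bg),
    pvalue = runif(n_bg, 1e-6, 1),
    stringsAsFactors = FALSE)
  snps <- rbind(planted_snps, bg_snps)
  snps <- snps[order(snps$rsid), ]
  rownames(snps) <- NULL

  # --- LD panel: proxies within +-10kb of each significant seed ----------
  ld_rows <- lapply(seq_len(sz$planted_snps), function(i) {
    data.frame(seed = planted_snps$rsid[i],
               proxy = sprintf("%s_p%d", planted_snps$rsid[i],
                               seq_len(sz$ld_block)),
               r2 = round(runif(sz$ld_block, 0.5, 1.0), 4),
               proxy_chrom = planted_snps$chrom[i],
               proxy_pos = planted_snps$pos[i] +
                 sample(c(-10000:-1, 1:10000), sz$ld_block),
               stringsAsFactors = FALSE)
  })
  ld <- structure(do.call(rbind, ld_rows),
                  class = c("xgr_ld_panel", "data.frame"),
                  population = "synthetic")

  # --- interval evidence: promoter-anchored windows around TSS -----------
  mk_intervals <- function(cover_genes, kind) {
    ti <- match(cover_genes, tss$gene)
    structure(
      data.frame(chrom = tss$chrom[ti],
                 start = pmax(0L, tss$tss[ti] - 25000L),
                 end = tss$tss[ti] + 25000L,
                 gene = cover_genes,
                 strength = round(runif(length(ti), 1, 10), 3),
                 stringsAsFactors = FALSE),
      class = c("xgr_interval_evidence", "data.frame"), kind = kind)
  }
  covered <- sort(unique(c(planted_snp_genes,
                           sample(genes, round(sz$genes * 0.3)))))
  pchic <- mk_intervals(covered, "pchic")
  region_genes <- sort(sample(planted_genes, sz$planted_regions))
  abc_cover <- sort(unique(c(region_genes, sample(genes, round(sz$genes * 0.3)))))
  abc <- mk_intervals(abc_cover, "abc")

  # --- QTL evidence: planted SNP -> its gene, plus random noise ----------
  qtl_noise <- data.frame(rsid = sample(bg_snps$rsid, 30),
                          gene = sample(genes, 30, replace = TRUE),
                          weight = round(runif(30, 0.2, 1), 4),
                          stringsAsFactors = FALSE)
  eqtl <- structure(
    rbind(data.frame(rsid = planted_snps$rsid, gene = planted_snp_genes,
                     weight = round(runif(sz$planted_snps, 0.5, 1), 4),
                     stringsAsFactors = FALSE), qtl_noise),
    class = c("xgr_qtl_evidence", "data.frame"), kind = "eqtl")
  pqtl <- structure(
    data.frame(rsid = sample(snps$rsid, 40),
               gene = sample(genes, 40, replace = TRUE),
               weight = round(runif(40, 0.2, 1), 4),
               stringsAsFactors = FALSE),
    class = c("xgr_qtl_evidence", "data.frame"), kind = "pqtl")

  # --- region input: planted regions over ABC intervals of planted genes -
  ri <- match(region_genes, tss$gene)
  planted_reg <- data.frame(chrom = tss$chrom[ri],
                            start = pmax(0L, tss$tss[ri] - 5000L),
                            end = tss$tss[ri] + 5000L,
                            stringsAsFactors = FALSE)
  n_bgr <- sz$regions - sz$planted_regions
  bg_start <- sample.int(half * 200000L, n_bgr)
  bg_reg <- data.frame(chrom = sample(c("chr1", "chr2"), n_bgr, replace = TRUE),
                       start = bg_start, end = bg_start + 2000L,
                       stringsAsFactors = FALSE)
  regions <- rbind(planted_reg, bg_reg)
  regions$score <- NA_real_
  regions$region_id <- sprintf("%s:%d-%d", regions$chrom, regions$start,
                               regions$end)
  regions <- regions[order(regions$region_id), c("chrom", "start", "end",
                                                 "region_id", "score")]
  rownames(regions) <- NULL

  # --- gene-level inputs --------------------------------------------------
  genes_input <- sort(c(sample(planted_genes, 30),
                        sample(setdiff(genes, planted_genes), 30)))
  gp <- runif(length(network$nodes))
  gp[match(module_genes, network$nodes)] <- 10^-runif(sz$module, 6, 10)
  gene_pvalues <- data.frame(gene = network$nodes, pvalue = gp,
                             stringsAsFactors = FALSE)

  manifest <- list(seed = seed, sizes = sz,
                   planted_term = planted_term,
                   planted_term_genes = planted_genes,
                   planted_module = module_genes,
                   planted_snp_genes = planted_snp_genes,
                   planted_region_genes = region_genes)

  list(ontology = ont, dag = dag, network = network, ld = ld, tss = tss,
       pchic = pchic, abc = abc, eqtl = eqtl, pqtl = pqtl,
       genes_input = genes_input, gene_pvalues = gene_pvalues,
       snps = snps, regions = regions, manifest = manifest)
}

#' Write a synthetic fixture bundle to disk
#'
#' Materializes [synth_knowledgebase()] as the plain-text formats the
#' loaders read (GMT, TSVs, BED) plus a `manifest.json` with the planted
#' ground truth.  Regeneration from the same seed is byte-identical.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer RNG seed.
#' @param sizes Size overrides, as in [synth_knowledgebase()].
#' @return The manifest list, invisibly; files are written under `out_dir`.
#' @export
generate_fixtures <- function(out_dir, seed, sizes = list()) {
  kb <- synth_knowledgebase(seed, sizes)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)

  gmt_lines <- vapply(kb$ontology$terms$term_id, function(t) {
    paste(c(t, kb$ontology$terms$name[match(t, kb$ontology$terms$term_id)],
            kb$ontology$direct[[t]]), collapse = "\t")
  }, character(1))
  writeLines(gmt_lines, p("ontology.gmt"))
  write_kb_tsv(kb$dag, p("dag.tsv"))
  write_kb_tsv(kb$network$edges, p("network.tsv"))
  write_kb_tsv(as.data.frame(kb$ld), p("ld.tsv"))
  write_kb_tsv(as.data.frame(kb$tss), p("tss.tsv"))
  write_kb_tsv(as.data.frame(kb$pchic), p("pchic.tsv"))
  write_kb_tsv(as.data.frame(kb$abc), p("abc.tsv"))
  write_kb_tsv(as.data.frame(kb$eqtl), p("eqtl.tsv"))
  write_kb_tsv(as.data.frame(kb$pqtl), p("pqtl.tsv"))
  writeLines(kb$genes_input, p("genes_input.txt"))
  write_kb_tsv(kb$gene_pvalues, p("gene_pvalues.tsv"))
  write_kb_tsv(kb$snps, p("snps.tsv"))
  bed <- kb$regions[, c("chrom", "start", "end")]
  write.table(bed, p("regions.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(kb$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(kb$manifest)
}
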