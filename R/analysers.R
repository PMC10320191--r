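# The six analysers.  Enrichment analysers (EAG/EAS/EAR) end in ontology
# enrichment of a gene list -- given directly, or derived from SNPs/regions
# by the linking module.  Subnetwork analysers (SAG/SAS/SAR) end in a
# prize-collecting Steiner tree search over a gene network with permutation
# significance.  Each run_* function composes the module-level APIs and
# (optionally) writes the result tables; the CLI adds no values of its own.

resolve_ontology <- function(ontology, dag = NULL, propagate = TRUE) {
  ont <- if (inherits(ontology, "xgr_ontology")) ontology else load_gmt(ontology)
  if (!is.null(dag)) ont <- attach_dag(ont, dag)
  if (propagate) ont <- propagate_annotations(ont)
  ont
}

resolve_network <- function(network, tier = "high", threshold = NULL) {
  if (inherits(network, "xgr_network")) network
  else load_network(network, tier = tier, threshold = threshold)
}

resolve_genes <- function(genes) {
  if (is.character(genes) && length(genes) == 1 && file.exists(genes)) {
    lines <- readLines(genes, warn = FALSE)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1)
  } else {
    as.character(genes)
  }
}

resolve_snps <- function(snps) {
  if (is.data.frame(snps)) snps else read_snps(snps)
}

resolve_regions <- function(regions) {
  if (is.data.frame(regions)) regions else read_regions(regions)
}

resolve_many <- function(x, loader, kind) {
  if (is.null(x)) return(list())
  if (is.data.frame(x)) return(list(x))
  if (is.list(x)) return(x)
  lapply(x, loader, kind = kind)
}

#' EAG: enrichment analysis of a gene list
#'
#' @param genes Character vector of gene symbols, or a path to a one-per-line
#'   gene list file.
#' @param ontology An `xgr_ontology` or a GMT path.
#' @param dag Optional DAG edges (data.frame or TSV path).
#' @param propagate Apply the true-path rule before testing (default `TRUE`).
#' @param out_dir Optional output directory (writes `enrichment.tsv` and
#'   `enrichment.json`).
#' @param ... Further arguments to [run_enrichment()].
#' @return An `xgr_enrichment` data.frame.
#' @export
run_eag <- function(genes, ontology, dag = NULL, propagate = TRUE,
                    out_dir = NULL, ...) {
  ont <- resolve_ontology(ontology, dag, propagate)
  res <- run_enrichment(resolve_genes(genes), ont, propagated = propagate, ...)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_enrichment(res, file.path(out_dir, "enrichment.tsv"),
                     file.path(out_dir, "enrichment.json"))
  }
  res
}

# shared SNP-linking front half of EAS/SAS
link_snps <- function(snps, ld, tss, pchic, eqtl, pqtl,
                      p_threshold, r2_min, window, pool) {
  snps <- resolve_snps(snps)
  panel <- if (is.null(ld) || inherits(ld, "xgr_ld_panel")) ld else load_ld_panel(ld)
  expanded <- filter_and_expand_snps(snps, panel, p_threshold, r2_min)
  ev <- list()
  if (!is.null(tss)) {
    tss_tab <- if (inherits(tss, "xgr_tss")) tss else load_tss(tss)
    ev <- c(ev, list(link_by_proximity(expanded, tss_tab, window)))
  }
  for (ds in resolve_many(pchic, load_interval_evidence, "pchic"))
    ev <- c(ev, list(link_by_interval_map(expanded, ds)))
  for (ds in resolve_many(eqtl, load_qtl_evidence, "eqtl"))
    ev <- c(ev, list(link_by_qtl(expanded, ds)))
  for (ds in resolve_many(pqtl, load_qtl_evidence, "pqtl"))
    ev <- c(ev, list(link_by_qtl(expanded, ds)))
  evidence <- do.call(rbind, c(ev, list(new_evidence())))
  linked <- combine_scores(evidence, setNames(snps$pvalue, snps$rsid), pool)
  xgr_log("linking: %d gene(s) linked from %d significant/proxy SNPs",
          nrow(linked$genes), nrow(expanded))
  linked
}

# shared region-linking front half of EAR/SAR
link_regions <- function(regions, tss, pchic, abc, window) {
  regions <- resolve_regions(regions)
  ev <- list()
  if (!is.null(tss)) {
    tss_tab <- if (inherits(tss, "xgr_tss")) tss else load_tss(tss)
    ev <- c(ev, list(link_by_proximity(regions, tss_tab, window)))
  }
  for (ds in resolve_many(pchic, load_interval_evidence, "pchic"))
    ev <- c(ev, list(link_by_interval_map(regions, ds)))
  for (ds in resolve_many(abc, load_interval_evidence, "abc"))
    ev <- c(ev, list(link_by_interval_map(regions, ds)))
  evidence <- do.call(rbind, c(ev, list(new_evidence())))
  linked <- combine_scores(evidence, NULL)
  xgr_log("linking: %d gene(s) linked from %d regions", nrow(linked$genes),
          nrow(regions))
  linked
}

write_linking_outputs <- function(linked, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_linked_genes(linked, file.path(out_dir, "linked_genes.tsv"),
                     file.path(out_dir, "evidence.tsv"))
}

#' EAS: SNPs to linked genes to enrichment
#'
#' Thresholds and LD-expands the input SNPs, links them to genes through
#' proximity / PCHi-C / e-pQTL evidence, scores the linked genes 1-10, and
#' runs ontology enrichment on the linked genes.
#'
#' @param snps SNP data.frame or TSV path (`rsid chrom pos pvalue`).
#' @param ontology An `xgr_ontology` or GMT path.
#' @param ld LD panel (object, path or `NULL` for no expansion).
#' @param tss TSS table (object/path) for proximity linking, or `NULL`.
#' @param pchic,eqtl,pqtl Evidence datasets: a single object, a list of
#'   objects, or a vector of paths.
#' @param p_threshold,r2_min SNP significance threshold (default `5e-8`) and
#'   minimum proxy r-squared (default `0.8`).
#' @param window Proximity window in bp (default 50000).
#' @param pool Evidence pooling, `"sum"` or `"max"`.
#' @param dag,propagate,out_dir,... As in [run_eag()].
#' @return List with `linked` (see [combine_scores()]) and `enrichment`.
#' @export
run_eas <- function(snps, ontology, ld = NULL, tss = NULL, pchic = NULL,
                    eqtl = NULL, pqtl = NULL, p_threshold = 5e-8,
                    r2_min = 0.8, window = 50000, pool = "sum", dag = NULL,
                    propagate = TRUE, out_dir = NULL, ...) {
  linked <- link_snps(snps, ld, tss, pchic, eqtl, pqtl,
                      p_threshold, r2_min, window, pool)
  ont <- resolve_ontology(ontology, dag, propagate)
  res <- run_enrichment(linked$genes$gene, ont, propagated = propagate, ...)
  if (!is.null(out_dir)) {
    write_linking_outputs(linked, out_dir)
    write_enrichment(res, file.path(out_dir, "enrichment.tsv"),
                     file.path(out_dir, "enrichment.json"))
  }
  list(linked = linked, enrichment = res)
}

#' EAR: genomic regions to linked genes to enrichment
#'
#' @param regions Region data.frame or BED path.
#' @param abc ABC enhancer-gene datasets (object, list or paths).
#' @inheritParams run_eas
#' @return List with `linked` and `enrichment`.
#' @export
run_ear <- function(regions, ontology, tss = NULL, pchic = NULL, abc = NULL,
                    window = 50000, dag = NULL, propagate = TRUE,
                    out_dir = NULL, ...) {
  linked <- link_regions(regions, tss, pchic, abc, window)
  ont <- resolve_ontology(ontology, dag, propagate)
  res <- run_enrichment(linked$genes$gene, ont, propagated = propagate, ...)
  if (!is.null(out_dir)) {
    write_linking_outputs(linked, out_dir)
    write_enrichment(res, file.path(out_dir, "enrichment.tsv"),
                     file.path(out_dir, "enrichment.json"))
  }
  list(linked = linked, enrichment = res)
}

run_subnetwork_common <- function(scores, significance, net, target_n, tol,
                                  max_iter, B, bins, seed, out_dir) {
  if (is.null(tol)) tol <- max(1, ceiling(0.1 * target_n))
  sub <- search_subnetwork(net, scores, target_n, tol, max_iter)
  sub <- permutation_significance(net, scores, sub, B = B, bins = bins,
                                  seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_subnetwork(sub, scores, net,
                     file.path(out_dir, "subnetwork_nodes.tsv"),
                     file.path(out_dir, "subnetwork_edges.tsv"),
                     file.path(out_dir, "subnetwork_summary.json"),
                     significance = significance, seed = seed)
  }
  sub
}

#' SAG: gene subnetwork from gene-level summary statistics
#'
#' Scores are `min(-log10(p), 16)`; the subnetwork is found by the
#' prize-collecting Steiner tree search at the desired size and assessed by
#' a degree-preserving permutation test.
#'
#' @param gene_pvalues Data.frame (`gene`, `pvalue`) or TSV path.
#' @param network An `xgr_network` or TSV path.
#' @param tier,threshold Network confidence filter (see [load_network()]).
#' @param target_n Desired subnetwork size (default 30).
#' @param tol Size tolerance (default `max(1, ceiling(0.1 * target_n))`).
#' @param max_iter Bisection iterations (default 50).
#' @param B Permutations (default 100).
#' @param bins Degree bins for the permutation test (default 10).
#' @param seed RNG seed (default 1).
#' @param out_dir Optional output directory.
#' @return An `xgr_subnetwork`.
#' @export
run_sag <- function(gene_pvalues, network, tier = "high", threshold = NULL,
                    target_n = 30, tol = NULL, max_iter = 50, B = 100,
                    bins = 10, seed = 1, out_dir = NULL) {
  gp <- if (is.data.frame(gene_pvalues)) gene_pvalues else
    read_tsv_file(gene_pvalues, c("gene", "pvalue"))
  gp$pvalue <- as.numeric(gp$pvalue)
  net <- resolve_network(network, tier, threshold)
  scores <- scores_from_pvalues(gp$gene, gp$pvalue)
  run_subnetwork_common(scores, setNames(gp$pvalue, gp$gene), net, target_n,
                        tol, max_iter, B, bins, seed, out_dir)
}

#' SAS: gene subnetwork from SNP summary statistics
#'
#' SNPs are linked to genes as in [run_eas()]; the linked genes' 1-10
#' display scores become the node scores for the subnetwork search.
#'
#' @inheritParams run_eas
#' @inheritParams run_sag
#' @return List with `linked` and `subnetwork`.
#' @export
run_sas <- function(snps, network, ld = NULL, tss = NULL, pchic = NULL,
                    eqtl = NULL, pqtl = NULL, p_threshold = 5e-8,
                    r2_min = 0.8, window = 50000, pool = "sum",
                    tier = "high", threshold = NULL, target_n = 30,
                    tol = NULL, max_iter = 50, B = 100, bins = 10, seed = 1,
                    out_dir = NULL) {
  linked <- link_snps(snps, ld, tss, pchic, eqtl, pqtl,
                      p_threshold, r2_min, window, pool)
  net <- resolve_network(network, tier, threshold)
  scores <- setNames(linked$genes$display_score, linked$genes$gene)
  sub <- run_subnetwork_common(scores, scores, net, target_n, tol, max_iter,
                               B, bins, seed, out_dir)
  if (!is.null(out_dir)) write_linking_outputs(linked, out_dir)
  list(linked = linked, subnetwork = sub)
}

#' SAR: gene subnetwork from genomic regions
#'
#' Regions are linked to genes as in [run_ear()]; linked-gene display scores
#' drive the subnetwork search.
#'
#' @inheritParams run_ear
#' @inheritParams run_sag
#' @return List with `linked` and `subnetwork`.
#' @export
run_sar <- function(regions, network, tss = NULL, pchic = NULL, abc = NULL,
                    window = 50000, tier = "high", threshold = NULL,
                    target_n = 30, tol = NULL, max_iter = 50, B = 100,
                    bins = 10, seed = 1, out_dir = NULL) {
  linked <- link_regions(regions, tss, pchic, abc, window)
  net <- resolve_network(network, tier, threshold)
  scores <- setNames(linked$genes$display_score, linked$genes$gene)
  sub <- run_subnetwork_common(scores, scores, net, target_n, tol, max_iter,
                               B, bins, seed, out_dir)
  if (!is.null(out_dir)) write_linking_outputs(linked, out_dir)
  list(linked = linked, subnetwork = sub)
}
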