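# SNP- and region-to-gene linking: LD expansion of genome-wide significant
# SNPs, then evidence from genomic proximity, chromatin interaction maps
# (PCHi-C / ABC) and e/pQTLs, combined into 1-10 gene scores with
# per-evidence provenance.

#' Read a SNP summary table
#'
#' TSV rows `rsid<TAB>chrom<TAB>pos<TAB>pvalue` (1-based positions).
#' Duplicate rsids are collapsed keeping the smallest p-value.
#'
#' @param path TSV path.
#' @return Data.frame `rsid`, `chrom`, `pos`, `pvalue`.
#' @export
read_snps <- function(path) {
  df <- read_tsv_file(path, c("rsid", "chrom", "pos", "pvalue"))
  df$rsid <- as.character(df$rsid)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$pvalue <- as.numeric(df$pvalue)
  if (anyNA(df$pos) || any(df$pos < 1))
    stop("SNP positions must be integers >= 1", call. = FALSE)
  if (anyNA(df$pvalue) || any(df$pvalue <= 0 | df$pvalue > 1))
    stop("SNP p-values must lie in (0,1]", call. = FALSE)
  df <- df[order(df$pvalue, df$rsid), ]
  dup <- duplicated(df$rsid)
  if (any(dup)) xgr_log("snps: collapsed %d duplicate rsid(s), keeping min p",
                        sum(dup))
  df <- df[!dup, ]
  df <- df[order(df$rsid), ]
  rownames(df) <- NULL
  df
}

#' Read genomic regions from a BED file
#'
#' 3- or 4-column BED (`chrom start end [score]`), 0-based half-open.
#'
#' @param path BED path.
#' @return Data.frame `chrom`, `start`, `end`, `region_id` (`chrom:start-end`)
#'   and `score` (NA when absent).
#' @export
read_regions <- function(path) {
  raw <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE, quote = "")
  if (ncol(raw) < 3) stop("BED needs >= 3 columns", call. = FALSE)
  df <- data.frame(chrom = as.character(raw[[1]]),
                   start = as.integer(raw[[2]]),
                   end = as.integer(raw[[3]]),
                   stringsAsFactors = FALSE)
  df$score <- if (ncol(raw) >= 4) suppressWarnings(as.numeric(raw[[4]])) else NA_real_
  if (any(df$start >= df$end))
    stop("region with start >= end at line ",
         which(df$start >= df$end)[1], call. = FALSE)
  df$region_id <- sprintf("%s:%d-%d", df$chrom, df$start, df$end)
  df[, c("chrom", "start", "end", "region_id", "score")]
}

new_evidence <- function(entity_id = character(0),
                         seed_entity_id = character(0),
                         gene = character(0), dataset_kind = character(0),
                         raw_weight = numeric(0)) {
  data.frame(entity_id = entity_id, seed_entity_id = seed_entity_id,
             gene = gene, dataset_kind = dataset_kind,
             raw_weight = raw_weight, stringsAsFactors = FALSE)
}

#' Threshold input SNPs and expand them through LD proxies
#'
#' Keeps input SNPs with `pvalue < p_threshold` (genome-wide significance by
#' default) and, for each kept seed, adds panel proxies with `r2 >= r2_min`.
#' Proxies inherit the seed's p-value and record the seed in `seed_rsid`; a
#' SNP reachable from several seeds keeps the most significant one.  Proxy
#' coordinates come from the panel's coordinate columns.
#'
#' @param snps Data.frame from [read_snps()].
#' @param panel An [load_ld_panel()] panel, or `NULL` for no expansion.
#' @param p_threshold Significance threshold (default `5e-8`).
#' @param r2_min Minimum r-squared for proxies (default `0.8`).
#' @return Data.frame `rsid`, `chrom`, `pos`, `pvalue`, `seed_rsid`.
#' @export
filter_and_expand_snps <- function(snps, panel = NULL, p_threshold = 5e-8,
                                   r2_min = 0.8) {
  kept <- snps[snps$pvalue < p_threshold, , drop = FALSE]
  xgr_log("snps: %d/%d input SNPs pass p < %g", nrow(kept), nrow(snps),
          p_threshold)
  if (nrow(kept) == 0)
    stop("no SNP passes the p-value threshold of ", format(p_threshold),
         "; consider relaxing it with --p-threshold", call. = FALSE)
  kept$seed_rsid <- kept$rsid
  cand <- kept[, c("rsid", "chrom", "pos", "pvalue", "seed_rsid")]
  if (!is.null(panel) && nrow(panel) > 0) {
    px <- panel[panel$seed %in% kept$rsid & panel$r2 >= r2_min, , drop = FALSE]
    if (nrow(px) > 0) {
      i <- match(px$seed, kept$rsid)
      proxies <- data.frame(rsid = px$proxy, chrom = px$proxy_chrom,
                            pos = px$proxy_pos, pvalue = kept$pvalue[i],
                            seed_rsid = px$seed, stringsAsFactors = FALSE)
      cand <- rbind(cand, proxies)
      xgr_log("snps: added %d LD prox(y/ies) at r2 >= %g", nrow(px), r2_min)
    }
  }
  # per rsid keep the most significant seed; input rows (seed == self) win ties
  self <- cand$rsid == cand$seed_rsid
  cand <- cand[order(cand$rsid, cand$pvalue, !self, cand$seed_rsid), ]
  cand <- cand[!duplicated(cand$rsid), ]
  rownames(cand) <- NULL
  cand
}

#' Link entities to genes by genomic proximity to the TSS
#'
#' A SNP at position `p` links gene `g` when the distance `d = |p - tss_g|`
#' is strictly below the window `W` (same chromosome); the evidence weight
#' decays linearly, `1 - d/W`.  For a region the distance is from the
#' interval to the TSS (0 when the TSS lies inside).
#'
#' @param entities SNP data.frame (columns `rsid`, `chrom`, `pos`, optional
#'   `seed_rsid`) or region data.frame (columns `chrom`, `start`, `end`,
#'   `region_id`).
#' @param tss A [load_tss()] table.
#' @param window Distance window in bp (default 50000).
#' @return Evidence data.frame `entity_id`, `seed_entity_id`, `gene`,
#'   `dataset_kind = "proximity"`, `raw_weight`.
#' @export
link_by_proximity <- function(entities, tss, window = 50000) {
  is_snp <- "pos" %in% names(entities)
  out <- vector("list", nrow(tss))
  for (j in seq_len(nrow(tss))) {
    same <- entities$chrom == tss$chrom[j]
    if (!any(same)) next
    e <- entities[same, , drop = FALSE]
    if (is_snp) {
      d <- abs(e$pos - tss$tss[j])
      id <- e$rsid
      seed <- if ("seed_rsid" %in% names(e)) e$seed_rsid else e$rsid
    } else {
      # region [start,end) in 0-based vs 1-based TSS occupying [tss-1, tss)
      t0 <- tss$tss[j] - 1L
      d <- ifelse(t0 < e$start, e$start - t0,
                  ifelse(t0 >= e$end, t0 - (e$end - 1L), 0L))
      id <- e$region_id
      seed <- id
    }
    hit <- d < window
    if (!any(hit)) next
    out[[j]] <- new_evidence(id[hit], seed[hit],
                             rep(tss$gene[j], sum(hit)), "proximity",
                             1 - d[hit] / window)
  }
  ev <- do.call(rbind, c(out[!vapply(out, is.null, logical(1))],
                         list(new_evidence())))
  missing_chrom <- setdiff(unique(entities$chrom), unique(tss$chrom))
  if (length(missing_chrom) > 0)
    xgr_log("proximity: no TSS on chromosome(s) %s",
            paste(missing_chrom, collapse = ","))
  rownames(ev) <- NULL
  ev
}

#' Link entities to genes through interval evidence (PCHi-C / ABC)
#'
#' Produces evidence for every half-open overlap between an entity and a
#' dataset interval; a SNP at 1-based position `p` is the 1-bp interval
#' `[p-1, p)`.  Weights are the interval strengths normalized by the
#' dataset-wide maximum; multiple intervals linking the same entity-gene
#' pair keep the maximum weight.
#'
#' @param entities SNP or region data.frame (see [link_by_proximity()]).
#' @param dataset A [load_interval_evidence()] dataset.
#' @return Evidence data.frame as in [link_by_proximity()] with
#'   `dataset_kind` equal to the dataset's kind.
#' @export
link_by_interval_map <- function(entities, dataset) {
  kind <- attr(dataset, "kind")
  if (nrow(dataset) == 0 || max(dataset$strength) <= 0)
    stop("interval dataset has no positive strengths", call. = FALSE)
  wmax <- max(dataset$strength)
  is_snp <- "pos" %in% names(entities)
  if (is_snp) {
    e_start <- entities$pos - 1L
    e_end <- entities$pos
    id <- entities$rsid
    seed <- if ("seed_rsid" %in% names(entities)) entities$seed_rsid else id
  } else {
    e_start <- entities$start
    e_end <- entities$end
    id <- entities$region_id
    seed <- id
  }
  if (length(id) == 0) return(new_evidence())
  # half-open [start,end) -> 1-based closed [start+1, end] for IRanges
  q <- GenomicRanges::GRanges(entities$chrom,
                              IRanges::IRanges(e_start + 1L, e_end))
  s <- GenomicRanges::GRanges(dataset$chrom,
                              IRanges::IRanges(dataset$start + 1L, dataset$end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, s))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ev <- new_evidence(id[qi], seed[qi], dataset$gene[si],
                     rep(kind, length(qi)), dataset$strength[si] / wmax)
  # multiple overlapping intervals to the same (entity, gene): keep max
  if (nrow(ev) > 0) {
    ev <- ev[order(ev$entity_id, ev$gene, -ev$raw_weight), ]
    ev <- ev[!duplicated(ev[, c("entity_id", "gene")]), ]
    rownames(ev) <- NULL
  }
  ev
}

#' Link SNPs to genes through e/pQTL evidence
#'
#' Every input or proxy rsid present in the dataset contributes one evidence
#' row per mapped gene, weighted by the dataset's QTL weight.
#'
#' @param snps SNP data.frame (columns `rsid`, optional `seed_rsid`).
#' @param dataset A [load_qtl_evidence()] dataset.
#' @return Evidence data.frame with `dataset_kind` equal to the dataset's
#'   kind.
#' @export
link_by_qtl <- function(snps, dataset) {
  kind <- attr(dataset, "kind")
  i <- match(dataset$rsid, snps$rsid)
  hit <- !is.na(i)
  if (!any(hit)) return(new_evidence())
  seed <- if ("seed_rsid" %in% names(snps)) snps$seed_rsid else snps$rsid
  ev <- new_evidence(dataset$rsid[hit], seed[i[hit]], dataset$gene[hit],
                     rep(kind, sum(hit)), dataset$weight[hit])
  rownames(ev) <- NULL
  ev
}

#' Combine evidence rows into scored linked genes
#'
#' Each evidence row contributes `raw_weight * s`, where for SNP-derived
#' evidence `s = min(-log10(p_seed), 10) / 10` (the seed's association
#' significance, capped) and for region evidence `s = 1`.  Per-gene raw
#' scores are the sum (or, with `pool = "max"`, the per-dataset-kind maximum
#' then summed across kinds) of contributions, then rescaled linearly to the
#' display range `[1, 10]`; when all raw scores are equal every gene gets 10.
#'
#' @param evidence Evidence data.frame (rows from the `link_by_*` functions).
#' @param snp_pvalues Named numeric vector mapping seed rsids to p-values
#'   (required for SNP workflows; `NULL` for region workflows).
#' @param pool `"sum"` (default) or `"max"` pooling of same-kind evidence.
#' @return List with `genes` (data.frame `gene`, `raw_score`,
#'   `display_score`, `n_evidence`, sorted by decreasing display score) and
#'   `evidence` (input rows plus `contribution`, sorted by gene,
#'   dataset_kind, entity_id).
#' @export
combine_scores <- function(evidence, snp_pvalues = NULL,
                           pool = c("sum", "max")) {
  pool <- match.arg(pool)
  if (is.null(evidence) || nrow(evidence) == 0)
    return(list(genes = data.frame(gene = character(0), raw_score = numeric(0),
                                   display_score = numeric(0),
                                   n_evidence = integer(0),
                                   stringsAsFactors = FALSE),
                evidence = new_evidence()))
  s <- rep(1, nrow(evidence))
  if (!is.null(snp_pvalues)) {
    p <- snp_pvalues[evidence$seed_entity_id]
    snpd <- !is.na(p)
    s[snpd] <- pmin(-log10(p[snpd]), 10) / 10
  }
  evidence$contribution <- evidence$raw_weight * s
  if (pool == "max") {
    key <- paste(evidence$gene, evidence$dataset_kind, sep = "\r")
    best <- tapply(evidence$contribution, key, max)
    pooled <- evidence[!duplicated(key), , drop = FALSE]
    pooled$contribution <- unname(best[paste(pooled$gene, pooled$dataset_kind,
                                             sep = "\r")])
    raw <- tapply(pooled$contribution, pooled$gene, sum)
  } else {
    raw <- tapply(evidence$contribution, evidence$gene, sum)
  }
  genes <- sort(names(raw))
  raw <- as.numeric(raw[genes])
  rng <- max(raw) - min(raw)
  display <- if (rng > 0) 1 + 9 * (raw - min(raw)) / rng else rep(10, length(raw))
  nev <- as.integer(table(evidence$gene)[genes])
  out <- data.frame(gene = genes, raw_score = raw, display_score = display,
                    n_evidence = nev, stringsAsFactors = FALSE)
  out <- out[order(-out$display_score, out$gene), ]
  rownames(out) <- NULL
  evidence <- evidence[order(evidence$gene, evidence$dataset_kind,
                             evidence$entity_id), ]
  rownames(evidence) <- NULL
  list(genes = out, evidence = evidence)
}

#' Write linked-gene and evidence tables
#'
#' @param linked Result of [combine_scores()].
#' @param genes_path,evidence_path Output TSV paths.
#' @return `genes_path`, invisibly.
#' @export
write_linked_genes <- function(linked, genes_path, evidence_path) {
  write_tsv_file(linked$genes, genes_path)
  ev <- linked$evidence[, c("entity_id", "seed_entity_id", "gene",
                            "dataset_kind", "raw_weight")]
  write_tsv_file(ev, evidence_path)
  invisible(genes_path)
}
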